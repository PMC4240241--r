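test_that("score generation is a pure function of spec and seed", {
  spec <- agreement_spec(n_sites = 60, seed = 42)
  g1 <- generate_score_table(spec)
  g2 <- generate_score_table(spec)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$gold, g2$gold)
  g3 <- generate_score_table(agreement_spec(n_sites = 60, seed = 43))
  expect_false(identical(g1$table, g3$table))
  # the caller's RNG stream is not disturbed
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_score_table(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("identity confusion rows reproduce the gold column everywhere", {
  cls <- reaction_classes()
  ident <- lapply(techniques(), function(tech) {
    vocab <- technique_vocabulary(tech)
    m <- matrix(0, 3, length(vocab), dimnames = list(cls, vocab))
    for (v in vocab) m[v, v] <- 1
    m["SCLEROTIC", 1] <- if ("SCLEROTIC" %in% vocab) m["SCLEROTIC", 1] else 1
    m
  })
  names(ident) <- techniques()
  spec <- agreement_spec(gold_marginals = c(NORMAL = 0.5, CARIOUS = 0.5, SCLEROTIC = 0),
                         confusion = ident, n_sites = 80, seed = 9)
  gen <- generate_score_table(spec)
  for (tech in techniques()) {
    expect_identical(to_canonical(tech, gen$table[[tech]]), gen$gold)
  }
  s <- summarize_combinations(gen$table)
  expect_true(all(s$accuracy == 1))
})

test_that("generated marginals track the specified gold marginals", {
  gen <- generate_score_table(agreement_spec(seed = 77))  # study defaults
  expect_equal(n_sites(gen$table), 168)
  # FBC column is the latent gold under the default identity row
  expect_identical(to_canonical("FBC", gen$table$FBC), gen$gold)
  counts <- count_reactions(gen$table, "FBC")
  expected <- c(NORMAL = 59, CARIOUS = 89, SCLEROTIC = 20)
  for (cl in names(expected)) {
    p <- expected[[cl]] / 168
    half <- 1.96 * sqrt(p * (1 - p) / 168)
    expect_true(abs(counts[[cl]] / 168 - p) < half + 1e-12,
                label = sprintf("FBC %s count within binomial CI", cl))
  }
  expect_error(agreement_spec(gold_marginals = c(NORMAL = 0.5, CARIOUS = 0.6,
                                                 SCLEROTIC = 0.1)), "sum to 1")
  bad_conf <- default_confusion()
  bad_conf$SW[1, ] <- c(0.5, 0.2, 0.2)
  expect_error(agreement_spec(confusion = bad_conf), "summing to 1")
})

test_that("micrograph generation recovers assigned indices in the noise-free limit", {
  b <- generate_micrograph(image_scenario(n_sites = 5, noise_sd = 0,
                                          vignette_model = "flat", seed = 8))
  rp <- measure_sites(b$mr, b$rois, "radiopacity")
  tr <- measure_sites(b$sm, b$rois, "translucency")
  expect_equal(rp$value, b$truth$radiopacity_true, tolerance = 1e-12)
  expect_equal(tr$value, b$truth$translucency_true, tolerance = 1e-12)
  expect_true(check_saturation(b$mr)$pass)
  expect_true(check_saturation(b$sm)$pass)

  # a single assigned index round-trips exactly
  one <- generate_micrograph(image_scenario(n_sites = 1, noise_sd = 0,
                                            vignette_model = "flat",
                                            index_range = c(0.75, 0.7500001),
                                            seed = 1))
  expect_equal(measure_sites(one$mr, one$rois, "radiopacity")$value, 0.75,
               tolerance = 1e-6)
})

test_that("micrograph scenarios validate and refuse impossible layouts", {
  expect_error(image_scenario(vignette_height = 1.2), "\\[0, 1\\)")
  expect_error(image_scenario(rho = 1.5), "\\[-1, 1\\]")
  expect_error(generate_micrograph(image_scenario(width = 40, height = 40,
                                                  n_sites = 50, seed = 1)),
               "cannot place")
})

test_that("correlated ground truth follows the copula correlation", {
  r_at <- function(rho, seed) {
    b <- generate_micrograph(image_scenario(n_sites = 80, width = 400, height = 200,
                                            pixel_size = 18.75, rho = rho,
                                            noise_sd = 0, vignette_model = "flat",
                                            seed = seed))
    cor(b$truth$translucency_true, b$truth$radiopacity_true)
  }
  expect_gt(r_at(0.9, 31), 0.7)
  expect_lt(abs(r_at(0, 32)), 0.3)
  expect_lt(r_at(-0.9, 33), -0.7)
})

test_that("fixture bundles are reproducible byte for byte", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- study_fixtures(123, d1)
  f2 <- study_fixtures(123, d2)
  expect_length(f1$paths, 1 + 5 * 3 + 1)
  for (i in seq_along(f1$paths)) {
    expect_identical(readBin(f1$paths[i], "raw", file.size(f1$paths[i])),
                     readBin(f2$paths[i], "raw", file.size(f2$paths[i])),
                     label = basename(f1$paths[i]))
  }
  tbl <- read_score_table(file.path(d1, "score_table.csv"))
  expect_equal(n_sites(tbl), 168)
  rois <- unlist(lapply(sprintf("%s/rois_%02d.csv", d1, 1:5), read_roi_table),
                 recursive = FALSE)
  expect_length(rois, 80)  # 16 sites per patch, 5 patches
})
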