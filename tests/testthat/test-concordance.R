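test_that("one-vs-rest confusion counts match the brute-force enumeration", {
  combo <- combination("SW", "FBC")
  # hand-enumerated toy: SW classes N,C,S,S,N,C vs FBC N,C,C,S,N,C
  cc <- binarize(toy_table(), combo, "NORMAL")
  expect_equal(as_confusion_vector(cc), c(TP = 2L, FP = 0L, TN = 4L, FN = 0L))
  cc_scl <- binarize(toy_table(), combo, "SCLEROTIC")
  expect_equal(as_confusion_vector(cc_scl), c(TP = 1L, FP = 1L, TN = 4L, FN = 0L))

  # randomized cross-check against the per-site oracle, both policies
  for (seed in 1:25) {
    tbl <- random_score_table(sample(5:50, 1), seed = seed)
    test_tech <- sample(techniques(), 1)
    combo <- combination(test_tech,
                         sample(setdiff(techniques()[1:5], test_tech), 1))
    for (policy in c("exclude_unscorable", "include_as_negative")) {
      for (rx in technique_vocabulary(combo$test)) {
        expect_equal(as_confusion_vector(binarize(tbl, combo, rx, policy)),
                     brute_force_binarize(tbl, combo, rx, policy))
      }
    }
  }
})

test_that("perfect agreement yields FP = FN = 0 and all metrics 1", {
  tbl <- score_table(data.frame(section = "S1", site = 1:6,
                                SW = c(1, 2, 3, 1, 2, 3),
                                SD = c(1, 2, 3, 1, 2, 3)))
  for (rx in reaction_classes()) {
    cc <- binarize(tbl, combination("SW", "SD"), rx)
    expect_equal(cc$FP, 0L)
    expect_equal(cc$FN, 0L)
    expect_equal(accuracy(cc), 1)
  }
})

test_that("confusion counts obey the conservation invariants", {
  for (seed in 1:10) {
    tbl <- random_score_table(40, seed = 100 + seed, missing_rate = 0)
    combo <- combination("SD", "NFBC")
    test_cls <- to_canonical("SD", tbl$SD)
    gold_cls <- to_canonical("NFBC", tbl$NFBC)
    ccs <- lapply(reaction_classes(), function(rx) binarize(tbl, combo, rx))
    expect_equal(sum(vapply(ccs, function(c) c$TP, integer(1))),
                 sum(test_cls == gold_cls))
    expect_equal(sum(vapply(ccs, function(c) c$FP, integer(1))),
                 sum(vapply(ccs, function(c) c$FN, integer(1))))
    # accuracy is symmetric in test and gold
    for (rx in reaction_classes()) {
      expect_equal(accuracy(binarize(tbl, combo, rx)),
                   accuracy(binarize(tbl, combination("NFBC", "SD"), rx)))
    }
  }
})

test_that("accuracy, PPV and NPV follow their defining ratios", {
  expect_equal(accuracy(confusion_counts(1, 0, 1, 0)), 1)
  expect_equal(accuracy(confusion_counts(0, 3, 0, 2)), 0)
  expect_equal(accuracy(confusion_counts(42, 17, 92, 17)), 134 / 168)
  expect_equal(round(accuracy(confusion_counts(42, 17, 92, 17)), 4), 0.7976)
  expect_equal(ppv(confusion_counts(5, 0, 1, 1)), 1)
  expect_equal(ppv(confusion_counts(42, 17, 0, 0)), 42 / 59)
  expect_equal(npv(confusion_counts(0, 0, 74, 63)), 74 / 137)
  # zero denominators are undefined, not coerced
  expect_true(is.na(ppv(confusion_counts(0, 0, 3, 2))))
  expect_true(is.na(npv(confusion_counts(3, 2, 0, 0))))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("confusion reconstruction from marginals and PPV/NPV is exact", {
  cc <- reconstruct_confusion(168, 59, ppv = 0.71, npv = 0.84)
  expect_equal(as_confusion_vector(cc), c(TP = 42L, FP = 17L, TN = 92L, FN = 17L))
  expect_equal(cc$n_effective, 168L)
  # identity: reconstructing from a table's own marginals and metrics
  tbl <- random_score_table(50, seed = 7, missing_rate = 0)
  orig <- binarize(tbl, combination("SW", "FBC"), "CARIOUS")
  back <- reconstruct_confusion(orig$n_effective, orig$TP + orig$FP,
                                ppv(orig), npv(orig))
  expect_equal(as_confusion_vector(back), as_confusion_vector(orig))
})

test_that("combination summaries cover each test technique's vocabulary", {
  tbl <- toy_table()
  s_sw <- summarize_combinations(tbl, combination("SW", "FBC"))
  expect_equal(nrow(s_sw), 3)
  s_plmq <- summarize_combinations(tbl, combination("PLMQ", "FBC"))
  expect_equal(nrow(s_plmq), 2)  # no SCLEROTIC row for PLMQ
  expect_false("SCLEROTIC" %in% s_plmq$reaction)

  full <- summarize_combinations(random_score_table(80, seed = 2))
  expect_equal(nrow(full), 6 * 3 + 3 * 2)
  expect_true(all(full$accuracy >= 0 & full$accuracy <= 1))
  expect_true(all(is.na(full$ppv) | (full$ppv >= 0 & full$ppv <= 1)))
})

test_that("gold-class policy controls sites the test technique cannot score", {
  # gold FBC says SCLEROTIC at site 4; PLMQ cannot express it
  tbl <- toy_table()
  tbl$PLMQ[4] <- 1L
  combo <- combination("PLMQ", "FBC")
  excl <- binarize(tbl, combo, "NORMAL", "exclude_unscorable")
  incl <- binarize(tbl, combo, "NORMAL", "include_as_negative")
  expect_equal(excl$n_effective, 5L)
  expect_equal(incl$n_effective, 6L)
  expect_equal(incl$FP, excl$FP + 1L)  # the gold-sclerotic site, called NORMAL
})

test_that("Cohen's kappa matches hand computation and an independent oracle", {
  expect_equal(cohen_kappa(c("A", "B", "C", "A"), c("A", "B", "C", "A")), 1)
  # observed agreement equal to chance agreement
  expect_equal(cohen_kappa(c("A", "A", "B", "B"), c("A", "B", "A", "B")), 0)
  # 2x2 cross-table (20,5;10,15): p_o = 0.7, p_e = 0.5
  a <- rep(c("P", "P", "N", "N"), c(20, 5, 10, 15))
  b <- rep(c("P", "N", "P", "N"), c(20, 5, 10, 15))
  expect_equal(cohen_kappa(a, b), 0.4)
  expect_error(cohen_kappa(c("A", "B"), c("A")), "equal length")

  skip_if_not_installed("e1071")
  for (seed in 1:10) {
    set.seed(seed)
    x <- sample(c("N", "C", "S"), 60, replace = TRUE)
    y <- ifelse(runif(60) < 0.6, x, sample(c("N", "C", "S"), 60, replace = TRUE))
    expect_equal(cohen_kappa(x, y),
                 e1071::classAgreement(table(x, y))$kappa)
  }
})
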