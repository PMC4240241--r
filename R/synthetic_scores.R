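#' Specify a synthetic score-table generator
#'
#' The generator draws, for each site, a latent gold-standard class from
#' `gold_marginals` (an FBC-like reference: filtered contrast-adjusted
#' microradiography), then each technique's observed class independently
#' from that technique's confusion row given the gold class, and finally
#' masks cells at the technique's missing rate. Defaults are the study
#' conditions: 168 sites, gold marginals equal to the FBC detection counts
#' (59/89/20 of 168), an identity confusion row for FBC (its column *is*
#' the latent gold), and confusion rows for the other techniques emulating
#' the observed biases (stereomicroscopy over-calls translucency; PLMQ
#' calls most demineralised and many sclerotic sites carious).
#'
#' @param gold_marginals probabilities over the three canonical classes
#'   (named, summing to 1).
#' @param confusion named list (one element per technique) of row-stochastic
#'   matrices: rows = gold class (NORMAL/CARIOUS/SCLEROTIC), columns = the
#'   technique's vocabulary. PLMQ matrices have no SCLEROTIC column (zero
#'   mass on it, structurally).
#' @param missing_rate per-technique missing-cell probability (scalar or
#'   named vector).
#' @param n_sites number of sites.
#' @param seed integer RNG seed; the generator is a pure function of spec
#'   and seed.
#' @return object of class `"agreement_spec"`.
#' @export
agreement_spec <- function(gold_marginals = c(NORMAL = 59, CARIOUS = 89, SCLEROTIC = 20) / 168,
                           confusion = default_confusion(),
                           missing_rate = 0, n_sites = 168, seed = 1) {
  cls <- reaction_classes()
  if (!setequal(names(gold_marginals), cls)) {
    stop("gold_marginals must be named over NORMAL/CARIOUS/SCLEROTIC", call. = FALSE)
  }
  gold_marginals <- gold_marginals[cls]
  if (any(gold_marginals < 0) || abs(sum(gold_marginals) - 1) > 1e-8) {
    stop("gold_marginals must be non-negative and sum to 1", call. = FALSE)
  }
  if (!all(techniques() %in% names(confusion))) {
    stop("confusion must have one matrix per technique", call. = FALSE)
  }
  for (tech in techniques()) {
    m <- confusion[[tech]]
    vocab <- technique_vocabulary(tech)
    if (!is.matrix(m) || !identical(rownames(m), cls) || !identical(colnames(m), vocab)) {
      stop(sprintf("confusion$%s must be a matrix with rows %s and columns %s",
                   tech, paste(cls, collapse = "/"), paste(vocab, collapse = "/")),
           call. = FALSE)
    }
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
      stop(sprintf("confusion$%s rows must be probabilities summing to 1", tech),
           call. = FALSE)
    }
  }
  if (length(missing_rate) == 1L && is.null(names(missing_rate))) {
    missing_rate <- stats::setNames(rep(missing_rate, 6), techniques())
  }
  if (!all(techniques() %in% names(missing_rate)) ||
      any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate must be in [0, 1) for every technique", call. = FALSE)
  }
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  structure(list(gold_marginals = gold_marginals, confusion = confusion,
                 missing_rate = missing_rate[techniques()],
                 n_sites = as.integer(n_sites), seed = as.integer(seed)),
            class = "agreement_spec")
}

#' @rdname agreement_spec
#' @export
default_confusion <- function() {
  cls <- reaction_classes()
  mk <- function(rows, vocab) {
    m <- do.call(rbind, rows)
    dimnames(m) <- list(cls, vocab)
    m
  }
  diag3 <- function(d) mk(list(c(d, (1 - d) / 2, (1 - d) / 2),
                               c((1 - d) / 2, d, (1 - d) / 2),
                               c((1 - d) / 2, (1 - d) / 2, d)), cls)
  sm <- mk(list(c(0.70, 0.05, 0.25),   # normal often read as translucent
                c(0.10, 0.50, 0.40),   # demineralised frequently read as translucent
                c(0.20, 0.15, 0.65)), cls)
  plmq <- mk(list(c(0.35, 0.65),       # positive birefringence under-detected
                  c(0.05, 0.95),
                  c(0.30, 0.70)),      # sclerotic mostly read as negative
             cls[1:2])
  list(SW = sm, SD = sm, NFNBC = diag3(0.8), NFBC = diag3(0.85),
       FBC = mk(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), cls), PLMQ = plmq)
}

#' Generate a synthetic per-site score table
#'
#' @param spec an [agreement_spec()].
#' @return list of class `"synthetic_scores"`: `table` (a [score_table()],
#'   sites grouped six per section) and `gold` (the latent gold-standard
#'   canonical class per site).
#' @examples
#' gen <- generate_score_table(agreement_spec(n_sites = 12, seed = 7))
#' count_reactions(gen$table, "FBC")
#' @export
generate_score_table <- function(spec) {
  stopifnot(inherits(spec, "agreement_spec"))
  cls <- reaction_classes()
  with_local_seed(spec$seed, {
    n <- spec$n_sites
    gold <- sample(cls, n, replace = TRUE, prob = spec$gold_marginals)
    df <- data.frame(section = sprintf("S%03d", ceiling(seq_len(n) / 6)),
                     site = as.character((seq_len(n) - 1) %% 6 + 1),
                     icdas = NA_integer_, stringsAsFactors = FALSE)
    for (tech in techniques()) {
      m <- spec$confusion[[tech]]
      vocab <- technique_vocabulary(tech)
      code <- integer(n)
      for (g in cls) {
        idx <- which(gold == g)
        if (length(idx)) {
          code[idx] <- sample.int(length(vocab), length(idx), replace = TRUE,
                                  prob = m[g, ])
        }
      }
      rate <- spec$missing_rate[[tech]]
      if (rate > 0) code[stats::runif(n) < rate] <- NA_integer_
      df[[tech]] <- code
    }
    structure(list(table = score_table(df), gold = gold),
              class = "synthetic_scores")
  })
}

#' @export
print.synthetic_scores <- function(x, ...) {
  cat("Synthetic score table with latent gold classes\n")
  print(x$table)
  cat("Gold marginals (realized):\n")
  print(table(factor(x$gold, levels = reaction_classes())))
  invisible(x)
}
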