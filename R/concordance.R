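#' Define a test-vs-gold technique combination
#'
#' A combination pairs a test technique with a reference ("gold") technique,
#' e.g. wet stereomicroscopy validated against filtered contrast-adjusted
#' microradiography.
#'
#' @param test,gold technique names from [techniques()]; must differ.
#' @return an object of class `"combination_spec"` with fields `test`,
#'   `gold` and a display `label` such as `"SW x FBC"`.
#' @export
combination <- function(test, gold) {
  test <- match.arg(test, techniques())
  gold <- match.arg(gold, techniques())
  if (identical(test, gold)) stop("test and gold technique must differ", call. = FALSE)
  structure(list(test = test, gold = gold, label = paste(test, "x", gold)),
            class = "combination_spec")
}

#' @export
print.combination_spec <- function(x, ...) {
  cat(sprintf("Combination: %s (test) vs %s (gold)\n", x$test, x$gold))
  invisible(x)
}

#' The nine standard test-vs-gold combinations
#'
#' SW and SD each validated against the three microradiographic image
#' conditions (combinations 1-6), and PLMQ against the same three (7-9).
#'
#' @return list of [combination()] objects.
#' @export
default_combinations <- function() {
  tests <- rep(c("SW", "SD", "PLMQ"), each = 3)
  golds <- rep(c("NFNBC", "NFBC", "FBC"), times = 3)
  unname(Map(combination, tests, golds))
}

#' Confusion counts for one combination and reaction
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return object of class `"confusion_counts"` with an `n_effective` field
#'   equal to `TP + FP + TN + FN`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stop("TP, FP, TN, FN must be non-negative integers", call. = FALSE)
  }
  structure(list(TP = as.integer(TP), FP = as.integer(FP), TN = as.integer(TN),
                 FN = as.integer(FN), n_effective = as.integer(sum(v))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (n = %d): TP=%d FP=%d TN=%d FN=%d\n",
              x$n_effective, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' One-vs-rest confusion counts between two techniques
#'
#' Reduces the multi-class scores to a 2x2 table for one reaction: a site is
#' positive when its canonical class equals `reaction`, negative otherwise.
#' Only sites scored by both techniques are counted (pairwise-complete).
#'
#' When the test technique cannot express a class the gold technique reports
#' (PLMQ never scores `SCLEROTIC`), `gold_class_policy` decides the fate of
#' sites whose gold class is outside the test vocabulary:
#' `"exclude_unscorable"` (default) drops them, `"include_as_negative"`
#' counts them as gold-negative for the reaction under study.
#'
#' @param table a [score_table()].
#' @param combo a [combination()].
#' @param reaction a canonical class in the test technique's vocabulary.
#' @param gold_class_policy see Details.
#' @return a [confusion_counts()] object.
#' @export
binarize <- function(table, combo, reaction,
                     gold_class_policy = c("exclude_unscorable", "include_as_negative")) {
  stopifnot(inherits(table, "score_table"), inherits(combo, "combination_spec"))
  gold_class_policy <- match.arg(gold_class_policy)
  reaction <- match.arg(reaction, technique_vocabulary(combo$test))

  test_cls <- to_canonical(combo$test, table[[combo$test]])
  gold_cls <- to_canonical(combo$gold, table[[combo$gold]])
  keep <- !is.na(test_cls) & !is.na(gold_cls)
  if (gold_class_policy == "exclude_unscorable") {
    keep <- keep & (is.na(gold_cls) | gold_cls %in% technique_vocabulary(combo$test))
  }
  if (!any(keep)) {
    stop(sprintf("no overlapping scored sites for %s", combo$label), call. = FALSE)
  }
  t_pos <- test_cls[keep] == reaction
  g_pos <- gold_cls[keep] == reaction
  confusion_counts(TP = sum(t_pos & g_pos), FP = sum(t_pos & !g_pos),
                   TN = sum(!t_pos & !g_pos), FN = sum(!t_pos & g_pos))
}

#' Accuracy, positive and negative predictive value
#'
#' `accuracy()` is the proportion of concordant sites,
#' `(TP + TN) / (TP + TN + FP + FN)`. `ppv()` is `TP / (TP + FP)` and
#' `npv()` is `TN / (TN + FN)`; both are reported as `NA` (undefined) when
#' their denominator is zero, never coerced to 0 or 1.
#'
#' @param counts a [confusion_counts()] object.
#' @return a proportion in `[0, 1]`, or `NA` where undefined.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$n_effective == 0L) stop("no sites: accuracy undefined", call. = FALSE)
  (counts$TP + counts$TN) / counts$n_effective
}

#' @rdname accuracy
#' @export
ppv <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$TP + counts$FP
  if (den == 0L) NA_real_ else counts$TP / den
}

#' @rdname accuracy
#' @export
npv <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$TN + counts$FN
  if (den == 0L) NA_real_ else counts$TN / den
}

#' Reconstruct confusion counts from marginals and predictive values
#'
#' Rebuilds a 2x2 table from a test technique's positive-call count, the
#' total number of sites and printed PPV/NPV values:
#' `TP = round(positives * PPV)`, `TN = round(negatives * NPV)` with
#' half-up rounding.
#'
#' @param n_total total number of sites.
#' @param n_positive sites the test technique called positive.
#' @param ppv,npv predictive values in `[0, 1]`.
#' @return a [confusion_counts()] object.
#' @export
reconstruct_confusion <- function(n_total, n_positive, ppv, npv) {
  stopifnot(n_total >= n_positive, n_positive >= 0,
            ppv >= 0, ppv <= 1, npv >= 0, npv <= 1)
  n_negative <- n_total - n_positive
  TP <- round_half_up(n_positive * ppv)
  TN <- round_half_up(n_negative * npv)
  confusion_counts(TP = TP, FP = n_positive - TP, TN = TN, FN = n_negative - TN)
}

#' Diagnostic summaries for a set of combinations
#'
#' Runs [binarize()] for every (combination, reaction) pair, with reactions
#' restricted to the test technique's vocabulary, and collects accuracy, PPV
#' and NPV.
#'
#' @param table a [score_table()].
#' @param combos list of [combination()] objects (default: the nine standard
#'   ones).
#' @inheritParams binarize
#' @return data frame of class `"diagnostic_summary"` with one row per
#'   (combination, reaction): columns `combination`, `test`, `gold`,
#'   `reaction`, `TP`, `FP`, `TN`, `FN`, `n_effective`, `accuracy`, `ppv`,
#'   `npv` (full precision; the print method rounds accuracy to 4 and
#'   PPV/NPV to 2 decimals).
#' @export
summarize_combinations <- function(table, combos = default_combinations(),
                                   gold_class_policy = c("exclude_unscorable",
                                                         "include_as_negative")) {
  gold_class_policy <- match.arg(gold_class_policy)
  if (inherits(combos, "combination_spec")) combos <- list(combos)
  rows <- lapply(combos, function(cb) {
    do.call(rbind, lapply(technique_vocabulary(cb$test), function(rx) {
      cc <- binarize(table, cb, rx, gold_class_policy)
      data.frame(combination = cb$label, test = cb$test, gold = cb$gold,
                 reaction = rx, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
                 n_effective = cc$n_effective, accuracy = accuracy(cc),
                 ppv = ppv(cc), npv = npv(cc), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diagnostic_summary", "data.frame")
  out
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$accuracy <- sprintf("%.4f", y$accuracy)
  y$ppv <- ifelse(is.na(y$ppv), "--", sprintf("%.2f", y$ppv))
  y$npv <- ifelse(is.na(y$npv), "--", sprintf("%.2f", y$npv))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Cohen's kappa for two categorical score sequences
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the product of the two raters' marginal proportions.
#' When both sequences are constant on the same category (`p_e = 1`,
#' `p_o = 1`) kappa is defined as 1.
#'
#' @param scores_a,scores_b equal-length vectors (length >= 2) of category
#'   labels; pairs with a missing value are dropped.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score sequences must have equal length", call. = FALSE)
  }
  keep <- !is.na(scores_a) & !is.na(scores_b)
  a <- as.character(scores_a[keep])
  b <- as.character(scores_b[keep])
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete score pairs", call. = FALSE)
  lev <- sort(unique(c(a, b)))
  a <- factor(a, levels = lev)
  b <- factor(b, levels = lev)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (isTRUE(all.equal(p_e, 1))) {
    if (isTRUE(all.equal(p_o, 1))) return(1)
    stop("degenerate marginals: chance agreement is 1 but observed is not",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}
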