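#' Arcsine transform of a proportion
#'
#' The variance-stabilizing transform `phi = 2 * arcsin(sqrt(P))`, in
#' radians: strictly increasing on `[0, 1]` with `phi(0) = 0` and
#' `phi(1) = pi`.
#'
#' @param P proportion(s) in `[0, 1]`.
#' @return radians in `[0, pi]`.
#' @export
phi <- function(P) {
  if (any(is.na(P)) || any(P < 0 | P > 1)) {
    stop("P must be in [0, 1]", call. = FALSE)
  }
  2 * asin(sqrt(P))
}

effect_size_label <- function(magnitude) {
  cut(magnitude, breaks = c(-Inf, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("negligible", "small", "moderate", "large")) |> as.character()
}

#' Cohen's effect size for two proportions
#'
#' `h = phi(p_test) - phi(p_gold)`, the difference of the arcsine
#' square-root transforms of the two proportions. Antisymmetric in its
#' arguments. Magnitudes are labelled by the conventional bands
#' (negligible < 0.2 <= small < 0.5 <= moderate < 0.8 <= large).
#'
#' @param p_test,p_gold proportions in `[0, 1]`.
#' @return object of class `"effect_size"`: fields `h`, `magnitude`,
#'   `phi_x` (= phi(p_test)), `phi_y` (= phi(p_gold)) and `label`.
#' @examples
#' cohen_h(0.26, 0.33)$magnitude  # ~0.154
#' @export
cohen_h <- function(p_test, p_gold) {
  phi_x <- phi(p_test)
  phi_y <- phi(p_gold)
  h <- phi_x - phi_y
  structure(list(h = h, magnitude = abs(h), phi_x = phi_x, phi_y = phi_y,
                 label = effect_size_label(abs(h))),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's h = %+.4f (magnitude %.4f, %s)\n",
              x$h, x$magnitude, x$label))
  invisible(x)
}

#' Effect sizes of every combination against a gold combination
#'
#' For each non-gold combination in `summaries`, computes Cohen's h between
#' its PPV (and NPV) and the gold combination's, per reaction. Reactions the
#' gold combination does not report, or metrics undefined for either side
#' (zero denominator), yield a missing entry rather than a number.
#'
#' @param summaries a `"diagnostic_summary"` from [summarize_combinations()].
#' @param gold_combo a [combination()] present in `summaries`.
#' @return data frame of class `"effect_size_table"`: `combination`,
#'   `reaction`, `metric` (`"ppv"`/`"npv"`), `p_test`, `p_gold`, `h`,
#'   `magnitude`, `label`.
#' @export
compare_combinations <- function(summaries, gold_combo) {
  stopifnot(inherits(summaries, "diagnostic_summary"),
            inherits(gold_combo, "combination_spec"))
  gold_rows <- summaries[summaries$combination == gold_combo$label, , drop = FALSE]
  if (nrow(gold_rows) == 0L) {
    stop(sprintf("gold combination %s not present in summaries", gold_combo$label),
         call. = FALSE)
  }
  test_rows <- summaries[summaries$combination != gold_combo$label, , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(test_rows)), function(i) {
    row <- test_rows[i, ]
    grow <- gold_rows[gold_rows$reaction == row$reaction, , drop = FALSE]
    do.call(rbind, lapply(c("ppv", "npv"), function(metric) {
      p_t <- row[[metric]]
      p_g <- if (nrow(grow) == 1L) grow[[metric]] else NA_real_
      if (is.na(p_t) || is.na(p_g)) {
        data.frame(combination = row$combination, reaction = row$reaction,
                   metric = metric, p_test = p_t, p_gold = p_g,
                   h = NA_real_, magnitude = NA_real_, label = NA_character_,
                   stringsAsFactors = FALSE)
      } else {
        es <- cohen_h(p_t, p_g)
        data.frame(combination = row$combination, reaction = row$reaction,
                   metric = metric, p_test = p_t, p_gold = p_g,
                   h = es$h, magnitude = es$magnitude, label = es$label,
                   stringsAsFactors = FALSE)
      }
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("effect_size_table", "data.frame")
  out
}

#' @export
print.effect_size_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("p_test", "p_gold")) y[[col]] <- sprintf("%.2f", y[[col]])
  for (col in c("h", "magnitude")) {
    y[[col]] <- ifelse(is.na(x[[col]]), "--", sprintf("%+.3f", x[[col]]))
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Temporary-gold-standard comparison of detection counts
#'
#' For one dentin reaction, the technique detecting the largest number of
#' sites is taken as the temporary gold standard; every technique's count is
#' converted to a proportion of that maximum and compared to the gold's own
#' proportion (exactly 1) by Cohen's h. Ties are broken by the first
#' technique in `tie_break` order, with a warning.
#'
#' @param counts per-technique counts for the reaction: a named numeric
#'   vector, or the matrix from [count_reactions_all()] together with
#'   `reaction`. `NA` counts (class outside a technique's vocabulary) are
#'   dropped.
#' @param reaction canonical class name; required when `counts` is a matrix.
#' @param tie_break character vector giving the tie-break preference order.
#' @return object of class `"temporary_gold"`: fields `reaction`,
#'   `gold_technique`, `gold_count` and a data frame `comparisons` with
#'   `technique`, `count`, `proportion`, `h`, `magnitude`, `label`.
#' @export
temporary_gold <- function(counts, reaction = NULL, tie_break = techniques()) {
  if (is.matrix(counts)) {
    if (is.null(reaction)) stop("reaction is required with a count matrix", call. = FALSE)
    reaction <- match.arg(reaction, reaction_classes())
    counts <- counts[, reaction]
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by technique", call. = FALSE)
  }
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0L || all(counts == 0)) {
    stop("no technique detected any site of this reaction", call. = FALSE)
  }
  ord <- order(match(names(counts), tie_break))
  counts <- counts[ord]
  top <- counts == max(counts)
  if (sum(top) > 1L) {
    warning(sprintf("tie for temporary gold standard (%s); taking %s by tie-break order",
                    paste(names(counts)[top], collapse = ", "),
                    names(counts)[which(top)[1]]), call. = FALSE)
  }
  gold_technique <- names(counts)[which(top)[1]]
  gold_count <- as.integer(counts[[gold_technique]])
  prop <- as.numeric(counts) / gold_count
  h <- phi(prop) - phi(1)
  comparisons <- data.frame(technique = names(counts), count = as.integer(counts),
                            proportion = prop, h = h, magnitude = abs(h),
                            label = effect_size_label(abs(h)),
                            stringsAsFactors = FALSE)
  rownames(comparisons) <- NULL
  structure(list(reaction = reaction, gold_technique = gold_technique,
                 gold_count = gold_count, comparisons = comparisons),
            class = "temporary_gold")
}

#' @export
print.temporary_gold <- function(x, ...) {
  cat(sprintf("Temporary gold standard%s: %s (%d sites)\n",
              if (is.null(x$reaction)) "" else sprintf(" for %s dentin", x$reaction),
              x$gold_technique, x$gold_count))
  y <- x$comparisons
  y$proportion <- sprintf("%.3f", y$proportion)
  y$h <- sprintf("%+.3f", y$h)
  y$magnitude <- sprintf("%.3f", y$magnitude)
  print(y, row.names = FALSE)
  invisible(x)
}
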