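#' Published reference values of the six-technique validation study
#'
#' The printed results of the dentin-reaction validation study the package
#' implements, shipped as plain-text CSVs: per-technique detection counts
#' over 168 sites (`"counts"`), PPV/NPV of the nine test-vs-gold
#' combinations (`"ppv_npv"`), the effect sizes of the five stereomicroscopy
#' combinations against the gold combination SD x FBC (`"effect_sizes"`),
#' and the reported one-vs-rest accuracies against the FBC gold standard
#' (`"accuracies"`). These are inputs for worked examples and for the
#' acceptance analysis that recomputes the study's derived quantities; they
#' are published numbers, not outputs of this package.
#'
#' @param which which reference table to load.
#' @return a data frame. For `"counts"` the technique column becomes the
#'   row names of an integer matrix (with `NA` for the class PLMQ cannot
#'   report), matching [count_reactions_all()] output.
#' @examples
#' reference_table("counts")["NFNBC", "NORMAL"]  # 77
#' @export
reference_table <- function(which = c("counts", "ppv_npv", "effect_sizes",
                                      "accuracies")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "dentinval", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (which == "counts") {
    m <- as.matrix(df[reaction_classes()])
    rownames(m) <- df$technique
    storage.mode(m) <- "integer"
    return(m)
  }
  df
}
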