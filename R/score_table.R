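#' Imaging techniques and reaction classes
#'
#' The six scoring techniques: stereomicroscopy of wet (`SW`) and dry (`SD`)
#' ground sections, microradiography without light-shaping filter and without
#' (`NFNBC`) or with (`NFBC`) brightness/contrast adjustment, filtered
#' contrast-adjusted microradiography (`FBC`), and polarized light microscopy
#' in quinoline (`PLMQ`). Canonical dentin-reaction classes are `NORMAL`,
#' `CARIOUS` and `SCLEROTIC`; PLMQ distinguishes only positive (normal) and
#' negative (carious) birefringence and never yields `SCLEROTIC`.
#'
#' @format `techniques()` returns a character vector of the six technique
#'   names in the conventional order; `reaction_classes()` the three canonical
#'   class names.
#' @export
techniques <- function() c("SW", "SD", "NFNBC", "NFBC", "FBC", "PLMQ")

#' @rdname techniques
#' @export
reaction_classes <- function() c("NORMAL", "CARIOUS", "SCLEROTIC")

#' @rdname techniques
#' @param technique a technique name.
#' @export
technique_modality <- function(technique) {
  technique <- match.arg(technique, techniques())
  switch(technique,
    SW = , SD = "stereomicroscopy",
    NFNBC = , NFBC = , FBC = "microradiography",
    PLMQ = "polarized-light")
}

## valid raw codes per technique (1..3, PLMQ 1..2)
technique_codes <- function(technique) {
  technique <- match.arg(technique, techniques())
  if (technique == "PLMQ") 1:2 else 1:3
}

#' Classes a technique can report
#'
#' @param technique a technique name.
#' @return character vector of canonical classes in the technique's
#'   vocabulary (`NORMAL`/`CARIOUS` for PLMQ, all three otherwise).
#' @export
technique_vocabulary <- function(technique) {
  reaction_classes()[technique_codes(technique)]
}

#' Map a raw technique code to a canonical reaction class
#'
#' Stereomicroscopy codes 1/2/3 mean normal, carious (discoloured) and
#' translucent; microradiography codes 1/2/3 mean normal, demineralised and
#' hypermineralized. Both third codes denote the same histological entity and
#' map to the canonical `SCLEROTIC` class. PLMQ codes 1/2 are positive
#' (normal) and negative (carious) birefringence.
#'
#' @param technique one of [techniques()].
#' @param code integer code(s) in the technique's range; `NA` allowed.
#' @return character vector of canonical classes (`NA` preserved).
#' @examples
#' to_canonical("SW", 3)    # "SCLEROTIC"
#' to_canonical("PLMQ", 1)  # "NORMAL"
#' @export
to_canonical <- function(technique, code) {
  technique <- match.arg(technique, techniques())
  ok <- is.na(code) | code %in% technique_codes(technique)
  if (!all(ok)) {
    stop(sprintf("invalid %s code(s): %s", technique,
                 paste(unique(code[!ok]), collapse = ", ")), call. = FALSE)
  }
  reaction_classes()[as.integer(code)]
}

score_columns <- function() c("section", "site", "icdas", techniques())

#' Construct and validate a per-site score table
#'
#' A score table has one row per histological site with a section identifier,
#' a site identifier, an optional ICDAS II score (0-6) and one raw-code
#' column per technique. Absent technique columns are added as all-missing.
#'
#' @param df data frame with at least `section` and `site` columns; technique
#'   columns hold integer codes in each technique's range or `NA`.
#' @return the validated data frame with class `"score_table"`, columns in
#'   canonical order.
#' @seealso [read_score_table()], [write_score_table()]
#' @export
score_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("section", "site")) {
    if (!col %in% names(df)) stop(sprintf("column '%s' is required", col), call. = FALSE)
  }
  if (nrow(df) < 1L) stop("a score table needs at least one site", call. = FALSE)
  if (!"icdas" %in% names(df)) df$icdas <- NA_integer_
  for (tech in techniques()) {
    if (!tech %in% names(df)) df[[tech]] <- NA_integer_
  }
  df <- df[score_columns()]
  df$section <- as.character(df$section)
  df$site <- as.character(df$site)
  df$icdas <- as.integer(df$icdas)

  key <- paste(df$section, df$site, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), c("section", "site"), drop = FALSE]
    stop(sprintf("duplicate (section, site) pair(s): %s",
                 paste(sprintf("(%s, %s)", d$section, d$site), collapse = "; ")),
         call. = FALSE)
  }
  bad_icdas <- !is.na(df$icdas) & !(df$icdas %in% 0:6)
  if (any(bad_icdas)) {
    stop(sprintf("icdas outside 0-6 in row(s) %s",
                 paste(which(bad_icdas), collapse = ", ")), call. = FALSE)
  }
  for (tech in techniques()) {
    v <- suppressWarnings(as.integer(df[[tech]]))
    if (any(is.na(v) & !is.na(df[[tech]]))) {
      stop(sprintf("non-integer code in column '%s'", tech), call. = FALSE)
    }
    bad <- !is.na(v) & !(v %in% technique_codes(tech))
    if (any(bad)) {
      stop(sprintf("out-of-range %s code %s in row(s) %s (valid: %s)",
                   tech, paste(unique(v[bad]), collapse = "/"),
                   paste(which(bad), collapse = ", "),
                   paste(range(technique_codes(tech)), collapse = "-")),
           call. = FALSE)
    }
    df[[tech]] <- v
  }
  rownames(df) <- NULL
  class(df) <- c("score_table", "data.frame")
  df
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Per-site score table: %d sites, %d sections\n",
              nrow(x), length(unique(x$section))))
  scored <- vapply(techniques(), function(t) sum(!is.na(x[[t]])), integer(1))
  cat("Scored sites per technique:\n")
  print(scored)
  invisible(x)
}

#' Number of sites in a score table
#' @param table a [score_table()].
#' @export
n_sites <- function(table) nrow(table)

#' Read a per-site score table from CSV
#'
#' Expects one row per histological site. Default column headers are
#' `section, site, icdas, SW, SD, NFNBC, NFBC, FBC, PLMQ`; a deposited file
#' with different headers can be bound via `dialect`, a named character
#' vector mapping canonical names to the file's headers, e.g.
#' `c(section = "Sample", SW = "sw_score")`. Empty cells and `"NA"` are read
#' as missing. Technique columns absent from the file are filled with `NA`.
#'
#' @param path CSV file path.
#' @param dialect optional named character vector, canonical name -> file
#'   header.
#' @return a [score_table()].
#' @export
read_score_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                        check.names = FALSE)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(names(dialect) == "")) {
      stop("dialect must be a named character vector (canonical = file header)",
           call. = FALSE)
    }
    unknown <- setdiff(names(dialect), score_columns())
    if (length(unknown)) {
      stop(sprintf("dialect names not canonical columns: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (canon in names(dialect)) {
      hdr <- dialect[[canon]]
      if (!hdr %in% names(df)) {
        stop(sprintf("dialect header '%s' not found in %s", hdr, path), call. = FALSE)
      }
      names(df)[names(df) == hdr] <- canon
    }
  }
  score_table(df)
}

#' Write a score table to CSV
#'
#' Columns are written in the fixed canonical order
#' `section, site, icdas, SW, SD, NFNBC, NFBC, FBC, PLMQ`; missing values are
#' written as empty cells. The output is readable by [read_score_table()].
#'
#' @param table a [score_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  utils::write.csv(as.data.frame(table)[score_columns()], path,
                   row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Count dentin reactions detected by a technique
#'
#' Tabulates the canonical classes of a technique's non-missing scores,
#' reproducing the layout of a per-technique detection-count table.
#'
#' @param table a [score_table()].
#' @param technique one of [techniques()].
#' @return named integer vector over the technique's vocabulary
#'   (`NORMAL`/`CARIOUS`(/`SCLEROTIC`)); counts sum to the number of
#'   non-missing scores.
#' @export
count_reactions <- function(table, technique) {
  stopifnot(inherits(table, "score_table"))
  technique <- match.arg(technique, techniques())
  codes <- table[[technique]]
  if (all(is.na(codes))) {
    stop(sprintf("technique %s has no scores in this table", technique), call. = FALSE)
  }
  cls <- factor(to_canonical(technique, codes), levels = technique_vocabulary(technique))
  out <- table(cls)
  stats::setNames(as.integer(out), names(out))
}

#' Detection counts for every scored technique
#'
#' @param table a [score_table()].
#' @return integer matrix, techniques (rows, those with any score) by the
#'   three canonical classes; `NA` where a class is outside a technique's
#'   vocabulary.
#' @export
count_reactions_all <- function(table) {
  stopifnot(inherits(table, "score_table"))
  present <- techniques()[vapply(techniques(), function(t) any(!is.na(table[[t]])),
                                 logical(1))]
  out <- matrix(NA_integer_, nrow = length(present), ncol = 3,
                dimnames = list(present, reaction_classes()))
  for (tech in present) {
    cnt <- count_reactions(table, tech)
    out[tech, names(cnt)] <- cnt
  }
  out
}
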