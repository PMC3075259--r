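PREDICTORS <- c("polyphen", "polyphen2", "snps3d", "sift")
PP_CATEGORIES <- c("benign", "possibly_damaging", "probably_damaging")

#' Load one predictor score table
#'
#' Two-column TSV `rsid, value`. PolyPhen and PolyPhen-2 values are
#' categorical (`benign`, `possibly_damaging`, `probably_damaging`); SNPs3D
#' values are real scores (negative = deleterious); SIFT values are
#' probabilities in `[0, 1]`. A value of the wrong type for the declared
#' predictor is an error.
#'
#' @param path TSV path.
#' @param predictor One of `"polyphen"`, `"polyphen2"`, `"snps3d"`, `"sift"`.
#' @return Data frame `rsid`, `predictor`, `value` (character for the
#'   categorical predictors, numeric otherwise).
#' @export
load_predictor_table <- function(path, predictor = PREDICTORS) {
  predictor <- match.arg(predictor)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("predictor table needs columns rsid, value")
  value <- df[[2]]
  if (predictor %in% c("polyphen", "polyphen2")) {
    value <- tolower(gsub("[ -]", "_", trimws(value)))
    bad <- which(!(value %in% PP_CATEGORIES))
    if (length(bad)) {
      stop(predictor, ": unknown category '", df[[2]][bad[1]], "' at line ",
           bad[1] + 1L)
    }
  } else {
    value <- suppressWarnings(as.numeric(value))
    if (anyNA(value)) {
      stop(predictor, ": non-numeric score at line ", which(is.na(value))[1] + 1L)
    }
    if (predictor == "sift" && any(value < 0 | value > 1)) {
      stop("sift scores must lie in [0, 1]")
    }
  }
  data.frame(rsid = df[[1]], predictor = predictor, value = value,
             stringsAsFactors = FALSE)
}

#' Aggregate predictor rows into per-SNP functional calls
#'
#' Rules per method: PolyPhen / PolyPhen-2 are functional when any of their
#' (possibly several) calls is `possibly_damaging` or `probably_damaging`;
#' SNPs3D keeps the lowest of its scores and is functional when that minimum
#' is strictly negative; SIFT keeps the lowest probability and is functional
#' when it is strictly below 0.05. A SNP absent from a predictor's table is
#' not evaluable by that method (`NA` flag).
#'
#' @param rows Data frame binding one or more [load_predictor_table()]
#'   outputs (`rsid`, `predictor`, `value`).
#' @param require_all Consensus convention: if `TRUE` (default) a SNP must
#'   be present and called functional by all four methods; if `FALSE`,
#'   absence is non-dissent and consensus requires all *available* methods
#'   functional (at least one present).
#' @return Data frame, one row per rsid: per-method call summaries
#'   (`polyphen_calls`, `polyphen2_calls` semicolon-joined, `snps3d_min`,
#'   `sift_min`), four logical per-method flags, and
#'   `consensus_functional`.
#' @export
aggregate_predictions <- function(rows, require_all = TRUE) {
  if (!nrow(rows)) {
    return(data.frame(rsid = character(), polyphen_calls = character(),
                      polyphen2_calls = character(), snps3d_min = numeric(),
                      sift_min = numeric(), polyphen_functional = logical(),
                      polyphen2_functional = logical(),
                      snps3d_functional = logical(), sift_functional = logical(),
                      consensus_functional = logical(), stringsAsFactors = FALSE))
  }
  stopifnot(all(rows$predictor %in% PREDICTORS))
  cat_rows <- rows$predictor %in% c("polyphen", "polyphen2")
  if (any(cat_rows) && !all(rows$value[cat_rows] %in% PP_CATEGORIES)) {
    stop("categorical predictor with non-categorical values")
  }
  num_rows <- !cat_rows
  num_val <- suppressWarnings(as.numeric(rows$value))
  if (any(num_rows) && anyNA(num_val[num_rows])) {
    stop("numeric predictor with non-numeric values")
  }
  rsids <- sort(unique(rows$rsid))
  one <- function(r) {
    sub <- rows[rows$rsid == r, , drop = FALSE]
    pp <- sub$value[sub$predictor == "polyphen"]
    pp2 <- sub$value[sub$predictor == "polyphen2"]
    s3d <- num_val[rows$rsid == r & rows$predictor == "snps3d"]
    sft <- num_val[rows$rsid == r & rows$predictor == "sift"]
    flag <- c(
      polyphen = if (length(pp)) any(pp != "benign") else NA,
      polyphen2 = if (length(pp2)) any(pp2 != "benign") else NA,
      snps3d = if (length(s3d)) min(s3d) < 0 else NA,
      sift = if (length(sft)) min(sft) < 0.05 else NA)
    consensus <- if (require_all) {
      !anyNA(flag) && all(flag)
    } else {
      any(!is.na(flag)) && all(flag, na.rm = TRUE)
    }
    data.frame(rsid = r,
               polyphen_calls = paste(pp, collapse = ";"),
               polyphen2_calls = paste(pp2, collapse = ";"),
               snps3d_min = if (length(s3d)) min(s3d) else NA_real_,
               sift_min = if (length(sft)) min(sft) else NA_real_,
               polyphen_functional = flag[["polyphen"]],
               polyphen2_functional = flag[["polyphen2"]],
               snps3d_functional = flag[["snps3d"]],
               sift_functional = flag[["sift"]],
               consensus_functional = consensus, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(rsids, one))
  rownames(out) <- NULL
  out
}

#' SNPs called functional by every predictor
#'
#' @param agg Output of [aggregate_predictions()].
#' @return Character vector of rsids with `consensus_functional = TRUE`.
#' @export
consensus_set <- function(agg) {
  if (!nrow(agg)) return(character(0))
  sort(agg$rsid[agg$consensus_functional %in% TRUE])
}
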