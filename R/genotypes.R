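#' Construct a genotype matrix
#'
#' Genotypes are stored as alternate-allele dosages (0, 1, 2; `NA` =
#' missing) in a SNP-by-sample integer matrix, with per-SNP reference and
#' alternate allele labels and an optional per-call confidence matrix of the
#' same shape.
#'
#' @param dosage Integer matrix, rows = SNPs (rownames = rsid), columns =
#'   samples (colnames = sample ids); entries in `{0, 1, 2, NA}`.
#' @param ref,alt Character vectors of allele labels per SNP; `alt` may be
#'   `NA` for loci where only one allele was ever observed.
#' @param confidence Optional numeric matrix in `[0, 1]`, same shape.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, ref, alt, confidence = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage must have rsid rownames and sample colnames")
  }
  if (any(dosage < 0L | dosage > 2L, na.rm = TRUE)) stop("dosage must be 0, 1, 2 or NA")
  if (length(ref) != nrow(dosage) || length(alt) != nrow(dosage)) {
    stop("ref/alt length must equal number of SNPs")
  }
  if (!is.null(confidence)) {
    confidence <- as.matrix(confidence)
    if (!identical(dim(confidence), dim(dosage))) {
      stop("confidence matrix shape must match dosage")
    }
    if (any(confidence < 0 | confidence > 1, na.rm = TRUE)) {
      stop("confidence values must lie in [0, 1]")
    }
    dimnames(confidence) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, ref = stats::setNames(ref, rownames(dosage)),
                 alt = stats::setNames(alt, rownames(dosage)),
                 confidence = confidence),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "SNPs x", ncol(x$dosage), "samples",
      if (!is.null(x$confidence)) "(with confidences)" else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' SNP identifiers of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of rsids.
#' @export
snp_ids <- function(g) rownames(g$dosage)

#' Sample identifiers of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(g) colnames(g$dosage)

#' Read genotypes from TSV
#'
#' Format: rows are SNPs, first column `rsid`, remaining columns one per
#' sample; cells are unordered allele pairs like `"A/G"`, with `"./."` (or
#' empty) for missing. Allele labels per SNP are taken from the data: the
#' alphabetically first observed allele is the reference. An optional
#' confidence TSV of identical shape carries per-call confidences.
#'
#' @param path Genotype TSV path.
#' @param confidence_path Optional confidence TSV path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, confidence_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (names(df)[1] != "rsid") stop("first genotype column must be 'rsid'")
  rsid <- df[[1]]
  if (anyDuplicated(rsid)) stop("duplicate rsid in genotype table")
  cells <- as.matrix(df[-1])
  rownames(cells) <- rsid
  n <- nrow(cells)
  dosage <- matrix(NA_integer_, n, ncol(cells), dimnames = dimnames(cells))
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    cc <- cells[i, ]
    ok <- !(cc %in% c("./.", ".", "", "NA")) & !is.na(cc)
    parts <- strsplit(cc[ok], "/", fixed = TRUE)
    if (any(vapply(parts, length, 0L) != 2L)) {
      stop("malformed genotype cell for SNP ", rsid[i])
    }
    a1 <- vapply(parts, `[[`, "", 1L); a2 <- vapply(parts, `[[`, "", 2L)
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) > 2L) stop("more than 2 alleles at SNP ", rsid[i])
    ref[i] <- if (length(alleles)) alleles[1] else NA_character_
    alt[i] <- if (length(alleles) == 2L) alleles[2] else NA_character_
    d <- (a1 == alt[i]) + (a2 == alt[i])
    d[is.na(d)] <- 0L  # monomorphic: every called genotype is ref/ref
    dosage[i, ok] <- as.integer(d)
  }
  conf <- NULL
  if (!is.null(confidence_path)) {
    cf <- utils::read.delim(confidence_path, header = TRUE, check.names = FALSE)
    if (!identical(cf[[1]], rsid)) stop("confidence rows do not match genotype rows")
    conf <- as.matrix(cf[-1])
    rownames(conf) <- rsid
    if (!identical(colnames(conf), colnames(dosage))) {
      stop("confidence columns do not match genotype columns")
    }
  }
  genotype_matrix(dosage, ref, alt, conf)
}

#' Write genotypes to TSV
#'
#' Inverse of [read_genotypes()]: allele-pair cells with `"./."` for
#' missing calls. Heterozygotes are written ref-first so a write/read
#' round trip is exact.
#'
#' @param g A [genotype_matrix()].
#' @param path Output TSV path.
#' @param confidence_path Optional path for the confidence TSV.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(g, path, confidence_path = NULL) {
  n <- nrow(g$dosage)
  cells <- matrix("./.", n, ncol(g$dosage), dimnames = dimnames(g$dosage))
  for (i in seq_len(n)) {
    r <- g$ref[i]; a <- g$alt[i]
    if (is.na(a)) a <- r
    gt <- c(paste(r, r, sep = "/"), paste(r, a, sep = "/"), paste(a, a, sep = "/"))
    d <- g$dosage[i, ]
    cells[i, !is.na(d)] <- gt[d[!is.na(d)] + 1L]
  }
  df <- data.frame(rsid = rownames(cells), cells, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(confidence_path)) {
    if (is.null(g$confidence)) stop("genotype matrix carries no confidences")
    cf <- data.frame(rsid = rownames(cells), round(g$confidence, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(cf, confidence_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Allele frequencies and call rate for one SNP
#'
#' Frequencies are computed from called genotypes only; each diploid call
#' contributes two alleles.
#'
#' @param g A [genotype_matrix()].
#' @param rsid SNP identifier.
#' @return List with `rsid`, `n_called`, `freq_ref`, `freq_alt`, `maf`,
#'   `call_rate`.
#' @export
allele_stats <- function(g, rsid) {
  if (!rsid %in% snp_ids(g)) stop("unknown rsid: ", rsid)
  d <- g$dosage[rsid, ]
  n_called <- sum(!is.na(d))
  if (n_called == 0L) stop("monomorphic/uncallable: no called genotypes for ", rsid)
  freq_alt <- sum(d, na.rm = TRUE) / (2 * n_called)
  list(rsid = rsid, n_called = n_called,
       freq_ref = 1 - freq_alt, freq_alt = freq_alt,
       maf = min(freq_alt, 1 - freq_alt),
       call_rate = n_called / length(d))
}
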