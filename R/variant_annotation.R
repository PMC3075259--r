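#' Closed consequence vocabulary
#'
#' The term set follows the ENSEMBL-v59-era naming used by array annotation
#' snapshots. Unknown terms are rejected at parse time: a SNP table with a
#' term outside this vocabulary is treated as a schema error, not silently
#' carried along.
#'
#' @return Character vector of admissible consequence terms.
#' @export
consequence_terms <- function() {
  c("ESSENTIAL_SPLICE_SITE", "SPLICE_SITE", "STOP_GAINED", "STOP_LOST",
    "NON_SYNONYMOUS_CODING", "SYNONYMOUS_CODING", "FRAMESHIFT_CODING",
    "5PRIME_UTR", "3PRIME_UTR", "UPSTREAM", "DOWNSTREAM", "INTRONIC",
    "WITHIN_NON_CODING_GENE", "HGMD_MUTATION")
}

#' Default central-SNP exclusion list
#'
#' SNPs whose only annotations are upstream, downstream, intronic, within a
#' non-coding gene, or HGMD-mutation records are not central: they sit
#' outside the coding/regulatory regions the screen targets. The list is a
#' parameter of [filter_central()] so alternative conventions remain usable.
#'
#' @return Character vector of excluded consequence terms.
#' @export
excluded_consequences <- function() {
  c("UPSTREAM", "DOWNSTREAM", "INTRONIC", "WITHIN_NON_CODING_GENE",
    "HGMD_MUTATION")
}

normalize_terms <- function(x) toupper(gsub("[ -]", "_", trimws(x)))

#' Load a SNP annotation table
#'
#' Expects a TSV with header columns `rsid, gene, chrom, pos, alleles,
#' transcript, consequence` and optionally `aa_change`. The consequence cell
#' may hold several semicolon-joined terms for one transcript. One row per
#' (rsid, gene, transcript, term) is returned; multi-transcript annotations
#' of the same SNP stay as separate rows and are aggregated by
#' [filter_central()]. Duplicate (rsid, gene, transcript, term) rows are
#' dropped with a warning.
#'
#' @param path Path to the annotation TSV.
#' @return A long data frame of class `snp_annotation` with columns `rsid`,
#'   `gene`, `chrom`, `pos`, `ref`, `alt`, `transcript`, `consequence`,
#'   `aa_change`.
#' @export
load_snp_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("rsid", "gene", "chrom", "pos", "alleles", "transcript", "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ", paste(miss, collapse = ", "))
  if (!"aa_change" %in% names(df)) df$aa_change <- NA_character_
  al <- strsplit(df$alleles, "/", fixed = TRUE)
  bad_al <- which(vapply(al, length, 0L) != 2L |
                  vapply(al, function(x) length(x) == 2L && x[1] == x[2], NA))
  if (length(bad_al)) {
    stop("line ", bad_al[1] + 1L, ": alleles must be two distinct values 'REF/ALT'")
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos) || any(pos < 1L)) stop("pos must be a positive 1-based integer")
  terms <- strsplit(df$consequence, ";", fixed = TRUE)
  vocab <- consequence_terms()
  rows <- rep(seq_len(nrow(df)), vapply(terms, length, 0L))
  term_vec <- normalize_terms(unlist(terms))
  unknown <- which(!(term_vec %in% vocab))
  if (length(unknown)) {
    stop("unknown consequence term '", unlist(terms)[unknown[1]],
         "' at line ", rows[unknown[1]] + 1L)
  }
  out <- data.frame(
    rsid = df$rsid[rows], gene = df$gene[rows], chrom = df$chrom[rows],
    pos = pos[rows],
    ref = vapply(al, `[[`, "", 1L)[rows], alt = vapply(al, `[[`, "", 2L)[rows],
    transcript = df$transcript[rows], consequence = term_vec,
    aa_change = df$aa_change[rows], stringsAsFactors = FALSE)
  if (any(!nzchar(out$rsid))) stop("empty rsid")
  key <- paste(out$rsid, out$gene, out$transcript, out$consequence, sep = "\r")
  if (anyDuplicated(key)) {
    warning("dropping ", sum(duplicated(key)), " duplicated annotation row(s)")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  class(out) <- c("snp_annotation", "data.frame")
  out
}

#' Filter SNP annotations to central SNPs
#'
#' A SNP is central when it carries at least one consequence outside the
#' exclusion list. `any_transcript` (default) considers every transcript's
#' terms; `first_transcript` evaluates only the first-listed transcript for
#' each (rsid, gene), reproducing annotation interfaces that return a single
#' transcript. Evaluation is per (rsid, gene) pair, so a SNP inside two
#' overlapping genes is assessed in each.
#'
#' @param records Long annotation frame from [load_snp_table()].
#' @param mode `"any_transcript"` or `"first_transcript"`.
#' @param exclude Consequence terms defining non-central SNPs.
#' @return Data frame of class `central_snps`: one row per central
#'   (rsid, gene) with `retained` (semicolon-joined non-excluded terms that
#'   were considered) plus locus columns.
#' @export
filter_central <- function(records, mode = c("any_transcript", "first_transcript"),
                           exclude = excluded_consequences()) {
  mode <- match.arg(mode)
  exclude <- normalize_terms(exclude)
  empty <- data.frame(rsid = character(), gene = character(), chrom = character(),
                      pos = integer(), retained = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("central_snps", "data.frame")
  if (!nrow(records)) return(empty)
  key <- paste(records$rsid, records$gene, sep = "\r")
  idx <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  keep <- lapply(idx, function(i) {
    if (mode == "first_transcript") {
      i <- i[records$transcript[i] == records$transcript[i[1]]]
    }
    terms <- records$consequence[i]
    retained <- setdiff(unique(terms), exclude)
    if (!length(retained)) return(NULL)
    j <- i[1]
    data.frame(rsid = records$rsid[j], gene = records$gene[j],
               chrom = records$chrom[j], pos = records$pos[j],
               retained = paste(sort(retained), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  keep <- keep[!vapply(keep, is.null, NA)]
  if (!length(keep)) return(empty)
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out <- out[order(out$rsid, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("central_snps", "data.frame")
  out
}

#' Count central SNPs per gene
#'
#' A SNP annotated in several overlapping genes counts once in each; such
#' rsids are listed in the `multi_gene` attribute rather than collapsed.
#'
#' @param central Frame from [filter_central()].
#' @return Named integer vector of per-gene counts with attribute
#'   `multi_gene`.
#' @export
central_snp_count_by_gene <- function(central) {
  if (!nrow(central)) {
    out <- integer(0)
    attr(out, "multi_gene") <- character(0)
    return(out)
  }
  counts <- table(central$gene)
  out <- as.integer(counts)
  names(out) <- names(counts)
  multi <- unique(central$rsid[duplicated(central$rsid)])
  attr(out, "multi_gene") <- sort(multi)
  out
}
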