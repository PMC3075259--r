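# Two-locus linkage disequilibrium from unphased genotypes.
#
# Haplotypes are indexed by their alternate-allele indicators at the two
# loci: f11 (alt,alt), f10 (alt,ref), f01 (ref,alt), f00 (ref,ref). Only the
# double-heterozygote genotype is phase-ambiguous; the EM splits it between
# the (11,00) and (10,01) configurations by their expected frequencies.

# 3x3 genotype count table (dosage a x dosage b, 0..2) -> EM haplotype freqs
em_hap_freqs <- function(counts, tol = 1e-10, max_iter = 1000L) {
  n <- sum(counts)
  pA <- sum(counts * matrix(0:2, 3, 3, byrow = FALSE)) / (2 * n)
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  # f[x, y]: frequency of haplotype with alt-indicator x-1 at locus A, y-1
  # at locus B; initialized at linkage equilibrium
  f <- outer(c(1 - pA, pA), c(1 - pB, pB))
  # fixed haplotype counts from phase-unambiguous genotype cells
  base <- matrix(0, 2, 2)
  for (i in 0:2) for (j in 0:2) {
    cnt <- counts[i + 1L, j + 1L]
    if (!cnt || (i == 1L && j == 1L)) next
    ha <- if (i == 1L) c(0L, 1L) else c(i %/% 2L, i %/% 2L)
    hb <- if (j == 1L) c(0L, 1L) else c(j %/% 2L, j %/% 2L)
    if (i == 1L && j != 1L) hb <- rep(j %/% 2L, 2L)
    if (j == 1L && i != 1L) ha <- rep(i %/% 2L, 2L)
    for (k in 1:2) base[ha[k] + 1L, hb[k] + 1L] <- base[ha[k] + 1L, hb[k] + 1L] + cnt
  }
  ndh <- counts[2L, 2L]
  for (iter in seq_len(max_iter)) {
    e <- base
    if (ndh > 0L) {
      w_cis <- f[2, 2] * f[1, 1]      # (alt,alt)/(ref,ref) configuration
      w_trans <- f[2, 1] * f[1, 2]    # (alt,ref)/(ref,alt)
      w <- if (w_cis + w_trans > 0) w_cis / (w_cis + w_trans) else 0.5
      e <- e + ndh * matrix(c(w, 1 - w, 1 - w, w), 2, 2)
    }
    f_new <- e / (2 * n)
    done <- max(abs(f_new - f)) < tol
    f <- f_new
    if (done) break
  }
  c(f11 = f[2, 2], f10 = f[2, 1], f01 = f[1, 2], f00 = f[1, 1])
}

#' Pairwise r-squared between two SNPs
#'
#' The `em` method (default) estimates the four two-locus haplotype
#' frequencies from unphased genotype counts by EM (convergence `1e-10`,
#' at most 1000 iterations) and returns
#' `r^2 = D^2 / (pA qA pB qB)` with `D = p(AB) - p(A) p(B)`.
#' The `allelic_corr` method returns the squared Pearson correlation of the
#' allele-dosage vectors; the two agree asymptotically under
#' Hardy-Weinberg equilibrium. Samples missing at either locus are excluded
#' (pairwise-complete deletion, reported as `n_used`). Computation is done
#' on the lexicographically ordered SNP pair, so results are exactly
#' symmetric in the two arguments.
#'
#' @param g A [genotype_matrix()].
#' @param a,b SNP identifiers.
#' @param method `"em"` or `"allelic_corr"`.
#' @return List of class `ld_result`: `snp_a`, `snp_b`, `r2`, `hap_freqs`
#'   (named numeric of length 4 for `em`, `NA` otherwise), `n_used`,
#'   `method`.
#' @export
pairwise_r2 <- function(g, a, b, method = c("em", "allelic_corr")) {
  method <- match.arg(method)
  swap <- a > b
  aa <- if (swap) b else a
  bb <- if (swap) a else b
  da <- g$dosage[aa, ]
  db <- g$dosage[bb, ]
  ok <- !is.na(da) & !is.na(db)
  da <- da[ok]; db <- db[ok]
  n_used <- length(da)
  if (n_used == 0L || stats::var(da) == 0 || stats::var(db) == 0) {
    stop("r2 undefined (zero variance) for pair ", aa, ", ", bb)
  }
  if (identical(aa, bb)) {
    # self-comparison: perfect LD by definition
    p <- mean(da) / 2
    hf <- c(f11 = p, f10 = 0, f01 = 0, f00 = 1 - p)
    res <- list(snp_a = a, snp_b = b, r2 = 1, hap_freqs = hf,
                n_used = n_used, method = method)
    class(res) <- "ld_result"
    return(res)
  }
  if (method == "em") {
    counts <- matrix(0, 3, 3)
    for (k in seq_len(n_used)) {
      counts[da[k] + 1L, db[k] + 1L] <- counts[da[k] + 1L, db[k] + 1L] + 1
    }
    f <- em_hap_freqs(counts)
    pA <- f["f11"] + f["f10"]
    pB <- f["f11"] + f["f01"]
    D <- f["f11"] - pA * pB
    r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
    hf <- f
  } else {
    r2 <- unname(stats::cor(da, db)^2)
    hf <- c(f11 = NA_real_, f10 = NA_real_, f01 = NA_real_, f00 = NA_real_)
  }
  r2 <- min(max(r2, 0), 1)
  res <- list(snp_a = a, snp_b = b, r2 = r2, hap_freqs = hf,
              n_used = n_used, method = method)
  class(res) <- "ld_result"
  res
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("LD %s ~ %s: r2 = %.4f (%s, n = %d)\n",
              x$snp_a, x$snp_b, x$r2, x$method, x$n_used))
  invisible(x)
}

#' Select tag-SNPs for central SNPs by pairwise r-squared
#'
#' Every (candidate, central) pair whose r-squared is computable and at or
#' above the threshold becomes a tag link; the mapping is many-to-many. A
#' SNP may appear on both sides, but never tags itself. Pairs with
#' undefined r-squared (monomorphic after pairwise deletion) are skipped
#' and counted in the `n_skipped` attribute.
#'
#' @param central Character vector of central SNP rsids present in `g`.
#' @param candidates Character vector of candidate tag rsids present in `g`.
#' @param g A [genotype_matrix()].
#' @param threshold Minimum r-squared in (0, 1]; default 0.8, the
#'   conventional tagging cutoff.
#' @param method LD method passed to [pairwise_r2()].
#' @return Data frame `tag`, `central`, `r2`, ordered by (tag, central),
#'   with attribute `n_skipped`.
#' @export
select_tags <- function(central, candidates, g, threshold = 0.8,
                        method = c("em", "allelic_corr")) {
  method <- match.arg(method)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  central <- intersect(unique(central), snp_ids(g))
  candidates <- intersect(unique(candidates), snp_ids(g))
  out <- list()
  skipped <- 0L
  for (tg in candidates) {
    for (ct in central) {
      if (tg == ct) next
      res <- tryCatch(pairwise_r2(g, tg, ct, method = method),
                      error = function(e) NULL)
      if (is.null(res)) {
        skipped <- skipped + 1L
        next
      }
      if (res$r2 >= threshold) {
        out[[length(out) + 1L]] <- data.frame(tag = tg, central = ct,
                                              r2 = res$r2,
                                              stringsAsFactors = FALSE)
      }
    }
  }
  links <- if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(), central = character(), r2 = numeric(),
               stringsAsFactors = FALSE)
  links <- links[order(links$tag, links$central), , drop = FALSE]
  rownames(links) <- NULL
  if (skipped) warning(skipped, " pair(s) skipped: r2 undefined")
  attr(links, "n_skipped") <- skipped
  links
}

#' Size of the combined central + tag SNP universe
#'
#' Inclusion-exclusion bookkeeping over the two identifier sets: the number
#' of distinct SNPs carried into downstream survival screening.
#'
#' @param central Character vector of central SNP rsids.
#' @param tags Character vector of tag-SNP rsids.
#' @return List `n_central`, `n_tags`, `n_both`, `n_union`.
#' @export
snp_universe <- function(central, tags) {
  central <- unique(central)
  tags <- unique(tags)
  n_both <- length(intersect(central, tags))
  list(n_central = length(central), n_tags = length(tags), n_both = n_both,
       n_union = length(central) + length(tags) - n_both)
}
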