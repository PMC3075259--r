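#' Quality-control parameters for the survival screen
#'
#' All thresholds are explicit parameters and are echoed in the QC report so
#' no run hides the values it used.
#'
#' @param confidence_min Calls with confidence below this are set missing
#'   (requires a confidence matrix); `NULL` disables the step.
#' @param max_missing_rate SNPs with a higher missing-genotype fraction are
#'   dropped.
#' @param min_maf SNPs with minor allele frequency below this are dropped.
#' @param min_sample_snr Samples with signal-to-noise ratio below this are
#'   dropped (requires per-sample SNR values); `NULL` disables the step.
#' @param merge_homo_freq Rare-homozygote merge threshold for
#'   [build_groups()] (fraction of called samples).
#' @param alpha Nominal significance level for the log-rank screen.
#' @return List of class `qc_params`.
#' @export
qc_params <- function(confidence_min = 0.95, max_missing_rate = 0.05,
                      min_maf = 0.05, min_sample_snr = 5,
                      merge_homo_freq = 0.10, alpha = 0.05) {
  chk <- function(x, lo, hi, name) {
    if (!is.null(x) && (!is.numeric(x) || x < lo || x > hi)) {
      stop(name, " out of range [", lo, ", ", hi, "]")
    }
  }
  chk(confidence_min, 0, 1, "confidence_min")
  chk(max_missing_rate, 0, 1, "max_missing_rate")
  chk(min_maf, 0, 0.5, "min_maf")
  if (!is.null(min_sample_snr) && min_sample_snr < 0) stop("min_sample_snr must be >= 0")
  chk(merge_homo_freq, 0, 0.5, "merge_homo_freq")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  structure(list(confidence_min = confidence_min,
                 max_missing_rate = max_missing_rate, min_maf = min_maf,
                 min_sample_snr = min_sample_snr,
                 merge_homo_freq = merge_homo_freq, alpha = alpha),
            class = "qc_params")
}

#' Genotype quality control
#'
#' Steps run in a fixed order: (1) calls with confidence below
#' `confidence_min` become missing; (2) samples with SNR below
#' `min_sample_snr` are dropped; (3) SNPs with missing rate above
#' `max_missing_rate` are dropped; (4) SNPs with MAF below `min_maf` are
#' dropped. The report records the count removed at each step and the
#' thresholds used.
#'
#' @param g A [genotype_matrix()].
#' @param params A [qc_params()] object.
#' @param sample_snr Optional named numeric vector of per-sample
#'   signal-to-noise ratios.
#' @return List: `genotypes` (filtered matrix) and `report`.
#' @export
qc_genotypes <- function(g, params = qc_params(), sample_snr = NULL) {
  stopifnot(inherits(params, "qc_params"))
  d <- g$dosage
  conf <- g$confidence
  n_masked <- 0L
  if (!is.null(params$confidence_min)) {
    if (is.null(conf)) stop("confidence_min set but genotypes carry no confidences")
    mask <- !is.na(d) & !is.na(conf) & conf < params$confidence_min
    n_masked <- sum(mask)
    d[mask] <- NA_integer_
  }
  dropped_samples <- character(0)
  if (!is.null(params$min_sample_snr) && !is.null(sample_snr)) {
    snr <- sample_snr[colnames(d)]
    if (anyNA(snr)) stop("sample_snr missing for some samples")
    dropped_samples <- colnames(d)[snr < params$min_sample_snr]
    d <- d[, snr >= params$min_sample_snr, drop = FALSE]
    if (!is.null(conf)) conf <- conf[, colnames(d), drop = FALSE]
  }
  miss_rate <- rowMeans(is.na(d))
  drop_miss <- rownames(d)[miss_rate > params$max_missing_rate]
  d <- d[miss_rate <= params$max_missing_rate, , drop = FALSE]
  maf <- apply(d, 1, function(x) {
    nc <- sum(!is.na(x))
    if (nc == 0) return(0)
    p <- sum(x, na.rm = TRUE) / (2 * nc)
    min(p, 1 - p)
  })
  drop_maf <- rownames(d)[maf < params$min_maf]
  d <- d[maf >= params$min_maf, , drop = FALSE]
  if (nrow(d) == 0L) stop("QC removed every SNP")
  keep <- rownames(d)
  out <- genotype_matrix(d, g$ref[keep], g$alt[keep],
                         if (!is.null(conf)) conf[keep, , drop = FALSE])
  report <- list(params = unclass(params),
                 n_calls_masked = n_masked,
                 samples_dropped = dropped_samples,
                 snps_dropped_missing = drop_miss,
                 snps_dropped_maf = drop_maf,
                 n_snps_kept = nrow(d), n_samples_kept = ncol(d))
  list(genotypes = out, report = report)
}

#' Genotype groups for one SNP, with rare-homozygote merging
#'
#' Samples are grouped as major-allele homozygotes, heterozygotes, and
#' minor-allele homozygotes. When the rarer homozygote class has frequency
#' below `merge_homo_freq` among called samples (and is non-empty), it is
#' combined with the heterozygotes, stabilising small-group survival
#' estimates. When the two homozygote classes are equally frequent, the
#' minor(alternate)-allele homozygote is the merge candidate.
#'
#' @param g A [genotype_matrix()].
#' @param rsid SNP identifier.
#' @param merge_homo_freq Merge threshold (default 0.10).
#' @return List of class `genotype_groups`: `rsid`, `assignment` (named
#'   character per called sample: `hom_major`, `het`, `hom_minor` or
#'   `merged_het_homminor`), `merged`, `group_sizes`, `untestable`.
#' @export
build_groups <- function(g, rsid, merge_homo_freq = 0.10) {
  d <- g$dosage[rsid, ]
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0L) stop("no called genotypes for ", rsid)
  p_alt <- sum(d) / (2 * n)
  # alt is minor on ties: with p_alt == 0.5 the alt homozygote merges
  alt_minor <- p_alt <= 0.5
  lab <- if (alt_minor) c("hom_major", "het", "hom_minor") else
    c("hom_minor", "het", "hom_major")
  assignment <- stats::setNames(lab[d + 1L], names(d))
  n_minor_hom <- sum(assignment == "hom_minor")
  merged <- FALSE
  if (n_minor_hom > 0L && n_minor_hom / n < merge_homo_freq) {
    assignment[assignment %in% c("het", "hom_minor")] <- "merged_het_homminor"
    merged <- TRUE
  }
  sizes <- table(assignment)
  res <- list(rsid = rsid, assignment = assignment, merged = merged,
              group_sizes = sizes,
              untestable = sum(sizes > 0) < 2L)
  class(res) <- "genotype_groups"
  res
}

#' @export
print.genotype_groups <- function(x, ...) {
  cat("genotype groups for", x$rsid, if (x$merged) "(rare homozygotes merged)",
      "\n")
  print(x$group_sizes)
  invisible(x)
}

#' Kaplan-Meier estimate per genotype group
#'
#' Product-limit estimator with Greenwood variance and 0.95 confidence
#' bands on the log-survival scale, clipped to `[0, 1]`.
#'
#' @param time Numeric follow-up times (same order as `group`).
#' @param event Logical/0-1 event indicators (TRUE = death observed).
#' @param group Character or factor group labels per sample.
#' @param conf_level Confidence level for the bands (default 0.95).
#' @return Named list of per-group data frames with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `se`, `lower`, `upper` (rows
#'   at distinct observed times).
#' @export
km_estimate <- function(time, event, group, conf_level = 0.95) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time < 0)) stop("negative follow-up time")
  event <- as.logical(event)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list()
  for (gl in sort(unique(as.character(group)))) {
    tt <- time[group == gl]
    ee <- event[group == gl]
    if (!length(tt)) stop("group with zero samples: ", gl)
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), 0)
    n_event <- vapply(ut, function(u) sum(tt == u & ee), 0)
    n_censor <- vapply(ut, function(u) sum(tt == u & !ee), 0)
    surv <- cumprod(1 - n_event / n_risk)
    # Greenwood: var(S) = S^2 * sum d / (n (n - d))
    gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), NA))
    se <- surv * sqrt(gw)
    se_log <- sqrt(gw)
    lower <- pmin(pmax(surv * exp(-z * se_log), 0), 1)
    upper <- pmin(surv * exp(z * se_log), 1)
    lower[surv == 0] <- 0
    upper[surv == 0] <- 0
    out[[gl]] <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                            n_censor = n_censor, surv = surv, se = se,
                            lower = lower, upper = upper)
  }
  out
}

#' k-group log-rank test
#'
#' At each distinct event time the observed per-group deaths are compared
#' with their hypergeometric expectation given the group at-risk sizes; the
#' statistic is the quadratic form of the summed O - E vector in its
#' covariance (first k - 1 groups), chi-square with k - 1 degrees of
#' freedom under the null.
#'
#' @param time,event,group As in [km_estimate()].
#' @return List: `chi2`, `df`, `p`, `observed`, `expected`, `no_events`
#'   (TRUE when no deaths occurred anywhere, in which case `chi2 = 0`,
#'   `p = 1`).
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  group <- factor(as.character(group))
  k <- nlevels(group)
  if (k < 2L) stop("log-rank test needs at least 2 non-empty groups")
  ut <- sort(unique(time[event]))
  O <- E <- stats::setNames(numeric(k), levels(group))
  V <- matrix(0, k, k, dimnames = list(levels(group), levels(group)))
  for (u in ut) {
    at_risk <- time >= u
    n <- sum(at_risk)
    if (n < 2) next
    n_g <- tapply(at_risk, group, sum)
    n_g[is.na(n_g)] <- 0
    d <- sum(event & time == u)
    d_g <- tapply(event & time == u, group, sum)
    d_g[is.na(d_g)] <- 0
    O <- O + d_g
    E <- E + d * n_g / n
    frac <- n_g / n
    V <- V + d * (n - d) / (n - 1) * (diag(frac, k) - outer(frac, frac))
  }
  if (!length(ut) || sum(O) == 0) {
    return(list(chi2 = 0, df = k - 1L, p = 1, observed = O, expected = E,
                no_events = TRUE))
  }
  idx <- seq_len(k - 1L)
  v <- V[idx, idx, drop = FALSE]
  oe <- (O - E)[idx]
  vinv <- tryCatch(solve(v), error = function(e) MASS::ginv(v))
  chi2 <- max(0, drop(t(oe) %*% vinv %*% oe))
  list(chi2 = chi2, df = k - 1L, p = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
       observed = O, expected = E, no_events = FALSE)
}

#' Genotype-group odds ratios by logistic regression
#'
#' Single-predictor logistic regression of the observed event indicator on
#' genotype group, reference = major-allele homozygotes: indicator coding
#' gives the heterozygote and minor-homozygote odds ratios with Wald
#' p-values. On a merged grouping only one contrast exists. Zero cells
#' (separation) make a contrast non-estimable; it is flagged, not an error.
#'
#' @param groups A [build_groups()] result.
#' @param event Named logical vector of event indicators (names = sample
#'   ids; at least the called samples in `groups`).
#' @return Data frame `contrast`, `or`, `p`, `estimable`.
#' @export
logistic_or <- function(groups, event) {
  a <- groups$assignment
  ev <- event[names(a)]
  if (anyNA(ev)) stop("event indicator missing for some grouped samples")
  levels_order <- intersect(c("hom_major", "het", "merged_het_homminor", "hom_minor"),
                            unique(a))
  if (!"hom_major" %in% levels_order) {
    # no reference group: nothing is estimable
    contrasts <- setdiff(levels_order, "hom_major")
    return(data.frame(contrast = contrasts, or = NA_real_, p = NA_real_,
                      estimable = FALSE, stringsAsFactors = FALSE))
  }
  f <- factor(a, levels = levels_order)
  tab <- table(f, factor(ev, levels = c(FALSE, TRUE)))
  contrasts <- setdiff(levels_order, "hom_major")
  est <- vapply(contrasts, function(cl) {
    all(tab["hom_major", ] > 0) && all(tab[cl, ] > 0)
  }, NA)
  out <- data.frame(contrast = contrasts, or = NA_real_, p = NA_real_,
                    estimable = est, stringsAsFactors = FALSE)
  if (any(est)) {
    keep <- a %in% c("hom_major", contrasts[est])
    ff <- droplevels(f[keep])
    fit <- stats::glm(ev[keep] ~ ff, family = stats::binomial())
    sm <- summary(fit)$coefficients
    for (cl in contrasts[est]) {
      rn <- paste0("ff", cl)
      if (rn %in% rownames(sm)) {
        out$or[out$contrast == cl] <- exp(sm[rn, "Estimate"])
        out$p[out$contrast == cl] <- sm[rn, "Pr(>|z|)"]
      }
    }
  }
  out
}

#' Survival screen over a set of array SNPs
#'
#' For every SNP: genotype groups (with rare-homozygote merging), log-rank
#' test across groups, logistic odds ratios, and a nominal significance
#' call at `alpha` (no multiplicity correction, matching a nominal-p
#' screen; a Benjamini-Hochberg column is emitted alongside for reference).
#'
#' @param snps Character vector of rsids to test (must be present in `g`).
#' @param g A QC-passed [genotype_matrix()].
#' @param clinical Data frame with columns `sample`, `time`, `event`.
#' @param merge_homo_freq Merge threshold for [build_groups()].
#' @param alpha Nominal significance level.
#' @param keep_curves Attach per-SNP Kaplan-Meier curves (list column
#'   `curves`); disable for large simulation screens.
#' @return List: `results` (data frame, one row per testable SNP),
#'   `untestable` (rsids with fewer than two genotype groups), `curves`
#'   (named list when `keep_curves`).
#' @export
survival_screen <- function(snps, g, clinical, merge_homo_freq = 0.10,
                            alpha = 0.05, keep_curves = FALSE) {
  stopifnot(all(c("sample", "time", "event") %in% names(clinical)))
  snps <- intersect(unique(snps), snp_ids(g))
  if (!length(snps)) {
    warning("no array SNPs intersect the genotype matrix")
    return(list(results = data.frame(), untestable = character(0), curves = list()))
  }
  ev <- stats::setNames(as.logical(clinical$event), clinical$sample)
  tm <- stats::setNames(as.numeric(clinical$time), clinical$sample)
  rows <- list()
  untestable <- character(0)
  curves <- list()
  for (s in snps) {
    gr <- build_groups(g, s, merge_homo_freq)
    samples <- intersect(names(gr$assignment), clinical$sample)
    a <- gr$assignment[samples]
    if (length(unique(a)) < 2L) {
      untestable <- c(untestable, s)
      next
    }
    lr <- logrank_test(tm[samples], ev[samples], a)
    gr_sub <- gr
    gr_sub$assignment <- a
    ors <- logistic_or(gr_sub, ev)
    get_or <- function(cl) {
      i <- which(ors$contrast %in% cl)
      if (length(i)) c(ors$or[i[1]], ors$p[i[1]]) else c(NA_real_, NA_real_)
    }
    het <- get_or(c("het", "merged_het_homminor"))
    hom <- get_or("hom_minor")
    sizes <- table(a)
    rows[[s]] <- data.frame(
      rsid = s, n = length(samples), n_groups = length(sizes),
      merged = gr$merged,
      group_sizes = paste(names(sizes), as.integer(sizes), sep = "=",
                          collapse = ";"),
      logrank_chi2 = lr$chi2, logrank_p = lr$p,
      hetero_or = het[1], hetero_p = het[2],
      homo_or = hom[1], homo_p = hom[2],
      stringsAsFactors = FALSE)
    if (keep_curves) curves[[s]] <- km_estimate(tm[samples], ev[samples], a)
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (nrow(results)) {
    rownames(results) <- NULL
    results$significant <- results$logrank_p < alpha
    results$logrank_p_bh <- stats::p.adjust(results$logrank_p, method = "BH")
  }
  list(results = results, untestable = untestable, curves = curves)
}

#' Map significant array SNPs back to central SNPs
#'
#' Significant array SNPs split into those that are themselves central
#' (direct hits) and those acting as tags; tagged central SNPs are resolved
#' through the tag links. The total is the number of distinct central SNPs
#' reached either way.
#'
#' @param significant Character vector of significant array rsids (or a
#'   `survival_screen()` results frame, from which they are taken).
#' @param links Tag-link data frame (`tag`, `central`) from [select_tags()].
#' @param central Character vector of all central rsids.
#' @return List: `direct` (sorted rsids), `tagged` (sorted rsids reached
#'   through links, self-links excluded), `n_total` = `|direct U tagged|`.
#' @export
map_to_central <- function(significant, links, central) {
  if (is.data.frame(significant)) {
    significant <- significant$rsid[significant$significant %in% TRUE]
  }
  significant <- unique(significant)
  central <- unique(central)
  direct <- sort(intersect(significant, central))
  tagged <- character(0)
  if (nrow(links)) {
    hit <- links$tag %in% significant & links$central != links$tag
    tagged <- sort(unique(links$central[hit]))
    tagged <- intersect(tagged, central)
  }
  list(direct = direct, tagged = tagged,
       n_total = length(union(direct, tagged)))
}
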