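# Independent oracles and small fixture builders shared across tests.

# Quick genotype_matrix from a dosage matrix (rows = SNPs).
make_gmat <- function(dosage, confidence = NULL) {
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("rs", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  genotype_matrix(dosage, ref = rep("A", nrow(dosage)),
                  alt = rep("G", nrow(dosage)), confidence = confidence)
}

# Draw an n-sample unphased genotype fixture from a two-locus haplotype pool.
draw_pair_dosages <- function(f, n) {
  haps <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  h1 <- sample.int(4L, n, replace = TRUE, prob = f)
  h2 <- sample.int(4L, n, replace = TRUE, prob = f)
  rbind(a = haps[h1, 1] + haps[h2, 1], b = haps[h1, 2] + haps[h2, 2])
}

# Maximum-likelihood two-locus r2 by direct likelihood maximization over the
# one free haplotype frequency (marginal allele frequencies are fixed by the
# genotype counts): a fine grid followed by local refinement. Independent of
# the EM implementation.
oracle_r2 <- function(dos_a, dos_b) {
  counts <- matrix(0, 3, 3)
  for (k in seq_along(dos_a)) {
    counts[dos_a[k] + 1L, dos_b[k] + 1L] <- counts[dos_a[k] + 1L, dos_b[k] + 1L] + 1
  }
  n <- sum(counts)
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  hap <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  loglik <- function(f11) {
    f <- c(f11, pA - f11, pB - f11, 1 - pA - pB + f11)
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 0)
    P <- matrix(0, 3, 3)
    for (i in 1:4) for (j in 1:4) {
      ga <- hap[i, 1] + hap[j, 1] + 1L
      gb <- hap[i, 2] + hap[j, 2] + 1L
      P[ga, gb] <- P[ga, gb] + f[i] * f[j]
    }
    if (any(P[counts > 0] <= 0)) return(-Inf)
    sum(counts[counts > 0] * log(P[counts > 0]))
  }
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 4001)
  ll <- vapply(grid, loglik, 0)
  best <- grid[which.max(ll)]
  step <- (hi - lo) / 4000
  opt <- stats::optimize(loglik, c(max(lo, best - 2 * step), min(hi, best + 2 * step)),
                         maximum = TRUE, tol = 1e-13)
  cand <- c(opt$maximum, lo, hi, best)
  f11 <- cand[which.max(vapply(cand, loglik, 0))]
  D <- f11 - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Brute-force focal-gene set: g is focal iff it is PPI-adjacent to a query or
# co-members a pathway with a query (other than itself).
oracle_focal <- function(queries, pathways, edges) {
  genes <- character(0)
  for (i in seq_len(nrow(pathways))) {
    mem <- pathways$members[[i]]
    for (g in mem) if (length(setdiff(intersect(queries, mem), g))) genes <- c(genes, g)
  }
  for (i in seq_len(nrow(edges))) {
    if (edges$a[i] == edges$b[i]) next
    if (edges$a[i] %in% queries) genes <- c(genes, edges$b[i])
    if (edges$b[i] %in% queries) genes <- c(genes, edges$a[i])
  }
  sort(unique(c(genes, queries)))
}

# Simulate one survival screen replicate: genotype at one SNP with the given
# MAF, exponential survival with hazard baseline * hr^dosage, independent
# exponential censoring; returns the log-rank p across genotype groups.
sim_logrank_p <- function(n, maf, hr, baseline = log(2), cens_frac = 0.3,
                          merge_homo_freq = 0.10) {
  dos <- stats::rbinom(n, 2L, maf)
  hz <- baseline * hr^dos
  t_event <- stats::rexp(n, hz)
  t_cens <- stats::rexp(n, baseline * cens_frac / (1 - cens_frac))
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  dm <- matrix(as.integer(dos), 1, n,
               dimnames = list("rs1", paste0("S", seq_len(n))))
  g <- make_gmat(dm)
  gr <- build_groups(g, "rs1", merge_homo_freq)
  if (gr$untestable) return(NA_real_)
  logrank_test(time, event, gr$assignment[paste0("S", seq_len(n))])$p
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
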