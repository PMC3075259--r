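test_that("QC steps run in order and report what they removed", {
  set.seed(10)
  n <- 40
  dosage <- rbind(good = rbinom(n, 2, 0.4),
                  gappy = rbinom(n, 2, 0.4),
                  rare = rbinom(n, 2, 0.01))
  dosage["gappy", 1:10] <- NA                  # 25% missing
  colnames(dosage) <- paste0("S", 1:n)
  conf <- matrix(1, 3, n, dimnames = dimnames(dosage))
  conf["good", 1] <- 0.90                      # one low-confidence call
  g <- genotype_matrix(dosage, rep("A", 3), rep("G", 3), conf)
  snr <- setNames(rep(10, n), colnames(dosage))
  snr["S2"] <- 2                               # one bad sample
  qc <- qc_genotypes(g, qc_params(), sample_snr = snr)
  expect_equal(qc$report$n_calls_masked, 1L)
  expect_equal(qc$report$samples_dropped, "S2")
  expect_equal(qc$report$snps_dropped_missing, "gappy")
  expect_equal(qc$report$snps_dropped_maf, "rare")
  expect_equal(snp_ids(qc$genotypes), "good")
  expect_true(is.na(qc$genotypes$dosage["good", "S1"]))
  # removing every SNP is an error, as are invalid thresholds
  expect_error(qc_genotypes(g, qc_params(min_maf = 0.5), sample_snr = snr),
               "every SNP")
  expect_error(qc_params(min_maf = -1), "range")
  expect_error(qc_params(alpha = 1.2), "alpha")
})

test_that("rare homozygotes merge exactly below the 10% threshold", {
  mk <- function(n0, n1, n2) {
    d <- matrix(c(rep(0L, n0), rep(1L, n1), rep(2L, n2)), 1)
    rownames(d) <- "rs1"; colnames(d) <- paste0("S", seq_len(ncol(d)))
    make_gmat(d)
  }
  gr <- build_groups(mk(70, 25, 5), "rs1")     # 5% < 10% -> merged
  expect_true(gr$merged)
  expect_equal(sort(unique(gr$assignment)), c("hom_major", "merged_het_homminor"))
  expect_equal(unname(gr$group_sizes["merged_het_homminor"]), 30L)

  gr2 <- build_groups(mk(50, 30, 20), "rs1")   # 20% >= 10% -> three groups
  expect_false(gr2$merged)
  expect_equal(length(gr2$group_sizes), 3L)

  gr3 <- build_groups(mk(95, 5, 0), "rs1")     # already two groups, no merge
  expect_false(gr3$merged)
  expect_equal(length(gr3$group_sizes[gr3$group_sizes > 0]), 2L)

  # the 11-of-209 homozygote class merges (boundary behaviour of the rule)
  gr4 <- build_groups(mk(129, 69, 11), "rs1")
  expect_true(gr4$merged)
  gr5 <- build_groups(mk(119, 69, 21), "rs1")  # 21/209 > 10%: no merge
  expect_false(gr5$merged)

  # monomorphic SNP is untestable
  gr6 <- build_groups(mk(10, 0, 0), "rs1")
  expect_true(gr6$untestable)
})

test_that("KM equals the empirical survivor function without censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1), rep("g", 3))$g
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # hand product-limit with censoring: 1,2+,3 -> 2/3 on [1,3), then 0
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1), rep("g", 3))$g
  expect_equal(km2$surv, c(2 / 3, 2 / 3, 0))
  # all censored: S identically 1
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0), rep("g", 3))$g
  expect_true(all(km3$surv == 1))
  set.seed(11)
  tt <- rexp(50); ee <- rep(TRUE, 50)
  km4 <- km_estimate(tt, ee, rep("g", 50))$g
  emp <- vapply(km4$time, function(u) mean(tt > u), 0)
  expect_equal(km4$surv, emp)
  expect_true(all(diff(km4$surv) <= 1e-12))
  expect_true(all(km4$lower <= km4$surv + 1e-12 & km4$surv <= km4$upper + 1e-12,
                  na.rm = TRUE))
})

test_that("KM curves and bands match the survival package", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 80
  tt <- rexp(n); ee <- runif(n) < 0.7
  grp <- sample(c("a", "b"), n, replace = TRUE)
  ours <- km_estimate(tt, ee, grp)
  fit <- survival::survfit(survival::Surv(tt, ee) ~ grp, conf.type = "log")
  sf <- summary(fit, times = sort(unique(tt)), extend = TRUE)
  for (gl in c("a", "b")) {
    ref <- sf$surv[sf$strata == paste0("grp=", gl)]
    ref_t <- sf$time[sf$strata == paste0("grp=", gl)]
    ours_g <- ours[[gl]]
    idx <- match(ours_g$time, ref_t)
    expect_equal(ours_g$surv, ref[idx], tolerance = 1e-10)
    lo <- sf$lower[sf$strata == paste0("grp=", gl)][idx]
    hi <- sf$upper[sf$strata == paste0("grp=", gl)][idx]
    cmp <- !is.na(lo) & ours_g$surv > 0
    expect_equal(ours_g$lower[cmp], lo[cmp], tolerance = 1e-8)
    expect_equal(ours_g$upper[cmp], hi[cmp], tolerance = 1e-8)
  }
})

test_that("log-rank statistic matches hand computation and survdiff", {
  # two identical groups: chi2 = 0, p = 1 by symmetry
  lr0 <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("x", "y"), each = 3))
  expect_equal(lr0$chi2, 0)
  expect_equal(lr0$p, 1)

  # 6-sample toy set: sum over event times of (O - E)^2 / V, tabulated by hand
  tt <- c(1, 2, 3, 4, 5, 6)
  ee <- c(1, 1, 1, 0, 1, 1)
  gg <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(tt, ee, gg)
  # hand tabulation: t=1 (na=3,nb=3,d=1,da=1), t=2 (2,3,1,0), t=3 (2,2,1,1),
  # t=5 (1,1,1,1), t=6 (0,1,1,0)
  O_a <- 1 + 0 + 1 + 1 + 0
  E_a <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 2 + 0
  V <- (3 * 3) / (6^2) + (2 * 3) / (5^2) + (2 * 2) / (4^2) + (1 * 1) / (2^2) + 0
  expect_equal(lr$chi2, (O_a - E_a)^2 / V, tolerance = 1e-12)
  # internal consistency: 2-group chi2 is the squared standardized O - E score
  expect_equal(lr$chi2,
               unname((lr$observed[1] - lr$expected[1])^2 / V), tolerance = 1e-12)

  skip_if_not_installed("survival")
  set.seed(13)
  n <- 120
  tt2 <- rexp(n); ee2 <- runif(n) < 0.7
  gg2 <- sample(c("a", "b", "c"), n, replace = TRUE)
  lr2 <- logrank_test(tt2, ee2, gg2)
  sd <- survival::survdiff(survival::Surv(tt2, ee2) ~ gg2)
  expect_equal(lr2$chi2, unname(sd$chisq), tolerance = 1e-8)
  expect_equal(lr2$df, 2L)

  # no events at all: flagged, chi2 = 0, p = 1
  lr3 <- logrank_test(c(1, 2), c(0, 0), c("a", "b"))
  expect_true(lr3$no_events)
  expect_equal(lr3$p, 1)
})

test_that("log-rank and KM are invariant under sample reordering", {
  set.seed(14)
  n <- 60
  tt <- rexp(n); ee <- runif(n) < 0.6; gg <- sample(c("a", "b"), n, TRUE)
  perm <- sample(n)
  expect_equal(logrank_test(tt, ee, gg)$p,
               logrank_test(tt[perm], ee[perm], gg[perm])$p)
  expect_equal(km_estimate(tt, ee, gg), km_estimate(tt[perm], ee[perm], gg[perm]))
})

test_that("logistic OR equals the 2x2 cross-product ratio", {
  # comparison group: 10 events / 20 non-events; reference: 30 / 5
  a <- c(rep("hom_major", 35), rep("het", 30))
  ev <- setNames(c(rep(TRUE, 30), rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 20)),
                 paste0("S", 1:65))
  names(a) <- paste0("S", 1:65)
  gr <- list(rsid = "rs1", assignment = a, merged = FALSE,
             group_sizes = table(a), untestable = FALSE)
  class(gr) <- "genotype_groups"
  ors <- logistic_or(gr, ev)
  expect_equal(ors$or[ors$contrast == "het"], (10 * 5) / (20 * 30),
               tolerance = 1e-6)
  # identical event rates: OR = 1, p ~ 1
  a2 <- setNames(rep(c("hom_major", "het"), each = 20), paste0("S", 1:40))
  ev2 <- setNames(rep(c(TRUE, FALSE), 20), paste0("S", 1:40))
  gr2 <- gr; gr2$assignment <- a2
  ors2 <- logistic_or(gr2, ev2)
  expect_equal(ors2$or[1], 1, tolerance = 1e-6)
  expect_gt(ors2$p[1], 0.9)
  # zero events in the reference group: non-estimable flag, no crash
  a3 <- setNames(rep(c("hom_major", "het"), each = 10), paste0("S", 1:20))
  ev3 <- setNames(c(rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 5)), paste0("S", 1:20))
  gr3 <- gr; gr3$assignment <- a3
  ors3 <- logistic_or(gr3, ev3)
  expect_false(ors3$estimable[1])
  expect_true(is.na(ors3$or[1]))
})

test_that("random 2x2 tables reproduce the cross-product ratio within 1e-6", {
  set.seed(15)
  for (rep in 1:10) {
    cells <- sample(3:40, 4, replace = TRUE)  # a, b: comparison; c, d: reference
    a <- setNames(c(rep("het", cells[1] + cells[2]),
                    rep("hom_major", cells[3] + cells[4])),
                  paste0("S", 1:sum(cells)))
    ev <- setNames(c(rep(TRUE, cells[1]), rep(FALSE, cells[2]),
                     rep(TRUE, cells[3]), rep(FALSE, cells[4])), names(a))
    gr <- list(rsid = "rs1", assignment = a, merged = FALSE,
               group_sizes = table(a), untestable = FALSE)
    class(gr) <- "genotype_groups"
    ors <- logistic_or(gr, ev)
    expect_equal(ors$or[1], (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
})

test_that("survival screen flags effects, skips untestables, maps to central", {
  set.seed(16)
  n <- 250
  samples <- paste0("S", 1:n)
  causal <- rbinom(n, 2, 0.3)
  null1 <- rbinom(n, 2, 0.4)
  mono <- rep(0L, n)
  dm <- rbind(causal = as.integer(causal), null1 = as.integer(null1),
              mono = mono)
  colnames(dm) <- samples
  g <- make_gmat(dm)
  hz <- log(2) * 3^causal
  t_event <- rexp(n, hz); t_cens <- rexp(n, log(2) * 0.4)
  clinical <- data.frame(sample = samples, time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens))
  scr <- survival_screen(c("causal", "null1", "mono"), g, clinical,
                         keep_curves = TRUE)
  expect_equal(scr$untestable, "mono")
  res <- scr$results
  expect_true(res$significant[res$rsid == "causal"])
  expect_equal(res$logrank_p < 0.05, res$significant)
  expect_true(all(c("logrank_p_bh", "hetero_or") %in% names(res)))
  expect_length(scr$curves[["causal"]], res$n_groups[res$rsid == "causal"])

  links <- data.frame(tag = c("causal", "null1"), central = c("rsC1", "rsC2"),
                      r2 = c(0.9, 0.9), stringsAsFactors = FALSE)
  hits <- map_to_central(res, links, central = c("rsC1", "rsC2", "causal"))
  expect_equal(hits$direct, "causal")
  expect_equal(hits$tagged, "rsC1")
  expect_equal(hits$n_total, 2L)

  # dedup: a significant SNP both central and tagging itself counts once
  links2 <- data.frame(tag = "causal", central = "causal", r2 = 1)
  hits2 <- map_to_central("causal", links2, central = "causal")
  expect_equal(hits2$n_total, 1L)
  expect_equal(map_to_central(character(0), links, c("rsC1"))$n_total, 0L)
})
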