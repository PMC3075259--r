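# Synthetic inputs for the full pipeline: pathway/PPI snapshots, SNP
# annotation tables, genotypes with LD structure and per-call confidences,
# exponential survival with optional genotype-dependent hazard, and
# predictor score tables. One integer seed drives every sub-generator
# through independent derived streams, so each component can be regenerated
# in isolation.

derive_seed <- function(seed, stream) {
  offsets <- c(network = 1L, snps = 2L, haplotypes = 3L, genotypes = 4L,
               clinical = 5L, predictors = 6L)
  as.integer((as.numeric(seed) * 131L + offsets[[stream]]) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults emulate a modest candidate-gene study: a 200-gene universe with
#' 20 pathways and a sparse PPI graph, 209 patients (a typical clinical
#' cohort size), 60 annotated SNPs plus tag partners in linkage
#' disequilibrium, 2% missing calls, exponential survival with baseline
#' hazard log(2) per year (median survival one year, as in glioblastoma)
#' and 30% censoring.
#'
#' @param seed Integer master seed.
#' @param n_genes,n_pathways,pathway_size_range,ppi_mean_degree Network
#'   snapshot dimensions.
#' @param n_samples,n_snps Cohort and panel sizes.
#' @param n_ld_pairs Number of (tag, central) haplotype-pool pairs added.
#' @param ld_target_r2 Recycled vector of target r-squared values for the
#'   LD pairs.
#' @param maf_range Uniform range for independent-SNP minor allele
#'   frequencies.
#' @param missing_rate Fraction of calls set missing.
#' @param confidence_noise Fraction of calls given sub-threshold (< 0.95)
#'   confidence.
#' @param baseline_hazard Exponential hazard per time unit.
#' @param censoring_rate Target fraction of censored samples.
#' @param effect_snp Optional list `list(rsid =, hazard_ratio =)`: hazard is
#'   multiplied by `hazard_ratio` per minor allele at that SNP.
#' @param predictor_damaging_fraction Fraction of non-synonymous SNPs made
#'   concordantly damaging across all four predictors.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_pathways = 20L,
                       pathway_size_range = c(5L, 25L), ppi_mean_degree = 2,
                       n_samples = 209L, n_snps = 60L, n_ld_pairs = 8L,
                       ld_target_r2 = c(0.85, 0.9, 0.95),
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       confidence_noise = 0.02, baseline_hazard = log(2),
                       censoring_rate = 0.3, effect_snp = NULL,
                       predictor_damaging_fraction = 0.1) {
  stopifnot(n_genes >= 2, n_pathways >= 0, n_samples >= 2, n_snps >= 1,
            ppi_mean_degree >= 0, all(ld_target_r2 >= 0 & ld_target_r2 <= 1),
            missing_rate >= 0, missing_rate < 1,
            confidence_noise >= 0, confidence_noise < 1,
            baseline_hazard > 0, censoring_rate >= 0, censoring_rate < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  if (pathway_size_range[2] > n_genes) stop("pathway size exceeds gene universe")
  if (!is.null(effect_snp)) {
    stopifnot(is.list(effect_snp), !is.null(effect_snp$rsid),
              effect_snp$hazard_ratio > 0)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a pathway/PPI database snapshot
#'
#' Gene symbols `G0001...`; pathways draw members uniformly without
#' replacement with sizes uniform in `pathway_size_range`; the PPI graph is
#' Erdos-Renyi with edge probability `ppi_mean_degree / (n_genes - 1)`;
#' every gene gets one synthetic protein accession alias.
#'
#' @param cfg A [sim_config()].
#' @return List: `genes`, `pathways` (frame as [load_pathway_db()]),
#'   `edges` (frame as [load_ppi()]), `aliases` (named vector).
#' @export
gen_network_snapshot <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "network"))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  ids <- if (cfg$n_pathways) sprintf("PW%02d", seq_len(cfg$n_pathways)) else character(0)
  members <- lapply(seq_len(cfg$n_pathways), function(i) {
    size <- sample(cfg$pathway_size_range[1]:cfg$pathway_size_range[2], 1L)
    sort(sample(genes, size))
  })
  pathways <- data.frame(pathway_id = ids,
                         name = if (length(ids)) tolower(ids) else character(0),
                         stringsAsFactors = FALSE)
  pathways$members <- members
  p_edge <- min(1, cfg$ppi_mean_degree / (cfg$n_genes - 1))
  pairs <- utils::combn(genes, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- data.frame(a = pairs[1, keep], b = pairs[2, keep],
                      source = "sim_ppi",
                      self_loop = FALSE, stringsAsFactors = FALSE)
  aliases <- stats::setNames(genes, sprintf("ACC%05d", seq_len(cfg$n_genes)))
  list(genes = genes, pathways = pathways, edges = edges, aliases = aliases)
}

#' Solve a two-locus haplotype pool with exact population r-squared
#'
#' Frequencies follow from `D = sqrt(r2 * pA qA pB qB)` (positive sign),
#' where `pA`, `pB` are the minor allele frequencies. Targets above the
#' feasibility bound `r2max` for the MAF pair are rejected.
#'
#' @param maf_a,maf_b Minor allele frequencies in (0, 0.5].
#' @param target_r2 Desired population r-squared in `[0, 1]`.
#' @return Named numeric of length 4 (`f11`, `f10`, `f01`, `f00`), the
#'   frequencies of the alt-alt, alt-ref, ref-alt and ref-ref haplotypes.
#' @export
gen_haplotype_pool <- function(maf_a, maf_b, target_r2) {
  stopifnot(maf_a > 0, maf_a <= 0.5, maf_b > 0, maf_b <= 0.5,
            target_r2 >= 0, target_r2 <= 1)
  pA <- maf_a; pB <- maf_b
  d_max <- min(pA * (1 - pB), (1 - pA) * pB)
  r2_max <- d_max^2 / (pA * (1 - pA) * pB * (1 - pB))
  if (target_r2 > r2_max + 1e-12) {
    stop(sprintf("target_r2 %.4g infeasible for MAFs (%.3g, %.3g): r2max = %.4g",
                 target_r2, maf_a, maf_b, r2_max))
  }
  D <- sqrt(target_r2 * pA * (1 - pA) * pB * (1 - pB))
  f <- c(f11 = pA * pB + D, f10 = pA * (1 - pB) - D,
         f01 = (1 - pA) * pB - D, f00 = (1 - pA) * (1 - pB) + D)
  f[abs(f) < 1e-15] <- 0
  if (any(f < 0)) stop("internal: negative haplotype frequency")
  f
}

# sample n diploid genotypes (dosage pairs) from a 2-locus haplotype pool
sample_ld_genotypes <- function(f, n) {
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE)
  h1 <- sample.int(4L, n, replace = TRUE, prob = f)
  h2 <- sample.int(4L, n, replace = TRUE, prob = f)
  cbind(haps[h1, 1] + haps[h2, 1], haps[h1, 2] + haps[h2, 2])
}

#' Generate a SNP annotation table over the gene universe
#'
#' `n_snps` annotated SNPs are assigned to random genes with a realistic
#' consequence mix (mostly intronic/upstream/downstream, a coding and
#' regulatory minority); each LD pair adds a tag partner annotated as
#' intronic, so tags are never central by construction.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene universe (from [gen_network_snapshot()]).
#' @return List: `annotations` (long frame as [load_snp_table()]),
#'   `panel` (rsids to genotype), `ld_pairs` (frame `tag`, `central`,
#'   `target_r2`, `maf_a`, `maf_b`).
#' @export
gen_snp_annotations <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "snps"))
  terms <- c("INTRONIC", "UPSTREAM", "DOWNSTREAM", "WITHIN_NON_CODING_GENE",
             "NON_SYNONYMOUS_CODING", "SYNONYMOUS_CODING", "5PRIME_UTR",
             "3PRIME_UTR", "ESSENTIAL_SPLICE_SITE", "STOP_GAINED")
  probs <- c(0.38, 0.10, 0.10, 0.02, 0.18, 0.08, 0.05, 0.05, 0.03, 0.01)
  rsid <- sprintf("rs%06d", seq_len(cfg$n_snps))
  gene <- sample(genes, cfg$n_snps, replace = TRUE)
  cons <- sample(terms, cfg$n_snps, replace = TRUE, prob = probs)
  aa <- ifelse(cons == "NON_SYNONYMOUS_CODING",
               paste0(sample(LETTERS, cfg$n_snps, TRUE),
                      sample(50:500, cfg$n_snps, TRUE),
                      sample(LETTERS, cfg$n_snps, TRUE)),
               NA_character_)
  ann <- data.frame(
    rsid = rsid, gene = gene, chrom = as.character(sample(1:22, cfg$n_snps, TRUE)),
    pos = sample.int(5e7, cfg$n_snps),
    ref = sample(c("A", "C", "G", "T"), cfg$n_snps, TRUE),
    transcript = paste0("T", seq_len(cfg$n_snps), ".1"),
    consequence = cons, aa_change = aa, stringsAsFactors = FALSE)
  ann$alt <- vapply(ann$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  central_pool <- rsid[!(cons %in% excluded_consequences())]
  n_pairs <- min(cfg$n_ld_pairs, length(central_pool))
  ld_pairs <- data.frame(tag = character(0), central = character(0),
                         target_r2 = numeric(0), maf_a = numeric(0),
                         maf_b = numeric(0), stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    central_sel <- sample(central_pool, n_pairs)
    tags <- sprintf("rsT%05d", seq_len(n_pairs))
    mafs <- stats::runif(n_pairs, 0.2, 0.5)
    ld_pairs <- data.frame(tag = tags, central = central_sel,
                           target_r2 = rep_len(cfg$ld_target_r2, n_pairs),
                           maf_a = mafs, maf_b = mafs, stringsAsFactors = FALSE)
    tag_ann <- data.frame(
      rsid = tags, gene = ann$gene[match(central_sel, ann$rsid)],
      chrom = ann$chrom[match(central_sel, ann$rsid)],
      pos = ann$pos[match(central_sel, ann$rsid)] + sample.int(5000, n_pairs),
      ref = sample(c("A", "C", "G", "T"), n_pairs, TRUE),
      transcript = paste0("TT", seq_len(n_pairs), ".1"),
      consequence = "INTRONIC", aa_change = NA_character_,
      stringsAsFactors = FALSE)
    tag_ann$alt <- vapply(tag_ann$ref,
                          function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    ann <- rbind(ann, tag_ann)
  }
  ann <- ann[, c("rsid", "gene", "chrom", "pos", "ref", "alt", "transcript",
                 "consequence", "aa_change")]
  list(annotations = ann, panel = ann$rsid, ld_pairs = ld_pairs)
}

#' Generate genotypes, confidences and clinical survival records
#'
#' LD-pair SNPs are drawn as two haplotypes per sample from their solved
#' pool; all other panel SNPs are independent `Binomial(2, maf)` draws under
#' Hardy-Weinberg. Missing calls and sub-threshold confidences are injected
#' at the configured rates. Survival times are exponential with hazard
#' `baseline_hazard * hazard_ratio^dosage` at the optional effect SNP;
#' censoring is independent exponential with its rate solved from the
#' target censoring fraction.
#'
#' @param cfg A [sim_config()].
#' @param panel Character vector of rsids to genotype.
#' @param ld_pairs LD-pair frame from [gen_snp_annotations()] (may be empty).
#' @return List: `genotypes` (a [genotype_matrix()] with confidences),
#'   `clinical` (frame `sample`, `time`, `event`, `snr`), `truth` (list of
#'   generating parameters).
#' @export
gen_genotypes_and_clinical <- function(cfg, panel, ld_pairs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "genotypes"))
  n <- cfg$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  dosage <- matrix(NA_integer_, length(panel), n,
                   dimnames = list(panel, samples))
  maf <- stats::setNames(stats::runif(length(panel), cfg$maf_range[1],
                                      cfg$maf_range[2]), panel)
  in_pair <- character(0)
  if (!is.null(ld_pairs) && nrow(ld_pairs)) {
    for (i in seq_len(nrow(ld_pairs))) {
      f <- gen_haplotype_pool(ld_pairs$maf_a[i], ld_pairs$maf_b[i],
                              ld_pairs$target_r2[i])
      gt <- sample_ld_genotypes(f, n)
      dosage[ld_pairs$tag[i], ] <- gt[, 1]
      dosage[ld_pairs$central[i], ] <- gt[, 2]
      maf[c(ld_pairs$tag[i], ld_pairs$central[i])] <-
        c(ld_pairs$maf_a[i], ld_pairs$maf_b[i])
    }
    in_pair <- c(ld_pairs$tag, ld_pairs$central)
  }
  for (s in setdiff(panel, in_pair)) {
    dosage[s, ] <- stats::rbinom(n, 2L, maf[s])
  }
  # missingness, then confidences: a fraction of calls get low confidence
  miss <- matrix(stats::runif(length(dosage)) < cfg$missing_rate,
                 nrow(dosage), ncol(dosage))
  dosage[miss] <- NA_integer_
  conf <- matrix(stats::runif(length(dosage), 0.95, 1),
                 nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  low <- matrix(stats::runif(length(dosage)) < cfg$confidence_noise,
                nrow(dosage), ncol(dosage))
  conf[low] <- stats::runif(sum(low), 0, 0.95)
  ref <- rep("A", length(panel))
  alt <- rep("G", length(panel))
  g <- genotype_matrix(dosage, ref, alt, conf)

  set.seed(derive_seed(cfg$seed, "clinical"))
  hazard <- rep(cfg$baseline_hazard, n)
  if (!is.null(cfg$effect_snp)) {
    es <- cfg$effect_snp
    if (!es$rsid %in% panel) stop("effect_snp not on the panel: ", es$rsid)
    dos <- dosage[es$rsid, ]
    dos[is.na(dos)] <- 0L
    hazard <- hazard * es$hazard_ratio^dos
  }
  t_event <- stats::rexp(n, hazard)
  if (cfg$censoring_rate > 0) {
    cens_rate <- cfg$baseline_hazard * cfg$censoring_rate / (1 - cfg$censoring_rate)
    t_cens <- stats::rexp(n, cens_rate)
  } else {
    t_cens <- rep(Inf, n)
  }
  clinical <- data.frame(sample = samples,
                         time = round(pmin(t_event, t_cens), 6),
                         event = as.integer(t_event <= t_cens),
                         snr = round(stats::rnorm(n, 10, 2), 3),
                         stringsAsFactors = FALSE)
  list(genotypes = g, clinical = clinical,
       truth = list(maf = maf, effect_snp = cfg$effect_snp,
                    censoring_rate = cfg$censoring_rate))
}

#' Generate the four predictor score tables
#'
#' A configured fraction of the non-synonymous SNPs is made concordantly
#' damaging across all four predictors (probably_damaging, negative SNPs3D
#' score, SIFT below 0.05); the rest receive benign or discordant values.
#'
#' @param cfg A [sim_config()].
#' @param annotations Annotation frame from [gen_snp_annotations()].
#' @return Named list of four data frames (`rsid`, `value`).
#' @export
gen_predictor_tables <- function(cfg, annotations) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "predictors"))
  nonsyn <- unique(annotations$rsid[annotations$consequence == "NON_SYNONYMOUS_CODING"])
  n <- length(nonsyn)
  if (!n) {
    empty <- data.frame(rsid = character(0), value = character(0),
                        stringsAsFactors = FALSE)
    return(list(polyphen = empty, polyphen2 = empty, snps3d = empty, sift = empty))
  }
  damaging <- stats::runif(n) < cfg$predictor_damaging_fraction
  cat_val <- function(dmg) {
    ifelse(dmg, sample(c("possibly_damaging", "probably_damaging"), n, TRUE),
           sample(c("benign", "benign", "possibly_damaging"), n, TRUE))
  }
  list(
    polyphen = data.frame(rsid = nonsyn, value = cat_val(damaging),
                          stringsAsFactors = FALSE),
    polyphen2 = data.frame(rsid = nonsyn, value = cat_val(damaging),
                           stringsAsFactors = FALSE),
    snps3d = data.frame(rsid = nonsyn,
                        value = round(ifelse(damaging,
                                             -stats::runif(n, 0.1, 2),
                                             stats::rnorm(n, 0.8, 0.5)), 4),
                        stringsAsFactors = FALSE),
    sift = data.frame(rsid = nonsyn,
                      value = round(ifelse(damaging, stats::runif(n, 0, 0.049),
                                           stats::runif(n, 0.05, 1)), 4),
                      stringsAsFactors = FALSE))
}

#' Write a pathway frame as GMT
#' @param pathways Frame from [load_pathway_db()]/[gen_network_snapshot()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(seq_len(nrow(pathways)), function(i) {
    paste(c(pathways$pathway_id[i], pathways$name[i], pathways$members[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an edge frame as SIF
#' @param edges Frame with columns `a`, `b` (and optional `source`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(edges, path) {
  src <- if ("source" %in% names(edges)) edges$source else "pp"
  writeLines(paste(edges$a, src, edges$b, sep = "\t"), path)
  invisible(path)
}

#' Generate and write a complete synthetic input set
#'
#' Writes every file the pipeline consumes, plus a JSON manifest of the true
#' generating parameters for recovery tests: `pathways.gmt`, `ppi.sif`,
#' `aliases.tsv`, `queries.tsv`, `snps.tsv`, `genotypes.tsv`,
#' `confidence.tsv`, `clinical.tsv`, `predictor_*.tsv`, `manifest.json`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param n_queries Number of candidate genes to sample as the query list.
#' @return Invisibly, a named list of the written paths.
#' @export
gen_dataset <- function(cfg, outdir, n_queries = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  net <- gen_network_snapshot(cfg)
  snp <- gen_snp_annotations(cfg, net$genes)
  dat <- gen_genotypes_and_clinical(cfg, snp$panel, snp$ld_pairs)
  pred <- gen_predictor_tables(cfg, snp$annotations)
  set.seed(derive_seed(cfg$seed, "network"))
  # prefer query genes that actually occur in a pathway, so expansion has
  # something to find (a query absent everywhere is still legal input)
  pool <- unique(unlist(net$pathways$members))
  if (length(pool) < n_queries) pool <- net$genes
  queries <- sort(sample(pool, n_queries))
  p <- function(f) file.path(outdir, f)
  write_gmt(net$pathways, p("pathways.gmt"))
  write_sif(net$edges, p("ppi.sif"))
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(data.frame(alias = names(net$aliases), symbol = unname(net$aliases)),
     "aliases.tsv")
  wt(data.frame(query = queries), "queries.tsv")
  ann <- snp$annotations
  wt(data.frame(rsid = ann$rsid, gene = ann$gene, chrom = ann$chrom,
                pos = ann$pos, alleles = paste(ann$ref, ann$alt, sep = "/"),
                transcript = ann$transcript, consequence = ann$consequence,
                aa_change = ifelse(is.na(ann$aa_change), "", ann$aa_change)),
     "snps.tsv")
  write_genotypes(dat$genotypes, p("genotypes.tsv"), p("confidence.tsv"))
  wt(dat$clinical, "clinical.tsv")
  for (nm in names(pred)) wt(pred[[nm]], paste0("predictor_", nm, ".tsv"))
  manifest <- list(seed = cfg$seed, n_samples = cfg$n_samples,
                   n_snps = cfg$n_snps, queries = queries,
                   ld_pairs = snp$ld_pairs, effect_snp = cfg$effect_snp,
                   censoring_rate = cfg$censoring_rate,
                   baseline_hazard = cfg$baseline_hazard)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(pathways = p("pathways.gmt"), ppi = p("ppi.sif"),
             aliases = p("aliases.tsv"), queries = p("queries.tsv"),
             snps = p("snps.tsv"), genotypes = p("genotypes.tsv"),
             confidence = p("confidence.tsv"), clinical = p("clinical.tsv"),
             polyphen = p("predictor_polyphen.tsv"),
             polyphen2 = p("predictor_polyphen2.tsv"),
             snps3d = p("predictor_snps3d.tsv"),
             sift = p("predictor_sift.tsv"), manifest = p("manifest.json"))
  invisible(files)
}
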