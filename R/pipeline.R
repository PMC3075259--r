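#' Validate and normalize a pipeline run configuration
#'
#' Accepts a list or a YAML file path. Required fields: `queries` (file with
#' one gene/accession per line after a header) or `pathway_names`,
#' `pathway_db`, `snps`, `genotypes`, `clinical`, `outdir`. Optional:
#' `ppi`, `aliases`, `confidence`, `predictors` (named list of the four
#' predictor TSVs), `pathway_format` ("gmt"/"tsv"), `filter_mode`,
#' `r2_threshold`, `r2_method`, `qc` (named list passed to [qc_params()]),
#' `alpha`, `merge_homo_freq`.
#'
#' @param config List or YAML path.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(pathway_format = "gmt", filter_mode = "any_transcript",
                   r2_threshold = 0.8, r2_method = "em", alpha = 0.05,
                   merge_homo_freq = 0.10, qc = list(), ppi = NULL,
                   aliases = NULL, confidence = NULL, predictors = NULL,
                   pathway_names = NULL, queries = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[nm] <- defaults[nm]
  }
  need <- c("pathway_db", "snps", "genotypes", "clinical", "outdir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  if (is.null(config$queries) && is.null(config$pathway_names)) {
    stop("config needs either 'queries' or 'pathway_names'")
  }
  if (!(config$alpha > 0 && config$alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(config$r2_threshold > 0 && config$r2_threshold <= 1)) {
    stop("r2_threshold must lie in (0, 1]")
  }
  for (f in c("pathway_db", "snps", "genotypes", "clinical", "ppi", "aliases",
              "confidence", "queries")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("input file for '", f, "' not found: ", config[[f]])
    }
  }
  class(config) <- c("run_config", "list")
  config
}

#' Write a result sheet as TSV
#'
#' Stable column order, one header row, UTF-8, plain decimal numbers,
#' empty string for missing values. Re-running on identical input produces
#' a byte-identical file.
#'
#' @param df Data frame (list columns are semicolon-joined).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_result_sheet <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) paste(x, collapse = ";"), "")
    } else if (is.numeric(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) {
        if (is.na(x)) "" else format(x, scientific = FALSE, trim = TRUE, digits = 10)
      }, "")
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

stage_log <- function(log, stage, n_in, n_out, note = "") {
  message(sprintf("[%s] in=%d out=%d %s", stage, n_in, n_out, note))
  rbind(log, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                        note = note, stringsAsFactors = FALSE))
}

#' Run the full candidate-gene SNP screening pipeline
#'
#' Stages execute in order: expand (focal genes) -> annotate/filter
#' (central SNPs) -> tag (LD links) -> predict (optional consensus) ->
#' survive (survival screen) -> map (central-hit accounting). Each stage
#' writes its TSV sheet into `outdir`; a JSON manifest with per-stage
#' record counts and the serialized configuration is written at the end.
#' A stage failure aborts with the stage name; earlier outputs remain on
#' disk.
#'
#' @param config A [run_config()] input (list or YAML path).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, NA)],
                       file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log <- data.frame()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- expand ---------------------------------------------------------------
  focal <- run_stage("expand", {
    pathways <- load_pathway_db(cfg$pathway_db, cfg$pathway_format)
    edges <- if (!is.null(cfg$ppi)) load_ppi(cfg$ppi) else
      data.frame(a = character(), b = character(), source = character(),
                 self_loop = logical())
    if (!is.null(cfg$queries)) {
      qdf <- utils::read.delim(cfg$queries, header = TRUE, colClasses = "character")
      aliases <- if (!is.null(cfg$aliases)) load_aliases(cfg$aliases) else NULL
      queries <- resolve_queries(qdf[[1]], aliases)
      expand_from_proteins(queries, pathways, edges)
    } else {
      expand_from_pathways(cfg$pathway_names, pathways)
    }
  })
  write_result_sheet(focal, file.path(cfg$outdir, "focal_genes.tsv"))
  log <- stage_log(log, "expand", NA_integer_, nrow(focal))

  # -- annotate / filter ----------------------------------------------------
  ann <- run_stage("annotate", {
    a <- load_snp_table(cfg$snps)
    a[a$gene %in% focal$gene, , drop = FALSE]
  })
  n_annotated <- length(unique(paste(ann$rsid, ann$gene)))
  central <- run_stage("annotate", filter_central(ann, mode = cfg$filter_mode))
  write_result_sheet(central, file.path(cfg$outdir, "central_snps.tsv"))
  log <- stage_log(log, "annotate", n_annotated, nrow(central))

  # -- tag ------------------------------------------------------------------
  g <- run_stage("tag", read_genotypes(cfg$genotypes, cfg$confidence))
  links <- run_stage("tag", {
    suppressWarnings(select_tags(intersect(central$rsid, snp_ids(g)),
                                 snp_ids(g), g,
                                 threshold = cfg$r2_threshold,
                                 method = cfg$r2_method))
  })
  write_result_sheet(links, file.path(cfg$outdir, "tag_links.tsv"))
  uni <- snp_universe(central$rsid, links$tag)
  log <- stage_log(log, "tag", length(snp_ids(g)), nrow(links),
                   sprintf("universe=%d", uni$n_union))

  # -- predict (optional) ---------------------------------------------------
  consensus <- character(0)
  if (!is.null(cfg$predictors) && length(cfg$predictors)) {
    agg <- run_stage("predict", {
      rows <- do.call(rbind, lapply(names(cfg$predictors), function(p) {
        load_predictor_table(cfg$predictors[[p]], p)
      }))
      aggregate_predictions(rows)
    })
    write_result_sheet(agg, file.path(cfg$outdir, "predictions.tsv"))
    consensus <- consensus_set(agg)
    log <- stage_log(log, "predict", nrow(agg), length(consensus),
                     "consensus set size")
  } else {
    message("[predict] skipped: no predictor tables configured")
  }

  # -- survive --------------------------------------------------------------
  surv <- run_stage("survive", {
    clinical <- utils::read.delim(cfg$clinical, header = TRUE)
    qp <- do.call(qc_params, c(cfg$qc,
                               list(merge_homo_freq = cfg$merge_homo_freq,
                                    alpha = cfg$alpha)))
    snr <- if ("snr" %in% names(clinical)) {
      stats::setNames(clinical$snr, clinical$sample)
    } else NULL
    qc <- qc_genotypes(g, qp, sample_snr = snr)
    array_snps <- intersect(snp_ids(qc$genotypes),
                            union(central$rsid, links$tag))
    res <- survival_screen(array_snps, qc$genotypes, clinical,
                           merge_homo_freq = cfg$merge_homo_freq,
                           alpha = cfg$alpha)
    res$qc_report <- qc$report
    res
  })
  write_result_sheet(surv$results, file.path(cfg$outdir, "survival_results.tsv"))
  n_sig <- if (nrow(surv$results)) sum(surv$results$significant) else 0L
  log <- stage_log(log, "survive", nrow(surv$results) + length(surv$untestable),
                   nrow(surv$results), sprintf("significant=%d", n_sig))

  # -- map ------------------------------------------------------------------
  hits <- map_to_central(surv$results, links, central$rsid)
  log <- stage_log(log, "map", n_sig, hits$n_total)
  write_result_sheet(log, file.path(cfg$outdir, "stage_log.tsv"))

  manifest <- list(
    n_focal_genes = nrow(focal),
    n_central_snps = nrow(central),
    n_tag_links = nrow(links),
    snp_universe = uni,
    n_consensus_functional = length(consensus),
    n_tested = nrow(surv$results),
    n_untestable = length(surv$untestable),
    n_significant = n_sig,
    central_hits = hits,
    qc = surv$qc_report[c("n_calls_masked", "n_snps_kept", "n_samples_kept")])
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
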