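# End-to-end orchestration: configuration, staged execution with a
# row-count log, and atomic CSV/JSON outputs.

#' Pipeline configuration
#'
#' Collects paths and thresholds for a full run. Defaults mirror the
#' screening conventions used throughout the package: significance 0.05,
#' drug eligibility at 1000 adverse-event rows, term eligibility at 2000
#' rows, three principal components, four clusters, monotherapy
#' filtering on.
#'
#' @param drug,reac paths to the DRUG and REAC tables (required).
#' @param demo,ther optional paths to the DEMO and THER tables.
#' @param smiles path to the drug-name to SMILES dictionary TSV.
#' @param terms path to the SMQ term-set TSV; `NULL` uses the packaged
#'   thrombosis set.
#' @param classes optional path to a drug-class TSV; `NULL` uses the
#'   packaged map.
#' @param allowlist optional path to a one-column TSV (`drug_name`) of
#'   names force-included in the cohort.
#' @param out_dir output directory.
#' @param alpha,min_drug_reports,min_pt_reports,n_components,n_clusters
#'   screening and multivariate thresholds.
#' @param monotherapy logical; restrict to single-drug cases.
#' @param suspect_only logical; count only suspect drugs for the
#'   monotherapy rule.
#' @param bh logical; Benjamini-Hochberg flag rule.
#' @param covariance_pca logical; covariance- instead of correlation-scale
#'   PCA.
#' @param market_cutoff_year optional year for the in-market report
#'   (requires `ther`); `NULL` skips it.
#' @param delim input field delimiter.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(drug, reac, smiles, out_dir,
                            demo = NULL, ther = NULL, terms = NULL,
                            classes = NULL, allowlist = NULL,
                            alpha = 0.05, min_drug_reports = 1000,
                            min_pt_reports = 2000, n_components = 3,
                            n_clusters = 4, monotherapy = TRUE,
                            suspect_only = FALSE, bh = FALSE,
                            covariance_pca = FALSE,
                            market_cutoff_year = NULL, delim = "$") {
  cfg <- list(drug = drug, reac = reac, smiles = smiles, out_dir = out_dir,
              demo = demo, ther = ther, terms = terms, classes = classes,
              allowlist = allowlist, alpha = alpha,
              min_drug_reports = min_drug_reports,
              min_pt_reports = min_pt_reports, n_components = n_components,
              n_clusters = n_clusters, monotherapy = monotherapy,
              suspect_only = suspect_only, bh = bh,
              covariance_pca = covariance_pca,
              market_cutoff_year = market_cutoff_year, delim = delim)
  stopifnot(alpha > 0, alpha < 1, min_drug_reports >= 1,
            min_pt_reports >= 0, n_components >= 1, n_clusters >= 1)
  for (p in c(drug, reac, smiles, demo, ther, terms, classes, allowlist)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("pipeline input does not exist: ", p, call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.atomic_write <- function(writer, x, path) {
  tmp <- paste0(path, ".tmp")
  writer(x, tmp)
  file.rename(tmp, path)
  path
}

#' Run the full signal-detection pipeline
#'
#' Executes all stages in order -- ingestion, integration, deduplication,
#' (optional) monotherapy filtering, cohort selection, signal scan,
#' stratified and class summaries, signal matrix, PCA, Ward clustering
#' and exports -- writing CSV/JSON outputs, a volcano plot, a resolved
#' copy of the configuration and a stage-by-stage row-count log under
#' `out_dir`. Outputs are written atomically (temp file then rename).
#'
#' Stages that need inputs the configuration did not provide (DEMO for
#' sex strata, THER for the market report) are skipped with a log note;
#' the multivariate block is skipped when fewer than two drugs are
#' flagged or fewer than two terms survive the report-count filter.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main intermediate objects
#'   (`rows`, `cohort`, `signals`, `strata`, `classes`, `matrix`, `pca`,
#'   `tree`, `clusters`, `counts`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- character()
  note <- function(stage, ...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " | ", stage,
                   " | ", paste0(..., collapse = ""))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  counts <- list()

  drug_tbl <- read_faers(config$drug, "drug", delim = config$delim)
  reac_tbl <- read_faers(config$reac, "reac", delim = config$delim)
  counts$drug_records <- nrow(drug_tbl)
  counts$reac_records <- nrow(reac_tbl)
  note("ingest", "drug=", nrow(drug_tbl), " reac=", nrow(reac_tbl))

  rows <- integrate_reports(drug_tbl, reac_tbl)
  counts$integrated <- nrow(rows)
  note("integrate", "rows=", nrow(rows))
  rows <- dedup_reports(rows)
  counts$deduplicated <- nrow(rows)
  note("deduplicate", "rows=", nrow(rows))
  if (config$monotherapy) {
    rows <- monotherapy_filter(rows, drug_tbl = drug_tbl,
                               suspect_only = config$suspect_only)
    counts$monotherapy <- nrow(rows)
    note("monotherapy", "rows=", nrow(rows))
  }

  dict <- read_smiles_dict(config$smiles)
  allow <- if (!is.null(config$allowlist)) {
    readr::read_tsv(config$allowlist, col_types = "c",
                    progress = FALSE)$drug_name
  }
  cohort <- build_cohort(unique(rows$drug_name), dict, allowlist = allow)
  counts$cohort <- length(cohort$cohort)
  note("cohort", "matched=", length(cohort$cohort),
       " unmapped=", length(cohort$unmapped),
       " invalid=", length(cohort$invalid))

  terms <- if (is.null(config$terms)) thrombosis_terms() else
    read_term_set(config$terms)
  note("terms", "n=", nrow(terms))

  signals <- signal_scan(rows, cohort$cohort, terms, alpha = config$alpha,
                         min_drug_reports = config$min_drug_reports,
                         bh = config$bh)
  counts$flagged <- sum(signals$flagged)
  note("signal_scan", "drugs=", nrow(signals), " flagged=",
       sum(signals$flagged))
  .atomic_write(function(x, p) readr::write_csv(x, p), signals,
                file.path(config$out_dir, "signals.csv"))
  .atomic_write(function(x, p) readr::write_csv(x, p),
                cohort$report, file.path(config$out_dir, "cohort.csv"))
  vp <- plot_volcano(signals, alpha = config$alpha)
  ggplot2::ggsave(file.path(config$out_dir, "volcano.png"), vp,
                  width = 7, height = 5, dpi = 150)

  strata_out <- NULL
  demo_tbl <- NULL
  if (!is.null(config$demo)) {
    demo_tbl <- read_faers(config$demo, "demo", delim = config$delim)
    sex_res <- stratified_ror(rows, case_strata(demo = demo_tbl, by = "sex"),
                              terms)
    sex_res$stratification <- "sex"
    route_res <- stratified_ror(rows,
                                case_strata(drug = drug_tbl, by = "route"),
                                terms)
    route_res$stratification <- "route"
    strata_out <- dplyr::bind_rows(sex_res, route_res)
    .atomic_write(function(x, p) readr::write_csv(x, p), strata_out,
                  file.path(config$out_dir, "strata.csv"))
    age_res <- tryCatch(age_comparison(rows, demo_tbl, terms),
                        error = function(e) NULL)
    if (!is.null(age_res)) {
      .atomic_write(function(x, p) jsonlite::write_json(x, p,
                                                        auto_unbox = TRUE,
                                                        digits = NA),
                    age_res, file.path(config$out_dir, "age_comparison.json"))
    }
    note("strata", "sex+route strata written")
  } else {
    note("strata", "skipped (no demo table)")
  }

  class_out <- NULL
  class_map <- if (is.null(config$classes)) steroid_drug_classes() else
    read_class_map(config$classes)
  class_out <- suppressWarnings(
    class_summary(signals, class_map, rows, terms))
  .atomic_write(function(x, p) readr::write_csv(x, p), class_out,
                file.path(config$out_dir, "class_summary.csv"))
  note("class_summary", "classes=", nrow(class_out))

  if (!is.null(config$ther) && !is.null(config$market_cutoff_year)) {
    ther_tbl <- read_faers(config$ther, "ther", delim = config$delim)
    current <- market_filter(ther_tbl, config$market_cutoff_year)
    .atomic_write(function(x, p) readr::write_csv(x, p),
                  tibble::tibble(drug_name = current),
                  file.path(config$out_dir, "in_market.csv"))
    note("market", "current=", length(current))
  }

  mat <- NULL; pca <- NULL; tree <- NULL; clusters <- NULL
  flagged <- signals$drug_name[signals$flagged]
  if (length(flagged) >= 2) {
    mat <- tryCatch(
      build_signal_matrix(rows, flagged, terms$pt,
                          min_pt_reports = config$min_pt_reports),
      error = function(e) NULL)
  }
  if (!is.null(mat) && ncol(mat) >= 2) {
    .atomic_write(function(x, p) {
      readr::write_csv(tibble::as_tibble(x, rownames = "drug_name"), p)
    }, mat, file.path(config$out_dir, "matrix.csv"))
    pca <- signal_pca(mat, scale = !config$covariance_pca)
    .atomic_write(function(x, p) {
      readr::write_csv(tibble::as_tibble(x, rownames = "pt"), p)
    }, pca$loadings, file.path(config$out_dir, "pca_loadings.csv"))
    .atomic_write(function(x, p) {
      readr::write_csv(tibble::as_tibble(x, rownames = "drug_name"), p)
    }, pca$scores, file.path(config$out_dir, "pca_scores.csv"))
    .atomic_write(function(x, p) readr::write_csv(x, p),
                  tibble::tibble(component = seq_along(pca$explained_ratio),
                                 explained_ratio = pca$explained_ratio),
                  file.path(config$out_dir, "explained.csv"))
    tree <- ward_cluster(pca$scores, n_components = config$n_components)
    clusters <- cut_clusters(tree, min(config$n_clusters,
                                       length(tree$order)))
    export_dendrogram(tree, config$out_dir, scores = pca$scores,
                      k = config$n_clusters)
    axis_cmp <- tryCatch(smq_axis_comparison(pca, terms, component = 2),
                         error = function(e) NULL)
    if (!is.null(axis_cmp)) {
      .atomic_write(function(x, p) jsonlite::write_json(x, p,
                                                        auto_unbox = TRUE,
                                                        digits = NA),
                    axis_cmp, file.path(config$out_dir, "smq_axis.json"))
    }
    note("multivariate", "matrix=", nrow(mat), "x", ncol(mat),
         " clusters=", length(unique(clusters)))
  } else {
    note("multivariate", "skipped (", length(flagged), " flagged drug(s))")
  }

  cfg_plain <- unclass(config)
  .atomic_write(function(x, p) yaml::write_yaml(x, p),
                cfg_plain[!vapply(cfg_plain, is.null, logical(1))],
                file.path(config$out_dir, "resolved_config.yaml"))
  writeLines(log_lines, log_path)
  invisible(list(rows = rows, cohort = cohort, signals = signals,
                 strata = strata_out, classes = class_out, matrix = mat,
                 pca = pca, tree = tree, clusters = clusters,
                 counts = counts))
}
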