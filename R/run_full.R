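#' Run the full biomarker pipeline
#'
#' Executes the complete analysis on either a simulated dataset (from a
#' [sim_config()]) or data read from files: rare-OTU filtering, Jaccard
#' randomization outlier screening (flagged samples removed from both
#' blocks), upper-quartile normalization and abundance-shift screening of the
#' OTU block; log2 transform, observation filter, median centering and
#' mixed-effects treatment tests of the metabolite block; log2 transform,
#' half-minimum imputation and median centering for the classification
#' branch; then per-treatment per-OTU presence/absence forests, the balanced
#' accuracy gate, and biomarker ranking. A manifest records seeds, configs
#' and feature/sample counts at every stage.
#'
#' @param input A [sim_config()], an `om_dataset`, or a named list
#'   `list(otus=, metabolites=, meta=)` of already-loaded containers.
#' @param config A [pipeline_config()].
#' @param params A [processing_params()].
#' @param master_seed Master seed; every stochastic stage derives its own
#'   stream from it. Defaults to the simulation seed (or 1 for file input).
#' @param outdir Optional directory; when given, writes
#'   `model_summaries.tsv`, `importance_matrix.tsv`, `strong_pairs.tsv`,
#'   `metabolite_ranking.tsv`, `otu_shift_tests.tsv`,
#'   `metabolite_tests.tsv`, and `manifest.json`.
#' @param run_univariate Set `FALSE` to skip the univariate stage (the
#'   classification branch does not depend on it).
#' @return A list of class `pipeline_result`: `rankings` (per treatment),
#'   `models` (per treatment `treatment_models`), `univariate`
#'   (metabolite and OTU test tables), `processed` (post-processing blocks),
#'   `manifest`.
#' @export
run_full_pipeline <- function(input = sim_config(),
                              config = pipeline_config(),
                              params = processing_params(),
                              master_seed = NULL,
                              outdir = NULL,
                              run_univariate = TRUE) {
  if (inherits(input, "sim_config")) {
    master_seed <- master_seed %||% input$seed
    dataset <- simulate_dataset(input)
  } else if (inherits(input, "om_dataset")) {
    master_seed <- master_seed %||% input$config$seed
    dataset <- input
  } else if (is.list(input) && all(c("otus", "metabolites", "meta") %in% names(input))) {
    master_seed <- master_seed %||% 1L
    dataset <- input
  } else {
    stop("input must be a sim_config, an om_dataset, or a list(otus, metabolites, meta)")
  }
  meta <- dataset$meta
  otus <- dataset$otus
  metab <- dataset$metabolites
  check_alignment(rownames(otus$counts), meta, "OTU table")
  check_alignment(rownames(metab$values), meta, "metabolite matrix")

  manifest <- list(
    package = "otumarker",
    version = as.character(packageVersion("otumarker")),
    master_seed = master_seed,
    configs = list(pipeline = unclass(config),
                   processing = unclass(params),
                   forest = unclass(config$forest),
                   simulation = if (!is.null(dataset$config))
                     unclass(dataset$config) else NULL),
    stages = list()
  )
  stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  stage("input",
        n_samples = nrow(meta),
        samples_per_treatment = as.list(table(meta$treatment)),
        n_otus = ncol(otus$counts),
        n_metabolites = ncol(metab$values))

  # --- OTU branch: outlier screen, rare-OTU filter, UQ normalization -------
  outliers <- detect_sample_outliers(otus, params,
                                     seed = seed_from(master_seed, "outlier"))
  drop_ids <- outliers$sample_id[outliers$flagged]
  if (length(drop_ids)) {
    keep <- !(meta$sample_id %in% drop_ids)
    meta <- droplevels(meta[keep, , drop = FALSE])
    otus <- otu_count_table(otus$counts[keep, , drop = FALSE], otus$taxonomy)
    metab$values <- metab$values[keep, , drop = FALSE]
  }
  stage("outlier_screen",
        flagged_samples = as.list(drop_ids),
        n_samples_retained = nrow(meta))

  otus_before <- ncol(otus$counts)
  otus <- filter_rare_otus(otus, params$min_otu_samples)
  stage("rare_otu_filter",
        n_otus_before = otus_before,
        n_otus_removed = otus_before - ncol(otus$counts),
        n_otus_retained = ncol(otus$counts))
  normalized <- upper_quartile_normalize(otus)

  # --- metabolite branches ---------------------------------------------------
  logm <- log2_transform(metab)
  # univariate branch: observation filter, center, keep missing as NA
  uni_metab <- filter_metabolites_for_univariate(logm, meta, params)
  uni_metab <- median_center(uni_metab)
  stage("metabolite_filter",
        n_metabolites_before = ncol(logm$values),
        n_metabolites_retained = ncol(uni_metab$values))
  # classification branch: impute then center, no observation filter
  rf_metab <- median_center(impute_half_minimum(logm))
  stage("imputation", imputation_value = rf_metab$imputation_value)

  # --- univariate stage ------------------------------------------------------
  univariate <- NULL
  if (run_univariate) {
    metab_tests <- with_seed(seed_from(master_seed, "univariate"), {
      suppressWarnings(test_metabolite_shifts(uni_metab, meta))
    })
    otu_tests <- test_otu_abundance_shifts(normalized, meta)
    univariate <- list(metabolites = metab_tests, otus = otu_tests)
    stage("univariate",
          n_metabolite_contrasts = nrow(metab_tests),
          n_significant_metabolite_contrasts = sum(metab_tests$p_adjusted < 0.05),
          n_otu_contrasts = nrow(otu_tests),
          n_significant_otu_contrasts = sum(otu_tests$significant))
  }

  # --- classification + ranking ---------------------------------------------
  fcfg <- config
  fcfg$forest$seed <- seed_from(master_seed, "forest")
  treatments <- levels(droplevels(meta$treatment))
  models <- list()
  rankings <- list()
  for (tr in treatments) {
    mod <- fit_models_for_treatment(otus, rf_metab, meta, tr, fcfg)
    models[[tr]] <- mod
    rankings[[tr]] <- suppressWarnings(rank_biomarkers(mod, fcfg))
    stage(paste0("classify_", tr),
          n_eligible_otus = nrow(mod$summaries),
          n_retained_models = length(rankings[[tr]]$retained_models),
          n_strong_pairs = nrow(rankings[[tr]]$strong_pairs))
  }
  if (config$pooling_scope == "global") {
    rankings <- rank_biomarkers_global(models, fcfg)
  }

  result <- structure(list(rankings = rankings, models = models,
                           univariate = univariate,
                           processed = list(meta = meta, otus = otus,
                                            normalized = normalized,
                                            metabolites_rf = rf_metab,
                                            metabolites_univariate = uni_metab,
                                            outliers = outliers),
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(result, outdir)
  result
}

# Global pooling: one importance cutoff across the retained models of all
# treatments (the per-treatment default mirrors how the treatments are
# reported separately).
rank_biomarkers_global <- function(models, config) {
  pool <- unlist(lapply(models, function(m) {
    s <- m$summaries
    kept <- s$otu_id[s$balanced_accuracy >= config$balanced_accuracy_threshold]
    as.vector(m$importance[kept, , drop = FALSE])
  }))
  cutoff <- if (length(pool)) {
    quantile(pool, 1 - config$importance_top_fraction, type = 7, names = FALSE)
  } else NA_real_
  lapply(models, function(m) {
    r <- suppressWarnings(rank_biomarkers(m, config))
    if (length(r$retained_models) && !is.na(cutoff)) {
      Mr <- m$importance[r$retained_models, , drop = FALSE]
      hit <- which(Mr >= cutoff, arr.ind = TRUE)
      r$pooled_importance_cutoff <- cutoff
      r$strong_pairs <- data.frame(metabolite = colnames(Mr)[hit[, 2]],
                                   otu_id = rownames(Mr)[hit[, 1]],
                                   importance = Mr[hit],
                                   stringsAsFactors = FALSE)
      r$strong_pairs <- r$strong_pairs[order(-r$strong_pairs$importance), ,
                                       drop = FALSE]
      rownames(r$strong_pairs) <- NULL
    }
    r
  })
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$manifest$stages
  cat(sprintf("<pipeline_result> %d samples; %d OTUs retained; imputation value %.7g\n",
              s$outlier_screen$n_samples_retained,
              s$rare_otu_filter$n_otus_retained,
              s$imputation$imputation_value))
  for (tr in names(x$rankings)) print(x$rankings[[tr]])
  invisible(x)
}

# Write all pipeline artifacts as TSV plus the JSON manifest.
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summaries <- do.call(rbind, lapply(result$models, `[[`, "summaries"))
  rownames(summaries) <- NULL
  write.table(summaries, file.path(outdir, "model_summaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- do.call(rbind, lapply(names(result$models), function(tr) {
    m <- result$models[[tr]]$importance
    if (nrow(m) == 0) return(NULL)
    data.frame(treatment = tr, otu_id = rownames(m), m,
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  if (!is.null(imp)) {
    write.table(imp, file.path(outdir, "importance_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  pairs <- do.call(rbind, lapply(names(result$rankings), function(tr) {
    sp <- result$rankings[[tr]]$strong_pairs
    if (nrow(sp) == 0) return(NULL)
    cbind(treatment = tr, sp, stringsAsFactors = FALSE)
  }))
  write.table(pairs %||% data.frame(treatment = character(),
                                    metabolite = character(),
                                    otu_id = character(),
                                    importance = numeric()),
              file.path(outdir, "strong_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ranks <- do.call(rbind, lapply(names(result$rankings), function(tr) {
    mr <- result$rankings[[tr]]$metabolite_rank
    if (nrow(mr) == 0) return(NULL)
    cbind(treatment = tr, mr, stringsAsFactors = FALSE)
  }))
  write.table(ranks %||% data.frame(treatment = character(),
                                    metabolite = character(),
                                    mean_importance = numeric()),
              file.path(outdir, "metabolite_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$univariate)) {
    write.table(result$univariate$metabolites,
                file.path(outdir, "metabolite_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$univariate$otus,
                file.path(outdir, "otu_shift_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outdir)
}
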