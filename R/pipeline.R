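#' Pipeline configuration
#'
#' Thresholds for the per-OTU presence/absence modelling stage: eligibility
#' floors (an OTU must be present in at least `min_present` and absent in at
#' least `min_absent` of a treatment's samples), the out-of-bag balanced
#' accuracy gate models must pass, and the pooled variable-importance
#' fraction defining "strong predictor" metabolites.
#'
#' @param min_present,min_absent Eligibility floors within a treatment.
#' @param balanced_accuracy_threshold Gate on out-of-bag balanced accuracy.
#' @param importance_top_fraction Fraction of pooled importance scores
#'   (across retained models) counted as strong.
#' @param forest A [forest_params()].
#' @param pooling_scope `"per-treatment"` (default) or `"global"`.
#' @param gate_first If `TRUE` (default), only models passing the gate
#'   contribute scores to the pooled importance quantile.
#' @param tie_rule Out-of-bag vote tie rule, see [oob_predict()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_present = 3, min_absent = 3,
                            balanced_accuracy_threshold = 0.80,
                            importance_top_fraction = 0.20,
                            forest = forest_params(),
                            pooling_scope = c("per-treatment", "global"),
                            gate_first = TRUE,
                            tie_rule = "present") {
  pooling_scope <- match.arg(pooling_scope)
  cfg <- list(min_present = as.integer(min_present),
              min_absent = as.integer(min_absent),
              balanced_accuracy_threshold = as.numeric(balanced_accuracy_threshold),
              importance_top_fraction = as.numeric(importance_top_fraction),
              forest = forest,
              pooling_scope = pooling_scope,
              gate_first = isTRUE(gate_first),
              tie_rule = tie_rule)
  if (cfg$min_present < 1 || cfg$min_absent < 1) {
    stop("min_present and min_absent must be >= 1")
  }
  if (cfg$balanced_accuracy_threshold < 0 || cfg$balanced_accuracy_threshold > 1) {
    stop("balanced_accuracy_threshold must lie in [0, 1]")
  }
  if (cfg$importance_top_fraction <= 0 || cfg$importance_top_fraction > 1) {
    stop("importance_top_fraction must lie in (0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

#' Binarize OTU counts to presence/absence
#'
#' An OTU is present in a sample iff its count is nonzero.
#'
#' @param counts Non-negative per-sample counts for one OTU.
#' @return Logical presence vector.
#' @export
binarize_otu <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts > 0
}

#' Select OTUs eligible for classification within a treatment
#'
#' Within the treatment's samples only, returns OTUs present in at least
#' `min_present` samples and absent in at least `min_absent` samples. OTUs
#' present (or absent) nearly everywhere carry no class contrast to learn.
#'
#' @param table An [otu_count_table()].
#' @param meta Sample metadata aligned to the table.
#' @param treatment Treatment label.
#' @param config A [pipeline_config()].
#' @return Character vector of eligible OTU IDs.
#' @export
select_eligible_otus <- function(table, meta, treatment,
                                 config = pipeline_config()) {
  check_alignment(rownames(table$counts), meta, "OTU table")
  idx <- which(meta$treatment == treatment)
  if (length(idx) < config$min_present + config$min_absent) {
    stop(sprintf("insufficient samples in treatment %s (%d < %d)", treatment,
                 length(idx), config$min_present + config$min_absent))
  }
  present <- colSums(table$counts[idx, , drop = FALSE] > 0)
  absent <- length(idx) - present
  colnames(table$counts)[present >= config$min_present &
                           absent >= config$min_absent]
}

#' Balanced accuracy
#'
#' The mean of the true-positive and true-negative rates,
#' `(TPR + TNR) / 2`; equal to plain accuracy whenever the truth labels are
#' balanced. `NA` predictions are dropped pairwise.
#'
#' @param truth Logical (or 0/1) true labels; both classes must occur.
#' @param predicted Logical (or 0/1) predictions of the same length.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("vectors must have equal length")
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  ok <- !is.na(predicted) & !is.na(truth)
  truth <- truth[ok]; predicted <- predicted[ok]
  if (!any(truth) || all(truth)) {
    stop("metric undefined: truth must contain both classes")
  }
  tpr <- sum(predicted & truth) / sum(truth)
  tnr <- sum(!predicted & !truth) / sum(!truth)
  (tpr + tnr) / 2
}

#' Fit per-OTU presence/absence forests for one treatment
#'
#' For each eligible OTU within the treatment's samples, fits a random forest
#' predicting its binarized presence from the processed (imputed,
#' median-centered log2) metabolite profiles, collects out-of-bag
#' predictions, balanced accuracy and mean-decrease-Gini importance. Each
#' OTU's forest is seeded by a deterministic hash of the master seed and the
#' OTU ID, so adding or removing OTUs never perturbs other models.
#'
#' @param otus An [otu_count_table()].
#' @param metab A fully imputed [metabolite_matrix()] with
#'   `scale = "log2-centered"`.
#' @param meta Sample metadata aligned to both blocks.
#' @param treatment Treatment label.
#' @param config A [pipeline_config()].
#' @return An object of class `treatment_models`: list with `treatment`,
#'   `summaries` (data.frame: otu_id, treatment, n_present, n_absent,
#'   true_positive_rate, true_negative_rate, balanced_accuracy),
#'   `importance` (models-by-metabolites matrix), and `oob_predictions`.
#' @export
fit_models_for_treatment <- function(otus, metab, meta, treatment,
                                     config = pipeline_config()) {
  stopifnot(inherits(otus, "otu_count_table"),
            inherits(metab, "metabolite_matrix"))
  if (metab$scale != "log2-centered" || anyNA(metab$values)) {
    stop("metabolite matrix must be imputed and median-centered (scale log2-centered)")
  }
  check_alignment(rownames(otus$counts), meta, "OTU table")
  check_alignment(rownames(metab$values), meta, "metabolite matrix")
  eligible <- select_eligible_otus(otus, meta, treatment, config)
  idx <- which(meta$treatment == treatment)
  X <- metab$values[idx, , drop = FALSE]
  summaries <- vector("list", length(eligible))
  imp <- matrix(NA_real_, length(eligible), ncol(X),
                dimnames = list(eligible, sort(colnames(X))))
  oob <- matrix(NA, length(eligible), length(idx),
                dimnames = list(eligible, meta$sample_id[idx]))
  for (k in seq_along(eligible)) {
    o <- eligible[k]
    y <- binarize_otu(otus$counts[idx, o])
    fp <- config$forest
    fp$seed <- seed_from(config$forest$seed, o)
    model <- fit_random_forest(X, y, fp)
    pred <- oob_predict(model, tie_rule = config$tie_rule)
    ok <- !is.na(pred)
    tpr <- sum(pred[ok] & y[ok]) / sum(y[ok])
    tnr <- sum(!pred[ok] & !y[ok]) / sum(!y[ok])
    summaries[[k]] <- data.frame(
      otu_id = o, treatment = treatment,
      n_present = sum(y), n_absent = sum(!y),
      true_positive_rate = tpr, true_negative_rate = tnr,
      balanced_accuracy = (tpr + tnr) / 2,
      stringsAsFactors = FALSE)
    imp[k, names(model$importance)] <- model$importance
    oob[k, ] <- pred
  }
  summaries <- if (length(summaries)) do.call(rbind, summaries) else
    data.frame(otu_id = character(), treatment = character(),
               n_present = integer(), n_absent = integer(),
               true_positive_rate = numeric(), true_negative_rate = numeric(),
               balanced_accuracy = numeric())
  rownames(summaries) <- NULL
  structure(list(treatment = treatment, summaries = summaries,
                 importance = imp, oob_predictions = oob, config = config),
            class = "treatment_models")
}

#' @export
print.treatment_models <- function(x, ...) {
  cat(sprintf("<treatment_models> %s: %d models; %d pass BA >= %.2f\n",
              x$treatment, nrow(x$summaries),
              sum(x$summaries$balanced_accuracy >=
                    x$config$balanced_accuracy_threshold),
              x$config$balanced_accuracy_threshold))
  invisible(x)
}

#' Rank biomarker metabolites across retained models
#'
#' Retains models whose out-of-bag balanced accuracy meets the gate, pools
#' every (metabolite, model) importance score from the retained models, sets
#' the cutoff at the empirical `1 - importance_top_fraction` quantile of the
#' pool, and reports score pairs at or above the cutoff as strong
#' metabolite-OTU predictor pairs. Metabolites are also ranked by their mean
#' importance across retained models.
#'
#' @param models A `treatment_models` object from
#'   [fit_models_for_treatment()].
#' @param config A [pipeline_config()]; defaults to the one stored in
#'   `models`.
#' @return An object of class `biomarker_ranking`: `treatment`,
#'   `retained_models`, `pooled_importance_cutoff`, `strong_pairs`
#'   (data.frame: metabolite, otu_id, importance), `metabolite_rank`
#'   (data.frame: metabolite, mean_importance, sorted descending).
#' @export
rank_biomarkers <- function(models, config = NULL) {
  stopifnot(inherits(models, "treatment_models"))
  config <- config %||% models$config
  s <- models$summaries
  retained <- s$otu_id[s$balanced_accuracy >= config$balanced_accuracy_threshold]
  if (length(retained) == 0) {
    warning(sprintf("no models pass the balanced-accuracy gate for %s; empty ranking",
                    models$treatment))
    return(structure(list(treatment = models$treatment,
                          retained_models = character(0),
                          pooled_importance_cutoff = NA_real_,
                          strong_pairs = data.frame(metabolite = character(),
                                                    otu_id = character(),
                                                    importance = numeric()),
                          metabolite_rank = data.frame(metabolite = character(),
                                                       mean_importance = numeric())),
                     class = "biomarker_ranking"))
  }
  pool_models <- if (config$gate_first) retained else s$otu_id
  M <- models$importance[pool_models, , drop = FALSE]
  cutoff <- quantile(as.vector(M), 1 - config$importance_top_fraction,
                     type = 7, names = FALSE)
  Mr <- models$importance[retained, , drop = FALSE]
  hit <- which(Mr >= cutoff, arr.ind = TRUE)
  strong <- data.frame(metabolite = colnames(Mr)[hit[, 2]],
                       otu_id = rownames(Mr)[hit[, 1]],
                       importance = Mr[hit],
                       stringsAsFactors = FALSE)
  strong <- strong[order(-strong$importance, strong$metabolite, strong$otu_id), ,
                   drop = FALSE]
  rownames(strong) <- NULL
  rank <- data.frame(metabolite = colnames(Mr),
                     mean_importance = colMeans(Mr),
                     stringsAsFactors = FALSE)
  rank <- rank[order(-rank$mean_importance, rank$metabolite), , drop = FALSE]
  rownames(rank) <- NULL
  structure(list(treatment = models$treatment,
                 retained_models = retained,
                 pooled_importance_cutoff = cutoff,
                 strong_pairs = strong,
                 metabolite_rank = rank),
            class = "biomarker_ranking")
}

#' @export
print.biomarker_ranking <- function(x, ...) {
  cat(sprintf("<biomarker_ranking> %s: %d retained models; %d strong pairs; cutoff %.4g\n",
              x$treatment, length(x$retained_models), nrow(x$strong_pairs),
              x$pooled_importance_cutoff))
  if (nrow(x$metabolite_rank)) {
    print(utils::head(x$metabolite_rank, 5), row.names = FALSE)
  }
  invisible(x)
}
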