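#' Processing parameters
#'
#' Thresholds and conventions for the filtering/normalization stage. The
#' quantile convention is fixed package-wide to linear interpolation between
#' order statistics (`stats::quantile` type 7), since "75th quartile" differs
#' across software.
#'
#' @param min_otu_samples An OTU must have nonzero counts in at least this
#'   many samples to be kept.
#' @param outlier_permutations Number of column-permutation datasets for the
#'   sample-outlier randomization test.
#' @param outlier_alpha Significance level for flagging outliers (applied to
#'   Bonferroni-adjusted p-values).
#' @param metabolite_min_samples,metabolite_min_treatments A metabolite must
#'   be observed in at least `metabolite_min_samples` samples within each of
#'   at least `metabolite_min_treatments` treatments.
#' @return A list of class `processing_params`.
#' @export
processing_params <- function(min_otu_samples = 2,
                              outlier_permutations = 999,
                              outlier_alpha = 0.05,
                              metabolite_min_samples = 2,
                              metabolite_min_treatments = 2) {
  p <- list(min_otu_samples = as.integer(min_otu_samples),
            outlier_permutations = as.integer(outlier_permutations),
            outlier_alpha = as.numeric(outlier_alpha),
            metabolite_min_samples = as.integer(metabolite_min_samples),
            metabolite_min_treatments = as.integer(metabolite_min_treatments),
            quantile_type = 7L)
  if (p$min_otu_samples < 1) stop("invalid parameter: min_otu_samples must be >= 1")
  if (p$outlier_permutations < 1) stop("invalid parameter: outlier_permutations must be >= 1")
  if (p$outlier_alpha <= 0 || p$outlier_alpha >= 1) {
    stop("invalid parameter: outlier_alpha must lie in (0, 1)")
  }
  if (p$metabolite_min_samples < 1 || p$metabolite_min_treatments < 1) {
    stop("invalid parameter: metabolite filter thresholds must be >= 1")
  }
  structure(p, class = "processing_params")
}

#' Remove rare OTUs
#'
#' Drops OTUs observed (nonzero count) in fewer than `min_otu_samples`
#' samples. The sample set is unchanged; taxonomy is subset accordingly.
#'
#' @param table An [otu_count_table()].
#' @param min_otu_samples Minimum number of samples with a nonzero count.
#' @return A filtered `otu_count_table`.
#' @export
filter_rare_otus <- function(table, min_otu_samples = 2) {
  if (min_otu_samples < 1) stop("invalid parameter: min_otu_samples must be >= 1")
  stopifnot(inherits(table, "otu_count_table"))
  if (ncol(table$counts) == 0) return(table)
  keep <- colSums(table$counts > 0) >= min_otu_samples
  otu_count_table(table$counts[, keep, drop = FALSE],
                  taxonomy = table$taxonomy[keep])
}

#' Jaccard distance between presence profiles
#'
#' `1 - |intersection| / |union|` on the sets of present (nonzero/TRUE)
#' features. If both profiles are empty the distance is undefined; 0 is
#' returned by convention with a warning.
#'
#' @param a,b Binary (logical or 0/1) vectors of equal length.
#' @return A distance in `[0, 1]`.
#' @export
#' @examples
#' jaccard_distance(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must have equal length")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0) {
    warning("both profiles empty; Jaccard distance undefined, returning 0")
    return(0)
  }
  1 - sum(a & b) / un
}

# Internal: mean Jaccard distance from each sample (row) to all others,
# computed on a logical presence matrix via cross-products.
mean_jaccard_to_others <- function(P) {
  n <- nrow(P)
  mode(P) <- "numeric"
  inter <- tcrossprod(P)
  sz <- rowSums(P)
  un <- outer(sz, sz, "+") - inter
  D <- 1 - inter / un
  D[un == 0] <- 0  # two empty profiles: convention
  diag(D) <- 0
  rowSums(D) / (n - 1)
}

#' Detect sample outliers by a Jaccard randomization test
#'
#' Each sample's statistic is its mean Jaccard distance to all other samples'
#' OTU presence profiles. The null distribution is built from datasets in
#' which every OTU column's presence entries are independently permuted
#' across samples (preserving per-OTU prevalence); one-sided p-values are
#' `(1 + #permuted >= observed) / (1 + permutations)`, Bonferroni-adjusted
#' across samples. Samples are canonicalized by ID before permutation so the
#' result is invariant to input row order.
#'
#' @param table An [otu_count_table()] with at least 3 samples.
#' @param params A [processing_params()].
#' @param seed Integer seed for the permutation stream.
#' @return A `data.frame` with one row per sample: `sample_id`, `statistic`,
#'   `p_value`, `p_adjusted`, `flagged`.
#' @export
detect_sample_outliers <- function(table, params = processing_params(), seed = 1) {
  stopifnot(inherits(table, "otu_count_table"))
  n <- nrow(table$counts)
  if (n < 3) stop("insufficient data: outlier test needs at least 3 samples")
  ord <- order(rownames(table$counts))
  P <- table$counts[ord, , drop = FALSE] > 0
  p <- ncol(P)
  obs <- mean_jaccard_to_others(P)
  B <- params$outlier_permutations
  exceed <- rep(0L, n)
  col_key <- rep(seq_len(p), each = n)
  with_seed(seed_from(seed, "outliers"), {
    for (b in seq_len(B)) {
      # within-column permutation via one sort on (column, random key)
      perm <- order(col_key, runif(n * p))
      Pb <- matrix(P[perm], n, p)
      sb <- mean_jaccard_to_others(Pb)
      exceed <- exceed + (sb >= obs)
    }
  })
  pval <- (1 + exceed) / (1 + B)
  padj <- pmin(1, pval * n)
  res <- data.frame(sample_id = rownames(table$counts)[ord],
                    statistic = obs,
                    p_value = pval,
                    p_adjusted = padj,
                    flagged = padj <= params$outlier_alpha,
                    stringsAsFactors = FALSE)
  res[match(rownames(table$counts), res$sample_id), , drop = FALSE]
}

#' Upper-quartile normalization of OTU counts
#'
#' Divides each sample's counts by the 75th percentile of that sample's
#' nonzero counts (linear-interpolation quantile), then rescales by the
#' across-sample mean of those percentiles so magnitudes stay count-like.
#' Set `rescale = FALSE` for pure division.
#'
#' @param table An [otu_count_table()]; every sample must have at least one
#'   nonzero count.
#' @param rescale Multiply back by the mean upper quartile (default TRUE).
#' @return A numeric samples-by-OTUs matrix of normalized abundances.
#' @export
upper_quartile_normalize <- function(table, rescale = TRUE) {
  stopifnot(inherits(table, "otu_count_table"))
  cnt <- table$counts
  zero_samples <- rownames(cnt)[rowSums(cnt > 0) == 0]
  if (length(zero_samples)) {
    stop("normalization undefined for all-zero sample(s): ",
         paste(zero_samples, collapse = ", "))
  }
  uq <- apply(cnt, 1, function(x) quantile(x[x > 0], 0.75, type = 7,
                                           names = FALSE))
  out <- cnt / uq
  if (rescale) out <- out * mean(uq)
  out
}

#' Log2-transform a metabolite matrix
#'
#' Observed entries are replaced by their base-2 logarithm; missing entries
#' stay missing. Input must be on the raw scale with positive observed values.
#'
#' @param matrix A raw-scale [metabolite_matrix()].
#' @return A `metabolite_matrix` with `scale = "log2"`.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (matrix$scale != "raw") stop("log2_transform expects raw-scale input")
  if (any(matrix$values <= 0, na.rm = TRUE)) {
    stop("domain error: observed abundances must be positive")
  }
  metabolite_matrix(log2(matrix$values), scale = "log2")
}

#' Median-center a log2 metabolite matrix
#'
#' Subtracts from each sample the median of that sample's observed values, so
#' every sample's observed median becomes 0.
#'
#' @param matrix A [metabolite_matrix()] with `scale = "log2"`.
#' @return A `metabolite_matrix` with `scale = "log2-centered"`.
#' @export
median_center <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (matrix$scale != "log2") stop("median_center expects log2-scale input")
  v <- matrix$values
  n_obs <- rowSums(!is.na(v))
  if (any(n_obs == 0)) {
    stop("sample(s) with no observed values: ",
         paste(rownames(v)[n_obs == 0], collapse = ", "))
  }
  med <- apply(v, 1, median, na.rm = TRUE)
  metabolite_matrix(v - med, scale = "log2-centered",
                    imputation_value = matrix$imputation_value)
}

#' Half-minimum imputation of missing metabolite values
#'
#' Replaces every missing entry with half of the lowest observed log2
#' abundance across the whole matrix. Applied on the log2 scale, before
#' median centering.
#'
#' @param matrix A [metabolite_matrix()] with `scale = "log2"`.
#' @return A complete `metabolite_matrix` with `imputation_value` recorded.
#' @export
impute_half_minimum <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  if (matrix$scale != "log2") stop("impute_half_minimum expects log2-scale input")
  v <- matrix$values
  if (all(is.na(v))) stop("no observed values to impute from")
  fill <- min(v, na.rm = TRUE) / 2
  v[is.na(v)] <- fill
  metabolite_matrix(v, scale = "log2", imputation_value = fill)
}

#' Filter metabolites for univariate testing
#'
#' Keeps metabolites observed (non-missing) in at least
#' `metabolite_min_samples` samples within each of at least
#' `metabolite_min_treatments` treatments.
#'
#' @param matrix A [metabolite_matrix()] aligned to `meta`.
#' @param meta Sample metadata (see [sample_metadata()]).
#' @param params A [processing_params()].
#' @return A filtered `metabolite_matrix`.
#' @export
filter_metabolites_for_univariate <- function(matrix, meta,
                                              params = processing_params()) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  check_alignment(rownames(matrix$values), meta, "metabolite matrix")
  if (anyNA(meta$treatment)) stop("unknown treatment label in metadata")
  obs <- !is.na(matrix$values)
  per_trt <- rowsum(obs + 0, group = as.character(meta$treatment))
  keep <- colSums(per_trt >= params$metabolite_min_samples) >=
    params$metabolite_min_treatments
  out <- matrix
  out$values <- matrix$values[, keep, drop = FALSE]
  out
}
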