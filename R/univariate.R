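#' Mixed-effects treatment test for one metabolite
#'
#' Fits, by REML, `value ~ treatment + (1 | core)`: a fixed moisture-treatment
#' effect with a random intercept for the soil core (technical replicates are
#' the repeated measures within core). All pairwise treatment contrasts are
#' tested with a single-step (max-t, multivariate-normal bound) multiplicity
#' adjustment over the contrast family; Bonferroni is available as a fallback.
#'
#' @param values Numeric vector of per-sample metabolite values (log2 or
#'   log2-centered scale); missing entries are dropped.
#' @param meta Sample metadata aligned to `values` (see [sample_metadata()]).
#' @param metabolite_id Identifier carried into the result.
#' @param adjust `"single-step"` (default) or `"bonferroni"`.
#' @return An object of class `mixed_model_fit`: a list with
#'   `metabolite_id`, `treatment_means`, `core_variance`,
#'   `residual_variance`, and a `contrasts` data.frame (pair, estimate,
#'   std_error, p_value, p_adjusted).
#' @export
fit_metabolite_mixed_model <- function(values, meta, metabolite_id = "metabolite",
                                       adjust = c("single-step", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(values) != nrow(meta)) stop("values must align to metadata rows")
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing")
  df <- data.frame(y = values[ok],
                   treatment = droplevels(meta$treatment[ok]),
                   core = factor(meta$core[ok]))
  tab <- table(df$treatment)
  if (length(tab) < 2) stop("insufficient design: need at least 2 treatments")
  if (any(tab < 2)) stop("insufficient design: need >= 2 samples per treatment")
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(y ~ treatment + (1 | core), data = df, REML = TRUE)
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  core_var <- vc$vcov[vc$grp == "core"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  trts <- levels(df$treatment)
  means <- setNames(rep(fe[1], length(trts)), trts)
  for (tr in trts[-1]) {
    means[tr] <- fe[1] + fe[paste0("treatment", tr)]
  }
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(treatment = "Tukey"))
  raw <- summary(glt, test = multcomp::adjusted("none"))$test
  adj <- summary(glt, test = multcomp::adjusted(
    if (adjust == "single-step") "single-step" else "bonferroni"))$test
  contrasts <- data.frame(
    pair = names(raw$coefficients),
    estimate = as.numeric(raw$coefficients),
    std_error = as.numeric(raw$sigma),
    p_value = as.numeric(raw$pvalues),
    p_adjusted = pmax(as.numeric(adj$pvalues), as.numeric(raw$pvalues)),
    stringsAsFactors = FALSE
  )
  structure(list(metabolite_id = metabolite_id,
                 treatment_means = means,
                 core_variance = core_var,
                 residual_variance = resid_var,
                 contrasts = contrasts),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> %s; core var %.4g; residual var %.4g\n",
              x$metabolite_id, x$core_variance, x$residual_variance))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Mixed-effects tests across all metabolites
#'
#' Applies [fit_metabolite_mixed_model()] to every metabolite column;
#' metabolites whose fit fails (e.g., too few observed samples) are skipped
#' with a warning.
#'
#' @param matrix A [metabolite_matrix()] on the log2 or log2-centered scale.
#' @param meta Sample metadata aligned to the matrix.
#' @param adjust Contrast-family adjustment, see
#'   [fit_metabolite_mixed_model()].
#' @return A `data.frame` with one row per metabolite-by-contrast.
#' @export
test_metabolite_shifts <- function(matrix, meta, adjust = "single-step") {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  check_alignment(rownames(matrix$values), meta, "metabolite matrix")
  rows <- lapply(colnames(matrix$values), function(m) {
    fit <- tryCatch(
      fit_metabolite_mixed_model(matrix$values[, m], meta, m, adjust = adjust),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    cbind(metabolite = m, fit$contrasts,
          core_variance = fit$core_variance,
          residual_variance = fit$residual_variance,
          stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    warning(sprintf("%d metabolite(s) skipped: insufficient data for the mixed model",
                    skipped))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(metabolite = character(), pair = character(),
                      estimate = numeric(), std_error = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      core_variance = numeric(), residual_variance = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' `m/i`, monotonicity enforced from the largest down, capped at 1; input
#' order is preserved.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Internal: vectorized Welch t-test per column between two groups.
# Returns statistic and two-sided p; handles constant columns (p = 1 when the
# group means coincide, p -> 0 otherwise).
welch_by_column <- function(X, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2, var)
  v2 <- apply(X[g2, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  dfree <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(abs(stat), dfree, lower.tail = FALSE)
  degenerate <- se2 == 0
  stat[degenerate] <- 0
  p[degenerate] <- ifelse(abs(m1 - m2)[degenerate] < .Machine$double.eps^0.5,
                          1, 0)
  list(statistic = stat, p_value = p)
}

#' Screen OTUs for relative-abundance shifts between treatments
#'
#' For each OTU and each pair of treatments, performs a two-sample location
#' test on log2-transformed upper-quartile-normalized abundances (with a
#' half-minimum pseudocount); Wilcoxon rank-sum is available as an
#' alternative. Benjamini-Hochberg correction is applied across the full
#' OTU-by-pair family; a shift is significant at adjusted p < 0.05.
#'
#' @param normalized Samples-by-OTUs matrix from [upper_quartile_normalize()].
#' @param meta Sample metadata aligned to the matrix rows.
#' @param test `"welch"` (default) or `"wilcoxon"`.
#' @param alpha Significance level on the adjusted scale.
#' @return A `data.frame`: `otu_id`, `pair`, `statistic`, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
test_otu_abundance_shifts <- function(normalized, meta, test = c("welch", "wilcoxon"),
                                      alpha = 0.05) {
  test <- match.arg(test)
  check_alignment(rownames(normalized), meta, "normalized matrix")
  pos <- normalized[normalized > 0]
  pc <- if (length(pos)) min(pos) / 2 else 1
  L <- log2(normalized + pc)
  trts <- levels(droplevels(meta$treatment))
  pairs <- if (length(trts) >= 2) utils::combn(trts, 2, simplify = FALSE) else list()
  blocks <- list()
  for (pr in pairs) {
    g1 <- which(meta$treatment == pr[1])
    g2 <- which(meta$treatment == pr[2])
    if (length(g1) < 2 || length(g2) < 2) {
      warning(sprintf("pair %s vs %s skipped: fewer than 2 samples in a group",
                      pr[1], pr[2]))
      next
    }
    res <- if (test == "welch") {
      welch_by_column(L, g1, g2)
    } else {
      ps <- apply(L, 2, function(x) {
        suppressWarnings(stats::wilcox.test(x[g1], x[g2], exact = FALSE)$p.value)
      })
      st <- apply(L, 2, function(x) {
        suppressWarnings(unname(stats::wilcox.test(x[g1], x[g2],
                                                   exact = FALSE)$statistic))
      })
      ps[is.na(ps)] <- 1
      list(statistic = st, p_value = ps)
    }
    blocks[[paste(pr, collapse = " vs ")]] <-
      data.frame(otu_id = colnames(normalized),
                 pair = paste(pr, collapse = " vs "),
                 statistic = res$statistic,
                 p_value = res$p_value,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    return(data.frame(otu_id = character(), pair = character(),
                      statistic = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  }
  out$p_adjusted <- benjamini_hochberg(out$p_value)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}
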