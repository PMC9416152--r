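# Independent oracles and small fixture builders shared across tests.

# Exhaustive best-split search over every (predictor, midpoint) pair, using
# the weighted Gini decrease n_t*G(t) - n_L*G(L) - n_R*G(R) and the same tie
# rule as the tree grower (first by decrease, then lowest predictor index,
# then lowest threshold; zero-gain splits inadmissible).
brute_force_best_split <- function(X, y, bag = seq_len(nrow(X)),
                                   min_node_size = 1) {
  ng <- function(a, b) if (a + b == 0) 0 else (a + b) - (a^2 + b^2) / (a + b)
  yb <- y[bag]
  parent <- ng(sum(yb == 0), sum(yb == 1))
  best <- NULL
  for (v in seq_len(ncol(X))) {
    xv <- X[bag, v]
    cuts <- sort(unique(xv))
    if (length(cuts) < 2) next
    thr <- (cuts[-length(cuts)] + cuts[-1]) / 2
    for (t in thr) {
      l <- xv <= t
      if (sum(l) < min_node_size || sum(!l) < min_node_size) next
      dec <- parent - ng(sum(yb[l] == 0), sum(yb[l] == 1)) -
        ng(sum(yb[!l] == 0), sum(yb[!l] == 1))
      if (dec > 1e-12 && (is.null(best) || dec > best$decrease + 1e-12)) {
        best <- list(var = v, threshold = t, decrease = dec)
      }
    }
  }
  best
}

# Literal step-up BH definition applied to sorted p-values.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Empirical mutual information (nats) between a binary vector and a
# continuous one discretized at its quartiles.
mutual_info_quartile <- function(x, y) {
  bins <- cut(x, breaks = unique(quantile(x, 0:4 / 4)), include.lowest = TRUE)
  tab <- table(bins, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  mi
}

# The log2 -> impute -> median-center branch feeding the classifiers.
rf_branch <- function(dataset) {
  median_center(impute_half_minimum(log2_transform(dataset$metabolites)))
}

# Small random OTU table fixture.
random_otu_table <- function(n_samples = 6, n_otus = 10, p_zero = 0.5) {
  m <- matrix(ifelse(runif(n_samples * n_otus) < p_zero, 0L,
                     rpois(n_samples * n_otus, 8) + 1L),
              n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("otu%03d", seq_len(n_otus))))
  otu_count_table(m)
}

# Hand-built one-tree, one-split model: root (5,5) splitting into pure
# children on the first predictor.
single_split_model <- function(predictors = c("metA", "metB")) {
  tree <- list(var = c(1L, NA_integer_, NA_integer_),
               threshold = c(0, NA, NA),
               left = c(2L, NA_integer_, NA_integer_),
               right = c(3L, NA_integer_, NA_integer_),
               n0 = c(5L, 5L, 0L), n1 = c(5L, 0L, 5L),
               pred = c(1L, 0L, 1L))
  structure(list(trees = list(tree), predictors = predictors),
            class = "rf_model")
}
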