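#' Random-forest hyperparameters
#'
#' Defaults follow the standard classification settings of the classical
#' random-forest method: 500 trees, `mtry = floor(sqrt(p))`, terminal nodes
#' of minimum size 1, and full-size bootstrap sampling with replacement.
#'
#' @param n_trees Number of trees.
#' @param mtry Predictors sampled (without replacement) at each node;
#'   `NULL` means `floor(sqrt(p))`, resolved at fit time.
#' @param min_node_size Minimum terminal-node size.
#' @param bootstrap_size Bootstrap draws per tree; `NULL` means `n`.
#' @param seed Master seed; per-tree streams derive from it deterministically.
#' @return A list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, mtry = NULL, min_node_size = 1,
                          bootstrap_size = NULL, seed = 1) {
  p <- list(n_trees = as.integer(n_trees),
            mtry = if (is.null(mtry)) NULL else as.integer(mtry),
            min_node_size = as.integer(min_node_size),
            bootstrap_size = if (is.null(bootstrap_size)) NULL else
              as.integer(bootstrap_size),
            seed = as.numeric(seed))
  if (p$n_trees < 1) stop("n_trees must be >= 1")
  if (!is.null(p$mtry) && p$mtry < 1) stop("mtry must be >= 1")
  if (p$min_node_size < 1) stop("min_node_size must be >= 1")
  structure(p, class = "forest_params")
}

#' Gini impurity of a binary class count
#'
#' `1 - sum((n_c / n)^2)` over the two classes.
#'
#' @param class_counts Non-negative pair of class counts with positive total.
#' @return Impurity in `[0, 0.5]`.
#' @export
#' @examples
#' gini_impurity(c(3, 3))  # 0.5
#' gini_impurity(c(1, 3))  # 0.375
gini_impurity <- function(class_counts) {
  if (length(class_counts) != 2 || any(class_counts < 0)) {
    stop("class_counts must be a pair of non-negative counts")
  }
  n <- sum(class_counts)
  if (n < 1) stop("empty node: impurity undefined")
  1 - sum((class_counts / n)^2)
}

# Internal: coerce presence labels to integer 0/1 with a "present" semantics.
as_binary_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1, logical, or 2-level factor)")
  as.integer(y)
}

# Internal: canonicalize predictors by ID so per-node predictor sampling acts
# on predictor identities, not column positions.
canonical_X <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("predictors must be complete (impute upstream)")
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  X[, order(colnames(X)), drop = FALSE]
}

#' Grow a single classification tree
#'
#' Recursive binary partitioning of a bagged sample: at each node `mtry`
#' predictors are drawn without replacement and the (predictor, midpoint
#' threshold) pair maximizing the Gini impurity decrease
#' `n_t G(t) - n_L G(L) - n_R G(R)` is chosen; quality ties break toward the
#' lowest predictor ID, then the lowest threshold. Recursion stops at purity,
#' the node-size floor, or when no split reduces impurity.
#'
#' @param X Samples-by-predictors numeric matrix (no missing values).
#' @param y Binary labels (`TRUE`/1 = present).
#' @param bag Integer vector of (possibly repeated) row indices forming the
#'   bootstrap bag; defaults to all rows.
#' @param params A [forest_params()].
#' @return A tree as a list of parallel node vectors (`var`, `threshold`,
#'   `left`, `right`, `n0`, `n1`, `pred`); `var` is an index into the
#'   predictors sorted by name (`attr(tree, "predictors")`).
#' @export
grow_tree <- function(X, y, bag = seq_len(nrow(X)), params = forest_params()) {
  Xc <- canonical_X(X)
  y <- as_binary_labels(y)
  if (length(y) != nrow(Xc)) stop("labels must align to predictor rows")
  if (length(bag) == 0) stop("bag must be nonempty")
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(Xc))))
  tree <- cpp_grow_tree(Xc, y, as.integer(bag), mtry, params$min_node_size,
                        params$seed)
  attr(tree, "predictors") <- colnames(Xc)
  tree
}

#' Fit a random forest for binary presence/absence
#'
#' Grows `n_trees` trees on independent bootstrap bags; each tree votes on
#' the samples left out of its bag (out-of-bag), giving an internal
#' validation set for every sample, and contributes its per-node Gini
#' impurity decreases to the mean-decrease-Gini importance of each predictor.
#'
#' @param X Samples-by-predictors numeric matrix (no missing values).
#' @param y Binary labels (`TRUE`/1 = present); both classes must occur at
#'   least twice.
#' @param params A [forest_params()].
#' @return An object of class `rf_model` with elements `trees`, `oob_votes`
#'   (samples by c(absent, present)), `importance` (named, per predictor),
#'   `y`, `predictors`, `params`.
#' @export
fit_random_forest <- function(X, y, params = forest_params()) {
  Xc <- canonical_X(X)
  y <- as_binary_labels(y)
  if (length(y) != nrow(Xc)) stop("labels must align to predictor rows")
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("model undefined: need at least 2 samples in each class")
  }
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(Xc))))
  if (mtry > ncol(Xc)) stop("mtry cannot exceed the number of predictors")
  bs <- params$bootstrap_size %||% nrow(Xc)
  fit <- cpp_fit_forest(Xc, y, params$n_trees, mtry, params$min_node_size,
                        bs, params$seed)
  votes <- fit$oob_votes
  dimnames(votes) <- list(rownames(Xc), c("absent", "present"))
  importance <- setNames(as.numeric(fit$importance), colnames(Xc))
  structure(list(trees = fit$trees, oob_votes = votes,
                 importance = importance, y = y,
                 predictors = colnames(Xc),
                 params = c(params, list(mtry_used = mtry,
                                         bootstrap_size_used = bs))),
            class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees; %d samples x %d predictors; top importance: %s\n",
              length(x$trees), nrow(x$oob_votes), length(x$predictors),
              names(sort(x$importance, decreasing = TRUE))[1]))
  invisible(x)
}

#' Out-of-bag predictions
#'
#' Majority vote per sample over the trees for which the sample was
#' out-of-bag. Vote ties break toward the class named by `tie_rule`
#' ("present" by default). Samples with zero out-of-bag votes (possible only
#' at very small `n_trees`) return `NA` with a warning.
#'
#' @param model An [fit_random_forest()] model.
#' @param tie_rule `"present"` or `"absent"`.
#' @return A logical vector: `TRUE` = predicted present.
#' @export
oob_predict <- function(model, tie_rule = c("present", "absent")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(model, "rf_model"))
  v <- model$oob_votes
  pred <- ifelse(v[, "present"] > v[, "absent"], TRUE,
                 ifelse(v[, "present"] < v[, "absent"], FALSE,
                        tie_rule == "present"))
  none <- rowSums(v) == 0
  if (any(none)) {
    warning(sprintf("%d sample(s) received no out-of-bag votes", sum(none)))
    pred[none] <- NA
  }
  setNames(pred, rownames(v))
}

#' Predict presence for new samples
#'
#' Majority vote across all trees of the forest.
#'
#' @param object An `rf_model`.
#' @param newdata Samples-by-predictors matrix containing the model's
#'   predictors (matched by name).
#' @param tie_rule Vote tie rule, as in [oob_predict()].
#' @param ... Unused.
#' @return Logical vector of predictions.
#' @export
predict.rf_model <- function(object, newdata, tie_rule = "present", ...) {
  X <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  votes <- matrix(0L, nrow(X), 2)
  for (tree in object$trees) {
    p <- cpp_predict_tree(tree, X)
    votes[cbind(seq_len(nrow(X)), p + 1L)] <-
      votes[cbind(seq_len(nrow(X)), p + 1L)] + 1L
  }
  pr <- votes[, 2] > votes[, 1] |
    (votes[, 2] == votes[, 1] & tie_rule == "present")
  setNames(pr, rownames(X))
}

#' Mean decrease in Gini importance
#'
#' Recomputes, from the stored per-node class counts of every tree, the total
#' impurity decrease `n_t G(t) - n_L G(L) - n_R G(R)` attributable to splits
#' on each predictor, averaged over trees. A predictor never selected scores
#' exactly 0.
#'
#' @param model An `rf_model`.
#' @return Named numeric vector of importances (one per predictor).
#' @export
mean_decrease_gini <- function(model) {
  stopifnot(inherits(model, "rf_model"))
  imp <- setNames(numeric(length(model$predictors)), model$predictors)
  for (tree in model$trees) {
    internal <- which(!is.na(tree$var))
    for (k in internal) {
      nt <- tree$n0[k] + tree$n1[k]
      l <- tree$left[k]; r <- tree$right[k]
      nl <- tree$n0[l] + tree$n1[l]
      nr <- tree$n0[r] + tree$n1[r]
      dec <- nt * gini_impurity(c(tree$n0[k], tree$n1[k])) -
        nl * gini_impurity(c(tree$n0[l], tree$n1[l])) -
        nr * gini_impurity(c(tree$n0[r], tree$n1[r]))
      imp[tree$var[k]] <- imp[tree$var[k]] + dec
    }
  }
  imp / length(model$trees)
}
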