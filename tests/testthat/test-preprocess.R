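test_that("rare-OTU filter keeps exactly the OTUs observed often enough, idempotently", {
  m <- matrix(0L, 5, 3, dimnames = list(paste0("s", 1:5), paste0("o", 1:3)))
  m[1, 1] <- 4L              # 1 sample
  m[c(2, 4), 2] <- 1L        # exactly 2 samples (boundary)
  m[, 3] <- 2L               # all samples
  tab <- otu_count_table(m, taxonomy = c(o1 = "p__A", o2 = "p__B", o3 = "p__C"))
  f <- filter_rare_otus(tab, 2)
  expect_identical(colnames(f$counts), c("o2", "o3"))
  expect_identical(names(f$taxonomy), c("o2", "o3"))
  expect_identical(rownames(f$counts), rownames(m))
  expect_identical(filter_rare_otus(f, 2), f)
  expect_error(filter_rare_otus(tab, 0), "invalid parameter")

  empty <- otu_count_table(m[, 0, drop = FALSE])
  expect_identical(filter_rare_otus(empty, 2), empty)

  set.seed(11)
  for (i in 1:20) {
    tab <- random_otu_table(7, 15)
    k <- sample(1:4, 1)
    kept <- colnames(filter_rare_otus(tab, k)$counts)
    expect_identical(kept,
                     colnames(tab$counts)[colSums(tab$counts > 0) >= k])
  }
})

test_that("jaccard distance matches set arithmetic and is a metric", {
  expect_equal(jaccard_distance(c(1, 1, 0), c(1, 1, 0)), 0)
  expect_equal(jaccard_distance(c(1, 0, 0, 1), c(0, 1, 1, 0)), 1)
  expect_equal(jaccard_distance(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)
  expect_warning(z <- jaccard_distance(c(0, 0), c(0, 0)), "undefined")
  expect_equal(z, 0)
  expect_error(jaccard_distance(c(1, 0), c(1, 0, 1)), "equal length")

  set.seed(7)
  for (i in 1:50) {
    a <- runif(12) < 0.5; b <- runif(12) < 0.5; c <- runif(12) < 0.5
    if (!any(a | b) || !any(b | c) || !any(a | c)) next
    dab <- jaccard_distance(a, b)
    expect_equal(dab, jaccard_distance(b, a))
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_lte(dab, jaccard_distance(a, c) + jaccard_distance(c, b) + 1e-12)
  }
})

test_that("upper-quartile normalization cancels library-size differences", {
  m <- matrix(c(2L, 0L, 6L, 10L,
                4L, 0L, 12L, 20L), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  tab <- otu_count_table(m)
  norm <- upper_quartile_normalize(tab)
  expect_equal(norm["s1", ], norm["s2", ])      # s2 = 2 x s1
  expect_true(all(norm[, 2] == 0))              # zeros in -> zeros out

  same <- otu_count_table(matrix(rep(c(1L, 3L, 8L), each = 3), 3, 3,
                                 dimnames = list(paste0("s", 1:3), paste0("o", 1:3))))
  expect_equal(upper_quartile_normalize(same), same$counts + 0,
               ignore_attr = FALSE)

  mz <- m; mz[2, ] <- 0L
  expect_error(upper_quartile_normalize(otu_count_table(mz)), "s2")

  # direct computation under the type-7 quantile convention
  x <- c(3L, 0L, 7L, 12L, 5L)
  tb <- otu_count_table(matrix(x, 1, 5, dimnames = list("s1", paste0("o", 1:5))))
  uq <- quantile(x[x > 0], 0.75, type = 7, names = FALSE)
  expect_equal(unname(upper_quartile_normalize(tb)[1, ]), x / uq * uq)
  expect_equal(unname(upper_quartile_normalize(tb, rescale = FALSE)[1, ]), x / uq)
})

test_that("log2 transform maps observed values and preserves missingness", {
  v <- matrix(c(2, 4, 8, NA, 1, 16), 2, 3,
              dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
  lm2 <- log2_transform(metabolite_matrix(v))
  expect_equal(lm2$values[1, ], c(m1 = 1, m2 = 3, m3 = 0))
  expect_true(is.na(lm2$values[2, 2]))
  expect_identical(lm2$scale, "log2")
  expect_error(log2_transform(lm2), "raw-scale")
  bad <- metabolite_matrix(v); bad$values[1, 1] <- -2
  expect_error(log2_transform(bad), "positive")
})

test_that("median centering zeroes every sample's observed median", {
  v <- matrix(c(1, 2, 3,
                1, NA, 3,
                5, NA, NA), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("m", 1:3)))
  cm <- median_center(metabolite_matrix(v, scale = "log2"))
  expect_equal(cm$values[1, ], c(m1 = -1, m2 = 0, m3 = 1))
  expect_equal(cm$values[2, ], c(m1 = -1, m2 = NA, m3 = 1))
  expect_equal(unname(cm$values[3, 1]), 0)   # single observed value
  expect_identical(cm$scale, "log2-centered")

  set.seed(3)
  r <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:20)))
  r[runif(200) < 0.2] <- NA
  rc <- median_center(metabolite_matrix(r, scale = "log2"))
  meds <- apply(rc$values, 1, median, na.rm = TRUE)
  expect_lt(max(abs(meds)), 1e-9)

  allna <- v; allna[2, ] <- NA
  expect_error(median_center(metabolite_matrix(allna, scale = "log2")), "s2")
})

test_that("half-minimum imputation fills every gap at half the global observed minimum", {
  v <- matrix(c(6.5984248, 9, NA, 12, NA, 8), 2, 3,
              dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
  im <- impute_half_minimum(metabolite_matrix(v, scale = "log2"))
  expect_equal(im$imputation_value, 3.2992124)
  expect_equal(unname(im$values[is.na(v)]), rep(3.2992124, 2))
  expect_identical(im$values[!is.na(v)], v[!is.na(v)])  # observed untouched
  expect_false(anyNA(im$values))
  expect_true(all(im$values >= min(v, na.rm = TRUE) / 2))

  v2 <- v; v2[is.na(v2)] <- 7
  im2 <- impute_half_minimum(metabolite_matrix(v2, scale = "log2"))
  expect_identical(im2$values, v2)
  expect_equal(im2$imputation_value, 3.2992124)

  v3 <- matrix(c(2, NA, 4, 8), 2, 2,
               dimnames = list(c("s1", "s2"), c("m1", "m2")))
  expect_equal(impute_half_minimum(metabolite_matrix(v3, scale = "log2"))$values[2, 1],
               1)
  expect_error(impute_half_minimum(metabolite_matrix(v, scale = "raw")),
               "log2-scale")
})

test_that("univariate metabolite filter applies the per-treatment observation rule", {
  meta <- sample_metadata(paste0("s", 1:9),
                          rep(c("D-W", "W-D", "Sat"), each = 3),
                          rep(c("c1", "c2", "c3"), each = 3), rep(1:3, 3))
  v <- matrix(NA_real_, 9, 3,
              dimnames = list(meta$sample_id, c("keep", "oneTrt", "full")))
  v[c(1, 2, 7, 8), "keep"] <- 5          # 2 D-W + 2 Sat -> retained
  v[4:6, "oneTrt"] <- 5                  # 3 samples, all W-D -> removed
  v[, "full"] <- 6                       # fully observed -> retained
  mm <- metabolite_matrix(v, scale = "raw")
  f <- filter_metabolites_for_univariate(mm, meta)
  expect_identical(colnames(f$values), c("keep", "full"))
  expect_identical(filter_metabolites_for_univariate(f, meta), f)

  set.seed(21)
  for (i in 1:10) {
    r <- matrix(ifelse(runif(9 * 8) < 0.5, NA, 5), 9, 8,
                dimnames = list(meta$sample_id, paste0("m", 1:8)))
    fr <- filter_metabolites_for_univariate(metabolite_matrix(r, scale = "raw"),
                                            meta)
    manual <- vapply(colnames(r), function(m) {
      obs <- tapply(!is.na(r[, m]), meta$treatment, sum)
      sum(obs >= 2) >= 2
    }, logical(1))
    expect_identical(colnames(fr$values), colnames(r)[manual])
  }
})

test_that("outlier screen is deterministic, order-invariant, and finds a planted outlier", {
  set.seed(5)
  backbone <- matrix(rbinom(60, 1, 0.5), 1, 60)
  m <- matrix(0L, 13, 60,
              dimnames = list(sprintf("s%02d", 1:13), sprintf("o%02d", 1:60)))
  for (i in 1:12) {
    flip <- runif(60) < 0.05
    m[i, ] <- as.integer(xor(backbone[1, ] == 1, flip)) * 3L
  }
  m[13, ] <- as.integer(runif(60) < 0.5) * 3L   # unrelated profile
  tab <- otu_count_table(m)
  params <- processing_params(outlier_permutations = 499)
  r1 <- detect_sample_outliers(tab, params, seed = 42)
  r2 <- detect_sample_outliers(tab, params, seed = 42)
  expect_identical(r1, r2)
  expect_true(r1$flagged[r1$sample_id == "s13"])

  perm <- sample(nrow(m))
  tabp <- otu_count_table(m[perm, , drop = FALSE])
  r3 <- detect_sample_outliers(tabp, params, seed = 42)
  expect_equal(r3[match(r1$sample_id, r3$sample_id), "p_value"], r1$p_value)

  expect_error(detect_sample_outliers(otu_count_table(m[1:2, ]), params, 1),
               "insufficient data")

  # identical samples: nobody can be an outlier
  same <- otu_count_table(matrix(rep(c(1L, 0L, 2L, 5L), 4), 4, 4, byrow = TRUE,
                                 dimnames = list(paste0("s", 1:4), paste0("o", 1:4))))
  rs <- detect_sample_outliers(same, processing_params(outlier_permutations = 99),
                               seed = 1)
  expect_false(any(rs$flagged))
})
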