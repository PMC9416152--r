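test_that("metadata layout reproduces the study design and is deterministic", {
  meta <- simulate_metadata(sim_config())
  expect_equal(nrow(meta), 41)
  expect_equal(as.vector(table(meta$treatment)[c("D-W", "W-D", "Sat")]),
               c(10, 18, 13))
  expect_false(anyDuplicated(meta$sample_id) > 0)
  expect_identical(meta, simulate_metadata(sim_config()))

  tiny <- sim_config(samples_per_treatment = c("D-W" = 1, "W-D" = 1, "Sat" = 1),
                     cores_per_treatment = 1)
  m3 <- simulate_metadata(tiny)
  expect_equal(nrow(m3), 3)
  expect_equal(length(unique(m3$core)), 3)

  expect_error(sim_config(samples_per_treatment = c("D-W" = 0, "W-D" = 1, "Sat" = 1)),
               "invalid config")
  expect_error(sim_config(cores_per_treatment = 0), "invalid config")
  expect_error(sim_config(missing_rate = 1), "invalid config")
  expect_error(sim_config(effect_size = -1), "invalid config")
})

test_that("metabolite matrix has the study dimensions and honors missingness settings", {
  cfg <- sim_config(seed = 5)
  meta <- simulate_metadata(cfg)
  mm <- simulate_metabolites(meta, cfg)
  expect_equal(dim(mm$metabolites$values), c(41, 125))
  expect_identical(rownames(mm$metabolites$values), meta$sample_id)
  frac <- mean(is.na(mm$metabolites$values))
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.2)

  none <- sim_config(missing_rate = 0, seed = 5)
  mm0 <- simulate_metabolites(simulate_metadata(none), none)
  expect_false(anyNA(mm0$metabolites$values))

  # under censoring, missing entries sit at the low end of the latent scale
  lat <- mm$truth$latent_log2
  miss <- is.na(mm$metabolites$values)
  expect_lt(mean(lat[miss]), mean(lat[!miss]) - 1)
  # mcar missingness is value-independent
  mc <- sim_config(missingness_mechanism = "mcar", seed = 5)
  mmc <- simulate_metabolites(simulate_metadata(mc), mc)
  missc <- is.na(mmc$metabolites$values)
  expect_lt(abs(mean(mmc$truth$latent_log2[missc]) -
                  mean(mmc$truth$latent_log2[!missc])), 0.5)
})

test_that("degenerate variance limit collapses samples onto metabolite baselines", {
  cfg <- sim_config(treatment_shift_sd = 0, core_sd = 0, residual_sd = 1e-9,
                    missing_rate = 0, seed = 2)
  mm <- simulate_metabolites(simulate_metadata(cfg), cfg)
  spread <- apply(log2(mm$metabolites$values), 2, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-6)
  expect_equal(unname(log2(mm$metabolites$values[1, ])),
               unname(mm$truth$baselines), tolerance = 1e-6)
})

test_that("OTU table generation is deterministic and aligned", {
  cfg <- sim_config(n_otus = 40, seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$otus$counts, d2$otus$counts)
  expect_identical(d1$metabolites$values, d2$metabolites$values)
  expect_identical(rownames(d1$otus$counts), d1$meta$sample_id)
  expect_true(all(d1$otus$counts >= 0))
  expect_true(all(names(d1$truth$driver_map) %in% colnames(d1$otus$counts)))
  expect_true(all(unlist(lapply(d1$truth$driver_map, `[[`, "metabolite")) %in%
                    colnames(d1$metabolites$values)))
})

test_that("a large presence intercept makes target OTUs ubiquitous with nonzero counts", {
  cfg <- sim_config(n_otus = 20, n_target_otus = 5, target_intercept = 50,
                    otu_zero_inflation = 0, seed = 4)
  d <- simulate_dataset(cfg)
  tgt <- d$otus$counts[, d$truth$target_otus, drop = FALSE]
  expect_true(all(tgt > 0))
})

test_that("effect_size zero leaves target OTUs independent of their drivers", {
  # chi-square independence screen across seeds; at true independence the
  # rejection rate at alpha = 0.01 stays near nominal
  n_pairs <- 0; n_reject <- 0
  for (s in 1:40) {
    cfg <- sim_config(samples_per_treatment = c("D-W" = 70, "W-D" = 70, "Sat" = 70),
                      cores_per_treatment = 7, n_otus = 6, n_target_otus = 3,
                      n_metabolites = 12, n_driver_metabolites = 3,
                      effect_size = 0, otu_zero_inflation = 0, seed = 1000 + s)
    d <- simulate_dataset(cfg)
    for (o in names(d$truth$driver_map)) {
      y <- factor(d$otus$counts[, o] > 0, levels = c(FALSE, TRUE))
      if (length(unique(y)) < 2) next
      for (m in d$truth$driver_map[[o]]$metabolite) {
        x <- d$truth$latent_log2[, m] > median(d$truth$latent_log2[, m])
        p <- suppressWarnings(chisq.test(table(x, y))$p.value)
        n_pairs <- n_pairs + 1
        n_reject <- n_reject + (p < 0.01)
      }
    }
  }
  expect_gt(n_pairs, 50)
  expect_lt(n_reject / n_pairs, 0.05)
})

test_that("planted drivers carry more mutual information about their targets than non-drivers", {
  hits <- 0; tot <- 0
  for (s in 1:5) {
    cfg <- sim_config(samples_per_treatment = c("D-W" = 40, "W-D" = 40, "Sat" = 40),
                      cores_per_treatment = 4, n_otus = 10, n_target_otus = 5,
                      n_metabolites = 30, n_driver_metabolites = 5,
                      effect_size = 3, seed = 300 + s)
    d <- simulate_dataset(cfg)
    lat <- d$truth$latent_log2 - apply(d$truth$latent_log2, 1, median)
    for (o in names(d$truth$driver_map)) {
      y <- d$otus$counts[, o] > 0
      if (min(sum(y), sum(!y)) < 5) next
      mi <- vapply(colnames(lat), function(m) mutual_info_quartile(lat[, m], y),
                   numeric(1))
      drv <- d$truth$driver_map[[o]]$metabolite
      tot <- tot + length(drv)
      hits <- hits + sum(mi[drv] >= max(mi[setdiff(names(mi), drv)]))
    }
  }
  expect_gt(tot, 10)
  expect_gte(hits / tot, 0.9)
})
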