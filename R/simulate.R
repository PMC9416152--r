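#' Simulation configuration
#'
#' Parameters for the coupled OTU/metabolite/metadata generator. Defaults
#' reproduce the study design the analysis assumes: 41 samples split 10/18/13
#' across the Dry-Wet (D-W), Wet-Dry (W-D) and continuous-saturation (Sat)
#' moisture treatments, samples nested within soil cores, 125 metabolites with
#' missing observations, and a sparse OTU table (at reduced scale) in which a
#' small set of "driver" metabolites controls the presence probability of a
#' small set of "target" OTUs through a logistic link.
#'
#' @param samples_per_treatment Named integer vector of sample counts per
#'   treatment.
#' @param cores_per_treatment Number of soil cores per treatment; samples are
#'   assigned to cores round-robin, so technical replicates share a core.
#' @param n_otus,n_metabolites Numbers of OTUs and metabolites to generate.
#' @param n_driver_metabolites Size of the driver-metabolite pool.
#' @param n_target_otus Number of OTUs whose presence depends on drivers.
#' @param drivers_per_target Drivers sampled (from the pool) per target OTU.
#' @param effect_size Log-odds slope magnitude of each planted driver link
#'   (on the standardized log2 metabolite scale); 0 plants no signal.
#' @param target_intercept Optional fixed logit intercept for target OTUs;
#'   `NULL` draws each target's intercept to match a prevalence sampled
#'   uniformly from `prevalence_range`.
#' @param prevalence_range Range of marginal presence probabilities for
#'   non-target OTUs.
#' @param target_prevalence_range Range from which target-OTU intercept
#'   prevalences are drawn (when `target_intercept` is `NULL`); kept inside
#'   the classifiable band by default, since near-ubiquitous or
#'   near-absent OTUs carry no class contrast to learn.
#' @param missing_rate Overall fraction of metabolite observations set
#'   missing.
#' @param missingness_mechanism `"censoring"` (default): observations go
#'   missing preferentially at low abundance, emulating the detection limit
#'   of GC-MS (the premise of half-minimum imputation); `"mcar"`: entries go
#'   missing independently of their value at rate `missing_rate`.
#' @param censor_softness Softness (log2 units) of the logistic detection
#'   boundary used by the censoring mechanism.
#' @param otu_zero_inflation Dropout probability: a truly present OTU entry is
#'   recorded as zero with this probability (sequencing dropout).
#' @param count_dispersion Negative-binomial size parameter for counts of
#'   present entries (smaller = more overdispersed).
#' @param treatment_shift_sd SD of per-metabolite-per-treatment mean shifts
#'   (log2 scale).
#' @param core_sd SD of per-core random intercepts (log2 scale).
#' @param residual_sd Residual SD of log2 abundances (must be > 0).
#' @param seed Master seed; all stage-level randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(samples_per_treatment = c("D-W" = 10, "W-D" = 18, "Sat" = 13),
                       cores_per_treatment = 4,
                       n_otus = 300,
                       n_metabolites = 125,
                       n_driver_metabolites = 5,
                       n_target_otus = 10,
                       drivers_per_target = 1,
                       effect_size = 3,
                       target_intercept = NULL,
                       prevalence_range = c(0.05, 0.95),
                       target_prevalence_range = c(0.3, 0.7),
                       missing_rate = 0.1,
                       missingness_mechanism = c("censoring", "mcar"),
                       censor_softness = 0.3,
                       otu_zero_inflation = 0.02,
                       count_dispersion = 0.5,
                       treatment_shift_sd = 0.5,
                       core_sd = 0.25,
                       residual_sd = 1,
                       seed = 1L) {
  missingness_mechanism <- match.arg(missingness_mechanism)
  cfg <- list(samples_per_treatment = samples_per_treatment,
              cores_per_treatment = as.integer(cores_per_treatment),
              n_otus = as.integer(n_otus),
              n_metabolites = as.integer(n_metabolites),
              n_driver_metabolites = as.integer(n_driver_metabolites),
              n_target_otus = as.integer(n_target_otus),
              drivers_per_target = as.integer(drivers_per_target),
              effect_size = as.numeric(effect_size),
              target_intercept = target_intercept,
              prevalence_range = as.numeric(prevalence_range),
              target_prevalence_range = as.numeric(target_prevalence_range),
              missing_rate = as.numeric(missing_rate),
              missingness_mechanism = missingness_mechanism,
              censor_softness = as.numeric(censor_softness),
              otu_zero_inflation = as.numeric(otu_zero_inflation),
              count_dispersion = as.numeric(count_dispersion),
              treatment_shift_sd = as.numeric(treatment_shift_sd),
              core_sd = as.numeric(core_sd),
              residual_sd = as.numeric(residual_sd),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  spt <- cfg$samples_per_treatment
  if (is.null(names(spt)) || anyDuplicated(names(spt))) {
    stop("invalid config: samples_per_treatment must be uniquely named by treatment")
  }
  if (length(spt) < 1 || any(spt < 1)) {
    stop("invalid config: every treatment needs at least one sample")
  }
  if (cfg$cores_per_treatment < 1) {
    stop("invalid config: every treatment needs at least one core")
  }
  if (cfg$n_otus < 1 || cfg$n_metabolites < 1) {
    stop("invalid config: n_otus and n_metabolites must be positive")
  }
  if (cfg$n_driver_metabolites < 0 || cfg$n_driver_metabolites > cfg$n_metabolites) {
    stop("invalid config: n_driver_metabolites must lie in [0, n_metabolites]")
  }
  if (cfg$n_target_otus < 0 || cfg$n_target_otus > cfg$n_otus) {
    stop("invalid config: n_target_otus must lie in [0, n_otus]")
  }
  if (cfg$n_target_otus > 0 && cfg$n_driver_metabolites > 0 &&
      cfg$drivers_per_target < 1) {
    stop("invalid config: drivers_per_target must be positive")
  }
  if (cfg$effect_size < 0) stop("invalid config: effect_size must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("invalid config: missing_rate must lie in [0, 1)")
  }
  if (cfg$otu_zero_inflation < 0 || cfg$otu_zero_inflation >= 1) {
    stop("invalid config: otu_zero_inflation must lie in [0, 1)")
  }
  if (cfg$count_dispersion <= 0) stop("invalid config: count_dispersion must be > 0")
  if (cfg$treatment_shift_sd < 0 || cfg$core_sd < 0) {
    stop("invalid config: treatment_shift_sd and core_sd must be >= 0")
  }
  if (cfg$residual_sd <= 0) stop("invalid config: residual_sd must be > 0")
  for (fld in c("prevalence_range", "target_prevalence_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2 || any(r <= 0) || any(r >= 1) || r[1] > r[2]) {
      stop("invalid config: ", fld, " must be an ordered pair inside (0, 1)")
    }
  }
  invisible(cfg)
}

#' Generate sample metadata
#'
#' Lays out samples per treatment, assigns each to a soil core round-robin,
#' and indexes technical replicates within cores. The layout is a
#' deterministic function of the configuration.
#'
#' @param config A [sim_config()].
#' @return A metadata `data.frame` (see [sample_metadata()]).
#' @export
#' @examples
#' meta <- simulate_metadata(sim_config())
#' table(meta$treatment)  # 10 D-W, 18 W-D, 13 Sat
simulate_metadata <- function(config) {
  validate_sim_config(config)
  spt <- config$samples_per_treatment
  rows <- lapply(names(spt), function(tr) {
    n <- spt[[tr]]
    core_idx <- rep_len(seq_len(config$cores_per_treatment), n)
    core_idx <- sort(core_idx)
    rep_idx <- stats::ave(core_idx, core_idx, FUN = seq_along)
    data.frame(sample_id = sprintf("%s_c%d_r%d", tr, core_idx, rep_idx),
               treatment = tr,
               core = sprintf("%s_core%d", tr, core_idx),
               replicate = rep_idx,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  sample_metadata(df$sample_id, df$treatment, df$core, df$replicate,
                  treatments = names(spt))
}

#' Generate a metabolite abundance matrix
#'
#' Draws raw-scale abundances log-normally: each log2 value is a metabolite
#' baseline plus a per-metabolite-per-treatment shift, a per-core intercept,
#' and a residual. A fraction `missing_rate` of entries then goes missing —
#' by default through a soft detection-limit boundary (low abundances drop
#' out first, as in GC-MS), or completely at random under the `"mcar"`
#' mechanism. The returned truth records every draw, including the complete
#' (pre-censoring) log2 matrix that later drives planted OTU links.
#'
#' @param meta Metadata from [simulate_metadata()].
#' @param config A [sim_config()].
#' @return `list(metabolites = metabolite_matrix (raw scale), truth = list)`.
#' @export
simulate_metabolites <- function(meta, config) {
  validate_sim_config(config)
  if (nrow(meta) == 0) stop("metadata must be nonempty")
  n_s <- nrow(meta)
  n_m <- config$n_metabolites
  met_ids <- sprintf("met%03d", seq_len(n_m))
  with_seed(seed_from(config$seed, "metabolites"), {
    baseline <- runif(n_m, 8, 14)
    trts <- levels(meta$treatment)
    shift <- matrix(rnorm(length(trts) * n_m, 0, config$treatment_shift_sd),
                    nrow = length(trts), dimnames = list(trts, met_ids))
    cores <- sort(unique(meta$core))
    core_eff <- setNames(rnorm(length(cores), 0, config$core_sd), cores)
    resid <- matrix(rnorm(n_s * n_m, 0, config$residual_sd), n_s, n_m)
    log2val <- matrix(baseline, n_s, n_m, byrow = TRUE) +
      shift[as.character(meta$treatment), , drop = FALSE] +
      core_eff[meta$core] + resid
    dimnames(log2val) <- list(meta$sample_id, met_ids)
    if (config$missing_rate > 0) {
      p_miss <- if (config$missingness_mechanism == "censoring") {
        lod <- quantile(log2val, config$missing_rate, type = 7, names = FALSE)
        plogis((lod - log2val) / config$censor_softness)
      } else {
        config$missing_rate
      }
      miss <- matrix(runif(n_s * n_m) < p_miss, n_s, n_m)
    } else {
      miss <- matrix(FALSE, n_s, n_m)
    }
    values <- 2^log2val
    values[miss] <- NA_real_
  })
  truth <- list(
    baselines = setNames(baseline, met_ids),
    treatment_effects = shift,
    core_effects = core_eff,
    latent_log2 = log2val
  )
  list(metabolites = metabolite_matrix(values, scale = "raw"), truth = truth)
}

#' Generate an OTU count table with planted metabolite links
#'
#' Target OTUs are present in a sample with probability
#' `plogis(intercept + sum(slope * z))`, where `z` is the driver metabolite's
#' latent log2 abundance, median-centered within each sample's profile and
#' then standardized within the sample's treatment group; every slope has
#' magnitude `effect_size` and random sign. The link therefore acts on the
#' metabolite's relative abundance — relative to the sample's overall
#' metabolite profile and to its moisture condition — which is the scale on
#' which occurrence models operate downstream; planting on absolute
#' abundance would instead bury part of the association in sample- and
#' treatment-level offsets that normalization deliberately removes.
#' Non-target OTUs are present independently with a prevalence drawn
#' uniformly from `prevalence_range`.
#' Present entries receive counts `1 + NegBin(size = count_dispersion)` so
#' presence always means a nonzero count, then sequencing dropout zeroes a
#' fraction `otu_zero_inflation` of them.
#'
#' @param meta Metadata from [simulate_metadata()].
#' @param metab Result of [simulate_metabolites()] (its truth supplies the
#'   latent log2 matrix).
#' @param truth Truth list from [simulate_metabolites()].
#' @param config A [sim_config()].
#' @return `list(otus = otu_count_table, truth = truth with driver_map)`.
#' @export
simulate_otus <- function(meta, metab, truth, config) {
  validate_sim_config(config)
  check_alignment(rownames(metab$values), meta, "metabolite matrix")
  n_s <- nrow(meta)
  n_o <- config$n_otus
  otu_ids <- sprintf("otu%04d", seq_len(n_o))
  # links act on relative abundance: profile-centered latent log2 values
  latent <- truth$latent_log2 - apply(truth$latent_log2, 1, median)
  with_seed(seed_from(config$seed, "otus"), {
    n_tgt <- min(config$n_target_otus,
                 if (config$n_driver_metabolites > 0) config$n_target_otus else 0)
    targets <- if (n_tgt > 0) sort(sample(otu_ids, n_tgt)) else character(0)
    pool <- if (config$n_driver_metabolites > 0) {
      sort(sample(colnames(latent), config$n_driver_metabolites))
    } else character(0)
    driver_map <- list()
    presence <- matrix(FALSE, n_s, n_o, dimnames = list(meta$sample_id, otu_ids))
    prevalence <- setNames(rep(NA_real_, n_o), otu_ids)
    for (o in otu_ids) {
      if (o %in% targets && length(pool) > 0) {
        k <- min(config$drivers_per_target, length(pool))
        drv <- sort(sample(pool, k))
        slopes <- config$effect_size * sample(c(-1, 1), k, replace = TRUE)
        icpt <- if (!is.null(config$target_intercept)) {
          config$target_intercept
        } else {
          qlogis(runif(1, config$target_prevalence_range[1],
                       config$target_prevalence_range[2]))
        }
        z <- vapply(drv, function(m) {
          x <- latent[, m]
          out <- numeric(n_s)
          for (tr in levels(meta$treatment)) {
            g <- meta$treatment == tr
            s <- sd(x[g])
            out[g] <- if (isTRUE(s > 0)) (x[g] - mean(x[g])) / s else 0
          }
          out
        }, numeric(n_s))
        eta <- icpt + as.vector(z %*% slopes)
        presence[, o] <- runif(n_s) < plogis(eta)
        driver_map[[o]] <- data.frame(metabolite = drv, slope = slopes,
                                      stringsAsFactors = FALSE)
      } else {
        prevalence[o] <- runif(1, config$prevalence_range[1],
                               config$prevalence_range[2])
        presence[, o] <- runif(n_s) < prevalence[o]
      }
    }
    mu <- rlnorm(n_o, meanlog = log(20), sdlog = 1)
    counts <- matrix(0L, n_s, n_o, dimnames = dimnames(presence))
    for (j in seq_len(n_o)) {
      idx <- which(presence[, j])
      if (length(idx)) {
        counts[idx, j] <- 1L + rnbinom(length(idx),
                                       size = config$count_dispersion,
                                       mu = mu[j])
      }
    }
    if (config$otu_zero_inflation > 0) {
      drop <- matrix(runif(n_s * n_o) < config$otu_zero_inflation, n_s, n_o)
      counts[drop] <- 0L
    }
  })
  phyla <- c("Acidobacteria", "Actinobacteria", "Bacteroidetes", "Firmicutes",
             "Latescibacteria", "Planctomycetes", "Proteobacteria",
             "Verrucomicrobia")
  tax <- setNames(paste0("p__", rep_len(phyla, n_o), ";g__genus",
                         seq_len(n_o)), otu_ids)
  truth$driver_map <- driver_map
  truth$target_otus <- names(driver_map)
  truth$driver_pool <- pool
  truth$background_prevalence <- prevalence[!otu_ids %in% names(driver_map)]
  list(otus = otu_count_table(counts, taxonomy = tax), truth = truth)
}

#' Simulate a complete coupled dataset
#'
#' Convenience wrapper chaining [simulate_metadata()],
#' [simulate_metabolites()] and [simulate_otus()].
#'
#' @param config A [sim_config()].
#' @return `list(meta, otus, metabolites, truth, config)` of class
#'   `om_dataset`.
#' @export
#' @examples
#' d <- simulate_dataset(sim_config(n_otus = 50, seed = 7))
#' d$otus
simulate_dataset <- function(config = sim_config()) {
  meta <- simulate_metadata(config)
  mm <- simulate_metabolites(meta, config)
  oo <- simulate_otus(meta, mm$metabolites, mm$truth, config)
  structure(list(meta = meta, otus = oo$otus, metabolites = mm$metabolites,
                 truth = oo$truth, config = config),
            class = "om_dataset")
}

#' @export
print.om_dataset <- function(x, ...) {
  cat(sprintf("<om_dataset> %d samples (%s); %d OTUs; %d metabolites; %d planted target OTUs\n",
              nrow(x$meta),
              paste(sprintf("%s=%d", names(table(x$meta$treatment)),
                            table(x$meta$treatment)), collapse = ", "),
              ncol(x$otus$counts), ncol(x$metabolites$values),
              length(x$truth$target_otus)))
  invisible(x)
}
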