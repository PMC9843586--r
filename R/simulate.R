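#' Configuration for the synthetic glioma-like cohort generator
#'
#' Defaults emulate the structure of a mixed LGG/GBM discovery cohort: a
#' favorable mutation status (`status1`, e.g. IDH mutation) with prevalence
#' about two thirds, a second favorable status (`status2`, e.g. 1p/19q
#' co-deletion) nested almost entirely within the first, gene pairs whose
#' within-sample ordering reverses with each status, survival hazard reduced
#' multiplicatively by the favorable statuses, and independent right
#' censoring.
#'
#' Expression is log-normal: cell value = `exp(mean + noise)` with Gaussian
#' log-scale noise. For a planted pair tied to a status, the two genes share a
#' baseline log-level and a per-sample pair-level random effect; their means
#' are offset by `+reversal_strength/2` and `-reversal_strength/2`, with the
#' offsets swapping when the status flips. The mean log-separation between the
#' paired genes is therefore `reversal_strength`, giving a closed-form
#' per-sample probability of observing the status-typical ordering of
#' `pnorm(reversal_strength / (noise_sd * sqrt(2)))` (the shared pair effect
#' cancels within the pair). The shared effect exists so that genes from two
#' different planted pairs do not themselves form strong reversal pairs.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param prevalence_s1 Probability a sample carries status 1 (favorable).
#' @param conditional_s2_given_s1,conditional_s2_given_not_s1 Probability of
#'   status 2 within and outside status-1 carriers. The defaults (0.40, 0)
#'   nest status 2 inside status 1, mirroring co-deletion occurring within
#'   IDH-mutant tumors; set both equal to make the statuses independent.
#' @param n_planted_pairs_s1,n_planted_pairs_s2 Number of reversal pairs
#'   planted for each status; the two gene sets are disjoint.
#' @param reversal_strength Mean log-expression separation between the two
#'   genes of a planted pair (see Details).
#' @param noise_sd Per-cell log-scale noise standard deviation (> 0).
#' @param pair_effect_sd Standard deviation of the shared per-pair per-sample
#'   log-scale effect.
#' @param baseline_mean,baseline_sd Log-scale baseline level distribution of
#'   the genes.
#' @param baseline_hazard Events per time unit for the reference group.
#' @param log_hr_s1,log_hr_s2 Log hazard ratios of the statuses (negative =
#'   protective).
#' @param censor_time_max Administrative censoring horizon; censoring times
#'   are `min(Uniform(0, 2 * censor_time_max), censor_time_max)`, mixing early
#'   drop-out with an administrative mass at the horizon.
#' @param status_names Names of the two status columns in the clinical table.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples = 300,
                       n_genes = 1000,
                       prevalence_s1 = 0.67,
                       conditional_s2_given_s1 = 0.40,
                       conditional_s2_given_not_s1 = 0,
                       n_planted_pairs_s1 = 10,
                       n_planted_pairs_s2 = 10,
                       reversal_strength = 2,
                       noise_sd = 1,
                       pair_effect_sd = 2,
                       baseline_mean = 7,
                       baseline_sd = 2,
                       baseline_hazard = 0.1,
                       log_hr_s1 = -1,
                       log_hr_s2 = -0.7,
                       censor_time_max = 10,
                       status_names = c("status1", "status2"),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    prevalence_s1 = prevalence_s1,
    conditional_s2_given_s1 = conditional_s2_given_s1,
    conditional_s2_given_not_s1 = conditional_s2_given_not_s1,
    n_planted_pairs_s1 = as.integer(n_planted_pairs_s1),
    n_planted_pairs_s2 = as.integer(n_planted_pairs_s2),
    reversal_strength = reversal_strength, noise_sd = noise_sd,
    pair_effect_sd = pair_effect_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    baseline_hazard = baseline_hazard,
    log_hr_s1 = log_hr_s1, log_hr_s2 = log_hr_s2,
    censor_time_max = censor_time_max,
    status_names = status_names, seed = as.integer(seed)
  )
  probs <- c(
    cfg$prevalence_s1, cfg$conditional_s2_given_s1,
    cfg$conditional_s2_given_not_s1
  )
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (cfg$n_samples < 2 || cfg$n_genes < 2) abort("Need at least 2 samples and 2 genes.")
  if (cfg$n_planted_pairs_s1 < 0 || cfg$n_planted_pairs_s2 < 0) {
    abort("Planted pair counts must be >= 0.")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0.")
  if (cfg$pair_effect_sd < 0) abort("pair_effect_sd must be >= 0.")
  if (cfg$censor_time_max <= 0) abort("censor_time_max must be > 0.")
  if (cfg$baseline_hazard <= 0) abort("baseline_hazard must be > 0.")
  n_planted_genes <- 2L * (cfg$n_planted_pairs_s1 + cfg$n_planted_pairs_s2)
  if (cfg$n_planted_pairs_s1 + cfg$n_planted_pairs_s2 > cfg$n_genes / 2) {
    abort("Planted pairs exceed n_genes / 2.")
  }
  if (length(cfg$status_names) != 2 || anyDuplicated(cfg$status_names)) {
    abort("status_names must be two distinct names.")
  }
  structure(cfg, class = "sim_config")
}

#' Generate survival times under a two-status proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hr_s1 * s1 + log_hr_s2 * s2)`; censoring times
#' are `min(Uniform(0, 2 * censor_time_max), censor_time_max)`, independent of
#' the event process. The marginal event fraction is reported via a message.
#'
#' @param s1,s2 Binary 0/1 status vectors of equal length.
#' @param baseline_hazard Events per time unit in the double-negative group.
#' @param log_hr_s1,log_hr_s2 Log hazard ratios.
#' @param censor_time_max Administrative horizon (> 0).
#' @param seed Integer seed.
#' @return A tibble with columns `os_time` and `event`.
#' @export
generate_survival <- function(s1, s2 = rep(0L, length(s1)),
                              baseline_hazard = 0.1,
                              log_hr_s1 = -1, log_hr_s2 = 0,
                              censor_time_max = 10, seed = 1L) {
  if (length(s1) != length(s2)) abort("Status vectors must have equal length.")
  n <- length(s1)
  withr::local_seed(as.integer(seed))
  hazard <- baseline_hazard * exp(log_hr_s1 * s1 + log_hr_s2 * s2)
  death <- rexp(n, rate = hazard)
  censor <- pmin(runif(n, 0, 2 * censor_time_max), censor_time_max)
  os_time <- pmin(death, censor)
  event <- as.integer(death <= censor)
  inform(sprintf("generate_survival: event fraction %.3f", mean(event)))
  tibble(os_time = os_time, event = event)
}

#' Generate a synthetic cohort with planted reversal pairs
#'
#' See [sim_config()] for the generative model. Returns the cohort together
#' with the ground truth needed to score recovery: the planted oriented pairs
#' per status and the per-sample statuses.
#'
#' In the planted-pair orientation, `gene_up` is the gene whose expression is
#' the higher of the pair in status-positive samples (and the lower in
#' status-negative samples); this matches the detection convention where
#' `gene_i` comes from the upregulated candidate set.
#'
#' Randomness is split into two phases. The structural draws (which genes are
#' planted, gene and pair baseline levels) depend only on the config's `seed`;
#' the sampling draws (statuses, noise, survival) use `sample_seed`, which
#' defaults to the config's `seed`. Calling with the same config and a
#' different `sample_seed` therefore yields an independent cohort from the
#' same population — i.e. an external validation cohort measuring the same
#' genes with the same planted pairs.
#'
#' @param config A [sim_config()] object.
#' @param sample_seed Optional integer overriding the seed of the
#'   sampling phase (see Details).
#' @return A list with elements `cohort` (a `pair_cohort`) and `truth` (a list
#'   with `planted_pairs_s1`, `planted_pairs_s2` tibbles of `gene_up`,
#'   `gene_down`, the per-sample `statuses` tibble, and the true log hazard
#'   ratios).
#' @export
generate_cohort <- function(config = sim_config(), sample_seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sample_seed <- as.integer(sample_seed %||% cfg$seed)

  n <- cfg$n_samples
  g <- cfg$n_genes
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(g))
  np1 <- cfg$n_planted_pairs_s1
  np2 <- cfg$n_planted_pairs_s2

  # structural phase: gene layout shared by every cohort from this config
  structure_draws <- withr::with_seed(cfg$seed, {
    list(
      planted_idx = sample.int(g, 2L * (np1 + np2)),
      baseline = rnorm(g, cfg$baseline_mean, cfg$baseline_sd),
      pair_baseline = rnorm(np1 + np2, cfg$baseline_mean, cfg$baseline_sd)
    )
  })
  idx1 <- structure_draws$planted_idx[seq_len(2L * np1)]
  idx2 <- structure_draws$planted_idx[seq_len(2L * np2) + 2L * np1]

  # sampling phase
  withr::local_seed(sample_seed)
  s1 <- rbinom(n, 1, cfg$prevalence_s1)
  p2 <- ifelse(s1 == 1, cfg$conditional_s2_given_s1, cfg$conditional_s2_given_not_s1)
  s2 <- rbinom(n, 1, p2)

  mean_mat <- matrix(structure_draws$baseline, nrow = g, ncol = n)
  delta <- cfg$reversal_strength
  plant <- function(idx, status, n_pairs, base_offset) {
    if (n_pairs == 0) {
      return(tibble(gene_up = character(), gene_down = character()))
    }
    up <- idx[seq_len(n_pairs)]
    down <- idx[seq_len(n_pairs) + n_pairs]
    for (p in seq_len(n_pairs)) {
      b <- structure_draws$pair_baseline[base_offset + p]
      u <- rnorm(n, 0, cfg$pair_effect_sd) # shared within the pair
      sgn <- ifelse(status == 1, 1, -1) # up gene higher when status present
      mean_mat[up[p], ] <<- b + sgn * delta / 2 + u
      mean_mat[down[p], ] <<- b - sgn * delta / 2 + u
    }
    tibble(gene_up = gene_ids[up], gene_down = gene_ids[down])
  }
  pairs1 <- plant(idx1, s1, np1, 0L)
  pairs2 <- plant(idx2, s2, np2, np1)

  values <- exp(mean_mat + matrix(rnorm(g * n, 0, cfg$noise_sd), g, n))
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "incomplete_genes") <- character()

  surv <- withCallingHandlers(
    generate_survival(
      s1, s2,
      baseline_hazard = cfg$baseline_hazard,
      log_hr_s1 = cfg$log_hr_s1, log_hr_s2 = cfg$log_hr_s2,
      censor_time_max = cfg$censor_time_max,
      seed = sample_seed + 77003L
    ),
    message = function(m) invokeRestart("muffleMessage")
  )

  clinical <- tibble(
    sample_id = sample_ids,
    !!cfg$status_names[1] := as.integer(s1),
    !!cfg$status_names[2] := as.integer(s2),
    os_time = surv$os_time,
    event = surv$event
  )

  cohort <- structure(
    list(expression = values, clinical = clinical),
    class = "pair_cohort"
  )
  truth <- list(
    planted_pairs_s1 = pairs1,
    planted_pairs_s2 = pairs2,
    statuses = tibble(
      sample_id = sample_ids,
      !!cfg$status_names[1] := as.integer(s1),
      !!cfg$status_names[2] := as.integer(s2)
    ),
    log_hr = setNames(
      c(cfg$log_hr_s1, cfg$log_hr_s2),
      cfg$status_names
    )
  )
  list(cohort = cohort, truth = truth)
}

#' Apply an independent strictly increasing distortion to every sample
#'
#' Emulates arbitrary per-sample platform/normalization differences: each
#' sample's values are passed through an independently drawn strictly
#' increasing map (a power, positive-affine, shifted-log or identity
#' transform). Within-sample orderings — and therefore every downstream
#' output of the pipeline — are preserved exactly.
#'
#' @param expr Positive numeric genes-by-samples matrix.
#' @param seed Integer seed for the per-sample draws.
#' @param kinds Transform families to draw from.
#' @return A matrix of the same shape and dimnames.
#' @export
apply_monotone_distortion <- function(expr, seed = 1L,
                                      kinds = c("power", "affine", "log")) {
  kinds <- match.arg(kinds,
    choices = c("power", "affine", "log", "identity"),
    several.ok = TRUE
  )
  if (any(expr <= 0, na.rm = TRUE)) {
    abort("apply_monotone_distortion() requires strictly positive values.")
  }
  withr::local_seed(as.integer(seed))
  out <- expr
  for (j in seq_len(ncol(expr))) {
    kind <- sample(kinds, 1)
    x <- expr[, j]
    out[, j] <- switch(kind,
      power = x^runif(1, 0.3, 3),
      affine = runif(1, 0.5, 2) * x + runif(1, 0, 5),
      log = log(x) * runif(1, 0.5, 2) + runif(1, 0, 3),
      identity = x
    )
  }
  attr(out, "incomplete_genes") <- attr(expr, "incomplete_genes")
  out
}
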