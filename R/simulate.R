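# Synthetic plate- and cohort-level data with the statistical structure the
# analysis assumes: latent per-ligand functionality scores, a logistic
# response model on the PD-1 score, response-dependent exponential survival
# with uniform right-censoring, CPS imperfectly concordant with PD-L1
# functionality, and raw wells constructed by inverting the score formula
# so that scoring them recovers the latent scores.

#' Generator configuration
#'
#' Defaults describe a 29-patient cohort with roughly half responders, a
#' strong association between the PD-1 score and response, mean overall
#' survival near 32 months for responders and 17 for non-responders, and
#' plate measurements whose scores invert exactly at zero noise.
#'
#' @param n_patients cohort size (default 29).
#' @param seed integer seed.
#' @param ligand_meanlog log-scale means of the latent PD-L1 and PD-L2
#'   functionality scores (log-normal).
#' @param ligand_sdlog log-scale SD of the latent scores.
#' @param response_intercept,response_slope logistic model of response on
#'   the latent PD-1 score: P(responder) = plogis(intercept + slope * pd1).
#' @param cps_concordance probability that CPS positivity agrees with
#'   (latent PD-L1 > `score_cutoff`).
#' @param score_cutoff stratification cutoff the concordance refers to.
#' @param score_margin half-width of an excluded band around `score_cutoff`
#'   on the latent PD-1 score: latents are rejection-sampled until they fall
#'   outside the band. Default 0 (no gap); the strong-effect preset uses a
#'   positive margin so that, combined with a steep response slope, the
#'   scores separate responders from non-responders nearly deterministically.
#' @param os_mean_responder,os_mean_nonresponder exponential mean survival
#'   (months) by response class; responders must survive longer.
#' @param pfs_frac mean PFS as a fraction of mean OS.
#' @param censor_time_max right-censoring times ~ Uniform(0, max].
#' @param well_noise_sd Gaussian well noise as a fraction of signal.
#' @param coverage_range tissue coverage (mm^2) drawn uniformly; low > 1.
#' @param pc_ratio_spread log-scale SD of per-plate positive-control ratios.
#' @param replicates wells per condition.
#' @param samples_per_plate samples per 96-well plate.
#' @param missing_cps_n patients with missing CPS (default 1, as cohorts
#'   commonly have an unevaluable stain).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_patients = 29, seed = 1,
                             ligand_meanlog = c(pdl1 = log(2), pdl2 = log(1.2)),
                             ligand_sdlog = 0.9,
                             response_intercept = -5.5, response_slope = 1.3,
                             cps_concordance = 0.7, score_cutoff = 4,
                             score_margin = 0,
                             os_mean_responder = 32, os_mean_nonresponder = 17,
                             pfs_frac = 0.7,
                             censor_time_max = 60,
                             well_noise_sd = 0.05,
                             coverage_range = c(2, 12),
                             pc_ratio_spread = 0.15,
                             replicates = 2, samples_per_plate = 10,
                             missing_cps_n = 1) {
  cfg <- list(n_patients = n_patients, seed = seed,
              ligand_meanlog = ligand_meanlog, ligand_sdlog = ligand_sdlog,
              response_intercept = response_intercept,
              response_slope = response_slope,
              cps_concordance = cps_concordance, score_cutoff = score_cutoff,
              score_margin = score_margin,
              os_mean_responder = os_mean_responder,
              os_mean_nonresponder = os_mean_nonresponder,
              pfs_frac = pfs_frac,
              censor_time_max = censor_time_max,
              well_noise_sd = well_noise_sd,
              coverage_range = coverage_range,
              pc_ratio_spread = pc_ratio_spread,
              replicates = replicates, samples_per_plate = samples_per_plate,
              missing_cps_n = missing_cps_n)
  .validate_config(cfg)
  structure(cfg, class = "generator_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, field) if (!ok) stop("invalid config field: ", field)
  chk(cfg$n_patients >= 1, "n_patients")
  chk(cfg$ligand_sdlog > 0, "ligand_sdlog")
  chk(cfg$cps_concordance >= 0 && cfg$cps_concordance <= 1, "cps_concordance")
  chk(cfg$score_margin >= 0, "score_margin")
  chk(cfg$os_mean_responder > cfg$os_mean_nonresponder,
      "os_mean_responder (responders must out-survive non-responders)")
  chk(cfg$censor_time_max > 0, "censor_time_max")
  chk(cfg$well_noise_sd >= 0, "well_noise_sd")
  chk(length(cfg$coverage_range) == 2 && cfg$coverage_range[1] > 1 &&
        diff(cfg$coverage_range) >= 0, "coverage_range")
  chk(cfg$pc_ratio_spread >= 0, "pc_ratio_spread")
  chk(cfg$replicates >= 1, "replicates")
  invisible(cfg)
}

#' Named generator presets
#'
#' `default` matches the study conditions; `strong-effect` raises the
#' response slope so the scores nearly determine response (for evaluating
#' the predictive protocol under a strong signal); `null` sets the slope to
#' zero so response is independent of the scores.
#'
#' @param preset one of `"default"`, `"strong-effect"`, `"null"`.
#' @param ... overrides passed to [generator_config()].
#' @return a `generator_config`.
#' @export
generator_preset <- function(preset = c("default", "strong-effect", "null"),
                             ...) {
  preset <- match.arg(preset)
  switch(preset,
         "default" = generator_config(...),
         "strong-effect" = generator_config(response_intercept = -100,
                                            response_slope = 25,
                                            score_margin = 0.75, ...),
         "null" = generator_config(response_intercept = 0,
                                   response_slope = 0, ...))
}

#' Generate a synthetic patient cohort
#'
#' Latent PD-L1 and PD-L2 functionality scores are log-normal; the latent
#' PD-1 score is their sum (receptor blockade ablates both ligand
#' interactions). Response is Bernoulli with a logistic link on the PD-1
#' score; OS is exponential with response-dependent mean, right-censored
#' uniformly; PFS is a fraction of OS; CPS positivity agrees with latent
#' PD-L1 functionality above the cutoff with probability
#' `cps_concordance`; line of treatment is multinomial with the 10/17/2
#' first/second/third-line pattern.
#'
#' @param config a `generator_config`.
#' @return list: `cohort` (patient data.frame ready for the cohort CSV
#'   schema) and `truth` (latent per-patient values for recovery tests).
#' @export
generate_cohort <- function(config = generator_config()) {
  .validate_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  pdl1 <- stats::rlnorm(n, config$ligand_meanlog[["pdl1"]], config$ligand_sdlog)
  pdl2 <- stats::rlnorm(n, config$ligand_meanlog[["pdl2"]], config$ligand_sdlog)
  pd1 <- pdl1 + pdl2
  if (config$score_margin > 0) {
    # rejection-sample latents out of the excluded band around the cutoff
    for (iter in 1:1000) {
      inband <- abs(pd1 - config$score_cutoff) < config$score_margin
      if (!any(inband)) break
      k <- sum(inband)
      pdl1[inband] <- stats::rlnorm(k, config$ligand_meanlog[["pdl1"]],
                                    config$ligand_sdlog)
      pdl2[inband] <- stats::rlnorm(k, config$ligand_meanlog[["pdl2"]],
                                    config$ligand_sdlog)
      pd1 <- pdl1 + pdl2
    }
  }

  p_resp <- stats::plogis(config$response_intercept +
                            config$response_slope * pd1)
  responder <- stats::rbinom(n, 1, p_resp) == 1
  best_response <- ifelse(responder,
                          ifelse(stats::runif(n) < 0.2, "CR", "PR"),
                          ifelse(stats::runif(n) < 0.5, "SD", "PD"))

  os_mean <- ifelse(responder, config$os_mean_responder,
                    config$os_mean_nonresponder)
  os_true <- stats::rexp(n, rate = 1 / os_mean)
  censor <- stats::runif(n, 0, config$censor_time_max)
  os_months <- pmin(os_true, censor)
  os_event <- os_true <= censor
  pfs_true <- pmin(os_true, stats::rexp(n, rate = 1 / (os_mean * config$pfs_frac)))
  pfs_months <- pmin(pfs_true, censor)
  pfs_event <- pfs_true <= censor

  pdl1_high <- pdl1 > config$score_cutoff
  agree <- stats::runif(n) < config$cps_concordance
  cps_positive <- ifelse(agree, pdl1_high, !pdl1_high)
  cps_value <- ifelse(cps_positive,
                      round(stats::rlnorm(n, log(8), 0.9), 1),
                      round(stats::runif(n, 0, 0.99), 2))
  cps_value[cps_positive & cps_value < 1] <- 1
  if (config$missing_cps_n > 0) {
    cps_value[sample.int(n, min(config$missing_cps_n, n))] <- NA_real_
  }

  line_of_treatment <- sample(1:3, n, replace = TRUE,
                              prob = c(10, 17, 2) / 29)

  # response timeline: responders start responding a few months in and the
  # response lasts until progression; progression-free at last follow-up
  # means the response is ongoing
  response_start <- ifelse(responder, pmin(stats::runif(n, 1, 4), pfs_months), NA)
  response_end <- pfs_months
  ongoing <- responder & !pfs_event
  response_end[!responder] <- NA
  response_end[ongoing] <- NA

  cohort <- data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    best_response = best_response,
    os_months = os_months, os_event = os_event,
    pfs_months = pfs_months, pfs_event = pfs_event,
    line_of_treatment = line_of_treatment,
    cps_value = cps_value,
    pd1_score = pd1, pdl1_score = pdl1, pdl2_score = pdl2,
    response_start_months = response_start,
    response_end_months = response_end,
    ongoing = ongoing,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_id = cohort$patient_id,
    pd1_latent = pd1, pdl1_latent = pdl1, pdl2_latent = pdl2,
    p_response = p_resp, responder = responder,
    pdl1_high = pdl1_high, cps_positive = cps_positive,
    os_true = os_true, censor_time = censor,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, truth = truth)
}

#' Generate raw plate wells realizing a cohort's latent scores
#'
#' Inverts the score formula: for each patient a shared no-antibody signal
#' is set high enough that every blocking condition's drop equals
#' `latent_score * log2(coverage) / pc_ratio`, plus optional Gaussian well
#' noise. Per-plate positive-control wells realize the drawn PC ratio, so
#' at zero noise scoring the wells (with the generator's `pc_reference`)
#' returns the latent scores exactly, regardless of plate effects.
#'
#' @param truth truth table from [generate_cohort()].
#' @param config the same `generator_config`.
#' @param pc_reference reference positive-control signal (assay units).
#' @param blocked_floor baseline fully-blocked signal (assay units).
#' @return list: `wells` data.frame in the plate CSV schema,
#'   `pc_reference`, and `plate_truth` (per-plate drawn PC ratios).
#' @export
generate_plates <- function(truth, config = generator_config(),
                            pc_reference = 1000, blocked_floor = 5) {
  .validate_config(config)
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  plate_of <- ceiling(seq_len(n) / config$samples_per_plate)
  plate_ids <- sprintf("PLATE%02d", plate_of)
  n_plates <- max(plate_of)
  pc_ratio <- exp(stats::rnorm(n_plates, 0, config$pc_ratio_spread))
  coverage <- stats::runif(n, config$coverage_range[1], config$coverage_range[2])

  noisy <- function(x) {
    if (config$well_noise_sd == 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, config$well_noise_sd)), 0)
  }
  rows <- vector("list", 0)
  add <- function(plate, sample, cond, signal, cov, rep_i) {
    rows[[length(rows) + 1]] <<- data.frame(
      plate_id = plate, sample_id = sample, condition = cond,
      signal = signal, coverage_mm2 = cov, replicate_index = rep_i,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    p <- plate_of[i]
    scale_i <- log2(coverage[i]) / pc_ratio[p]
    lat <- c(BLOCK_PD1 = truth$pd1_latent[i],
             BLOCK_PDL1 = truth$pdl1_latent[i],
             BLOCK_PDL2 = truth$pdl2_latent[i])
    unblocked <- blocked_floor + max(lat) * scale_i
    for (r in seq_len(config$replicates)) {
      add(plate_ids[i], truth$patient_id[i], "NO_AB",
          noisy(unblocked), coverage[i], r)
      for (cond in names(lat)) {
        add(plate_ids[i], truth$patient_id[i], cond,
            noisy(unblocked - lat[[cond]] * scale_i), coverage[i], r)
      }
    }
  }
  for (p in seq_len(n_plates)) {
    for (r in seq_len(config$replicates)) {
      add(sprintf("PLATE%02d", p), "PC", "POSITIVE_CONTROL",
          noisy(pc_reference / pc_ratio[p]), NA_real_, r)
    }
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  list(wells = wells, pc_reference = pc_reference,
       plate_truth = data.frame(plate_id = sprintf("PLATE%02d", seq_len(n_plates)),
                                pc_ratio = pc_ratio))
}
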