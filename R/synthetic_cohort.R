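#' Specification of a simulated DCIS survival cohort
#'
#' Defines the covariate model, the two cause-specific baseline hazards
#' (in-situ recurrence and invasive progression), the planted log hazard
#' ratios per cause, the radiotherapy-by-TIL interaction on the log-hazard
#' scale, and administrative censoring. Defaults emulate the scale of a
#' DCIS trial biomarker cohort: age ~ Normal(57.4, 6.0) years, tumour size
#' ~ Normal(15.6, 8.5) mm truncated positive, roughly one patient in five
#' with an ipsilateral breast event by ~12.7 years of follow-up, in-situ
#' and invasive recurrences in about a 3:2 ratio.
#'
#' Continuous covariates enter the linear predictor centred (age at 57.4,
#' size at 15.6) so the baseline hazards refer to an average patient.
#'
#' @param n cohort size.
#' @param til_prevalence,her2_prevalence probability of TIL-high and of
#'   HER2-positive.
#' @param tamoxifen_prevalence,radiotherapy_prevalence allocation
#'   probabilities (0.5 = randomised arms).
#' @param age_mean,age_sd,size_mean,size_sd covariate distribution
#'   parameters.
#' @param baseline_hazards named vector `c(dcis_ibe=, i_ibe=)`, events per
#'   year at covariate reference.
#' @param log_hr list with per-cause named log-HR vectors (`dcis_ibe`,
#'   `i_ibe`) over any of `til, her2, tamoxifen, radiotherapy, age, size`.
#' @param interaction_log_hr named vector `c(dcis_ibe=, i_ibe=)`: extra
#'   radiotherapy log-HR in TIL-high patients (the planted interaction).
#' @param admin_censor_time administrative censoring time, years.
#' @param score_threshold score value separating the TIL categories on the
#'   x10 scale (default 0.71).
#' @param seed integer seed.
#' @return Object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n,
                            til_prevalence = 0.5,
                            her2_prevalence = 0.35,
                            tamoxifen_prevalence = 0.5,
                            radiotherapy_prevalence = 0.5,
                            age_mean = 57.4, age_sd = 6.0,
                            size_mean = 15.6, size_sd = 8.5,
                            baseline_hazards = c(dcis_ibe = 0.0115,
                                                 i_ibe = 0.0072),
                            log_hr = list(
                              dcis_ibe = c(til = log(1.92),
                                           radiotherapy = log(0.45),
                                           tamoxifen = log(0.65)),
                              i_ibe = c(til = log(2.42),
                                        radiotherapy = log(0.40),
                                        tamoxifen = log(0.65))),
                            interaction_log_hr = c(dcis_ibe = log(0.6),
                                                   i_ibe = 0),
                            admin_censor_time = 12.7,
                            score_threshold = 0.71,
                            seed = 1L) {
  stopifnot(n >= 1L, all(baseline_hazards > 0), admin_censor_time >= 0)
  prev <- c(til_prevalence, her2_prevalence, tamoxifen_prevalence,
            radiotherapy_prevalence)
  if (any(prev <= 0) || any(prev >= 1))
    stop("prevalences must lie in (0, 1)", call. = FALSE)
  causes <- c("dcis_ibe", "i_ibe")
  stopifnot(all(causes %in% names(baseline_hazards)),
            all(causes %in% names(log_hr)),
            all(causes %in% names(interaction_log_hr)))
  ok_covs <- c("til", "her2", "tamoxifen", "radiotherapy", "age", "size")
  for (cs in causes)
    if (!all(names(log_hr[[cs]]) %in% ok_covs))
      stop("unknown covariate in log_hr: ",
           paste(setdiff(names(log_hr[[cs]]), ok_covs), collapse = ", "),
           call. = FALSE)
  structure(list(n = as.integer(n), til_prevalence = til_prevalence,
                 her2_prevalence = her2_prevalence,
                 tamoxifen_prevalence = tamoxifen_prevalence,
                 radiotherapy_prevalence = radiotherapy_prevalence,
                 age_mean = age_mean, age_sd = age_sd,
                 size_mean = size_mean, size_sd = size_sd,
                 baseline_hazards = baseline_hazards[causes],
                 log_hr = log_hr[causes],
                 interaction_log_hr = interaction_log_hr[causes],
                 admin_censor_time = admin_censor_time,
                 score_threshold = score_threshold,
                 seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a DCIS cohort with planted effects
#'
#' Draws covariates, then for each cause an exponential latent event time
#' with rate `lambda_c * exp(x' beta_c)` (including the planted
#' radiotherapy-by-TIL interaction); the observed outcome is the earliest
#' latent event if it precedes administrative censoring, with its cause
#' recorded, otherwise censoring at the administrative time. Deterministic
#' under the spec seed.
#'
#' @param spec a [cohort_sim_spec()].
#' @return List with `cohort` (data frame in the cohort-table schema:
#'   `patient_id, age, score, category, tumour_size, grade, necrosis,
#'   her2, er, excision, tamoxifen, radiotherapy, time, event`) and
#'   `truth` (planted log-HRs, realised per-cause event counts, censoring
#'   fraction).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n
  til <- rbinom(n, 1L, spec$til_prevalence)
  her2 <- rbinom(n, 1L, spec$her2_prevalence)
  tam <- rbinom(n, 1L, spec$tamoxifen_prevalence)
  rt <- rbinom(n, 1L, spec$radiotherapy_prevalence)
  age <- rnorm(n, spec$age_mean, spec$age_sd)
  size <- .rtruncnorm_pos(n, spec$size_mean, spec$size_sd)
  # score consistent with category at the threshold
  m <- spec$score_threshold
  score <- ifelse(til == 1L, m * exp(abs(rnorm(n, 0, 0.45))),
                  m * exp(-abs(rnorm(n, 0, 0.45)) - 1e-6))
  grade <- .sample_cond(n, til, c("low", "intermediate", "high"),
                        p0 = c(0.12, 0.28, 0.60), p1 = c(0.02, 0.09, 0.89))
  necrosis <- .sample_cond(n, til, c("absent", "<10%", "10-50%", ">50%"),
                           p0 = c(0.10, 0.15, 0.27, 0.48),
                           p1 = c(0.03, 0.08, 0.21, 0.68))
  er <- .sample_cond(n, til, c("neg", "pos"), p0 = c(0.20, 0.80),
                     p1 = c(0.54, 0.46))
  excision <- sample(c("complete", "uncertain", "incomplete"), n,
                     replace = TRUE, prob = c(0.68, 0.16, 0.16))

  covs <- list(til = til, her2 = her2, tamoxifen = tam, radiotherapy = rt,
               age = age - spec$age_mean, size = size - spec$size_mean)
  causes <- names(spec$baseline_hazards)
  lat <- matrix(NA_real_, n, length(causes),
                dimnames = list(NULL, causes))
  rates_tot <- numeric(n)
  for (cs in causes) {
    lp <- numeric(n)
    bh <- spec$log_hr[[cs]]
    for (nm in names(bh)) lp <- lp + bh[[nm]] * covs[[nm]]
    lp <- lp + spec$interaction_log_hr[[cs]] * til * rt
    rate <- spec$baseline_hazards[[cs]] * exp(lp)
    rates_tot <- rates_tot + rate
    lat[, cs] <- rexp(n, rate)
  }
  if (mean(1 - exp(-rates_tot * 0.01)) > 0.99)
    warning("degenerate spec: nearly all events occur before t = 0.01")
  t_event <- do.call(pmin, as.data.frame(lat))
  cause_idx <- max.col(-lat)  # which cause fired first
  censored <- t_event >= spec$admin_censor_time
  time <- pmin(t_event, spec$admin_censor_time)
  event <- ifelse(censored, "none",
                  ifelse(causes[cause_idx] == "dcis_ibe", "DCIS-IBE",
                         "I-IBE"))
  cohort <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, score = score,
    category = ifelse(til == 1L, "high", "low"),
    tumour_size = size, grade = grade, necrosis = necrosis,
    her2 = ifelse(her2 == 1L, "pos", "neg"), er = er,
    excision = excision, tamoxifen = tam, radiotherapy = rt,
    time = time, event = event, stringsAsFactors = FALSE)
  truth <- list(
    log_hr = spec$log_hr,
    interaction_log_hr = spec$interaction_log_hr,
    event_counts = c(table(factor(event,
                                  levels = c("none", "DCIS-IBE", "I-IBE")))),
    censoring_fraction = mean(censored))
  list(cohort = cohort, truth = truth)
}

.rtruncnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

.sample_cond <- function(n, z, levels, p0, p1) {
  out <- character(n)
  i0 <- z == 0L
  out[i0] <- sample(levels, sum(i0), replace = TRUE, prob = p0)
  out[!i0] <- sample(levels, sum(!i0), replace = TRUE, prob = p1)
  out
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates cohorts from a spec and refits the Cox model,
#' reporting the mean bias of the log hazard ratio, the mean estimated HR,
#' and empirical 95% confidence-interval coverage for the planted value.
#' Non-convergent replicates are excluded and counted.
#'
#' @param spec a [cohort_sim_spec()]; replicate `k` uses seed
#'   `spec$seed + k`.
#' @param n_reps number of replicates (`>= 50`).
#' @param parameter covariate whose recovery is assessed (default
#'   `"til"`, fitted as the `category` column).
#' @param outcome outcome passed to [cox_fit()] (default `"IBE"`).
#' @param covariates model covariates (default the planted treatment set).
#' @param true_log_hr planted value; defaults to the spec's value when it
#'   is identical across causes.
#' @return List with `mean_hr`, `mean_bias` (log scale), `coverage`,
#'   `n_reps_used`, `n_excluded`, and the per-replicate `estimates`.
#' @export
recovery_experiment <- function(spec, n_reps,
                                parameter = "til", outcome = "IBE",
                                covariates = c("category", "tamoxifen",
                                               "radiotherapy"),
                                true_log_hr = NULL) {
  stopifnot(inherits(spec, "cohort_sim_spec"), n_reps >= 50L)
  col_of <- c(til = "category", her2 = "her2", tamoxifen = "tamoxifen",
              radiotherapy = "radiotherapy", age = "age", size = "size")
  term_col <- col_of[[parameter]]
  if (is.null(true_log_hr)) {
    vals <- vapply(spec$log_hr, function(b)
      if (parameter %in% names(b)) b[[parameter]] else 0, numeric(1))
    if (length(unique(round(vals, 12))) != 1L)
      stop("planted log-HR differs across causes; supply true_log_hr",
           call. = FALSE)
    true_log_hr <- vals[[1]]
  }
  est <- matrix(NA_real_, n_reps, 2L, dimnames = list(NULL, c("beta", "se")))
  excl <- 0L
  for (k in seq_len(n_reps)) {
    sp <- spec; sp$seed <- spec$seed + k
    sim <- simulate_cohort(sp)
    f <- tryCatch(cox_fit(sim$cohort, outcome, covariates),
                  error = function(e) NULL)
    if (is.null(f)) { excl <- excl + 1L; next }
    i <- grep(term_col, f$terms$name)[1]
    b <- log(f$terms$hr[i])
    est[k, ] <- c(b, (log(f$terms$hi[i]) - log(f$terms$lo[i])) /
                       (2 * qnorm(0.975)))
  }
  ok <- !is.na(est[, 1])
  beta <- est[ok, 1]; se <- est[ok, 2]
  cover <- mean(true_log_hr >= beta - qnorm(0.975) * se &
                true_log_hr <= beta + qnorm(0.975) * se)
  list(mean_hr = mean(exp(beta)), mean_bias = mean(beta) - true_log_hr,
       coverage = cover, n_reps_used = sum(ok), n_excluded = excl,
       true_log_hr = true_log_hr,
       estimates = data.frame(beta = beta, se = se))
}
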