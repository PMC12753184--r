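#' Cross-tabulate a covariate by CPath TIL category
#'
#' Mirrors the structure of a baseline-characteristics table: for a
#' categorical covariate, counts and within-category column percentages
#' (denominator = column total over non-missing values) with a
#' Kruskal-Wallis p value over the ordinal level codes; for a continuous
#' covariate, medians with IQR and a Mann-Whitney p value.
#'
#' @param cohort data frame with a `category` column (`"low"`/`"high"`)
#'   and the covariate.
#' @param covariate covariate column name.
#' @param category_col name of the TIL category column (default
#'   `"category"`).
#' @return A list with `table` (data frame), `p`, `test`, and `n`
#'   (non-missing rows used).
#' @export
crosstab_summary <- function(cohort, covariate, category_col = "category") {
  if (!covariate %in% names(cohort))
    stop("unknown field: ", covariate, call. = FALSE)
  cat_v <- cohort[[category_col]]
  x <- cohort[[covariate]]
  keep <- !is.na(cat_v) & !is.na(x)
  any_missing <- any(!is.na(cat_v) & is.na(x))
  cat_v <- factor(cat_v[keep], levels = c("low", "high"))
  x <- x[keep]
  if (is.numeric(x)) {
    tab <- do.call(rbind, lapply(levels(cat_v), function(l) {
      q <- quantile(x[cat_v == l], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(category = l, n = sum(cat_v == l), median = q[2],
                 q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
    }))
    p <- rank_test(x, cat_v)$p
    return(list(table = tab, p = p, test = "Mann-Whitney", n = length(x),
                incomplete = any_missing))
  }
  x <- if (is.factor(x)) droplevels(x) else factor(x, levels = unique(x))
  counts <- table(x, cat_v)
  col_tot <- colSums(counts)
  pct <- sweep(counts, 2, pmax(col_tot, 1L), "/") * 100
  tab <- data.frame(level = rownames(counts),
                    n_low = as.integer(counts[, "low"]),
                    n_high = as.integer(counts[, "high"]),
                    pct_low = as.numeric(pct[, "low"]),
                    pct_high = as.numeric(pct[, "high"]),
                    stringsAsFactors = FALSE)
  p <- rank_test(as.numeric(x), cat_v, force = "kruskal")$p
  list(table = tab, p = p, test = "Kruskal-Wallis", n = length(x),
       incomplete = any_missing)
}

#' Kaplan-Meier estimate and t-year event rate
#'
#' Product-limit estimator with Greenwood standard errors; the t-year event
#' rate is `1 - S(t)`. If the horizon lies beyond the last observed time
#' the rate at the last time is returned and flagged.
#'
#' @param times follow-up times (years), `>= 0`.
#' @param events event indicator (logical or 0/1).
#' @param horizon horizon in years (default 10).
#' @return List with `fit` (a [survival::survfit] object), `surv`
#'   (`S(horizon)`), `event_rate`, `ci` (95% for `S`), and `truncated`.
#' @export
km_estimate <- function(times, events, horizon = 10) {
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "plain")
  truncated <- horizon > max(times)
  t_eval <- min(horizon, max(times))
  if (truncated)
    warning("horizon beyond last observed time; rate at last time returned")
  sm <- summary(fit, times = t_eval, extend = TRUE)
  list(fit = fit, surv = sm$surv, event_rate = 1 - sm$surv,
       ci = c(lower = sm$lower, upper = sm$upper), horizon = t_eval,
       truncated = truncated)
}

# event indicator for a cause-specific outcome; competing first events are
# censored at their time
.outcome_status <- function(cohort, outcome = c("IBE", "I-IBE", "DCIS-IBE")) {
  outcome <- match.arg(outcome)
  ev <- as.character(cohort$event)
  if (!all(ev %in% c("none", "I-IBE", "DCIS-IBE")))
    stop("event must be one of 'none', 'I-IBE', 'DCIS-IBE'", call. = FALSE)
  if (outcome == "IBE") as.integer(ev != "none") else as.integer(ev == outcome)
}

#' Cause-specific Cox proportional hazards fit
#'
#' Fits a Cox model for the chosen outcome (IBE composite, or a
#' cause-specific hazard with the competing first-event type censored at
#' its time), with Efron tie handling, Wald confidence intervals and a
#' model chi-square from the likelihood-ratio test against the null model.
#' Complete-case: rows missing any covariate are dropped and the model n
#' recorded.
#'
#' @param cohort cohort data frame (`time`, `event`, covariates).
#' @param outcome `"IBE"`, `"I-IBE"` or `"DCIS-IBE"`.
#' @param covariates character vector of covariate column names.
#' @return Object of class `cpath_coxfit`: list with `terms` (data frame
#'   `name, hr, lo, hi, p`), `model_chi2`, `df`, `n`, `n_events`,
#'   `covariates`, `outcome` and the underlying `fit`.
#' @export
cox_fit <- function(cohort, outcome = "IBE", covariates) {
  stopifnot(length(covariates) >= 1L, all(covariates %in% names(cohort)))
  status <- .outcome_status(cohort, outcome)
  dat <- cohort[, covariates, drop = FALSE]
  dat <- data.frame(.time = cohort$time, .status = status, dat,
                    check.names = FALSE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (sum(dat$.status) < 2L)
    stop("fewer than 2 events for outcome ", outcome, call. = FALSE)
  for (cv in covariates) {
    v <- dat[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("constant covariate: ", cv, call. = FALSE)
    if (is.character(v)) {
      lev <- if (all(unique(v) %in% c("low", "high"))) c("low", "high")
             else sort(unique(v))
      dat[[cv]] <- factor(v, levels = lev)
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  if (any(!is.finite(coef(fit))) || any(abs(coef(fit)) > 15))
    stop("Cox model did not converge (possible separation); iterations: ",
         fit$iter, call. = FALSE)
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  terms <- data.frame(name = names(beta), hr = exp(beta),
                      lo = exp(beta - qnorm(0.975) * se),
                      hi = exp(beta + qnorm(0.975) * se),
                      p = 2 * pnorm(-abs(beta / se)),
                      stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  structure(list(terms = terms,
                 model_chi2 = 2 * diff(fit$loglik),
                 df = length(beta), n = fit$n, n_events = fit$nevent,
                 covariates = covariates, outcome = outcome, fit = fit),
            class = "cpath_coxfit")
}

#' @export
print.cpath_coxfit <- function(x, ...) {
  cat(sprintf("Cox PH fit, outcome %s: n=%d, events=%d, model chi2=%.2f (df %d)\n",
              x$outcome, x$n, x$n_events, x$model_chi2, x$df))
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-28s HR %.2f [95%% CI %.2f-%.2f]; p=%.4g\n",
                t$name[i], t$hr[i], t$lo[i], t$hi[i], t$p[i]))
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox models
#'
#' The incremental information of the extra covariates is measured as the
#' difference in likelihood-ratio model chi-squares, with degrees of
#' freedom equal to the difference in parameter counts.
#'
#' @param full,reduced `cpath_coxfit` objects; `reduced`'s covariates must
#'   be a subset of `full`'s and both must be fitted on the same
#'   observations.
#' @return List with `delta_chi2`, `df`, `p`.
#' @export
lrt_compare <- function(full, reduced) {
  stopifnot(inherits(full, "cpath_coxfit"), inherits(reduced, "cpath_coxfit"))
  if (!all(reduced$covariates %in% full$covariates))
    stop("models are not nested", call. = FALSE)
  if (full$n != reduced$n || full$n_events != reduced$n_events)
    stop("models were fitted on different observations", call. = FALSE)
  delta <- full$model_chi2 - reduced$model_chi2
  df <- full$df - reduced$df
  if (delta < -1e-8) stop("nested LRT chi2 decreased; models inconsistent",
                          call. = FALSE)
  delta <- max(delta, 0)
  p <- if (df == 0L) 1 else pchisq(delta, df, lower.tail = FALSE)
  list(delta_chi2 = delta, df = df, p = p)
}

#' Treatment-by-biomarker interaction test
#'
#' Fits a Cox model with both main effects and their product term;
#' `p_interaction` comes from the likelihood-ratio test of the product
#' term (Wald optionally). Subgroup treatment HRs are estimated from
#' stratified fits (treatment effect within each biomarker category).
#'
#' @param cohort cohort data frame.
#' @param outcome `"IBE"`, `"I-IBE"` or `"DCIS-IBE"`.
#' @param factor_a binary biomarker column (e.g. `"category"`).
#' @param factor_b binary treatment column (e.g. `"radiotherapy"`).
#' @param covariates optional further adjustment covariates.
#' @param method `"lrt"` (default) or `"wald"` for the interaction p.
#' @return List with `subgroups` (data frame of within-stratum treatment
#'   HRs), `p_interaction`, and `joint` (the `cpath_coxfit` with product
#'   term).
#' @export
interaction_test <- function(cohort, outcome = "IBE", factor_a = "category",
                             factor_b = "radiotherapy", covariates = NULL,
                             method = c("lrt", "wald")) {
  method <- match.arg(method)
  a <- cohort[[factor_a]]; b <- cohort[[factor_b]]
  av <- sort(unique(a[!is.na(a)])); bv <- sort(unique(b[!is.na(b)]))
  if (length(av) != 2L || length(bv) != 2L)
    stop("both interaction factors must be binary", call. = FALSE)
  cells <- table(a, b)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("empty subgroup: %s=%s, %s=%s", factor_a,
                 rownames(cells)[bad[1]], factor_b, colnames(cells)[bad[2]]),
         call. = FALSE)
  }
  dat <- cohort
  dat$.ab <- .as01(a) * .as01(b)
  main <- cox_fit(dat, outcome, c(factor_a, factor_b, covariates))
  joint <- cox_fit(dat, outcome, c(factor_a, factor_b, covariates, ".ab"))
  p_int <- if (method == "lrt") lrt_compare(joint, main)$p
           else joint$terms$p[joint$terms$name == ".ab"]
  subgroups <- do.call(rbind, lapply(av, function(l) {
    sub <- cohort[!is.na(a) & a == l, , drop = FALSE]
    f <- cox_fit(sub, outcome, c(factor_b, covariates))
    tr <- f$terms[1, ]
    data.frame(stratum = as.character(l), n = f$n, n_events = f$n_events,
               hr = tr$hr, lo = tr$lo, hi = tr$hi, p = tr$p,
               stringsAsFactors = FALSE)
  }))
  list(subgroups = subgroups, p_interaction = p_int, joint = joint,
       method = method)
}

.as01 <- function(x) {
  if (is.numeric(x)) return(as.numeric(x != 0))
  if (all(stats::na.omit(unique(as.character(x))) %in% c("low", "high")))
    return(as.numeric(as.character(x) == "high"))
  as.numeric(factor(x)) - 1
}

#' Match cases to event-free controls (nested case-control design)
#'
#' Each case (patient with an ipsilateral breast event) is matched, with
#' seeded random sampling without replacement, to up to `ratio` controls
#' with identical treatment allocation (tamoxifen and radiotherapy), age
#' within `age_caliper` years either way, and follow-up at least as long
#' as the case's time to event. Cases lacking a full complement keep the
#' controls found or are dropped; drops are recorded.
#'
#' @param cohort cohort data frame (`patient_id`, `age`, `tamoxifen`,
#'   `radiotherapy`, `time`, `event`).
#' @param ratio controls per case (default 2).
#' @param age_caliper maximum absolute age difference in years (default 7).
#' @param seed RNG seed for control sampling.
#' @return Data frame of matched rows (`set_id`, `case`, plus the cohort
#'   columns), with attributes `n_dropped_cases` and `n_short_sets`.
#' @export
match_case_control <- function(cohort, ratio = 2L, age_caliper = 7,
                               seed = 1L) {
  is_case <- cohort$event != "none"
  cases <- cohort[is_case, , drop = FALSE]
  ctrls <- cohort[!is_case, , drop = FALSE]
  if (!nrow(cases)) stop("no cases in cohort", call. = FALSE)
  set.seed(seed)
  used <- character(0)
  out <- list(); dropped <- 0L; short <- 0L
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    elig <- ctrls$tamoxifen == cs$tamoxifen &
            ctrls$radiotherapy == cs$radiotherapy &
            abs(ctrls$age - cs$age) <= age_caliper &
            ctrls$time >= cs$time &
            !(ctrls$patient_id %in% used)
    idx <- which(elig)
    if (!length(idx)) { dropped <- dropped + 1L; next }
    take <- if (length(idx) <= ratio) idx else sample(idx, ratio)
    if (length(take) < ratio) short <- short + 1L
    used <- c(used, ctrls$patient_id[take])
    set <- rbind(cbind(cs, case = 1L),
                 cbind(ctrls[take, , drop = FALSE], case = 0L))
    set$set_id <- cs$patient_id
    out[[length(out) + 1L]] <- set
  }
  if (!length(out))
    stop("no case could be matched to any eligible control", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped_cases") <- dropped
  attr(res, "n_short_sets") <- short
  res
}

#' Conditional logistic regression on matched sets
#'
#' Maximises the conditional likelihood within each matched set to
#' estimate the matched odds ratio of the exposure, with a Wald confidence
#' interval.
#'
#' @param sets matched data frame from [match_case_control()] (columns
#'   `set_id`, `case`, exposure, covariates).
#' @param exposure exposure column name (binary; `"low"`/`"high"` or 0/1).
#' @param covariates optional additional covariate names.
#' @return List of class `matched_or`: `or`, `ci` (lower, upper), `p`,
#'   `n_sets`, `fit`.
#' @export
conditional_logistic <- function(sets, exposure = "category",
                                 covariates = NULL) {
  stopifnot(all(c("set_id", "case", exposure) %in% names(sets)))
  x <- .as01(sets[[exposure]])
  disc <- tapply(x, sets$set_id, function(v) length(unique(v)) > 1L)
  if (!any(disc))
    stop("matched OR undefined: no exposure-discordant set", call. = FALSE)
  dat <- data.frame(case = sets$case, .x = x, set_id = sets$set_id,
                    stringsAsFactors = FALSE)
  for (cv in covariates) dat[[cv]] <- sets[[cv]]
  # the conditional likelihood is a stratified Cox exact partial likelihood
  # at a common event time (the clogit trick)
  fml <- stats::as.formula(paste(
    "survival::Surv(rep(1, nrow(dat)), case) ~ .x",
    if (length(covariates))
      paste("+", paste(sprintf("`%s`", covariates), collapse = " + "))
    else "",
    "+ survival::strata(set_id)"))
  fit <- survival::coxph(fml, data = dat, method = "exact")
  beta <- unname(coef(fit)[".x"])
  se <- unname(sqrt(diag(vcov(fit)))[".x"])
  structure(list(or = exp(beta),
                 ci = c(lower = exp(beta - qnorm(0.975) * se),
                        upper = exp(beta + qnorm(0.975) * se)),
                 p = 2 * pnorm(-abs(beta / se)),
                 n_sets = length(unique(sets$set_id)), fit = fit),
            class = "matched_or")
}

#' @export
print.matched_or <- function(x, ...) {
  cat(sprintf("Matched OR %.2f [95%% CI %.2f-%.2f]; p=%.4g (%d sets)\n",
              x$or, x$ci[1], x$ci[2], x$p, x$n_sets))
  invisible(x)
}

#' Spearman rank correlation with mid-rank ties
#'
#' @param x,y numeric vectors of equal length `>= 3`.
#' @return The rank correlation coefficient; `NA` (with a warning) when
#'   either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("Spearman correlation undefined for a constant vector")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Rank-based group comparison
#'
#' Two continuous groups are compared with the Mann-Whitney test,
#' otherwise (or with `force = "kruskal"`) Kruskal-Wallis is used. With a
#' total n of 10 or fewer the p value is obtained by exact enumeration of
#' all group assignments; otherwise the normal / chi-square approximation
#' with mid-rank tie correction applies.
#'
#' @param values numeric response vector.
#' @param groups group labels (2 or more non-empty groups).
#' @param force `"auto"` (default), `"mw"` or `"kruskal"`.
#' @return List with `p`, `method`, and `exact`.
#' @export
rank_test <- function(values, groups, force = c("auto", "mw", "kruskal")) {
  force <- match.arg(force)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("a group is empty", call. = FALSE)
  n <- length(values)
  two <- nlevels(groups) == 2L
  use_mw <- (force == "mw") || (force == "auto" && two)
  if (use_mw && !two) stop("Mann-Whitney requires exactly 2 groups",
                           call. = FALSE)
  if (use_mw) {
    exact <- n <= 10L && !any(duplicated(values))
    # no continuity correction: the large-sample p then agrees exactly with
    # the 2-group Kruskal-Wallis chi-square p
    wt <- suppressWarnings(
      wilcox.test(values[groups == levels(groups)[1]],
                  values[groups == levels(groups)[2]],
                  exact = exact, correct = FALSE))
    return(list(p = wt$p.value, method = "Mann-Whitney", exact = exact))
  }
  if (n <= 10L) {
    return(list(p = .kruskal_exact(values, groups),
                method = "Kruskal-Wallis", exact = TRUE))
  }
  kt <- kruskal.test(values, groups)
  list(p = kt$p.value, method = "Kruskal-Wallis", exact = FALSE)
}

# exact Kruskal-Wallis p by enumeration of all distinct assignments of the
# observed values to groups of the observed sizes (feasible for n <= 10)
.kruskal_exact <- function(values, groups) {
  sizes <- as.integer(table(groups))
  r <- rank(values)
  h_stat <- function(perm_ranks) {
    n <- length(perm_ranks)
    start <- 1L; h <- 0
    for (s in sizes) {
      h <- h + sum(perm_ranks[start:(start + s - 1L)])^2 / s
      start <- start + s
    }
    h <- 12 / (n * (n + 1)) * h - 3 * (n + 1)
    # tie correction
    t <- table(perm_ranks)
    cf <- 1 - sum(t^3 - t) / (n^3 - n)
    if (cf > 0) h / cf else 0
  }
  obs <- h_stat(unlist(split(r, groups), use.names = FALSE))
  perms <- .group_assignments(seq_along(r), sizes)
  hs <- vapply(perms, function(idx) h_stat(r[idx]), numeric(1))
  mean(hs >= obs - 1e-12)
}

# all ways to partition indices into ordered groups of the given sizes
.group_assignments <- function(idx, sizes) {
  if (length(sizes) == 1L) return(list(idx))
  first <- utils::combn(idx, sizes[1], simplify = FALSE)
  out <- list()
  for (f in first) {
    rest <- .group_assignments(setdiff(idx, f), sizes[-1])
    out <- c(out, lapply(rest, function(r) c(f, r)))
  }
  out
}
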