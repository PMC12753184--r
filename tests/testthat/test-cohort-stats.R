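test_that("crosstab percentages use within-column non-missing denominators", {
  coh <- counts_to_cohort(c("low_grade", "intermediate", "high_grade"),
                          n_low = c(29, 78, 208), n_high = c(7, 28, 291))
  ct <- crosstab_summary(coh, "covariate")
  expect_equal(ct$table$n_high, c(7, 28, 291))
  expect_equal(round(ct$table$pct_high[3]), 89)  # 291 / 326
  expect_equal(round(ct$table$pct_low[3]), 66)   # 208 / 315
  expect_true(ct$p < 0.05)
  expect_error(crosstab_summary(coh, "nope"), "unknown field")
})

test_that("continuous covariates are summarised by medians and Mann-Whitney", {
  set.seed(2)
  coh <- data.frame(category = rep(c("low", "high"), each = 60),
                    tumour_size = c(rnorm(60, 13, 4), rnorm(60, 16, 4)))
  ct <- crosstab_summary(coh, "tumour_size")
  expect_equal(ct$test, "Mann-Whitney")
  expect_equal(ct$table$median,
               c(median(coh$tumour_size[1:60]),
                 median(coh$tumour_size[61:120])))
})

test_that("Kaplan-Meier reproduces the hand product-limit example", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 0), horizon = 3)
  expect_equal(km$surv, 0.25, tolerance = 1e-12)  # (3/4)(2/3)(1/2)
  expect_equal(km$event_rate, 0.75, tolerance = 1e-12)

  none <- km_estimate(c(2, 5, 7), c(0, 0, 0), horizon = 6)
  expect_equal(none$surv, 1)
  all1 <- km_estimate(rep(1, 5), rep(1, 5), horizon = 1)
  expect_equal(all1$surv, 0)
  expect_warning(km_estimate(c(1, 2), c(1, 0), horizon = 10), "horizon")
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(8)
  t <- rexp(40, 0.3)
  km <- km_estimate(t, rep(1, 40), horizon = median(t))
  expect_equal(km$surv, mean(t > median(t)), tolerance = 1e-12)
})

test_that("Cox fit recovers a two-group exponential rate ratio", {
  coh <- exp_two_arm(2000, rate0 = 0.1, hr = 2, seed = 17)
  f <- cox_fit(coh, "I-IBE", "group")
  expect_gt(f$terms$hr, 1.85)
  expect_lt(f$terms$hr, 2.16)
  expect_gt(f$model_chi2, 0)
})

test_that("Cox fit covers a planted null and ignores orthogonal noise", {
  set.seed(23)
  coh <- exp_two_arm(1000, rate0 = 0.1, hr = 1, seed = 23)
  f <- cox_fit(coh, "I-IBE", "group")
  expect_true(f$terms$lo < 1 && 1 < f$terms$hi)

  coh2 <- exp_two_arm(2500, rate0 = 0.1, hr = 2, seed = 29)
  coh2$noise <- rnorm(nrow(coh2))
  base <- cox_fit(coh2, "I-IBE", "group")$terms$hr[1]
  adj <- cox_fit(coh2, "I-IBE", c("group", "noise"))$terms$hr[1]
  expect_lt(abs(adj - base) / base, 0.05)
})

test_that("Cox fit validates its inputs", {
  coh <- exp_two_arm(20, 0.1, 2, seed = 3)
  coh$event <- "none"
  expect_error(cox_fit(coh, "IBE", "group"), "fewer than 2 events")
  coh2 <- exp_two_arm(20, 0.1, 2, seed = 3)
  coh2$flat <- 1
  expect_error(cox_fit(coh2, "I-IBE", "flat"), "constant covariate")
})

test_that("likelihood-ratio comparison is zero for equal models and additive", {
  coh <- exp_two_arm(300, 0.1, 2, seed = 5)
  set.seed(6)
  coh$x2 <- rnorm(nrow(coh)); coh$x3 <- rnorm(nrow(coh))
  fA <- cox_fit(coh, "I-IBE", "group")
  same <- lrt_compare(fA, fA)
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p, 1)
  fB <- cox_fit(coh, "I-IBE", c("group", "x2"))
  fC <- cox_fit(coh, "I-IBE", c("group", "x2", "x3"))
  expect_equal(fB$df - fA$df, 1L)  # one added term, one df
  ab <- lrt_compare(fB, fA)$delta_chi2
  bc <- lrt_compare(fC, fB)$delta_chi2
  ac <- lrt_compare(fC, fA)$delta_chi2
  expect_equal(ac, ab + bc, tolerance = 1e-6)
  expect_error(lrt_compare(fB, cox_fit(coh, "I-IBE", "x3")), "not nested")
})

test_that("the LRT detects a planted incremental effect", {
  rejected <- 0; n_sims <- 100
  for (k in seq_len(n_sims)) {
    set.seed(1000 + k)
    n <- 300
    x <- rbinom(n, 1, 0.5); z <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * exp(0.4 * x + 0.6 * z))
    coh <- data.frame(patient_id = as.character(seq_len(n)), group = x,
                      z = z, time = t, event = "I-IBE")
    full <- cox_fit(coh, "I-IBE", c("group", "z"))
    red <- cox_fit(coh, "I-IBE", "group")
    if (lrt_compare(full, red)$delta_chi2 > 3.84) rejected <- rejected + 1
  }
  expect_gt(rejected / n_sims, 0.5)
})

test_that("subgroup HRs match the joint interaction model algebraically", {
  set.seed(41)
  n <- 4000
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.7 * a + log(0.8) * b + log(0.4) * a * b))
  coh <- data.frame(patient_id = as.character(seq_len(n)),
                    category = ifelse(a == 1, "high", "low"),
                    radiotherapy = b, time = pmin(t, 15),
                    event = ifelse(t < 15, "I-IBE", "none"))
  it <- interaction_test(coh, "I-IBE", "category", "radiotherapy")
  jt <- it$joint$terms
  b_b <- log(jt$hr[jt$name == "radiotherapy"])
  b_ab <- log(jt$hr[jt$name == ".ab"])
  hr_low <- it$subgroups$hr[it$subgroups$stratum == "low"]
  hr_high <- it$subgroups$hr[it$subgroups$stratum == "high"]
  expect_equal(hr_low, exp(b_b), tolerance = 0.02)
  expect_equal(hr_high, exp(b_b + b_ab), tolerance = 0.02)
  expect_lt(it$p_interaction, 0.05)
})

test_that("empty interaction cells are reported by name", {
  coh <- exp_two_arm(40, 0.1, 2, seed = 2)
  coh$category <- ifelse(coh$group == 1, "high", "low")
  coh$radiotherapy <- coh$group  # perfectly confounded: two cells empty
  expect_error(interaction_test(coh, "I-IBE", "category", "radiotherapy"),
               "empty subgroup")
})

test_that("case-control matching honours arm, caliper and risk-set rules", {
  sim <- simulate_cohort(cohort_sim_spec(800, seed = 77))
  sets <- match_case_control(sim$cohort, ratio = 2L, seed = 5)
  for (s in unique(sets$set_id)) {
    g <- sets[sets$set_id == s, ]
    cs <- g[g$case == 1L, ]
    ct <- g[g$case == 0L, ]
    expect_lte(nrow(ct), 2L)
    expect_true(all(ct$tamoxifen == cs$tamoxifen))
    expect_true(all(ct$radiotherapy == cs$radiotherapy))
    expect_true(all(abs(ct$age - cs$age) <= 7))
    expect_true(all(ct$time >= cs$time))
    expect_true(all(ct$event == "none"))
  }
  # controls are sampled without replacement across sets
  ctrl_ids <- sets$patient_id[sets$case == 0L]
  expect_false(any(duplicated(ctrl_ids)))
})

test_that("ineligible controls are excluded for the documented reasons", {
  coh <- data.frame(
    patient_id = c("case1", "shortFU", "tooOld", "ok1", "ok2"),
    age = c(55, 55, 64, 56, 50),
    tamoxifen = 0L, radiotherapy = 1L,
    time = c(5, 4, 12, 9, 11),
    event = c("I-IBE", "none", "none", "none", "none"),
    stringsAsFactors = FALSE)
  sets <- match_case_control(coh, ratio = 2L, seed = 1)
  ctrls <- sets$patient_id[sets$case == 0L]
  expect_setequal(ctrls, c("ok1", "ok2"))
})

test_that("matched OR on 1:1 sets equals the discordant-pair ratio", {
  sets <- build_matched_sets(60, ratio = 1L, seed = 13)
  by_set <- split(sets, sets$set_id)
  b <- sum(vapply(by_set, function(g)
    g$exposure[g$case == 1L] == 1 && g$exposure[g$case == 0L] == 0,
    logical(1)))
  cc <- sum(vapply(by_set, function(g)
    g$exposure[g$case == 1L] == 0 && g$exposure[g$case == 0L] == 1,
    logical(1)))
  res <- conditional_logistic(sets, exposure = "exposure")
  expect_equal(res$or, b / cc, tolerance = 1e-6)
})

test_that("concordant-only sets leave the matched OR undefined", {
  sets <- data.frame(set_id = rep(c("a", "b"), each = 3),
                     case = rep(c(1L, 0L, 0L), 2),
                     exposure = c(1, 1, 1, 0, 0, 0))
  expect_error(conditional_logistic(sets, exposure = "exposure"),
               "discordant")
})

test_that("conditional logistic regression recovers a planted log odds ratio", {
  set.seed(55)
  beta <- log(2)
  sets <- do.call(rbind, lapply(seq_len(500), function(s) {
    x <- rbinom(3, 1, 0.4)
    # conditional sampling: pick the case within the set wp exp(beta*x)
    p <- exp(beta * x); p <- p / sum(p)
    case <- rmultinom(1, 1, p)[, 1]
    data.frame(set_id = sprintf("s%03d", s), case = case, exposure = x)
  }))
  res <- conditional_logistic(sets, exposure = "exposure")
  expect_gt(res$or, 1.6); expect_lt(res$or, 2.5)
  expect_true(res$ci[1] < res$or && res$or < res$ci[2])
})

test_that("Spearman handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:5, (1:5)^2), 1)
  expect_equal(spearman_rho(1:5, -(1:5)), -1)
  # mid-rank oracle for x=(1,2,2,4), y=(1,3,2,4)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)
  expect_warning(r <- spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
})

test_that("rank tests enumerate exactly for tiny samples", {
  res <- rank_test(c(1, 2, 3, 4), factor(c("a", "a", "b", "b")))
  expect_true(res$exact)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)  # 2 x (1/6)
  # exact Kruskal-Wallis enumeration agrees for the same 2-group case
  resk <- rank_test(c(1, 2, 3, 4), factor(c("a", "a", "b", "b")),
                    force = "kruskal")
  expect_true(resk$exact)
  expect_equal(resk$p, 1 / 3, tolerance = 1e-12)
  expect_error(rank_test(1:3, factor(c("a", "a", "a"))), "2 groups")
})

test_that("two-group Kruskal-Wallis equals the Mann-Whitney approximation", {
  set.seed(61)
  x <- sample(seq_len(400), 40)  # no ties
  g <- factor(rep(c("a", "b"), each = 20))
  p_kw <- rank_test(x, g, force = "kruskal")$p
  p_mw <- rank_test(x, g, force = "mw")$p
  expect_equal(p_kw, p_mw, tolerance = 1e-6)
})

test_that("the rank test holds its nominal size", {
  set.seed(71)
  rej <- mean(replicate(1000, {
    v <- rnorm(100)
    rank_test(v, factor(rep(c("a", "b"), each = 50)))$p <= 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})
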