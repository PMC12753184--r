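# minimal patch_grid built by hand
mk_grid <- function(stroma_px, assignments = NULL, mpp = 1) {
  n <- length(stroma_px)
  patches <- data.frame(patch_id = seq_len(n),
                        r0 = 0, c0 = (seq_len(n) - 1) * 100,
                        r1 = 100, c1 = seq_len(n) * 100,
                        stroma_px = stroma_px,
                        n_lymphocytes = 0L)
  if (is.null(assignments))
    assignments <- data.frame(nucleus_id = integer(), patch_id = integer())
  structure(list(patches = patches, assignments = assignments,
                 patch_size_um = 100, mpp = mpp), class = "patch_grid")
}

test_that("patch TIL fraction is lymphocyte area over stroma area, clipped", {
  nuc <- data.frame(id = 1:2, area_um2 = c(500, 20000))
  g <- mk_grid(c(10000, 10000, 5000),
               assignments = data.frame(nucleus_id = c(1L, 2L),
                                        patch_id = c(1L, 2L)))
  p <- patch_til_fractions(g, nuc)
  expect_equal(p$til_fraction, c(0.05, 1, 0))  # clip rule on patch 2
})

test_that("the CPath TIL score is ten times the weighted mean density", {
  g <- mk_grid(rep(10000, 4))
  p <- patch_til_fractions(g, data.frame(id = integer(),
                                         area_um2 = numeric()))
  p$til_fraction <- rep(0.071, 4)
  sc <- cpath_til_score(p, "p1", radius_um = 250)
  expect_equal(sc$score, 0.71, tolerance = 1e-12)
  expect_identical(sc$score, 10 * sc$raw_density)

  # stroma-area weighting: p = (0, 0.2), areas (3, 1) -> raw 0.05
  p2 <- data.frame(patch_id = 1:2, stroma_um2 = c(3, 1) * 1e5,
                   til_fraction = c(0, 0.2))
  sc2 <- cpath_til_score(p2, "p2")
  expect_equal(sc2$raw_density, 0.05)
  expect_equal(sc2$score, 0.5)
  # permutation invariance
  sc2r <- cpath_til_score(p2[2:1, ], "p2")
  expect_equal(sc2r$score, sc2$score)
})

test_that("too little stroma renders a patient non-evaluable", {
  p <- data.frame(patch_id = 1L, stroma_um2 = 5000, til_fraction = 0.1)
  sc <- cpath_til_score(p, "tiny")  # 0.005 mm^2 < 0.01 mm^2 floor
  expect_false(sc$evaluable)
  expect_true(is.na(sc$score))
})

test_that("dichotomisation applies the >= rule at the published scale", {
  s <- data.frame(patient_id = c("a", "b"), score = c(0.71, 0.70),
                  evaluable = TRUE)
  d <- dichotomize(s, threshold = 0.71)
  expect_equal(d$category, c("high", "low"))

  s2 <- data.frame(patient_id = letters[1:4],
                   score = c(0.2, 0.4, 0.6, 0.8), evaluable = TRUE)
  d2 <- dichotomize(s2)
  expect_equal(attr(d2, "threshold"), 0.5)  # even-n midpoint convention
  expect_equal(d2$category, c("low", "low", "high", "high"))

  expect_error(dichotomize(data.frame(score = 1, evaluable = TRUE)),
               "at least 2")
  expect_error(dichotomize(data.frame(score = NA_real_, evaluable = FALSE),
                           threshold = 1), "non-evaluable")
})

test_that("median split balances categories for odd distinct scores", {
  set.seed(31)
  for (k in 1:5) {
    sc <- data.frame(patient_id = seq_len(9),
                     score = sample(seq(0.1, 4, length.out = 9)),
                     evaluable = TRUE)
    d <- dichotomize(sc)
    n_high <- sum(d$category == "high"); n_low <- sum(d$category == "low")
    expect_gte(n_high, n_low)
    expect_lte(n_high - n_low, 1L)
  }
})

test_that("estimated scores rise with planted density", {
  means <- vapply(c(0, 50, 200), function(dens) {
    mean(vapply(1:3, function(s) {
      spec <- fixture_tile_spec(500, 1, density = dens, seed = 70 + s)
      gt <- generate_tile(spec)
      score_tile(gt$image, spec$annotations, run_config(), "x")$score
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a tile without DCIS scores as non-evaluable", {
  img <- calibrated_image(array(230L, dim = c(60, 60, 3)), mpp = 2)
  sc <- score_tile(img, annotation_set(list()), run_config(), "noduct")
  expect_false(sc$evaluable)
})

test_that("identical radii give identical rankings", {
  cases <- lapply(1:3, function(s) {
    spec <- fixture_tile_spec(400, 1, density = 60 * s, seed = 400 + s)
    gt <- generate_tile(spec)
    list(patient_id = paste0("p", s), image = gt$image,
         annotations = spec$annotations)
  })
  rs <- radius_sensitivity(cases, run_config(), r1 = 150, r2 = 150)
  expect_equal(rs$rho, 1)
  expect_equal(rs$category_agreement, 1)
  expect_error(radius_sensitivity(cases[1:2]), "at least 3")
})

test_that("a rank flip lowers the Spearman correlation below 1", {
  x <- c(0.2, 0.5, 0.9, 1.4)
  y <- c(0.2, 0.9, 0.5, 1.4)
  expect_lt(spearman_rho(x, y), 1)
})
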