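# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a standard mid-density tile with ducts, glass and planted lymphocytes
std_tile <- function() cached("std_tile", {
  spec <- fixture_tile_spec(600, 1, density = 150, seed = 42)
  c(generate_tile(spec), list(spec = spec))
})

# its segmentation products
std_seg <- function() cached("std_seg", {
  tl <- std_tile()
  stains <- deconvolve_stains(rgb_to_od(tl$image))
  nuc <- classify_lymphocytes(segment_nuclei(stains, tl$image$mpp))
  list(stains = stains, nuclei = nuc)
})

# stain_channels built directly from a hematoxylin OD matrix
stains_from_hema <- function(hema) {
  structure(list(hematoxylin_od = hema,
                 eosin_od = matrix(0, nrow(hema), ncol(hema))),
            class = "stain_channels")
}

# paint a disk into a matrix (independent of package internals)
test_paint_disk <- function(m, r0, c0, rad, value = TRUE) {
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if ((i - 0.5 - r0)^2 + (j - 0.5 - c0)^2 <= rad^2) m[i, j] <- value
  m
}

# cohort reconstructed from printed two-column counts of a covariate
counts_to_cohort <- function(levels, n_low, n_high) {
  data.frame(
    category = c(rep("low", sum(n_low)), rep("high", sum(n_high))),
    covariate = factor(c(rep(levels, n_low), rep(levels, n_high)),
                       levels = levels),
    stringsAsFactors = FALSE)
}

# two-arm exponential survival data (no censoring)
exp_two_arm <- function(n_per_arm, rate0, hr, seed) {
  set.seed(seed)
  data.frame(
    patient_id = sprintf("S%05d", seq_len(2 * n_per_arm)),
    group = rep(c(0, 1), each = n_per_arm),
    time = c(rexp(n_per_arm, rate0), rexp(n_per_arm, rate0 * hr)),
    event = "I-IBE", stringsAsFactors = FALSE)
}

# hand-built 1:ratio matched sets with binary exposure
build_matched_sets <- function(n_sets, ratio, p_case = 0.6, p_ctrl = 0.3,
                               seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_sets), function(s) {
    data.frame(set_id = sprintf("set%02d", s),
               case = c(1L, rep(0L, ratio)),
               exposure = c(rbinom(1, 1, p_case), rbinom(ratio, 1, p_ctrl)),
               stringsAsFactors = FALSE)
  }))
}

# conditional log-likelihood of 1 case : m controls matched sets, coded for
# use as an independent oracle (maximised by grid/Brent search, never by
# the package's own fitting route)
clr_loglik <- function(beta, sets) {
  ll <- 0
  for (s in unique(sets$set_id)) {
    x <- sets$exposure[sets$set_id == s]
    cs <- sets$case[sets$set_id == s] == 1L
    ll <- ll + beta * x[cs] - log(sum(exp(beta * x)))
  }
  ll
}
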