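#' Per-patch TIL fraction
#'
#' For each patch of a [tile_patches()] grid, the TIL fraction is the total
#' lymphocyte-nucleus area in the patch divided by the patch's stromal area
#' (both in um^2), clipped to `[0, 1]`. This area-fraction definition is a
#' deterministic analogue of a patch-level "percentage of TILs"; a
#' count-per-mm^2 alternative is available via `definition`.
#'
#' @param grid a `patch_grid` from [tile_patches()].
#' @param nuclei labelled nucleus data frame (provides lymphocyte areas).
#' @param definition `"area_fraction"` (default) or `"count_per_mm2"`.
#' @return The grid's `patches` data frame with an extra column `til_fraction`
#'   (or `til_count_per_mm2`), plus `stroma_um2`.
#' @export
patch_til_fractions <- function(grid, nuclei,
                                definition = c("area_fraction",
                                               "count_per_mm2")) {
  stopifnot(inherits(grid, "patch_grid"))
  definition <- match.arg(definition)
  p <- grid$patches
  p$stroma_um2 <- p$stroma_px * grid$mpp^2
  if (definition == "area_fraction") {
    lym_area <- numeric(nrow(p))
    if (nrow(grid$assignments)) {
      ar <- nuclei$area_um2[match(grid$assignments$nucleus_id, nuclei$id)]
      s <- rowsum(ar, grid$assignments$patch_id)
      lym_area[match(as.integer(rownames(s)), p$patch_id)] <- s[, 1]
    }
    p$til_fraction <- pmin(pmax(lym_area / p$stroma_um2, 0), 1)
  } else {
    p$til_count_per_mm2 <- p$n_lymphocytes / (p$stroma_um2 / 1e6)
  }
  p
}

#' CPath TIL score for one patient
#'
#' The raw CPath TIL density is the stroma-area-weighted mean of the patch
#' TIL fractions over the periductal microenvironment; the CPath TIL score
#' is that density multiplied by ten (the published scale, on which the
#' cohort median threshold is expressed). A patient is evaluable only with
#' at least one patch and at least `min_stroma_mm2` of microenvironment
#' stroma.
#'
#' @param patches data frame from [patch_til_fractions()].
#' @param patient_id patient/tile identifier.
#' @param radius_um microenvironment radius used (recorded in the result).
#' @param min_stroma_mm2 minimum evaluable stroma (default 0.01 mm^2).
#' @param weighting `"area"` (stroma-area-weighted, default) or `"patch"`
#'   (unweighted patch mean).
#' @return One-row data frame: `patient_id, n_patches, stroma_mm2,
#'   raw_density, score, radius_um, evaluable`. For non-evaluable patients
#'   `raw_density` and `score` are `NA`.
#' @export
cpath_til_score <- function(patches, patient_id = "patient",
                            radius_um = NA_real_, min_stroma_mm2 = 0.01,
                            weighting = c("area", "patch")) {
  weighting <- match.arg(weighting)
  frac_col <- intersect(c("til_fraction", "til_count_per_mm2"),
                        names(patches))
  if (!length(frac_col) && nrow(patches))
    stop("patches carry no TIL fraction column; run patch_til_fractions()",
         call. = FALSE)
  stroma_mm2 <- sum(patches$stroma_um2) / 1e6
  if (!nrow(patches) || stroma_mm2 < min_stroma_mm2) {
    return(data.frame(patient_id = patient_id, n_patches = nrow(patches),
                      stroma_mm2 = stroma_mm2, raw_density = NA_real_,
                      score = NA_real_, radius_um = radius_um,
                      evaluable = FALSE, stringsAsFactors = FALSE))
  }
  x <- patches[[frac_col[1]]]
  w <- if (weighting == "area") patches$stroma_um2 else
    rep(1, nrow(patches))
  raw <- sum(w * x) / sum(w)
  data.frame(patient_id = patient_id, n_patches = nrow(patches),
             stroma_mm2 = stroma_mm2, raw_density = raw, score = 10 * raw,
             radius_um = radius_um, evaluable = TRUE,
             stringsAsFactors = FALSE)
}

#' Dichotomise CPath TIL scores at a threshold
#'
#' With no threshold given, the cohort median of the evaluable scores
#' (midpoint convention for even n) becomes the pre-defined threshold.
#' Category is `"high"` iff `score >= threshold`, `"low"` iff
#' `score < threshold`; non-evaluable patients get `NA`.
#'
#' @param scores data frame with columns `patient_id`, `score`,
#'   `evaluable` (as from [cpath_til_score()]).
#' @param threshold optional frozen threshold on the x10 score scale.
#' @return `scores` with columns `category` and `threshold` added; the
#'   threshold is also attached as attribute `"threshold"` for
#'   serialisation and reuse on new patients.
#' @export
dichotomize <- function(scores, threshold = NULL) {
  stopifnot(is.data.frame(scores), "score" %in% names(scores))
  if (!"evaluable" %in% names(scores))
    scores$evaluable <- !is.na(scores$score)
  ev <- scores$evaluable & !is.na(scores$score)
  if (is.null(threshold)) {
    if (sum(ev) < 2L)
      stop("need at least 2 evaluable scores to set a median threshold",
           call. = FALSE)
    threshold <- median(scores$score[ev])
  }
  if (!any(ev)) stop("all scores non-evaluable", call. = FALSE)
  scores$category <- ifelse(ev,
                            ifelse(scores$score >= threshold, "high", "low"),
                            NA_character_)
  scores$threshold <- threshold
  attr(scores, "threshold") <- threshold
  scores
}

#' Score one annotated tile end to end
#'
#' Full imaging pipeline for a single patient region: stain deconvolution,
#' nuclei segmentation and lymphocyte classification, stroma masking,
#' periductal ring construction, patch partition and CPath TIL score.
#'
#' @param image a [calibrated_image()].
#' @param annotations an [annotation_set()] of DCIS outlines.
#' @param config a [run_config()]; controls radius, patch size,
#'   classification thresholds, score definition and evaluability floor.
#' @param patient_id identifier recorded in the result.
#' @return One-row score data frame as from [cpath_til_score()]. A tile
#'   without DCIS yields a non-evaluable row rather than an error.
#' @export
score_tile <- function(image, annotations, config = run_config(),
                       patient_id = "patient") {
  stopifnot(inherits(image, "calibrated_image"))
  shape <- dim(image$pixels)[1:2]
  dcis <- rasterize_annotations(annotations, shape, image$mpp)
  if (!any(dcis)) {
    return(data.frame(patient_id = patient_id, n_patches = 0L,
                      stroma_mm2 = 0, raw_density = NA_real_,
                      score = NA_real_, radius_um = config$radius_um,
                      evaluable = FALSE, stringsAsFactors = FALSE))
  }
  stains <- deconvolve_stains(rgb_to_od(image))
  nuc <- segment_nuclei(stains, image$mpp,
                        min_area_um2 = config$min_nucleus_area_um2)
  nuc <- classify_lymphocytes(nuc, config$lymphocyte)
  stroma <- segment_stroma(image, dcis, nuc)
  ring <- periductal_ring(dcis, config$radius_um, image$mpp)
  grid <- tile_patches(ring, stroma, nuc, config$patch_size_um)
  patches <- patch_til_fractions(grid, nuc, definition = config$score_definition)
  cpath_til_score(patches, patient_id = patient_id,
                  radius_um = config$radius_um,
                  min_stroma_mm2 = config$min_stroma_mm2,
                  weighting = config$weighting)
}

#' Sensitivity of the CPath TIL score to the microenvironment radius
#'
#' Recomputes the full pipeline at a second radius and reports the Spearman
#' correlation between the two score vectors plus the fraction of patients
#' whose category (each cohort dichotomised at its own median) is
#' unchanged.
#'
#' @param cases list of cases, each a list with `patient_id`, `image`
#'   (a [calibrated_image()]) and `annotations` (an [annotation_set()]).
#' @param config a [run_config()] used at both radii.
#' @param r1,r2 the two radii in microns (defaults 250 and 200).
#' @return List with `rho`, `category_agreement`, and the per-patient
#'   `scores` data frame (both radii, both categories).
#' @export
radius_sensitivity <- function(cases, config = run_config(),
                               r1 = 250, r2 = 200) {
  if (length(cases) < 3L)
    stop("need at least 3 patients for radius sensitivity", call. = FALSE)
  cfg1 <- config; cfg1$radius_um <- r1
  cfg2 <- config; cfg2$radius_um <- r2
  s1 <- do.call(rbind, lapply(cases, function(cs)
    score_tile(cs$image, cs$annotations, cfg1, cs$patient_id)))
  s2 <- do.call(rbind, lapply(cases, function(cs)
    score_tile(cs$image, cs$annotations, cfg2, cs$patient_id)))
  ev <- s1$evaluable & s2$evaluable
  if (sum(ev) < 3L)
    stop("fewer than 3 patients evaluable at both radii", call. = FALSE)
  d1 <- dichotomize(s1[ev, , drop = FALSE])
  d2 <- dichotomize(s2[ev, , drop = FALSE])
  rho <- spearman_rho(d1$score, d2$score)
  agree <- mean(d1$category == d2$category)
  scores <- data.frame(patient_id = d1$patient_id,
                       score_r1 = d1$score, score_r2 = d2$score,
                       category_r1 = d1$category, category_r2 = d2$category,
                       stringsAsFactors = FALSE)
  list(rho = rho, category_agreement = agree, r1 = r1, r2 = r2,
       scores = scores)
}
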