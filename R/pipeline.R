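#' Pipeline run configuration
#'
#' Bundles every tunable of the imaging pipeline. Unknown keys are
#' rejected, all numeric fields must be positive, and the configuration
#' hashes stably so output tables can record the exact settings used.
#'
#' @param radius_um microenvironment radius in microns (default 250; 200
#'   is the standard sensitivity setting).
#' @param patch_size_um patch edge length in microns (default 100).
#' @param lymphocyte a [lymphocyte_rule()].
#' @param score_definition `"area_fraction"` (default) or
#'   `"count_per_mm2"`.
#' @param weighting patch aggregation, `"area"` or `"patch"`.
#' @param threshold optional frozen dichotomisation threshold (x10 scale);
#'   `NULL` means use the cohort median.
#' @param min_stroma_mm2 minimum evaluable microenvironment stroma
#'   (default 0.01 mm^2).
#' @param min_nucleus_area_um2 segmentation floor (default 10 um^2).
#' @param seed seed for any stochastic stage (e.g. control matching).
#' @param ... rejected; guards against misspelled keys. Leading position
#'   also disables partial argument matching, so every key must be spelled
#'   out in full.
#' @return Object of class `run_config`.
#' @export
run_config <- function(..., radius_um = 250, patch_size_um = 100,
                       lymphocyte = lymphocyte_rule(),
                       score_definition = c("area_fraction", "count_per_mm2"),
                       weighting = c("area", "patch"),
                       threshold = NULL, min_stroma_mm2 = 0.01,
                       min_nucleus_area_um2 = 10, seed = 1L) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config keys: ", paste(names(extra), collapse = ", "),
         call. = FALSE)
  score_definition <- match.arg(score_definition)
  weighting <- match.arg(weighting)
  for (v in c(radius_um, patch_size_um, min_stroma_mm2,
              min_nucleus_area_um2))
    if (!is.numeric(v) || v <= 0)
      stop("config numeric fields must be positive", call. = FALSE)
  if (!is.null(threshold) && (!is.numeric(threshold) || threshold < 0))
    stop("threshold must be a non-negative number or NULL", call. = FALSE)
  structure(list(radius_um = radius_um, patch_size_um = patch_size_um,
                 lymphocyte = lymphocyte,
                 score_definition = score_definition, weighting = weighting,
                 threshold = threshold, min_stroma_mm2 = min_stroma_mm2,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()], with `lymphocyte` a
#'   nested mapping of the [lymphocyte_rule()] thresholds.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$lymphocyte)) y$lymphocyte <- do.call(lymphocyte_rule,
                                                      y$lymphocyte)
  do.call(run_config, y)
}

#' Stable hash of a run configuration
#' @param config a [run_config()].
#' @return MD5 string identifying the settings.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Score a manifest of annotated tiles
#'
#' Runs the full imaging pipeline over every tile in a manifest
#' (`tile_id,path,mpp,...` as written by [write_fixture_set()]), looking
#' up `<tile_id>.geojson` in `annotations_dir`. Tiles with a missing
#' annotation or no DCIS are retained as non-evaluable rows; the run
#' continues. Output is deterministic for a fixed config.
#'
#' @param manifest manifest CSV path or data frame.
#' @param annotations_dir directory of per-tile GeoJSON annotations.
#' @param config a [run_config()].
#' @param out optional path for the scores CSV.
#' @return Scores data frame, one row per tile, with `category` and
#'   `threshold` when 2+ tiles are evaluable; attributes `config_hash` and
#'   `timings`.
#' @export
run_score <- function(manifest, annotations_dir, config = run_config(),
                      out = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  stopifnot(all(c("tile_id", "path", "mpp") %in% names(manifest)))
  t0 <- proc.time()[["elapsed"]]
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    ann_path <- file.path(annotations_dir, paste0(m$tile_id, ".geojson"))
    if (!file.exists(m$path) || !file.exists(ann_path)) {
      return(data.frame(patient_id = m$tile_id, n_patches = 0L,
                        stroma_mm2 = 0, raw_density = NA_real_,
                        score = NA_real_, radius_um = config$radius_um,
                        evaluable = FALSE, stringsAsFactors = FALSE))
    }
    img <- read_calibrated_image(m$path, mpp = m$mpp)
    ann <- read_annotations_geojson(ann_path)
    score_tile(img, ann, config, patient_id = m$tile_id)
  })
  scores <- do.call(rbind, rows)
  if (sum(scores$evaluable) >= 2L || !is.null(config$threshold))
    scores <- dichotomize(scores, threshold = config$threshold)
  attr(scores, "config_hash") <- config_hash(config)
  attr(scores, "timings") <- c(elapsed_s = proc.time()[["elapsed"]] - t0)
  if (!is.null(out)) write.csv(scores, out, row.names = FALSE)
  scores
}

#' Validate scores against outcomes
#'
#' Joins per-patient scores to a cohort table and reproduces the standard
#' biomarker validation battery: baseline crosstabs by TIL category,
#' univariate and multivariate Cox models per outcome, the
#' radiotherapy-interaction analysis, and (optionally) the matched nested
#' case-control conditional logistic regression.
#'
#' @param scores scores data frame (or CSV path) with `patient_id`,
#'   `score`, `category` or `evaluable`.
#' @param cohort cohort data frame (or CSV path) in the cohort-table
#'   schema; joined on `patient_id`.
#' @param config a [run_config()].
#' @param crosstab_covariates covariates for the baseline table.
#' @param multivariate_covariates adjustment set for the multivariate Cox
#'   model (intersected with available columns; complete-case).
#' @param matched logical: also run the matched case-control analysis.
#' @return List of class `cpath_validation` with elements `crosstabs`,
#'   `cox` (per outcome: univariate/multivariate fits or an
#'   `"insufficient events"` marker), `interaction`, `matched`,
#'   `join_failures`, `config_hash`.
#' @export
run_validate <- function(scores, cohort, config = run_config(),
                         crosstab_covariates = c("grade", "necrosis", "er",
                                                 "her2", "tumour_size"),
                         multivariate_covariates = c("age", "her2",
                                                     "excision",
                                                     "tumour_size", "grade",
                                                     "necrosis", "tamoxifen",
                                                     "radiotherapy"),
                         matched = TRUE) {
  if (is.character(scores)) scores <- read.csv(scores,
                                               stringsAsFactors = FALSE)
  if (is.character(cohort)) cohort <- read.csv(cohort,
                                               stringsAsFactors = FALSE)
  join_failures <- setdiff(scores$patient_id, cohort$patient_id)
  dat <- merge(cohort[, setdiff(names(cohort), c("score", "category")),
                      drop = FALSE],
               scores[, intersect(c("patient_id", "score", "category"),
                                  names(scores)), drop = FALSE],
               by = "patient_id")
  if (!"category" %in% names(dat))
    dat <- dichotomize(dat, threshold = config$threshold)
  dat <- dat[!is.na(dat$category), , drop = FALSE]

  crosstabs <- lapply(intersect(crosstab_covariates, names(dat)),
                      function(cv) crosstab_summary(dat, cv))
  names(crosstabs) <- intersect(crosstab_covariates, names(dat))

  outcomes <- c("IBE", "I-IBE", "DCIS-IBE")
  cox <- lapply(outcomes, function(oc) {
    if (sum(.outcome_status(dat, oc)) < 2L)
      return(list(status = "insufficient events"))
    mv_cov <- intersect(multivariate_covariates, names(dat))
    uni <- cox_fit(dat, oc, "category")
    mv <- tryCatch(cox_fit(dat, oc, c("category", mv_cov)),
                   error = function(e) list(status = conditionMessage(e)))
    list(status = "ok", univariate = uni, multivariate = mv,
         multivariate_covariates = mv_cov)
  })
  names(cox) <- outcomes

  inter <- tryCatch(
    interaction_test(dat, "IBE", "category", "radiotherapy"),
    error = function(e) list(status = conditionMessage(e)))

  matched_res <- NULL
  if (matched) {
    matched_res <- tryCatch({
      sets <- match_case_control(dat, ratio = 2L, seed = config$seed)
      conditional_logistic(sets, exposure = "category")
    }, error = function(e) list(status = conditionMessage(e)))
  }
  structure(list(crosstabs = crosstabs, cox = cox, interaction = inter,
                 matched = matched_res, join_failures = join_failures,
                 n = nrow(dat), config_hash = config_hash(config)),
            class = "cpath_validation")
}

#' @export
print.cpath_validation <- function(x, ...) {
  cat(sprintf("CPath TIL validation (n=%d, config %s)\n", x$n,
              substr(x$config_hash, 1, 8)))
  for (oc in names(x$cox)) {
    f <- x$cox[[oc]]
    if (!identical(f$status, "ok")) {
      cat(sprintf("  %s: %s\n", oc, f$status)); next
    }
    t <- f$univariate$terms[1, ]
    cat(sprintf("  %s univariate: HR %.2f [%.2f-%.2f]; p=%.4g\n",
                oc, t$hr, t$lo, t$hi, t$p))
  }
  if (!is.null(x$interaction$p_interaction))
    cat(sprintf("  radiotherapy x TIL interaction p=%.4g\n",
                x$interaction$p_interaction))
  if (!is.null(x$matched$or))
    cat(sprintf("  matched OR %.2f [%.2f-%.2f]\n", x$matched$or,
                x$matched$ci[1], x$matched$ci[2]))
  invisible(x)
}
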