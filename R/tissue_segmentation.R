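#' Hematoxylin/eosin stain vectors
#'
#' Unit-norm optical-density absorption vectors for hematoxylin and eosin
#' in the Ruifrok-Johnston convention. Rows are stains, columns RGB.
#'
#' @return A `2 x 3` matrix with rownames `hematoxylin`, `eosin`.
#' @export
he_stain_vectors <- function() {
  v <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
             eosin       = c(0.072, 0.990, 0.105))
  v / sqrt(rowSums(v^2))
}

#' Convert an RGB image to optical density
#'
#' Per channel, `OD = -log10((I + 1) / 256)` so that pure white (255) maps
#' to 0 absorbance and black to `-log10(1/256) ~ 2.408`. OD is additive
#' across stains (Beer-Lambert), which is what makes linear deconvolution
#' meaningful.
#'
#' @param image a [calibrated_image()].
#' @return Numeric `H x W x 3` array of non-negative optical densities.
#' @export
rgb_to_od <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  -log10((image$pixels + 1) / 256)
}

#' Deconvolve optical density into hematoxylin and eosin channels
#'
#' Least-squares projection of each pixel's OD vector onto the two stain
#' vectors; negative coefficients (noise outside the stain cone) are
#' clipped to zero.
#'
#' @param od `H x W x 3` OD array from [rgb_to_od()].
#' @param stain_vectors `2 x 3` matrix of unit stain vectors, rows
#'   (hematoxylin, eosin).
#' @return A list of class `stain_channels` with matrices
#'   `hematoxylin_od` and `eosin_od`.
#' @export
deconvolve_stains <- function(od, stain_vectors = he_stain_vectors()) {
  stopifnot(is.array(od), length(dim(od)) == 3L, dim(od)[3] == 3L,
            is.matrix(stain_vectors), all(dim(stain_vectors) == c(2L, 3L)))
  sv <- stain_vectors / sqrt(rowSums(stain_vectors^2))
  if (kappa(sv, exact = TRUE) > 1e6)
    stop("degenerate stain vectors: near-collinear", call. = FALSE)
  d <- dim(od)
  flat <- matrix(od, nrow = d[1] * d[2], ncol = 3L)
  # pseudoinverse solve: coef = (S S^T)^-1 S od
  coefs <- flat %*% t(sv) %*% solve(sv %*% t(sv))
  coefs[coefs < 0] <- 0
  structure(list(hematoxylin_od = matrix(coefs[, 1], d[1], d[2]),
                 eosin_od       = matrix(coefs[, 2], d[1], d[2])),
            class = "stain_channels")
}

#' Segment nuclei from the hematoxylin channel
#'
#' Classical chain: Otsu threshold on hematoxylin OD, morphological opening
#' (disk of radius `opening_um`), Euclidean distance transform, watershed
#' split of touching blobs seeded at distance-transform maxima separated by
#' at least `min_separation_um`, and removal of components smaller than
#' `min_area_um2`. All length thresholds are in microns and converted with
#' the image calibration.
#'
#' @param stains `stain_channels` from [deconvolve_stains()].
#' @param mpp microns per pixel.
#' @param min_area_um2 discard components below this area (default 10 um^2).
#' @param opening_um radius of the opening structuring element (default 1 um).
#' @param min_separation_um minimum watershed seed separation (default 3 um,
#'   the lymphocyte diameter floor).
#' @return Data frame with one row per nucleus: `id`, `row`, `col`
#'   (centroid, 0-based continuous pixel coordinates), `area_um2`,
#'   `circularity` (`4*pi*A/P^2`, perimeter from the city-block exposed-edge
#'   count scaled by `pi/4`, clamped to `[0, 1.05]`), `mean_hema_od`, and
#'   `label` (`NA` until [classify_lymphocytes()] is applied).
#' @export
segment_nuclei <- function(stains, mpp, min_area_um2 = 10,
                           opening_um = 1, min_separation_um = 3) {
  stopifnot(inherits(stains, "stain_channels"), mpp > 0)
  hema <- stains$hematoxylin_od
  empty <- data.frame(id = integer(), row = numeric(), col = numeric(),
                      area_um2 = numeric(), circularity = numeric(),
                      mean_hema_od = numeric(), label = character(),
                      stringsAsFactors = FALSE)
  # blank channel: nothing absorbs enough to be a nucleus
  if (max(hema) < 0.1) return(empty)
  img <- EBImage::Image(t(hema))
  thr <- EBImage::otsu(img, range = range(hema))
  bin <- img > thr
  open_px <- max(1L, round(opening_um / mpp))
  bin <- EBImage::opening(bin, EBImage::makeBrush(2L * open_px + 1L, "disc"))
  if (!any(bin)) return(empty)
  dm <- EBImage::distmap(bin)
  ext <- max(1L, round(min_separation_um / (2 * mpp)))
  lab <- EBImage::watershed(dm, tolerance = 0.5, ext = ext)
  nlab <- max(lab)
  if (nlab == 0L) return(empty)
  labm <- t(EBImage::imageData(lab))  # H x W label matrix

  area_px <- tabulate(labm[labm > 0L], nbins = nlab)
  min_px <- min_area_um2 / mpp^2
  keep <- which(area_px >= min_px)
  if (!length(keep)) return(empty)

  # centroids and mean OD
  idx <- which(labm > 0L)
  lv <- labm[idx]
  rr <- ((idx - 1L) %% nrow(labm)) + 1L
  cc <- ((idx - 1L) %/% nrow(labm)) + 1L
  sum_r <- rowsum(as.numeric(rr), lv)
  sum_c <- rowsum(as.numeric(cc), lv)
  sum_od <- rowsum(hema[idx], lv)
  ids_all <- as.integer(rownames(sum_r))
  cent_r <- sum_r[, 1] / area_px[ids_all]
  cent_c <- sum_c[, 1] / area_px[ids_all]
  mean_od <- sum_od[, 1] / area_px[ids_all]

  per <- .cityblock_edges(labm, nlab) * pi / 4
  circ <- 4 * pi * area_px / per^2
  circ <- pmin(pmax(circ, 0), 1.05)

  sel <- match(keep, ids_all)
  out <- data.frame(
    id = seq_along(keep),
    row = cent_r[sel] - 0.5,   # 0-based continuous coordinates
    col = cent_c[sel] - 0.5,
    area_um2 = area_px[keep] * mpp^2,
    circularity = circ[keep],
    mean_hema_od = mean_od[sel],
    label = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Exposed 4-neighbour edge count per label: 4*area minus twice the number of
# same-label horizontal/vertical adjacencies. pi/4 times this is an unbiased
# perimeter estimate for convex digital shapes (exact for disks).
.cityblock_edges <- function(labm, nlab) {
  area <- tabulate(labm[labm > 0L], nbins = nlab)
  h <- labm[, -ncol(labm)] == labm[, -1] & labm[, -ncol(labm)] > 0L
  v <- labm[-nrow(labm), ] == labm[-1, ] & labm[-nrow(labm), ] > 0L
  same_h <- tabulate(labm[, -ncol(labm)][h], nbins = nlab)
  same_v <- tabulate(labm[-nrow(labm), ][v], nbins = nlab)
  4 * area - 2 * (same_h + same_v)
}

#' Morphometric lymphocyte classification rule
#'
#' Lymphocytes are small, round and hyperchromatic: the rule labels a
#' nucleus `lymphocyte` iff area lies in `[area_min, area_max]` um^2, the
#' circularity is at least `circ_min` and the mean hematoxylin OD at least
#' `od_min` (all bounds inclusive). Everything else is `other`.
#'
#' @param area_min,area_max nuclear area bounds in um^2 (defaults 15 and 80).
#' @param circ_min minimum circularity (default 0.80).
#' @param od_min minimum mean hematoxylin OD (default 0.40).
#' @return A named list of thresholds, class `lymphocyte_rule`.
#' @export
lymphocyte_rule <- function(area_min = 15, area_max = 80,
                            circ_min = 0.80, od_min = 0.40) {
  stopifnot(area_min > 0, area_max > area_min, circ_min > 0, od_min >= 0)
  structure(list(area_min = area_min, area_max = area_max,
                 circ_min = circ_min, od_min = od_min),
            class = "lymphocyte_rule")
}

#' Label nuclei as lymphocyte or other
#'
#' Pure function of each record's morphometrics under a
#' [lymphocyte_rule()]; the same record always gets the same label.
#'
#' @param nuclei data frame from [segment_nuclei()].
#' @param rule a [lymphocyte_rule()].
#' @return The same data frame with `label` filled in.
#' @export
classify_lymphocytes <- function(nuclei, rule = lymphocyte_rule()) {
  stopifnot(is.data.frame(nuclei), inherits(rule, "lymphocyte_rule"))
  if (!nrow(nuclei)) return(nuclei)
  is_lym <- nuclei$area_um2 >= rule$area_min &
            nuclei$area_um2 <= rule$area_max &
            nuclei$circularity >= rule$circ_min &
            nuclei$mean_hema_od >= rule$od_min
  nuclei$label <- ifelse(is_lym, "lymphocyte", "other")
  nuclei
}

#' Segment periductal stroma
#'
#' Tissue is detected in HSV space (saturation at least `sat_min` and value
#' at most `val_max`, robust to faintly stained eosin); the DCIS annotation
#' mask and dilated epithelial (non-lymphocyte) nuclei inside the
#' annotation are then removed, leaving the stromal compartment in which
#' TILs are sought.
#'
#' @param image a [calibrated_image()].
#' @param dcis_mask logical `H x W` DCIS mask.
#' @param nuclei labelled nucleus data frame (may be `NULL`).
#' @param sat_min minimum HSV saturation for tissue (default 0.05).
#' @param val_max maximum HSV value for tissue (default 0.95).
#' @param dilate_um dilation radius for epithelial nucleus exclusion
#'   (default 2 um).
#' @return An object of class `stroma_mask`: list with `mask` (logical
#'   `H x W`) and `mpp`.
#' @export
segment_stroma <- function(image, dcis_mask, nuclei = NULL,
                           sat_min = 0.05, val_max = 0.95, dilate_um = 2) {
  stopifnot(inherits(image, "calibrated_image"))
  d <- dim(image$pixels)
  if (!is.matrix(dcis_mask) || !all(dim(dcis_mask) == d[1:2]))
    stop("dcis_mask shape does not match the image", call. = FALSE)
  px <- image$pixels
  hsv <- rgb2hsv(r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
                 b = as.vector(px[, , 3]), maxColorValue = 255)
  tissue <- matrix(hsv[2, ] >= sat_min & hsv[3, ] <= val_max, d[1], d[2])
  mask <- tissue & !dcis_mask
  if (!is.null(nuclei) && nrow(nuclei)) {
    epi <- nuclei[!is.na(nuclei$label) & nuclei$label == "other", ,
                  drop = FALSE]
    if (nrow(epi)) {
      ri <- pmin(pmax(floor(epi$row) + 1L, 1L), d[1])
      ci <- pmin(pmax(floor(epi$col) + 1L, 1L), d[2])
      inside <- dcis_mask[cbind(ri, ci)]
      epi <- epi[inside, , drop = FALSE]
      if (nrow(epi)) {
        blob <- matrix(FALSE, d[1], d[2])
        rad_px <- sqrt(epi$area_um2 / pi) / image$mpp
        for (k in seq_len(nrow(epi)))
          blob <- .paint_disk(blob, epi$row[k], epi$col[k], rad_px[k], TRUE)
        dil <- max(1L, round(dilate_um / image$mpp))
        blob <- t(as.matrix(EBImage::dilate(
          EBImage::Image(t(blob) * 1), EBImage::makeBrush(2L * dil + 1L, "disc")))) > 0
        mask <- mask & !blob
      }
    }
  }
  structure(list(mask = mask, mpp = image$mpp), class = "stroma_mask")
}

# Set (or logically OR) a disk of radius `rad` px centred at 0-based
# continuous coordinates (r0, c0) into logical matrix `m`.
.paint_disk <- function(m, r0, c0, rad, value = TRUE) {
  H <- nrow(m); W <- ncol(m)
  ri <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad + 1))
  ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad + 1))
  if (!length(ri) || !length(ci)) return(m)
  d2 <- outer((ri - 0.5 - r0)^2, (ci - 0.5 - c0)^2, "+")
  m[ri, ci][d2 <= rad^2] <- value
  m
}
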