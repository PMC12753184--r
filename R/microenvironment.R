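#' DCIS annotation set
#'
#' A collection of closed polygons outlining DCIS-bearing regions, as drawn
#' by a pathologist (e.g. exported from QuPath as GeoJSON). Polygons are in
#' `(x, y)` order where `x` runs along columns and `y` along rows, in a
#' 0-based continuous pixel (or micron) coordinate system in which pixel
#' `(i, j)` (1-based indices) occupies `[j-1, j) x [i-1, i)` and has centre
#' `(j - 0.5, i - 0.5)`.
#'
#' @param polygons list of numeric matrices, each `n x 2` with columns
#'   `(x, y)` and `n >= 3`; the closing vertex may be repeated or omitted.
#' @param units `"px"` or `"um"`; micron coordinates are divided by the
#'   image mpp at rasterisation time.
#' @param source_id identifier of the annotated slide/region.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(polygons, units = c("px", "um"), source_id = "") {
  units <- match.arg(units)
  if (!is.list(polygons)) stop("`polygons` must be a list", call. = FALSE)
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || !is.numeric(p))
      stop("each polygon must be an n x 2 numeric matrix", call. = FALSE)
    # drop an explicitly repeated closing vertex
    n <- nrow(p)
    if (n >= 2L && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
    if (nrow(p) < 3L)
      stop("each polygon needs at least 3 distinct vertices", call. = FALSE)
    if (anyNA(p) || any(!is.finite(p)))
      stop("polygon coordinates must be finite", call. = FALSE)
    if (.polygon_self_intersects(p))
      stop("invalid annotation: self-intersecting polygon", call. = FALSE)
    unname(p)
  })
  structure(list(polygons = polygons, units = units,
                 source_id = as.character(source_id)),
            class = "annotation_set")
}

# Segment-crossing test over all non-adjacent edge pairs (polygons here have
# tens of vertices, so the quadratic scan is immaterial).
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex
    for (j in js) {
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterise DCIS annotations to a binary mask
#'
#' A pixel is set iff its centre lies inside any polygon (even-odd crossing
#' rule). Micron-unit annotations are converted to pixels using `mpp`.
#'
#' @param ann an [annotation_set()].
#' @param shape integer vector `c(H, W)`.
#' @param mpp microns per pixel of the target image.
#' @return Logical `H x W` matrix.
#' @export
rasterize_annotations <- function(ann, shape, mpp) {
  stopifnot(inherits(ann, "annotation_set"), length(shape) == 2L, mpp > 0)
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  mask <- matrix(FALSE, H, W)
  if (length(ann$polygons) == 0L) return(mask)
  scale <- if (ann$units == "um") 1 / mpp else 1
  for (p in ann$polygons) {
    p <- p * scale
    if (min(p[, 1]) < -0.5 || max(p[, 1]) > W + 0.5 ||
        min(p[, 2]) < -0.5 || max(p[, 2]) > H + 0.5)
      stop("annotation polygon extends beyond the image bounds", call. = FALSE)
    # pixel centres (0-based continuous coordinates) within the bounding box
    ci <- max(1L, floor(min(p[, 1]) + 0.5)):min(W, ceiling(max(p[, 1]) + 0.5))
    ri <- max(1L, floor(min(p[, 2]) + 0.5)):min(H, ceiling(max(p[, 2]) + 0.5))
    if (!length(ri) || !length(ci)) next
    pts <- cbind(rep(ci - 0.5, each = length(ri)),
                 rep(ri - 0.5, times = length(ci)))
    inside <- mgcv::in.out(rbind(p, p[1, ]), pts)
    mask[ri, ci][inside] <- TRUE
  }
  mask
}

#' Read annotations from a GeoJSON FeatureCollection
#'
#' One Feature per duct; Polygon geometries only (first ring; holes are not
#' used for DCIS outlines). Coordinates are `(x, y)` pixels.
#'
#' @param path GeoJSON file path.
#' @return An [annotation_set()] in pixel units.
#' @export
read_annotations_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features %||% list()
  polys <- lapply(feats, function(f) {
    g <- f$geometry
    if (is.null(g) || !identical(g$type, "Polygon")) return(NULL)
    ring <- g$coordinates[[1]]
    do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
  })
  polys <- Filter(Negate(is.null), polys)
  annotation_set(polys, units = "px",
                 source_id = basename(tools::file_path_sans_ext(path)))
}

#' Write annotations as a GeoJSON FeatureCollection
#'
#' Each duct becomes one Feature with property `classification = "DCIS"`,
#' the convention used by common pathology viewers.
#'
#' @param ann an [annotation_set()] (pixel units).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_geojson <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  feats <- lapply(ann$polygons, function(p) {
    ring <- lapply(seq_len(nrow(p) + 1L), function(i) {
      j <- if (i > nrow(p)) 1L else i
      c(p[j, 1], p[j, 2])
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(classification = "DCIS"))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Periductal microenvironment ring
#'
#' The microenvironment of a DCIS lesion is the periductal region within a
#' fixed radius (default in the pipeline: 250 um) of the DCIS boundary.
#' Computed as the set of non-DCIS pixels whose Euclidean distance to the
#' rasterised DCIS mask is at most `radius_um`; rings of multiple ducts
#' merge by union, and epithelium of every annotated duct is excluded.
#'
#' @param dcis_mask logical `H x W` DCIS mask (all annotated ducts).
#' @param radius_um ring radius in microns, `> 0`.
#' @param mpp microns per pixel.
#' @return An object of class `ring_mask`: list with `mask` (logical
#'   `H x W`), `radius_um`, `mpp`.
#' @export
periductal_ring <- function(dcis_mask, radius_um, mpp) {
  stopifnot(is.matrix(dcis_mask), radius_um > 0, mpp > 0)
  if (!any(dcis_mask))
    stop("no DCIS in annotation mask: patient not evaluable", call. = FALSE)
  d <- .edt_to_mask(dcis_mask)
  ring <- !dcis_mask & d <= radius_um / mpp
  structure(list(mask = ring, radius_um = radius_um, mpp = mpp),
            class = "ring_mask")
}

# Euclidean distance (in px) from every pixel to the nearest TRUE pixel of
# `mask`; 0 inside the mask.
.edt_to_mask <- function(mask) {
  img <- EBImage::Image(t(!mask) * 1)
  t(as.matrix(EBImage::distmap(img, metric = "euclidean")))
}

#' Partition the ring stroma into a patch grid
#'
#' Lays a fixed square grid (anchored at the image origin, half-open boxes)
#' over the image, counts stromal microenvironment pixels per patch, and
#' assigns each lymphocyte to the patch containing its centroid. Patches
#' with no stroma in the ring are dropped.
#'
#' @param ring a `ring_mask` from [periductal_ring()].
#' @param stroma a `stroma_mask` from [segment_stroma()] (or a logical
#'   matrix of the same shape).
#' @param nuclei nucleus data frame from [segment_nuclei()] +
#'   [classify_lymphocytes()]; only rows labelled `"lymphocyte"` whose
#'   centroid lies in the ring are assigned.
#' @param patch_size_um patch edge length in microns (default 100).
#' @return An object of class `patch_grid`: list with `patches` (data frame
#'   `patch_id, r0, c0, r1, c1, stroma_px, n_lymphocytes`), `assignments`
#'   (data frame `nucleus_id, patch_id`), `patch_size_um`, `mpp`.
#' @export
tile_patches <- function(ring, stroma, nuclei, patch_size_um = 100) {
  stopifnot(inherits(ring, "ring_mask"))
  smask <- if (is.list(stroma)) stroma$mask else stroma
  if (!all(dim(smask) == dim(ring$mask)))
    stop("ring and stroma masks differ in shape", call. = FALSE)
  mpp <- ring$mpp
  if (patch_size_um < 2 * mpp)
    stop("degenerate patch: patch_size_um must be at least 2 pixels",
         call. = FALSE)
  s_px <- patch_size_um / mpp
  H <- nrow(smask); W <- ncol(smask)
  sel <- ring$mask & smask
  # patch index of each pixel (0-based grid coordinates)
  pr <- floor((row(smask)[sel] - 0.5) / s_px)
  pc <- floor((col(smask)[sel] - 0.5) / s_px)
  if (!length(pr)) {
    patches <- data.frame(patch_id = integer(), r0 = numeric(),
                          c0 = numeric(), r1 = numeric(), c1 = numeric(),
                          stroma_px = integer(), n_lymphocytes = integer())
    assign <- data.frame(nucleus_id = integer(), patch_id = integer())
    return(structure(list(patches = patches, assignments = assign,
                          patch_size_um = patch_size_um, mpp = mpp),
                     class = "patch_grid"))
  }
  ncols_grid <- ceiling(W / s_px)
  key <- pr * ncols_grid + pc
  tab <- table(key)
  keys <- as.numeric(names(tab))
  kr <- floor(keys / ncols_grid); kc <- keys - kr * ncols_grid
  patches <- data.frame(
    patch_id = seq_along(keys),
    r0 = kr * s_px, c0 = kc * s_px,
    r1 = pmin((kr + 1) * s_px, H), c1 = pmin((kc + 1) * s_px, W),
    stroma_px = as.integer(tab),
    n_lymphocytes = 0L)
  key_lookup <- setNames(patches$patch_id, as.character(keys))

  assign <- data.frame(nucleus_id = integer(), patch_id = integer())
  if (!is.null(nuclei) && nrow(nuclei)) {
    ly <- nuclei[!is.na(nuclei$label) & nuclei$label == "lymphocyte", ,
                 drop = FALSE]
    if (nrow(ly)) {
      # pixel containing a 0-based continuous coordinate v is floor(v) + 1
      ri <- pmin(pmax(floor(ly$row) + 1L, 1L), H)
      ci <- pmin(pmax(floor(ly$col) + 1L, 1L), W)
      in_ring <- ring$mask[cbind(ri, ci)]
      ly <- ly[in_ring, , drop = FALSE]
      if (nrow(ly)) {
        k <- floor(ly$row / s_px) * ncols_grid + floor(ly$col / s_px)
        pid <- unname(key_lookup[as.character(k)])
        keep <- !is.na(pid)
        assign <- data.frame(nucleus_id = ly$id[keep], patch_id = pid[keep])
        if (nrow(assign)) {
          cnt <- table(assign$patch_id)
          patches$n_lymphocytes[match(as.integer(names(cnt)),
                                      patches$patch_id)] <- as.integer(cnt)
        }
      }
    }
  }
  structure(list(patches = patches, assignments = assign,
                 patch_size_um = patch_size_um, mpp = mpp),
            class = "patch_grid")
}
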