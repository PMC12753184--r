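#' Specification for a synthetic H&E tile
#'
#' Defines the geometry and planted cell populations of one calibrated
#' synthetic tile: duct outlines, expected lymphocyte density in stroma,
#' epithelial nucleus density inside ducts, a glass (background) fraction
#' and the seed that makes generation deterministic.
#'
#' @param width_px,height_px tile size in pixels.
#' @param mpp microns per pixel (`> 0`).
#' @param duct_polygons list of `n x 2` polygon matrices (`(x, y)` pixel
#'   coordinates) lying within the tile, or an [annotation_set()].
#' @param lymphocyte_density expected lymphocytes per mm^2 of stroma.
#' @param epithelial_nucleus_density expected epithelial nuclei per mm^2 of
#'   duct region (default 3000, a loosely packed epithelium).
#' @param background_fraction fraction of the tile rendered as glass, laid
#'   as a strip along the right edge (default 0).
#' @param seed integer RNG seed.
#' @return An object of class `tile_spec`.
#' @export
tile_spec <- function(width_px, height_px, mpp, duct_polygons = list(),
                      lymphocyte_density = 0,
                      epithelial_nucleus_density = 3000,
                      background_fraction = 0, seed = 1L) {
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("invalid tile spec: mpp must be a positive number", call. = FALSE)
  if (width_px < 1 || height_px < 1)
    stop("invalid tile spec: empty tile", call. = FALSE)
  if (!is.finite(lymphocyte_density) || lymphocyte_density < 0 ||
      !is.finite(epithelial_nucleus_density) || epithelial_nucleus_density < 0)
    stop("invalid tile spec: densities must be finite and non-negative",
         call. = FALSE)
  if (background_fraction < 0 || background_fraction > 1)
    stop("invalid tile spec: background_fraction must be in [0, 1]",
         call. = FALSE)
  ann <- if (inherits(duct_polygons, "annotation_set")) duct_polygons
         else annotation_set(duct_polygons, units = "px")
  for (p in ann$polygons)
    if (min(p) < 0 || max(p[, 1]) > width_px || max(p[, 2]) > height_px)
      stop("invalid tile spec: duct polygon outside tile bounds",
           call. = FALSE)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), mpp = mpp,
                 annotations = ann,
                 lymphocyte_density = lymphocyte_density,
                 epithelial_nucleus_density = epithelial_nucleus_density,
                 background_fraction = background_fraction,
                 seed = as.integer(seed)),
            class = "tile_spec")
}

#' Irregular duct outline polygon
#'
#' Convenience constructor for a roughly circular duct boundary with
#' radial jitter, in `(x, y)` pixel coordinates. Uses the current RNG
#' state.
#'
#' @param cx,cy centre, 0-based pixel coordinates.
#' @param radius_px mean radius in pixels.
#' @param n_vertices number of vertices (default 28).
#' @param irregularity relative radial jitter (default 0.12).
#' @return An `n x 2` polygon matrix.
#' @export
duct_polygon <- function(cx, cy, radius_px, n_vertices = 28,
                         irregularity = 0.12) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- radius_px * (1 + runif(n_vertices, -irregularity, irregularity))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Generate a calibrated synthetic H&E tile with ground truth
#'
#' Renders glass, eosin-dominant stroma, duct epithelium with clustered
#' ellipsoidal nuclei, and lymphocyte nuclei drawn as small round
#' hematoxylin-dominant disks (diameter 6-9 um) Poisson-scattered over the
#' stroma at the planted density. Rendering mixes optical densities with
#' the published H&E stain vectors ([he_stain_vectors()]), adds Gaussian
#' OD noise (sd 0.02) and a 1 px blur, then converts OD to 8-bit RGB - so
#' the analysis chain's stain deconvolution is exercised by construction.
#' The same spec and seed always yield a bit-identical tile.
#'
#' @param spec a [tile_spec()].
#' @return A list with elements `image` (a [calibrated_image()]) and
#'   `truth`, a ground-truth list: `duct_mask`, `stroma_mask`,
#'   `background_mask` (logical matrices partitioning the tile),
#'   `lymphocyte_centroids` (`n x 2` matrix, `(row, col)` 0-based
#'   continuous), `lymphocyte_count`, `lymphocyte_diameters_um`,
#'   `epithelial_centroids`, `stroma_mm2`, `true_density` (realised
#'   lymphocytes per mm^2 stroma) and `true_area_fraction` (planted
#'   lymphocyte nucleus area over stroma area).
#' @export
generate_tile <- function(spec) {
  stopifnot(inherits(spec, "tile_spec"))
  set.seed(spec$seed)
  H <- spec$height_px; W <- spec$width_px; mpp <- spec$mpp

  duct <- rasterize_annotations(spec$annotations, c(H, W), mpp)
  glass <- matrix(FALSE, H, W)
  strip <- round(spec$background_fraction * W)
  if (strip > 0) glass[, (W - strip + 1L):W] <- TRUE
  glass <- glass & !duct
  stroma <- !duct & !glass

  px_mm2 <- mpp^2 / 1e6
  stroma_mm2 <- sum(stroma) * px_mm2
  duct_mm2 <- sum(duct) * px_mm2

  # --- lymphocytes: Poisson number, uniform over stroma pixels ----------
  n_lym <- rpois(1L, spec$lymphocyte_density * stroma_mm2)
  s_idx <- which(stroma)
  n_lym <- min(n_lym, length(s_idx))
  lym_r <- lym_c <- numeric(0); lym_d <- numeric(0)
  if (n_lym > 0L) {
    pick <- sample(s_idx, n_lym)
    lym_r <- ((pick - 1L) %% H) + 0.5 + runif(n_lym, -0.3, 0.3)
    lym_c <- ((pick - 1L) %/% H) + 0.5 + runif(n_lym, -0.3, 0.3)
    lym_d <- runif(n_lym, 6, 9)  # diameter, um
  }

  # --- epithelial nuclei: clustered ellipses inside ducts ---------------
  epi_r <- epi_c <- epi_a <- epi_b <- epi_th <- numeric(0)
  d_idx <- which(duct)
  if (length(d_idx) && spec$epithelial_nucleus_density > 0) {
    n_epi <- rpois(1L, spec$epithelial_nucleus_density * duct_mm2)
    n_epi <- min(n_epi, length(d_idx))
    if (n_epi > 0L) {
      n_clust <- max(1L, ceiling(n_epi / 8))
      ctr <- sample(d_idx, min(n_clust, length(d_idx)))
      ctr_r <- ((ctr - 1L) %% H) + 0.5
      ctr_c <- ((ctr - 1L) %/% H) + 0.5
      k <- sample.int(length(ctr), n_epi, replace = TRUE)
      jit <- 12 / mpp  # cluster spread, um -> px
      rr <- ctr_r[k] + rnorm(n_epi, 0, jit)
      cc <- ctr_c[k] + rnorm(n_epi, 0, jit)
      ri <- pmin(pmax(floor(rr) + 1L, 1L), H)
      ci <- pmin(pmax(floor(cc) + 1L, 1L), W)
      ok <- duct[cbind(ri, ci)]
      rr <- rr[ok]; cc <- cc[ok]
      n_epi <- length(rr)
      if (n_epi > 0L) {
        dmaj <- runif(n_epi, 9, 14)               # major diameter, um
        dmin <- dmaj * runif(n_epi, 0.55, 0.8)    # minor diameter, um
        epi_r <- rr; epi_c <- cc
        epi_a <- dmaj / 2; epi_b <- dmin / 2
        epi_th <- runif(n_epi, 0, pi)
      }
    }
  }

  # --- render OD canvases ----------------------------------------------
  odH <- matrix(0, H, W); odE <- matrix(0, H, W)
  odH[stroma] <- 0.06; odE[stroma] <- 0.30
  odH[duct] <- 0.10;   odE[duct] <- 0.20
  for (i in seq_along(epi_r)) {
    win <- .ellipse_window(epi_r[i], epi_c[i], epi_a[i] / mpp, epi_b[i] / mpp,
                           epi_th[i], H, W)
    odH[win] <- 0.35; odE[win] <- 0.10
  }
  for (i in seq_along(lym_r)) {
    win <- .disk_window(lym_r[i], lym_c[i], lym_d[i] / 2 / mpp, H, W)
    odH[win] <- 0.85; odE[win] <- 0.10
  }
  odH <- odH + matrix(rnorm(H * W, 0, 0.02), H, W)
  odE <- odE + matrix(rnorm(H * W, 0, 0.02), H, W)
  odH <- t(as.matrix(EBImage::gblur(EBImage::Image(t(odH)), sigma = 1)))
  odE <- t(as.matrix(EBImage::gblur(EBImage::Image(t(odE)), sigma = 1)))
  odH[odH < 0] <- 0; odE[odE < 0] <- 0

  sv <- he_stain_vectors()
  px <- array(0L, dim = c(H, W, 3L))
  for (ch in 1:3) {
    od_ch <- odH * sv[1, ch] + odE * sv[2, ch]
    px[, , ch] <- pmin(pmax(round(256 * 10^(-od_ch) - 1), 0L), 255L)
  }

  lym_area_um2 <- sum(pi * (lym_d / 2)^2)
  truth <- list(
    duct_mask = duct, stroma_mask = stroma, background_mask = glass,
    lymphocyte_centroids = cbind(row = lym_r, col = lym_c),
    lymphocyte_count = length(lym_r),
    lymphocyte_diameters_um = lym_d,
    epithelial_centroids = cbind(row = epi_r, col = epi_c),
    stroma_mm2 = stroma_mm2,
    true_density = if (stroma_mm2 > 0) length(lym_r) / stroma_mm2 else 0,
    true_area_fraction = if (stroma_mm2 > 0)
      lym_area_um2 / (stroma_mm2 * 1e6) else 0)
  list(image = calibrated_image(px, mpp), truth = truth)
}

# logical index matrix (cells of m) covered by a disk / rotated ellipse,
# in 0-based continuous coordinates
.disk_window <- function(r0, c0, rad, H, W) {
  ri <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad + 1))
  ci <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad + 1))
  d2 <- outer((ri - 0.5 - r0)^2, (ci - 0.5 - c0)^2, "+")
  cbind(rep(ri, times = length(ci))[d2 <= rad^2],
        rep(ci, each = length(ri))[d2 <= rad^2])
}

.ellipse_window <- function(r0, c0, a, b, theta, H, W) {
  ext <- max(a, b)
  ri <- max(1L, floor(r0 - ext)):min(H, ceiling(r0 + ext + 1))
  ci <- max(1L, floor(c0 - ext)):min(W, ceiling(c0 + ext + 1))
  dy <- rep(ri - 0.5 - r0, times = length(ci))
  dx <- rep(ci - 0.5 - c0, each = length(ri))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  cbind(rep(ri, times = length(ci))[inside],
        rep(ci, each = length(ri))[inside])
}

#' Write a reproducible synthetic fixture set
#'
#' Generates `n_tiles` tiles at every density in `density_grid`, each with
#' one or two annotated ducts, and writes per tile: the PNG image, a
#' GeoJSON duct annotation, a JSON ground-truth sidecar and a lymphocyte
#' centroid CSV; plus a `manifest.csv` with one row per tile
#' (`tile_id,path,mpp,true_density,lymphocyte_count,seed`).
#'
#' @param n_tiles replicates per density.
#' @param density_grid vector of planted lymphocyte densities (per mm^2
#'   stroma), all `>= 0`.
#' @param out_dir output directory (created if needed).
#' @param mpp microns per pixel (default 1).
#' @param tile_px tile edge length in pixels (default 800).
#' @param background_fraction glass fraction per tile (default 0.08).
#' @param seed base seed; tile `k` uses `seed + k`.
#' @return The manifest as a data frame, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
write_fixture_set <- function(n_tiles, density_grid, out_dir, mpp = 1,
                              tile_px = 800, background_fraction = 0.08,
                              seed = 1L) {
  if (any(!is.finite(density_grid)) || any(density_grid < 0))
    stop("densities must be finite and non-negative", call. = FALSE)
  manifest <- data.frame(tile_id = character(), path = character(),
                         mpp = numeric(), true_density = numeric(),
                         lymphocyte_count = integer(), seed = integer(),
                         stringsAsFactors = FALSE)
  if (n_tiles > 0L) {
    ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  k <- 0L
  for (dens in density_grid) for (rep_i in seq_len(n_tiles)) {
    k <- k + 1L
    tile_seed <- as.integer(seed) + k
    spec <- fixture_tile_spec(tile_px, mpp, dens, background_fraction,
                              tile_seed)
    gt <- generate_tile(spec)
    tile_id <- sprintf("tile_%03d", k)
    img_path <- file.path(out_dir, paste0(tile_id, ".png"))
    write_calibrated_image(gt$image, img_path)
    write_annotations_geojson(spec$annotations,
                              file.path(out_dir, paste0(tile_id, ".geojson")))
    tr <- gt$truth
    jsonlite::write_json(
      list(tile_id = tile_id, mpp = mpp, planted_density = dens,
           true_density = tr$true_density,
           true_area_fraction = tr$true_area_fraction,
           lymphocyte_count = tr$lymphocyte_count,
           stroma_mm2 = tr$stroma_mm2, seed = tile_seed),
      file.path(out_dir, paste0(tile_id, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
    write.csv(as.data.frame(tr$lymphocyte_centroids),
              file.path(out_dir, paste0(tile_id, "_lymphocytes.csv")),
              row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      tile_id = tile_id, path = img_path, mpp = mpp,
      true_density = tr$true_density,
      lymphocyte_count = tr$lymphocyte_count, seed = tile_seed,
      stringsAsFactors = FALSE))
  }
  if (n_tiles > 0L)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Standard fixture tile layout
#'
#' One large central duct and one smaller satellite duct (when the tile is
#' big enough), glass strip along the right edge, planted lymphocyte
#' density as given. Duct outlines get seeded radial jitter.
#'
#' @param tile_px tile edge length (square tile).
#' @param mpp microns per pixel.
#' @param density lymphocytes per mm^2 stroma.
#' @param background_fraction glass fraction.
#' @param seed tile seed.
#' @return A [tile_spec()].
#' @export
fixture_tile_spec <- function(tile_px, mpp, density,
                              background_fraction = 0.08, seed = 1L) {
  set.seed(seed)
  usable <- tile_px * (1 - background_fraction)
  r_main <- 0.11 * tile_px
  polys <- list(duct_polygon(usable * 0.42, tile_px * 0.5, r_main))
  if (usable * 0.42 - r_main > 2.2 * r_main) {
    polys <- c(polys, list(duct_polygon(usable * 0.16, tile_px * 0.22,
                                        0.06 * tile_px)))
  }
  tile_spec(tile_px, tile_px, mpp, duct_polygons = polys,
            lymphocyte_density = density,
            background_fraction = background_fraction, seed = seed)
}
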