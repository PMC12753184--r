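# independent even-odd crossing test used as the rasterisation oracle
eo_inside <- function(px, py, poly) {
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

test_that("axis-aligned square rasterises to its exact pixel area", {
  ann <- annotation_set(list(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))))
  m <- rasterize_annotations(ann, c(120, 120), mpp = 1)
  expect_equal(sum(m), 10000L)
})

test_that("rasterisation agrees with a point-in-polygon oracle", {
  poly <- cbind(x = c(3.2, 30.5, 35.1, 18.4, 5.0),
                y = c(4.1, 2.8, 25.3, 33.7, 20.2))
  m <- rasterize_annotations(annotation_set(list(poly)), c(40, 40), mpp = 1)
  oracle <- matrix(FALSE, 40, 40)
  for (i in 1:40) for (j in 1:40)
    oracle[i, j] <- eo_inside(j - 0.5, i - 0.5, poly)
  expect_identical(m, oracle)
})

test_that("empty and disjoint annotations behave additively", {
  expect_equal(sum(rasterize_annotations(annotation_set(list()),
                                         c(50, 50), 1)), 0L)
  p1 <- cbind(c(2, 12, 12, 2), c(2, 2, 12, 12))
  p2 <- cbind(c(30, 44, 44, 30), c(30, 30, 44, 44))
  both <- rasterize_annotations(annotation_set(list(p1, p2)), c(50, 50), 1)
  a1 <- rasterize_annotations(annotation_set(list(p1)), c(50, 50), 1)
  a2 <- rasterize_annotations(annotation_set(list(p2)), c(50, 50), 1)
  expect_equal(sum(both), sum(a1) + sum(a2))
})

test_that("self-intersecting polygons are rejected", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(annotation_set(list(bowtie)), "self-intersecting")
})

test_that("micron-unit annotations honour the calibration", {
  ann_um <- annotation_set(list(cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))),
                           units = "um")
  m <- rasterize_annotations(ann_um, c(60, 60), mpp = 1)  # 50 um = 50 px
  expect_equal(sum(m), 2500L)
  m2 <- rasterize_annotations(ann_um, c(120, 120), mpp = 0.5)  # 100 px
  expect_equal(sum(m2), 10000L)
})

test_that("ring area matches brute-force distance scan on a small blob", {
  set.seed(4)
  H <- 80; W <- 80
  mask <- matrix(FALSE, H, W)
  mask <- test_paint_disk(mask, 35, 30, 8)
  mask <- test_paint_disk(mask, 50, 55, 5)
  r_um <- 12; mpp <- 1
  ring <- periductal_ring(mask, r_um, mpp)
  # brute force: min distance from each pixel centre to any mask pixel centre
  mi <- which(mask, arr.ind = TRUE)
  brute <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j]) next
    d <- sqrt(min((mi[, 1] - i)^2 + (mi[, 2] - j)^2))
    brute[i, j] <- d <= r_um / mpp
  }
  expect_equal(sum(ring$mask & brute) / sum(ring$mask | brute), 1,
               tolerance = 0.01)
  expect_false(any(ring$mask & mask))
})

test_that("rings merge by union and never double count", {
  m1 <- test_paint_disk(matrix(FALSE, 120, 400), 60, 100, 20)
  m2 <- test_paint_disk(matrix(FALSE, 120, 400), 60, 200, 20)
  r <- 60
  ring1 <- sum(periductal_ring(m1, r, 1)$mask)
  ring2 <- sum(periductal_ring(m2, r, 1)$mask)
  both <- sum(periductal_ring(m1 | m2, r, 1)$mask)
  expect_lt(both, ring1 + ring2)
})

test_that("ring is monotone in radius and empty masks error", {
  set.seed(9)
  for (k in 1:3) {
    m <- matrix(runif(60 * 60) < 0.003, 60, 60)
    if (!any(m)) m[30, 30] <- TRUE
    small <- periductal_ring(m, 5, 1)$mask
    large <- periductal_ring(m, 15, 1)$mask
    expect_true(all(large[small]))
  }
  expect_error(periductal_ring(matrix(FALSE, 10, 10), 5, 1),
               "not evaluable")
})

test_that("patch grid conserves stroma pixels and partitions cleanly", {
  mask <- test_paint_disk(matrix(FALSE, 200, 200), 100, 100, 30)
  ring <- periductal_ring(mask, 40, 1)
  stroma <- matrix(TRUE, 200, 200) & !mask
  nuc <- data.frame(id = 1:3, row = c(100.5, 100.0, 5), col = c(139.5, 65.0, 5),
                    area_um2 = 40, circularity = 1, mean_hema_od = 0.6,
                    label = "lymphocyte")
  grid <- tile_patches(ring, stroma, nuc, patch_size_um = 50)
  expect_equal(sum(grid$patches$stroma_px), sum(ring$mask & stroma))
  # boxes pairwise disjoint (half-open): no two patches share an origin
  expect_false(any(duplicated(grid$patches[, c("r0", "c0")])))
  # each assigned lymphocyte lands in exactly one patch
  expect_false(any(duplicated(grid$assignments$nucleus_id)))
  # nucleus 3 lies far outside the ring and is not assigned at all
  expect_false(3L %in% grid$assignments$nucleus_id)
  # the centroid at row 100 sits on the boundary of two 50 px boxes:
  # the half-open rule puts it in the box starting at (100, 50)
  a <- grid$assignments[grid$assignments$nucleus_id == 2L, ]
  p <- grid$patches[grid$patches$patch_id == a$patch_id, ]
  expect_equal(c(p$r0, p$c0), c(100, 50))
})

test_that("degenerate patches and empty rings are handled", {
  mask <- test_paint_disk(matrix(FALSE, 40, 40), 20, 20, 6)
  ring <- periductal_ring(mask, 8, 1)
  expect_error(tile_patches(ring, matrix(TRUE, 40, 40), NULL,
                            patch_size_um = 1.5), "degenerate")
  none <- tile_patches(ring, matrix(FALSE, 40, 40), NULL, 20)
  expect_equal(nrow(none$patches), 0L)
})
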