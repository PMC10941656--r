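test_that("find_regions extracts 8-connected components with size filtering", {
  g <- matrix(0L, 20, 20)
  g[2:6, 2:6] <- 1L    # first in raster-scan order
  g[10:14, 10:14] <- 1L
  m <- mask_from_grid(g)
  regs <- find_regions(m, 1L, min_area_px = 10)
  expect_length(regs, 2L)
  expect_equal(vapply(regs, function(r) nrow(r$pixels), 0L), c(25L, 25L))
  expect_equal(vapply(regs, function(r) r$id, 0L), 1:2)
  expect_equal(regs[[1]]$bbox[["rmin"]], 2)

  # a 2-px speck below min_area is dropped
  g2 <- matrix(0L, 8, 8); g2[3, 3:4] <- 1L
  expect_length(find_regions(mask_from_grid(g2), 1L, min_area_px = 5), 0L)

  # diagonal-only contact joins under 8-connectivity
  g3 <- matrix(0L, 6, 6); g3[2, 2] <- 1L; g3[3, 3] <- 1L
  expect_length(find_regions(mask_from_grid(g3), 1L, 1), 1L)
})

test_that("component labelling matches a brute-force flood-fill oracle", {
  for (s in 1:50) {
    set.seed(7000 + s)
    bin <- matrix(runif(64 * 64) < 0.35, 64, 64)
    m <- mask_from_grid(matrix(as.integer(bin), 64, 64),
                        c(background = 0, body = 1))
    regs <- find_regions(m, 1L, min_area_px = 1)
    got <- lapply(regs, function(r) sort((r$pixels[, 2] - 1) * 64 + r$pixels[, 1]))
    want <- lapply(label_sets(flood_fill_labels(bin)), sort)
    # same partition into components regardless of labelling order
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("morphometrics of axis-aligned blocks are exact", {
  g <- matrix(0L, 14, 14); g[3:12, 3:12] <- 1L # 10 x 10 square
  sq <- find_regions(mask_from_grid(g), 1L)[[1]]
  m <- morphometrics(sq, scale = 1)
  expect_equal(m$area_um2, 100)
  expect_equal(m$centroid_x_px, mean(2:11))
  expect_equal(m$centroid_y_px, mean(2:11))
  expect_equal(m$aspect_ratio, 1.0)

  g2 <- matrix(0L, 30, 30); g2[4:23, 6:15] <- 1L # 20 rows x 10 cols
  rect <- find_regions(mask_from_grid(g2), 1L)[[1]]
  expect_equal(morphometrics(rect, 1)$aspect_ratio, 0.5)

  # scale propagates quadratically to area, linearly to perimeter
  m2 <- morphometrics(sq, scale = 0.5)
  expect_equal(m2$area_um2, 25)
  expect_equal(m2$perimeter_um, morphometrics(sq, 1)$perimeter_um * 0.5)
})

test_that("rasterised discs score near-circular metrics", {
  bin <- disc_mat(c(70, 70), c(35, 35), 30)
  m <- mask_from_grid(matrix(as.integer(bin), 70, 70),
                      c(background = 0, body = 1))
  reg <- find_regions(m, 1L)[[1]]
  mm <- morphometrics(reg, 1)
  expect_equal(mm$area_um2, pi * 30^2, tolerance = 0.02)
  expect_gt(mm$circularity, 0.9)
  expect_lt(mm$circularity, 1.1)
  expect_equal(mm$aspect_ratio, 1.0, tolerance = 0.05)
  # aspect ratio stays in (0, 1] and ~1 for discs of radius >= 15
  for (r in c(15, 20, 25)) {
    b <- disc_mat(c(60, 60), c(30, 30), r)
    reg <- find_regions(mask_from_grid(matrix(as.integer(b), 60, 60),
                                       c(background = 0, body = 1)), 1L)[[1]]
    ar <- morphometrics(reg, 1)$aspect_ratio
    expect_gt(ar, 0.95); expect_lte(ar, 1)
  }
})

test_that("single-pixel regions have zero perimeter and missing circularity", {
  g <- matrix(0L, 5, 5); g[3, 3] <- 1L
  reg <- find_regions(mask_from_grid(g), 1L)[[1]]
  m <- morphometrics(reg, 1)
  expect_equal(m$perimeter_um, 0)
  expect_true(is.na(m$circularity))
})

test_that("morphometrics are translation invariant except the centroid", {
  set.seed(42)
  g <- matrix(0L, 80, 80)
  bin <- disc_mat(c(80, 80), c(25, 25), 14)
  g[bin] <- 1L
  a <- morphometrics(find_regions(mask_from_grid(g), 1L)[[1]], 1)
  g2 <- matrix(0L, 80, 80)
  g2[disc_mat(c(80, 80), c(25 + 17, 25 + 9), 14)] <- 1L
  b <- morphometrics(find_regions(mask_from_grid(g2), 1L)[[1]], 1)
  expect_equal(b$area_um2, a$area_um2)
  expect_equal(b$perimeter_um, a$perimeter_um)
  expect_equal(b$aspect_ratio, a$aspect_ratio)
  expect_equal(b$circularity, a$circularity)
  expect_equal(b$centroid_x_px - a$centroid_x_px, 9)  # x shifts by delta-col
  expect_equal(b$centroid_y_px - a$centroid_y_px, 17) # y shifts by delta-row
})

test_that("zone partition bands a large disc and degenerates a small one", {
  cfg <- filo_config()
  bin <- disc_mat(c(100, 100), c(50, 50), 40)
  reg <- find_regions(mask_from_grid(matrix(as.integer(bin), 100, 100),
                                     c(background = 0, body = 1)), 1L)[[1]]
  z <- partition_zones(reg, cfg)
  expect_false(z$degenerate)
  expect_gt(nrow(z$interior), 0)
  annulus <- pi * (40^2 - 34^2)
  expect_equal(nrow(z$cortex), annulus, tolerance = 0.1)

  small <- disc_mat(c(30, 30), c(15, 15), 10)
  reg2 <- find_regions(mask_from_grid(matrix(as.integer(small), 30, 30),
                                      c(background = 0, body = 1)), 1L)[[1]]
  z2 <- partition_zones(reg2, cfg)
  expect_true(z2$degenerate)
  expect_equal(nrow(z2$separator), 0)
  expect_equal(nrow(z2$cortex) + nrow(z2$interior), nrow(reg2$pixels))
})

test_that("zone partition is exact on every cell of random scenes", {
  for (s in 1:10) {
    sc <- generate_tip_scene(small_params(), seed = 3000 + s)
    cells <- detect_cells(sc$mask, sc$image)
    for (o in attr(cells, "objects")) {
      z <- o$zones
      all_px <- rbind(z$cortex, z$separator, z$interior)
      key <- function(p) paste(p[, 1], p[, 2])
      expect_setequal(key(all_px), key(o$region$pixels))
      expect_equal(nrow(all_px), nrow(o$region$pixels)) # pairwise disjoint
    }
  }
})

test_that("leading edge selects the hotspot neighbourhood with stable ties", {
  cfg <- filo_config()
  bin <- disc_mat(c(90, 90), c(45, 45), 35)
  reg <- find_regions(mask_from_grid(matrix(as.integer(bin), 90, 90),
                                     c(background = 0, body = 1)), 1L)[[1]]
  z <- partition_zones(reg, cfg)
  # uniform cortex: patch of exactly 50 px containing the first cortex pixel
  img_u <- uniform_image(c(90, 90), 10)
  le <- leading_edge(z, img_u, cfg)
  expect_equal(nrow(le), 50)
  nc <- 90
  scan <- (z$cortex[, 1] - 1) * nc + z$cortex[, 2]
  first <- z$cortex[which.min(scan), ]
  expect_true(any(le[, 1] == first[1] & le[, 2] == first[2]))

  # single hotspot: returned set contains it
  g <- matrix(10, 90, 90)
  hot <- z$cortex[nrow(z$cortex) %/% 2L, ]
  g[hot[1], hot[2]] <- 999
  le2 <- leading_edge(z, intensity_image(g), cfg)
  expect_equal(nrow(le2), 50)
  expect_true(any(le2[, 1] == hot[1] & le2[, 2] == hot[2]))

  # cortex smaller than the patch: whole cortex returned
  tiny <- disc_mat(c(16, 16), c(8, 8), 3)
  regt <- find_regions(mask_from_grid(matrix(as.integer(tiny), 16, 16),
                                      c(background = 0, body = 1)), 1L,
                       min_area_px = 1)[[1]]
  zt <- partition_zones(regt, cfg)
  expect_lt(nrow(zt$cortex), 50)
  expect_equal(nrow(leading_edge(zt, uniform_image(c(16, 16)), cfg)),
               nrow(zt$cortex))
})

test_that("shaving removes thin protrusions but keeps the body", {
  dims <- c(120, 120)
  disc <- disc_mat(dims, c(60, 60), 40)
  withp <- disc
  for (a in c(0, pi / 2, pi, 3 * pi / 2)) {
    for (t in seq(0, 30, by = 0.5)) {
      p <- round(c(60 + (40 + t) * sin(a), 60 + (40 + t) * cos(a)))
      for (dr in -1:1) {
        q <- p + c(dr * abs(cos(a)), dr * abs(sin(a)))
        if (all(q >= 1 & q <= 120)) withp[q[1], q[2]] <- TRUE
      }
    }
  }
  shaved <- shave_protrusions(withp, 5)
  expect_true(all(!shaved | withp)) # anti-extensive
  expect_equal(sum(shaved), sum(disc), tolerance = 0.05)

  # opening a convex disc only grazes the boundary rim
  shaved_disc <- shave_protrusions(disc, 5)
  expect_true(all(!shaved_disc | disc))
  removed <- which(disc & !shaved_disc, arr.ind = TRUE)
  if (nrow(removed)) {
    d_from_center <- sqrt((removed[, 1] - 60)^2 + (removed[, 2] - 60)^2)
    expect_true(all(d_from_center > 40 - 2.5))
  }
  # empty in, empty out; zero rounds is the identity
  expect_equal(sum(shave_protrusions(matrix(0, 10, 10), 5)), 0)
  expect_identical(shave_protrusions(disc, 0), disc)
})
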