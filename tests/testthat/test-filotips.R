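test_that("detect_cells measures bodies and recovers the generator's cortex ratio", {
  g <- matrix(0L, 60, 200)
  g[10:30, 10:40] <- 1L
  g[10:30, 70:100] <- 1L
  g[10:30, 130:160] <- 1L
  m <- mask_from_grid(g)
  cells <- detect_cells(m, uniform_image(c(60, 200)))
  expect_equal(cells$cell_id, 1:3)

  # noiseless synthetic cell: cortex band at 120, interior at 100 -> 1.2
  sc <- generate_tip_scene(scene_params(n_cells = 1, cell_radius = c(24, 28),
                                        cortex_factor = 1.2),
                           seed = 5)
  cells2 <- detect_cells(sc$mask, sc$image)
  expect_equal(cells2$cortex_body_ratio, 1.2, tolerance = 1e-9)
  expect_equal(cells2$body_mean, 100)
  expect_false(cells2$degenerate)

  # degenerate small cell: separator dropped, ratios still computed
  small <- disc_mat(c(40, 40), c(20, 20), 10)
  gm <- matrix(0L, 40, 40); gm[small] <- 1L
  cells3 <- detect_cells(mask_from_grid(gm), uniform_image(c(40, 40)))
  expect_true(cells3$degenerate)
  expect_equal(nrow(attr(cells3, "objects")[[1]]$zones$separator), 0)
  expect_equal(cells3$cortex_body_ratio, 1)
})

test_that("detect_tips finds puncta with size filtering and raw intensities", {
  set.seed(31)
  g <- matrix(0L, 64, 64)
  centers <- cbind(row = rep(c(8, 24, 40, 56), 3),
                   col = rep(c(10, 30, 50), each = 4))
  for (i in seq_len(12)) {
    g[centers[i, 1] + (-1:1), centers[i, 2] + (-1:1)] <- 2L
  }
  img <- matrix(10, 64, 64); img[g == 2L] <- 500
  tips <- detect_tips(mask_from_grid(g), intensity_image(img))
  expect_equal(nrow(tips), 12)
  expect_equal(tips$mean_intensity, rep(500, 12))
  expect_equal(tips$sum_intensity, rep(500 * 9, 12))

  # a 1-px speck falls below min_tip_area_px = 2
  g[2, 2] <- 2L
  tips2 <- detect_tips(mask_from_grid(g), intensity_image(img))
  expect_equal(nrow(tips2), 12)
})

test_that("tip assignment follows the 10-um artifact rule and the tie rule", {
  cfg <- filo_config()
  # a 30x30 body whose nearest boundary corner to the tip is (35,35)
  g <- matrix(0L, 60, 60); g[6:35, 6:35] <- 1L
  cells <- detect_cells(mask_from_grid(g), uniform_image(c(60, 60)),
                        filo_config(min_body_area_px = 10))
  tip345 <- tibble::tibble(tip_id = 1L, centroid_row = 38, centroid_col = 39,
                           area_px = 1L, mean_intensity = 200,
                           sum_intensity = 200)
  rec <- assign_tips(tip345, cells, cfg)
  expect_equal(rec$distance_px, 5) # 3-4-5 triangle to the corner
  expect_equal(rec$length_um, 0.5495)
  expect_equal(rec$status, "assigned")
  expect_equal(rec$tip_body_ratio, 2)

  # nearest boundary 95 px away: 10.4405 um > 10 um -> artifact
  far <- tibble::tibble(tip_id = 1L, centroid_row = 10, centroid_col = 105,
                        area_px = 1L, mean_intensity = 200,
                        sum_intensity = 200)
  g2 <- matrix(0L, 120, 120); g2[1:10, 1:10] <- 1L
  cells2 <- detect_cells(mask_from_grid(g2), uniform_image(c(120, 120)),
                         filo_config(min_body_area_px = 10))
  rec2 <- assign_tips(far, cells2, cfg)
  expect_equal(rec2$status, "artifact")
  expect_true(is.na(rec2$cell_id))
  expect_match(rec2$reason, "10.44")

  # equidistant tip goes to the lower cell id, flagged as a tie
  g3 <- matrix(0L, 40, 60)
  g3[16:24, 6:14] <- 1L   # cell 1, right edge col 14
  g3[16:24, 28:36] <- 1L  # cell 2, left edge col 28
  cells3 <- detect_cells(mask_from_grid(g3), uniform_image(c(40, 60)),
                         filo_config(min_body_area_px = 10))
  mid <- tibble::tibble(tip_id = 1L, centroid_row = 20, centroid_col = 21,
                        area_px = 1L, mean_intensity = 200,
                        sum_intensity = 200)
  rec3 <- assign_tips(mid, cells3, cfg)
  expect_equal(rec3$cell_id, 1L)
  expect_true(rec3$tie)

  # no cells at all: artifact with reason "no cell"
  no_cells <- detect_cells(label_mask(matrix(0L, 8, 8)),
                           uniform_image(c(8, 8)))
  rec4 <- assign_tips(mid, no_cells, cfg)
  expect_equal(rec4$status, "artifact")
  expect_equal(rec4$reason, "no cell")
})

test_that("the tip pipeline conserves tips and fills per-cell densities", {
  sc <- generate_tip_scene(small_params(), seed = 77)
  res <- run_filotips(sc$mask, sc$image)
  expect_equal(nrow(res$filopodia),
               sum(res$filopodia$status == "assigned") + nrow(res$artifacts))
  expect_equal(res$cells$filopodia_per_10um,
               res$cells$filopodia_count / res$cells$perimeter_um * 10)
  # every assigned record references an existing cell
  expect_true(all(stats::na.omit(res$filopodia$cell_id) %in% res$cells$cell_id))
  # counts match the number of records per cell
  for (i in seq_len(nrow(res$cells))) {
    expect_equal(res$cells$filopodia_count[i],
                 sum(res$filopodia$cell_id %in% res$cells$cell_id[i]))
  }
})

test_that("a tip beyond 10 um of every cell is reported as an artifact", {
  sc <- generate_tip_scene(scene_params(n_cells = 1), seed = 13)
  g <- sc$mask$grid
  # paint an extra punctum ~12 um (109 px) away from the cell centre
  ctr <- c(sc$truth$cells$center_y_px[1] + 1, sc$truth$cells$center_x_px[1] + 1)
  far <- round(ctr + c(0, sc$truth$cells$radius_px[1] + 110))
  g[far[1] + (-1:1), far[2] + (-1:1)] <- 2L
  img <- sc$image$grid; img[far[1] + (-1:1), far[2] + (-1:1)] <- 300
  res <- run_filotips(label_mask(g), intensity_image(img))
  expect_equal(nrow(res$artifacts), 1L)
  expect_equal(sum(res$cells$filopodia_count), nrow(sc$truth$filopodia))
})

test_that("assignment matches the exhaustive boundary-scan oracle", {
  for (s in 1:6) {
    sc <- generate_tip_scene(small_params(), seed = 500 + s)
    cells <- detect_cells(sc$mask, sc$image)
    tips <- detect_tips(sc$mask, sc$image)
    rec <- assign_tips(tips, cells, filo_config())
    objs <- attr(cells, "objects")
    for (i in seq_len(nrow(tips))) {
      oracle <- assignment_oracle(c(tips$centroid_row[i], tips$centroid_col[i]),
                                  objs)
      expect_equal(rec$distance_px[i], oracle$distance, tolerance = 1e-12)
      expect_equal(rec$cell_id[i], cells$cell_id[oracle$owner])
    }
  }
})

test_that("noiseless scenes recover counts exactly and lengths within the tip radius", {
  params <- small_params()
  all_meas <- c(); all_true <- c()
  for (s in 1:10) {
    sc <- generate_tip_scene(params, seed = s)
    res <- run_filotips(sc$mask, sc$image)
    truth <- sc$truth$cells
    j <- match(truth$cell_id, res$cells$cell_id)
    expect_equal(res$cells$filopodia_count[j], truth$filopodia_count)
    all_meas <- c(all_meas, res$cells$filopodia_count[j])
    all_true <- c(all_true, truth$filopodia_count)
    # straight protrusions: |measured - true| <= (tip_radius + 1.5 px) * scale
    f <- res$filopodia; tr <- sc$truth$filopodia
    m <- vapply(seq_len(nrow(f)), function(i) {
      which.min((tr$tip_x_px - f$tip_x_px[i])^2 + (tr$tip_y_px - f$tip_y_px[i])^2)
    }, 0L)
    tol <- (params$tip_radius + 1.5) * params$pixel_size_um
    expect_true(all(abs(f$length_um - tr$true_length_um[m]) <= tol))
  }
  if (sd(all_true) > 0) {
    expect_equal(pearson_validate(all_meas, all_true)$r, 1.0)
  }
})

test_that("intensity ratios are exact without noise and robust to 5% noise", {
  base <- small_params()
  sc <- generate_tip_scene(base, seed = 99)
  res <- run_filotips(sc$mask, sc$image)
  expect_equal(res$cells$cortex_body_ratio, rep(1.2, nrow(res$cells)),
               tolerance = 1e-9)
  assigned <- res$filopodia$status == "assigned"
  expect_equal(res$filopodia$tip_body_ratio[assigned],
               rep(3, sum(assigned)), tolerance = 1e-9)

  noisy <- small_params(noise_sd = 5) # 5% of the body level of 100
  scn <- generate_tip_scene(noisy, seed = 99)
  resn <- run_filotips(scn$mask, scn$image)
  expect_equal(resn$cells$cortex_body_ratio, rep(1.2, nrow(resn$cells)),
               tolerance = 0.02)
  expect_equal(resn$filopodia$tip_body_ratio[resn$filopodia$status == "assigned"],
               rep(3, sum(resn$filopodia$status == "assigned")),
               tolerance = 0.02)
})

test_that("total signal includes assigned tip pixels on top of the body", {
  sc <- generate_tip_scene(scene_params(n_cells = 1), seed = 3)
  res <- run_filotips(sc$mask, sc$image)
  body_px <- attr(detect_cells(sc$mask, sc$image), "objects")[[1]]$region$pixels
  body_sum <- sum(sc$image$grid[body_px])
  tip_sum <- sum(res$filopodia$tip_sum[res$filopodia$status == "assigned"])
  expect_equal(res$cells$total_signal, body_sum + tip_sum)
})

test_that("tidy, glance and autoplot expose the result", {
  sc <- generate_tip_scene(small_params(), seed = 8)
  res <- run_filotips(sc$mask, sc$image)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(res$filopodia))
  gl <- glance(res)
  expect_equal(gl$n_cells, nrow(res$cells))
  expect_equal(gl$n_filopodia, sum(res$filopodia$status == "assigned"))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
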