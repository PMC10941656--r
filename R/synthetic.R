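# Deterministic synthetic filopodia scenes with exact ground truth.
#
# Scenes emulate low-density plated cells imaged with a tip marker (and, in
# skeleton mode, an actin label): near-circular bodies, radial protrusions
# carrying a bright tip punctum, a cortex band enriched by a fixed factor
# over the cytosolic body level, and optional additive Gaussian noise.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene parameters
#'
#' Defaults describe the reference conditions used throughout the test
#' suite: a 480 px square field at 0.1099 um/px holding a few well-separated
#' amoeboid-like cells (radius 18-28 px) with 3-8 radial protrusions each of
#' 12-32 px, 3 px wide stalks, 2 px tip puncta, a cytosolic body level of
#' 100, a 1.2-fold cortex enrichment and a tip level of 300 on a background
#' of 5 (arbitrary fluorescence units), noiseless unless `noise_sd > 0`.
#' Cells are placed so that body boundaries are at least two maximum
#' protrusion lengths apart, which guarantees every tip is nearer its own
#' cell than any other (the synthetic analogue of low-density plating).
#'
#' @param image_size Field side length, px.
#' @param n_cells Number of cells.
#' @param cell_radius Length-2 range of body radii, px.
#' @param protrusions_per_cell Length-2 integer range of filopodia per cell.
#' @param protrusion_length Length-2 range of protrusion lengths
#'   (boundary-to-tip-centre), px.
#' @param protrusion_width Stalk width, px (skeleton mode).
#' @param tip_radius Tip punctum radius, px.
#' @param background_level,body_level,tip_level Intensity levels (a.u.).
#' @param cortex_factor Cortex level = `body_level * cortex_factor`.
#' @param cortex_band_px Depth of the painted cortex band, px.
#' @param noise_sd Additive Gaussian noise sd (truncated at 0); 0 disables.
#' @param pixel_size_um Pixel size, um.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_size = 480,
                         n_cells = 3,
                         cell_radius = c(18, 28),
                         protrusions_per_cell = c(3, 8),
                         protrusion_length = c(12, 32),
                         protrusion_width = 3,
                         tip_radius = 2,
                         background_level = 5,
                         body_level = 100,
                         cortex_factor = 1.2,
                         tip_level = 300,
                         cortex_band_px = 6,
                         noise_sd = 0,
                         pixel_size_um = 0.1099) {
  p <- list(image_size = image_size, n_cells = n_cells,
            cell_radius = cell_radius,
            protrusions_per_cell = protrusions_per_cell,
            protrusion_length = protrusion_length,
            protrusion_width = protrusion_width, tip_radius = tip_radius,
            background_level = background_level, body_level = body_level,
            cortex_factor = cortex_factor, tip_level = tip_level,
            cortex_band_px = cortex_band_px, noise_sd = noise_sd,
            pixel_size_um = pixel_size_um)
  stopifnot(p$image_size >= 64, p$n_cells >= 0,
            all(p$cell_radius > 0), all(p$protrusion_length > 0),
            p$tip_radius >= 1, p$noise_sd >= 0,
            p$background_level >= 0, p$body_level >= 0, p$tip_level >= 0)
  structure(p, class = "scene_params")
}

# sample one integer uniformly from [a, b] without R's length-1 sample() trap
sample_int_range <- function(a, b) {
  if (a >= b) return(as.integer(a))
  a + sample.int(b - a + 1L, 1L) - 1L
}

disc_pixels <- function(center, radius, dims) {
  r0 <- max(1L, floor(center[1L] - radius)); r1 <- min(dims[1L], ceiling(center[1L] + radius))
  c0 <- max(1L, floor(center[2L] - radius)); c1 <- min(dims[2L], ceiling(center[2L] + radius))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - center[1L])^2 + (g$col - center[2L])^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# place n cell centres with pairwise boundary gaps >= 2 * max protrusion
# length (+ margin) and full protrusion clearance from the field border
place_cells <- function(params) {
  n <- params$n_cells
  if (n == 0L) return(list(centers = matrix(0, 0, 2), radii = numeric()))
  lmax <- max(params$protrusion_length)
  radii <- runif(n, params$cell_radius[1L], params$cell_radius[2L])
  margin <- radii + lmax + params$tip_radius + 3
  if (any(2 * margin + 2 >= params$image_size)) {
    stop("cannot place cells: protrusion clearance exceeds the ",
         params$image_size, " px field", call. = FALSE)
  }
  centers <- matrix(0, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(4000L)) {
      p <- runif(2, margin[i] + 1, params$image_size - margin[i])
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                2, p)^2))
        need <- radii[seq_len(i - 1L)] + radii[i] + 2 * lmax + 4
        ok <- all(d >= need)
      }
      if (ok) { centers[i, ] <- p; placed <- TRUE; break }
    }
    if (!placed) {
      stop("cannot place ", n, " cells with the required separation in a ",
           params$image_size, " px field; reduce n_cells or sizes",
           call. = FALSE)
    }
  }
  list(centers = centers, radii = radii)
}

protrusion_angles <- function(k) {
  base <- runif(1, 0, 2 * pi)
  jit <- runif(k, -0.22, 0.22) * 2 * pi / max(k, 1)
  (base + (seq_len(k) - 1) * 2 * pi / k + jit) %% (2 * pi)
}

# cortex band of the painted body class: pixels within band_px of the
# background (same depth definition the measurement engine uses)
paint_cortex <- function(body, band_px) {
  d <- EBImage::imageData(EBImage::distmap(body * 1))
  body & d <= band_px
}

# map generated cells to the ids the engine will assign (raster-scan order
# of each painted component's first pixel)
truth_cell_ids <- function(body, centers) {
  lab <- label_components8(body)
  vapply(seq_len(nrow(centers)), function(i) {
    lab[round(centers[i, 1L]), round(centers[i, 2L])]
  }, 0L)
}

#' Generate a tip-marker scene
#'
#' Draws `n_cells` disc bodies with radially placed tip puncta at protrusion
#' distance beyond the boundary (no stalks: tip-marker imaging shows puncta
#' only), paints the intensity image (background / body / cortex-band / tip
#' levels, plus optional truncated-Gaussian noise) and returns the exact
#' ground truth. Output is byte-identical for identical `(params, seed)`.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed controlling all randomness of the scene.
#' @return A `filo_scene` list: `mask` (`filo_mask`, classes 0/1/2),
#'   `image` (`filo_image`), `truth` (list of tibbles `cells`, `filopodia`),
#'   `params`, `seed`.
#' @examples
#' sc <- generate_tip_scene(scene_params(n_cells = 2), seed = 7)
#' nrow(sc$truth$filopodia)
#' @export
generate_tip_scene <- function(params = scene_params(), seed = 1) {
  with_seed(seed, {
    dims <- c(params$image_size, params$image_size)
    pl <- place_cells(params)
    n <- params$n_cells
    body <- matrix(FALSE, dims[1L], dims[2L])
    for (i in seq_len(n)) {
      body[disc_pixels(pl$centers[i, ], pl$radii[i], dims)] <- TRUE
    }
    grid <- matrix(0L, dims[1L], dims[2L])
    grid[body] <- 1L
    filo <- list()
    for (i in seq_len(n)) {
      k <- sample_int_range(params$protrusions_per_cell[1L], params$protrusions_per_cell[2L])
      ang <- protrusion_angles(k)
      len <- runif(k, params$protrusion_length[1L], params$protrusion_length[2L])
      for (j in seq_len(k)) {
        u <- c(cos(ang[j]), sin(ang[j]))
        tip_c <- pl$centers[i, ] + (pl$radii[i] + len[j]) * u
        tp <- disc_pixels(tip_c, params$tip_radius, dims)
        tp <- tp[grid[tp] == 0L, , drop = FALSE]
        grid[tp] <- 2L
        filo[[length(filo) + 1L]] <- tibble::tibble(
          gen_cell = i, tip_x_px = tip_c[2L] - 1, tip_y_px = tip_c[1L] - 1,
          true_length_px = len[j],
          true_length_um = len[j] * params$pixel_size_um,
          true_tip_mean = params$tip_level,
          tip_body_ratio = params$tip_level / params$body_level,
          crossing = FALSE
        )
      }
    }
    img <- matrix(params$background_level, dims[1L], dims[2L])
    img[body] <- params$body_level
    if (any(body)) {
      cortex <- paint_cortex(body, params$cortex_band_px)
      img[cortex] <- params$body_level * params$cortex_factor
    }
    img[grid == 2L] <- params$tip_level
    if (params$noise_sd > 0) {
      img <- pmax(img + matrix(rnorm(length(img), 0, params$noise_sd),
                               dims[1L], dims[2L]), 0)
    }
    ids <- truth_cell_ids(body, pl$centers)
    filo_tbl <- if (length(filo)) dplyr::bind_rows(filo) else
      tibble::tibble(gen_cell = integer(), tip_x_px = double(),
                     tip_y_px = double(), true_length_px = double(),
                     true_length_um = double(), true_tip_mean = double(),
                     tip_body_ratio = double(), crossing = logical())
    filo_tbl$cell_id <- if (nrow(filo_tbl)) ids[filo_tbl$gen_cell] else integer()
    counts <- table(factor(filo_tbl$cell_id, levels = ids))
    cells_tbl <- tibble::tibble(
      cell_id = ids,
      center_x_px = pl$centers[, 2L] - 1, center_y_px = pl$centers[, 1L] - 1,
      radius_px = pl$radii,
      area_px = vapply(seq_len(max(n, 0L)), function(i)
        nrow(disc_pixels(pl$centers[i, ], pl$radii[i], dims)), 0L),
      cortex_body_ratio = params$cortex_factor,
      filopodia_count = as.integer(counts)
    )
    cells_tbl <- dplyr::arrange(cells_tbl, .data$cell_id)
    structure(list(
      mask = label_mask(grid, c(background = 0, body = 1, tip = 2)),
      image = intensity_image(img),
      truth = list(cells = cells_tbl,
                   filopodia = dplyr::arrange(filo_tbl, .data$cell_id)),
      params = params, seed = seed
    ), class = "filo_scene")
  })
}

rot2 <- function(v, a) c(cos(a) * v[1L] - sin(a) * v[2L],
                         sin(a) * v[1L] + cos(a) * v[2L])

# dense centreline of one protrusion path; returns the point list and its
# arc length. shape: straight, L (two arms), arc (constant-curvature bend)
stalk_path <- function(center, radius, angle, length, shape) {
  u <- c(cos(angle), sin(angle))
  step <- 0.5
  if (shape == "straight") {
    t <- seq(0, length, by = step)
    pts <- sweep(outer(radius + t, u), 2, center, "+")
    return(list(pts = pts, length = length))
  }
  if (shape == "L") {
    a <- 0.55 * length; b <- 0.45 * length
    w <- rot2(u, sample(c(-1, 1), 1L) * pi / 3) # 60 degree elbow
    t1 <- seq(0, a, by = step)
    t2 <- seq(step, b, by = step)
    elbow <- center + (radius + a) * u
    pts <- rbind(sweep(outer(radius + t1, u), 2, center, "+"),
                 sweep(outer(t2, w), 2, elbow, "+"))
    return(list(pts = pts, length = a + b))
  }
  # arc: heading turns at a constant rate, total turn 40-60 degrees
  turn <- sample(c(-1, 1), 1L) * runif(1, 40, 60) * pi / 180
  kappa <- turn / length
  nsteps <- ceiling(length / step)
  pts <- matrix(0, nsteps + 1L, 2L)
  pos <- center + radius * u
  h <- u
  pts[1L, ] <- pos
  for (s in seq_len(nsteps)) {
    pos <- pos + h * step
    h <- rot2(h, kappa * step)
    pts[s + 1L, ] <- pos
  }
  list(pts = pts, length = length)
}

stamp_path <- function(grid_dims, pts, width) {
  rad <- width / 2
  out <- matrix(FALSE, grid_dims[1L], grid_dims[2L])
  for (i in seq_len(nrow(pts))) {
    px <- disc_pixels(pts[i, ], rad, grid_dims)
    out[px] <- TRUE
  }
  out
}

#' Generate an actin + tip-marker scene
#'
#' Draws disc bodies and stalk protrusions (straight, L-shaped or arc,
#' stamped at `protrusion_width`) into the actin mask (body 1, stalk 2), tip
#' puncta at the distal stalk ends into a binary tip mask, and the two
#' intensity images (actin: body + stalks at `body_level`; tip marker:
#' cytosolic body pool at `body_level`, puncta at `tip_level`). Optional
#' extras: one disembodied stalk+tip fragment placed at least 8 px from any
#' body, and one crossing stalk pair (flagged in the truth, since traced
#' lengths are unreliable for crossing shafts). Scenes where stamped stalks
#' or puncta would accidentally merge are re-drawn deterministically from a
#' derived sub-seed.
#'
#' @inheritParams generate_tip_scene
#' @param shapes Character vector of allowed stalk shapes.
#' @param disembodied Add one detached stalk fragment.
#' @param crossing Add one crossing stalk pair.
#' @return A `filo_scene` list: `actin_mask`, `tip_mask`, `actin_image`,
#'   `tip_image`, `truth`, `params`, `seed`.
#' @export
generate_skeleton_scene <- function(params = scene_params(), seed = 1,
                                    shapes = c("straight", "L", "arc"),
                                    disembodied = FALSE, crossing = FALSE) {
  for (attempt in 0:19) {
    sc <- with_seed(seed * 1000L + attempt, {
      draw_skeleton_scene(params, shapes, disembodied, crossing)
    })
    if (!is.null(sc)) {
      sc$params <- params; sc$seed <- seed
      return(structure(sc, class = "filo_scene"))
    }
  }
  stop("could not draw a non-merging skeleton scene for this seed; ",
       "reduce protrusions_per_cell or lengths", call. = FALSE)
}

draw_skeleton_scene <- function(params, shapes, disembodied, crossing) {
  dims <- c(params$image_size, params$image_size)
  pl <- place_cells(params)
  n <- params$n_cells
  body <- matrix(FALSE, dims[1L], dims[2L])
  for (i in seq_len(n)) {
    body[disc_pixels(pl$centers[i, ], pl$radii[i], dims)] <- TRUE
  }
  stalk <- matrix(FALSE, dims[1L], dims[2L])
  tipm <- matrix(FALSE, dims[1L], dims[2L])
  filo <- list()
  n_stalks_drawn <- 0L
  expected_merged <- 0L
  for (i in seq_len(n)) {
    k <- sample_int_range(params$protrusions_per_cell[1L], params$protrusions_per_cell[2L])
    ang <- protrusion_angles(k)
    len <- runif(k, params$protrusion_length[1L], params$protrusion_length[2L])
    shp <- sample(shapes, k, replace = TRUE)
    cross_here <- crossing && i == 1L && k >= 2L
    if (cross_here) shp[1:2] <- "straight"
    for (j in seq_len(k)) {
      if (cross_here && j == 2L) {
        # second stalk of the crossing pair: starts next to stalk 1 and aims
        # through a point on stalk 1's path so the two shafts intersect
        base <- pl$centers[i, ] + pl$radii[i] *
          c(cos(ang[1L] + 0.45), sin(ang[1L] + 0.45))
        target <- pl$centers[i, ] + (pl$radii[i] + 0.6 * len[1L]) *
          c(cos(ang[1L]), sin(ang[1L]))
        w <- target - base; w <- w / sqrt(sum(w^2))
        t <- seq(0, len[2L], by = 0.5)
        pts <- sweep(outer(t, w), 2, base, "+")
        path <- list(pts = pts, length = len[2L])
      } else {
        path <- stalk_path(pl$centers[i, ], pl$radii[i], ang[j], len[j], shp[j])
      }
      sm <- stamp_path(dims, path$pts, params$protrusion_width) & !body
      stalk <- stalk | sm
      n_stalks_drawn <- n_stalks_drawn + 1L
      tip_c <- path$pts[nrow(path$pts), ]
      tp <- disc_pixels(tip_c, params$tip_radius, dims)
      tipm[tp] <- TRUE
      filo[[length(filo) + 1L]] <- tibble::tibble(
        gen_cell = i, tip_x_px = tip_c[2L] - 1, tip_y_px = tip_c[1L] - 1,
        true_shaft_length_px = path$length,
        true_shaft_length_um = path$length * params$pixel_size_um,
        true_tip_mean = params$tip_level,
        tip_body_ratio = params$tip_level / params$body_level,
        crossing = cross_here && j <= 2L, disembodied = FALSE
      )
    }
    if (cross_here) expected_merged <- 1L
  }
  if (disembodied) {
    lmax <- max(params$protrusion_length)
    frag_len <- 15
    placed <- FALSE
    for (try in seq_len(2000L)) {
      p <- runif(2, 12, params$image_size - 12)
      clear <- if (n > 0L) {
        d <- sqrt(rowSums(sweep(pl$centers, 2, p)^2))
        all(d >= pl$radii + lmax + frag_len + 10)
      } else TRUE
      if (clear) { placed <- TRUE; break }
    }
    if (!placed) return(NULL)
    a <- runif(1, 0, 2 * pi)
    u <- c(cos(a), sin(a))
    t <- seq(0, frag_len, by = 0.5)
    pts <- sweep(outer(t, u), 2, p, "+")
    stalk <- stalk | (stamp_path(dims, pts, params$protrusion_width) & !body)
    n_stalks_drawn <- n_stalks_drawn + 1L
    tip_c <- pts[nrow(pts), ]
    tipm[disc_pixels(tip_c, params$tip_radius, dims)] <- TRUE
    filo[[length(filo) + 1L]] <- tibble::tibble(
      gen_cell = NA_integer_, tip_x_px = tip_c[2L] - 1,
      tip_y_px = tip_c[1L] - 1, true_shaft_length_px = frag_len,
      true_shaft_length_um = frag_len * params$pixel_size_um,
      true_tip_mean = params$tip_level,
      tip_body_ratio = params$tip_level / params$body_level,
      crossing = FALSE, disembodied = TRUE
    )
  }
  # reject accidental merges: stalk components and tip components must match
  # the construction (crossing merges exactly one pair)
  n_filo <- length(filo)
  if (max(label_components8(tipm)) != n_filo) return(NULL)
  if (max(label_components8(stalk)) != n_stalks_drawn - expected_merged)
    return(NULL)

  actin <- matrix(0L, dims[1L], dims[2L])
  actin[body] <- 1L
  actin[stalk] <- 2L
  tgrid <- matrix(0L, dims[1L], dims[2L])
  tgrid[tipm] <- 1L
  actin_img <- matrix(params$background_level, dims[1L], dims[2L])
  actin_img[body | stalk] <- params$body_level
  tip_img <- matrix(params$background_level, dims[1L], dims[2L])
  tip_img[body] <- params$body_level
  tip_img[tipm] <- params$tip_level
  if (params$noise_sd > 0) {
    actin_img <- pmax(actin_img + matrix(rnorm(length(actin_img), 0,
                                               params$noise_sd),
                                         dims[1L], dims[2L]), 0)
    tip_img <- pmax(tip_img + matrix(rnorm(length(tip_img), 0,
                                           params$noise_sd),
                                     dims[1L], dims[2L]), 0)
  }
  ids <- truth_cell_ids(body, pl$centers)
  filo_tbl <- dplyr::bind_rows(filo)
  filo_tbl$cell_id <- ifelse(is.na(filo_tbl$gen_cell), NA_integer_,
                             ids[filo_tbl$gen_cell])
  counts <- table(factor(filo_tbl$cell_id[!filo_tbl$disembodied], levels = ids))
  cells_tbl <- tibble::tibble(
    cell_id = ids,
    center_x_px = pl$centers[, 2L] - 1, center_y_px = pl$centers[, 1L] - 1,
    radius_px = pl$radii,
    cortex_body_ratio = NA_real_,
    filopodia_count = as.integer(counts)
  )
  list(
    actin_mask = label_mask(actin, c(background = 0, body = 1, stalk = 2)),
    tip_mask = label_mask(tgrid, c(background = 0, tip = 1)),
    actin_image = intensity_image(actin_img),
    tip_image = intensity_image(tip_img),
    truth = list(cells = dplyr::arrange(cells_tbl, .data$cell_id),
                 filopodia = filo_tbl)
  )
}

#' Degrade a mask by random pixel dropout
#'
#' Each non-background pixel is independently reset to background with
#' probability `flip_rate`, producing an imperfect "prediction" for
#' exercising the evaluation metrics. Deterministic per seed.
#'
#' @param mask A `filo_mask`.
#' @param flip_rate Dropout probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `filo_mask`.
#' @export
perturb_mask <- function(mask, flip_rate, seed = 1) {
  stopifnot(flip_rate >= 0, flip_rate <= 1)
  with_seed(seed, {
    g <- mask$grid
    fg <- which(g != 0L)
    drop <- fg[runif(length(fg)) < flip_rate]
    g[drop] <- 0L
    label_mask(g, mask$classes)
  })
}

#' @export
print.filo_scene <- function(x, ...) {
  mode <- if (!is.null(x$actin_mask)) "skeleton" else "tips"
  cat("<filo_scene> ", mode, " mode: ", nrow(x$truth$cells), " cell(s), ",
      nrow(x$truth$filopodia), " filopodia, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
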