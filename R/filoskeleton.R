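# Actin + tip-marker engine: stalk detection, tip-to-stalk matching, shaft
# tracing to the cortex, disembodied-fragment exclusion.

#' Detect filopodia stalks in an actin-channel mask
#'
#' One object per 8-connected stalk-class component, with no minimum size
#' (stalks can be a single pixel wide). 8-connectivity keeps thin diagonal
#' stalks in one piece.
#'
#' @param actin_mask A `filo_mask` with classes background 0, body 1, stalk 2.
#' @param config A [filo_config()].
#' @return A list of `filo_region` objects.
#' @export
detect_stalks <- function(actin_mask, config = filo_config()) {
  code <- if ("stalk" %in% names(actin_mask$classes))
    actin_mask$classes[["stalk"]] else 2L
  find_regions(actin_mask, code, min_area_px = 1)
}

#' Match a tip focus to the nearest stalk
#'
#' A tip counts as a filopodium only if some stalk pixel lies within
#' `tip_stalk_max_dist_px` of a tip pixel (overlap means distance 0). The
#' nearest stalk wins; ties go to the lowest stalk id.
#'
#' @param tip_pixels n x 2 matrix of tip (row, col) pixels.
#' @param stalks List of `filo_region` stalk objects.
#' @param config A [filo_config()].
#' @return A list `list(stalk_id, distance_px)` or `NULL` when no stalk is in
#'   range.
#' @export
match_tip_to_stalk <- function(tip_pixels, stalks, config = filo_config()) {
  if (!length(stalks) || nrow(tip_pixels) == 0L) return(NULL)
  thr <- config$tip_stalk_max_dist_px
  best <- Inf; best_id <- NA_integer_
  for (s in stalks) {
    # bounding-box prefilter before the exact pairwise scan
    gap_r <- max(0, s$bbox["rmin"] - max(tip_pixels[, 1L]),
                 min(tip_pixels[, 1L]) - s$bbox["rmax"])
    gap_c <- max(0, s$bbox["cmin"] - max(tip_pixels[, 2L]),
                 min(tip_pixels[, 2L]) - s$bbox["cmax"])
    if (sqrt(gap_r^2 + gap_c^2) > min(best, thr) + 1e-9) next
    d2 <- outer(tip_pixels[, 1L], s$pixels[, 1L], "-")^2 +
      outer(tip_pixels[, 2L], s$pixels[, 2L], "-")^2
    d <- sqrt(min(d2))
    if (d < best - 1e-9) { best <- d; best_id <- s$id }
  }
  if (best <= thr + 1e-9) list(stalk_id = best_id, distance_px = best) else NULL
}

# Euclidean distance of every pixel to the nearest body-edge pixel, plus the
# flat list of edge coordinates and their owning cell ids (for terminal
# assignment). NULL when there are no bodies.
body_distance_field <- function(bodies, dims) {
  if (!length(bodies)) return(NULL)
  seed <- matrix(1, dims[1L], dims[2L])
  edges <- do.call(rbind, lapply(bodies, function(b) b$edge))
  owner <- rep(vapply(bodies, function(b) b$id, 0L),
               vapply(bodies, function(b) nrow(b$edge), 0L))
  seed[edges] <- 0
  list(dist = EBImage::imageData(EBImage::distmap(seed)), edges = edges,
       owner = owner)
}

nearest_edge_owner <- function(field, p) {
  d2 <- (field$edges[, 1L] - p[1L])^2 + (field$edges[, 2L] - p[2L])^2
  j <- which.min(d2)
  list(owner = field$owner[j], dist = sqrt(d2[j]))
}

#' Trace a filopodium shaft from its tip to the cell cortex
#'
#' Starting from the stalk pixel nearest the tip centroid, the walk
#' repeatedly moves to the stalk pixel within `trace_step_px` of the current
#' waypoint that most reduces the Euclidean distance to the nearest cell
#' boundary, requiring a strict decrease so it cannot oscillate. This
#' operationalises "move toward the nearest cortex along the stalk" as a
#' deterministic greedy descent. Termination:
#' * **attached** - the waypoint comes within `disembodied_min_dist_px` of a
#'   body boundary; the remaining straight-line gap is added to the length so
#'   lengths do not systematically undershoot, and the owning cell is the one
#'   holding the nearest boundary pixel;
#' * **disembodied** - no descending move exists and the whole stalk stays at
#'   least `disembodied_min_dist_px` from every body (a detached fragment);
#' * **trace_failed** - the walk stalls while the stalk does approach a body
#'   (a pathological geometry), or `max_trace_steps` is exceeded.
#'
#' @param tip One-row slice of the [detect_tips()] tibble (needs
#'   `centroid_row`/`centroid_col`).
#' @param stalk A `filo_region` stalk object.
#' @param bodies List of `filo_region` body objects.
#' @param config A [filo_config()].
#' @param field Optional precomputed [body_distance_field()]; passed by
#'   [run_filoskeleton()] so the distance transform is computed once per
#'   image.
#' @return A list: `status`, `shaft_length_um`, `shaft_length_px`,
#'   `terminal_cell_id`, `waypoints` (k x 2 matrix).
#' @export
trace_shaft <- function(tip, stalk, bodies, config = filo_config(),
                        field = NULL) {
  if (is.null(field)) field <- body_distance_field(bodies, stalk$mask_dim)
  sp <- stalk$pixels
  start_d2 <- (sp[, 1L] - tip$centroid_row)^2 + (sp[, 2L] - tip$centroid_col)^2
  cur <- sp[which.min(start_d2), ]
  waypoints <- matrix(cur, 1L, 2L, dimnames = list(NULL, c("row", "col")))
  if (is.null(field)) {
    return(list(status = "disembodied", shaft_length_um = NA_real_,
                shaft_length_px = NA_real_, terminal_cell_id = NA_integer_,
                waypoints = waypoints))
  }
  D <- field$dist
  dval <- function(p) D[p[1L], p[2L]]
  len_px <- 0
  step <- config$trace_step_px
  stalk_min_d <- min(D[sp])
  for (it in seq_len(config$max_trace_steps)) {
    dc <- dval(cur)
    if (dc <= config$disembodied_min_dist_px) {
      term <- nearest_edge_owner(field, cur)
      len_px <- len_px + term$dist
      return(list(status = "attached",
                  shaft_length_um = len_px * config$pixel_size_um,
                  shaft_length_px = len_px,
                  terminal_cell_id = term$owner,
                  waypoints = waypoints))
    }
    near <- (sp[, 1L] - cur[1L])^2 + (sp[, 2L] - cur[2L])^2 <= step^2 + 1e-9
    cand <- sp[near, , drop = FALSE]
    dv <- D[cand]
    j <- which.min(dv)
    if (!length(j) || dv[j] >= dc - 1e-9) {
      status <- if (stalk_min_d >= config$disembodied_min_dist_px)
        "disembodied" else "trace_failed"
      return(list(status = status, shaft_length_um = NA_real_,
                  shaft_length_px = NA_real_,
                  terminal_cell_id = NA_integer_, waypoints = waypoints))
    }
    nxt <- cand[j, ]
    len_px <- len_px + sqrt(sum((nxt - cur)^2))
    cur <- nxt
    waypoints <- rbind(waypoints, cur)
  }
  list(status = "trace_failed", shaft_length_um = NA_real_,
       shaft_length_px = NA_real_, terminal_cell_id = NA_integer_,
       waypoints = waypoints)
}

#' Run the actin + tip-marker pipeline
#'
#' Detects cell bodies from the actin mask (class 1) with full morphometrics,
#' tip foci from the binary tip mask with intensities from the tip-marker
#' image, and stalks from the actin mask (class 2). Each tip is matched to a
#' stalk (within `tip_stalk_max_dist_px`); matched tips are traced along
#' their stalk to the cortex for the true shaft length and assigned to the
#' terminal cell. Disembodied fragments and failed traces are reported but
#' excluded from per-cell counts; tips with no stalk in range are artifacts.
#' There is no cortex/separator banding in this mode: `body_mean` for the
#' tip/body ratio is the tip-marker mean over the whole actin-derived body
#' region.
#'
#' @param actin_mask `filo_mask`, classes background 0, body 1, stalk 2.
#' @param tip_mask `filo_mask`, classes background 0, tip 1.
#' @param actin_image,tip_image `filo_image`s, same shape as the masks.
#' @param config A [filo_config()].
#' @param scene_id Label written into the output tables.
#' @return A `filo_result` (mode `"skeleton"`); `filopodia` carries
#'   `shaft_length_um` and status in
#'   `{attached, disembodied, trace_failed, artifact}`.
#' @examples
#' sc <- generate_skeleton_scene(scene_params(n_cells = 1), seed = 1)
#' res <- run_filoskeleton(sc$actin_mask, sc$tip_mask, sc$actin_image, sc$tip_image)
#' table(res$filopodia$status)
#' @export
run_filoskeleton <- function(actin_mask, tip_mask, actin_image, tip_image,
                             config = filo_config(), scene_id = "scene") {
  shapes <- list(actin_mask$shape, tip_mask$shape, actin_image$shape,
                 tip_image$shape)
  if (length(unique(lapply(shapes, as.integer))) != 1L) {
    stop("all masks and images must share one shape", call. = FALSE)
  }
  bodies <- find_regions(actin_mask, 1L, config$min_body_area_px)
  stalks <- detect_stalks(actin_mask, config)
  tips <- detect_tips(tip_mask, tip_image, config, tip_code = 1L)
  tip_objects <- attr(tips, "objects")
  field <- body_distance_field(bodies, actin_mask$shape)

  cells <- skeleton_cells(bodies, tip_image, config)
  n <- nrow(tips)
  filo <- tibble::tibble(
    filo_id = seq_len(n), cell_id = NA_integer_,
    tip_x_px = tips$centroid_col - 1, tip_y_px = tips$centroid_row - 1,
    length_um = NA_real_, shaft_length_um = NA_real_,
    tip_mean = tips$mean_intensity, tip_sum = tips$sum_intensity,
    tip_area_px = tips$area_px, tip_body_ratio = NA_real_,
    stalk_id = NA_integer_, status = rep("artifact", n),
    reason = NA_character_, tie = FALSE
  )
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    m <- match_tip_to_stalk(tip_objects[[i]]$pixels, stalks, config)
    if (is.null(m)) {
      filo$reason[i] <- sprintf("no stalk within %g px",
                                config$tip_stalk_max_dist_px)
      next
    }
    filo$stalk_id[i] <- m$stalk_id
    tr <- trace_shaft(tips[i, ], stalks[[m$stalk_id]], bodies, config, field)
    traces[[i]] <- tr
    filo$status[i] <- tr$status
    if (tr$status == "attached") {
      filo$cell_id[i] <- tr$terminal_cell_id
      filo$shaft_length_um[i] <- tr$shaft_length_um
      # straight-line tip-to-boundary distance, the tip-mode length analogue
      p <- c(tips$centroid_row[i], tips$centroid_col[i])
      filo$length_um[i] <- nearest_edge_owner(field, p)$dist *
        config$pixel_size_um
      owner_row <- match(tr$terminal_cell_id, cells$cell_id)
      filo$tip_body_ratio[i] <- safe_ratio(tips$mean_intensity[i],
                                           cells$body_mean[owner_row])
    }
  }
  res <- result_assemble(cells, filo, lapply(bodies, function(b)
    list(region = b, zones = NULL, leading_edge = NULL)),
    tip_objects = tip_objects, mode = "skeleton", scene_id = scene_id,
    config = config, mask = actin_mask,
    extra = list(stalks = stalks, traces = traces))
  res
}

skeleton_cells <- function(bodies, tip_image, config) {
  rows <- lapply(bodies, function(reg) {
    morph <- morphometrics(reg, config$pixel_size_um)
    body_mean <- mean(tip_image$grid[reg$pixels])
    dplyr::bind_cols(
      tibble::tibble(cell_id = reg$id), morph,
      tibble::tibble(
        body_mean = body_mean, cortex_mean = NA_real_,
        leading_edge_mean = NA_real_, cortex_body_ratio = NA_real_,
        leading_edge_body_ratio = NA_real_,
        total_signal = sum(tip_image$grid[reg$pixels]),
        degenerate = FALSE, filopodia_count = NA_integer_,
        filopodia_per_10um = NA_real_
      )
    )
  })
  if (length(rows)) dplyr::bind_rows(rows) else empty_cell_tibble()
}
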