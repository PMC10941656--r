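# Tip-marker-only measurement engine: cells, tip puncta, distance-based
# assignment, intensity ratios and per-cell summaries.

#' Detect and measure cell bodies (tip-marker mode)
#'
#' One record per 8-connected body-class component of at least
#' `min_body_area_px` pixels, numbered in raster-scan order. Each cell gets
#' full morphometrics, the cortex/separator/interior band partition, the
#' leading-edge patch, zone mean intensities and the enrichment ratios.
#' `body_mean` is the mean over the interior band only (the separator is a
#' neutral buffer and the cortex is its own compartment); `total_signal`
#' sums the raw image over the entire body region (all three bands) and,
#' after tip assignment in [run_filotips()], the assigned tip pixels too.
#'
#' @param mask A `filo_mask` with classes background 0, body 1, tip 2.
#' @param image A `filo_image` (tip-marker channel), same shape.
#' @param config A [filo_config()].
#' @return A tibble of cell records (one row per cell) with a `"objects"`
#'   attribute holding the underlying regions, zones and leading-edge
#'   patches for rendering and assignment.
#' @export
detect_cells <- function(mask, image, config = filo_config()) {
  stopifnot(inherits(mask, "filo_mask"), inherits(image, "filo_image"))
  if (!identical(mask$shape, image$shape)) {
    stop("mask and image shapes differ", call. = FALSE)
  }
  body_code <- if ("body" %in% names(mask$classes)) mask$classes[["body"]] else 1L
  regions <- find_regions(mask, body_code, config$min_body_area_px)
  objects <- vector("list", length(regions))
  rows <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    zones <- partition_zones(reg, config)
    le <- leading_edge(zones, image, config)
    morph <- morphometrics(reg, config$pixel_size_um)
    body_mean <- zone_mean(image, zones$interior)
    cortex_mean <- zone_mean(image, zones$cortex)
    le_mean <- zone_mean(image, le)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(cell_id = reg$id),
      morph,
      tibble::tibble(
        body_mean = body_mean,
        cortex_mean = cortex_mean,
        leading_edge_mean = le_mean,
        cortex_body_ratio = safe_ratio(cortex_mean, body_mean),
        leading_edge_body_ratio = safe_ratio(le_mean, body_mean),
        total_signal = sum(image$grid[reg$pixels]),
        degenerate = zones$degenerate,
        filopodia_count = NA_integer_,
        filopodia_per_10um = NA_real_
      )
    )
    objects[[i]] <- list(region = reg, zones = zones, leading_edge = le)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_cell_tibble()
  attr(out, "objects") <- objects
  out
}

zone_mean <- function(image, pixels) {
  if (is.null(pixels) || nrow(pixels) == 0L) return(NA_real_)
  mean(image$grid[pixels])
}

safe_ratio <- function(a, b) {
  if (is.na(a) || is.na(b) || b == 0) NA_real_ else a / b
}

empty_cell_tibble <- function() {
  tibble::tibble(
    cell_id = integer(), area_um2 = double(), perimeter_um = double(),
    centroid_x_px = double(), centroid_y_px = double(),
    aspect_ratio = double(), circularity = double(), body_mean = double(),
    cortex_mean = double(), leading_edge_mean = double(),
    cortex_body_ratio = double(), leading_edge_body_ratio = double(),
    total_signal = double(), degenerate = logical(),
    filopodia_count = integer(), filopodia_per_10um = double()
  )
}

#' Detect filopodia tip puncta
#'
#' One record per 8-connected tip-class component of at least
#' `min_tip_area_px` pixels, with its real-valued centroid and raw intensity
#' statistics over the punctum.
#'
#' @param mask A `filo_mask` containing a tip class.
#' @param image A `filo_image` (tip-marker channel).
#' @param config A [filo_config()].
#' @param tip_code Class code of tips; defaults to the `"tip"` entry of the
#'   mask vocabulary (2 in tip mode, 1 in a binary tip mask).
#' @return A tibble (tip_id, centroid_row, centroid_col, area_px, mean_intensity,
#'   sum_intensity) with an `"objects"` attribute of `filo_region`s.
#' @export
detect_tips <- function(mask, image, config = filo_config(), tip_code = NULL) {
  stopifnot(inherits(mask, "filo_mask"), inherits(image, "filo_image"))
  if (is.null(tip_code)) {
    tip_code <- if ("tip" %in% names(mask$classes)) mask$classes[["tip"]]
                else max(mask$classes)
  }
  regions <- find_regions(mask, tip_code, config$min_tip_area_px)
  rows <- lapply(regions, function(reg) {
    vals <- image$grid[reg$pixels]
    tibble::tibble(
      tip_id = reg$id,
      centroid_row = mean(reg$pixels[, "row"]),
      centroid_col = mean(reg$pixels[, "col"]),
      area_px = nrow(reg$pixels),
      mean_intensity = mean(vals),
      sum_intensity = sum(vals)
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(tip_id = integer(), centroid_row = double(),
                   centroid_col = double(), area_px = integer(),
                   mean_intensity = double(), sum_intensity = double())
  attr(out, "objects") <- regions
  out
}

#' Assign tip puncta to cells by Euclidean distance
#'
#' For each tip, the Euclidean distances from the tip centroid to every
#' boundary (outline) pixel of every cell are computed; the tip belongs to
#' the cell achieving the minimum (ties go to the lowest cell id and are
#' flagged in the `tie` column). That minimum distance, converted to
#' micrometres, is the filopodium length. If no cell outline lies within
#' `max_tip_distance_um` the tip is an artifact and gets no cell.
#'
#' @param tips Tibble from [detect_tips()].
#' @param cells Tibble from [detect_cells()] (needs its `"objects"`
#'   attribute).
#' @param config A [filo_config()].
#' @return A tibble: filo_id, cell_id, tip_x_px, tip_y_px (0-based),
#'   distance_px, length_um, tip_mean, tip_sum, tip_area_px, tip_body_ratio,
#'   status (`"assigned"` or `"artifact"`), reason, tie.
#' @export
assign_tips <- function(tips, cells, config = filo_config()) {
  objects <- attr(cells, "objects")
  boundaries <- lapply(objects, function(o) o$region$boundary)
  n <- nrow(tips)
  out <- tibble::tibble(
    filo_id = seq_len(n),
    cell_id = NA_integer_, tip_x_px = tips$centroid_col - 1,
    tip_y_px = tips$centroid_row - 1, distance_px = NA_real_,
    length_um = NA_real_, tip_mean = tips$mean_intensity,
    tip_sum = tips$sum_intensity, tip_area_px = tips$area_px,
    tip_body_ratio = NA_real_,
    status = rep("artifact", n), reason = NA_character_,
    tie = rep(FALSE, n)
  )
  if (n == 0L) return(out)
  if (length(boundaries) == 0L) {
    out$reason <- "no cell"
    return(out)
  }
  for (i in seq_len(n)) {
    p <- c(tips$centroid_row[i], tips$centroid_col[i])
    dmin <- vapply(boundaries, function(b) {
      sqrt(min((b[, 1L] - p[1L])^2 + (b[, 2L] - p[2L])^2))
    }, 0)
    best <- min(dmin)
    owner <- which(dmin <= best + 1e-9)
    out$tie[i] <- length(owner) > 1L
    owner <- owner[1L]
    len_um <- best * config$pixel_size_um
    if (len_um > config$max_tip_distance_um) {
      out$reason[i] <- sprintf("nearest cell outline %.4g um away (> %g um)",
                               len_um, config$max_tip_distance_um)
    } else {
      out$cell_id[i] <- cells$cell_id[owner]
      out$distance_px[i] <- best
      out$length_um[i] <- len_um
      out$tip_body_ratio[i] <- safe_ratio(tips$mean_intensity[i],
                                          cells$body_mean[owner])
      out$status[i] <- "assigned"
    }
  }
  out
}

#' Run the tip-marker pipeline
#'
#' Composes [detect_cells()], [detect_tips()] and [assign_tips()], then fills
#' per-cell filopodia counts, the perimeter-normalised density
#' `filopodia_per_10um = count / perimeter_um * 10`, and adds the assigned
#' tip signal to each cell's `total_signal`. Detected tips are conserved:
#' every tip ends up either assigned or in the artifact records.
#'
#' @inheritParams detect_cells
#' @param scene_id Label written into the output tables.
#' @return A `filo_result` with elements `cells` and `filopodia` (tibbles;
#'   artifact tips appear in `filopodia` with status `"artifact"`),
#'   `artifacts` (the artifact subset), `mode = "tips"`, `provenance`.
#' @examples
#' sc <- generate_tip_scene(scene_params(n_cells = 1), seed = 1)
#' res <- run_filotips(sc$mask, sc$image)
#' res$cells$filopodia_count
#' @export
run_filotips <- function(mask, image, config = filo_config(),
                         scene_id = "scene") {
  cells <- detect_cells(mask, image, config)
  tips <- detect_tips(mask, image, config)
  filo <- assign_tips(tips, cells, config)
  result_assemble(cells, filo, attr(cells, "objects"),
                  tip_objects = attr(tips, "objects"),
                  mode = "tips", scene_id = scene_id, config = config,
                  mask = mask)
}

result_assemble <- function(cells, filo, cell_objects, tip_objects, mode,
                            scene_id, config, mask, extra = list()) {
  counts <- table(factor(filo$cell_id[filo$status %in% c("assigned", "attached")],
                         levels = cells$cell_id))
  cells$filopodia_count <- as.integer(counts)
  cells$filopodia_per_10um <- ifelse(cells$perimeter_um > 0,
                                     cells$filopodia_count /
                                       cells$perimeter_um * 10, NA_real_)
  # total signal = whole body region + pixels of tips assigned to the cell
  if (nrow(filo)) {
    add <- tapply(filo$tip_sum[!is.na(filo$cell_id)],
                  filo$cell_id[!is.na(filo$cell_id)], sum)
    j <- match(as.integer(names(add)), cells$cell_id)
    cells$total_signal[j] <- cells$total_signal[j] + as.numeric(add)
  }
  cells <- tibble::add_column(cells, scene_id = scene_id, .before = 1L)
  filo <- tibble::add_column(filo, scene_id = scene_id, .before = 1L)
  structure(list(
    cells = cells,
    filopodia = filo,
    artifacts = dplyr::filter(filo, .data$status == "artifact"),
    mode = mode,
    scene_id = scene_id,
    config = config,
    mask_dim = mask$shape,
    objects = c(list(cells = cell_objects, tips = tip_objects), extra),
    provenance = list(config = unclass(config), timestamp = format(Sys.time()))
  ), class = "filo_result")
}

#' @export
print.filo_result <- function(x, ...) {
  cat("<filo_result> mode ", x$mode, ": ", nrow(x$cells), " cell(s), ",
      sum(!x$filopodia$status %in% "artifact" &
            !x$filopodia$status %in% c("disembodied", "trace_failed")),
      " filopodia, ", nrow(x$artifacts), " artifact(s)\n", sep = "")
  invisible(x)
}
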