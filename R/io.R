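# Measurement-table export and annotation rendering.

cell_table_cols <- c("scene_id", "cell_id", "area_um2", "perimeter_um",
                     "aspect_ratio", "circularity", "centroid_x_px",
                     "centroid_y_px", "body_mean", "cortex_mean",
                     "leading_edge_mean", "cortex_body_ratio",
                     "leading_edge_body_ratio", "total_signal",
                     "filopodia_count", "filopodia_per_10um")

filo_table_cols <- function(mode) {
  base <- c("scene_id", "cell_id", "filo_id", "tip_x_px", "tip_y_px",
            "length_um", "tip_mean", "tip_body_ratio")
  if (mode == "skeleton") c(base, "shaft_length_um", "status")
  else c(base, "status")
}

#' Write the per-cell and per-filopodium summary tables
#'
#' Writes `cells.csv` and `filopodia.csv` into `out_dir` with fixed column
#' sets, rows ordered by ascending cell then filopodium id; artifact tips are
#' included in `filopodia.csv` with status `"artifact"` so nothing is
#' silently dropped. Floating values are printed at full precision, so
#' writing the same result twice gives byte-identical files.
#'
#' @param result A `filo_result`.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the written paths, invisibly.
#' @export
write_summary_tables <- function(result, out_dir) {
  stopifnot(inherits(result, "filo_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  cells <- dplyr::arrange(result$cells, .data$cell_id)[, cell_table_cols]
  filo <- dplyr::arrange(result$filopodia, !is.na(.data$cell_id),
                         .data$cell_id, .data$filo_id)
  filo <- filo[, filo_table_cols(result$mode)]
  paths <- c(cells = file.path(out_dir, "cells.csv"),
             filopodia = file.path(out_dir, "filopodia.csv"))
  write_csv_stable(cells, paths["cells"])
  write_csv_stable(filo, paths["filopodia"])
  invisible(paths)
}

# deterministic CSV writer: fixed precision-independent formatting, no
# locale effects, LF endings
write_csv_stable <- function(df, path) {
  if (nrow(df) == 0L) {
    lines <- paste(names(df), collapse = ",")
  } else {
    cols <- lapply(df, function(v) {
      out <- if (is.double(v)) {
        format(v, digits = 12, trim = TRUE, scientific = FALSE)
      } else {
        as.character(v)
      }
      out[is.na(v)] <- "NA"
      out
    })
    m <- do.call(cbind, cols)
    lines <- c(paste(names(df), collapse = ","),
               apply(m, 1L, paste, collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# 3x5 bitmap digits for drawing cell numbers into annotations
digit_font <- local({
  rows <- c(
    "111101101101111", # 0
    "010110010010111", # 1
    "111001111100111", # 2
    "111001111001111", # 3
    "101101111001001", # 4
    "111100111001111", # 5
    "111100111101111", # 6
    "111001001001001", # 7
    "111101111101111", # 8
    "111101111001111"  # 9
  )
  lapply(rows, function(s) {
    matrix(as.integer(strsplit(s, "")[[1]]) == 1L, 5L, 3L, byrow = TRUE)
  })
})

draw_number <- function(canvas, num, at, col) {
  digits <- as.integer(strsplit(as.character(num), "")[[1]])
  r0 <- round(at[1L]) - 2L
  c0 <- round(at[2L]) - 2L * length(digits)
  for (k in seq_along(digits)) {
    glyph <- digit_font[[digits[k] + 1L]]
    for (i in 1:5) for (j in 1:3) {
      if (!glyph[i, j]) next
      r <- r0 + i - 1L; cc <- c0 + (k - 1L) * 4L + j - 1L
      if (r >= 1L && r <= dim(canvas)[1L] && cc >= 1L && cc <= dim(canvas)[2L])
        canvas[r, cc, ] <- col
    }
  }
  canvas
}

paint_px <- function(canvas, pixels, col) {
  if (is.null(pixels) || nrow(pixels) == 0L) return(canvas)
  for (ch in 1:3) {
    plane <- canvas[, , ch]
    plane[pixels[, 1:2, drop = FALSE]] <- col[ch]
    canvas[, , ch] <- plane
  }
  canvas
}

pal <- list(
  yellow = c(1, 1, 0), orange = c(1, 0.647, 0), gray = c(0.5, 0.5, 0.5),
  pink = c(1, 0.412, 0.706), blue = c(0, 0, 1), green = c(0, 1, 0),
  white = c(1, 1, 1), aqua = c(0, 1, 1), red = c(1, 0, 0)
)

#' Render an annotation overlay
#'
#' Produces an RGB raster of the analysis for visual audit. Tip mode uses
#' the palette: yellow body (interior), orange cortex, gray separator band,
#' pink filopodia tips, blue leading edge, green centroid, white cell
#' numbers; artifact tips are drawn red. Skeleton mode: aqua body, yellow
#' stalks, red tips of attached filopodia, blue tips of disembodied
#' fragments (orange for failed traces), white cell numbers.
#'
#' @param mask The `filo_mask` the result was computed from (tip-mode mask
#'   or actin mask).
#' @param result The matching `filo_result`.
#' @param mode `"tips"` or `"skeleton"`.
#' @return An height x width x 3 numeric array in `[0, 1]`.
#' @export
render_annotation <- function(mask, result, mode = result$mode) {
  stopifnot(inherits(result, "filo_result"))
  if (!identical(mode, result$mode)) {
    stop("result was produced in '", result$mode, "' mode, not '", mode, "'",
         call. = FALSE)
  }
  if (!identical(mask$shape, result$mask_dim)) {
    stop("mask shape does not match the analysed mask", call. = FALSE)
  }
  dims <- mask$shape
  canvas <- array(0, c(dims[1L], dims[2L], 3L))
  tip_objects <- result$objects$tips
  if (mode == "tips") {
    for (o in result$objects$cells) {
      canvas <- paint_px(canvas, o$zones$interior, pal$yellow)
      canvas <- paint_px(canvas, o$zones$separator, pal$gray)
      canvas <- paint_px(canvas, o$zones$cortex, pal$orange)
      canvas <- paint_px(canvas, o$leading_edge, pal$blue)
    }
    for (i in seq_len(nrow(result$filopodia))) {
      col <- if (result$filopodia$status[i] == "assigned") pal$pink else pal$red
      canvas <- paint_px(canvas, tip_objects[[i]]$pixels, col)
    }
  } else {
    for (o in result$objects$cells) {
      canvas <- paint_px(canvas, o$region$pixels, pal$aqua)
    }
    for (s in result$objects$stalks) {
      canvas <- paint_px(canvas, s$pixels, pal$yellow)
    }
    status_col <- c(attached = "red", disembodied = "blue",
                    trace_failed = "orange", artifact = "red")
    for (i in seq_len(nrow(result$filopodia))) {
      col <- pal[[status_col[[result$filopodia$status[i]]]]]
      canvas <- paint_px(canvas, tip_objects[[i]]$pixels, col)
    }
  }
  for (i in seq_len(nrow(result$cells))) {
    ct <- c(result$cells$centroid_y_px[i] + 1, result$cells$centroid_x_px[i] + 1)
    if (mode == "tips") {
      cross <- cbind(row = round(ct[1L]) + c(0, -1, 1, 0, 0),
                     col = round(ct[2L]) + c(0, 0, 0, -1, 1))
      cross <- cross[cross[, 1L] >= 1 & cross[, 1L] <= dims[1L] &
                       cross[, 2L] >= 1 & cross[, 2L] <= dims[2L], ,
                     drop = FALSE]
      canvas <- paint_px(canvas, cross, pal$green)
    }
    canvas <- draw_number(canvas, result$cells$cell_id[i],
                          c(ct[1L] - 8, ct[2L]), pal$white)
  }
  canvas
}

#' Write an annotation overlay as PNG
#'
#' @inheritParams render_annotation
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(mask, result, path, mode = result$mode) {
  png::writePNG(render_annotation(mask, result, mode), path)
  invisible(path)
}
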