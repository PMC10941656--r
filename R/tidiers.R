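# broom-style accessors and plotting for analysis results.

#' Tidy a filopodia analysis result
#'
#' Returns the per-filopodium table (one row per detected tip, including
#' artifacts and, in skeleton mode, disembodied and failed traces).
#'
#' @param x A `filo_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.filo_result <- function(x, ...) {
  x$filopodia
}

#' One-row summary of a filopodia analysis result
#'
#' @param x A `filo_result`.
#' @param ... Unused.
#' @return A one-row tibble: cell count, filopodia counted per cell on
#'   average, artifacts, excluded records and mean enrichment ratios.
#' @export
glance.filo_result <- function(x, ...) {
  counted <- sum(x$filopodia$status %in% c("assigned", "attached"))
  tibble::tibble(
    mode = x$mode,
    n_cells = nrow(x$cells),
    n_filopodia = counted,
    n_artifacts = sum(x$filopodia$status == "artifact"),
    n_excluded = sum(x$filopodia$status %in% c("disembodied", "trace_failed")),
    mean_filopodia_per_cell = if (nrow(x$cells)) mean(x$cells$filopodia_count)
      else NA_real_,
    mean_cortex_body_ratio = mean(x$cells$cortex_body_ratio, na.rm = TRUE),
    mean_tip_body_ratio = mean(x$filopodia$tip_body_ratio, na.rm = TRUE),
    mean_length_um = mean(x$filopodia$length_um, na.rm = TRUE)
  )
}

#' Plot the annotation overlay of a result
#'
#' Renders the colour-coded annotation ([render_annotation()]) as a ggplot
#' raster, so results can be inspected visually straight from the pipeline.
#'
#' @param object A `filo_result`.
#' @param mask The `filo_mask` it was computed from; only its shape is used.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filo_result <- function(object, mask = NULL, ...) {
  if (is.null(mask)) {
    mask <- list(shape = object$mask_dim)
    class(mask) <- "filo_mask"
  }
  arr <- render_annotation(mask, object)
  df <- expand.grid(y = seq_len(dim(arr)[1L]), x = seq_len(dim(arr)[2L]))
  df$fill <- grDevices::rgb(arr[, , 1L][as.matrix(df[, c("y", "x")])],
                            arr[, , 2L][as.matrix(df[, c("y", "x")])],
                            arr[, , 3L][as.matrix(df[, c("y", "x")])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%s-mode annotation (%d cells, %d filopodia)",
                                  object$mode, nrow(object$cells),
                                  sum(object$filopodia$status %in%
                                        c("assigned", "attached"))))
}
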