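#' Analysis configuration
#'
#' Bundles the pixel scale and the geometric constants used by both
#' measurement engines. Defaults reproduce the published tool's constants.
#'
#' @param pixel_size_um Physical pixel size in micrometres. Default 0.1099.
#' @param contour_thickness_px Total thickness (px) of the band grown inward
#'   from the cell edge during zone construction; the cortex and separator
#'   bands live inside it. Default 15.
#' @param cortex_band_px Depth (px) of the cortex band measured from the cell
#'   boundary. Default 6.
#' @param separator_band_px Depth (px) of the neutral band between cortex and
#'   interior, used so that cortex and body signal do not bleed into each
#'   other. Default 15.
#' @param max_tip_distance_um Maximum tip-to-cell distance (micrometres) for a
#'   tip to be assigned as a filopodium; beyond it the tip is an artifact.
#'   Default 10.
#' @param leading_edge_px Number of cortex pixels (including the brightest
#'   one) that make up the leading-edge patch. Default 50.
#' @param tip_stalk_max_dist_px Maximum pixel distance between a tip focus and
#'   a stalk for the tip to count as a filopodium in skeleton mode. Default 3.
#' @param trace_step_px Step radius (px) of the shaft-tracing walk. Default 5.
#' @param disembodied_min_dist_px Distance (px) from the cell boundary beyond
#'   which an unreachable stalk is called disembodied; also the attachment
#'   radius at which a trace terminates. Default 5.
#' @param shave_rounds Rounds of 3x3 erosion then dilation used to shave
#'   protrusions off a body mask. Default 5.
#' @param min_body_area_px Minimum pixel area of a cell body object. Default 50.
#' @param min_tip_area_px Minimum pixel area of a tip object. Default 2.
#' @param max_trace_steps Iteration cap of the shaft-tracing walk; hitting it
#'   flags the trace as failed rather than truncating silently. Default 2000.
#'
#' @return An object of class `filo_config` (a named list).
#' @examples
#' cfg <- filo_config()
#' cfg$pixel_size_um
#' @export
filo_config <- function(pixel_size_um = 0.1099,
                        contour_thickness_px = 15,
                        cortex_band_px = 6,
                        separator_band_px = 15,
                        max_tip_distance_um = 10,
                        leading_edge_px = 50,
                        tip_stalk_max_dist_px = 3,
                        trace_step_px = 5,
                        disembodied_min_dist_px = 5,
                        shave_rounds = 5,
                        min_body_area_px = 50,
                        min_tip_area_px = 2,
                        max_trace_steps = 2000) {
  cfg <- list(
    pixel_size_um = pixel_size_um,
    contour_thickness_px = contour_thickness_px,
    cortex_band_px = cortex_band_px,
    separator_band_px = separator_band_px,
    max_tip_distance_um = max_tip_distance_um,
    leading_edge_px = leading_edge_px,
    tip_stalk_max_dist_px = tip_stalk_max_dist_px,
    trace_step_px = trace_step_px,
    disembodied_min_dist_px = disembodied_min_dist_px,
    shave_rounds = shave_rounds,
    min_body_area_px = min_body_area_px,
    min_tip_area_px = min_tip_area_px,
    max_trace_steps = max_trace_steps
  )
  validate_config(cfg)
  structure(cfg, class = "filo_config")
}

validate_config <- function(cfg) {
  num_keys <- setdiff(names(cfg), c("shave_rounds", "max_trace_steps"))
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("config parameter '", k, "' must be a single positive number, got: ",
           deparse(v), call. = FALSE)
    }
  }
  for (k in c("shave_rounds", "max_trace_steps")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("config parameter '", k, "' must be a single nonnegative number",
           call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML key/value document and overlays it on the defaults of
#' [filo_config()]. A missing path returns the defaults unchanged.
#'
#' @param path Path to a YAML file, or `NULL` for defaults.
#' @return A `filo_config` object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("pixel_size_um: 0.2", f)
#' load_config(f)$pixel_size_um
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(filo_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(filo_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(filo_config, vals)
}

#' @export
print.filo_config <- function(x, ...) {
  cat("<filo_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' @export
format.filo_config <- function(x, ...) {
  paste(sprintf("%s=%s", names(x), vapply(x, format, "")), collapse = " ")
}
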