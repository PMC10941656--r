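# Morphometrics and band partitions of body regions.

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

#' Morphometrics of a region
#'
#' Computes the standard cell-shape metrics from a region's pixel set and
#' traced boundary:
#' * `area_um2`: pixel count times `scale^2`;
#' * `perimeter_um`: arc length of the closed boundary polyline through pixel
#'   centres (axial steps 1, diagonal steps sqrt(2)) times `scale`;
#' * `centroid_x_px`, `centroid_y_px`: mean pixel coordinate, 0-based,
#'   x = column, y = row (row 0 at the top);
#' * `aspect_ratio`: short side over long side of the minimum-area rotated
#'   bounding rectangle of the boundary (1 for a square). Rectangle sides are
#'   taken as the projected extent of pixel centres plus one pixel footprint.
#' * `circularity`: `4 * pi * area / perimeter^2` in pixel units (1 for a
#'   perfect disc, up to rasterisation error). `NA` for single-pixel regions,
#'   whose polyline perimeter is 0.
#'
#' @param region A `filo_region` from [find_regions()].
#' @param scale Pixel size in micrometres per pixel.
#' @return A one-row tibble.
#' @examples
#' g <- matrix(0L, 12, 12); g[2:11, 2:11] <- 1L
#' m <- label_mask(g, c(background = 0, body = 1, tip = 2))
#' morphometrics(find_regions(m, 1L)[[1]], scale = 1)
#' @export
morphometrics <- function(region, scale = 1) {
  stopifnot(inherits(region, "filo_region"))
  npx <- nrow(region$pixels)
  per_px <- polyline_length(region$boundary)
  tibble::tibble(
    area_um2 = npx * scale^2,
    perimeter_um = per_px * scale,
    centroid_x_px = mean(region$pixels[, "col"]) - 1,
    centroid_y_px = mean(region$pixels[, "row"]) - 1,
    aspect_ratio = min_area_rect_aspect(region$boundary),
    circularity = if (per_px > 0) 4 * pi * npx / per_px^2 else NA_real_
  )
}

# rotating-calipers minimum-area bounding rectangle over the convex hull of
# boundary pixel centres; each side is extent + 1 so a pixel row has unit
# width, making axis-aligned n x m pixel blocks score exactly min(n,m)/max(n,m)
min_area_rect_aspect <- function(pts) {
  xy <- unique(cbind(x = pts[, "col"], y = pts[, "row"]))
  if (nrow(xy) == 1L) return(1)
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  best <- c(area = Inf, short = NA, long = NA)
  nh <- nrow(hull)
  segs <- if (nh >= 2L) seq_len(nh) else 1L
  for (i in segs) {
    p <- hull[i, ]
    q <- hull[if (i == nh) 1L else i + 1L, ]
    e <- q - p
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len
    v <- c(-u[2L], u[1L])
    pu <- xy %*% u
    pv <- xy %*% v
    sides <- c(diff(range(pu)), diff(range(pv))) + 1
    a <- prod(sides)
    if (a < best["area"]) best <- c(area = a, short = min(sides), long = max(sides))
  }
  if (!is.finite(best["area"])) { # all hull points coincide or collinear
    d <- xy[which.max(rowSums(sweep(xy, 2, xy[1L, ])^2)), ] - xy[1L, ]
    u <- d / sqrt(sum(d^2))
    ext <- diff(range(xy %*% u)) + 1
    return(min(1, 1 / ext))
  }
  unname(best["short"] / best["long"])
}

#' Partition a body region into cortex, separator and interior bands
#'
#' With `d(p)` the Euclidean distance from pixel `p` to the nearest pixel
#' outside the region (so boundary pixels have depth 1), the cortex is
#' `d <= cortex_band_px` -- equivalently the region minus its erosion by a
#' disc of that radius -- the separator the
#' next `separator_band_px` of depth, and the interior everything deeper. The
#' cortex is the measurement band for cortical enrichment; the separator is a
#' neutral buffer so cortex and body signal do not contaminate each other.
#' When the region is too small to have an interior the partition degenerates:
#' the separator is dropped first (the cortex is never sacrificed) and the
#' interior becomes everything deeper than the cortex.
#'
#' @param region A `filo_region` (body).
#' @param config A [filo_config()].
#' @return A `filo_zones` object: `cortex`, `separator`, `interior` (each an
#'   n x 2 matrix of (row, col) pixel coordinates), logical `degenerate`, and
#'   the distance values `depth` aligned with `region$pixels`.
#' @export
partition_zones <- function(region, config = filo_config()) {
  stopifnot(inherits(region, "filo_region"))
  crop <- region_crop(region$pixels, region$bbox, pad = 1L)
  d <- EBImage::imageData(EBImage::distmap(crop$m * 1))
  depth <- d[cbind(region$pixels[, 1L] - crop$roff,
                   region$pixels[, 2L] - crop$coff)]
  cb <- config$cortex_band_px
  sb <- config$separator_band_px
  in_cortex <- depth <= cb
  in_sep <- depth > cb & depth <= cb + sb
  in_int <- depth > cb + sb
  degenerate <- !any(in_int)
  if (degenerate) {
    in_int <- depth > cb
    in_sep <- rep(FALSE, length(depth))
  }
  structure(list(
    cortex = region$pixels[in_cortex, , drop = FALSE],
    separator = region$pixels[in_sep, , drop = FALSE],
    interior = region$pixels[in_int, , drop = FALSE],
    degenerate = degenerate,
    depth = depth
  ), class = "filo_zones")
}

#' @export
print.filo_zones <- function(x, ...) {
  cat("<filo_zones> cortex ", nrow(x$cortex), " px, separator ",
      nrow(x$separator), " px, interior ", nrow(x$interior), " px",
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Leading-edge patch of the cortex
#'
#' Locates the brightest cortex pixel and returns it together with its
#' `leading_edge_px - 1` nearest cortex pixels by Euclidean distance (the
#' whole cortex if it is smaller). Captures asymmetric cortical enrichment of
#' the tip marker. Ties in intensity, and ties in distance, are broken by
#' raster-scan order so the patch is deterministic.
#'
#' @param zones A `filo_zones`.
#' @param image A `filo_image` (tip-marker channel).
#' @param config A [filo_config()].
#' @return An n x 2 matrix of (row, col) coordinates.
#' @export
leading_edge <- function(zones, image, config = filo_config()) {
  cx <- zones$cortex
  if (nrow(cx) == 0L) return(cx)
  n <- min(config$leading_edge_px, nrow(cx))
  vals <- image$grid[cx]
  nc <- ncol(image$grid)
  scan <- (cx[, 1L] - 1) * nc + cx[, 2L]
  hot <- order(-vals, scan)[1L]
  d2 <- (cx[, 1L] - cx[hot, 1L])^2 + (cx[, 2L] - cx[hot, 2L])^2
  sel <- order(d2, scan)[seq_len(n)]
  cx[sel, , drop = FALSE]
}

#' Morphological shaving of protrusions
#'
#' Applies `rounds` of 3x3 square erosion followed by `rounds` of 3x3
#' dilation (a morphological opening of order `rounds`). Five rounds remove
#' thin filopodia stalks from a cell mask while approximately restoring the
#' body outline, isolating the cell-body pixels.
#'
#' @param binary_mask Logical or 0/1 matrix.
#' @param rounds Number of erosion (then dilation) rounds; 0 returns the
#'   input unchanged.
#' @return A logical matrix of the same shape.
#' @examples
#' m <- matrix(0, 20, 20); m[5:15, 5:15] <- 1
#' sum(shave_protrusions(m, 2)) <= sum(m)
#' @export
shave_protrusions <- function(binary_mask, rounds = 5) {
  stopifnot(rounds >= 0)
  m <- matrix(as.numeric(binary_mask != 0), nrow(binary_mask),
              ncol(binary_mask))
  if (rounds == 0 || !any(m > 0)) return(m > 0)
  kern <- EBImage::makeBrush(3, shape = "box")
  for (i in seq_len(rounds)) m <- EBImage::erode(m, kern)
  if (any(m > 0)) for (i in seq_len(rounds)) m <- EBImage::dilate(m, kern)
  matrix(m > 0.5, nrow(binary_mask), ncol(binary_mask))
}
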