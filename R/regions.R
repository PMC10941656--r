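# Connected objects from label masks.
#
# All pixel coordinates are (row, col), 1-based internally; user-facing
# tables export 0-based x = col - 1, y = row - 1 with row 0 at the top.
# Raster-scan order is row-major: (r, c) precedes (r, c + 1) and any (r + 1, .).

# 8-connected component labelling of a logical matrix. Components are
# numbered 1..k in raster-scan order of their first pixel. Implemented as a
# union over the 4 forward neighbour directions via igraph components;
# EBImage::bwlabel is 4-connected and unsuitable for 1-px diagonal structures.
label_components8 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  idx <- which(bin)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  id <- integer(nr * nc)
  id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (i in seq_along(offs)) {
    r2 <- r + offs[[i]][1L]; c2 <- cc + offs[[i]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- bin[j]
    if (any(keep)) edges[[i]] <- rbind(id[idx[ok][keep]], id[j[keep]])
  }
  edges <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, as.vector(edges))
  memb <- igraph::components(g)$membership
  # renumber by raster-scan order of each component's first pixel
  scan <- (r - 1L) * nc + cc
  first <- tapply(scan, memb, min)
  rank <- match(memb, as.integer(names(sort(first))))
  lab[idx] <- rank
  lab
}

#' Extract connected regions of one class from a label mask
#'
#' Finds the 8-connected components of `class_code` pixels with at least
#' `min_area_px` pixels. Region ids are assigned in raster-scan order of each
#' component's first pixel, starting at 1. Each region carries its pixel set,
#' its ordered outer boundary (a closed Moore-traced polyline), its edge
#' pixel set (all pixels touching non-region pixels, holes included) and its
#' bounding box.
#'
#' @param mask A `filo_mask`.
#' @param class_code Integer class code to extract.
#' @param min_area_px Minimum component size in pixels.
#' @return A list of `filo_region` objects (possibly empty).
#' @examples
#' g <- matrix(0L, 8, 8); g[2:4, 2:4] <- 1L; g[6:7, 6:7] <- 1L
#' m <- label_mask(g, c(background = 0, body = 1, tip = 2))
#' length(find_regions(m, 1L, min_area_px = 1))
#' @export
find_regions <- function(mask, class_code, min_area_px = 1) {
  stopifnot(inherits(mask, "filo_mask"))
  if (!class_code %in% mask$classes) {
    stop("class code ", class_code, " is not in the mask vocabulary",
         call. = FALSE)
  }
  bin <- mask$grid == class_code
  lab <- label_components8(bin)
  k <- max(lab)
  if (k == 0L) return(list())
  regions <- list()
  nxt <- 1L
  for (i in seq_len(k)) {
    pix_lin <- which(lab == i)
    if (length(pix_lin) < min_area_px) next
    nr <- nrow(bin)
    pr <- ((pix_lin - 1L) %% nr) + 1L
    pc <- ((pix_lin - 1L) %/% nr) + 1L
    pix <- cbind(row = pr, col = pc)
    regions[[nxt]] <- new_region(nxt, pix, dim(bin))
    nxt <- nxt + 1L
  }
  regions
}

new_region <- function(id, pixels, mask_dim) {
  bbox <- c(rmin = min(pixels[, 1L]), rmax = max(pixels[, 1L]),
            cmin = min(pixels[, 2L]), cmax = max(pixels[, 2L]))
  crop <- region_crop(pixels, bbox, pad = 1L)
  boundary <- moore_boundary(crop$m)
  boundary[, 1L] <- boundary[, 1L] + crop$roff
  boundary[, 2L] <- boundary[, 2L] + crop$coff
  edge <- region_edge(crop, pixels)
  structure(list(id = id, pixels = pixels, boundary = boundary, edge = edge,
                 bbox = bbox, mask_dim = mask_dim),
            class = "filo_region")
}

#' @export
print.filo_region <- function(x, ...) {
  cat("<filo_region> id ", x$id, ": ", nrow(x$pixels), " px, bbox rows ",
      x$bbox["rmin"], "-", x$bbox["rmax"], " cols ", x$bbox["cmin"], "-",
      x$bbox["cmax"], "\n", sep = "")
  invisible(x)
}

# logical matrix of the region within its padded bounding box;
# roff/coff translate cropped coords back: original = cropped + offset
region_crop <- function(pixels, bbox, pad = 1L) {
  roff <- bbox["rmin"] - 1L - pad
  coff <- bbox["cmin"] - 1L - pad
  m <- matrix(FALSE, bbox["rmax"] - bbox["rmin"] + 1L + 2L * pad,
              bbox["cmax"] - bbox["cmin"] + 1L + 2L * pad)
  m[cbind(pixels[, 1L] - roff, pixels[, 2L] - coff)] <- TRUE
  list(m = m, roff = unname(roff), coff = unname(coff))
}

# edge pixels: region pixels with at least one 4-neighbour outside the
# region (the standard inner boundary of an 8-connected region; keeps the
# edge one pixel thin on diagonals). Image border counts as outside via the
# crop pad.
region_edge <- function(crop, pixels) {
  m <- crop$m
  nr <- nrow(m); nc <- ncol(m)
  inner <- matrix(TRUE, nr, nc)
  for (o in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + o[1L]):min(nr, nr + o[1L])
    cs <- max(1L, 1L + o[2L]):min(nc, nc + o[2L])
    sh[rs, cs] <- m[rs - o[1L], cs - o[2L]]
    inner <- inner & sh
  }
  edge <- m & !inner
  w <- which(edge, arr.ind = TRUE)
  cbind(row = w[, 1L] + crop$roff, col = w[, 2L] + crop$coff)
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion on a
# logical matrix whose border is all FALSE. Returns the ordered closed outer
# boundary (start pixel not repeated at the end). A single pixel traces to
# itself.
moore_boundary <- function(m) {
  w <- which(m, arr.ind = TRUE)
  if (nrow(w) == 1L) return(cbind(row = w[1L, 1L], col = w[1L, 2L]))
  # start: topmost, then leftmost pixel; its W neighbour is background
  r0 <- min(w[, 1L])
  c0 <- min(w[w[, 1L] == r0, 2L])
  dirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)) # N..NW cw
  dir_index <- function(d) which(dirs[, 1L] == d[1L] & dirs[, 2L] == d[2L])
  start <- c(r0, c0)
  b0 <- start + c(0L, -1L)
  cur <- start; b <- b0
  pts <- matrix(0L, 4L * nrow(w) + 8L, 2L)
  pts[1L, ] <- start
  n <- 1L
  maxit <- 8L * nrow(w) + 16L
  for (it in seq_len(maxit)) {
    d0 <- dir_index(b - cur)
    moved <- FALSE
    for (k in 1:8) {
      d <- ((d0 + k - 1L) %% 8L) + 1L
      cand <- cur + dirs[d, ]
      if (m[cand[1L], cand[2L]]) {
        b <- cur + dirs[((d0 + k - 2L) %% 8L) + 1L, ]
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break # isolated pixel; cannot happen for a >1 px component
    if (cur[1L] == start[1L] && cur[2L] == start[2L] &&
        b[1L] == b0[1L] && b[2L] == b0[2L]) break
    n <- n + 1L
    if (n > nrow(pts)) pts <- rbind(pts, pts) # safety growth
    pts[n, ] <- cur
  }
  out <- pts[seq_len(n), , drop = FALSE]
  colnames(out) <- c("row", "col")
  out
}
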