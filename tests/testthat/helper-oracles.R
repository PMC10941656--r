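# Fixture builders and independent brute-force oracles used across tests.

# rasterized disc as a logical matrix
disc_mat <- function(dims, center, radius) {
  m <- matrix(FALSE, dims[1L], dims[2L])
  for (r in seq_len(dims[1L])) {
    dc2 <- radius^2 - (r - center[1L])^2
    if (dc2 < 0) next
    cs <- ceiling(center[2L] - sqrt(dc2)):floor(center[2L] + sqrt(dc2))
    cs <- cs[cs >= 1 & cs <= dims[2L]]
    m[r, cs] <- TRUE
  }
  m
}

mask_from_grid <- function(grid, classes = c(background = 0, body = 1, tip = 2)) {
  label_mask(grid, classes)
}

uniform_image <- function(dims, value = 100) {
  intensity_image(matrix(value, dims[1L], dims[2L]))
}

# queue-based BFS flood fill, 8-connected: the independent labelling oracle
flood_fill_labels <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (cc in seq_len(nc)) for (r in seq_len(nr)) {
    # scan column-major here; relabelling below is order-independent
    if (!bin[r, cc] || lab[r, cc] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- p[1L] + dr; c2 <- p[2L] + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        if (bin[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# canonicalise a labelling to sets of pixel index vectors for comparison
label_sets <- function(lab) {
  sets <- split(which(lab != 0L), lab[lab != 0L])
  unname(sets[order(vapply(sets, min, 0L))])
}

# geodesic shortest-path length over the pixels of a stalk (8-neighbour
# graph, axial weight 1, diagonal sqrt(2)) between the pixels nearest two
# anchor points
geodesic_oracle <- function(pixels, from_pt, to_pt) {
  n <- nrow(pixels)
  key <- paste(pixels[, 1L], pixels[, 2L])
  idx <- stats::setNames(seq_len(n), key)
  ed <- NULL
  wt <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- paste(pixels[, 1L] + dr, pixels[, 2L] + dc)
    hit <- !is.na(idx[nb])
    if (!any(hit)) next
    ed <- rbind(ed, cbind(which(hit), unname(idx[nb[hit]])))
    wt <- c(wt, rep(sqrt(dr^2 + dc^2), sum(hit)))
  }
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- wt
  g <- igraph::simplify(g, edge.attr.comb = "first")
  from <- which.min((pixels[, 1L] - from_pt[1L])^2 +
                      (pixels[, 2L] - from_pt[2L])^2)
  to <- which.min((pixels[, 1L] - to_pt[1L])^2 + (pixels[, 2L] - to_pt[2L])^2)
  igraph::distances(g, v = from, to = to)[1L, 1L]
}

# exhaustive tip assignment: scan every boundary pixel of every cell
assignment_oracle <- function(tip_centroid_rc, cell_objects) {
  best <- Inf; owner <- NA_integer_
  for (i in seq_along(cell_objects)) {
    b <- cell_objects[[i]]$region$boundary
    for (j in seq_len(nrow(b))) {
      d <- sqrt((b[j, 1L] - tip_centroid_rc[1L])^2 +
                  (b[j, 2L] - tip_centroid_rc[2L])^2)
      if (d < best - 1e-12) { best <- unname(d); owner <- i }
    }
  }
  list(owner = owner, distance = best)
}

# small scene parameter set used where full-size scenes would be slow
small_params <- function(...) {
  defaults <- list(image_size = 260, n_cells = 2, cell_radius = c(16, 22),
                   protrusions_per_cell = c(2, 5),
                   protrusion_length = c(10, 24))
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# longer stalks for shaft-length work: short stalks are dominated by
# rasterisation, curved filopodia worth tracing are tens of pixels long
skel_params <- function(...) {
  defaults <- list(image_size = 420, n_cells = 2, cell_radius = c(16, 22),
                   protrusions_per_cell = c(3, 4),
                   protrusion_length = c(30, 60))
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}
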