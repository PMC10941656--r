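# Segmentation-quality metrics and the correlation validation harness.

check_same_shape <- function(pred, truth) {
  if (!identical(dim(pred$grid), dim(truth$grid))) {
    stop("pred shape ", paste(dim(pred$grid), collapse = "x"),
         " differs from truth shape ",
         paste(dim(truth$grid), collapse = "x"), call. = FALSE)
  }
}

#' Per-class intersection-over-union (Jaccard index)
#'
#' Overlap between predicted and true pixel sets of one class, as the ratio
#' of their intersection to their union. `NA` when the union is empty (an
#' absent class should not poison macro averages).
#'
#' @param pred,truth `filo_mask`s of the same shape.
#' @param class_code Class to score.
#' @return A number in `[0, 1]`, or `NA`.
#' @export
class_iou <- function(pred, truth, class_code) {
  check_same_shape(pred, truth)
  p <- pred$grid == class_code
  t <- truth$grid == class_code
  u <- sum(p | t)
  if (u == 0L) return(NA_real_)
  sum(p & t) / u
}

#' Per-class pixel F1 (Dice) score
#'
#' `2 TP / (2 TP + FP + FN)` over pixels of the class; identically
#' `2 IoU / (1 + IoU)`. `NA` when both masks lack the class.
#'
#' @inheritParams class_iou
#' @return A number in `[0, 1]`, or `NA`.
#' @export
class_f1 <- function(pred, truth, class_code) {
  check_same_shape(pred, truth)
  p <- pred$grid == class_code
  t <- truth$grid == class_code
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0L) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Panoptic quality of one class
#'
#' Instances are the 8-connected components of the class in each mask (the
#' way to instantiate instance scoring from semantic output). A predicted and
#' a true instance match when their pairwise IoU exceeds `match_iou`
#' (default 0.5, which makes the matching unique). Then
#' `PQ = sum(matched IoU) / (TP + FP/2 + FN/2)`.
#'
#' @inheritParams class_iou
#' @param match_iou Matching threshold on pairwise instance IoU.
#' @return A list: `pq`, `tp`, `fp`, `fn`, `matched_iou` (vector). `pq` is
#'   `NA` when neither mask has an instance of the class.
#' @export
panoptic_quality <- function(pred, truth, class_code, match_iou = 0.5) {
  check_same_shape(pred, truth)
  lp <- label_components8(pred$grid == class_code)
  lt <- label_components8(truth$grid == class_code)
  np <- max(lp); nt <- max(lt)
  if (np == 0L && nt == 0L) {
    return(list(pq = NA_real_, tp = 0L, fp = 0L, fn = 0L,
                matched_iou = numeric()))
  }
  matched <- numeric()
  if (np > 0L && nt > 0L) {
    both <- lp > 0L & lt > 0L
    if (any(both)) {
      inter <- table(lp[both], lt[both])
      ap <- tabulate(lp[lp > 0L], np)
      at <- tabulate(lt[lt > 0L], nt)
      for (i in rownames(inter)) for (j in colnames(inter)) {
        ov <- inter[i, j]
        if (ov == 0) next
        iou <- ov / (ap[as.integer(i)] + at[as.integer(j)] - ov)
        if (iou > match_iou) matched <- c(matched, iou)
      }
    }
  }
  tp <- length(matched)
  fp <- np - tp
  fn <- nt - tp
  list(pq = sum(matched) / (tp + fp / 2 + fn / 2), tp = tp, fp = fp, fn = fn,
       matched_iou = matched)
}

#' Evaluate a predicted mask against ground truth
#'
#' Per-class IoU, F1 and panoptic quality, plus a macro-average row over the
#' scored (non-background) classes.
#'
#' @inheritParams class_iou
#' @param classes Integer class codes to score (background excluded by
#'   default).
#' @return A tibble with columns class, iou, f1, pq, tp, fp, fn; the last row
#'   is the macro average (`class = NA`).
#' @export
evaluate_masks <- function(pred, truth,
                           classes = setdiff(unname(truth$classes), 0L)) {
  rows <- lapply(classes, function(cl) {
    pano <- panoptic_quality(pred, truth, cl)
    tibble::tibble(class = cl, iou = class_iou(pred, truth, cl),
                   f1 = class_f1(pred, truth, cl), pq = pano$pq,
                   tp = pano$tp, fp = pano$fp, fn = pano$fn)
  })
  per <- dplyr::bind_rows(rows)
  macro <- tibble::tibble(
    class = NA_integer_,
    iou = mean(per$iou, na.rm = TRUE), f1 = mean(per$f1, na.rm = TRUE),
    pq = mean(per$pq, na.rm = TRUE),
    tp = sum(per$tp), fp = sum(per$fp), fn = sum(per$fn)
  )
  dplyr::bind_rows(per, macro)
}

#' Pearson correlation validation
#'
#' Two-sided Pearson product-moment correlation between paired measurement
#' vectors (e.g. automated vs manual filopodia counts), with the p-value from
#' the usual t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. The p-value is reported, never thresholded here.
#' Degenerate input (fewer than 3 pairs, or zero variance) yields missing
#' values with a reason.
#'
#' @param x,y Equal-length numeric vectors.
#' @return A one-row tibble: `r`, `p`, `n`, `reason`.
#' @examples
#' pearson_validate(1:4, c(2, 4, 6, 8))
#' @export
pearson_validate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                          reason = "fewer than 3 complete pairs"))
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                          reason = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                 reason = NA_character_)
}
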