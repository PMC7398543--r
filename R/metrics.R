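#' Jaccard index between two binary masks
#'
#' `|I ∩ I'| / |I ∪ I'|` over pixel sets. When both masks are empty the
#' index is defined as 1 (perfect agreement on absence) — callers that need
#' to distinguish that case should test emptiness, as [evaluate_segmentation()]
#' does via its `both_empty` flag.
#'
#' @param a,b Logical (or 0/1) matrices of equal shape.
#' @return Value in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  ab <- check_masks(a, b)
  uni <- sum(ab$a | ab$b)
  if (uni == 0L) return(1)
  sum(ab$a & ab$b) / uni
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |I ∩ I'| / (|I| + |I'|)`; algebraically `2 JI / (1 + JI)`. Both masks
#' empty is defined as 1, as for [jaccard()].
#'
#' @inheritParams jaccard
#' @return Value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ab <- check_masks(a, b)
  tot <- sum(ab$a) + sum(ab$b)
  if (tot == 0L) return(1)
  2 * sum(ab$a & ab$b) / tot
}

check_masks <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop_validation("mask shapes differ: %s vs %s",
                    paste(dim(a), collapse = "x"),
                    paste(dim(b), collapse = "x"))
  list(a = a != 0, b = b != 0)
}

#' Hausdorff distance between two binary masks
#'
#' The larger of the two directed maxima of Euclidean nearest-point
#' distances over the masks' pixel coordinates (row/column units): the
#' smallest `d` such that every point of each set has a point of the other
#' within `d`. Computed on the full masks, exactly as defined — not a
#' boundary or percentile variant. Symmetric, and 0 iff the masks coincide.
#' If either mask is empty the distance is undefined and `NaN` is returned
#' with a warning, never a silent 0.
#'
#' @inheritParams jaccard
#' @return Distance in pixels, or `NaN` if either mask is empty.
#' @export
#' @examples
#' a <- matrix(FALSE, 5, 5); a[1, 1] <- TRUE
#' b <- matrix(FALSE, 5, 5); b[4, 5] <- TRUE
#' hausdorff(a, b)  # 5: the 3-4-5 triangle
hausdorff <- function(a, b) {
  ab <- check_masks(a, b)
  pa <- which(ab$a, arr.ind = TRUE)
  pb <- which(ab$b, arr.ind = TRUE)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    warning("Hausdorff distance undefined for an empty mask; returning NaN")
    return(NaN)
  }
  .hausdorff_points(matrix(as.numeric(pa), ncol = 2L),
                    matrix(as.numeric(pb), ncol = 2L))
}

#' Mean squared error between two label maps
#'
#' `(1/MN) * sum((I - I')^2)` over the integer class labels themselves.
#' Note this makes the value depend on the class coding (0 background,
#' 1 CSF, 2 GM, 3 WM): confusing CSF with WM costs more than confusing CSF
#' with GM. It is reported as a whole-map summary alongside the per-class
#' overlap metrics.
#'
#' @param a,b Integer label matrices of equal shape.
#' @return Non-negative value.
#' @export
label_mse <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)))
    stop_validation("label map shapes differ: %s vs %s",
                    paste(dim(a), collapse = "x"),
                    paste(dim(b), collapse = "x"))
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Evaluate a predicted segmentation against ground truth
#'
#' Derives per-class binary masks from the two label maps and reports Dice,
#' Jaccard and Hausdorff distance for each tissue class (CSF, GM, WM;
#' background is excluded from per-class reporting), plus the whole-map
#' label MSE. A class absent from both maps scores DSC = JI = 1 and an
#' undefined (NA) Hausdorff distance, with `both_empty = TRUE` so the
#' condition is never hidden.
#'
#' @param pred,gt Integer label matrices (classes `0:(n_classes-1)`).
#' @param n_classes Number of classes including background (default 4).
#' @return A `seg_report`: list with `per_class` (tibble: class, dice,
#'   jaccard, hausdorff, pixel counts, `both_empty`) and `mse`.
#' @export
evaluate_segmentation <- function(pred, gt, n_classes = 4L) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  if (!identical(dim(pred), dim(gt)))
    stop_validation("prediction and ground truth shapes differ")
  cls <- tissue_classes()
  tissues <- cls[cls > 0 & cls < n_classes]
  rows <- lapply(names(tissues), function(nm) {
    c0 <- tissues[[nm]]
    mp <- pred == c0; mg <- gt == c0
    empty <- !any(mp) && !any(mg)
    hd <- if (empty || !any(mp) || !any(mg)) NA_real_
          else hausdorff(mg, mp)
    tibble::tibble(class = nm,
                   dice = dice(mg, mp),
                   jaccard = jaccard(mg, mp),
                   hausdorff = hd,
                   gt_pixels = sum(mg),
                   pred_pixels = sum(mp),
                   both_empty = empty)
  })
  structure(list(per_class = do.call(rbind, rows),
                 mse = label_mse(gt, pred),
                 shape = dim(gt)),
            class = "seg_report")
}

#' @export
print.seg_report <- function(x, ...) {
  cat(sprintf("<seg_report> %s, MSE %.4f\n",
              paste(x$shape, collapse = "x"), x$mse))
  print(x$per_class)
  invisible(x)
}

#' @rdname evaluate_segmentation
#' @param x A `seg_report`.
#' @param ... Unused.
#' @export
tidy.seg_report <- function(x, ...) x$per_class

#' @rdname evaluate_segmentation
#' @export
glance.seg_report <- function(x, ...) {
  tibble::tibble(mean_dice = mean(x$per_class$dice),
                 mean_jaccard = mean(x$per_class$jaccard),
                 mean_hausdorff = mean(x$per_class$hausdorff, na.rm = TRUE),
                 mse = x$mse)
}

#' Aggregate per-slice evaluations
#'
#' Evaluates each prediction/truth pair and reports, per tissue class, the
#' mean and standard deviation of DSC, JI and HD across slices (HD over the
#' slices where it is defined), plus mean MSE — the usual
#' mean-plus-minus-sd presentation for a test set.
#'
#' @param preds,gts Lists of label matrices, pairwise comparable.
#' @param n_classes Number of classes including background.
#' @return List with `summary` (tibble) and `per_slice` (tibble of every
#'   slice/class value, from which the summary is recomputable).
#' @export
evaluate_slices <- function(preds, gts, n_classes = 4L) {
  stopifnot(length(preds) == length(gts), length(preds) > 0L)
  per <- lapply(seq_along(preds), function(i) {
    r <- evaluate_segmentation(preds[[i]], gts[[i]], n_classes)
    cbind(tibble::tibble(slice = i), r$per_class,
          tibble::tibble(mse = r$mse))
  })
  per <- do.call(rbind, per)
  agg <- lapply(split(per, per$class), function(d) {
    tibble::tibble(class = d$class[1L],
                   dice_mean = mean(d$dice), dice_sd = sd(d$dice),
                   jaccard_mean = mean(d$jaccard), jaccard_sd = sd(d$jaccard),
                   hausdorff_mean = mean(d$hausdorff, na.rm = TRUE),
                   hausdorff_sd = sd(d$hausdorff, na.rm = TRUE),
                   n_slices = nrow(d))
  })
  agg <- do.call(rbind, agg)
  agg <- agg[order(match(agg$class, c("CSF", "GM", "WM"))), ]
  list(summary = tibble::as_tibble(agg),
       mse_mean = mean(per$mse[!duplicated(per$slice)]),
       per_slice = tibble::as_tibble(per))
}
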