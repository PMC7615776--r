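# Segmentation evaluation: per-class Dice, Hausdorff distance (maximum and
# 95th-percentile variants on 4-connected boundary pixels, in pixel units),
# brain-tumour region label algebra, and the composite training loss.

#' Dice similarity coefficient for one class
#'
#' `2|A n B| / (|A| + |B|)` on the binary masks of class `cls`. When the
#' class is absent from both masks the score is 1 (perfect agreement on
#' absence); when absent from exactly one, 0.
#'
#' @param pred,gt integer label masks of identical shape (class ids from 0).
#' @param cls class id to score.
#' @return numeric in \[0, 1\].
#' @export
dice_coefficient <- function(pred, gt, cls) {
  if (!all(dim(pred) == dim(gt))) {
    stop("prediction and reference masks differ in shape")
  }
  a <- pred == cls
  b <- gt == cls
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# 4-connected boundary of a logical mask: a foreground pixel with at least
# one background (or out-of-image) 4-neighbour
.boundary <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1)] & pad[3:(d[1] + 2), 2:(d[2] + 1)] &
    pad[2:(d[1] + 1), 1:d[2]] & pad[2:(d[1] + 1), 3:(d[2] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

# directed nearest-boundary distances from each point of A to the set B
.directed_dists <- function(A, B) {
  dr <- outer(A[, 1], B[, 1], `-`)
  dc <- outer(A[, 2], B[, 2], `-`)
  sqrt(apply(dr * dr + dc * dc, 1, min))
}

#' Hausdorff distance between two class regions
#'
#' Boundary pixels (4-connectivity) of the two binary masks are extracted
#' and the symmetric Hausdorff distance computed from the two directed
#' nearest-neighbour distance sets: the maximum (`percentile = 100`) or the
#' maximum of the two directed 95th percentiles (`percentile = 95`, the
#' common HD95 variant). Units are pixels.
#'
#' @param pred,gt integer label masks of identical shape.
#' @param cls class id.
#' @param percentile 100 (classic) or 95 (HD95).
#' @return numeric >= 0, or `NA_real_` (with a message) when the class is
#'   empty in either mask - undefined distances are excluded from averages.
#' @export
hausdorff <- function(pred, gt, cls, percentile = 95) {
  if (!all(dim(pred) == dim(gt))) {
    stop("prediction and reference masks differ in shape")
  }
  stopifnot(percentile %in% c(95, 100))
  A <- .boundary(pred == cls)
  B <- .boundary(gt == cls)
  if (nrow(A) == 0 || nrow(B) == 0) {
    message("hausdorff undefined for class ", cls,
            " (empty region); excluded from averages")
    return(NA_real_)
  }
  dab <- .directed_dists(A, B)
  dba <- .directed_dists(B, A)
  if (percentile == 100) {
    max(max(dab), max(dba))
  } else {
    max(stats::quantile(dab, 0.95, names = FALSE),
        stats::quantile(dba, 0.95, names = FALSE))
  }
}

#' Combine brain-tumour labels into evaluation regions
#'
#' From the 4-class convention (0 background, 1 necrotic/non-enhancing core
#' NCR/NET, 2 peritumoral edema ED, 3 enhancing tumour ET) build the three
#' nested evaluation regions: whole tumour WT = NCR/NET + ED + ET, tumour
#' core TC = NCR/NET + ET, and ET alone, so WT >= TC >= ET as sets.
#'
#' @param mask integer mask with values in `{0, 1, 2, 3}`.
#' @param labels named integer vector mapping `ncr_net`, `ed`, `et` to ids.
#' @return list of logical masks `WT`, `TC`, `ET`.
#' @export
combine_tumor_regions <- function(mask,
                                  labels = c(ncr_net = 1L, ed = 2L, et = 3L)) {
  allowed <- c(0L, unname(labels))
  bad <- setdiff(unique(as.vector(mask)), allowed)
  if (length(bad)) {
    stop("unexpected label id(s) in mask: ", paste(bad, collapse = ", "))
  }
  list(WT = mask == labels[["ncr_net"]] | mask == labels[["ed"]] |
            mask == labels[["et"]],
       TC = mask == labels[["ncr_net"]] | mask == labels[["et"]],
       ET = mask == labels[["et"]])
}

## ---- training loss --------------------------------------------------------

# composite loss on an (N x K) logits node and 1-based target vector:
# w_ce * cross-entropy + w_dice * (1 - mean soft Dice over classes)
.seg_loss <- function(logits, target, K, w_ce = 0.5, w_dice = 0.5,
                      eps = 1e-6) {
  ce <- ag_cross_entropy(logits, target)
  P <- ag_softmax_rows(logits)
  Tm <- matrix(0, length(target), K)
  Tm[cbind(seq_along(target), target)] <- 1
  inter <- ag_colsums(ag_mul(P, ag(Tm)))
  sums <- ag_add(ag_colsums(P), ag(colSums(Tm)))
  dice <- ag_div(ag_shift(ag_scale(inter, 2), eps), ag_shift(sums, eps))
  dice_loss <- ag_shift(ag_scale(ag_mean(dice), -1), 1)
  ag_add(ag_scale(ce, w_ce), ag_scale(dice_loss, w_dice))
}

#' Composite segmentation training loss
#'
#' `w_ce * pixelwise cross-entropy + w_dice * (1 - mean soft Dice)`, the
#' soft Dice being computed per class on the softmax probabilities over all
#' classes (background included). Approaches 0 only as the prediction tends
#' to the perfect one-hot labelling.
#'
#' @param logits numeric array `num_classes x H x W`.
#' @param gt integer mask `H x W` with class ids in `0..num_classes-1`.
#' @param w_ce,w_dice loss weights (default 0.5 / 0.5).
#' @return scalar loss value.
#' @export
training_loss <- function(logits, gt, w_ce = 0.5, w_dice = 0.5) {
  d <- dim(logits)
  K <- d[1]
  if (!all(dim(gt) == d[2:3])) stop("logits and mask shapes disagree")
  if (any(gt < 0L) || any(gt >= K)) {
    stop("class id out of range 0..", K - 1L)
  }
  lmat <- matrix(aperm(logits, c(2, 3, 1)), d[2] * d[3], K)
  target <- as.vector(gt) + 1L
  as.numeric(ag_value(ag_no_grad(
    .seg_loss(ag(lmat), target, K, w_ce, w_dice))))
}

## ---- evaluation reports ---------------------------------------------------

#' Per-class and mean metrics for one predicted mask
#'
#' Scores every foreground class (background 0 excluded from all averages)
#' with Dice and Hausdorff; undefined Hausdorff values (class empty in
#' either mask) are dropped from the mean.
#'
#' @param pred,gt integer masks `H x W`.
#' @param num_classes total class count including background.
#' @param percentile Hausdorff percentile (95 or 100).
#' @return list with `dsc` and `hd` vectors (length `num_classes - 1`),
#'   `mean_dsc`, `mean_hd`.
#' @export
evaluate_masks <- function(pred, gt, num_classes, percentile = 95) {
  cls <- seq_len(num_classes - 1L)
  dsc <- vapply(cls, function(k) dice_coefficient(pred, gt, k), numeric(1))
  hd <- vapply(cls, function(k)
    suppressMessages(hausdorff(pred, gt, k, percentile)), numeric(1))
  list(dsc = dsc, hd = hd,
       mean_dsc = mean(dsc),
       mean_hd = if (all(is.na(hd))) NA_real_ else mean(hd, na.rm = TRUE))
}

#' Write a metrics report as CSV and JSON
#'
#' @param report data.frame with one row per case (as produced by
#'   [dsga_evaluate()]).
#' @param path_prefix files `<prefix>.csv` and `<prefix>.json` are written.
#' @return invisible list of the two paths.
#' @export
write_metrics <- function(report, path_prefix) {
  csv <- paste0(path_prefix, ".csv")
  jsn <- paste0(path_prefix, ".json")
  utils::write.csv(report, csv, row.names = FALSE)
  summary <- list(
    n_cases = nrow(report),
    mean_dsc = mean(report$mean_dsc),
    mean_hd = if (all(is.na(report$mean_hd))) NA_real_
              else mean(report$mean_hd, na.rm = TRUE)
  )
  jsonlite::write_json(summary, jsn, auto_unbox = TRUE, digits = NA)
  invisible(list(csv = csv, json = jsn))
}
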