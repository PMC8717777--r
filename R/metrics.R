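# Stroke-challenge evaluation metrics: Dice coefficient, Hausdorff distance
# and average symmetric surface distance, all with physical pixel spacing.

check_binary_mask <- function(m, arg = "mask") {
  if (!is.matrix(m)) stop(arg, " must be a matrix")
  if (!all(m %in% c(0, 1))) stop(arg, " must be binary (0/1)")
  invisible(m)
}

#' Dice similarity coefficient between two binary masks
#'
#' Computes `2 |X ∩ Y| / (|X| + |Y|)`. When both masks are empty the
#' coefficient is returned as 1 by convention (empty-vs-empty is a perfect
#' match) and the result carries the attribute `both_empty = TRUE`.
#'
#' @param pred,truth binary matrices of equal dimensions.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth) {
  check_binary_mask(pred, "pred")
  check_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    stop("dice_coefficient: mask shapes differ (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), ")")
  }
  sp <- sum(pred)
  st <- sum(truth)
  if (sp + st == 0) {
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(pred * truth) / (sp + st)
}

#' Extract the surface (boundary) pixels of a binary mask
#'
#' A surface pixel is a foreground pixel with at least one background pixel
#' among its 8-neighbours; pixels on the image border count as adjacent to
#' background. This is the surface definition used by the distance metrics.
#'
#' @param mask binary matrix.
#' @param spacing_mm isotropic pixel spacing in millimetres.
#' @return A list with `points` (n x 2 integer matrix of row/col indices,
#'   1-based) and `spacing_mm`.
#' @export
extract_surface <- function(mask, spacing_mm = 1) {
  check_binary_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(0, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- mask
  nmin <- matrix(1, H, W)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- padded[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
      nmin <- pmin(nmin, nb)
    }
  }
  surf <- mask == 1 & nmin == 0
  idx <- which(surf, arr.ind = TRUE)
  colnames(idx) <- c("row", "col")
  list(points = idx, spacing_mm = spacing_mm)
}

surface_dist_matrix <- function(a, b) {
  # full pairwise Euclidean distances between two surface point sets (pixels)
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

empty_mask_sentinel <- function(which) {
  warning("empty mask: surface distance undefined for ", which,
          "; returning NA (excluded from aggregates)", call. = FALSE)
  structure(NA_real_, empty_mask = TRUE)
}

#' Hausdorff distance between two binary masks (mm)
#'
#' Maximum over both directed maxima of nearest-surface-point distances
#' between the boundary point sets of `pred` and `truth`, scaled by the
#' isotropic pixel spacing. Symmetric; zero iff the surfaces coincide.
#' An empty mask yields `NA` with a warning (the metric is undefined).
#'
#' @inheritParams dice_coefficient
#' @param spacing_mm isotropic pixel spacing in millimetres.
#' @export
hausdorff_distance <- function(pred, truth, spacing_mm = 1) {
  sp <- extract_surface(pred)$points
  st <- extract_surface(truth)$points
  if (nrow(sp) == 0 || nrow(st) == 0) {
    return(empty_mask_sentinel(if (nrow(sp) == 0) "pred" else "truth"))
  }
  D <- surface_dist_matrix(sp, st)
  max(max(apply(D, 1, min)), max(apply(D, 2, min))) * spacing_mm
}

#' Average symmetric surface distance between two binary masks (mm)
#'
#' Mean of nearest-surface distances from each boundary point of `pred` to
#' `truth` and vice versa, averaged over both directions and scaled by pixel
#' spacing. Symmetric in its mask arguments.
#'
#' @inheritParams hausdorff_distance
#' @export
assd <- function(pred, truth, spacing_mm = 1) {
  sp <- extract_surface(pred)$points
  st <- extract_surface(truth)$points
  if (nrow(sp) == 0 || nrow(st) == 0) {
    return(empty_mask_sentinel(if (nrow(sp) == 0) "pred" else "truth"))
  }
  D <- surface_dist_matrix(sp, st)
  0.5 * (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) * spacing_mm
}

#' Evaluate predicted masks against ground truth, case by case
#'
#' Produces the challenge-style report: per-case Dice, Hausdorff distance and
#' average symmetric surface distance (both in mm), plus a mean/sd summary.
#' Cases where either mask is empty are flagged: they contribute to the Dice
#' aggregate but are excluded from the HD/ASSD means, mirroring how surface
#' distances are undefined on empty segmentations.
#'
#' @param predictions named list of binary matrices (names are case ids).
#' @param truths named list of binary matrices with matching names.
#' @param spacing_mm isotropic pixel spacing in millimetres.
#' @return List with `per_case` (data.frame: case_id, dc, hd_mm, assd_mm,
#'   empty_flag) and `summary` (data.frame: metric, mean, sd, n).
#' @export
evaluate_cases <- function(predictions, truths, spacing_mm = 1) {
  ids_p <- names(predictions)
  ids_t <- names(truths)
  if (is.null(ids_p) || is.null(ids_t)) {
    stop("predictions and truths must be named lists keyed by case_id")
  }
  unmatched <- c(setdiff(ids_p, ids_t), setdiff(ids_t, ids_p))
  if (length(unmatched) > 0) {
    stop("unmatched case ids: ", paste(unique(unmatched), collapse = ", "))
  }
  per <- lapply(ids_p, function(id) {
    p <- predictions[[id]]
    tr <- truths[[id]]
    dc <- dice_coefficient(p, tr)
    empty <- sum(p) == 0 || sum(tr) == 0
    if (empty) {
      hd <- NA_real_; as_ <- NA_real_
    } else {
      hd <- hausdorff_distance(p, tr, spacing_mm)
      as_ <- assd(p, tr, spacing_mm)
    }
    data.frame(case_id = id, dc = as.numeric(dc), hd_mm = hd, assd_mm = as_,
               empty_flag = empty, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  summarise <- function(x) {
    x <- x[!is.na(x)]
    data.frame(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
               n = length(x))
  }
  summary <- cbind(metric = c("dc", "hd_mm", "assd_mm"),
                   rbind(summarise(per$dc), summarise(per$hd_mm),
                         summarise(per$assd_mm)))
  list(per_case = per, summary = summary)
}

#' Write a per-case metrics table plus MEAN/SD rows to CSV
#'
#' @param report result of [evaluate_cases()].
#' @param path output CSV path.
#' @export
write_metrics_csv <- function(report, path) {
  per <- report$per_case
  s <- report$summary
  mean_row <- data.frame(case_id = "MEAN", dc = s$mean[1], hd_mm = s$mean[2],
                         assd_mm = s$mean[3], empty_flag = NA)
  sd_row <- data.frame(case_id = "SD", dc = s$sd[1], hd_mm = s$sd[2],
                       assd_mm = s$sd[3], empty_flag = NA)
  utils::write.csv(rbind(per, mean_row, sd_row), path, row.names = FALSE)
  invisible(path)
}
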