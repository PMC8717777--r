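# The three training losses and their mixed combination.
#
# The segmentation branch minimises a soft Dice loss on labeled slices; the
# reconstruction branch minimises mean squared error plus a generator-side
# adversarial cross-entropy, while the discriminator minimises its own
# real-vs-reconstructed cross-entropy. The mixed objective couples the two
# branches with a weight lambda on the reconstruction term, so lambda = 0
# recovers a purely supervised segmenter.

CE_CLAMP <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, CE_CLAMP), 1 - CE_CLAMP)

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)`.
#' With `smooth = 0` and a nonzero denominator the value lies in `[0, 1]`.
#' When both `pred` and `target` are all-zero and `smooth = 0` the loss is 0
#' by convention (an empty prediction of an empty mask is a perfect match);
#' a message notes the convention.
#'
#' @param pred matrix (or array) of foreground probabilities in `[0, 1]`.
#' @param target binary mask of the same shape.
#' @param smooth nonnegative smoothing constant; the trainer uses 1 for
#'   stability on empty masks, reporting uses 0.
#' @return Scalar loss.
#' @export
soft_dice_loss <- function(pred, target, smooth = 0) {
  if (!all(dim(pred) == dim(target))) stop("soft_dice_loss: shape mismatch")
  if (min(pred) < 0 || max(pred) > 1) {
    stop("soft_dice_loss: pred must contain probabilities in [0, 1]")
  }
  if (smooth < 0) stop("smooth must be nonnegative")
  den <- sum(pred) + sum(target) + smooth
  if (den == 0) {
    message("soft_dice_loss: empty prediction and target; returning 0 by convention")
    return(0)
  }
  1 - (2 * sum(pred * target) + smooth) / den
}

check_prob_pairs <- function(p, arg) {
  if (is.null(dim(p)) && length(p) == 2) p <- matrix(p, 1, 2)
  if (!is.matrix(p) || ncol(p) != 2) {
    stop(arg, " must be an n x 2 matrix of probability pairs")
  }
  if (any(abs(rowSums(p) - 1) > 1e-4)) {
    stop(arg, ": probability pairs must sum to 1 (within 1e-4)")
  }
  p
}

#' Reconstruction loss: MSE plus adversarial terms
#'
#' The generator side is what the reconstruction branch minimises: the mean
#' squared error between the reconstruction and the input plus an adversarial
#' cross-entropy pushing the discriminator to call reconstructions real. The
#' discriminator side is the usual real-vs-fake cross-entropy it minimises in
#' its own update. Probability pairs are columns `(P(reconstructed), P(real))`
#' and are clamped to `[1e-7, 1 - 1e-7]` before the log.
#'
#' @param x input batch (any numeric array).
#' @param r_out reconstruction of the same shape.
#' @param d_on_fake,d_on_real n x 2 matrices of discriminator probability
#'   pairs on reconstructed and on real images.
#' @param adv_weight weight of the generator-side adversarial term.
#' @return List with `generator_side` and `discriminator_side` scalars and the
#'   `mse` component.
#' @export
reconstruction_loss <- function(x, r_out, d_on_fake, d_on_real,
                                adv_weight = 1) {
  if (!all(dim(x) == dim(r_out))) stop("reconstruction_loss: shape mismatch")
  d_on_fake <- check_prob_pairs(d_on_fake, "d_on_fake")
  d_on_real <- check_prob_pairs(d_on_real, "d_on_real")
  mse <- mean((r_out - x)^2)
  ce_real_label <- function(p) mean(-log(clamp_prob(p[, 2])))  # label = real
  ce_fake_label <- function(p) mean(-log(clamp_prob(p[, 1])))  # label = fake
  list(
    generator_side = mse + adv_weight * ce_real_label(d_on_fake),
    discriminator_side = ce_real_label(d_on_real) + ce_fake_label(d_on_fake),
    mse = mse
  )
}

#' Mixed co-optimization loss
#'
#' `loss_s + lam * loss_r`: the supervised Dice loss plus the
#' reconstruction branch's generator-side loss weighted by `lam`. With
#' `lam = 0` the reconstruction branch does not contribute and the objective
#' is exactly the supervised segmentation loss.
#'
#' @param loss_s supervised segmentation loss.
#' @param loss_r_generator generator-side reconstruction loss.
#' @param lam nonnegative weight of the reconstruction term.
#' @export
mix_loss <- function(loss_s, loss_r_generator, lam) {
  stopifnot(is.finite(loss_s), is.finite(loss_r_generator), lam >= 0)
  loss_s + lam * loss_r_generator
}
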