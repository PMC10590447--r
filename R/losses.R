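# The loss system of the adversarial autoencoder, exposed as pure functions
# so each term can be inspected and tested in isolation. All probabilities
# are clamped to [1e-9, 1 - 1e-9] before any logarithm, so every loss is
# finite even on saturated outputs.

#' Binary cross-entropy against a constant label
#'
#' @param p Vector or matrix of predicted probabilities in (0, 1).
#' @param label Target label, 0 or 1.
#' @return Mean binary cross-entropy over all elements.
#' @export
binary_cross_entropy <- function(p, label) {
  p <- clamp_prob(p)
  mean(-label * log(p) - (1 - label) * log(1 - p))
}

#' Reconstruction loss: abundance cross-entropy plus composition MSE
#'
#' The abundance head reconstructs a per-contig distribution over samples,
#' scored by cross-entropy `-sum(A_in * log(A_out))` per row, batch-averaged;
#' the composition head is scored by elementwise mean squared error. The two
#' terms are weighted by `w_coab` and `w_tnf`.
#'
#' @param a_in,a_out Batch x S abundance matrices; `a_in` rows sum to one.
#' @param t_in,t_out Batch x 103 composition matrices.
#' @param w_coab,w_tnf Nonnegative term weights.
#' @return List with components `L_rec`, `CE` and `MSE`.
#' @export
reconstruction_loss <- function(a_in, a_out, t_in, t_out, w_coab, w_tnf) {
  ce <- mean(rowSums(-a_in * log(clamp_prob(a_out))))
  mse <- mean((t_in - t_out)^2)
  list(L_rec = w_coab * ce + w_tnf * mse, CE = ce, MSE = mse)
}

#' Discriminator loss on a latent/prior sample pair
#'
#' The discriminator is pushed to output 0 on codes coming from the encoder
#' and 1 on samples drawn from the prior:
#' `1/2 BCE(D(latent), 0) + 1/2 BCE(D(prior), 1)`.
#'
#' @param p_latent Discriminator probabilities on encoder codes.
#' @param p_prior Discriminator probabilities on prior samples.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(p_latent, p_prior) {
  0.5 * binary_cross_entropy(p_latent, 0) +
    0.5 * binary_cross_entropy(p_prior, 1)
}

#' Encoder regularisation loss
#'
#' The encoder is pushed to fool both discriminators; its adversarial terms
#' are `LRz = BCE(D_z(z), 1)` and `LRy = BCE(D_y(y), 1)`, mixed by `slr`:
#' `L_reg = (1 - slr) * LRz + slr * LRy`.
#'
#' @param p_z,p_y Discriminator probabilities on the continuous and
#'   categorical codes of the batch.
#' @param slr Mixing weight in `[0, 1]`.
#' @return List with components `L_reg`, `LRz`, `LRy`.
#' @export
regularization_loss <- function(p_z, p_y, slr) {
  lrz <- binary_cross_entropy(p_z, 1)
  lry <- binary_cross_entropy(p_y, 1)
  list(L_reg = (1 - slr) * lrz + slr * lry, LRz = lrz, LRy = lry)
}

#' Total model loss
#'
#' `L = (1 - sl) * L_rec + sl * L_reg`.
#'
#' @param l_rec Reconstruction loss.
#' @param l_reg Regularisation loss.
#' @param sl Mixing weight in `[0, 1]`.
#' @return Scalar loss.
#' @export
total_loss <- function(l_rec, l_reg, sl) {
  (1 - sl) * l_rec + sl * l_reg
}

#' Draw relaxed one-hot categorical (Gumbel-softmax) samples
#'
#' Adds Gumbel noise to the logits and applies a temperature-scaled softmax.
#' Rows sum to one; as `tau -> 0` the samples approach one-hot vectors.
#'
#' @param logits Batch x K matrix of (unnormalised) log-probabilities.
#' @param tau Temperature, > 0.
#' @return Batch x K matrix of relaxed samples.
#' @export
gumbel_softmax <- function(logits, tau) {
  stopifnot(tau > 0)
  u <- matrix(runif(length(logits)), nrow(logits), ncol(logits))
  g <- -log(-log(pmax(u, 1e-12)))
  softmax_rows((logits + g) / tau)
}
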