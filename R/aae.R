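# The adversarial autoencoder: a continuous Gaussian code z and a
# categorical code y, jointly trained to reconstruct [TNF, Coab] input
# vectors while two discriminators push the codes toward their priors
# (standard normal for z, relaxed one-hot categorical for y).

#' Adversarial autoencoder configuration
#'
#' Defaults are the model as tuned for full-scale metagenome catalogues:
#' two hidden layers of 547 units, a 283-dimensional continuous code, a
#' 700-category categorical code, temperature `tau = 0.1596`,
#' reconstruction/regularisation mix `sl = 0.0964` and z/y regularisation
#' mix `slr = 0.5`. `n_y` should be set to roughly the expected taxonomic
#' diversity of the catalogue; desk-scale runs shrink all dimensions.
#'
#' The reconstruction weights default to `w_coab = 0.85 / log(S)` (kept
#' scale-stable as the number of samples grows) and `w_tnf = 0.15 / 103`,
#' mirroring the weighting convention of variational binning models; both
#' can be overridden.
#'
#' @param n_hidden Hidden-layer width.
#' @param n_hidden_layers Number of hidden layers in encoder and decoder.
#' @param n_z Dimension of the continuous latent code.
#' @param n_y Number of categories of the categorical latent code.
#' @param tau Gumbel-softmax temperature (> 0), used both for the encoder's
#'   relaxed categorical samples and for the categorical prior.
#' @param sl Weight of the regularisation term in the total loss, in `[0, 1]`.
#' @param slr Weight of the categorical term within the regularisation loss,
#'   in `[0, 1]`.
#' @param w_coab,w_tnf Reconstruction term weights; `NULL` means the
#'   S-dependent defaults above.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate, shared by all three optimisers.
#' @param seed Integer seed controlling initialisation, shuffling and all
#'   sampling.
#' @param reg_form `"bce"` (default) scores the encoder's adversarial terms
#'   as cross-entropy against label 1; `"neg_disc"` uses the negated
#'   discriminator losses instead.
#' @param record_steps Keep a per-minibatch loss log (used by diagnostics).
#' @return An object of class `aae_config`.
#' @export
aae_config <- function(n_hidden = 547, n_hidden_layers = 2, n_z = 283,
                       n_y = 700, tau = 0.1596, sl = 0.0964, slr = 0.5,
                       w_coab = NULL, w_tnf = NULL, batch_size = 256,
                       epochs = 300, learning_rate = 1e-3, seed = 1,
                       reg_form = c("bce", "neg_disc"), record_steps = TRUE) {
  reg_form <- match.arg(reg_form)
  stopifnot(tau > 0, sl >= 0, sl <= 1, slr >= 0, slr <= 1,
            n_hidden >= 1, n_z >= 1, n_y >= 1, n_hidden_layers >= 1,
            batch_size >= 1, epochs >= 1, learning_rate > 0)
  structure(
    list(n_hidden = as.integer(n_hidden),
         n_hidden_layers = as.integer(n_hidden_layers),
         n_z = as.integer(n_z), n_y = as.integer(n_y),
         tau = tau, sl = sl, slr = slr,
         w_coab = w_coab, w_tnf = w_tnf,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = learning_rate, seed = as.integer(seed),
         reg_form = reg_form, record_steps = isTRUE(record_steps)),
    class = "aae_config"
  )
}

#' @export
print.aae_config <- function(x, ...) {
  cat("<aae_config> hidden ", x$n_hidden, " x", x$n_hidden_layers,
      ", n_z ", x$n_z, ", n_y ", x$n_y,
      ", tau ", x$tau, ", sl ", x$sl, ", slr ", x$slr,
      ", epochs ", x$epochs, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

SIGMA_MIN <- 1e-6
SIGMA_MAX <- 50

aae_init <- function(n_in, n_samples, n_tnf, cfg) {
  list(
    enc = list(
      trunk = nn_trunk(n_in, cfg$n_hidden, cfg$n_hidden_layers, batchnorm = TRUE),
      mu = nn_linear(cfg$n_hidden, cfg$n_z),
      lsig = nn_linear(cfg$n_hidden, cfg$n_z),
      ly = nn_linear(cfg$n_hidden, cfg$n_y)
    ),
    dec = list(
      trunk = nn_trunk(cfg$n_z + cfg$n_y, cfg$n_hidden, cfg$n_hidden_layers,
                       batchnorm = TRUE),
      a = nn_linear(cfg$n_hidden, n_samples),
      t = nn_linear(cfg$n_hidden, n_tnf)
    ),
    dz = disc_init(cfg$n_z, cfg),
    dy = disc_init(cfg$n_y, cfg)
  )
}

# Discriminators mirror the decoder trunk but without batch normalisation,
# ending in a single sigmoid probability node.
disc_init <- function(n_in, cfg) {
  list(trunk = nn_trunk(n_in, cfg$n_hidden, cfg$n_hidden_layers,
                        batchnorm = FALSE),
       out = nn_linear(cfg$n_hidden, 1))
}

encoder_fwd <- function(enc, x, train) {
  tr <- trunk_fwd(enc$trunk, x, train)
  enc$trunk <- tr$trunk
  mu_c <- linear_fwd(enc$mu, tr$out)
  sig_c <- linear_fwd(enc$lsig, tr$out)
  sigma <- pmin(pmax(exp(sig_c$out), SIGMA_MIN), SIGMA_MAX)
  y_c <- linear_fwd(enc$ly, tr$out)
  y_probs <- softmax_rows(y_c$out)
  list(mu = mu_c$out, sigma = sigma, y_logits = y_c$out, y_probs = y_probs,
       cache = list(trunk = tr, mu = mu_c, lsig = sig_c, ly = y_c,
                    sigma = sigma),
       enc = enc)
}

#' Encode a batch of feature vectors
#'
#' Runs the encoder in evaluation mode (batch normalisation uses running
#' statistics) and returns the Gaussian parameters and categorical
#' probabilities per row.
#'
#' @param fit A fitted model from [aae()].
#' @param x_batch Batch x (103 + S) feature matrix.
#' @return List with `mu`, `sigma` (both batch x n_z, `sigma` strictly
#'   positive) and `y_probs` (batch x n_y, rows summing to one).
#' @export
encode <- function(fit, x_batch) {
  stopifnot(inherits(fit, "aae_fit"))
  if (!all(is.finite(x_batch))) stop("non-finite input batch", call. = FALSE)
  out <- encoder_fwd(fit$params$enc, x_batch, train = FALSE)
  list(mu = out$mu, sigma = out$sigma, y_probs = out$y_probs)
}

#' Sample latent codes from encoder outputs
#'
#' Draws `z = mu + sigma * eps` with standard-normal `eps`, and a relaxed
#' one-hot categorical sample from the categorical logits at temperature
#' `tau`.
#'
#' @param enc_out List with `mu`, `sigma` and `y_probs` (see [encode()]).
#' @param tau Temperature > 0.
#' @return List with matrices `z` and `y_relaxed` (rows summing to one).
#' @export
sample_latents <- function(enc_out, tau) {
  eps <- matrix(rnorm(length(enc_out$mu)), nrow(enc_out$mu))
  z <- enc_out$mu + enc_out$sigma * eps
  y_relaxed <- gumbel_softmax(log(clamp_prob(enc_out$y_probs)), tau)
  list(z = z, y_relaxed = y_relaxed)
}

decoder_fwd <- function(dec, z, y, train) {
  x <- cbind(z, y)
  tr <- trunk_fwd(dec$trunk, x, train)
  dec$trunk <- tr$trunk
  a_c <- linear_fwd(dec$a, tr$out)
  a_out <- softmax_rows(a_c$out)
  t_c <- linear_fwd(dec$t, tr$out)
  list(a_out = a_out, t_out = t_c$out,
       cache = list(trunk = tr, a = a_c, t = t_c), dec = dec)
}

#' Decode latent codes into reconstructed features
#'
#' Evaluation-mode decoder pass: abundance rows come through a softmax and
#' sum to one; composition outputs are unconstrained.
#'
#' @param fit A fitted model from [aae()].
#' @param z Batch x n_z continuous codes.
#' @param y Batch x n_y categorical codes (relaxed or one-hot).
#' @return List with `a_out` (batch x S) and `t_out` (batch x 103).
#' @export
decode <- function(fit, z, y) {
  stopifnot(inherits(fit, "aae_fit"))
  out <- decoder_fwd(fit$params$dec, z, y, train = FALSE)
  list(a_out = out$a_out, t_out = out$t_out)
}

disc_fwd <- function(d, x, train = TRUE) {
  tr <- trunk_fwd(d$trunk, x, train)
  o_c <- linear_fwd(d$out, tr$out)
  p <- sigmoid(o_c$out[, 1])
  list(p = p, cache = list(trunk = tr, out = o_c))
}

# Backpropagate d(loss)/d(logit) through a discriminator; returns the
# gradient with respect to the input and, optionally, parameter gradients.
disc_bwd <- function(d, cache, d_logit, want_grads = TRUE) {
  d_out <- matrix(d_logit, ncol = 1)
  lb <- linear_bwd(d$out, cache$out, d_out)
  tb <- trunk_bwd(d$trunk, cache$trunk$caches, lb$dx)
  list(dx = tb$dx,
       grads = if (want_grads) list(trunk = tb$grads, out = lb$grads))
}

resolve_weights <- function(cfg, n_samples, n_tnf) {
  w_coab <- cfg$w_coab
  w_tnf <- cfg$w_tnf
  if (is.null(w_coab)) {
    w_coab <- if (n_samples > 1) 0.85 / log(n_samples) else 0.85
  }
  if (is.null(w_tnf)) w_tnf <- 0.15 / n_tnf
  list(w_coab = w_coab, w_tnf = w_tnf)
}

#' Train the adversarial autoencoder
#'
#' Per minibatch, three updates run in fixed order: (1) encoder/decoder on
#' `(1 - sl) * L_rec + sl * L_reg`, (2) the z discriminator on `LDz`,
#' (3) the y discriminator on `LDy`. All three use Adam. Shuffling,
#' initialisation and sampling are driven by `config$seed`, so identical
#' data and configuration reproduce identical loss histories.
#'
#' @param features An `aae_features` object from [assemble_features()].
#' @param config An [aae_config()].
#' @return An object of class `aae_fit` holding the trained parameters, the
#'   configuration, a per-epoch loss history (see [tidy.aae_fit()]) and,
#'   if `config$record_steps`, a per-minibatch loss log under `$steps`.
#' @export
aae <- function(features, config = aae_config()) {
  stopifnot(inherits(features, "aae_features"))
  cfg <- config
  X <- features$X
  n <- nrow(X)
  if (n < 1) stop("empty dataset", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix", call. = FALSE)
  n_s <- features$n_samples
  n_t <- features$n_tnf
  a_in_all <- X[, n_t + seq_len(n_s), drop = FALSE]
  t_in_all <- X[, seq_len(n_t), drop = FALSE]
  w <- resolve_weights(cfg, n_s, n_t)

  set.seed(cfg$seed)
  params <- aae_init(ncol(X), n_s, n_t, cfg)
  opt <- list(
    encdec = adam_init(params[c("enc", "dec")]),
    dz = adam_init(params$dz),
    dy = adam_init(params$dy)
  )
  t_encdec <- 0L; t_dz <- 0L; t_dy <- 0L

  steps <- list()
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    batches <- lapply(starts, function(s) idx[s:min(s + cfg$batch_size - 1, n)])
    # A trailing singleton batch has no batch statistics; fold it into the
    # previous batch.
    nb <- length(batches)
    if (nb > 1 && length(batches[[nb]]) == 1) {
      batches[[nb - 1]] <- c(batches[[nb - 1]], batches[[nb]])
      batches <- batches[-nb]
    }
    epoch_log <- matrix(NA_real_, length(batches), 7,
                        dimnames = list(NULL, c("L_rec", "LRz", "LRy",
                                                "LDz", "LDy", "L_reg", "L")))

    for (b in seq_along(batches)) {
      rows <- batches[[b]]
      xb <- X[rows, , drop = FALSE]
      a_in <- a_in_all[rows, , drop = FALSE]
      t_in <- t_in_all[rows, , drop = FALSE]
      nb_rows <- length(rows)

      ## ---- (1) encoder/decoder update ----
      ef <- encoder_fwd(params$enc, xb, train = TRUE)
      params$enc <- ef$enc
      eps <- matrix(rnorm(nb_rows * cfg$n_z), nb_rows)
      z <- ef$mu + ef$sigma * eps
      u <- matrix(runif(nb_rows * cfg$n_y), nb_rows)
      gum <- -log(-log(pmax(u, 1e-12)))
      y_pre <- (ef$y_logits + gum) / cfg$tau
      y <- softmax_rows(y_pre)

      df <- decoder_fwd(params$dec, z, y, train = TRUE)
      params$dec <- df$dec
      rec <- reconstruction_loss(a_in, df$a_out, t_in, df$t_out,
                                 w$w_coab, w$w_tnf)

      dzf <- disc_fwd(params$dz, z)
      dyf <- disc_fwd(params$dy, y)
      reg <- regularization_loss(dzf$p, dyf$p, cfg$slr)

      # Gradients from the reconstruction term.
      d_a_logits <- (1 - cfg$sl) * w$w_coab * (df$a_out - a_in) / nb_rows
      d_t <- (1 - cfg$sl) * w$w_tnf * 2 * (df$t_out - t_in) /
        (nb_rows * n_t)
      ab <- linear_bwd(params$dec$a, df$cache$a, d_a_logits)
      tb <- linear_bwd(params$dec$t, df$cache$t, d_t)
      dtr <- trunk_bwd(params$dec$trunk, df$cache$trunk$caches, ab$dx + tb$dx)
      dec_grads <- list(trunk = dtr$grads, a = ab$grads, t = tb$grads)
      d_z <- dtr$dx[, seq_len(cfg$n_z), drop = FALSE]
      d_y <- dtr$dx[, cfg$n_z + seq_len(cfg$n_y), drop = FALSE]

      # Gradients from the adversarial term (discriminator parameters
      # frozen; gradients flow into the codes only).
      pz <- clamp_prob(dzf$p)
      py <- clamp_prob(dyf$p)
      if (cfg$reg_form == "bce") {
        dlz <- -cfg$sl * (1 - cfg$slr) * (1 - pz) / nb_rows
        dly <- -cfg$sl * cfg$slr * (1 - py) / nb_rows
      } else {
        # negated discriminator losses: only the latent branch of each LD
        # depends on the codes.
        dlz <- -cfg$sl * (1 - cfg$slr) * 0.5 * pz / nb_rows
        dly <- -cfg$sl * cfg$slr * 0.5 * py / nb_rows
      }
      d_z <- d_z + disc_bwd(params$dz, dzf$cache, dlz, want_grads = FALSE)$dx
      d_y <- d_y + disc_bwd(params$dy, dyf$cache, dly, want_grads = FALSE)$dx

      # Through the sampling reparameterisations into the encoder heads.
      d_mu <- d_z
      d_sigma <- d_z * eps
      sig_open <- ef$sigma > SIGMA_MIN & ef$sigma < SIGMA_MAX
      d_lsig <- d_sigma * ef$sigma * sig_open
      d_ylogits <- softmax_bwd(y, d_y) / cfg$tau

      mu_b <- linear_bwd(params$enc$mu, ef$cache$mu, d_mu)
      sig_b <- linear_bwd(params$enc$lsig, ef$cache$lsig, d_lsig)
      y_b <- linear_bwd(params$enc$ly, ef$cache$ly, d_ylogits)
      d_h <- mu_b$dx + sig_b$dx + y_b$dx
      etr <- trunk_bwd(params$enc$trunk, ef$cache$trunk$caches, d_h)
      enc_grads <- list(trunk = etr$grads, mu = mu_b$grads,
                        lsig = sig_b$grads, ly = y_b$grads)

      t_encdec <- t_encdec + 1L
      upd <- adam_step(params[c("enc", "dec")],
                       list(enc = enc_grads, dec = dec_grads),
                       opt$encdec, cfg$learning_rate, t_encdec)
      params$enc <- upd$params$enc
      params$dec <- upd$params$dec
      opt$encdec <- upd$state

      ## ---- (2) z discriminator update ----
      prior_z <- matrix(rnorm(nb_rows * cfg$n_z), nb_rows)
      dz_lat <- disc_fwd(params$dz, z)
      dz_pri <- disc_fwd(params$dz, prior_z)
      ldz <- discriminator_loss(dz_lat$p, dz_pri$p)
      g_lat <- disc_bwd(params$dz, dz_lat$cache,
                        0.5 * clamp_prob(dz_lat$p) / nb_rows)$grads
      g_pri <- disc_bwd(params$dz, dz_pri$cache,
                        -0.5 * (1 - clamp_prob(dz_pri$p)) / nb_rows)$grads
      t_dz <- t_dz + 1L
      upd <- adam_step(params$dz, grad_tree_add(g_lat, g_pri), opt$dz,
                       cfg$learning_rate, t_dz)
      params$dz <- upd$params
      opt$dz <- upd$state

      ## ---- (3) y discriminator update ----
      prior_y <- gumbel_softmax(matrix(0, nb_rows, cfg$n_y), cfg$tau)
      dy_lat <- disc_fwd(params$dy, y)
      dy_pri <- disc_fwd(params$dy, prior_y)
      ldy <- discriminator_loss(dy_lat$p, dy_pri$p)
      g_lat <- disc_bwd(params$dy, dy_lat$cache,
                        0.5 * clamp_prob(dy_lat$p) / nb_rows)$grads
      g_pri <- disc_bwd(params$dy, dy_pri$cache,
                        -0.5 * (1 - clamp_prob(dy_pri$p)) / nb_rows)$grads
      t_dy <- t_dy + 1L
      upd <- adam_step(params$dy, grad_tree_add(g_lat, g_pri), opt$dy,
                       cfg$learning_rate, t_dy)
      params$dy <- upd$params
      opt$dy <- upd$state

      l_total <- total_loss(rec$L_rec, reg$L_reg, cfg$sl)
      row <- c(rec$L_rec, reg$LRz, reg$LRy, ldz, ldy, reg$L_reg, l_total)
      if (!all(is.finite(row))) {
        bad <- c("L_rec", "LRz", "LRy", "LDz", "LDy", "L_reg", "L")[!is.finite(row)]
        stop("non-finite loss term(s) at epoch ", epoch, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      epoch_log[b, ] <- row
    }

    if (cfg$record_steps) steps[[epoch]] <- epoch_log
    history[[epoch]] <- colMeans(epoch_log)
  }

  hist_tbl <- as_tibble(do.call(rbind, history))
  hist_tbl <- dplyr::bind_cols(tibble(epoch = seq_len(cfg$epochs)), hist_tbl)
  steps_tbl <- NULL
  if (cfg$record_steps) {
    steps_tbl <- as_tibble(do.call(rbind, steps))
    steps_tbl$epoch <- rep(seq_len(cfg$epochs), vapply(steps, nrow, 1L))
    steps_tbl$step <- seq_len(nrow(steps_tbl))
  }

  structure(
    list(params = params, config = cfg, history = hist_tbl, steps = steps_tbl,
         n_samples = n_s, n_tnf = n_t,
         w_coab = w$w_coab, w_tnf = w$w_tnf),
    class = "aae_fit"
  )
}

grad_tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (!is.list(a)) return(a + b)
  out <- a
  for (nm in names(a)) out[[nm]] <- grad_tree_add(a[[nm]], b[[nm]])
  out
}

#' @export
print.aae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat("<aae_fit> ", x$config$epochs, " epochs; final L = ",
      signif(last$L, 4), " (L_rec ", signif(last$L_rec, 4), ", L_reg ",
      signif(last$L_reg, 4), ")\n", sep = "")
  invisible(x)
}

#' Extract deterministic latent codes for a dataset
#'
#' Evaluation-mode encoding with no sampling: the continuous code of each
#' contig is the Gaussian mean `mu`, and the categorical label is the argmax
#' category of the softmax probabilities. Repeated calls give identical
#' output.
#'
#' @param fit A fitted model from [aae()].
#' @param features The `aae_features` the codes are wanted for.
#' @return An object of class `aae_latent`: list with `Z` (n x n_z matrix,
#'   contig-id rownames), `y` (integer labels in `1..n_y`, named by contig)
#'   and the contig metadata needed downstream.
#' @export
latent_codes <- function(fit, features) {
  stopifnot(inherits(fit, "aae_fit"), inherits(features, "aae_features"))
  enc <- encode(fit, features$X)
  y <- apply(enc$y_probs, 1, which.max)
  Z <- enc$mu
  rownames(Z) <- features$contig_ids
  structure(
    list(Z = Z, y = setNames(as.integer(y), features$contig_ids),
         contig_ids = features$contig_ids, lengths = features$lengths,
         samples = features$samples, n_y = fit$config$n_y),
    class = "aae_latent"
  )
}

#' @export
print.aae_latent <- function(x, ...) {
  cat("<aae_latent> ", nrow(x$Z), " contigs, n_z ", ncol(x$Z),
      ", ", length(unique(x$y)), " occupied categories\n", sep = "")
  invisible(x)
}

#' Per-epoch loss history of a fitted model
#'
#' @param x An `aae_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch and columns `epoch`, `L_rec`,
#'   `LRz`, `LRy`, `LDz`, `LDy`, `L_reg`, `L`.
#' @method tidy aae_fit
#' @export
tidy.aae_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `aae_fit`.
#' @param ... Unused.
#' @return One-row tibble with dimensions, seed and final losses.
#' @method glance aae_fit
#' @export
glance.aae_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble(
    epochs = x$config$epochs, n_z = x$config$n_z, n_y = x$config$n_y,
    n_hidden = x$config$n_hidden, seed = x$config$seed,
    L = last$L, L_rec = last$L_rec, L_reg = last$L_reg,
    LDz = last$LDz, LDy = last$LDy
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint is self-describing: configuration, weights and feature
#' dimensions in one file.
#'
#' @param fit An `aae_fit`.
#' @param path Destination file.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the `aae_fit`.
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "aae_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "aae_fit"))
  fit
}
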