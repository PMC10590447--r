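# A tiny shared fixture: separable synthetic features at toy scale, plus a
# short-trained model for shape and determinism checks.

tiny_features <- function(seed = 42, n_genomes = 3, n_samples = 3) {
  sim <- simulate_metagenome(synthetic_spec(
    n_genomes = n_genomes, genome_bp = 4000, n_samples = n_samples,
    contigs_per_genome = 4, seed = seed
  ))
  tnf <- compute_tnf(sim$contigs)
  list(features = assemble_features(sim$contigs, tnf, sim$depths), sim = sim)
}

tiny_config <- function(epochs = 3, ...) {
  aae_config(n_hidden = 16, n_z = 4, n_y = 6, epochs = epochs,
             batch_size = 16, seed = 1, ...)
}

test_that("encoder outputs respect shape, simplex and positivity contracts", {
  fx <- tiny_features()
  fit <- aae(fx$features, tiny_config())
  enc <- encode(fit, fx$features$X[1:8, ])
  expect_equal(dim(enc$mu), c(8L, 4L))
  expect_equal(dim(enc$y_probs), c(8L, 6L))
  expect_true(all(enc$sigma > 0))
  expect_lt(max(abs(rowSums(enc$y_probs) - 1)), 1e-6)
  expect_error(encode(fit, matrix(NA_real_, 2, ncol(fx$features$X))),
               "non-finite")

  dec <- decode(fit, enc$mu, enc$y_probs)
  expect_equal(dim(dec$a_out), c(8L, 3L))
  expect_equal(dim(dec$t_out), c(8L, 103L))
  expect_lt(max(abs(rowSums(dec$a_out) - 1)), 1e-6)
  expect_identical(dec, decode(fit, enc$mu, enc$y_probs)) # eval is pure
})

test_that("latent sampling is a seeded reparameterisation", {
  enc_out <- list(mu = matrix(1:6, 2), sigma = matrix(1e-12, 2, 3),
                  y_probs = matrix(1 / 4, 2, 4))
  set.seed(1)
  s <- sample_latents(enc_out, tau = 0.5)
  expect_lt(max(abs(s$z - enc_out$mu)), 1e-9) # sigma -> 0 gives z -> mu
  expect_lt(max(abs(rowSums(s$y_relaxed) - 1)), 1e-9)
  set.seed(1)
  expect_identical(s, sample_latents(enc_out, tau = 0.5))
})

test_that("gumbel-softmax samples approach one-hot at low temperature", {
  set.seed(123)
  logits <- matrix(rnorm(1000 * 5), 1000, 5)
  y <- gumbel_softmax(logits, tau = 0.01)
  expect_gt(mean(apply(y, 1, max)), 0.99)
})

test_that("reconstruction loss matches closed forms", {
  a <- matrix(0.5, 2, 2)
  t0 <- matrix(rnorm(6), 2, 3)
  r <- reconstruction_loss(a, a, t0, t0, w_coab = 2, w_tnf = 1)
  expect_equal(r$L_rec, 2 * log(2), tolerance = 1e-12)
  expect_equal(r$MSE, 0)

  r <- reconstruction_loss(a, a, t0, t0 + 1, w_coab = 0, w_tnf = 1)
  expect_equal(r$MSE, 1, tolerance = 1e-12)
  expect_equal(r$L_rec, 1, tolerance = 1e-12)

  # w_coab = 0 makes the loss independent of the abundance branch
  a2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  expect_equal(reconstruction_loss(a, a2, t0, t0, 0, 1)$L_rec,
               reconstruction_loss(a, a, t0, t0, 0, 1)$L_rec)
})

test_that("discriminator and regularisation losses match closed forms", {
  expect_equal(discriminator_loss(0.5, 0.5), log(2), tolerance = 1e-9)
  expect_lt(discriminator_loss(1e-12, 1 - 1e-12), 1e-8)
  worst <- discriminator_loss(1, 0)
  expect_true(is.finite(worst) && worst > 10)

  r <- regularization_loss(p_z = 0.5, p_y = 0.5, slr = 0.3)
  expect_equal(r$L_reg, log(2), tolerance = 1e-9)
  expect_equal(regularization_loss(1 - 1e-12, 0.5, slr = 0)$L_reg, 0,
               tolerance = 1e-8)
  expect_equal(regularization_loss(0.5, exp(-2), slr = 1)$L_reg, 2,
               tolerance = 1e-9)

  expect_equal(total_loss(1, 2, sl = 0), 1)
  expect_equal(total_loss(1, 2, sl = 1), 2)
  expect_equal(total_loss(1, 2, sl = 0.0964), 1.0964, tolerance = 1e-12)
})

test_that("training records finite losses satisfying the total-loss identity", {
  fx <- tiny_features()
  cfg <- tiny_config(epochs = 2)
  fit <- aae(fx$features, cfg)
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(as.matrix(fit$history[-1]))))
  # L = (1 - sl) L_rec + sl L_reg at every logged minibatch step
  expect_lt(max(abs(fit$steps$L - ((1 - cfg$sl) * fit$steps$L_rec +
                                     cfg$sl * fit$steps$L_reg))), 1e-9)
})

test_that("training is bit-reproducible under a fixed seed", {
  fx <- tiny_features()
  f1 <- aae(fx$features, tiny_config())
  f2 <- aae(fx$features, tiny_config())
  expect_identical(f1$history, f2$history)
  expect_identical(latent_codes(f1, fx$features)$Z,
                   latent_codes(f2, fx$features)$Z)
})

test_that("with sl = 0 the model trains as a plain autoencoder", {
  fx <- tiny_features()
  cfg <- aae_config(n_hidden = 16, n_z = 4, n_y = 6, epochs = 200,
                    batch_size = 64, sl = 0, seed = 1)
  fit <- aae(fx$features, cfg)
  expect_lt(fit$history$L_rec[200], fit$history$L_rec[1])
})

test_that("latent extraction is deterministic with labels in range", {
  fx <- tiny_features()
  fit <- aae(fx$features, tiny_config())
  lat <- latent_codes(fit, fx$features)
  expect_equal(nrow(lat$Z), nrow(fx$features$X))
  expect_true(all(lat$y >= 1 & lat$y <= 6))
  expect_identical(lat$Z, latent_codes(fit, fx$features)$Z)
  expect_identical(lat$y, latent_codes(fit, fx$features)$y)
})

test_that("checkpoints round-trip and broom/ggplot accessors work", {
  fx <- tiny_features()
  fit <- aae(fx$features, tiny_config())
  path <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(fit, path)
  fit2 <- read_checkpoint(path)
  expect_identical(latent_codes(fit2, fx$features)$Z,
                   latent_codes(fit, fx$features)$Z)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_latent(latent_codes(fit, fx$features)), "ggplot")
})
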