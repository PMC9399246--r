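nn_new <- anoscore:::nn_new
nn_forward <- anoscore:::nn_forward
nn_backward <- anoscore:::nn_backward
nn_output <- anoscore:::nn_output
nn_jvp <- anoscore:::nn_jvp
nn_jvp_backward <- anoscore:::nn_jvp_backward

test_that("backpropagation matches central finite differences", {
  set.seed(42)
  net <- nn_new(c(5, 7, 4, 3), c("tanh", "tanh", "linear"))
  X <- matrix(rnorm(5 * 6), 5, 6)
  loss_of <- function(nt) sum(nn_output(nt, X)^2)
  cache <- nn_forward(net, X)
  g <- nn_backward(net, cache, 2 * cache$a[[4]])
  eps <- 1e-6
  for (l in 1:3) {
    idx <- sample(seq_along(net$layers[[l]]$W), 10)
    for (i in idx) {
      np <- net; np$layers[[l]]$W[i] <- np$layers[[l]]$W[i] + eps
      nm <- net; nm$layers[[l]]$W[i] <- nm$layers[[l]]$W[i] - eps
      fd <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(g$gW[[l]][i], fd, tolerance = 1e-5)
    }
  }
  # input gradient
  for (i in sample(seq_along(X), 10)) {
    Xp <- X; Xp[i] <- Xp[i] + eps
    Xm <- X; Xm[i] <- Xm[i] - eps
    fd <- (sum(nn_output(net, Xp)^2) - sum(nn_output(net, Xm)^2)) / (2 * eps)
    expect_equal(g$dinput[i], fd, tolerance = 1e-5)
  }
})

test_that("gradient-penalty parameter gradient is exact for a piecewise-linear critic", {
  set.seed(7)
  D <- nn_new(c(6, 8, 5, 1), c("lrelu", "lrelu", "linear"))
  Xh <- matrix(rnorm(6 * 4), 6, 4)
  b <- ncol(Xh)
  penalty_of <- function(Dn) {
    ch <- nn_forward(Dn, Xh)
    gin <- nn_backward(Dn, ch, matrix(1, 1, b), want_params = FALSE)$dinput
    mean((sqrt(colSums(gin^2)) - 1)^2)
  }
  ch <- nn_forward(D, Xh)
  gin <- nn_backward(D, ch, matrix(1, 1, b), want_params = FALSE)$dinput
  gn <- sqrt(colSums(gin^2)) + 1e-12
  U <- gin / rep(gn, each = 6)
  tl <- nn_jvp(D, ch, U)
  # the forward-mode directional derivative equals u . grad exactly
  expect_equal(as.vector(tl[[4]]), colSums(U * gin), tolerance = 1e-12)
  gp <- nn_jvp_backward(D, ch, tl, matrix(2 * (gn - 1) / b, 1, b))
  eps <- 1e-6
  for (l in 1:3) {
    idx <- sample(seq_along(D$layers[[l]]$W),
                  min(8, length(D$layers[[l]]$W)))
    for (i in idx) {
      Dp <- D; Dp$layers[[l]]$W[i] <- Dp$layers[[l]]$W[i] + eps
      Dm <- D; Dm$layers[[l]]$W[i] <- Dm$layers[[l]]$W[i] - eps
      fd <- (penalty_of(Dp) - penalty_of(Dm)) / (2 * eps)
      expect_equal(gp$gW[[l]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("WGAN training completes on constant images and is seed-deterministic", {
  imgs <- replicate(64, matrix(0.5, 32, 32), simplify = FALSE)
  hp <- gan_hyperparams(input_size = 32, latent_dim = 8, batch_size = 16,
                        hidden_units = c(48, 24), seed = 2)
  m1 <- train_wgan(imgs, hp, n_steps = 50)
  expect_s3_class(m1, "gan_model")
  expect_true(m1$trained$gan)
  expect_false(m1$trained$encoder)
  # generator output varies across latent draws and stays finite
  set.seed(1)
  Z <- matrix(rnorm(8 * 16), 8, 16)
  Xf <- anoscore:::model_generate(m1, Z)
  expect_true(all(is.finite(Xf)))
  expect_gt(var(as.vector(Xf)), 0)

  m2 <- train_wgan(imgs, hp, n_steps = 50)
  expect_identical(m1$training_log, m2$training_log)
})

test_that("training rejects images of the wrong size, naming the offender", {
  imgs <- replicate(20, matrix(0.5, 16, 16), simplify = FALSE)
  imgs[[13]] <- matrix(0.5, 8, 8)
  hp <- gan_hyperparams(input_size = 16, latent_dim = 4, batch_size = 8,
                        hidden_units = c(16, 8), seed = 1)
  expect_error(train_wgan(imgs, hp, n_steps = 5),
               "image 13", class = "anoscore_size_mismatch")
})

test_that("critic Wasserstein estimate shrinks in magnitude over a toy run", {
  m <- toy_trained_model()$model
  w <- m$training_log$wasserstein
  first <- mean(abs(head(w, 50)))
  last <- mean(abs(tail(w, 50)))
  expect_lt(last, first)
})

test_that("encoder training enforces the loss decomposition identity at every step", {
  tm <- toy_trained_model()
  el <- tm$model$encoder_log
  # k = 1: exact decomposition Loss_izi = Loss_images + k * Loss_features
  expect_identical(el$loss_izi, el$loss_images + el$loss_features)
  expect_true(all(el$loss_images >= 0 & el$loss_features >= 0))
  # optimization makes progress at toy scale
  n <- nrow(el)
  expect_lt(median(tail(el$loss_izi, ceiling(n / 10))),
            median(head(el$loss_izi, ceiling(n / 10))))
})

test_that("k = 0 reduces the encoder objective to the image loss alone", {
  tm <- toy_trained_model()
  hp0 <- tm$model$hp
  hp0$k_feature_weight <- 0
  m0 <- train_encoder(tm$model, tm$train, hp0, n_steps = 20)
  expect_identical(m0$encoder_log$loss_izi, m0$encoder_log$loss_images)
})

test_that("encoder training requires a trained generator and critic", {
  m <- list(trained = list(gan = FALSE, encoder = FALSE))
  class(m) <- "gan_model"
  expect_error(train_encoder(m, list(), gan_hyperparams(input_size = 16)),
               "must be trained")
})

test_that("compute_losses reproduces the hand oracle on stub networks", {
  # n = 2 pixels, m = 1 feature: X = (0,0), X' = (1,1), f(X) = 0, f(X') = 2
  m <- stub_model(
    encode = function(x) matrix(0, 1, 1),
    generate = function(z) matrix(c(1, 1), 2, 1),
    features = function(x) matrix(if (all(x == 0)) 0 else 2, 1, 1))
  got <- compute_losses(c(0, 0), m)
  expect_identical(got$loss_images, 1.0)   # ||(0,0)-(1,1)||^2 / 2
  expect_identical(got$loss_features, 4.0) # ||0-2||^2 / 1
})

test_that("loss_images equals a brute-force elementwise MSE on real networks", {
  tm <- toy_trained_model()
  X <- tm$held_out[[1]]
  m <- tm$model
  got <- compute_losses(X, m)
  xv <- matrix(as.vector(X), ncol = 1)
  xp <- anoscore:::model_generate(m, anoscore:::model_encode(m, xv))
  brute <- sum((xv - xp)^2) / length(xv)
  expect_equal(got$loss_images, brute, tolerance = 1e-14)
  fx <- anoscore:::model_features(m, xv)
  fxp <- anoscore:::model_features(m, xp)
  expect_equal(got$loss_features, sum((fx - fxp)^2) / length(fx),
               tolerance = 1e-14)
  # perfect autoencoding gives (0, 0)
  idm <- stub_model(encode = identity, generate = identity,
                    features = function(x) sum(x))
  expect_identical(compute_losses(c(0.3, 0.7), idm),
                   list(loss_images = 0, loss_features = 0))
})

test_that("model checkpoints round-trip through save/load", {
  tm <- toy_trained_model()
  dir <- file.path(tempdir(), "ckpt")
  save_gan_model(tm$model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- load_gan_model(dir)
  expect_identical(m2$G, tm$model$G)
  expect_identical(m2$E, tm$model$E)
  x <- tm$held_out[[2]]
  expect_identical(compute_losses(x, m2), compute_losses(x, tm$model))
})
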