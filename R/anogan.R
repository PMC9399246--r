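#' Hyperparameters for the anomaly GAN
#'
#' Defaults follow the published configuration of the method: Adam with
#' learning rate 0.001, batch size 32, 7000 epochs, latent dimension 128,
#' 256 x 256 input, beta1 = 0.5, beta2 = 0.999. The feature-matching weight
#' `k_feature_weight` (the weighting factor of the encoder loss) defaults to
#' 1 and the gradient-penalty weight to 10, as in the original fast anomaly
#' GAN. Toy-scale runs override `input_size`, `latent_dim` and the step
#' count.
#'
#' @param optimizer only `"adam"` is supported.
#' @param learning_rate positive step size.
#' @param batch_size minibatch size.
#' @param n_epochs number of training epochs (one epoch = one pass worth of
#'   generator updates over the training set).
#' @param latent_dim dimension of the latent space (>= 1).
#' @param input_size image side length in pixels.
#' @param beta1,beta2 Adam moment decay rates in `[0, 1)`.
#' @param critic_feature_layer index of the critic layer whose activation is
#'   the feature map `f(.)`; defaults to the penultimate layer.
#' @param gradient_penalty_weight weight of the critic gradient penalty.
#' @param k_feature_weight weighting factor of the feature term in the
#'   encoder loss.
#' @param n_critic critic updates per generator update.
#' @param hidden_units integer length-2 hidden-layer widths; derived from
#'   `input_size` when `NULL`.
#' @param seed integer seed for initialization and batch sampling.
#' @return An object of class `gan_hyperparams`.
#' @export
gan_hyperparams <- function(optimizer = "adam",
                            learning_rate = 0.001,
                            batch_size = 32,
                            n_epochs = 7000,
                            latent_dim = 128,
                            input_size = 256,
                            beta1 = 0.5,
                            beta2 = 0.999,
                            critic_feature_layer = NULL,
                            gradient_penalty_weight = 10,
                            k_feature_weight = 1,
                            n_critic = 5,
                            hidden_units = NULL,
                            seed = 1L) {
  stopifnot(identical(optimizer, "adam"),
            learning_rate > 0,
            beta1 >= 0, beta1 < 1, beta2 >= 0, beta2 < 1,
            is_count(latent_dim, 1), is_count(batch_size, 1),
            is_count(n_epochs, 1), is_count(input_size, 8),
            gradient_penalty_weight >= 0, k_feature_weight >= 0,
            is_count(n_critic, 1))
  if (is.null(hidden_units)) {
    hidden_units <- c(max(64L, 3L * as.integer(input_size)),
                      max(32L, (3L * as.integer(input_size)) %/% 2L))
  }
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 latent_dim = as.integer(latent_dim),
                 input_size = as.integer(input_size),
                 beta1 = beta1, beta2 = beta2,
                 critic_feature_layer = critic_feature_layer,
                 gradient_penalty_weight = gradient_penalty_weight,
                 k_feature_weight = k_feature_weight,
                 n_critic = as.integer(n_critic),
                 hidden_units = as.integer(hidden_units),
                 seed = as.integer(seed)),
            class = "gan_hyperparams")
}

# stack a list of images into an (n_pixels x N) matrix, checking sizes
as_image_matrix <- function(images, input_size) {
  if (is.matrix(images) && !is.list(images)) {
    # already flattened (n_pixels x N)
    if (nrow(images) != input_size^2) {
      stop_named("anoscore_size_mismatch",
                 "flattened images have ", nrow(images),
                 " pixels; expected ", input_size^2)
    }
    return(images)
  }
  X <- matrix(0, input_size^2, length(images))
  for (i in seq_along(images)) {
    p <- as_pixel_matrix(images[[i]])
    if (nrow(p) != input_size || ncol(p) != input_size) {
      stop_named("anoscore_size_mismatch",
                 "image ", i, " is ", nrow(p), "x", ncol(p),
                 "; expected ", input_size, "x", input_size)
    }
    X[, i] <- as.vector(p)
  }
  X
}

check_finite <- function(x, what, step) {
  if (!all(is.finite(x))) {
    stop_named("anoscore_numeric_error",
               "non-finite ", what, " at step ", step)
  }
  x
}

#' Train the Wasserstein GAN on normal images
#'
#' Alternates `n_critic` critic updates (Wasserstein loss with gradient
#' penalty) with one generator update, establishing a latent representation
#' of the normal images. The returned model holds the trained generator and
#' critic, an untrained encoder slot, and a per-generator-step training log
#' (critic loss, generator loss, Wasserstein estimate, penalty). Runs are
#' deterministic given `hp$seed` and fixed data.
#'
#' @param images list of pixel matrices (all `input_size` x `input_size`), or
#'   an already-flattened `(pixels x N)` matrix.
#' @param hp a [gan_hyperparams()].
#' @param n_steps total generator updates; defaults to
#'   `n_epochs * ceiling(N / batch_size)`.
#' @return An object of class `gan_model`.
#' @export
train_wgan <- function(images, hp, n_steps = NULL) {
  stopifnot(inherits(hp, "gan_hyperparams"))
  X <- as_image_matrix(images, hp$input_size)
  N <- ncol(X)
  if (N < hp$batch_size) {
    stop("need at least batch_size (", hp$batch_size, ") images; got ", N)
  }
  n_px <- hp$input_size^2
  h <- hp$hidden_units
  steps <- as.integer(n_steps %||% (hp$n_epochs * ceiling(N / hp$batch_size)))

  with_seed(hp$seed, {
    G <- nn_new(c(hp$latent_dim, h[2], h[1], n_px), c("lrelu", "lrelu", "sigmoid"))
    D <- nn_new(c(n_px, h[1], h[2], 1), c("lrelu", "lrelu", "linear"))
    optG <- adam_new(G, hp$learning_rate, hp$beta1, hp$beta2)
    optD <- adam_new(D, hp$learning_rate, hp$beta1, hp$beta2)
    b <- hp$batch_size
    gp_w <- hp$gradient_penalty_weight
    log <- data.frame(step = seq_len(steps), d_loss = NA_real_,
                      g_loss = NA_real_, wasserstein = NA_real_,
                      gp = NA_real_)

    for (s in seq_len(steps)) {
      d_losses <- w_ests <- gps <- numeric(hp$n_critic)
      for (ci in seq_len(hp$n_critic)) {
        idx <- sample.int(N, b, replace = TRUE)
        Xr <- X[, idx, drop = FALSE]
        Z <- matrix(stats::rnorm(hp$latent_dim * b), hp$latent_dim, b)
        Xf <- nn_output(G, Z)

        cf <- nn_forward(D, Xf)
        cr <- nn_forward(D, Xr)
        Df <- cf$a[[length(cf$a)]]
        Dr <- cr$a[[length(cr$a)]]
        gf <- nn_backward(D, cf, matrix(1 / b, 1, b), want_input = FALSE)
        gr <- nn_backward(D, cr, matrix(-1 / b, 1, b), want_input = FALSE)
        gD <- grads_add(grads_add(grads_zero(D), gf), gr)

        gp_val <- 0
        if (gp_w > 0) {
          eps <- matrix(stats::runif(b), 1, b)
          Xh <- Xr * rep(eps, each = n_px) + Xf * rep(1 - eps, each = n_px)
          ch <- nn_forward(D, Xh)
          gin <- nn_backward(D, ch, matrix(1, 1, b), want_params = FALSE)$dinput
          gn <- sqrt(colSums(gin^2)) + 1e-12
          U <- gin / rep(gn, each = n_px)
          tl <- nn_jvp(D, ch, U)
          cvec <- matrix(2 * (gn - 1) / b, 1, b)
          gpgrad <- nn_jvp_backward(D, ch, tl, cvec)
          gD <- grads_add(gD, gpgrad, scale = gp_w)
          gp_val <- mean((gn - 1)^2)
        }
        upd <- adam_step(D, gD, optD)
        D <- upd$net; optD <- upd$state
        d_losses[ci] <- mean(Df) - mean(Dr) + gp_w * gp_val
        w_ests[ci] <- mean(Dr) - mean(Df)
        gps[ci] <- gp_val
        check_finite(d_losses[ci], "critic loss", s)
      }

      # generator update: minimize -mean(D(G(z)))
      Z <- matrix(stats::rnorm(hp$latent_dim * b), hp$latent_dim, b)
      gc_ <- nn_forward(G, Z)
      Xf <- gc_$a[[length(gc_$a)]]
      cf <- nn_forward(D, Xf)
      dXf <- nn_backward(D, cf, matrix(-1 / b, 1, b), want_params = FALSE)$dinput
      gG <- nn_backward(G, gc_, dXf, want_input = FALSE)
      upd <- adam_step(G, list(gW = gG$gW, gb = gG$gb), optG)
      G <- upd$net; optG <- upd$state
      g_loss <- -mean(cf$a[[length(cf$a)]])
      check_finite(g_loss, "generator loss", s)

      log$d_loss[s] <- mean(d_losses)
      log$g_loss[s] <- g_loss
      log$wasserstein[s] <- mean(w_ests)
      log$gp[s] <- mean(gps)
    }

    structure(list(G = G, D = D, E = NULL, hp = hp,
                   feature_layer = hp$critic_feature_layer %||%
                     (length(D$layers) - 1L),
                   trained = list(gan = TRUE, encoder = FALSE),
                   training_log = log, encoder_log = NULL,
                   data_fingerprint = fingerprint_images(X)),
              class = "gan_model")
  })
}

fingerprint_images <- function(X) {
  list(n = ncol(X), n_pixels = nrow(X),
       mean = mean(X), sd = stats::sd(as.vector(X)))
}

#' Train the latent-space encoder (izi_f scheme)
#'
#' With the generator and critic frozen, trains an encoder `E` mapping images
#' to latent codes by minimizing
#' `Loss_izi = Loss_images + k * Loss_features`, where `Loss_images` is the
#' per-pixel mean squared error between `X` and its re-generation
#' `X' = G(E(X))` and `Loss_features` is the mean squared error between the
#' critic's intermediate feature maps `f(X)` and `f(X')`.
#'
#' @param model a `gan_model` with trained generator and critic.
#' @param images training images (same contract as [train_wgan()]).
#' @param hp hyperparameters; defaults to the model's.
#' @param n_steps total encoder updates; defaults to
#'   `n_epochs * ceiling(N / batch_size)`.
#' @return The model with `E` trained and a per-step `encoder_log`
#'   (`loss_images`, `loss_features`, `loss_izi`).
#' @export
train_encoder <- function(model, images, hp = model$hp, n_steps = NULL) {
  stopifnot(inherits(model, "gan_model"))
  if (!isTRUE(model$trained$gan)) {
    stop("generator and critic must be trained before the encoder")
  }
  X <- as_image_matrix(images, hp$input_size)
  N <- ncol(X)
  n_px <- hp$input_size^2
  fl <- model$feature_layer
  k <- hp$k_feature_weight
  steps <- as.integer(n_steps %||% (hp$n_epochs * ceiling(N / hp$batch_size)))
  G <- model$G; D <- model$D
  h <- hp$hidden_units

  with_seed(derive_seed(hp$seed, 1L), {
    E <- nn_new(c(n_px, h[1], h[2], hp$latent_dim), c("lrelu", "lrelu", "linear"))
    optE <- adam_new(E, hp$learning_rate, hp$beta1, hp$beta2)
    b <- min(hp$batch_size, N)
    log <- data.frame(step = seq_len(steps), loss_images = NA_real_,
                      loss_features = NA_real_, loss_izi = NA_real_)

    for (s in seq_len(steps)) {
      idx <- sample.int(N, b, replace = TRUE)
      Xb <- X[, idx, drop = FALSE]
      ce <- nn_forward(E, Xb)
      Zb <- ce$a[[length(ce$a)]]
      cg <- nn_forward(G, Zb)
      Xp <- cg$a[[length(cg$a)]]

      cfx <- nn_forward(D, Xb)
      cfp <- nn_forward(D, Xp)
      fX <- cfx$a[[fl + 1L]]
      fXp <- cfp$a[[fl + 1L]]
      m <- nrow(fX)

      li <- sum((Xb - Xp)^2) / (n_px * b)
      lf <- sum((fX - fXp)^2) / (m * b)
      loss <- li + k * lf
      check_finite(loss, "encoder loss", s)

      dXp <- -2 * (Xb - Xp) / (n_px * b)
      if (k > 0) {
        dfp <- 2 * k * (fXp - fX) / (m * b)
        dXp <- dXp + nn_backward(D, cfp, dfp, start_layer = fl,
                                 want_params = FALSE)$dinput
      }
      dZ <- nn_backward(G, cg, dXp, want_params = FALSE)$dinput
      gE <- nn_backward(E, ce, dZ, want_input = FALSE)
      upd <- adam_step(E, list(gW = gE$gW, gb = gE$gb), optE)
      E <- upd$net; optE <- upd$state

      log$loss_images[s] <- li
      log$loss_features[s] <- lf
      log$loss_izi[s] <- loss
    }
    model$E <- E
    model$trained$encoder <- TRUE
    model$encoder_log <- log
    model
  })
}

# component accessors that also accept plain-function stand-ins, so loss
# arithmetic can be tested against hand oracles with injected stubs
model_encode <- function(model, X) {
  if (is.function(model$E)) return(model$E(X))
  if (is.null(model$E)) stop("encoder is untrained")
  nn_output(model$E, X)
}

model_generate <- function(model, Z) {
  if (is.function(model$G)) return(model$G(Z))
  nn_output(model$G, Z)
}

model_features <- function(model, X) {
  if (is.function(model$D)) return(model$D(X))
  cache <- nn_forward(model$D, X)
  cache$a[[model$feature_layer + 1L]]
}

#' Reconstruction and feature losses of an image under the model
#'
#' Computes, for `X' = G(E(X))`, the per-pixel mean squared error
#' `Loss_images = ||X - X'||^2 / n` and the critic feature-space error
#' `Loss_features = ||f(X) - f(X')||^2 / m`, with `n` the number of pixels
#' and `m` the feature dimensionality.
#'
#' @param X image (matrix or `rendered_image`) matching the model input size,
#'   or an already-flattened numeric vector.
#' @param model a `gan_model` (network components may be replaced by plain
#'   functions, e.g. for testing).
#' @return A list with `loss_images` and `loss_features`.
#' @export
compute_losses <- function(X, model) {
  x <- if (is.numeric(X) && !is.matrix(X)) matrix(X, ncol = 1)
       else matrix(as.vector(as_pixel_matrix(X)), ncol = 1)
  if (!is.function(model$E) && !is.null(model$hp) &&
      nrow(x) != model$hp$input_size^2) {
    stop_named("anoscore_size_mismatch",
               "image has ", nrow(x), " pixels; model expects ",
               model$hp$input_size^2)
  }
  z <- model_encode(model, x)
  xp <- model_generate(model, z)
  fx <- model_features(model, x)
  fxp <- model_features(model, xp)
  list(loss_images = sum((x - xp)^2) / length(x),
       loss_features = sum((fx - fxp)^2) / length(fx))
}

#' Save / load a trained model
#'
#' Writes the networks plus a JSON manifest (hyperparameters, seed, data
#' fingerprint, step counts) and the training logs as CSV.
#'
#' @param model a `gan_model`.
#' @param dir checkpoint directory.
#' @return `load_gan_model` returns the `gan_model`.
#' @export
save_gan_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model[c("G", "D", "E", "feature_layer", "trained")],
          file.path(dir, "networks.rds"))
  jsonlite::write_json(
    list(hyperparams = unclass(model$hp), trained = model$trained,
         feature_layer = model$feature_layer,
         data_fingerprint = model$data_fingerprint,
         n_gan_steps = nrow(model$training_log %||% data.frame()),
         n_encoder_steps = nrow(model$encoder_log %||% data.frame())),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(model$training_log)) {
    utils::write.csv(model$training_log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  }
  if (!is.null(model$encoder_log)) {
    utils::write.csv(model$encoder_log, file.path(dir, "encoder_log.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_gan_model
#' @export
load_gan_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  nets <- readRDS(file.path(dir, "networks.rds"))
  hp <- do.call(gan_hyperparams, man$hyperparams[
    setdiff(names(man$hyperparams), character(0))])
  logp <- file.path(dir, "training_log.csv")
  elogp <- file.path(dir, "encoder_log.csv")
  structure(list(G = nets$G, D = nets$D, E = nets$E, hp = hp,
                 feature_layer = nets$feature_layer,
                 trained = nets$trained,
                 training_log = if (file.exists(logp)) utils::read.csv(logp),
                 encoder_log = if (file.exists(elogp)) utils::read.csv(elogp),
                 data_fingerprint = man$data_fingerprint),
            class = "gan_model")
}
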