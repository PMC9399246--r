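# analytic sphere volumes -----------------------------------------------------

# smooth signed-distance field of a sphere (positive inside), iso level 0
sphere_sdf_volume <- function(n, spacing, radius = 10) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  A0 <- array(ax, c(n, n, n))
  A1 <- array(rep(ax, each = n), c(n, n, n))
  A2 <- array(rep(ax, each = n * n), c(n, n, n))
  volume_grid(array(radius - sqrt(A0^2 + A1^2 + A2^2), c(n, n, n)),
              spacing = rep(spacing, 3))
}

# clamped-ramp density sphere in [0,1] centred on the grid, iso level 0.5
sphere_density_volume <- function(n, spacing, radius = 10) {
  v <- sphere_sdf_volume(n, spacing, radius)
  volume_grid(array(pmin(1, pmax(0, 0.5 + v$values / (1.5 * spacing))),
                    dim(v$values)),
              spacing = rep(spacing, 3))
}

# closed-form paired t-test ----------------------------------------------------

paired_t_oracle <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1),
       mean_diff = mean(d))
}

# stub model with injected plain-function components ---------------------------

stub_model <- function(encode, generate, features) {
  structure(list(G = generate, D = features, E = encode, hp = NULL,
                 feature_layer = NA, trained = list(gan = TRUE, encoder = TRUE)),
            class = "gan_model")
}

# shared toy-scale trained model (one training run per test session) -----------

.toy_cache <- new.env(parent = emptyenv())

toy_trained_model <- function() {
  if (!is.null(.toy_cache$model)) return(.toy_cache$model)
  ds <- generate_image_dataset(76, 8, phantom_spec(image_size = 32, severity = 1),
                               seed = 11)
  normals <- ds$images[ds$labels == "normal"]
  hp <- gan_hyperparams(input_size = 32, latent_dim = 8, batch_size = 16,
                        seed = 3)
  m <- train_wgan(normals[1:56], hp, n_steps = 300)
  m <- train_encoder(m, normals[1:56], hp, n_steps = 300)
  .toy_cache$model <- list(model = m,
                           train = normals[1:56],
                           held_out = normals[57:76],
                           anomalous = ds$images[ds$labels != "normal"],
                           ref = fit_reference(
                             score_images(normals[1:56], m)$raw_as))
  .toy_cache$model
}
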