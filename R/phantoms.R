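#' Specification of a synthetic torso phantom
#'
#' Describes a half-torso slab with two breast mounds, rendered later as a
#' frontal depth map. One mound can be deformed to emulate a cosmetic
#' abnormality; `severity` scales the deformation continuously, with
#' `severity = 0` reproducing the normal phantom exactly.
#'
#' @param image_size side length in pixels of the (square) rendered image.
#' @param torso_width_frac torso width as a fraction of image width.
#' @param mound_radius_frac mound radius as a fraction of image width.
#' @param mound_separation_frac distance between mound centres as a fraction
#'   of image width.
#' @param anomaly_kind one of `"none"`, `"asymmetry"`, `"missing_mound"`,
#'   `"contracture"`, `"expander_bulge"`.
#' @param severity deformation severity in `[0, 1]`.
#' @param noise_sd standard deviation of additive Gaussian voxel noise
#'   (grayscale units).
#' @param seed integer seed governing the phantom's randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64,
                         torso_width_frac = 0.8,
                         mound_radius_frac = 0.16,
                         mound_separation_frac = 0.42,
                         anomaly_kind = "none",
                         severity = 0,
                         noise_sd = 0.01,
                         seed = 1L) {
  kinds <- c("none", "asymmetry", "missing_mound", "contracture", "expander_bulge")
  if (!is.character(anomaly_kind) || length(anomaly_kind) != 1 ||
      !(anomaly_kind %in% kinds)) {
    stop_named("anoscore_invalid_anomaly",
               "unknown anomaly_kind '", anomaly_kind,
               "'; valid kinds: ", paste(kinds, collapse = ", "))
  }
  if (!is_count(image_size, min = 16)) {
    stop_named("anoscore_invalid_spec", "image_size must be an integer >= 16")
  }
  stopifnot(torso_width_frac > 0, torso_width_frac <= 1,
            mound_radius_frac > 0, mound_radius_frac < 0.5,
            mound_separation_frac >= 0, mound_separation_frac < 1,
            severity >= 0, severity <= 1, noise_sd >= 0)
  structure(list(image_size = as.integer(image_size),
                 torso_width_frac = torso_width_frac,
                 mound_radius_frac = mound_radius_frac,
                 mound_separation_frac = mound_separation_frac,
                 anomaly_kind = anomaly_kind,
                 severity = severity,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the volumetric density field of a torso phantom
#'
#' Constructs a smooth (ramped signed-distance) density field in `[0, 1]` for
#' a half-torso slab with two spherical mounds centred on the chest wall.
#' Axis 0 of the array is anterior--posterior (anterior at index 1), axis 1 is
#' left--right, axis 2 is cranio--caudal; voxel spacing is 1 mm. The anomaly,
#' applied to the mound on the high-index side of axis 1, deforms it
#' proportionally to `severity`:
#' * `contracture` shrinks the mound and pulls it posteriorly,
#' * `missing_mound` shrinks it to nothing at severity 1,
#' * `asymmetry` translates it cranially and mildly rescales it,
#' * `expander_bulge` over-inflates it and cuts a flat anterior face.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume_grid()] whose values lie in `[0, 1]`.
#' @export
make_phantom_volume <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  n <- spec$image_size
  n0 <- as.integer(ceiling(n / 2))
  # coordinates in units of image width
  u0 <- (seq_len(n0) - 1) / n
  u1 <- (seq_len(n) - 1) / n
  u2 <- (seq_len(n) - 1) / n
  h <- 1.5 / n  # smoothing ramp half-width ~ 1.5 voxels

  cw <- 0.30                       # chest-wall depth from anterior face
  curve <- 0.06
  front1 <- cw + curve * (2 * (u1 - 0.5))^2   # per-column chest wall depth
  tw <- spec$torso_width_frac
  r <- spec$mound_radius_frac
  sep <- spec$mound_separation_frac
  sev <- spec$severity
  kind <- spec$anomaly_kind

  # torso slab: inside when u0 >= front(u1) and |u1 - 0.5| <= tw/2
  A0 <- array(u0, dim = c(n0, n, n))
  A1 <- array(rep(u1, each = n0), dim = c(n0, n, n))
  A2 <- array(rep(u2, each = n0 * n), dim = c(n0, n, n))
  Fr <- array(rep(front1, each = n0), dim = c(n0, n, n))
  sdf_torso <- pmin(A0 - Fr, tw / 2 - abs(A1 - 0.5))
  field <- clamp01(0.5 + sdf_torso / h)

  mound_field <- function(c1, c2, rad, ripple = NULL, c0_shift = 0) {
    c0 <- cw + curve * (2 * (c1 - 0.5))^2 + c0_shift
    rr <- rad
    if (!is.null(ripple)) {
      # cranio-caudal surface corrugation of the mound radius
      rr <- rad + ripple$amplitude *
        sin(2 * pi * ripple$cycles * (A2 - c2) / (2 * rad))
    }
    d <- sqrt((A0 - c0)^2 + (A1 - c1)^2 + (A2 - c2)^2)
    clamp01(0.5 + (rr - d) / h)
  }

  # right mound (low-index side of axis 1): always normal
  f_r <- mound_field(0.5 - sep / 2, 0.5, r)

  # left mound: anomaly target
  c1L <- 0.5 + sep / 2
  c2L <- 0.5
  rL <- r
  ripple <- NULL
  shiftL <- 0
  if (sev > 0) {
    if (kind == "contracture") {
      # shrink and pull posteriorly
      rL <- r * (1 - 0.55 * sev)
      shiftL <- 0.25 * r * sev
    } else if (kind == "missing_mound") {
      rL <- r * (1 - sev)
    } else if (kind == "asymmetry") {
      c2L <- 0.5 + 0.9 * r * sev
      rL <- r * (1 - 0.25 * sev)
    } else if (kind == "expander_bulge") {
      # mild over-inflation plus surface rippling, the characteristic
      # surface signature of a tissue expander
      rL <- r * (1 + 0.15 * sev)
      ripple <- list(amplitude = 0.2 * r * sev, cycles = 3)
    }
  }
  f_l <- if (rL > 0) mound_field(c1L, c2L, rL, ripple, shiftL)
         else array(0, dim = c(n0, n, n))

  field <- array(pmax(field, f_r, f_l), dim = c(n0, n, n))

  if (spec$noise_sd > 0) {
    field <- with_seed(spec$seed, {
      field + array(stats::rnorm(length(field), sd = spec$noise_sd), dim = dim(field))
    })
    field <- clamp01(field)
  }

  volume_grid(field, spacing = c(1, 1, 1),
              axis_convention = c("anterior_posterior", "left_right", "cranio_caudal"))
}

#' Generate a labelled set of phantom surface renders
#'
#' Renders `n_normal` normal phantoms plus `n_anomalous_per_kind` phantoms of
#' each anomaly kind through the preprocessing chain (volume, frontal depth
#' render at `render_size`, bilinear resize to `spec_template$image_size`).
#' Per-image geometry jitter (mound radius and separation) and voxel noise are
#' drawn from a per-image seed derived deterministically from `seed`, so the
#' whole dataset is reproducible bit-for-bit.
#'
#' @param n_normal number of normal images.
#' @param n_anomalous_per_kind number of images per anomaly kind.
#' @param spec_template a [phantom_spec()] providing geometry defaults; its
#'   `severity` is used for the anomalous images.
#' @param seed integer master seed.
#' @param anomaly_kinds kinds to include (default all four).
#' @param render_size native render resolution before the final resize
#'   (default `round(1.25 * image_size)`).
#' @return A list with `images` (list of pixel matrices), `labels`
#'   (character), and `meta` (data.frame of per-image parameters).
#' @export
generate_image_dataset <- function(n_normal, n_anomalous_per_kind = 0,
                                   spec_template = phantom_spec(),
                                   seed = 1L,
                                   anomaly_kinds = c("asymmetry", "missing_mound",
                                                     "contracture", "expander_bulge"),
                                   render_size = NULL) {
  stopifnot(is_count(n_normal), is_count(n_anomalous_per_kind))
  if (!inherits(spec_template, "phantom_spec")) stop("spec_template must be a phantom_spec")
  out_size <- spec_template$image_size
  render_size <- as.integer(render_size %||% round(1.25 * out_size))

  kinds <- c(rep("none", n_normal),
             rep(anomaly_kinds, each = n_anomalous_per_kind))
  n_img <- length(kinds)
  images <- vector("list", n_img)
  meta <- data.frame(id = character(n_img), kind = kinds,
                     severity = numeric(n_img), seed = integer(n_img),
                     radius = numeric(n_img), separation = numeric(n_img),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_img)) {
    si <- derive_seed(seed, i)
    jit <- with_seed(si, stats::runif(2, c(0.92, 0.96), c(1.08, 1.04)))
    sev <- if (kinds[i] == "none") 0 else spec_template$severity
    sp <- phantom_spec(image_size = render_size,
                       torso_width_frac = spec_template$torso_width_frac,
                       mound_radius_frac = spec_template$mound_radius_frac * jit[1],
                       mound_separation_frac = spec_template$mound_separation_frac * jit[2],
                       anomaly_kind = kinds[i], severity = sev,
                       noise_sd = spec_template$noise_sd,
                       seed = derive_seed(si, 1))
    vol <- make_phantom_volume(sp)
    img <- render_frontal(vol, image_size = render_size)
    img <- resize_normalize(img, out_size)
    images[[i]] <- as_pixel_matrix(img)
    meta$id[i] <- sprintf("phantom_%04d_%s", i, kinds[i])
    meta$severity[i] <- sev
    meta$seed[i] <- si
    meta$radius[i] <- sp$mound_radius_frac
    meta$separation[i] <- sp$mound_separation_frac
  }
  list(images = images,
       labels = ifelse(kinds == "none", "normal", kinds),
       meta = meta)
}

#' Write a labelled image set as 8-bit grayscale PNGs
#'
#' @param dataset result of [generate_image_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_image_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    paths[i] <- file.path(dir, paste0(dataset$meta$id[i], ".png"))
    png::writePNG(clamp01(dataset$images[[i]]), paths[i])
  }
  utils::write.csv(cbind(dataset$meta, label = dataset$labels,
                         file = basename(paths)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(paths)
}
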