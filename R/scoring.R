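#' Anomaly score of an image
#'
#' Weighted sum of the reconstruction loss `R(X)` and the critic
#' feature-dissimilarity `D(X)` of an image under a trained model:
#' `AS = (1 - lambda) * R(X) + lambda * D(X)`. The default weight
#' `lambda = 0.95` follows the published configuration. Higher scores
#' indicate a more abnormal appearance.
#'
#' @param X image (matrix, `rendered_image`, or flattened vector).
#' @param model a trained `gan_model` (encoder required).
#' @param lambda weight in `[0, 1]`.
#' @param image_id optional identifier carried into the result.
#' @return An object of class `anomaly_result` with fields `image_id`,
#'   `r_term`, `d_term`, `lambda`, `raw_as` and `z_as` (`NA` until
#'   [standardize()] is applied).
#' @export
anomaly_score <- function(X, model, lambda = 0.95, image_id = NA_character_) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (!is.function(model$E) && !isTRUE(model$trained$encoder)) {
    stop("encoder is untrained; run train_encoder() first")
  }
  losses <- compute_losses(X, model)
  structure(list(image_id = image_id,
                 r_term = losses$loss_images,
                 d_term = losses$loss_features,
                 lambda = lambda,
                 raw_as = (1 - lambda) * losses$loss_images +
                   lambda * losses$loss_features,
                 z_as = NA_real_),
            class = "anomaly_result")
}

#' Reference statistics of the normal score distribution
#'
#' Mean and sample standard deviation (n - 1 denominator) of raw anomaly
#' scores on a normal reference set, used to standardize scores as z-scores.
#'
#' @param normal_scores numeric vector of raw anomaly scores (>= 2 finite
#'   values with nonzero variance).
#' @param source description of the reference image set.
#' @return An object of class `reference_stats` with `mean`, `sd`,
#'   `n_reference`, `source`.
#' @export
fit_reference <- function(normal_scores, source = "normal training images") {
  s <- normal_scores[is.finite(normal_scores)]
  if (length(s) < 2) stop("need at least 2 finite reference scores")
  sd_ <- stats::sd(s)
  if (sd_ == 0) stop_named("anoscore_zero_variance",
                           "reference scores have zero variance")
  structure(list(mean = mean(s), sd = sd_, n_reference = length(s),
                 source = source),
            class = "reference_stats")
}

#' Standardize an anomaly score as a z-score
#'
#' @param result an `anomaly_result` (or a numeric raw score).
#' @param ref a [fit_reference()] object.
#' @return The `anomaly_result` with `z_as` set (or, for numeric input, the
#'   z-score itself).
#' @export
standardize <- function(result, ref) {
  stopifnot(inherits(ref, "reference_stats"))
  if (is.numeric(result)) return((result - ref$mean) / ref$sd)
  stopifnot(inherits(result, "anomaly_result"))
  result$z_as <- (result$raw_as - ref$mean) / ref$sd
  result
}

#' Score a set of images
#'
#' @param images list of images (all of the model's input size).
#' @param model trained `gan_model`.
#' @param lambda score weight.
#' @param ref optional [fit_reference()]; when supplied, z-scores are filled.
#' @param ids optional image identifiers.
#' @return A data.frame with one row per image: `image_id`, `r_term`,
#'   `d_term`, `raw_as`, `z_as`.
#' @export
score_images <- function(images, model, lambda = 0.95, ref = NULL, ids = NULL) {
  ids <- ids %||% sprintf("img_%04d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    r <- anomaly_score(images[[i]], model, lambda, image_id = ids[i])
    if (!is.null(ref)) r <- standardize(r, ref)
    data.frame(image_id = r$image_id, r_term = r$r_term, d_term = r$d_term,
               raw_as = r$raw_as, z_as = r$z_as, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score a patient's visit series
#'
#' Scores each supplied visit independently with the same frozen model and
#' reference statistics; visits that are absent from the input are absent
#' from the output (never imputed).
#'
#' @param images named list with any subset of `pre_rt`, `post_1y`,
#'   `post_2y`.
#' @param model trained `gan_model`.
#' @param lambda score weight.
#' @param ref a [fit_reference()] object.
#' @return Named list of standardized `anomaly_result`s, one per supplied
#'   visit.
#' @export
score_timeseries <- function(images, model, lambda = 0.95, ref) {
  visits <- c("pre_rt", "post_1y", "post_2y")
  if (length(images) == 0) stop("at least one visit must be present")
  if (!all(names(images) %in% visits)) {
    stop("visit names must be among: ", paste(visits, collapse = ", "))
  }
  sizes <- vapply(images, function(im) nrow(as_pixel_matrix(im)), integer(1))
  if (length(unique(sizes)) > 1) {
    stop_named("anoscore_size_mismatch", "inconsistent image sizes across visits")
  }
  out <- lapply(names(images), function(v) {
    standardize(anomaly_score(images[[v]], model, lambda, image_id = v), ref)
  })
  names(out) <- names(images)
  out[visits[visits %in% names(images)]]
}
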