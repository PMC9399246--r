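#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded generators are reproducible without disturbing the session.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic per-item seed stream split, kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 100003 + as.double(i) * 7919) %% 2147483647)
}

clamp01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  # pmin/pmax take attributes from their first (scalar) argument; keep dims
  attributes(y) <- attributes(x)
  y
}

stop_named <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == round(x)
}

# Coerce a rendered_image or plain matrix to a pixel matrix in [0,1]
as_pixel_matrix <- function(x) {
  if (inherits(x, "rendered_image")) return(x$pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a rendered_image or a numeric matrix")
}
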