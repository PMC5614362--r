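# Feature channels: derived 3D scalar grids computed from the raw data or
# from other channels. Array-level filter functions are exported separately
# from the channel wrappers so they can be used (and cross-checked) on plain
# arrays.

gaussian_kernel <- function(sigma, order = 0, truncate = 4) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(truncate * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = -x / sigma^2 * g, # odd: sums to zero exactly
    "2" = {
      k <- (x^2 / sigma^4 - 1 / sigma^2) * g
      k - mean(k) # zero-sum so constants map to exactly zero
    },
    stop("unsupported kernel order"))
}

boundary_code <- function(boundary) {
  switch(match.arg(boundary, c("reflect", "periodic")),
         reflect = 0L, periodic = 1L)
}

conv_axis <- function(x, kernel, axis, boundary = "reflect") {
  conv_axis_cpp(as.numeric(x), as.integer(dim(x)), as.numeric(kernel),
                as.integer(axis), boundary_code(boundary))
}

#' Separable 3D Gaussian smoothing
#'
#' Isotropic Gaussian filter with the kernel truncated at 4 standard
#' deviations and reflect (or periodic) boundary handling.
#'
#' @param x numeric 3D array.
#' @param sigma standard deviation in voxels (> 0).
#' @param boundary `"reflect"` (default) or `"periodic"`.
#' @param order per-axis derivative order, length 3 (0, 1 or 2); the default
#'   `c(0, 0, 0)` is plain smoothing.
#' @return filtered array, same extent.
#' @export
gaussian_filter <- function(x, sigma, boundary = "reflect",
                            order = c(0, 0, 0)) {
  stopifnot(length(dim(x)) == 3, sigma > 0, length(order) == 3)
  for (a in 1:3) x <- conv_axis(x, gaussian_kernel(sigma, order[a]), a,
                                boundary)
  x
}

#' Total-variation denoising (Chambolle dual projection)
#'
#' Isotropic ROF denoising `min_u ||u - f||^2 / 2 + lambda * TV_w(u)` run for
#' a fixed number of dual-projection iterations; `spacing` weights the
#' per-axis finite differences inside the TV term, and `clamp` truncates the
#' input intensities before denoising.
#'
#' @param x numeric 3D array.
#' @param lambda regularization weight (> 0); larger values smooth more.
#' @param spacing per-axis gradient weights `(z, y, x)`.
#' @param n_iter number of iterations (>= 1, no early stopping).
#' @param clamp optional `c(lo, hi)`; use `NA` for an open bound.
#' @return denoised array.
#' @export
tv_denoise <- function(x, lambda = 10, spacing = c(1, 1, 1), n_iter = 100,
                       clamp = NULL) {
  stopifnot(lambda > 0, n_iter >= 1, length(spacing) == 3, all(spacing > 0))
  if (!is.null(clamp)) {
    stopifnot(length(clamp) == 2)
    if (!anyNA(clamp) && clamp[1] > clamp[2])
      stop("clamp bounds must be ordered")
    if (!is.na(clamp[1])) x <- pmax(x, clamp[1])
    if (!is.na(clamp[2])) x <- pmin(x, clamp[2])
  }
  d <- dim(x)
  w <- spacing
  fwd <- function(u, a, wt) { # weighted forward difference, Neumann far edge
    g <- array(0, d)
    n <- d[a]
    if (n > 1) {
      idx <- slice.index(u, a)
      g <- (shift_axis(u, a, -1) - u) * wt
      g[idx == n] <- 0
    }
    g
  }
  tau <- 1 / (12 * max(w)^2)
  p1 <- array(0, d); p2 <- array(0, d); p3 <- array(0, d)
  fol <- x / lambda
  for (it in seq_len(n_iter)) {
    divp <- div3(p1, p2, p3, w)
    r <- divp - fol
    g1 <- fwd(r, 1, w[1]); g2 <- fwd(r, 2, w[2]); g3 <- fwd(r, 3, w[3])
    nrm <- sqrt(g1^2 + g2^2 + g3^2)
    den <- 1 + tau * nrm
    p1 <- (p1 + tau * g1) / den
    p2 <- (p2 + tau * g2) / den
    p3 <- (p3 + tau * g3) / den
  }
  x - lambda * div3(p1, p2, p3, w)
}

# shift array along axis: k = -1 brings element i+1 to position i
shift_axis <- function(u, a, k) {
  d <- dim(u)
  idx <- rep(list(quote(expr = )), 3)
  n <- d[a]
  src <- pmin(pmax(seq_len(n) - k, 1L), n)
  idx[[a]] <- src
  do.call(`[`, c(list(u), idx, list(drop = FALSE)))
}

div3 <- function(p1, p2, p3, w) {
  d <- dim(p1)
  bwd <- function(p, a, wt) { # adjoint of the weighted forward difference
    n <- d[a]
    idx <- slice.index(p, a)
    pm <- shift_axis(p, a, 1)
    out <- (p - pm) * wt
    out[idx == 1] <- p[idx == 1] * wt
    if (n > 1) out[idx == n] <- -pm[idx == n] * wt
    out
  }
  bwd(p1, 1, w[1]) + bwd(p2, 2, w[2]) + bwd(p3, 3, w[3])
}

#' Discrete (isotropic) total variation of a 3D array
#' @param x numeric 3D array.
#' @param spacing per-axis gradient weights.
#' @return scalar TV value.
#' @export
discrete_tv <- function(x, spacing = c(1, 1, 1)) {
  d <- dim(x)
  acc <- array(0, d)
  for (a in 1:3) {
    g <- (shift_axis(x, a, -1) - x) * spacing[a]
    g[slice.index(x, a) == d[a]] <- 0
    acc <- acc + g^2
  }
  sum(sqrt(acc))
}

#' Binary threshold mask
#' @param x numeric array.
#' @param vmin,vmax inclusive bounds; either may be `NULL` (open), not both.
#' @return 0/1 array of the same extent.
#' @export
threshold_mask <- function(x, vmin = NULL, vmax = NULL) {
  if (is.null(vmin) && is.null(vmax)) stop("at least one bound is required")
  m <- array(TRUE, dim(x))
  if (!is.null(vmin)) m <- m & (x >= vmin)
  if (!is.null(vmax)) m <- m & (x <= vmax)
  out <- m * 1
  dim(out) <- dim(x)
  out
}

#' Local mean removal (Gaussian centering)
#' @inheritParams gaussian_filter
#' @return `x - G_sigma(x)`.
#' @export
local_centering <- function(x, sigma = 2, boundary = "reflect") {
  x - gaussian_filter(x, sigma, boundary)
}

#' Local z-score (Gaussian normalization)
#'
#' `(x - G(x)) / sqrt(G((x - G(x))^2) + eps)` with
#' `eps = 1e-8 * var(x)` guarding against division by zero in flat regions.
#' @inheritParams gaussian_filter
#' @return locally normalized array.
#' @export
local_normalization <- function(x, sigma = 2, boundary = "reflect") {
  c0 <- local_centering(x, sigma, boundary)
  eps <- 1e-8 * max(stats::var(as.numeric(x)), .Machine$double.eps)
  c0 / sqrt(gaussian_filter(c0^2, sigma, boundary) + eps)
}

#' Laplacian-of-Gaussian blob response
#'
#' Sum of the three second-derivative-of-Gaussian responses. With
#' `response = "bright"` the sign is flipped so bright blobs score positive;
#' `thresh = TRUE` zeroes negative responses after the sign convention.
#' @inheritParams gaussian_filter
#' @param thresh zero out negative responses.
#' @param response `"bright"` or `"dark"`.
#' @export
log_filter <- function(x, sigma = 2, thresh = FALSE, response = "bright",
                       boundary = "reflect") {
  response <- match.arg(response, c("bright", "dark"))
  out <- gaussian_filter(x, sigma, boundary, order = c(2, 0, 0)) +
         gaussian_filter(x, sigma, boundary, order = c(0, 2, 0)) +
         gaussian_filter(x, sigma, boundary, order = c(0, 0, 2))
  if (response == "bright") out <- -out
  if (thresh) out[out < 0] <- 0
  out
}

#' Difference of Gaussians
#' @inheritParams gaussian_filter
#' @param sigma_init inner scale.
#' @param sigma_ratio outer/inner scale ratio (> 1).
#' @export
dog_filter <- function(x, sigma_init = 2, sigma_ratio = 1.6,
                       boundary = "reflect") {
  stopifnot(sigma_ratio > 1)
  gaussian_filter(x, sigma_init, boundary) -
    gaussian_filter(x, sigma_init * sigma_ratio, boundary)
}

#' Determinant of the 3D structure tensor
#'
#' Gradients are taken as Gaussian derivatives at scale `sigma1`; the six
#' tensor products are averaged at scale `sigma_area`; the per-voxel 3x3
#' determinant is returned (non-negative up to numerical tolerance).
#' @inheritParams gaussian_filter
#' @param sigma1 gradient scale.
#' @param sigma_area tensor averaging scale.
#' @export
structure_tensor_det_filter <- function(x, sigma1 = 2, sigma_area = 2,
                                        boundary = "reflect") {
  gz <- gaussian_filter(x, sigma1, boundary, order = c(1, 0, 0))
  gy <- gaussian_filter(x, sigma1, boundary, order = c(0, 1, 0))
  gx <- gaussian_filter(x, sigma1, boundary, order = c(0, 0, 1))
  S <- function(v) gaussian_filter(v, sigma_area, boundary)
  jzz <- S(gz * gz); jyy <- S(gy * gy); jxx <- S(gx * gx)
  jzy <- S(gz * gy); jzx <- S(gz * gx); jyx <- S(gy * gx)
  jzz * (jyy * jxx - jyx^2) - jzy * (jzy * jxx - jyx * jzx) +
    jzx * (jzy * jyx - jyy * jzx)
}

# ---------------------------------------------------------------------------
# Channel wrappers over a workspace
# ---------------------------------------------------------------------------

# Table-of-defaults parameter ranges; values outside warn, not error.
PARAM_RANGES <- list(
  sigma = c(0.5, 10), lambda = c(0.1, 30), n_iter = c(50, 500),
  tv_spacing = c(0.1, 10), sigma_ratio = c(1.1, 3), compactness = c(1, 200),
  sv_spacing = c(0.1, 5), lambda_mv = c(0.01, 1), num_bins = c(10, 200),
  n_trees = c(10, 100), refine_lambda = c(1, 500), radius = c(1, 20)
)

check_range <- function(value, key, what = key) {
  r <- PARAM_RANGES[[key]]
  if (!is.null(r) && any(value < r[1] | value > r[2]))
    warning(what, " = ", paste(value, collapse = ","),
            " is outside the usual range [", r[1], ", ", r[2], "]",
            call. = FALSE)
  value
}

CHANNEL_OPERATORS <- c("gaussian", "total_variation", "threshold",
                       "gaussian_centering", "gaussian_normalization",
                       "log", "dog", "structure_tensor_det")

#' Compute a feature channel
#'
#' Computes one derived channel over the workspace ROI and stores it under
#' `name`. Sources may be `"raw"` or any previously computed channel, so
#' filter sets can be layered (e.g. a Gaussian channel feeding a
#' total-variation channel). Recomputing a channel drops channels derived
#' from it.
#'
#' Operators and their parameters (defaults in parentheses):
#' \describe{
#'   \item{gaussian}{`sigma` (1)}
#'   \item{total_variation}{`lambda` (10), `spacing` (1,1,1), `n_iter` (100),
#'     `clamp` (none)}
#'   \item{threshold}{`vmin`, `vmax` (at least one)}
#'   \item{gaussian_centering}{`sigma` (2)}
#'   \item{gaussian_normalization}{`sigma` (2)}
#'   \item{log}{`sigma` (2), `thresh` (FALSE), `response` ("bright")}
#'   \item{dog}{`sigma_init` (2), `sigma_ratio` (1.6)}
#'   \item{structure_tensor_det}{`sigma1` (2), `sigma_area` (2)}
#' }
#'
#' @param ws a workspace.
#' @param name channel name (unique within the workspace).
#' @param operator one of the eight operator names above.
#' @param source `"raw"` or an existing channel name.
#' @param params named list of operator parameters.
#' @return the `feature_channel` record, invisibly.
#' @export
compute_channel <- function(ws, name, operator, source = "raw",
                            params = list()) {
  stopifnot(inherits(ws, "srvox_workspace"))
  operator <- match.arg(operator, CHANNEL_OPERATORS)
  x <- source_data(ws, source)
  p <- params
  data <- switch(operator,
    gaussian = {
      sigma <- check_range(p$sigma %||% 1, "sigma")
      gaussian_filter(x, sigma, p$boundary %||% "reflect")
    },
    total_variation = {
      lambda <- check_range(p$lambda %||% 10, "lambda")
      n_iter <- check_range(p$n_iter %||% 100, "n_iter")
      tv_denoise(x, lambda, p$spacing %||% c(1, 1, 1), n_iter, p$clamp)
    },
    threshold = threshold_mask(x, p$vmin, p$vmax),
    gaussian_centering = local_centering(
      x, check_range(p$sigma %||% 2, "sigma"), p$boundary %||% "reflect"),
    gaussian_normalization = local_normalization(
      x, check_range(p$sigma %||% 2, "sigma"), p$boundary %||% "reflect"),
    log = log_filter(x, check_range(p$sigma %||% 2, "sigma"),
                     p$thresh %||% FALSE, p$response %||% "bright"),
    dog = dog_filter(x, check_range(p$sigma_init %||% 2, "sigma"),
                     check_range(p$sigma_ratio %||% 1.6, "sigma_ratio")),
    structure_tensor_det = structure_tensor_det_filter(
      x, check_range(p$sigma1 %||% 2, "sigma"),
      check_range(p$sigma_area %||% 2, "sigma"))
  )
  invalidate_dependents(ws, name)
  ch <- structure(list(name = name, operator = operator, source = source,
                       params = params, data = data),
                  class = "feature_channel")
  ws$channels[[name]] <- ch
  invisible(ch)
}

invalidate_dependents <- function(ws, name) {
  dep <- names(ws$channels)[vapply(ws$channels,
                                   function(ch) identical(ch$source, name),
                                   logical(1))]
  for (d in dep) {
    ws$channels[[d]] <- NULL
    invalidate_dependents(ws, d)
  }
  invisible(NULL)
}

#' @export
print.feature_channel <- function(x, ...) {
  cat("feature channel '", x$name, "': ", x$operator, "(", x$source, ")",
      "  extent ", paste(dim(x$data), collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Compute a queue of feature channels in dependency order
#'
#' Channel specs may reference each other as sources; the queue is
#' topologically sorted before computation (a cycle or a missing source is
#' an error), matching the batch compute-features behavior of the protocol.
#'
#' @param ws a workspace.
#' @param specs list of channel specs: `list(name=, operator=, source=,
#'   params=)`; `source` defaults to `"raw"`.
#' @return names of the computed channels, invisibly.
#' @export
compute_queue <- function(ws, specs) {
  if (length(specs) == 0) return(invisible(character(0)))
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate channel names in queue")
  src <- vapply(specs, function(s) s$source %||% "raw", character(1))
  known <- c("raw", names(ws$channels))
  # Kahn topological sort over in-queue dependencies
  order <- character(0)
  pending <- nm
  while (length(pending)) {
    ready <- pending[vapply(pending, function(n) {
      s <- src[match(n, nm)]
      s %in% known || s %in% order
    }, logical(1))]
    if (!length(ready)) {
      bad <- src[match(pending, nm)]
      if (any(!bad %in% c(known, nm)))
        stop("queue references undefined source(s): ",
             paste(setdiff(bad, c(known, nm)), collapse = ", "))
      stop("cyclic dependency in channel queue: ",
           paste(pending, collapse = ", "))
    }
    order <- c(order, ready)
    pending <- setdiff(pending, ready)
  }
  for (n in order) {
    s <- specs[[match(n, nm)]]
    compute_channel(ws, s$name, s$operator, s$source %||% "raw",
                    s$params %||% list())
  }
  invisible(order)
}
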