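#' Multi-echo magnitude image
#'
#' Container for a multi-echo gradient-echo magnitude acquisition: a 4D
#' array (x, y, z, echo) with echo times in ms.
#'
#' @param data 4D numeric array, echo along the 4th axis (a list of 3D
#'   arrays is also accepted).
#' @param echo_times Echo times, ms, strictly increasing, one per echo.
#' @param tr Repetition time, ms.
#' @param voxel_size mm per axis.
#' @return Object of class `multi_echo_image`.
#' @export
multi_echo_image <- function(data, echo_times, tr = 800,
                             voxel_size = c(1, 1, 1)) {
  if (is.list(data)) {
    shp <- dim(data[[1]])
    stopifnot(all(vapply(data, function(d) identical(dim(d), shp), logical(1))))
    arr <- array(0, dim = c(shp, length(data)))
    for (e in seq_along(data)) arr[, , , e] <- data[[e]]
    data <- arr
  }
  stopifnot(is.array(data), length(dim(data)) == 4L)
  ne <- dim(data)[4]
  if (ne < 2L) stop("need at least two echoes")
  if (length(echo_times) != ne) stop("one echo time per echo required")
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0)) {
    stop("echo_times must be positive and strictly increasing")
  }
  if (any(data < 0)) stop("magnitude intensities must be non-negative")
  structure(
    list(data = data, echo_times = echo_times, tr = tr,
         voxel_size = voxel_size),
    class = "multi_echo_image"
  )
}

#' Mono-exponential signal model
#'
#' Predicted multi-echo magnitude signal `s0 * exp(-r2star * TE)`, with
#' TE in ms and R2* in s^-1.
#'
#' @param s0 Signal at TE = 0.
#' @param r2star Effective transverse relaxation rate, s^-1; must be
#'   non-negative.
#' @param echo_times Echo times, ms.
#' @return Numeric vector of predicted signals, one per echo.
#' @export
signal_model <- function(s0, r2star, echo_times) {
  if (any(echo_times < 0)) stop("echo times must be non-negative")
  if (r2star < 0) stop("r2star must be non-negative")
  s0 * exp(-r2star * echo_times / 1000)
}

#' Fit a voxelwise R2* map
#'
#' Estimates (S0, R2*) per voxel from the multi-echo decay
#' `S(TE) = S0 * exp(-R2* * TE)`. The default is log-linear weighted
#' least squares with weights proportional to the squared signal
#' (near maximum-likelihood at moderate SNR); `method = "nonlinear"`
#' refines each in-mask voxel with a bounded Gauss-Newton fit
#' (stats::nls, port algorithm) started from the log-linear solution.
#'
#' Voxels whose first-echo signal falls below `floor_factor` times the
#' estimated background noise level, or that contain non-positive
#' signals, are masked out (`fit_ok = FALSE`, R2* = 0). Negative fitted
#' decay rates are clamped to 0 with `fit_ok` retained, so downstream
#' delta-R2* thresholds behave.
#'
#' @param img A [multi_echo_image()].
#' @param method "loglinear" or "nonlinear".
#' @param floor_factor Signal-floor multiple of the background noise
#'   estimate (first-echo median absolute deviation of the lowest-decile
#'   voxels); set 0 to disable the floor.
#' @return Object of class `r2star_map` with arrays `r2star` (s^-1),
#'   `s0`, logical `fit_ok`, `residual` (root-mean-square residual in
#'   signal units), and the source `echo_times`/`voxel_size`.
#' @export
fit_r2star_map <- function(img, method = c("loglinear", "nonlinear"),
                           floor_factor = 3) {
  stopifnot(inherits(img, "multi_echo_image"))
  method <- match.arg(method)
  te_s <- img$echo_times / 1000
  if (anyDuplicated(te_s)) stop("duplicate echo times")
  shp <- dim(img$data)[1:3]
  nv <- prod(shp)
  ne <- length(te_s)
  sig <- matrix(img$data, nrow = nv, ncol = ne)   # voxels x echoes

  # background noise level from the dimmest decile of first-echo voxels
  s1 <- sig[, 1]
  floor_level <- 0
  if (floor_factor > 0) {
    dim_vox <- s1[s1 <= stats::quantile(s1, 0.1)]
    noise_est <- stats::median(dim_vox) + stats::mad(dim_vox)
    # if the image has no dark background the estimate approaches the
    # signal itself; only apply the floor when it is genuinely low
    floor_level <- if (noise_est < stats::median(s1) / floor_factor) {
      floor_factor * noise_est
    } else 0
  }
  fit_ok <- s1 > floor_level & matrixStats_all_positive(sig)

  r2 <- numeric(nv)
  s0 <- numeric(nv)
  rss <- numeric(nv)
  idx <- which(fit_ok)
  if (length(idx)) {
    y <- log(sig[idx, , drop = FALSE])
    w <- sig[idx, , drop = FALSE]^2
    sw   <- rowSums(w)
    swx  <- w %*% te_s
    swx2 <- w %*% te_s^2
    swy  <- rowSums(w * y)
    swxy <- (w * y) %*% te_s
    denom <- sw * swx2 - swx^2
    slope <- (sw * swxy - swx * swy) / denom
    icept <- (swy - slope * swx) / sw
    r2[idx] <- pmax(-slope, 0)
    s0[idx] <- exp(icept)
    if (method == "nonlinear") {
      for (k in idx) {
        fit <- tryCatch(
          stats::nls(y ~ a * exp(-b * te_s), data = list(y = sig[k, ]),
                     start = list(a = s0[k], b = max(r2[k], 1e-6)),
                     algorithm = "port", lower = c(0, 0)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          cf <- stats::coef(fit)
          s0[k] <- cf[["a"]]
          r2[k] <- cf[["b"]]
        }
      }
    }
    pred <- outer(s0[idx], rep(1, ne)) *
      exp(-outer(r2[idx], te_s))
    rss[idx] <- sqrt(rowMeans((sig[idx, , drop = FALSE] - pred)^2))
  }

  structure(
    list(r2star = array(r2, dim = shp),
         s0 = array(s0, dim = shp),
         fit_ok = array(fit_ok, dim = shp),
         residual = array(rss, dim = shp),
         echo_times = img$echo_times,
         voxel_size = img$voxel_size),
    class = "r2star_map"
  )
}

matrixStats_all_positive <- function(m) {
  rowSums(m > 0) == ncol(m)
}

#' Construct an R2* map object from a bare array
#'
#' Convenience constructor used when a rate map comes from ground truth
#' or external software rather than [fit_r2star_map()].
#'
#' @param r2star 3D array of rates, s^-1.
#' @param s0 Optional signal-scale array.
#' @param fit_ok Optional logical mask (default all TRUE).
#' @param voxel_size mm per axis.
#' @return Object of class `r2star_map`.
#' @export
r2star_map <- function(r2star, s0 = NULL, fit_ok = NULL,
                       voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(r2star), length(dim(r2star)) == 3L)
  if (is.null(fit_ok)) fit_ok <- array(TRUE, dim = dim(r2star))
  if (is.null(s0)) s0 <- array(1, dim = dim(r2star))
  structure(
    list(r2star = r2star, s0 = s0, fit_ok = fit_ok,
         residual = array(0, dim = dim(r2star)),
         echo_times = NULL, voxel_size = voxel_size),
    class = "r2star_map"
  )
}
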