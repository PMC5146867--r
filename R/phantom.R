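#' Default ROI geometry
#'
#' Axis-aligned box regions for seven named brain regions of interest
#' (mPFC, NAc, CPu, HP, SSC, MC, LS), scaled to an arbitrary grid. The
#' boxes are mutually disjoint. Real atlas geometry is deliberately out
#' of scope; the boxes only need to give each region a contiguous,
#' non-overlapping voxel set.
#'
#' @param grid_shape Integer vector of length 3, voxels per axis.
#' @return Named list of integer vectors of linear voxel indices.
#' @export
default_roi_geometry <- function(grid_shape = c(64L, 64L, 16L)) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4))
  # fractional (x0,x1, y0,y1, z0,z1) extents per region
  frac <- list(
    mPFC = c(.44, .56, .78, .88, .35, .55),
    NAc  = c(.38, .47, .62, .72, .25, .45),
    CPu  = c(.60, .72, .60, .72, .35, .62),
    HP   = c(.31, .44, .31, .44, .50, .75),
    SSC  = c(.69, .81, .38, .50, .62, .82),
    MC   = c(.47, .59, .19, .28, .62, .82),
    LS   = c(.47, .56, .47, .56, .44, .62)
  )
  axis_range <- function(f0, f1, n) {
    lo <- max(1L, as.integer(ceiling(f0 * n + 1e-9)))
    hi <- min(n, max(lo, as.integer(floor(f1 * n + 1e-9))))
    lo:hi
  }
  lapply(frac, function(f) {
    xs <- axis_range(f[1], f[2], grid_shape[1])
    ys <- axis_range(f[3], f[4], grid_shape[2])
    zs <- axis_range(f[5], f[6], grid_shape[3])
    idx <- expand.grid(x = xs, y = ys, z = zs)
    as.integer(idx$x + (idx$y - 1L) * grid_shape[1] +
                 (idx$z - 1L) * grid_shape[1] * grid_shape[2])
  })
}

#' Default gene panel
#'
#' Three transcripts with a target region each and per-paradigm copy
#' numbers (copies per ng total RNA). Absolute values are synthetic
#' placeholders chosen to span a 10-fold range; the qualitative ordering
#' encodes reduced striatal HDAC5 after chronic amphetamine challenge
#' (A7WA) relative to saline (S1) and acute (A1) conditions.
#'
#' @return data.frame with columns gene, roi and one column per paradigm.
#' @export
default_gene_panel <- function() {
  data.frame(
    gene = c("HDAC5", "GFAP", "FosB"),
    roi  = c("CPu", "HP", "mPFC"),
    S1   = c(8000, 20000, 2000),
    A1   = c(8000, 20000, 2000),
    A7WS = c(8000, 20000, 2000),
    A7WA = c(4000, 24000, 2000),
    S7WS = c(8000, 20000, 2000),
    stringsAsFactors = FALSE
  )
}

paradigm_levels <- c("S1", "A1", "A7WS", "A7WA", "S7WS")

#' Phantom configuration
#'
#' Full description of the synthetic multi-echo phantom: grid, ROI
#' geometry, per-ROI baseline R2* distribution, gene panel with
#' per-paradigm copy numbers, the linear binding coefficient converting
#' copy number to bound iron, the uptake schedule, acquisition
#' parameters, and the noise model.
#'
#' @param grid_shape Voxels per axis (length 3).
#' @param voxel_size mm per axis.
#' @param roi_geometry Named list of linear voxel index vectors; regions
#'   must be disjoint.
#' @param baseline_r2star data.frame with columns roi, mean, sd (s^-1);
#'   one row per region in `roi_geometry`.
#' @param background_r2star Baseline R2* of non-ROI tissue, s^-1.
#' @param gene_panel data.frame as [default_gene_panel()].
#' @param binding_coeff Bound iron (mM) per unit copy number.
#' @param uptake_times Hours post-delivery at which post images are made.
#' @param plateau_time Hour at which uptake reaches its plateau; must be
#'   one of `uptake_times`.
#' @param uptake_shape "linear" (piecewise-linear rise) or "exponential"
#'   (saturating approach, renormalised to reach the plateau level
#'   exactly at `plateau_time`).
#' @param noise_sigma Noise scale as a fraction of `s0` (Rician by
#'   default); 0 disables noise.
#' @param noise_model "rician" or "gaussian".
#' @param s0 Proton-density signal scale.
#' @param tr Repetition time, ms.
#' @param echo_times Echo times, ms, strictly increasing.
#' @param subject_sd_scale Multiplier on the per-ROI baseline SD used to
#'   draw a subject-level baseline offset (0 gives every subject the
#'   population mean).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 16L),
                           voxel_size = c(0.15, 0.15, 0.5),
                           roi_geometry = default_roi_geometry(grid_shape),
                           baseline_r2star = NULL,
                           background_r2star = 15,
                           gene_panel = default_gene_panel(),
                           binding_coeff = 5e-5,
                           uptake_times = c(2, 4, 6),
                           plateau_time = 4,
                           uptake_shape = c("linear", "exponential"),
                           noise_sigma = 0.025,
                           noise_model = c("rician", "gaussian"),
                           s0 = 100,
                           tr = 800,
                           echo_times = c(1.94, 3.41, 4.88, 6.35, 7.82, 9.29),
                           subject_sd_scale = 1) {
  uptake_shape <- match.arg(uptake_shape)
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (is.null(baseline_r2star)) {
    baseline_r2star <- data.frame(
      roi  = c("mPFC", "NAc", "CPu", "HP", "SSC", "MC", "LS"),
      mean = c(19, 21, 20, 22, 18, 19, 21),
      sd   = rep(2, 7),
      stringsAsFactors = FALSE
    )
    baseline_r2star <- baseline_r2star[baseline_r2star$roi %in%
                                         names(roi_geometry), , drop = FALSE]
  }
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            is.list(roi_geometry), length(roi_geometry) > 0,
            !is.null(names(roi_geometry)))
  if (length(echo_times) < 2L || any(echo_times <= 0) ||
      any(diff(echo_times) <= 0)) {
    stop("echo_times must be positive and strictly increasing")
  }
  nvox <- prod(grid_shape)
  all_idx <- unlist(roi_geometry, use.names = FALSE)
  if (any(all_idx < 1L | all_idx > nvox)) {
    stop("roi_geometry indices out of grid range")
  }
  if (anyDuplicated(all_idx)) stop("roi_geometry regions must be disjoint")
  if (!setequal(baseline_r2star$roi, names(roi_geometry))) {
    stop("baseline_r2star must cover exactly the regions in roi_geometry")
  }
  if (any(baseline_r2star$mean <= 0)) stop("baseline means must be positive")
  if (any(baseline_r2star$sd < 0)) stop("baseline SDs must be non-negative")
  stopifnot(all(c("gene", "roi") %in% names(gene_panel)),
            all(gene_panel$roi %in% names(roi_geometry)))
  if (length(uptake_times) < 1L || is.unsorted(uptake_times, strictly = TRUE) ||
      any(uptake_times <= 0)) {
    stop("uptake_times must be positive and strictly increasing")
  }
  if (!plateau_time %in% uptake_times) {
    stop("plateau_time must be one of uptake_times")
  }
  stopifnot(binding_coeff >= 0, noise_sigma >= 0, s0 > 0, tr > 0,
            subject_sd_scale >= 0)
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         roi_geometry = roi_geometry, baseline_r2star = baseline_r2star,
         background_r2star = background_r2star, gene_panel = gene_panel,
         binding_coeff = binding_coeff, uptake_times = uptake_times,
         plateau_time = plateau_time, uptake_shape = uptake_shape,
         noise_sigma = noise_sigma, noise_model = noise_model,
         s0 = s0, tr = tr, echo_times = echo_times,
         subject_sd_scale = subject_sd_scale),
    class = "phantom_config"
  )
}

#' ROI label map as an integer array
#'
#' @param config A [phantom_config()].
#' @return Integer array of `grid_shape`, 0 outside ROIs, i inside the
#'   i-th region; region names in attribute `roi_names`.
#' @export
roi_label_map <- function(config) {
  lab <- array(0L, dim = config$grid_shape)
  for (i in seq_along(config$roi_geometry)) {
    lab[config$roi_geometry[[i]]] <- i
  }
  attr(lab, "roi_names") <- names(config$roi_geometry)
  lab
}

uptake_fraction <- function(times, plateau_time, shape = "linear") {
  f <- switch(shape,
    linear = pmin(times / plateau_time, 1),
    exponential = {
      k <- 3 / plateau_time      # ~95% of plateau level approached at t = plateau
      pmin((1 - exp(-k * times)) / (1 - exp(-3)), 1)
    },
    stop("unknown uptake shape")
  )
  pmin(pmax(f, 0), 1)
}

#' Simulate the probe uptake time course
#'
#' Bound-iron concentration rising smoothly from 0 to `final_level`,
#' reaching it exactly at the configured plateau time and holding it for
#' all later times (plateau at 4 h, held at 6 h, under the defaults).
#'
#' @param config A [phantom_config()].
#' @param final_level Plateau bound-iron concentration, mM.
#' @return data.frame with columns `time` (hours) and `level` (mM).
#' @export
simulate_uptake_timecourse <- function(config, final_level) {
  if (!is.numeric(final_level) || length(final_level) != 1L ||
      final_level < 0) {
    stop("final_level must be a single non-negative number")
  }
  frac <- uptake_fraction(config$uptake_times, config$plateau_time,
                          config$uptake_shape)
  data.frame(time = config$uptake_times, level = final_level * frac)
}

#' Copy numbers for a paradigm
#'
#' @param config A [phantom_config()].
#' @param paradigm One of S1, A1, A7WS, A7WA, S7WS.
#' @return data.frame gene, roi, copies.
#' @export
paradigm_copy_numbers <- function(config, paradigm) {
  paradigm <- match.arg(paradigm, paradigm_levels)
  gp <- config$gene_panel
  if (!paradigm %in% names(gp)) stop("gene panel lacks paradigm ", paradigm)
  data.frame(gene = gp$gene, roi = gp$roi, copies = gp[[paradigm]],
             stringsAsFactors = FALSE)
}

add_mri_noise <- function(signal, sigma_abs, model) {
  if (sigma_abs <= 0) return(signal)
  n <- length(signal)
  if (model == "rician") {
    # magnitude of complex Gaussian noise around the true signal
    re <- signal + stats::rnorm(n, 0, sigma_abs)
    im <- stats::rnorm(n, 0, sigma_abs)
    array(sqrt(re^2 + im^2), dim = dim(signal))
  } else {
    array(pmax(signal + stats::rnorm(n, 0, sigma_abs), 0),
          dim = dim(signal))
  }
}

make_echo_stack <- function(r2star_map, config) {
  te_s <- config$echo_times / 1000   # ms -> s; R2* is s^-1
  stack <- array(0, dim = c(config$grid_shape, length(te_s)))
  for (e in seq_along(te_s)) {
    sig <- config$s0 * exp(-r2star_map * te_s[e])
    stack[, , , e] <- add_mri_noise(sig, config$noise_sigma * config$s0,
                                    config$noise_model)
  }
  multi_echo_image(stack, echo_times = config$echo_times, tr = config$tr,
                   voxel_size = config$voxel_size)
}

#' Generate a synthetic subject session
#'
#' Builds a baseline multi-echo stack and one post-SPION stack per
#' uptake time. The forward model is linear: each targeted region's
#' bound-iron concentration is `binding_coeff * copies` at plateau,
#' scaled by the uptake fraction at earlier times, and elevates R2* by
#' `r2 * [Fe]` (s^-1) on top of the subject's baseline. The noiseless
#' echo signal is `s0 * exp(-R2* * TE)`; Rician (or Gaussian) noise of
#' scale `noise_sigma * s0` is then applied per voxel and echo. The
#' full ground truth is retained in the returned session.
#'
#' @param config A [phantom_config()].
#' @param paradigm Exposure paradigm label (S1, A1, A7WS, A7WA, S7WS).
#' @param seed Integer seed; identical (config, paradigm, seed) give
#'   identical output.
#' @param agent A [contrast_agent()] supplying the transverse relaxivity.
#' @param subject_id Subject label.
#' @return Object of class `subject_session` with elements `subject_id`,
#'   `paradigm`, `baseline` (multi_echo_image), `post` (named list of
#'   multi_echo_image, names = hours), and `truth` (class
#'   `phantom_truth`: `true_baseline_r2star` array, `true_bound_fe`
#'   ROI x time matrix (mM), `true_post_r2star` list of arrays,
#'   `copy_numbers` data.frame).
#' @export
generate_phantom <- function(config, paradigm = "S1", seed = 1L,
                             agent = contrast_agent(),
                             subject_id = sprintf("%s-seed%d", paradigm, seed)) {
  stopifnot(inherits(config, "phantom_config"))
  paradigm <- match.arg(paradigm, paradigm_levels)
  withr::with_seed(as.integer(seed), {
    base_map <- array(config$background_r2star, dim = config$grid_shape)
    bl <- config$baseline_r2star
    for (i in seq_len(nrow(bl))) {
      subj_mean <- bl$mean[i] +
        stats::rnorm(1, 0, bl$sd[i] * config$subject_sd_scale)
      base_map[config$roi_geometry[[bl$roi[i]]]] <- max(subj_mean, 0.1)
    }

    cn <- paradigm_copy_numbers(config, paradigm)
    rois <- names(config$roi_geometry)
    frac <- uptake_fraction(config$uptake_times, config$plateau_time,
                            config$uptake_shape)
    fe_final <- stats::setNames(numeric(length(rois)), rois)
    for (i in seq_len(nrow(cn))) {
      fe_final[cn$roi[i]] <- fe_final[cn$roi[i]] +
        config$binding_coeff * cn$copies[i]
    }
    bound_fe <- outer(fe_final, frac)   # ROI x time, mM
    colnames(bound_fe) <- as.character(config$uptake_times)

    post_maps <- vector("list", length(config$uptake_times))
    names(post_maps) <- as.character(config$uptake_times)
    for (t in seq_along(config$uptake_times)) {
      m <- base_map
      for (r in rois) {
        m[config$roi_geometry[[r]]] <-
          m[config$roi_geometry[[r]]] + agent$r2 * bound_fe[r, t]
      }
      post_maps[[t]] <- m
    }

    baseline_img <- make_echo_stack(base_map, config)
    post_imgs <- lapply(post_maps, make_echo_stack, config = config)

    truth <- structure(
      list(true_baseline_r2star = base_map,
           true_bound_fe = bound_fe,
           true_post_r2star = post_maps,
           copy_numbers = cn),
      class = "phantom_truth"
    )
    structure(
      list(subject_id = subject_id, paradigm = paradigm,
           baseline = baseline_img, post = post_imgs, truth = truth,
           config = config, agent = agent, seed = as.integer(seed)),
      class = "subject_session"
    )
  })
}
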