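#' Baseline R2* reference
#'
#' Per-ROI reference statistics of pre-contrast R2*: mean, SD across
#' reference subjects (or voxels), SEM = SD/sqrt(n). Used both for the
#' 3-SEM delta-R2* threshold and for the 1-SD baseline stratification of
#' incoming subjects.
#'
#' @param roi Character vector of region names.
#' @param mean,sd Per-ROI mean and SD of baseline R2*, s^-1.
#' @param n Number of observations behind each mean (subjects or voxels).
#' @return Object of class `baseline_reference` (a data.frame with
#'   columns roi, mean, sd, sem, n).
#' @export
baseline_reference <- function(roi, mean, sd, n) {
  stopifnot(length(roi) == length(mean), length(mean) == length(sd),
            all(sd >= 0), all(n >= 2))
  ref <- data.frame(roi = roi, mean = mean, sd = sd,
                    sem = sd / sqrt(n), n = n, stringsAsFactors = FALSE)
  class(ref) <- c("baseline_reference", "data.frame")
  ref
}

roi_means_of_map <- function(map, atlas) {
  arr <- if (inherits(map, "r2star_map")) map$r2star else map
  vapply(atlas, function(idx) mean(arr[idx]), numeric(1))
}

# subjects x ROIs matrix of ROI means (robust to a single-ROI atlas,
# where vapply collapses to a vector)
roi_mean_matrix <- function(maps, atlas) {
  res <- vapply(maps, roi_means_of_map, numeric(length(atlas)),
                atlas = atlas)
  m <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1)
  colnames(m) <- names(atlas)
  m
}

#' Build a baseline reference from R2* maps
#'
#' With several maps (a reference cohort), statistics are taken across
#' subjects' ROI means; with a single map, across the voxels of each
#' ROI.
#'
#' @param maps An `r2star_map` or list of them.
#' @param atlas Named list of linear voxel index vectors.
#' @return A [baseline_reference()].
#' @export
baseline_reference_from_maps <- function(maps, atlas) {
  if (inherits(maps, "r2star_map")) {
    arr <- maps$r2star
    m <- vapply(atlas, function(idx) mean(arr[idx]), numeric(1))
    s <- vapply(atlas, function(idx) stats::sd(arr[idx]), numeric(1))
    n <- vapply(atlas, length, numeric(1))
    s[n < 2] <- 0   # singleton ROI: no voxel spread to estimate
    return(baseline_reference(names(atlas), m, s, pmax(n, 2)))
  }
  stopifnot(is.list(maps), length(maps) >= 2)
  rm <- roi_mean_matrix(maps, atlas)
  baseline_reference(names(atlas), colMeans(rm), apply(rm, 2, stats::sd),
                     rep(nrow(rm), length(atlas)))
}

ref_row <- function(ref, roi) {
  i <- match(roi, ref$roi)
  if (is.na(i)) stop("ROI '", roi, "' missing from baseline reference")
  ref[i, ]
}

#' Stratify a subject on baseline R2*
#'
#' A subject is rejected when any ROI's baseline mean R2* deviates from
#' the reference mean by strictly more than one reference SD (a subject
#' sitting exactly at +1 SD is accepted). Used to exclude animals whose
#' baseline is perturbed before contrast delivery.
#'
#' @param baseline_map An `r2star_map` (or bare 3D array) of the
#'   subject's pre-contrast R2*.
#' @param ref A [baseline_reference()].
#' @param atlas Named list of voxel index vectors; must contain every
#'   ROI in `ref`.
#' @return List with `accept` (logical) and `flags`, a data.frame of
#'   per-ROI means, deviations in SD units, and pass/fail.
#' @export
stratify_subject <- function(baseline_map, ref, atlas) {
  missing_rois <- setdiff(ref$roi, names(atlas))
  if (length(missing_rois)) {
    stop("atlas lacks ROI(s): ", paste(missing_rois, collapse = ", "))
  }
  m <- roi_means_of_map(baseline_map, atlas[ref$roi])
  dev_sd <- (m - ref$mean) / ifelse(ref$sd > 0, ref$sd, Inf)
  ok <- abs(m - ref$mean) <= ref$sd   # strict "more than 1 SD" rejects
  list(accept = all(ok),
       flags = data.frame(roi = ref$roi, mean = m, deviation_sd = dev_sd,
                          ok = ok, stringsAsFactors = FALSE))
}

#' Compute a thresholded delta-R2* map
#'
#' Per voxel, the contrast-attributable R2* elevation above a
#' significance threshold of the baseline reference:
#' `delta = max(0, post - (ref_mean + 3 * ref_SEM))`, with the
#' ROI-specific reference mean and SEM (`mode = "roi"`, the default).
#' `mode = "voxel"` thresholds against the subject's own baseline map
#' voxelwise (`post - (baseline + 3 * ref_SEM)`). The percent map is
#' `delta / ref_mean * 100`.
#'
#' @param post,baseline `r2star_map`s (baseline is only consulted in
#'   voxelwise mode but shape-checked always).
#' @param ref A [baseline_reference()] with finite SEM.
#' @param atlas Named list of voxel index vectors.
#' @param mode "roi" or "voxel".
#' @param n_sem Threshold multiple of the SEM (default 3).
#' @return Object of class `delta_r2star_map`: arrays `delta` (s^-1, 0
#'   below threshold and outside the atlas) and `percent`, plus the
#'   per-ROI `threshold` table.
#' @export
compute_delta_map <- function(post, baseline, ref, atlas,
                              mode = c("roi", "voxel"), n_sem = 3) {
  mode <- match.arg(mode)
  post_arr <- if (inherits(post, "r2star_map")) post$r2star else post
  base_arr <- if (inherits(baseline, "r2star_map")) baseline$r2star else baseline
  if (!identical(dim(post_arr), dim(base_arr))) stop("map shapes differ")
  if (any(!is.finite(ref$sem))) stop("baseline reference SEM missing")
  delta <- array(0, dim = dim(post_arr))
  pct <- array(0, dim = dim(post_arr))
  thr <- data.frame(roi = ref$roi, threshold = ref$mean + n_sem * ref$sem)
  for (r in names(atlas)) {
    rr <- ref_row(ref, r)
    idx <- atlas[[r]]
    lim <- if (mode == "roi") rr$mean + n_sem * rr$sem
           else base_arr[idx] + n_sem * rr$sem
    d <- pmax(post_arr[idx] - lim, 0)
    delta[idx] <- d
    pct[idx] <- d / rr$mean * 100
  }
  structure(
    list(delta = delta, percent = pct, threshold = thr,
         mode = mode, n_sem = n_sem),
    class = "delta_r2star_map"
  )
}

#' Contrast-to-noise ratio
#'
#' The study's operational CNR: mean delta-R2* divided by the square
#' root of the baseline R2* standard deviation, implemented exactly as
#' printed despite its unusual units. `conventional = TRUE` gives the
#' textbook variant delta / SD instead.
#'
#' @param delta_mean Mean delta-R2* in the ROI, s^-1 (non-negative).
#' @param baseline_sd Baseline R2* SD, s^-1 (positive).
#' @param roi Optional ROI label.
#' @param conventional Use delta / SD instead of delta / sqrt(SD).
#' @return Object of class `cnr_result` (list with roi, cnr, delta_mean,
#'   baseline_sd).
#' @export
compute_cnr <- function(delta_mean, baseline_sd, roi = NA_character_,
                        conventional = FALSE) {
  if (!is.numeric(baseline_sd) || baseline_sd <= 0) {
    stop("baseline_sd must be positive")
  }
  if (delta_mean < 0) stop("delta_mean must be non-negative")
  cnr <- if (conventional) delta_mean / baseline_sd
         else delta_mean / sqrt(baseline_sd)
  structure(list(roi = roi, cnr = cnr, delta_mean = delta_mean,
                 baseline_sd = baseline_sd, conventional = conventional),
            class = "cnr_result")
}

#' Detect the uptake plateau
#'
#' Earliest time point whose mean is matched, within a relative
#' tolerance, by every later mean. A curve still rising at the last
#' sample has no plateau: the last time is returned with
#' `no_plateau = TRUE`.
#'
#' @param curve data.frame with columns `time` (hours) and `delta_mean`.
#' @param rel_tol Relative tolerance (fraction of the candidate mean).
#' @return List with `plateau_time` and `no_plateau` flag.
#' @export
detect_plateau <- function(curve, rel_tol = 0.05) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 3,
            all(c("time", "delta_mean") %in% names(curve)))
  m <- curve$delta_mean
  n <- length(m)
  for (i in seq_len(n - 1)) {
    later <- m[(i + 1):n]
    tol <- rel_tol * max(abs(m[i]), .Machine$double.eps)
    if (all(abs(later - m[i]) <= tol)) {
      return(list(plateau_time = curve$time[i], no_plateau = FALSE))
    }
  }
  list(plateau_time = curve$time[n], no_plateau = TRUE)
}

neighbor_offsets_26 <- function(shp) {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  d <- d[order(d$dx, d$dy, d$dz), ]
  d[seq_len(nrow(d) / 2), ]   # half-space; each pair found once
}

#' Subtract two R2* maps and find candidate ROIs
#'
#' Voxelwise `a - b` clipped at 0; connected components
#' (26-connectivity) of voxels exceeding `threshold` are reported as
#' candidate regions with size, centroid, and mean difference. Used to
#' discover regions differentially elevated between conditions
#' (e.g. chronic minus acute).
#'
#' @param map_a,map_b `r2star_map`s (or arrays) on the same grid.
#' @param threshold Difference threshold, s^-1.
#' @return List with `difference` (array) and `candidates`, a data.frame
#'   (id, n_voxels, centroid_x/y/z, mean_diff) sorted by size, plus
#'   `voxels`, a list of linear index vectors per candidate.
#' @export
subtract_maps <- function(map_a, map_b, threshold = 1) {
  a <- if (inherits(map_a, "r2star_map")) map_a$r2star else map_a
  b <- if (inherits(map_b, "r2star_map")) map_b$r2star else map_b
  if (!identical(dim(a), dim(b))) stop("map grids differ")
  shp <- dim(a)
  diff <- pmax(a - b, 0)
  supra <- which(diff > threshold)
  empty <- list(difference = diff,
                candidates = data.frame(id = integer(), n_voxels = integer(),
                                        centroid_x = numeric(),
                                        centroid_y = numeric(),
                                        centroid_z = numeric(),
                                        mean_diff = numeric()),
                voxels = list())
  if (!length(supra)) return(empty)

  rank <- array(0L, dim = shp)
  rank[supra] <- seq_along(supra)
  coords <- arrayInd(supra, shp)
  offs <- neighbor_offsets_26(shp)
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, as.numeric(offs[k, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] &
          nb[, 2] >= 1 & nb[, 2] <= shp[2] &
          nb[, 3] >= 1 & nb[, 3] <= shp[3]
    if (!any(ok)) next
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * shp[1] +
      (nb[ok, 3] - 1) * shp[1] * shp[2]
    hit <- rank[lin] > 0L
    if (any(hit)) {
      edges <- rbind(edges,
                     cbind(which(ok)[hit], rank[lin][hit]))
    }
  }
  g <- igraph::make_empty_graph(n = length(supra), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  cand <- lapply(seq_len(comp$no), function(ci) supra[comp$membership == ci])
  stats_df <- do.call(rbind, lapply(seq_along(cand), function(ci) {
    idx <- cand[[ci]]
    cc <- arrayInd(idx, shp)
    data.frame(id = ci, n_voxels = length(idx),
               centroid_x = mean(cc[, 1]), centroid_y = mean(cc[, 2]),
               centroid_z = mean(cc[, 3]), mean_diff = mean(diff[idx]))
  }))
  ord <- order(-stats_df$n_voxels)
  stats_df <- stats_df[ord, ]
  stats_df$id <- seq_len(nrow(stats_df))
  rownames(stats_df) <- NULL
  list(difference = diff, candidates = stats_df, voxels = cand[ord])
}

#' Per-subject ROI means of a delta map
#'
#' @param delta A `delta_r2star_map` (or bare array).
#' @param atlas Named list of voxel index vectors.
#' @return Named numeric vector of ROI means.
#' @export
roi_delta_means <- function(delta, atlas) {
  arr <- if (inherits(delta, "delta_r2star_map")) delta$delta else delta
  vapply(atlas, function(idx) {
    if (!length(idx)) stop("empty ROI in atlas")
    mean(arr[idx])
  }, numeric(1))
}

perm_test_two_sample <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- abs(mean(x) - mean(y))
  combs <- utils::combn(length(pooled), nx)
  diffs <- apply(combs, 2, function(ix) {
    abs(mean(pooled[ix]) - mean(pooled[-ix]))
  })
  mean(diffs >= obs - 1e-12)
}

#' Aggregate delta-R2* by ROI and group
#'
#' Computes per-ROI group means and SEMs of subject-level ROI means, and
#' annotates each ROI with a two-sample test p-value between two groups.
#'
#' @param delta_list List of `delta_r2star_map`s (or arrays), one per
#'   subject.
#' @param atlas Named list of voxel index vectors.
#' @param groups Character vector of group labels, one per subject.
#' @param comparison Length-2 character vector of group labels to test;
#'   default the first two distinct labels (skipped if only one group).
#' @param test "welch", "student", or "permutation" (exact, small n).
#' @return data.frame with columns roi, group, mean, sem, n, p_value
#'   (p_value repeated within ROI; NA when not computable).
#' @export
roi_aggregate <- function(delta_list, atlas, groups,
                          comparison = NULL,
                          test = c("welch", "student", "permutation")) {
  test <- match.arg(test)
  stopifnot(length(delta_list) == length(groups), length(delta_list) >= 1)
  for (d in delta_list) roi_delta_means(d, atlas)  # validates ROIs
  sm <- roi_mean_matrix(
    lapply(delta_list, function(d) {
      if (inherits(d, "delta_r2star_map")) d$delta else d
    }), atlas)
  glev <- unique(groups)
  if (is.null(comparison) && length(glev) >= 2) comparison <- glev[1:2]

  rows <- list()
  for (r in names(atlas)) {
    pv <- NA_real_
    if (!is.null(comparison)) {
      x <- sm[groups == comparison[1], r]
      y <- sm[groups == comparison[2], r]
      if (length(x) >= 2 && length(y) >= 2) {
        pv <- switch(test,
          welch = stats::t.test(x, y)$p.value,
          student = stats::t.test(x, y, var.equal = TRUE)$p.value,
          permutation = perm_test_two_sample(x, y))
        if (is.nan(pv)) pv <- 1   # identical constant groups
      }
    }
    for (g in glev) {
      v <- sm[groups == g, r]
      rows[[length(rows) + 1L]] <- data.frame(
        roi = r, group = g, mean = mean(v),
        sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        n = length(v), p_value = pv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
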