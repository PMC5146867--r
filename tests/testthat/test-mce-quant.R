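one_roi_atlas <- function(shape) {
  list(ROI = seq_len(prod(shape)))
}

test_that("baseline stratification applies a strict 1-SD rule", {
  shape <- c(4, 4, 2)
  atlas <- one_roi_atlas(shape)
  ref <- baseline_reference("ROI", mean = 20, sd = 2, n = 500)
  at_mean <- r2star_map(array(20, shape))
  expect_true(stratify_subject(at_mean, ref, atlas)$accept)
  # +1.5 SD deviates by more than one SD -> reject
  expect_false(stratify_subject(r2star_map(array(23, shape)), ref,
                                atlas)$accept)
  expect_false(stratify_subject(r2star_map(array(17, shape)), ref,
                                atlas)$accept)
  # the boundary subject at exactly +1.0 SD is accepted
  expect_true(stratify_subject(r2star_map(array(22, shape)), ref,
                               atlas)$accept)
  expect_error(stratify_subject(at_mean, ref, list(other = atlas$ROI)),
               "lacks ROI")
})

test_that("delta map follows the printed 3-SEM threshold arithmetic", {
  shape <- c(3, 3, 1)
  atlas <- one_roi_atlas(shape)
  ref <- baseline_reference("ROI", mean = 20, sd = 0.5 * sqrt(4), n = 4)
  expect_equal(ref$sem, 0.5)
  post <- r2star_map(array(25, shape))
  base <- r2star_map(array(20, shape))
  dm <- compute_delta_map(post, base, ref, atlas)
  # 25 - (20 + 3*0.5) = 3.5 s^-1 ; percent = 3.5/20*100
  expect_equal(unique(as.vector(dm$delta)), 3.5)
  expect_equal(unique(as.vector(dm$percent)), 17.5)

  # post at the reference mean -> all zero
  dm0 <- compute_delta_map(base, base, ref, atlas)
  expect_equal(unique(as.vector(dm0$delta)), 0)
  expect_true(all(dm$delta >= 0))

  ref_bad <- ref
  ref_bad$sem <- NA_real_
  expect_error(compute_delta_map(post, base, ref_bad, atlas), "SEM")

  # voxelwise mode thresholds against the subject's own baseline
  base_v <- r2star_map(array(21, shape))
  dmv <- compute_delta_map(post, base_v, ref, atlas, mode = "voxel")
  expect_equal(unique(as.vector(dmv$delta)), 25 - (21 + 1.5))
})

test_that("the 3-SEM rule has the Gaussian null false-positive rate", {
  # 10^5 simulated ROI-mean draws from the baseline distribution
  shape <- c(50, 50, 40)
  atlas <- one_roi_atlas(shape)
  ref <- baseline_reference("ROI", mean = 20, sd = 1 * sqrt(100), n = 100)
  withr::with_seed(1234, {
    post <- r2star_map(array(rnorm(prod(shape), 20, ref$sem), shape))
  })
  dm <- compute_delta_map(post, post, ref, atlas)
  fp <- mean(dm$delta > 0)
  p_true <- pnorm(3, lower.tail = FALSE)   # ~1.35e-3
  mc_se <- sqrt(p_true * (1 - p_true) / prod(shape))
  expect_lt(abs(fp - p_true), 5 * mc_se)
})

test_that("CNR is computed exactly as defined (delta over root-SD)", {
  r <- compute_cnr(6.4, 4.0)
  expect_equal(r$cnr, 3.2)
  expect_equal(compute_cnr(0, 4)$cnr, 0)
  expect_error(compute_cnr(1, 0), "positive")
  expect_error(compute_cnr(-1, 4), "non-negative")
  # conventional variant divides by SD itself
  expect_equal(compute_cnr(6.4, 4, conventional = TRUE)$cnr, 1.6)
})

test_that("plateau detection finds the earliest stable time", {
  cv <- data.frame(time = c(2, 4, 6), delta_mean = c(1, 5, 5.1))
  expect_equal(detect_plateau(cv, rel_tol = 0.05)$plateau_time, 4)
  cv2 <- data.frame(time = c(2, 4, 6), delta_mean = c(3, 3, 3))
  expect_equal(detect_plateau(cv2)$plateau_time, 2)
  rising <- data.frame(time = c(2, 4, 6, 8),
                       delta_mean = c(1, 1.1, 1.21, 1.331))
  pl <- detect_plateau(rising, rel_tol = 0.05)
  expect_equal(pl$plateau_time, 8)
  expect_true(pl$no_plateau)
  expect_error(detect_plateau(cv[1:2, ]), "nrow")
})

test_that("subtraction maps recover a planted region exactly", {
  shape <- c(20, 20, 8)
  planted <- default_roi_geometry(shape)$LS
  a <- array(20, shape)
  a[planted] <- 26
  b <- array(20, shape)
  sm <- subtract_maps(a, b, threshold = 2)
  expect_equal(nrow(sm$candidates), 1)
  expect_setequal(sm$voxels[[1]], planted)
  expect_equal(sm$candidates$mean_diff, 6)

  # identical maps -> empty candidate list
  expect_equal(nrow(subtract_maps(a, a, 2)$candidates), 0)
  expect_error(subtract_maps(a, array(0, c(4, 4, 4))), "grids differ")

  # two separated blobs at low threshold merge into fewer (never more)
  # candidates as the threshold rises
  a2 <- array(0, shape)
  a2[default_roi_geometry(shape)$HP] <- 4
  a2[default_roi_geometry(shape)$SSC] <- 8
  prev <- Inf
  for (thr in c(1, 3, 5, 9)) {
    ncand <- nrow(subtract_maps(a2, b * 0, thr)$candidates)
    expect_lte(ncand, prev)
    prev <- ncand
  }
})

test_that("ROI aggregation reports group stats and honest p-values", {
  shape <- c(3, 3, 1)
  atlas <- one_roi_atlas(shape)
  const_map <- function(v) array(v, shape)

  # single subject with constant delta: mean exact, SEM undefined
  agg1 <- roi_aggregate(list(const_map(2.5)), atlas, groups = "g")
  expect_equal(agg1$mean, 2.5)
  expect_true(is.na(agg1$sem))

  # identical groups: exact permutation p-value is 1
  maps <- lapply(c(1, 2, 3, 1, 2, 3), const_map)
  agg2 <- roi_aggregate(maps, atlas, groups = rep(c("a", "b"), each = 3),
                        test = "permutation")
  expect_equal(unique(agg2$p_value), 1)

  expect_error(roi_aggregate(list(const_map(1)), list(ROI = integer()),
                             groups = "g"), "empty ROI")
})

test_that("empirical two-group power matches the noncentral-t closed form", {
  shape <- c(2, 2, 1)
  atlas <- one_roi_atlas(shape)
  n <- 8
  d <- 1.5
  reps <- 300
  hits <- withr::with_seed(99, {
    vapply(seq_len(reps), function(i) {
      g1 <- lapply(rnorm(n, 0, 1), function(v) array(v, shape))
      g2 <- lapply(rnorm(n, d, 1), function(v) array(v, shape))
      agg <- roi_aggregate(c(g1, g2), atlas,
                           groups = rep(c("a", "b"), each = n),
                           test = "student")
      agg$p_value[1] < 0.05
    }, logical(1))
  })
  p_theory <- power_two_sample_t(n, d, 0.05)
  mc_se <- sqrt(p_theory * (1 - p_theory) / reps)
  expect_lt(abs(mean(hits) - p_theory), 4 * mc_se)
})
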