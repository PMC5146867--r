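test_that("forward model converts bound iron to R2* elevation via the transverse relaxivity", {
  cfg <- tiny_config()
  ag <- contrast_agent()
  # configure exactly 1 mM bound Fe in the HDAC5 target ROI at plateau
  cfg$binding_coeff <- 1 / 8000
  s <- generate_phantom(cfg, "S1", seed = 1, agent = ag)
  roi <- cfg$roi_geometry$CPu
  t_plateau <- as.character(cfg$plateau_time)
  elev <- s$truth$true_post_r2star[[t_plateau]][roi] -
    s$truth$true_baseline_r2star[roi]
  expect_equal(unname(s$truth$true_bound_fe["CPu", t_plateau]), 1)
  expect_equal(unique(elev), 33.9, tolerance = 1e-12)

  # pre-noise linearity holds in every ROI and at every time
  for (tn in names(s$truth$true_post_r2star)) {
    for (r in names(cfg$roi_geometry)) {
      idx <- cfg$roi_geometry[[r]]
      d <- s$truth$true_post_r2star[[tn]][idx] -
        s$truth$true_baseline_r2star[idx]
      expect_equal(unique(round(d, 10)),
                   round(ag$r2 * s$truth$true_bound_fe[r, tn], 10))
    }
  }
})

test_that("zero binding gives identical pre and post truth", {
  cfg <- tiny_config()
  cfg$binding_coeff <- 0
  s <- generate_phantom(cfg, "A1", seed = 3)
  for (tn in names(s$truth$true_post_r2star)) {
    expect_identical(s$truth$true_post_r2star[[tn]],
                     s$truth$true_baseline_r2star)
  }
})

test_that("generation is a pure function of (config, paradigm, seed)", {
  cfg <- tiny_config(noise_sigma = 0.05)
  a <- generate_phantom(cfg, "A7WA", seed = 11)
  b <- generate_phantom(cfg, "A7WA", seed = 11)
  expect_identical(a$baseline$data, b$baseline$data)
  expect_identical(lapply(a$post, `[[`, "data"),
                   lapply(b$post, `[[`, "data"))
  c2 <- generate_phantom(cfg, "A7WA", seed = 12)
  expect_false(identical(a$baseline$data, c2$baseline$data))
})

test_that("raising a copy number never lowers any voxel's post R2*", {
  cfg <- tiny_config()
  lo <- generate_phantom(cfg, "S1", seed = 5)
  cfg2 <- cfg
  cfg2$gene_panel$S1 <- cfg$gene_panel$S1 * c(3, 1, 1)
  hi <- generate_phantom(cfg2, "S1", seed = 5)
  for (tn in names(lo$truth$true_post_r2star)) {
    expect_true(all(hi$truth$true_post_r2star[[tn]] >=
                      lo$truth$true_post_r2star[[tn]] - 1e-12))
  }
})

test_that("Rician magnitude noise is unbiased at high SNR", {
  cfg <- tiny_config(noise_sigma = 0.02, grid = c(32, 32, 10))  # SNR 50
  s <- generate_phantom(cfg, "S1", seed = 7)
  # >10^4 voxels at a fixed echo; mean magnitude within 1% of noiseless
  true_sig <- cfg$s0 * exp(-s$truth$true_baseline_r2star *
                             cfg$echo_times[1] / 1000)
  obs <- s$baseline$data[, , , 1]
  expect_lt(abs(mean(obs) / mean(true_sig) - 1), 0.01)
})

test_that("invalid phantom configurations are rejected", {
  geom <- default_roi_geometry(c(24, 24, 8))
  geom$NAc[1] <- geom$CPu[1]   # overlap
  expect_error(phantom_config(grid_shape = c(24, 24, 8),
                              roi_geometry = geom), "disjoint")
  expect_error(phantom_config(echo_times = c(3, 2, 1)), "increasing")
  expect_error(phantom_config(plateau_time = 5), "plateau_time")
})

test_that("uptake rises smoothly to the plateau and holds", {
  cfg <- tiny_config()
  u <- simulate_uptake_timecourse(cfg, 1)
  expect_equal(u$level[u$time == 4], 1)
  expect_equal(u$level[u$time == 6], 1)
  expect_gt(u$level[u$time == 2], 0)
  expect_lt(u$level[u$time == 2], 1)

  expect_equal(simulate_uptake_timecourse(cfg, 0)$level, c(0, 0, 0))
  expect_error(simulate_uptake_timecourse(cfg, -1), "non-negative")
})

test_that("uptake levels are non-decreasing over a grid of configurations", {
  for (shape in c("linear", "exponential")) {
    for (pt in c(2, 4, 6)) {
      for (final in c(0.1, 1, 5)) {
        cfg <- tiny_config(uptake_times = c(1, 2, 4, 6, 8),
                           plateau_time = pt, uptake_shape = shape)
        u <- simulate_uptake_timecourse(cfg, final)
        expect_true(all(diff(u$level) >= -1e-12))
        expect_equal(u$level[u$time >= pt], rep(final, sum(u$time >= pt)))
      }
    }
  }
})

test_that("simulated Ct values follow the efficiency model", {
  # equal copies -> dCt 0
  p <- data.frame(gene = c("G", "Actin"), copies = c(1e5, 1e5))
  ct <- simulate_qpcr_plate(p, ct_noise_sd = 0, seed = 1)
  expect_equal(mean(ct$ct[ct$gene == "G"]) -
                 mean(ct$ct[ct$gene == "Actin"]), 0)
  # 4x reference at efficiency 2 -> dCt = -2 cycles
  p$copies <- c(4e5, 1e5)
  ct <- simulate_qpcr_plate(p, efficiency = 2, ct_noise_sd = 0, seed = 1)
  expect_equal(mean(ct$ct[ct$gene == "G"]) -
                 mean(ct$ct[ct$gene == "Actin"]), -2)
  # 10-fold copy ratio between two genes -> log2(10) cycles apart
  p2 <- data.frame(gene = c("A", "B", "Actin"), copies = c(1e4, 1e5, 1e5))
  ct2 <- simulate_qpcr_plate(p2, ct_noise_sd = 0, seed = 1)
  expect_equal(mean(ct2$ct[ct2$gene == "A"]) -
                 mean(ct2$ct[ct2$gene == "B"]),
               log2(10), tolerance = 1e-12)
  expect_error(simulate_qpcr_plate(
    data.frame(gene = c("G", "Actin"), copies = c(-1, 1e5))), "positive")
  expect_error(simulate_qpcr_plate(p, efficiency = 2.5), "efficiency")
})

test_that("beam-break generator obeys rates, delays, and determinism", {
  # all-zero rates -> empty stream
  st0 <- simulate_beambreak_stream("S1", 10, seed = 1,
                                   rates = list(ambulation_rate = 0,
                                                fine_rate = 0))
  expect_equal(nrow(st0$events), 0)

  # A7WA first-bin ambulation: Monte-Carlo mean matches rate * 5 min
  rate <- 45
  counts <- vapply(1:300, function(s) {
    st <- simulate_beambreak_stream("A7WA", 5, seed = s)
    sum(activity_summary(st, bin_min = 5)$bins$ambulation)
  }, numeric(1))
  expected <- rate * 5
  mc_se <- sqrt(expected / 300)   # Poisson variance / n
  expect_lt(abs(mean(counts) - expected), 5 * mc_se)

  # A1 with a 20-min onset delay: early ambulation far below late
  st <- simulate_beambreak_stream("A1", 40, seed = 4)
  su <- activity_summary(st, bin_min = 20)
  expect_lt(su$bins$ambulation[1], 0.35 * su$bins$ambulation[2])

  expect_error(simulate_beambreak_stream("X1", 10), "arg")
  s1 <- simulate_beambreak_stream("A1", 15, seed = 9)
  s2 <- simulate_beambreak_stream("A1", 15, seed = 9)
  expect_identical(s1$events, s2$events)
})

test_that("paradigm copy tables encode reduced chronic striatal HDAC5", {
  cfg <- tiny_config()
  s1 <- paradigm_copy_numbers(cfg, "S1")
  a7 <- paradigm_copy_numbers(cfg, "A7WA")
  expect_lt(a7$copies[a7$gene == "HDAC5"], s1$copies[s1$gene == "HDAC5"])
  expect_error(paradigm_copy_numbers(cfg, "bogus"), "arg")
})
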