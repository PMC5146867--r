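test_that("transitions classify by the adjacent/single-beam rule", {
  cls <- classify_events(stream_from_beams(c(3, 4)))
  expect_equal(cls$class, "ambulation")
  cls2 <- classify_events(stream_from_beams(c(3, 3, 3)))
  expect_equal(cls2$class, c("fine", "fine"))
  # |delta beam| >= 2 is neither class but is retained for audit
  cls3 <- classify_events(stream_from_beams(c(1, 3, 4, 4)))
  expect_equal(cls3$class, c("other", "ambulation", "fine"))
  # empty stream
  empty <- beambreak_stream(data.frame(time_s = numeric(),
                                       beam = integer()))
  expect_equal(nrow(classify_events(empty)), 0)
  s <- activity_summary(empty)
  expect_true(all(s$bins$ambulation == 0) && all(s$bins$fine == 0))

  expect_error(beambreak_stream(data.frame(time_s = c(2, 1),
                                           beam = c(1, 2))),
               "non-decreasing")
  expect_error(beambreak_stream(data.frame(time_s = 1, beam = 7L)),
               "out of range")
})

test_that("distance is exactly 0.05 m per ambulation count", {
  # 500 alternating adjacent breaks in 40 min -> 25 m
  beams <- rep(c(2L, 3L), length.out = 501)
  times <- seq(1, 40 * 60 - 1, length.out = 501)
  st <- beambreak_stream(data.frame(time_s = times, beam = beams),
                         session_min = 40)
  su <- activity_summary(st)
  expect_equal(sum(su$bins$ambulation), 500)
  expect_equal(distance_traveled(su, c(0, 40)), 25)

  # 1800 counts -> 90 m
  beams2 <- rep(c(2L, 3L), length.out = 1801)
  st2 <- beambreak_stream(data.frame(
    time_s = seq(1, 40 * 60 - 1, length.out = 1801), beam = beams2),
    session_min = 40)
  expect_equal(distance_traveled(activity_summary(st2), c(0, 40)), 90)

  expect_equal(distance_traveled(su, c(0, 5)),
               su$bins$distance_m[1])
  expect_error(distance_traveled(su, c(10, 5)), "exceed")
  expect_error(distance_traveled(su, c(0, 90)), "outside")
})

test_that("transition classes partition every consecutive event pair", {
  for (seed in 1:5) {
    st <- simulate_beambreak_stream("A1", 30, seed = seed)
    cls <- classify_events(st)
    expect_equal(nrow(cls), nrow(st$events) - 1)
    su <- activity_summary(st)
    expect_equal(sum(su$bins$ambulation) + sum(su$bins$fine) +
                   sum(su$bins$other), nrow(cls))
    expect_equal(su$bins$distance_m, su$bins$ambulation * 0.05)
    expect_equal(su$bins$cumulative_m, cumsum(su$bins$distance_m))
  }
})

test_that("onset delay finds planted change points within one bin", {
  # immediate full-rate profile: onset inside the first bin
  st <- simulate_beambreak_stream("A7WA", 60, seed = 8)
  su <- activity_summary(st, bin_min = 5)
  expect_equal(onset_delay(su, baseline_rate = 8, factor = 2), 0)

  # planted step at minute 20 (no ramp): detected at 20 +/- one bin
  st2 <- simulate_beambreak_stream(
    "A1", 60, seed = 8,
    rates = list(ambulation_rate = 40, onset_delay = 20,
                 suppress = 0.05, ramp_min = 0))
  su2 <- activity_summary(st2, bin_min = 5)
  det <- onset_delay(su2, baseline_rate = 2, factor = 5)
  expect_lte(abs(det - 20), 5)

  # flat low-rate stream never reaches onset: session length returned
  st3 <- simulate_beambreak_stream("S1", 60, seed = 8)
  expect_equal(onset_delay(activity_summary(st3), baseline_rate = 8,
                           factor = 3), 60)
  expect_error(onset_delay(activity_summary(st3), 8, factor = 0),
               "positive")
})

test_that("group mean distance reproduces the planted rate ratio", {
  dist_for <- function(paradigm, seeds) {
    mean(vapply(seeds, function(s) {
      st <- simulate_beambreak_stream(paradigm, 40, seed = s)
      distance_traveled(activity_summary(st), c(0, 40))
    }, numeric(1)))
  }
  m_fast <- dist_for("A7WA", 1:20)
  m_slow <- dist_for("S1", 1:20)
  planted_ratio <- 45 / 8
  expect_equal(m_fast / m_slow, planted_ratio, tolerance = 0.1)
  # and the absolute scales sit near the design anchors (90 m vs A1 25 m)
  expect_equal(m_fast, 90, tolerance = 0.05)
  expect_equal(dist_for("A1", 1:20), 25, tolerance = 0.12)
})

test_that("beam event CSV round-trips", {
  st <- simulate_beambreak_stream("A1", 10, seed = 3)
  tf <- tempfile(fileext = ".csv")
  write_beambreak_csv(st, tf)
  back <- read_beambreak_csv(tf, session_min = 10)
  expect_equal(back$events$beam, st$events$beam)
  expect_equal(back$events$time_s, st$events$time_s, tolerance = 1e-9)
})
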