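# Small shared fixtures. Grids are kept small so the default test run
# stays fast; the phantom geometry scales with the grid.

tiny_config <- function(noise_sigma = 0, grid = c(24, 24, 8), ...) {
  phantom_config(grid_shape = grid, noise_sigma = noise_sigma,
                 subject_sd_scale = 0, ...)
}

# analytic two-point R2* solution (ms -> s^-1), used as the
# relaxometry oracle when exactly two echoes are given
two_echo_r2star <- function(s1, s2, te1_ms, te2_ms) {
  log(s1 / s2) / ((te2_ms - te1_ms) / 1000)
}

# independent longest-common-substring DP oracle for duplex_call:
# longest run of antiparallel WC pairing == LCS of a and revcomp(b)
lcs_run_oracle <- function(a_bases, b_bases) {
  norm <- function(s) chartr("u", "t", tolower(s))
  rc <- function(s) chartr("acgt", "tgca",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  x <- strsplit(norm(a_bases), "")[[1]]
  y <- strsplit(rc(norm(b_bases)), "")[[1]]
  n <- length(x); m <- length(y)
  best <- 0L
  prev <- integer(m)
  for (i in seq_len(n)) {
    cur <- integer(m)
    for (j in seq_len(m)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j > 1) prev[j - 1] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

random_oligo <- function(len = 20, alphabet = c("a", "c", "g", "t")) {
  oligo_seq("rnd", paste(sample(alphabet, len, replace = TRUE),
                         collapse = ""))
}

# build a beam-break stream from an explicit beam sequence, one event
# per second starting at t = 1
stream_from_beams <- function(beams, session_min = 60) {
  beambreak_stream(data.frame(time_s = seq_along(beams), beam = beams),
                   session_min = session_min)
}
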