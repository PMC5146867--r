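#' Simulate a qPCR plate
#'
#' Generates threshold-cycle values for a set of samples and genes from
#' known copy numbers. Within each sample,
#' `Ct(gene) = Ct(ref) - log_E(copies_gene / copies_ref) + noise`,
#' where E is the amplification efficiency (fold per cycle) and the
#' reference gene anchors the scale at `ref_ct` cycles. Replicates are
#' independent.
#'
#' @param panel data.frame with columns `sample`, `gene`, `copies`
#'   (copies per ng RNA; must include the reference gene in every
#'   sample) or columns `gene`, `copies` for a single sample.
#' @param reference_gene Internal-control gene (e.g. "Actin").
#' @param efficiency Fold amplification per cycle, in (1, 2].
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param n_replicates Technical replicates per well.
#' @param ref_ct Mean Ct of the reference gene.
#' @param seed Integer seed.
#' @return data.frame with columns sample, gene, replicate, ct.
#' @export
simulate_qpcr_plate <- function(panel, reference_gene = "Actin",
                                efficiency = 2, ct_noise_sd = 0.15,
                                n_replicates = 3, ref_ct = 18, seed = 1L) {
  if (!"sample" %in% names(panel)) panel$sample <- "S"
  stopifnot(all(c("sample", "gene", "copies") %in% names(panel)),
            n_replicates >= 1, ct_noise_sd >= 0)
  if (!(efficiency > 1 && efficiency <= 2)) {
    stop("efficiency must be in (1, 2]")
  }
  if (any(panel$copies <= 0)) stop("copy numbers must be positive")
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (s in unique(panel$sample)) {
      sub <- panel[panel$sample == s, ]
      iref <- match(reference_gene, sub$gene)
      if (is.na(iref)) {
        stop("reference gene '", reference_gene,
             "' missing from sample ", s)
      }
      for (i in seq_len(nrow(sub))) {
        mu <- ref_ct - log(sub$copies[i] / sub$copies[iref]) / log(efficiency)
        ct <- mu + stats::rnorm(n_replicates, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, gene = sub$gene[i],
          replicate = seq_len(n_replicates), ct = ct,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default locomotor rate profile for a paradigm
#'
#' Post-onset ambulation and fine-motor rates (events per minute) and
#' the onset shape. Saline-type paradigms are flat and low; acute
#' amphetamine (A1) has a suppressed first phase followed by a gradual
#' rise; the chronic challenge (A7WA) responds at full rate immediately.
#' Scales are set so that 40-min distances fall near 25 m for A1-like
#' and 90 m for A7WA-like sessions.
#'
#' @param paradigm One of S1, A1, A7WS, A7WA, S7WS.
#' @return List with `ambulation_rate`, `fine_rate` (per min),
#'   `onset_delay` (min), `suppress` (pre-onset rate multiplier),
#'   `ramp_min` (minutes over which the rate rises after onset).
#' @export
default_locomotor_rates <- function(paradigm) {
  paradigm <- match.arg(paradigm, paradigm_levels)
  switch(paradigm,
    S1   = list(ambulation_rate = 8,  fine_rate = 10, onset_delay = 0,
                suppress = 1, ramp_min = 0),
    A7WS = list(ambulation_rate = 8,  fine_rate = 10, onset_delay = 0,
                suppress = 1, ramp_min = 0),
    S7WS = list(ambulation_rate = 8,  fine_rate = 10, onset_delay = 0,
                suppress = 1, ramp_min = 0),
    A1   = list(ambulation_rate = 38, fine_rate = 12, onset_delay = 20,
                suppress = 0.1, ramp_min = 20),
    A7WA = list(ambulation_rate = 45, fine_rate = 12, onset_delay = 0,
                suppress = 1, ramp_min = 0))
}

ambulation_rate_profile <- function(duration_min, rate, onset_delay,
                                    suppress, ramp_min) {
  mins <- seq_len(duration_min) - 1   # minute start times
  mult <- rep(1, duration_min)
  if (onset_delay > 0) {
    mult[mins < onset_delay] <- suppress
    if (ramp_min > 0) {
      ramping <- mins >= onset_delay & mins < onset_delay + ramp_min
      frac <- (mins[ramping] - onset_delay) / ramp_min
      mult[ramping] <- suppress + (1 - suppress) * frac
    }
  }
  rate * mult
}

#' Simulate a photocell beam-break stream
#'
#' Plants per-minute Poisson counts of ambulation (moves between
#' adjacent beams) and fine-motor events (repeated breaks of one beam)
#' and realises them as a timestamped event stream on beams 1-5. The
#' ambulation rate follows the paradigm profile: delayed-onset profiles
#' (A1) run at `suppress * rate` before `onset_delay` minutes and rise
#' to full rate over `ramp_min` minutes; immediate profiles (A7WA,
#' saline controls) run at full rate from t = 0.
#'
#' @param paradigm Paradigm label (closed set; unknown labels error).
#' @param duration_min Session length, minutes.
#' @param rates Optional override of [default_locomotor_rates()]: a list
#'   with any of `ambulation_rate` (scalar or per-minute vector),
#'   `fine_rate`, `onset_delay`, `suppress`, `ramp_min`.
#' @param seed Integer seed.
#' @param n_beams,beam_spacing_cm Chamber geometry (5 beams, 5 cm).
#' @return A [beambreak_stream()].
#' @export
simulate_beambreak_stream <- function(paradigm, duration_min = 60,
                                      rates = NULL, seed = 1L,
                                      n_beams = 5L, beam_spacing_cm = 5) {
  prof <- default_locomotor_rates(paradigm)
  if (!is.null(rates)) prof[names(rates)] <- rates
  stopifnot(duration_min > 0)
  amb_rate <- prof$ambulation_rate
  if (any(amb_rate < 0) || any(prof$fine_rate < 0)) {
    stop("rates must be non-negative")
  }
  duration_min <- as.integer(duration_min)
  amb_profile <- if (length(amb_rate) == duration_min) amb_rate else {
    ambulation_rate_profile(duration_min, amb_rate[1], prof$onset_delay,
                            prof$suppress, prof$ramp_min)
  }
  fine_profile <- if (length(prof$fine_rate) == duration_min) {
    prof$fine_rate
  } else rep(prof$fine_rate[1], duration_min)

  withr::with_seed(as.integer(seed), {
    amb_counts <- stats::rpois(duration_min, amb_profile)
    fine_counts <- stats::rpois(duration_min, fine_profile)
    total <- sum(amb_counts) + sum(fine_counts)
    if (total == 0) {
      ev <- data.frame(time_s = numeric(), beam = integer())
      return(beambreak_stream(ev, n_beams = n_beams,
                              beam_spacing_cm = beam_spacing_cm,
                              session_min = duration_min))
    }
    beam <- integer(total + 1L)
    times <- numeric(total + 1L)
    beam[1] <- as.integer(ceiling(n_beams / 2))
    times[1] <- 0
    k <- 1L
    for (m in seq_len(duration_min)) {
      nm <- amb_counts[m] + fine_counts[m]
      if (nm == 0) next
      labels <- sample(c(rep("amb", amb_counts[m]),
                         rep("fine", fine_counts[m])))
      tt <- sort(stats::runif(nm, (m - 1) * 60, m * 60))
      for (j in seq_len(nm)) {
        k <- k + 1L
        prev <- beam[k - 1L]
        if (labels[j] == "amb") {
          step <- sample(c(-1L, 1L), 1)
          nxt <- prev + step
          if (nxt < 1L || nxt > n_beams) nxt <- prev - step
          beam[k] <- nxt
        } else {
          beam[k] <- prev
        }
        times[k] <- tt[j]
      }
    }
    beambreak_stream(data.frame(time_s = times, beam = beam),
                     n_beams = n_beams, beam_spacing_cm = beam_spacing_cm,
                     session_min = duration_min)
  })
}
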