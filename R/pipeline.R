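#' Regress delta-R2* on mRNA copy number
#'
#' Ordinary least-squares calibration of ROI-mean delta-R2* (s^-1)
#' against transcript copy number, the pipeline's headline linearity
#' check. Pairs may be supplied pre-matched (one data.frame with
#' `delta` and `copies` columns) or as two tables matched on their
#' shared key columns among gene / roi / paradigm / group / sample.
#'
#' @param roi_stats data.frame carrying a `delta` column (ROI-mean
#'   delta-R2*) and key columns, or a pre-matched table also carrying
#'   `copies`.
#' @param quant_results Optional data.frame carrying a `copies` column
#'   and key columns.
#' @return Object of class `correlation_result`: slope (s^-1 per copy),
#'   intercept (s^-1), r_squared, n, degenerate flag.
#' @export
correlate_delta_copies <- function(roi_stats, quant_results = NULL) {
  if (is.null(quant_results)) {
    pairs <- roi_stats
  } else {
    keys <- intersect(intersect(names(roi_stats), names(quant_results)),
                      c("gene", "roi", "paradigm", "group", "sample"))
    if (!length(keys)) stop("no shared key columns to match pairs on")
    pairs <- merge(roi_stats, quant_results, by = keys)
  }
  stopifnot(all(c("delta", "copies") %in% names(pairs)))
  pairs <- pairs[stats::complete.cases(pairs[, c("delta", "copies")]), ]
  if (nrow(pairs) < 2) stop("need at least two matched (delta, copies) pairs")
  if (stats::var(pairs$copies) == 0) {
    stop("degenerate fit: copy numbers have zero variance")
  }
  degenerate <- stats::var(pairs$delta) == 0
  fit <- stats::lm(delta ~ copies, data = pairs)
  # r^2 computed directly; summary.lm warns on exact fits
  r2 <- if (degenerate) NA_real_ else {
    1 - sum(stats::residuals(fit)^2) /
      sum((pairs$delta - mean(pairs$delta))^2)
  }
  if (degenerate) {
    warning("delta-R2* has zero variance; r-squared undefined")
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = nrow(pairs), degenerate = degenerate,
         pairs = pairs),
    class = "correlation_result"
  )
}

#' Power of the two-sample two-sided t-test
#'
#' Exact noncentral-t power at standardized effect size `d` with `n`
#' per group.
#'
#' @param n Per-group sample size (>= 2).
#' @param d Standardized effect size (difference in SD units).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2)
  df <- 2 * n - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  1 - stats::pt(tcrit, df, ncp = ncp) + stats::pt(-tcrit, df, ncp = ncp)
}

#' Per-group sample size for a target power
#'
#' Smallest integer n per group at which a two-sample two-sided t-test
#' reaches the requested power, by direct search over the exact
#' noncentral-t power (`method = "normal"` uses the z approximation
#' instead, which can undershoot by one at small n).
#'
#' @param effect_size Standardized effect size (positive).
#' @param alpha Significance level.
#' @param power Target power in (0, 1); the study convention is at
#'   least 0.85 at alpha 0.05.
#' @param method "noncentral_t" or "normal".
#' @param n_max Search limit.
#' @return Integer n per group.
#' @export
sample_size <- function(effect_size, alpha = 0.05, power = 0.85,
                        method = c("noncentral_t", "normal"),
                        n_max = 1e6) {
  method <- match.arg(method)
  if (effect_size <= 0) stop("effect_size must be positive")
  if (power >= 1 || power <= 0) stop("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (method == "normal") {
    n <- 2 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
      effect_size^2
    return(max(2L, as.integer(ceiling(n))))
  }
  for (n in 2:n_max) {
    if (power_two_sample_t(n, effect_size, alpha) >= power) return(n)
  }
  stop("no n up to ", n_max, " reaches the requested power")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 3)
  unname(tools::md5sum(tf))
}

#' Run the full simulate -> fit -> quantify -> correlate pipeline
#'
#' Generates a phantom session for one paradigm, fits R2* maps for the
#' baseline and every post-contrast time, builds the baseline reference
#' from the subject's own baseline map, computes thresholded delta-R2*
#' maps, the ROI uptake curve and plateau, per-ROI CNR, a simulated
#' qPCR plate quantified by delta-delta-Ct (copies via the Actin
#' internal control), the calibration regression of ROI-mean plateau
#' delta-R2* on measured copy number, and a locomotor session summary.
#' Fully deterministic for a given (config, paradigm, seed).
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed driving every stochastic stage.
#' @param paradigm Exposure paradigm.
#' @param agent A [contrast_agent()].
#' @param ct_noise_sd Ct noise of the simulated qPCR plate, cycles.
#' @param actin_copies Copy number of the Actin internal control
#'   (copies per ng RNA) used to convert relative quantities.
#' @param fit_method Relaxometry method, "loglinear" or "nonlinear".
#' @param out_dir Optional directory; when given, NIfTI maps, TSV
#'   tables, and a JSON manifest are written there.
#' @return List of stage outputs: `session`, `baseline_fit`,
#'   `post_fits`, `ref`, `delta_maps`, `uptake_curve`, `plateau`,
#'   `cnr`, `ct_table`, `quant`, `copies_measured`, `calibration`
#'   (correlation_result or NULL), `calibration_warning`, `behavior`
#'   (stream, summary, distance over 0-40 min, onset), `manifest`.
#' @export
run_pipeline <- function(config, seed = 1L, paradigm = "S1",
                         agent = contrast_agent(), ct_noise_sd = 0.15,
                         actin_copies = 1e5,
                         fit_method = c("loglinear", "nonlinear"),
                         out_dir = NULL) {
  fit_method <- match.arg(fit_method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  session <- stage("simulate",
                   generate_phantom(config, paradigm, seed, agent))
  atlas <- config$roi_geometry

  baseline_fit <- stage("relaxometry",
                        fit_r2star_map(session$baseline, fit_method))
  post_fits <- stage("relaxometry",
                     lapply(session$post, fit_r2star_map,
                            method = fit_method))
  ref <- stage("reference",
               baseline_reference_from_maps(baseline_fit, atlas))

  delta_maps <- stage("quantify", lapply(post_fits, compute_delta_map,
                                         baseline = baseline_fit,
                                         ref = ref, atlas = atlas))

  cn <- session$truth$copy_numbers
  curve_roi <- cn$roi[which.max(cn$copies)]
  curve <- data.frame(
    time = config$uptake_times,
    delta_mean = vapply(delta_maps, function(d) {
      roi_delta_means(d, atlas[curve_roi])
    }, numeric(1)))
  plateau <- stage("quantify", detect_plateau(curve))

  t_last <- as.character(max(config$uptake_times))
  delta_plateau <- delta_maps[[t_last]]
  roi_means <- roi_delta_means(delta_plateau, atlas)
  cnr <- do.call(rbind, lapply(cn$roi, function(r) {
    rr <- ref_row(ref, r)
    res <- compute_cnr(roi_means[[r]], max(rr$sd, .Machine$double.eps),
                       roi = r)
    data.frame(roi = r, cnr = res$cnr, delta_mean = res$delta_mean,
               baseline_sd = res$baseline_sd)
  }))

  panel <- rbind(
    data.frame(sample = "calibrator", gene = c(cn$gene, "Actin"),
               copies = c(paradigm_copy_numbers(config, "S1")$copies,
                          actin_copies)),
    data.frame(sample = paradigm, gene = c(cn$gene, "Actin"),
               copies = c(cn$copies, actin_copies)))
  ct_table <- stage("qpcr",
                    simulate_qpcr_plate(panel, "Actin",
                                        ct_noise_sd = ct_noise_sd,
                                        seed = seed))
  grp <- stats::setNames(c("S1", paradigm), c("calibrator", paradigm))
  quant <- stage("qpcr", ddct_quantify(ct_table, "Actin",
                                       calibrator_group = "S1",
                                       groups = grp))
  qp <- quant[quant$sample == paradigm, ]
  copies_measured <- data.frame(
    gene = qp$gene,
    copies = copy_number_estimate(qp$rel_quantity, actin_copies))

  pairs <- merge(data.frame(gene = cn$gene, roi = cn$roi,
                            delta = unname(roi_means[cn$roi])),
                 copies_measured, by = "gene")
  calib <- NULL
  calib_warning <- NULL
  calib <- withCallingHandlers(
    tryCatch(correlate_delta_copies(pairs),
             error = function(e) {
               calib_warning <<- conditionMessage(e)
               warning("calibration degenerate: ", conditionMessage(e),
                       call. = FALSE)
               NULL
             }),
    warning = function(w) {
      calib_warning <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  if (!is.null(calib) && isTRUE(calib$degenerate)) {
    warning("calibration degenerate: delta-R2* has zero variance across ",
            "the gene panel", call. = FALSE)
  }

  stream <- stage("behavior", simulate_beambreak_stream(paradigm, 60,
                                                        seed = seed))
  summ <- activity_summary(stream, bin_min = 5)
  behav <- list(
    stream = stream, summary = summ,
    distance_40min_m = distance_traveled(summ, c(0, 40)),
    onset_min = onset_delay(summ,
                            baseline_rate =
                              default_locomotor_rates("S1")$ambulation_rate,
                            factor = 2))

  manifest <- list(
    package = "mcemri",
    version = as.character(utils::packageVersion("mcemri")),
    seed = as.integer(seed), paradigm = paradigm,
    fit_method = fit_method, ct_noise_sd = ct_noise_sd,
    actin_copies = actin_copies,
    config_hash = config_hash(config),
    grid_shape = config$grid_shape,
    calibration_r_squared = if (!is.null(calib)) calib$r_squared else NA)

  result <- list(session = session, baseline_fit = baseline_fit,
                 post_fits = post_fits, ref = ref,
                 delta_maps = delta_maps, uptake_curve = curve,
                 plateau = plateau, cnr = cnr, ct_table = ct_table,
                 quant = quant, copies_measured = copies_measured,
                 calibration = calib, calibration_warning = calib_warning,
                 behavior = behav, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}
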