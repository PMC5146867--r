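#' Read a Ct table
#'
#' CSV with columns `sample,gene,replicate,ct`; Ct values must be
#' positive and finite.
#'
#' @param path File path.
#' @return data.frame of Ct records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_records(df)
}

validate_ct_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample", "gene", "ct") %in% names(records)))
  if (!"replicate" %in% names(records)) records$replicate <- 1L
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    stop("Ct values must be positive and finite")
  }
  records
}

#' Relative quantification by the comparative-Ct (delta-delta-Ct) model
#'
#' Per sample and gene: `dCt = mean Ct(gene) - mean Ct(reference gene)`;
#' `ddCt = dCt - mean dCt over the calibrator group`;
#' `fold = efficiency^(-ddCt)`. Replicates are aggregated by arithmetic
#' mean of Ct. The relative quantity against the reference gene,
#' `efficiency^(-dCt)`, is also reported, for conversion to copy
#' numbers via [copy_number_estimate()].
#'
#' @param records Ct data.frame (`sample,gene,replicate,ct`).
#' @param reference_gene Internal-control gene present in every sample.
#' @param calibrator_group Group (or sample) against which fold changes
#'   are expressed.
#' @param efficiency Amplification efficiency, fold per cycle.
#' @param groups Optional named character vector mapping sample ->
#'   group; defaults to each sample being its own group.
#' @return data.frame with columns gene, sample, group, delta_ct,
#'   rel_quantity, delta_delta_ct, fold_change.
#' @export
ddct_quantify <- function(records, reference_gene = "Actin",
                          calibrator_group, efficiency = 2,
                          groups = NULL) {
  records <- validate_ct_records(records)
  stopifnot(efficiency > 1)
  samples <- unique(records$sample)
  if (is.null(groups)) groups <- stats::setNames(samples, samples)
  if (!calibrator_group %in% groups) {
    stop("calibrator group '", calibrator_group, "' has no samples")
  }

  mean_ct <- stats::aggregate(ct ~ sample + gene, data = records, FUN = mean)
  rows <- list()
  for (s in samples) {
    sub <- mean_ct[mean_ct$sample == s, ]
    ref_ct <- sub$ct[sub$gene == reference_gene]
    if (!length(ref_ct)) {
      stop("reference gene '", reference_gene, "' missing from sample ", s)
    }
    for (i in which(sub$gene != reference_gene)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = sub$gene[i], sample = s, group = unname(groups[s]),
        delta_ct = sub$ct[i] - ref_ct, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$rel_quantity <- efficiency^(-out$delta_ct)
  out$delta_delta_ct <- NA_real_
  for (g in unique(out$gene)) {
    cal <- out$delta_ct[out$gene == g & out$group == calibrator_group]
    if (!length(cal)) {
      stop("calibrator group lacks gene ", g)
    }
    out$delta_delta_ct[out$gene == g] <-
      out$delta_ct[out$gene == g] - mean(cal)
  }
  out$fold_change <- efficiency^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out
}

#' Copy number from a reference-gene-relative quantity
#'
#' Converts a quantity expressed relative to the internal-control gene
#' into absolute copies, given that gene's copy number. Refuses to
#' guess: when no trusted reference copy number is supplied (e.g. under
#' treatments that may themselves perturb the internal control), an
#' informative error is raised instead of a default.
#'
#' @param fold_change Quantity relative to the reference gene
#'   (e.g. `rel_quantity` from [ddct_quantify()]).
#' @param reference_copies Copies of the reference gene, or NULL/NA if
#'   the internal control is not trusted.
#' @return Estimated copies.
#' @export
copy_number_estimate <- function(fold_change, reference_copies) {
  if (missing(reference_copies) || is.null(reference_copies) ||
      any(is.na(reference_copies))) {
    stop("no trusted reference-gene copy number supplied: copy numbers ",
         "cannot be estimated when the internal control may be altered ",
         "by the treatment")
  }
  if (any(reference_copies <= 0)) stop("reference_copies must be positive")
  if (any(fold_change <= 0)) stop("fold_change must be positive")
  fold_change * reference_copies
}

#' RNA aliquot mass
#'
#' Mass of RNA taken into a reaction from a stock of known total mass
#' and volume: 2.8 ug in 40 ul gives 280 ng in a 4 ul aliquot.
#'
#' @param total_mass_ug Total RNA mass in the stock, micrograms.
#' @param total_volume_ul Stock volume, microliters.
#' @param aliquot_volume_ul Aliquot volume, microliters (at most the
#'   stock volume).
#' @return Aliquot mass in nanograms.
#' @export
rna_aliquot_mass <- function(total_mass_ug, total_volume_ul,
                             aliquot_volume_ul) {
  stopifnot(total_mass_ug >= 0)
  if (total_volume_ul <= 0 || aliquot_volume_ul <= 0) {
    stop("volumes must be positive")
  }
  if (aliquot_volume_ul > total_volume_ul) {
    stop("aliquot exceeds stock volume")
  }
  total_mass_ug * aliquot_volume_ul / total_volume_ul * 1000
}
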