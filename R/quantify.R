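# Enrichment-fold calibration and back-calculation of original sample VAF.
#
# Enrichment is modelled as a multiplicative factor E on allele odds (the
# quantitative reading of "fold enrichment"): a linear VRF/VAF ratio is
# rejected because it cannot saturate as VRF -> 1.

#' Calibrate enrichment folds from spike-in records
#'
#' For each record, `E = [VRF / (1 - VRF)] / [VAF / (1 - VAF)]` (observed
#' post-enrichment odds over known pre-enrichment odds). Multiple records per
#' locus are combined by geometric mean. Records with `VRF = 1` or `VAF = 0`
#' (infinite odds ratio) are excluded with a warning.
#'
#' @param records data.frame with columns `locus`, `vaf` (known spike-in VAF)
#'   and `vrf` (observed), both strictly inside (0, 1).
#' @return data.frame with columns `locus`, `E`, `n_records`.
#' @export
calibrate_enrichment <- function(records) {
  stopifnot(all(c("locus", "vaf", "vrf") %in% names(records)))
  bad <- records$vaf <= 0 | records$vaf >= 1 | records$vrf <= 0 | records$vrf >= 1
  if (any(bad)) {
    warning(sum(bad), " calibration record(s) with VAF or VRF at 0/1 excluded ",
            "(infinite odds)")
    records <- records[!bad, , drop = FALSE]
  }
  if (!nrow(records)) stop("no usable calibration records")
  E <- (records$vrf / (1 - records$vrf)) / (records$vaf / (1 - records$vaf))
  agg <- tapply(E, records$locus, function(e) exp(mean(log(e))))
  data.frame(locus = names(agg), E = as.numeric(agg),
             n_records = as.integer(table(records$locus)[names(agg)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate original sample VAF from observed VRF
#'
#' Exact inverse of [enriched_fraction()]:
#' `VAF = [VRF/(1-VRF)]/E / (1 + [VRF/(1-VRF)]/E)`. When VRF exceeds
#' `saturation_vrf` the estimate is unreliable (sequencing error dominates the
#' small wildtype remainder), so the locus is flagged saturated and classified
#' high-VAF irrespective of the calculated value; otherwise classification is
#' high-VAF iff the estimate exceeds `high_vaf_threshold`. `VRF = 1` returns
#' an estimate of 1 with the saturation flag.
#'
#' @param vrf observed variant read fraction(s) in `[0, 1]`.
#' @param E calibrated enrichment fold(s), positive (recycled).
#' @param saturation_vrf saturation threshold (default 0.90).
#' @param high_vaf_threshold high-VAF classification threshold (default 0.05).
#' @return data.frame with columns `vrf`, `E`, `estimated_vaf`, `saturated`,
#'   `classification` (`"high-VAF"` / `"low-VAF"`).
#' @export
estimate_vaf <- function(vrf, E, saturation_vrf = 0.90,
                         high_vaf_threshold = 0.05) {
  if (any(vrf < 0 | vrf > 1, na.rm = TRUE)) stop("VRF must lie in [0, 1]")
  if (any(E <= 0)) stop("enrichment fold must be positive")
  n <- max(length(vrf), length(E))
  vrf <- rep_len(vrf, n); E <- rep_len(E, n)
  odds <- vrf / (1 - vrf) / E
  est <- odds / (1 + odds)
  est[vrf == 1] <- 1
  saturated <- !is.na(vrf) & vrf > saturation_vrf
  classification <- ifelse(saturated | (!is.na(est) & est > high_vaf_threshold),
                           "high-VAF", "low-VAF")
  classification[is.na(est) & !saturated] <- NA_character_
  data.frame(vrf = vrf, E = E, estimated_vaf = est, saturated = saturated,
             classification = classification, stringsAsFactors = FALSE)
}

#' Expected VAF of a sample mixture
#'
#' Weighted mean of component VAFs; fractions must sum to 1 (tolerance 1e-9).
#' E.g. 1% of a 50%-VAF reference diluted into 99% wildtype gives 0.5% VAF.
#'
#' @param vafs component VAFs.
#' @param fractions mixing fractions summing to 1.
#' @return the expected mixture VAF.
#' @export
mixture_vaf <- function(vafs, fractions) {
  if (length(vafs) != length(fractions))
    stop("vafs and fractions must have equal length")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("mixture fractions must sum to 1")
  sum(vafs * fractions)
}

#' Append VAF estimates to a call table
#'
#' Looks up the calibrated enrichment fold for each called locus (per-locus
#' override first, then the per-amplicon fold) and appends `estimated_vaf`,
#' `saturated` and `classification` columns. A called locus with no calibrated
#' fold is an error: estimation refuses rather than guessing. Multi-base
#' indel estimates additionally carry the `indel_caveat` flag set by
#' [call_variants()] (indels enrich more strongly than the substitutions used
#' in calibration, so their VAF tends to be overestimated).
#'
#' @param calls a [call_table()].
#' @param panel the [amplicon_panel()] holding enrichment folds.
#' @param gate a [gate_config()] (source of `saturation_vrf`).
#' @return the call table with estimation columns filled for called rows.
#' @export
add_vaf_estimates <- function(calls, panel, gate = gate_config()) {
  if (!nrow(calls)) return(calls)
  idx <- which(calls$called)
  E <- panel_fold(panel, calls$amplicon[idx], calls$position[idx],
                  calls$variant[idx])
  if (anyNA(E)) {
    miss <- idx[is.na(E)]
    stop("no calibrated enrichment fold for called locus/loci: ",
         paste(paste0(calls$amplicon[miss], ":", calls$position[miss]),
               collapse = ", "))
  }
  calls$estimated_vaf <- NA_real_
  calls$saturated <- NA
  calls$classification <- NA_character_
  if (length(idx)) {
    est <- estimate_vaf(calls$vrf[idx], E, saturation_vrf = gate$saturation_vrf)
    calls$estimated_vaf[idx] <- est$estimated_vaf
    calls$saturated[idx] <- est$saturated
    calls$classification[idx] <- est$classification
  }
  calls
}
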