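# Concordance against comparator call sets: 2x2 tables, sensitivity and
# specificity, precision-recall curves with AUC, and phred utilities.

#' Phred score / error rate conversion
#'
#' `e = 10^(-Q/10)`; mutually inverse to 1e-12. A mean phred of 9.87
#' corresponds to a 10.3% error rate; 11.55 to 7.0%.
#'
#' @param Q phred score(s), >= 0.
#' @return error rate(s) in (0, 1].
#' @export
phred_to_error <- function(Q) {
  if (any(Q < 0)) stop("phred score must be >= 0")
  10^(-Q / 10)
}

#' @rdname phred_to_error
#' @param e error rate(s) in (0, 1].
#' @return phred score(s).
#' @export
error_to_phred <- function(e) {
  if (any(e <= 0 | e > 1)) stop("error rate must lie in (0, 1]")
  -10 * log10(e)
}

#' Build a comparator call table
#'
#' In `"ngs"` mode a locus is comparator-positive iff its VRF strictly exceeds
#' 5% and coverage is at least 80x (the short-read verification rule). In
#' `"ddpcr"` mode an explicit `positive` column is required.
#'
#' @param df data.frame with locus keys (`sample`, `amplicon`, `position`) and
#'   either `vrf` + `depth` (ngs) or `positive` (ddpcr).
#' @param mode `"ngs"` or `"ddpcr"`.
#' @param vrf_threshold,min_depth NGS positivity rule (defaults 0.05
#'   exclusive, 80 inclusive).
#' @return a `comparator_table` data.frame with a logical `positive` column.
#' @export
comparator_table <- function(df, mode = c("ngs", "ddpcr"),
                             vrf_threshold = 0.05, min_depth = 80) {
  mode <- match.arg(mode)
  stopifnot(all(c("sample", "amplicon", "position") %in% names(df)))
  if (mode == "ngs") {
    stopifnot(all(c("vrf", "depth") %in% names(df)))
    df$positive <- df$vrf > vrf_threshold & df$depth >= min_depth
  } else {
    stopifnot("positive" %in% names(df))
    df$positive <- as.logical(df$positive)
  }
  class(df) <- c("comparator_table", "data.frame")
  df
}

locus_key <- function(df) paste(df$sample, df$amplicon, df$position, sep = "\r")

#' Enumerate the assessed locus universe
#'
#' Every enrichment-region position of every panel amplicon, crossed with the
#' sample set: the denominator of all concordance statistics (e.g. 384 panel
#' loci across 25 samples give 9600 assessed loci).
#'
#' @param panel an [amplicon_panel()].
#' @param samples character vector of sample names (or a sample count).
#' @return list with `loci` (data.frame `sample`, `amplicon`, `position`) and
#'   `n` (universe size).
#' @export
locus_universe <- function(panel, samples) {
  if (is.numeric(samples) && length(samples) == 1)
    samples <- if (samples >= 1) sprintf("sample%02d", seq_len(samples)) else character()
  a <- panel$amplicons
  per_amp <- lapply(seq_len(nrow(a)), function(i)
    data.frame(amplicon = a$name[i],
               position = seq(a$enrich_start[i], a$enrich_end[i] - 1L),
               stringsAsFactors = FALSE))
  panel_loci <- do.call(rbind, per_amp)
  if (!length(samples))
    return(list(loci = data.frame(sample = character(), amplicon = character(),
                                  position = integer()), n = 0L))
  loci <- do.call(rbind, lapply(samples, function(s)
    cbind(sample = s, panel_loci, stringsAsFactors = FALSE)))
  list(loci = loci, n = nrow(loci))
}

#' Concordance of calls against a comparator
#'
#' Classifies every universe locus as TP/FP/FN/TN from the two call flags and
#' derives sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision and
#' recall. Loci absent from either table count as negative for it. A called
#' locus outside the universe is an error (it would silently distort the
#' denominators).
#'
#' @param calls a [call_table()] (rows with `called == TRUE` are the positive
#'   set), or any data.frame with locus keys and a logical `called` column.
#' @param comparator a [comparator_table()].
#' @param universe a locus universe from [locus_universe()] (or a data.frame
#'   of loci).
#' @return a `concordance_table` list: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `precision`, `recall`, `n`. Rates with empty denominators
#'   are `NA`.
#' @export
concordance <- function(calls, comparator, universe) {
  loci <- if (is.list(universe) && !is.data.frame(universe)) universe$loci else universe
  ukey <- locus_key(loci)
  if (anyDuplicated(ukey)) stop("duplicate loci in universe")
  called_pos <- unique(locus_key(calls[which(calls$called), , drop = FALSE]))
  if (length(setdiff(called_pos, ukey)))
    stop("called locus outside the assessed universe")
  comp_pos <- unique(locus_key(comparator[which(comparator$positive), , drop = FALSE]))
  if (length(setdiff(comp_pos, ukey)))
    stop("comparator-positive locus outside the assessed universe")
  is_call <- ukey %in% called_pos
  is_comp <- ukey %in% comp_pos
  tp <- sum(is_call & is_comp); fp <- sum(is_call & !is_comp)
  fn <- sum(!is_call & is_comp); tn <- sum(!is_call & !is_comp)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = rate(tp, tp + fn),
                 specificity = rate(tn, tn + fp),
                 precision = rate(tp, tp + fp),
                 recall = rate(tp, tp + fn),
                 n = length(ukey)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("concordance over", x$n, "loci\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat("  sensitivity", pct(x$sensitivity), " specificity", pct(x$specificity),
      " precision", pct(x$precision), "\n")
  invisible(x)
}

#' Precision-recall curve over the calculated-VAF cutoff
#'
#' Sweeps the estimated-VAF cutoff over all distinct values (saturated loci
#' rank above every finite estimate, honouring their unconditional high-VAF
#' classification); at each cutoff a locus is predicted positive iff its
#' estimate is at or above the cutoff. AUC is the trapezoid over recall, with
#' the curve anchored at recall 0 using the highest-cutoff precision
#' (average-precision-style convention).
#'
#' @param estimated_vaf numeric estimates, one per assessed locus.
#' @param saturated logical, same length (saturated loci outrank all finite
#'   estimates).
#' @param positive logical comparator labels; must contain at least one
#'   positive and one negative.
#' @return list with `curve` (data.frame `cutoff`, `n_called`, `precision`,
#'   `recall`; `cutoff = Inf` is the saturated tier) and `auc`.
#' @export
pr_curve <- function(estimated_vaf, saturated, positive) {
  stopifnot(length(estimated_vaf) == length(positive))
  if (missing(saturated) || is.null(saturated))
    saturated <- rep(FALSE, length(estimated_vaf))
  if (!any(positive) || all(positive))
    stop("comparator labels are degenerate (need >= 1 positive and >= 1 negative)")
  rank_val <- ifelse(saturated, Inf, estimated_vaf)
  cutoffs <- sort(unique(rank_val), decreasing = TRUE)
  npos <- sum(positive)
  curve <- data.frame(cutoff = cutoffs, n_called = NA_integer_,
                      precision = NA_real_, recall = NA_real_)
  for (i in seq_along(cutoffs)) {
    pred <- rank_val >= cutoffs[i]
    curve$n_called[i] <- sum(pred)
    curve$precision[i] <- sum(pred & positive) / sum(pred)
    curve$recall[i] <- sum(pred & positive) / npos
  }
  rec <- c(0, curve$recall)
  prec <- c(curve$precision[1], curve$precision)
  auc <- sum(diff(rec) * (head(prec, -1) + prec[-1]) / 2)
  list(curve = curve, auc = auc)
}

#' Depth-stratified discordance report
#'
#' Histogram of comparator read depth at comparator-negative loci, with the
#' fraction per depth bin where the primary assay saw VRF at or above the call
#' threshold; discordant calls concentrate at low comparator depth.
#'
#' @param vrf primary-assay VRF per locus.
#' @param comparator_depth comparator read depth per locus.
#' @param comparator_positive logical comparator labels.
#' @param breaks depth bin edges (the comparator bins are configurable; the
#'   default spans 0 to the maximum depth in steps of 100).
#' @param vrf_threshold VRF call threshold (default 0.20).
#' @return data.frame with columns `bin`, `n_loci`, `n_discordant`,
#'   `frac_discordant`.
#' @export
discordance_by_depth <- function(vrf, comparator_depth, comparator_positive,
                                 breaks = NULL, vrf_threshold = 0.20) {
  neg <- !comparator_positive
  d <- comparator_depth[neg]; v <- vrf[neg]
  if (is.null(breaks))
    breaks <- seq(0, max(d, 100), by = 100)
  if (max(d) > max(breaks)) breaks <- c(breaks, max(d))
  bin <- cut(d, breaks, include.lowest = TRUE, right = FALSE)
  disc <- !is.na(v) & v >= vrf_threshold
  out <- data.frame(bin = levels(bin),
                    n_loci = as.integer(table(bin)),
                    n_discordant = as.integer(tapply(disc, bin, sum, default = 0L)))
  out$frac_discordant <- ifelse(out$n_loci > 0, out$n_discordant / out$n_loci, NA)
  out
}
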