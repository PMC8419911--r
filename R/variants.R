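# VRF / delta-VRF statistics, confidence scoring, and the dual-gate calling
# rule (VRF threshold AND confidence-score threshold).

#' Gate configuration for variant calling
#'
#' Defaults mirror the validated operating point: a variant is called only
#' when both the VRF and the confidence score clear their thresholds
#' (VRF >= 0.20 and score >= 180), at a minimum post-downsampling coverage of
#' 50x; VRF above `saturation_vrf` (0.90) marks the back-calculated VAF as
#' saturated.
#'
#' @param vrf_threshold minimum VRF for a call (inclusive).
#' @param score_threshold minimum confidence score (inclusive).
#' @param min_coverage minimum coverage for a scoreable locus.
#' @param saturation_vrf VRF above which quantitation saturates.
#' @return a `gate_config` list.
#' @export
gate_config <- function(vrf_threshold = 0.20, score_threshold = 180,
                        min_coverage = 50, saturation_vrf = 0.90) {
  stopifnot(vrf_threshold >= 0, vrf_threshold <= 1,
            score_threshold >= 0, min_coverage >= 0,
            saturation_vrf > 0, saturation_vrf <= 1)
  structure(list(vrf_threshold = vrf_threshold,
                 score_threshold = score_threshold,
                 min_coverage = min_coverage,
                 saturation_vrf = saturation_vrf), class = "gate_config")
}

# fixed tie-break order of single-base events at a position:
# substitutions by alphabetical base, then insertion, then deletion
event_order <- function(ref_base) {
  subs <- setdiff(c("A", "C", "G", "T"), ref_base)
  c(subs, "ins", "del")
}

#' Per-position variant read fraction profile
#'
#' At each position the top non-reference single-base event (three possible
#' substitutions, insertion-after, deletion) is selected; VRF is its count
#' divided by depth. Ties are broken by a fixed event order (substitutions
#' alphabetically, then insertion, then deletion). Primer-region positions are
#' masked from calling; positions below `min_coverage` are flagged, not
#' dropped; zero-depth positions get `NA` VRF.
#'
#' @param pileup a `pileup_matrix` from [build_pileup()].
#' @param min_coverage coverage flag threshold (default from [gate_config()]).
#' @return a `vrf_profile` data.frame with columns `amplicon`, `position`
#'   (0-based), `ref`, `depth`, `variant` (`"ref>alt"`, `"ins"`, `"del"`),
#'   `count`, `vrf`, `region` (`primer`/`enrichment`/`other`), `ok_coverage`.
#'   The source pileup is attached as attribute `pileup` (used by
#'   [delta_vrf()]).
#' @export
vrf_profile <- function(pileup, min_coverage = 50) {
  panel <- pileup$panel
  out <- lapply(seq_len(nrow(panel$amplicons)), function(ai) {
    arow <- panel$amplicons[ai, ]
    m <- pileup$counts[[arow$name]]
    L <- ncol(m)
    refs <- strsplit(arow$sequence, "")[[1]]
    depth <- pileup_depth(pileup, arow$name)
    variant <- character(L); count <- integer(L); vrf <- rep(NA_real_, L)
    for (j in seq_len(L)) {
      ev <- event_order(refs[j])
      cnts <- m[ev, j]   # rows named A/C/G/T/del/ins; ev gives the tie order
      top <- ev[which.max(cnts)]   # which.max takes the first maximum: tie rule
      count[j] <- cnts[[top]]
      variant[j] <- if (top %in% c("ins", "del")) top else paste0(refs[j], ">", top)
      if (depth[j] > 0) vrf[j] <- count[j] / depth[j]
    }
    data.frame(amplicon = arow$name, position = seq_len(L) - 1L, ref = refs,
               depth = depth, variant = variant, count = count, vrf = vrf,
               region = region_of(arow, seq_len(L) - 1L),
               ok_coverage = depth >= min_coverage, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "pileup") <- pileup
  class(out) <- c("vrf_profile", "data.frame")
  out
}

# count of a specific event at a position of a pileup
pileup_event_count <- function(pileup, amplicon, position, variant) {
  m <- pileup$counts[[amplicon]]
  row <- if (variant %in% c("ins", "del")) variant else sub("^.*>", "", variant)
  m[row, position + 1L]
}

#' Tumor-vs-normal delta-VRF and robust z-scores
#'
#' For each position, `delta = VRF_tumor - VRF_normal`, where the normal VRF
#' is evaluated for the tumor's top variant at that position (matched-normal
#' subtraction of systematic, sequence-dependent error). The z-score of
#' position i is computed against the leave-one-out median and scaled MAD of
#' delta over unmasked (enrichment-region, coverage-adequate) positions:
#' robust statistics because top-variant VRFs are heavy-tailed at
#' homopolymers.
#'
#' @param tumor,normal `vrf_profile` objects over the same panel.
#' @return the tumor profile with added columns `vrf_normal`, `delta`, `z`.
#' @export
delta_vrf <- function(tumor, normal) {
  if (!identical(unique(tumor$amplicon), unique(normal$amplicon)) ||
      nrow(tumor) != nrow(normal))
    stop("tumor and normal profiles cover different amplicon sets")
  npile <- attr(normal, "pileup")
  vrf_n <- numeric(nrow(tumor))
  for (i in seq_len(nrow(tumor))) {
    cnt <- pileup_event_count(npile, tumor$amplicon[i], tumor$position[i],
                              tumor$variant[i])
    vrf_n[i] <- if (normal$depth[i] > 0) cnt / normal$depth[i] else NA_real_
  }
  out <- tumor
  out$vrf_normal <- vrf_n
  out$delta <- out$vrf - out$vrf_normal
  usable <- out$region == "enrichment" & out$ok_coverage &
    normal$ok_coverage & !is.na(out$delta)
  z <- rep(NA_real_, nrow(out))
  d <- out$delta
  idx <- which(usable)
  for (i in idx) {
    others <- d[setdiff(idx, i)]
    s <- mad(others)              # 1.4826 * median absolute deviation
    if (s > 0) z[i] <- (d[i] - median(others)) / s
  }
  out$z <- z
  attr(out, "pileup") <- attr(tumor, "pileup")
  class(out) <- c("vrf_profile", "data.frame")
  out
}

#' Default confidence-score provider: binomial log-likelihood ratio
#'
#' Scores a candidate variant by the log10 likelihood ratio of a binomial with
#' the observed variant fraction against a sequencing-error null (a specific
#' single-base event under total error rate `error_rate` has null probability
#' `error_rate / 3`), mapped onto a 0-999 scale (scale factor 45, clipped).
#' With the default gates, a score of 180 is attainable at VRF >= 0.2,
#' depth >= 50 and error rate <= 0.1. Loci below `min_coverage` get no score
#' (`NA`): the score gate fails closed.
#'
#' The provider is pluggable: [call_variants()] accepts any function with this
#' signature, or an explicit score table (e.g. parsed from an external
#' caller's VCF via [scores_from_vcf()]).
#'
#' @param count variant-supporting read count(s).
#' @param depth coverage.
#' @param error_rate total per-base error rate of the reads (default 0.07,
#'   the concatemer-read regime).
#' @param min_coverage minimum coverage for a score.
#' @param null_rate optional per-locus null event probability overriding
#'   `error_rate / 3` (used by [call_variants()] for homopolymer-aware
#'   deletion/insertion nulls).
#' @return numeric score(s) in `[0, 999]`, `NA` below `min_coverage`.
#' @export
score_binomial_llr <- function(count, depth, error_rate = 0.07,
                               min_coverage = 50, null_rate = NULL) {
  p0 <- if (is.null(null_rate)) error_rate / 3 else null_rate
  p0 <- pmin(pmax(p0, 1e-6), 0.49)
  p1 <- pmax(ifelse(depth > 0, count / depth, 0), p0)
  llr <- count * log10(p1 / p0) + (depth - count) * log10((1 - p1) / (1 - p0))
  score <- pmin(999, pmax(0, 45 * llr))
  score[depth < min_coverage] <- NA_real_
  score
}

# homopolymer run length containing each position of a sequence
homopolymer_runs <- function(seq) {
  r <- rle(strsplit(seq, "")[[1]])
  rep.int(r$lengths, r$lengths)
}

# Per-locus null event probabilities for the default score provider.
# Substitutions: a specific base error has probability error_rate / 3.
# Deletions inside (or bordering) a homopolymer run of length L >= 3 are
# inflated by hp_del_multiplier and concentrate at one canonical alignment
# position, so their null is error_rate / 3 * hp_del_multiplier * L;
# insertion placement concentrates the same way (factor L, no rate
# inflation). This is the locus-awareness an external ML-based caller brings;
# without it, homopolymer deletion pileups score as confident variants.
null_event_rates <- function(panel, amplicon, position, variant, error_rate,
                             hp_del_multiplier = 3) {
  base <- error_rate / 3
  out <- rep(base, length(amplicon))
  is_indel <- variant %in% c("ins", "del")
  if (!any(is_indel)) return(out)
  runs <- lapply(setNames(panel$amplicons$sequence, panel$amplicons$name),
                 homopolymer_runs)
  for (i in which(is_indel)) {
    r <- runs[[amplicon[i]]]
    j <- position[i] + 1L
    L <- max(r[max(1L, j - 1L):min(length(r), j + 1L)])
    if (L >= 3)
      out[i] <- base * L * (if (variant[i] == "del") hp_del_multiplier else 1)
  }
  out
}

#' Ingest confidence scores from an external caller's VCF
#'
#' Adapter for substituting an external variant caller as the score provider.
#' CHROM is interpreted as the amplicon name and POS as the 1-based amplicon
#' position; QUAL is the score.
#'
#' @param path VCF file path.
#' @return data.frame with columns `amplicon`, `position` (0-based), `score`.
#' @export
scores_from_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(amplicon = character(), position = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(amplicon = vapply(f, `[[`, "", 1L),
             position = as.integer(vapply(f, `[[`, "", 2L)) - 1L,
             score = suppressWarnings(as.numeric(vapply(f, `[[`, "", 6L))),
             stringsAsFactors = FALSE)
}

#' Call variants with the dual-gate rule
#'
#' A locus is called iff all gates pass: VRF >= `vrf_threshold` AND
#' score >= `score_threshold` AND depth >= `min_coverage` AND the locus is in
#' the enrichment region AND not blacklisted. All enrichment-region loci are
#' retained in the table with per-gate flags, so near-misses remain
#' inspectable. Insertion/deletion calls carry an informational
#' `indel_caveat` flag (external score providers are less reliable for
#' indels); the flag does not gate.
#'
#' @param profile a `vrf_profile` (optionally with delta-VRF columns).
#' @param panel the [amplicon_panel()] (blacklist source).
#' @param gate a [gate_config()].
#' @param sample sample label for the output table.
#' @param scores optional explicit score table (`amplicon`, `position`,
#'   `score`), e.g. from [scores_from_vcf()]; overrides `score_fun`.
#' @param score_fun score provider, default [score_binomial_llr()].
#' @param error_rate per-base error rate passed to the default provider; when
#'   `NULL`, a rate of 0.07 is used.
#' @return a [call_table()] with gate flag columns.
#' @export
call_variants <- function(profile, panel, gate = gate_config(),
                          sample = "sample", scores = NULL,
                          score_fun = score_binomial_llr, error_rate = NULL) {
  rows <- profile[profile$region == "enrichment", , drop = FALSE]
  if (is.null(error_rate)) error_rate <- 0.07
  if (!is.null(scores)) {
    key <- paste(rows$amplicon, rows$position)
    skey <- paste(scores$amplicon, scores$position)
    sc <- scores$score[match(key, skey)]
    sc[rows$depth < gate$min_coverage] <- NA_real_
  } else if (identical(score_fun, score_binomial_llr)) {
    nr <- null_event_rates(panel, rows$amplicon, rows$position, rows$variant,
                           error_rate)
    sc <- score_fun(rows$count, rows$depth, error_rate = error_rate,
                    min_coverage = gate$min_coverage, null_rate = nr)
  } else {
    sc <- score_fun(rows$count, rows$depth, error_rate = error_rate,
                    min_coverage = gate$min_coverage)
  }
  black <- is_blacklisted(panel, rows$amplicon, rows$position, rows$variant)
  gate_vrf <- !is.na(rows$vrf) & rows$vrf >= gate$vrf_threshold
  gate_score <- !is.na(sc) & sc >= gate$score_threshold
  gate_cov <- rows$depth >= gate$min_coverage
  called <- gate_vrf & gate_score & gate_cov & !black
  df <- data.frame(sample = sample, amplicon = rows$amplicon,
                   position = rows$position, ref_base = rows$ref,
                   variant = rows$variant, vrf = rows$vrf,
                   coverage = rows$depth, score = sc, called = called,
                   gate_vrf = gate_vrf, gate_score = gate_score,
                   gate_coverage = gate_cov, gate_blacklist = black,
                   indel_caveat = rows$variant %in% c("ins", "del"),
                   stringsAsFactors = FALSE)
  if (!is.null(rows$z)) df$z <- rows$z
  call_table(df)
}
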