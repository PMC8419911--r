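# Synthetic data generator: enriched amplicon monomers, concatemer assembly,
# and a nanopore-like error model. This is first-class, tested code: every
# downstream stage is exercised against its ground truth.

#' Simulation configuration
#'
#' @param true_vaf data.frame of spiked-in variants with columns `amplicon`,
#'   `position` (0-based), `ref` (reference base at that position), `alt`
#'   (variant allele: a single base for a substitution, `"-"` for a single-base
#'   deletion, or `"+X"` for a single-base insertion after the position) and
#'   `vaf` in `[0, 1]`. May have zero rows (pure wildtype).
#' @param enrichment_fold enrichment fold E applied to each variant's allele
#'   odds (recycled across variants). `E = 1` means no enrichment.
#' @param n_reads number of concatemer reads to simulate.
#' @param monomer_mean target mean monomers per concatemer (default 13.5, the
#'   centre of the 12-15 range observed by capillary electrophoresis).
#' @param monomer_distribution `"truncated-geometric"` (support 1-40,
#'   reparameterised by the mean) or `"fixed"`.
#' @param error_rates named numeric vector `c(sub=, ins=, del=)` of per-base
#'   event probabilities; the default totals 0.07, the concatemer-read error
#'   rate regime (phred ~11.5).
#' @param homopolymer_del_multiplier multiplier (>= 1) applied to the deletion
#'   rate inside homopolymer runs of length >= 3.
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(true_vaf = NULL, enrichment_fold = 1,
                              n_reads = 1000, monomer_mean = 13.5,
                              monomer_distribution = c("truncated-geometric", "fixed"),
                              error_rates = c(sub = 0.035, ins = 0.015, del = 0.02),
                              homopolymer_del_multiplier = 3,
                              seed = 1L) {
  monomer_distribution <- match.arg(monomer_distribution)
  if (is.null(true_vaf))
    true_vaf <- data.frame(amplicon = character(), position = integer(),
                           ref = character(), alt = character(), vaf = numeric(),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("amplicon", "position", "ref", "alt", "vaf") %in% names(true_vaf)))
  if (nrow(true_vaf) && (any(true_vaf$vaf < 0) || any(true_vaf$vaf > 1)))
    stop("true VAF must lie in [0, 1]")
  if (any(enrichment_fold <= 0)) stop("enrichment fold must be positive")
  er <- error_rates[c("sub", "ins", "del")]
  if (anyNA(er)) stop("error_rates must be named c(sub=, ins=, del=)")
  if (any(er < 0) || any(er >= 1) || sum(er) >= 1)
    stop("error rates must each be in [0, 1) and sum to < 1")
  if (monomer_mean < 1) stop("monomer_mean must be >= 1")
  if (homopolymer_del_multiplier < 1)
    stop("homopolymer_del_multiplier must be >= 1")
  if (nrow(true_vaf))
    true_vaf$enrichment_fold <- rep_len(enrichment_fold, nrow(true_vaf))
  structure(list(true_vaf = true_vaf, n_reads = as.integer(n_reads),
                 monomer_mean = monomer_mean,
                 monomer_distribution = monomer_distribution,
                 error_rates = er,
                 homopolymer_del_multiplier = homopolymer_del_multiplier,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Expected variant read fraction after allele enrichment
#'
#' Enrichment acts multiplicatively on allele odds: post-enrichment odds equal
#' `E * v / (1 - v)`, so the expected VRF is
#' `E v / (1 - v) / (1 + E v / (1 - v))`. At `E = 1` this is the identity; it
#' is strictly increasing in both arguments and maps 0 to 0 and 1 to 1.
#'
#' @param vaf variant allele fraction(s) in `[0, 1]`.
#' @param E enrichment fold(s), positive.
#' @return expected post-enrichment variant fraction(s) in `[0, 1]`.
#' @seealso [estimate_vaf()], its exact inverse.
#' @export
enriched_fraction <- function(vaf, E) {
  if (any(vaf < 0 | vaf > 1)) stop("VAF must lie in [0, 1]")
  if (any(E <= 0)) stop("enrichment fold must be positive")
  out <- E * vaf / (E * vaf + (1 - vaf))
  out[vaf == 1] <- 1
  out
}

# solve for the truncated-geometric success parameter giving a target mean on
# support 1..kmax
tgeom_param <- function(mean, kmax = 40L) {
  if (mean <= 1) return(1 - 1e-12)
  if (mean >= (1 + kmax) / 2) stop("monomer_mean too large for support 1..", kmax)
  mean_of <- function(p) {
    k <- seq_len(kmax)
    w <- (1 - p)^(k - 1)
    sum(k * w) / sum(w)
  }
  uniroot(function(p) mean_of(p) - mean, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

draw_monomer_counts <- function(n, config, kmax = 40L) {
  if (config$monomer_distribution == "fixed")
    return(rep(as.integer(round(config$monomer_mean)), n))
  p <- tgeom_param(config$monomer_mean, kmax)
  k <- seq_len(kmax)
  w <- (1 - p)^(k - 1)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate error-free, enrichment-weighted amplicon monomers
#'
#' Each monomer is a full copy of one panel amplicon (chosen uniformly).
#' Every configured variant on that amplicon is present with probability
#' [enriched_fraction()]`(vaf, E)`, emulating the post-enrichment allele pool.
#' Strand is +/- with probability 1/2; minus-strand monomers are
#' reverse-complemented. Variants must lie inside the amplicon's enrichment
#' region: a variant in a primer span is an error (enrichment cannot act
#' there, and primer regions are non-callable).
#'
#' @param panel an [amplicon_panel()].
#' @param config a [simulation_config()].
#' @param n_monomers number of monomers; defaults to
#'   `ceiling(n_reads * monomer_mean)` so that [assemble_concatemers()] can
#'   build `n_reads` concatemers from the pool.
#' @return list with `reads` (a [read_set()] of error-free monomers, constant
#'   quality corresponding to error rate 0) and `truth` (data.frame: one row
#'   per monomer with `monomer_id`, `amplicon`, `strand`, `variants`
#'   (comma-separated `position:alt` keys, `""` if wildtype)), plus
#'   `expected_fraction` (per-variant expected post-enrichment fraction).
#' @export
simulate_monomers <- function(panel, config, n_monomers = NULL) {
  amps <- panel$amplicons
  tv <- config$true_vaf
  if (nrow(tv)) {
    idx <- match(tv$amplicon, amps$name)
    if (anyNA(idx)) stop("variant on unknown amplicon: ",
                         paste(unique(tv$amplicon[is.na(idx)]), collapse = ", "))
    for (i in seq_len(nrow(tv))) {
      a <- amps[idx[i], ]
      reg <- region_of(a, tv$position[i])
      if (reg == "primer")
        stop("variant at ", tv$amplicon[i], ":", tv$position[i],
             " lies in a primer region; enrichment cannot act there")
      if (reg != "enrichment")
        stop("variant at ", tv$amplicon[i], ":", tv$position[i],
             " lies outside the enrichment region")
      refb <- substr(a$sequence, tv$position[i] + 1L, tv$position[i] + 1L)
      if (refb != tv$ref[i])
        stop("variant ref mismatch at ", tv$amplicon[i], ":", tv$position[i],
             " (panel has ", refb, ")")
    }
  }
  if (is.null(n_monomers))
    n_monomers <- as.integer(ceiling(config$n_reads * config$monomer_mean))
  amp_idx <- sample.int(nrow(amps), n_monomers, replace = TRUE)
  seqs <- amps$sequence[amp_idx]
  variants <- character(n_monomers)
  expected <- numeric(0)
  if (nrow(tv)) {
    expected <- enriched_fraction(tv$vaf, tv$enrichment_fold)
    names(expected) <- paste(tv$amplicon, tv$position, tv$alt, sep = ":")
    # order indels by descending position so earlier edits don't shift later ones
    ord <- order(-tv$position)
    for (i in ord) {
      on_amp <- which(amps$name[amp_idx] == tv$amplicon[i])
      if (!length(on_amp)) next
      has <- on_amp[runif(length(on_amp)) < expected[i]]
      if (!length(has)) next
      pos <- tv$position[i]
      alt <- tv$alt[i]
      if (nchar(alt) == 1 && alt %in% c("A", "C", "G", "T")) {
        substr(seqs[has], pos + 1L, pos + 1L) <- alt
      } else if (alt == "-") {
        seqs[has] <- paste0(substr(seqs[has], 1L, pos),
                            substr(seqs[has], pos + 2L, nchar(seqs[has])))
      } else if (startsWith(alt, "+")) {
        seqs[has] <- paste0(substr(seqs[has], 1L, pos + 1L), substring(alt, 2L),
                            substr(seqs[has], pos + 2L, nchar(seqs[has])))
      } else stop("unsupported alt allele: ", alt)
      variants[has] <- ifelse(nzchar(variants[has]),
                              paste(variants[has], paste(pos, alt, sep = ":"), sep = ","),
                              paste(pos, alt, sep = ":"))
    }
  }
  minus <- runif(n_monomers) < 0.5
  if (any(minus))
    seqs[minus] <- cpp_revcomp(seqs[minus])
  ids <- sprintf("monomer_%06d", seq_len(n_monomers))
  reads <- read_set(ids, seqs, qual_string(nchar(seqs), 1e-9),
                    role = "monomer-segment",
                    strand = ifelse(minus, "-", "+"))
  truth <- data.frame(monomer_id = ids, amplicon = amps$name[amp_idx],
                      strand = ifelse(minus, "-", "+"), variants = variants,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, expected_fraction = expected)
}

#' Assemble monomers into concatemer reads
#'
#' Each concatemer is `adapter + monomer (+ junction + monomer) x (k - 1)`,
#' with the same sequence serving as leading adapter and junction. Monomer
#' counts `k` are drawn from the configured distribution; monomers are sampled
#' uniformly from the pool with replacement, without regard to amplicon
#' identity (stochastic incorporation).
#'
#' @param monomers a [read_set()] of monomers (from [simulate_monomers()]).
#' @param junction_adapter the junction/adapter sequence.
#' @param config a [simulation_config()]; `n_reads` concatemers are built.
#' @return list with `reads` (concatemer [read_set()]) and `truth`
#'   (data.frame: `read_id`, `slot` (1-based position within the read),
#'   `monomer_id`).
#' @export
assemble_concatemers <- function(monomers, junction_adapter, config) {
  if (!nrow(monomers)) stop("monomer pool is empty")
  n <- config$n_reads
  counts <- draw_monomer_counts(n, config)
  total <- sum(counts)
  picks <- sample.int(nrow(monomers), total, replace = TRUE)
  read_of <- rep(seq_len(n), counts)
  seqs <- vapply(split(monomers$sequence[picks], read_of), function(parts)
    paste0(junction_adapter, paste(parts, collapse = junction_adapter)),
    character(1), USE.NAMES = FALSE)
  ids <- sprintf("concatemer_%06d", seq_len(n))
  truth <- data.frame(read_id = ids[read_of],
                      slot = unlist(lapply(counts, seq_len), use.names = FALSE),
                      monomer_id = monomers$id[picks],
                      stringsAsFactors = FALSE)
  reads <- read_set(ids, seqs, qual_string(nchar(seqs), 1e-9),
                    role = "concatemer")
  list(reads = reads, truth = truth)
}

#' Corrupt reads with a nanopore-like error model
#'
#' Independent per-base substitution, insertion and deletion events at the
#' configured rates; the deletion rate is multiplied by
#' `homopolymer_del_multiplier` inside homopolymer runs of length >= 3.
#' Emitted base qualities are constant at the phred equivalent of the total
#' configured error rate. Deterministic under a fixed RNG seed.
#'
#' @param reads a [read_set()].
#' @param config a [simulation_config()] supplying `error_rates` and
#'   `homopolymer_del_multiplier`.
#' @return a [read_set()] of corrupted reads (same ids and roles).
#' @export
apply_error_model <- function(reads, config) {
  er <- config$error_rates
  if (!nrow(reads)) return(reads)
  if (sum(er) == 0) return(reads)
  seqs <- cpp_apply_errors(reads$sequence, er[["sub"]], er[["ins"]], er[["del"]],
                           config$homopolymer_del_multiplier)
  read_set(reads$id, seqs, qual_string(nchar(seqs), sum(er)),
           role = reads$role, parent = reads$parent, strand = reads$strand)
}

#' Simulate one sequencing sample end to end
#'
#' Convenience wrapper: seeds the RNG from `config$seed`, simulates the
#' enriched monomer pool, assembles `n_reads` concatemers and applies the
#' error model.
#'
#' @param panel an [amplicon_panel()].
#' @param config a [simulation_config()].
#' @return list with `reads` (corrupted concatemer [read_set()]),
#'   `monomer_truth`, `concatemer_truth` and `expected_fraction`.
#' @export
simulate_sample <- function(panel, config) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  mono <- simulate_monomers(panel, config)
  cat_ <- assemble_concatemers(mono$reads, panel$junction_adapter, config)
  reads <- apply_error_model(cat_$reads, config)
  list(reads = reads, monomer_truth = mono$truth,
       concatemer_truth = cat_$truth,
       expected_fraction = mono$expected_fraction)
}

#' Write simulation ground truth to TSV
#'
#' @param truth data.frame (monomer or concatemer truth).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
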