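# End-to-end orchestration: (simulate ->) deconcat -> classify -> downsample ->
# align -> pileup -> profile -> call -> quantify, with a manifest and full
# determinism under a fixed seed.

#' Pipeline run configuration
#'
#' Stage parameters default to the validated operating point: gates from
#' [gate_config()], coverage cap 150x, analysis read cap 10,000 reads per
#' sample, junction matching at a quarter of the adapter length, minimum
#' segment length half the shortest panel amplicon.
#'
#' @param panel an [amplicon_panel()] (or a panel config path for
#'   [read_panel()]).
#' @param input a [read_set()] of concatemer reads, a FASTQ path, or a
#'   [simulation_config()] (reads are then simulated).
#' @param normal optional matched-normal input (same forms); enables
#'   delta-VRF columns.
#' @param sample sample label.
#' @param seed integer master seed; every stochastic stage draws its own
#'   substream seed from it.
#' @param read_cap reads per sample entering analysis (default 10,000); when
#'   the input exceeds it, a seeded shuffle is taken first so the cap is an
#'   unbiased subsample.
#' @param max_depth per-amplicon coverage cap for downsampling (default 150).
#' @param gate a [gate_config()].
#' @param max_edit_fraction junction matching budget, see [find_junctions()].
#' @param min_segment_length minimum retained segment length; default
#'   `NULL` = half the shortest panel amplicon.
#' @param scoring alignment scoring, see [alignment_scoring()].
#' @param estimate_vafs append VAF estimates to called loci (requires
#'   calibrated folds in the panel).
#' @param output_dir optional directory; when given, all stage outputs and a
#'   manifest are written there.
#' @return a `run_config` list.
#' @export
run_config <- function(panel, input, normal = NULL, sample = "sample",
                       seed = 1L, read_cap = 10000L, max_depth = 150L,
                       gate = gate_config(), max_edit_fraction = 0.25,
                       min_segment_length = NULL,
                       scoring = alignment_scoring(),
                       estimate_vafs = TRUE, output_dir = NULL) {
  if (is.character(panel)) panel <- read_panel(panel)
  if (is.null(min_segment_length))
    min_segment_length <- floor(0.5 * min(nchar(panel$amplicons$sequence)))
  structure(list(panel = panel, input = input, normal = normal,
                 sample = sample, seed = as.integer(seed),
                 read_cap = as.integer(read_cap),
                 max_depth = as.integer(max_depth), gate = gate,
                 max_edit_fraction = max_edit_fraction,
                 min_segment_length = as.integer(min_segment_length),
                 scoring = scoring, estimate_vafs = estimate_vafs,
                 output_dir = output_dir),
            class = "run_config")
}

# deterministic substream seeds below 2^31
stage_seeds <- function(seed, stages) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

resolve_input <- function(input, panel, seed, sample) {
  if (inherits(input, "simulation_config")) {
    input$seed <- seed
    sim <- simulate_sample(panel, input)
    list(reads = sim$reads, truth = sim)
  } else if (is.character(input)) {
    list(reads = read_fastq(input), truth = NULL)
  } else {
    list(reads = input, truth = NULL)
  }
}

# one sample through deconcat -> classify -> downsample -> align -> pileup
sample_stages <- function(reads, config, seeds) {
  stats <- list(reads_in = nrow(reads))
  if (nrow(reads) > config$read_cap) {
    set.seed(seeds[["cap"]])
    reads <- reads[sample.int(nrow(reads))[seq_len(config$read_cap)], ,
                   drop = FALSE]
  }
  stats$reads_analyzed <- nrow(reads)
  dec <- deconcatenate(reads, config$panel$junction_adapter,
                       config$max_edit_fraction, config$min_segment_length)
  stats$segments <- dec$summary$n_segments
  stats$mean_segments_per_read <- dec$summary$mean_segments_per_read
  # classification pass (amplicon + strand) for downsampling; the full
  # alignment that feeds the pileup runs only on retained segments
  cls <- classify_segments(dec$segments, config$panel)
  stats$segments_classified <- sum(!is.na(cls))
  set.seed(seeds[["downsample"]])
  keep <- downsample_segments(cls, max_depth = config$max_depth)
  retained <- dec$segments[keep, , drop = FALSE]
  stats$segments_retained <- nrow(retained)
  aln <- align_segments(retained, config$panel, config$scoring,
                        return_events = TRUE)
  stats$segments_aligned <- sum(aln$status == "aligned")
  pileup <- build_pileup(retained, config$panel, alignments = aln,
                         scoring = config$scoring)
  err <- mean_phred(retained)
  list(pileup = pileup, alignments = aln, deconcat = dec, stats = stats,
       error_rate = if (is.na(err)) 0.07 else phred_to_error(err))
}

#' Fast amplicon/strand classification of segments
#'
#' Shared-11-mer screen only (no full alignment): returns the best-matching
#' amplicon per segment, or NA when no amplicon shares enough k-mers. Used by
#' [run_pipeline()] to pick the segments that enter downsampling; the retained
#' segments are then fully aligned under the [align_segments()] contract.
#'
#' @param segments a [read_set()] or character vector.
#' @param panel an [amplicon_panel()].
#' @return character vector of amplicon names (NA = unclassified).
#' @export
classify_segments <- function(segments, panel) {
  seqs <- if (is.data.frame(segments)) segments$sequence else segments
  res <- cpp_classify_kmer(seqs, panel$amplicons$sequence)
  panel$amplicons$name[res]
}

#' Run the full pipeline on one sample
#'
#' Stages: input resolution (simulation or FASTQ), read cap via seeded
#' shuffle, deconcatenation, k-mer classification, per-amplicon downsampling
#' to `< max_depth`, affine alignment of retained segments, pileup, VRF
#' profile (plus delta-VRF when a matched normal is given), dual-gate calling,
#' and VAF estimation. Identical config and seed give a byte-identical call
#' table. When `output_dir` is set, writes segments FASTQ, pileup TSV, call
#' TSV/VCF and a JSON manifest recording every parameter that affects output.
#'
#' @param config a [run_config()].
#' @return list with `calls` (a [call_table()]), `profile`, `pileup`,
#'   `stats` (per-stage counts), `truth` (for simulated input) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- stage_seeds(config$seed,
                       c("sim", "cap", "downsample", "sim_n", "cap_n",
                         "downsample_n"))
  inp <- resolve_input(config$input, config$panel, seeds[["sim"]],
                       config$sample)
  res <- sample_stages(inp$reads, config,
                       c(cap = seeds[["cap"]],
                         downsample = seeds[["downsample"]]))
  profile <- vrf_profile(res$pileup, min_coverage = config$gate$min_coverage)
  if (!is.null(config$normal)) {
    ninp <- resolve_input(config$normal, config$panel, seeds[["sim_n"]],
                          paste0(config$sample, "_normal"))
    nres <- sample_stages(ninp$reads, config,
                          c(cap = seeds[["cap_n"]],
                            downsample = seeds[["downsample_n"]]))
    nprofile <- vrf_profile(nres$pileup,
                            min_coverage = config$gate$min_coverage)
    profile <- delta_vrf(profile, nprofile)
  }
  calls <- call_variants(profile, config$panel, gate = config$gate,
                         sample = config$sample, error_rate = res$error_rate)
  if (config$estimate_vafs && any(calls$called))
    calls <- add_vaf_estimates(calls, config$panel, gate = config$gate)
  manifest <- list(
    package_version = as.character(utils::packageVersion("concatseq")),
    sample = config$sample, seed = config$seed,
    parameters = list(
      read_cap = config$read_cap, max_depth = config$max_depth,
      max_edit_fraction = config$max_edit_fraction,
      min_segment_length = config$min_segment_length,
      gate = unclass(config$gate), scoring = config$scoring,
      error_rate_used = res$error_rate),
    panel = list(n_amplicons = nrow(config$panel$amplicons),
                 amplicons = config$panel$amplicons$name,
                 junction_adapter = config$panel$junction_adapter),
    stage_counts = res$stats,
    n_called = sum(calls$called))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    write_fastq(res$deconcat$segments, p("segments.fastq"))
    write_pileup(res$pileup, p("pileup.tsv"))
    write_calls(calls, p("calls.tsv"), format = "tsv")
    write_calls(calls, p("calls.vcf"), format = "vcf", panel = config$panel)
    write.table(res$deconcat$per_read, p("deconcat_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  list(calls = calls, profile = profile, pileup = res$pileup,
       stats = res$stats, truth = inp$truth, manifest = manifest)
}
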