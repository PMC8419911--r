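# Shared fixtures: all test data is generated in code.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# small deterministic panel for unit tests
tiny_panel <- function(n = 3, seed = 11, ...) {
  withr::with_seed(seed, synthetic_panel(n_amplicons = n, ...))
}

# a single spiked variant inside the enrichment region of amplicon `amp_idx`
spike_variant <- function(panel, vaf, amp_idx = 1, offset = 5L) {
  a <- panel$amplicons[amp_idx, ]
  pos <- a$enrich_start + offset
  ref <- substr(a$sequence, pos + 1L, pos + 1L)
  data.frame(amplicon = a$name, position = pos, ref = ref,
             alt = setdiff(c("A", "C", "G", "T"), ref)[1], vaf = vaf,
             stringsAsFactors = FALSE)
}

# error-free reads from sequences
plain_reads <- function(seqs, ids = sprintf("read%03d", seq_along(seqs))) {
  read_set(ids, seqs, vapply(nchar(seqs), function(n) strrep("I", n), ""))
}

# multiset recovery rate: per read, how many ground-truth monomers were
# recovered as segments assigned to the correct amplicon
recovery_rate <- function(sim, segments, assigned_amplicon) {
  truth_amp <- sim$monomer_truth$amplicon[
    match(sim$concatemer_truth$monomer_id, sim$monomer_truth$monomer_id)]
  truth_by_read <- split(truth_amp, sim$concatemer_truth$read_id)
  ok <- !is.na(assigned_amplicon)
  seg_by_read <- split(assigned_amplicon[ok], segments$parent[ok])
  rec <- 0; tot <- 0
  for (r in names(truth_by_read)) {
    tt <- table(truth_by_read[[r]])
    ss <- table(seg_by_read[[r]])
    common <- intersect(names(tt), names(ss))
    rec <- rec + sum(pmin(tt[common], ss[common]))
    tot <- tot + sum(tt)
  }
  c(recovered = rec, total = tot)
}
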