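test_that("find_junctions locates exact adapters and respects thresholds", {
  ad <- "ATGGTCTCACGGATCGTTGAGACC"
  withr::with_seed(1, {
    m <- replicate(3, rand_dna(100))
  })
  cc <- paste0(ad, m[1], ad, m[2], ad, m[3])
  h <- find_junctions(cc, ad)
  expect_equal(h$start, c(0, 124, 248))
  expect_equal(h$end, c(24, 148, 272))
  expect_equal(h$edits, c(0, 0, 0))

  # adapter absent -> empty hit list
  expect_equal(nrow(find_junctions(m[1], ad)), 0)
  # adapter shorter than 10 nt -> error
  expect_error(find_junctions(cc, "ACGTACGT"), "at least 10")
})

test_that("edit-distance threshold controls approximate junction recovery", {
  # 20-mer adapter embedded with exactly 2 edits: found at 0.25, missed at 0.05
  ad <- "ACGGATTACCAGGTTCAGTC"  # 20-mer
  mutated <- ad
  substr(mutated, 3, 3) <- "T"
  mutated <- paste0(substr(mutated, 1, 9), substr(mutated, 11, 20))  # 1 sub + 1 del
  withr::with_seed(2, {
    left <- rand_dna(80); right <- rand_dna(80)
  })
  read <- paste0(left, mutated, right)
  # independent oracle: sliding-window edit distance via adist
  best <- min(vapply(1:(nchar(read) - 15), function(s)
    min(utils::adist(ad, substring(read, s, pmin(nchar(read), s + 16:24)))),
    numeric(1)))
  expect_equal(best, 2)
  hit <- find_junctions(read, ad, max_edit_fraction = 0.25)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$edits, 2)
  expect_equal(nrow(find_junctions(read, ad, max_edit_fraction = 0.05)), 0)
})

test_that("junction hits match a brute-force edit-distance oracle", {
  # property: minimal reported distance equals the adist sliding-window
  # minimum (both orientations) whenever it is within budget
  withr::with_seed(3, {
    for (rep in 1:15) {
      ad <- rand_dna(16)
      read <- rand_dna(120)
      k <- floor(0.4 * 16)
      oracle_one <- function(pat) {
        min(vapply(seq_len(nchar(read)), function(s)
          min(utils::adist(pat, substring(read, s,
                                          pmin(nchar(read), s + 10:22)))),
          numeric(1)))
      }
      o <- min(oracle_one(ad), oracle_one(revcomp_chr(ad)))
      h <- find_junctions(read, ad, max_edit_fraction = 0.4)
      if (o <= k) {
        expect_equal(min(h$edits), o)
      } else {
        expect_equal(nrow(h), 0)
      }
    }
  })
})

test_that("split_read conserves bases and handles edge cases", {
  withr::with_seed(4, seq <- rand_dna(300))
  reads <- plain_reads(seq)
  # 0 hits -> one segment equal to the whole read
  sp0 <- split_read(reads[1, ], find_junctions("ACGT", strrep("GATC", 5)))
  expect_equal(sp0$n_segments, 1)
  expect_identical(sp0$segments$sequence, seq)

  # 2 hits -> 3 segments; segments + junction spans reconstruct the read
  hits <- data.frame(start = c(100, 200), end = c(120, 220), edits = 0,
                     strand = "+")
  sp <- split_read(reads[1, ], hits, min_segment_length = 10)
  expect_equal(sp$n_segments, 3)
  expect_identical(paste0(sp$segments$sequence[1], substr(seq, 101, 120),
                          sp$segments$sequence[2], substr(seq, 201, 220),
                          sp$segments$sequence[3]), seq)
  # qualities sliced in register
  expect_equal(nchar(sp$segments$quality), nchar(sp$segments$sequence))

  # dropped short segments are counted, conserving total bases
  hits2 <- data.frame(start = c(5, 200), end = c(25, 220), edits = 0,
                      strand = "+")
  sp2 <- split_read(reads[1, ], hits2, min_segment_length = 30)
  expect_equal(sp2$dropped_bases, 5)
  expect_equal(sum(nchar(sp2$segments$sequence)) + sp2$junction_bases +
                 sp2$dropped_bases, 300)
})

test_that("deconcatenation is exact on error-free reads and conserves bases", {
  pan <- tiny_panel(2)
  cfg <- simulation_config(n_reads = 60, monomer_mean = 8, seed = 6,
                           error_rates = c(sub = 0, ins = 0, del = 0))
  sim <- simulate_sample(pan, cfg)
  dec <- deconcatenate(sim$reads, pan$junction_adapter,
                       min_segment_length = 80)
  # exact recovery: segment count equals ground-truth monomer count per read
  k_truth <- table(sim$concatemer_truth$read_id)
  expect_equal(dec$per_read$n_segments,
               as.integer(k_truth[dec$per_read$read_id]))
  # conservation across the whole run
  s <- dec$summary
  expect_equal(s$segment_bases + s$junction_bases + s$dropped_bases,
               s$total_input_bases)
  # monomer-only input passes through unchanged
  mono <- withr::with_seed(7, simulate_monomers(pan, cfg, n_monomers = 10))
  thru <- deconcatenate(mono$reads, pan$junction_adapter,
                        min_segment_length = 80)
  expect_identical(thru$segments$sequence, mono$reads$sequence)
  # empty input
  empty <- deconcatenate(empty_read_set(), pan$junction_adapter)
  expect_equal(nrow(empty$segments), 0)
  expect_equal(empty$summary$n_reads, 0)
})

test_that("deconcatenation output is invariant to read order", {
  pan <- tiny_panel(2)
  cfg <- simulation_config(n_reads = 30, seed = 8)
  sim <- simulate_sample(pan, cfg)
  dec1 <- deconcatenate(sim$reads, pan$junction_adapter, min_segment_length = 80)
  perm <- withr::with_seed(9, sample.int(nrow(sim$reads)))
  dec2 <- deconcatenate(sim$reads[perm, ], pan$junction_adapter,
                        min_segment_length = 80)
  expect_equal(sort(dec1$segments$sequence), sort(dec2$segments$sequence))
})

test_that("a simulated 12-monomer concatemer at 7% error yields >= 10 segments", {
  pan <- tiny_panel(1)
  cfg <- simulation_config(n_reads = 20, monomer_mean = 12,
                           monomer_distribution = "fixed", seed = 10)
  sim <- simulate_sample(pan, cfg)
  dec <- deconcatenate(sim$reads, pan$junction_adapter, min_segment_length = 80)
  expect_true(all(dec$per_read$n_segments >= 10))
})
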