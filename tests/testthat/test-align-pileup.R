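test_that("exact and reverse-complement copies align to the right amplicon", {
  pan <- tiny_panel(3)
  a2 <- pan$amplicons$sequence[2]
  al <- align_segment(a2, pan)
  expect_equal(al$amplicon, "AMP02")
  expect_equal(al$strand, "+")
  expect_equal(al$identity, 1)
  expect_equal(al$ref_start, 0)
  expect_equal(al$ref_end, 160)

  al_rc <- align_segment(revcomp_chr(a2), pan)
  expect_equal(al_rc$amplicon, "AMP02")
  expect_equal(al_rc$strand, "-")
  expect_equal(al_rc$identity, 1)
})

test_that("noisy copies pick the correct amplicon in >= 99% of 1000 trials", {
  pan <- tiny_panel(4)
  cfg <- simulation_config(seed = 1)  # default 7% total error
  truth_idx <- withr::with_seed(2, sample.int(4, 1000, replace = TRUE))
  reads <- plain_reads(pan$amplicons$sequence[truth_idx])
  noisy <- withr::with_seed(3, apply_error_model(reads, cfg))
  aln <- align_segments(noisy, pan)
  correct <- aln$amplicon == pan$amplicons$name[truth_idx]
  expect_gte(mean(correct, na.rm = TRUE) * mean(!is.na(correct)), 0.99)
})

test_that("pileup counts reference and substitution events correctly", {
  pan <- tiny_panel(1)
  seq <- pan$amplicons$sequence[1]
  # 10 identical error-free segments -> depth 10, ref base count 10 everywhere
  pile <- build_pileup(plain_reads(rep(seq, 10)), pan)
  expect_true(all(pileup_depth(pile, "AMP01") == 10))
  refs <- strsplit(seq, "")[[1]]
  m <- pile$counts$AMP01
  expect_true(all(m[cbind(match(refs, rownames(m)), seq_along(refs))] == 10))

  # 9 ref + 1 with a substitution at 0-based position 57
  mut <- seq
  ref57 <- substr(seq, 58, 58)
  alt <- setdiff(c("A", "C", "G", "T"), ref57)[1]
  substr(mut, 58, 58) <- alt
  pile2 <- build_pileup(plain_reads(c(rep(seq, 9), mut)), pan)
  m2 <- pile2$counts$AMP01
  expect_equal(unname(m2[alt, 58]), 1L)
  expect_equal(unname(m2[ref57, 58]), 9L)
  expect_equal(pileup_depth(pile2, "AMP01")[58], 10)
})

test_that("indel events land on the documented pileup rows (frozen construction)", {
  pan <- tiny_panel(1)
  seq <- pan$amplicons$sequence[1]
  # single-base deletion at 0-based 70: del count at that ref position
  del <- paste0(substr(seq, 1, 70), substr(seq, 72, 160))
  # two-base insertion after 0-based 100: one event at anchor 100
  ins <- paste0(substr(seq, 1, 101), "CA", substr(seq, 102, 160))
  pile <- build_pileup(plain_reads(c(seq, del, ins)), pan)
  m <- pile$counts$AMP01
  expect_equal(unname(m["del", 71]), 1L)
  expect_equal(sum(m["del", ]), 1L)
  expect_equal(unname(m["ins", 101]), 1L)
  expect_equal(sum(m["ins", ]), 1L)
  # depth: deletion contributes at the deleted position, insertion does not
  expect_equal(pileup_depth(pile, "AMP01")[71], 3)
})

test_that("column conservation holds and pileup is order-invariant", {
  pan <- tiny_panel(2)
  cfg <- simulation_config(seed = 4)
  truth_idx <- withr::with_seed(5, sample.int(2, 60, replace = TRUE))
  noisy <- withr::with_seed(6, apply_error_model(
    plain_reads(pan$amplicons$sequence[truth_idx]), cfg))
  pile <- build_pileup(noisy, pan)
  for (a in names(pile$counts)) {
    m <- pile$counts[[a]]
    expect_equal(as.integer(colSums(m[c("A", "C", "G", "T", "del"), ])),
                 pileup_depth(pile, a))
    expect_true(all(m >= 0))
  }
  perm <- withr::with_seed(7, sample.int(nrow(noisy)))
  pile2 <- build_pileup(noisy[perm, ], pan)
  expect_identical(pile$counts, pile2$counts)
})

test_that("pileup equals an independent per-column tally over pairwise alignments", {
  # oracle: Biostrings::pairwiseAlignment per segment (global in the segment,
  # local in the amplicon, same scoring) + an R tally loop. Substitution-only
  # errors keep the optimal alignment unique, so agreement must be exact.
  pan <- tiny_panel(2)
  cfg <- simulation_config(error_rates = c(sub = 0.07, ins = 0, del = 0),
                           seed = 8)
  truth_idx <- withr::with_seed(9, sample.int(2, 20, replace = TRUE))
  segs <- withr::with_seed(10, apply_error_model(
    plain_reads(pan$amplicons$sequence[truth_idx]), cfg))
  # truncate a few segments (junction-trimmed monomers)
  segs$sequence[1:5] <- substring(segs$sequence[1:5], 31)
  segs$quality[1:5] <- substring(segs$quality[1:5], 31)

  pile <- build_pileup(segs, pan)

  submat <- matrix(-4L, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  diag(submat) <- 2L
  oracle <- lapply(pan$amplicons$sequence, function(s)
    matrix(0L, 6, nchar(s), dimnames = list(c("A", "C", "G", "T", "del", "ins"),
                                            NULL)))
  names(oracle) <- pan$amplicons$name
  for (i in seq_len(nrow(segs))) {
    best <- NULL; best_score <- -Inf; best_a <- NA
    for (ai in seq_len(2)) for (q in c(segs$sequence[i],
                                       revcomp_chr(segs$sequence[i]))) {
      pa <- Biostrings::pairwiseAlignment(
        q, pan$amplicons$sequence[ai], type = "global-local",
        substitutionMatrix = submat, gapOpening = 4, gapExtension = 2)
      if (Biostrings::score(pa) > best_score) {
        best_score <- Biostrings::score(pa); best <- pa
        best_a <- pan$amplicons$name[ai]
      }
    }
    sub_start <- Biostrings::start(Biostrings::subject(best))
    al_q <- strsplit(as.character(Biostrings::alignedPattern(best)), "")[[1]]
    al_s <- strsplit(as.character(Biostrings::alignedSubject(best)), "")[[1]]
    pos <- sub_start - 1L  # 0-based ref cursor
    for (k in seq_along(al_s)) {
      if (al_s[k] != "-") {
        pos <- pos + 1L
        row <- if (al_q[k] == "-") "del" else al_q[k]
        oracle[[best_a]][row, pos] <- oracle[[best_a]][row, pos] + 1L
      }
    }
  }
  expect_identical(pile$counts$AMP01[c("A", "C", "G", "T", "del"), ],
                   oracle$AMP01[c("A", "C", "G", "T", "del"), ])
  expect_identical(pile$counts$AMP02[c("A", "C", "G", "T", "del"), ],
                   oracle$AMP02[c("A", "C", "G", "T", "del"), ])
})

test_that("downsampling caps coverage strictly below the limit, reproducibly", {
  amp <- c(rep("A1", 100), rep("A2", 1000), NA, NA)
  # below the cap: unchanged
  keep1 <- withr::with_seed(1, downsample_segments(amp, max_depth = 150))
  expect_equal(sum(amp[keep1] == "A1", na.rm = TRUE), 100)
  # above: strictly below 150 retained
  expect_equal(sum(amp[keep1] == "A2", na.rm = TRUE), 149)
  expect_lt(sum(amp[keep1] == "A2", na.rm = TRUE), 150)
  # unassigned segments always dropped
  expect_true(all(!is.na(amp[keep1])))
  # same seed twice -> identical subset
  keep2 <- withr::with_seed(1, downsample_segments(amp, max_depth = 150))
  expect_identical(keep1, keep2)
})

test_that("ambiguous and low-identity segments are reported unaligned", {
  pan <- tiny_panel(2)
  junk <- withr::with_seed(12, rand_dna(160))
  al <- align_segment(junk, pan)
  expect_true(al$status %in% c("low_identity", "no_kmer_match", "low_aligned_fraction", "ambiguous"))
  expect_true(is.na(al$amplicon))
  # duplicated amplicon sequence forces a cross-amplicon score tie
  amps <- rbind(pan$amplicons[1, ], pan$amplicons[1, ])
  amps$name <- c("DUP1", "DUP2")
  pan2 <- amplicon_panel(amps, junction_adapter = pan$junction_adapter)
  al2 <- align_segment(pan$amplicons$sequence[1], pan2)
  expect_equal(al2$status, "ambiguous")
})
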