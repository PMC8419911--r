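make_profile <- function(pan, counts_mod = NULL, depth = 100) {
  # error-free pileup of `depth` reference copies, then apply count edits
  pile <- build_pileup(plain_reads(rep(pan$amplicons$sequence[1], depth)), pan)
  if (!is.null(counts_mod)) pile <- counts_mod(pile)
  pile
}

test_that("vrf_profile selects the top variant with the documented tie rule", {
  pan <- tiny_panel(1)
  seq <- pan$amplicons$sequence[1]
  pos <- 71L  # 0-based, inside enrichment region for the 160/20/26 layout
  ref <- substr(seq, pos + 1, pos + 1)
  pile <- make_profile(pan, function(p) {
    m <- p$counts$AMP01
    # move 10 of 100 reads to a substitution at pos: depth stays 100
    alt <- setdiff(c("A", "C", "G", "T"), ref)
    m[ref, pos + 1] <- 90L
    m[alt[2], pos + 1] <- 10L
    p$counts$AMP01 <- m
    p
  })
  prof <- vrf_profile(pile)
  row <- prof[prof$position == pos, ]
  expect_equal(row$vrf, 0.10)
  expect_equal(row$variant, paste0(ref, ">", sort(setdiff(c("A","C","G","T"), ref))[2]))

  # all-reference position: VRF 0
  row0 <- prof[prof$position == pos + 1L, ]
  expect_equal(row0$vrf, 0)

  # tie between two substitutions resolves alphabetically
  pile2 <- make_profile(pan, function(p) {
    m <- p$counts$AMP01
    alt <- sort(setdiff(c("A", "C", "G", "T"), ref))
    m[ref, pos + 1] <- 80L
    m[alt[1], pos + 1] <- 10L
    m[alt[2], pos + 1] <- 10L
    p$counts$AMP01 <- m
    p
  })
  row2 <- vrf_profile(pile2)[prof$position == pos, ]
  expect_equal(row2$variant,
               paste0(ref, ">", sort(setdiff(c("A", "C", "G", "T"), ref))[1]))

  # primer positions are masked, zero depth is flagged
  expect_true(all(prof$region[prof$position < 20] == "primer"))
  pile0 <- pile
  pile0$counts$AMP01[, 1] <- 0L
  prof0 <- vrf_profile(pile0)
  expect_true(is.na(prof0$vrf[1]))
})

test_that("delta_vrf recovers a constructed spike against flat noise", {
  # constructed arrays: background delta ~ N(0, 0.005) over ~200 positions,
  # one position elevated by 0.05 -> z around 10
  pan <- withr::with_seed(31, synthetic_panel(2, amplicon_length = 240,
                                              enrichment_width = 100))
  depth <- 4000L
  spike_pos <- pan$amplicons$enrich_start[1] + 50L
  mk <- function(delta_at_spike, noise) {
    pile <- build_pileup(plain_reads(rep(pan$amplicons$sequence, each = depth)),
                         pan)
    k <- 0
    for (a in names(pile$counts)) {
      m <- pile$counts[[a]]
      seq <- pan$amplicons$sequence[pan$amplicons$name == a]
      for (j in seq_len(ncol(m))) {
        k <- k + 1
        ref <- substr(seq, j, j)
        alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
        vr <- max(0, 0.02 + noise[k])
        if (a == "AMP01" && j == spike_pos + 1) vr <- vr + delta_at_spike
        n_alt <- round(vr * depth)
        m[ref, j] <- depth - n_alt
        m[alt, j] <- n_alt
      }
      pile$counts[[a]] <- m
    }
    pile
  }
  # tumor carries N(0, 0.005) background noise, normal is flat: background
  # delta is then Normal(0, 0.005) and the spiked excess of 0.05 sits ~10
  # robust SDs above it
  noise <- withr::with_seed(32, rnorm(480, 0, 0.005))
  tum <- vrf_profile(mk(0.05, noise))
  nor <- vrf_profile(mk(0, rep(0, 480)))
  d <- delta_vrf(tum, nor)
  spike_row <- d[d$amplicon == "AMP01" & d$position == spike_pos, ]
  expect_gt(spike_row$z, 6)
  expect_lt(spike_row$z, 25)
  idx <- which(!is.na(d$z))
  expect_equal(idx[which.max(abs(d$z[idx]))],
               which(d$amplicon == "AMP01" & d$position == spike_pos))
  # identical profiles -> delta 0 everywhere
  d0 <- delta_vrf(nor, nor)
  expect_true(all(abs(d0$delta) < 1e-12, na.rm = TRUE))
})

test_that("simulated 5% spike-ins vs matched normal carry the top-2 z-scores", {
  # two SNP-like loci at 5% VAF, no enrichment, against a 0% normal
  pan <- tiny_panel(2, seed = 33)
  tv <- rbind(spike_variant(pan, 0.05, amp_idx = 1, offset = 4L),
              spike_variant(pan, 0.05, amp_idx = 2, offset = 12L))
  cfg_t <- simulation_config(true_vaf = tv, enrichment_fold = 1, seed = 34)
  cfg_n <- simulation_config(seed = 35)
  depth <- 2500
  pile_t <- withr::with_seed(34, build_pileup(apply_error_model(
    simulate_monomers(pan, cfg_t, n_monomers = depth)$reads, cfg_t), pan))
  pile_n <- withr::with_seed(35, build_pileup(apply_error_model(
    simulate_monomers(pan, cfg_n, n_monomers = depth)$reads, cfg_n), pan))
  d <- delta_vrf(vrf_profile(pile_t), vrf_profile(pile_n))
  usable <- which(!is.na(d$z))
  top2 <- usable[order(-d$z[usable])][1:2]
  got <- paste(d$amplicon[top2], d$position[top2])
  want <- paste(tv$amplicon, tv$position)
  expect_setequal(got, want)
})

test_that("confidence score behaves per contract", {
  # VRF 0.9, depth 150, error 0.07 -> far above 180
  expect_gt(score_binomial_llr(135, 150, error_rate = 0.07), 180)
  # VRF 0.2 at depth 50, error 0.1: the calibrated floor stays above the gate
  expect_gte(score_binomial_llr(10, 50, error_rate = 0.1), 180)
  # VRF 0 -> minimal score
  expect_equal(score_binomial_llr(0, 150), 0)
  # depth below min coverage -> no score (gate fails closed)
  expect_true(is.na(score_binomial_llr(9, 10)))
  # monotone in count at fixed depth
  s <- score_binomial_llr(10:100, 150)
  expect_true(all(diff(s) >= 0))
})

test_that("dual-gate calling requires both gates plus coverage and region", {
  pan <- tiny_panel(1)
  seq <- pan$amplicons$sequence[1]
  pos <- pan$amplicons$enrich_start[1] + 3L
  ref <- substr(seq, pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk_calls <- function(n_alt, depth = 100L, scores = NULL, panel = pan) {
    pile <- build_pileup(plain_reads(rep(seq, depth)), panel)
    m <- pile$counts$AMP01
    m[ref, pos + 1] <- depth - n_alt
    m[alt, pos + 1] <- n_alt
    pile$counts$AMP01 <- m
    call_variants(vrf_profile(pile), panel, scores = scores,
                  error_rate = 0.02)
  }
  # VRF 0.25 with high score and depth 100 -> called
  calls <- mk_calls(25)
  row <- calls[calls$position == pos, ]
  expect_true(row$called)
  expect_gte(row$score, 180)

  # explicit low score: one gate fails -> not called
  sc <- data.frame(amplicon = "AMP01", position = pos, score = 100)
  calls2 <- mk_calls(25, scores = sc)
  row2 <- calls2[calls2$position == pos, ]
  expect_true(row2$gate_vrf)
  expect_false(row2$gate_score)
  expect_false(row2$called)

  # blacklisted locus with huge VRF -> not called
  pan_bl <- pan
  pan_bl$blacklist <- data.frame(amplicon = "AMP01", position = pos,
                                 variant = "*", stringsAsFactors = FALSE)
  calls3 <- mk_calls(90, panel = pan_bl)
  row3 <- calls3[calls3$position == pos, ]
  expect_equal(row3$vrf, 0.9)
  expect_false(row3$called)
  expect_true(row3$gate_blacklist)

  # depth below 50 -> coverage gate fails
  calls4 <- mk_calls(20, depth = 40L)
  expect_false(any(calls4$called))

  # monotone in VRF: raising the variant count never un-calls
  called_by_count <- vapply(15:60, function(k) {
    cl <- mk_calls(k)
    cl$called[cl$position == pos]
  }, logical(1))
  expect_true(all(diff(as.integer(called_by_count)) >= 0))
})

test_that("scores_from_vcf parses amplicon-space VCF records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "AMP01\t58\t.\tG\tT\t212.5\tPASS\t.",
               "AMP02\t90\t.\tA\tC\t55\tPASS\t."), path)
  sc <- scores_from_vcf(path)
  expect_equal(sc$position, c(57L, 89L))
  expect_equal(sc$score, c(212.5, 55))
})
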