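test_that("enriched_fraction obeys identity, boundaries and monotonicity", {
  expect_equal(enriched_fraction(0.3, 1), 0.3)
  expect_equal(enriched_fraction(0, 1e6), 0)
  expect_equal(enriched_fraction(1, 1e-3), 1)
  expect_error(enriched_fraction(1.2, 10), "VAF")
  expect_error(enriched_fraction(0.5, 0), "positive")
  # strictly increasing in VAF and in E
  v <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(enriched_fraction(v, 50)) > 0))
  E <- c(1, 2, 10, 100, 1000)
  expect_true(all(diff(enriched_fraction(0.005, E)) > 0))
})

test_that("brute-force grid inversion confirms VAF 0.5%, E 199 -> VRF 0.5", {
  # independent oracle: invert the odds model by grid search over E
  grid <- seq(1, 1000, by = 1)
  err <- abs(enriched_fraction(0.005, grid) - 0.5)
  expect_equal(grid[which.min(err)], 199)
  expect_equal(enriched_fraction(0.005, 199), 0.5, tolerance = 1e-12)
})

test_that("simulated monomers carry variants at the enriched fraction", {
  pan <- tiny_panel(2)
  tv <- spike_variant(pan, vaf = 1)
  cfg <- simulation_config(true_vaf = tv, enrichment_fold = 1, seed = 5)
  withr::with_seed(5, {
    mono <- simulate_monomers(pan, cfg, n_monomers = 200)
    on_amp <- mono$truth$amplicon == tv$amplicon
    # VAF 1: every monomer of that amplicon is variant
    expect_true(all(nzchar(mono$truth$variants[on_amp])))
  })

  # VAF 0.5% at E 199 enriches to ~50% variant monomers (binomial interval)
  tv2 <- spike_variant(pan, vaf = 0.005)
  cfg2 <- simulation_config(true_vaf = tv2, enrichment_fold = 199, seed = 6)
  withr::with_seed(6, {
    mono <- simulate_monomers(pan, cfg2, n_monomers = 20000)
    on_amp <- mono$truth$amplicon == tv2$amplicon
    frac <- mean(nzchar(mono$truth$variants[on_amp]))
    # ~10,000 draws at p = 0.5: 5 sigma is ~0.025
    expect_lt(abs(frac - 0.5), 0.03)
  })

  # minus-strand monomers are reverse complements of the amplicon
  withr::with_seed(7, {
    mono <- simulate_monomers(pan, simulation_config(seed = 7), n_monomers = 50)
    minus <- which(mono$truth$strand == "-")[1]
    amp_seq <- pan$amplicons$sequence[pan$amplicons$name ==
                                        mono$truth$amplicon[minus]]
    expect_identical(mono$reads$sequence[minus], revcomp_chr(amp_seq))
  })

  # variant in a primer region is an error
  bad <- data.frame(amplicon = pan$amplicons$name[1], position = 5L,
                    ref = substr(pan$amplicons$sequence[1], 6, 6), alt = "A",
                    vaf = 0.5)
  bad$alt <- setdiff(c("A", "C", "G", "T"), bad$ref)[1]
  expect_error(
    simulate_monomers(pan, simulation_config(true_vaf = bad, seed = 1)),
    "primer")
})

test_that("concatemer assembly matches the configured structure exactly", {
  pan <- tiny_panel(1)
  ad <- pan$junction_adapter
  cfg <- simulation_config(n_reads = 10, monomer_mean = 3,
                           monomer_distribution = "fixed", seed = 2)
  withr::with_seed(2, {
    mono <- simulate_monomers(pan, cfg, n_monomers = 40)
    cc <- assemble_concatemers(mono$reads, ad, cfg)
  })
  # fixed(3): every read has exactly 2 internal junctions
  hits_per_read <- vapply(cc$reads$sequence, function(s)
    nrow(find_junctions(s, ad)), integer(1), USE.NAMES = FALSE)
  expect_true(all(hits_per_read == 3))  # leading adapter + 2 internal

  # exact sequence: adapter + m (+ junction + m)^(k-1)
  first <- cc$truth[cc$truth$read_id == cc$reads$id[1], ]
  monos <- mono$reads$sequence[match(first$monomer_id, mono$reads$id)]
  expect_identical(cc$reads$sequence[1],
                   paste0(ad, paste(monos, collapse = ad)))

  # truncated geometric: empirical mean within the observed 12-15 range
  cfg2 <- simulation_config(n_reads = 2000, monomer_mean = 13.5, seed = 3)
  withr::with_seed(3, {
    mono2 <- simulate_monomers(pan, cfg2, n_monomers = 1000)
    cc2 <- assemble_concatemers(mono2$reads, ad, cfg2)
  })
  k <- table(cc2$truth$read_id)
  expect_gte(mean(k), 12)
  expect_lte(mean(k), 15)
  # concatemer length ~ monomers x (amplicon + junction) + adapter overhead
  len1 <- nchar(cc2$reads$sequence[cc2$reads$id == names(k)[1]])
  expect_equal(len1, nchar(ad) + k[[1]] * (160 + nchar(ad)) - nchar(ad))
})

test_that("error model is identity at zero rates and deterministic", {
  reads <- plain_reads(withr::with_seed(4, replicate(20, rand_dna(300))))
  cfg0 <- simulation_config(error_rates = c(sub = 0, ins = 0, del = 0))
  expect_identical(apply_error_model(reads, cfg0)$sequence, reads$sequence)

  cfg <- simulation_config(error_rates = c(sub = 0.035, ins = 0.015, del = 0.02),
                           homopolymer_del_multiplier = 1)
  a <- withr::with_seed(8, apply_error_model(reads, cfg))
  b <- withr::with_seed(8, apply_error_model(reads, cfg))
  expect_identical(a$sequence, b$sequence)

  # observed edit distance per base ~ total configured rate (no hp boost here)
  big <- plain_reads(withr::with_seed(9, replicate(50, rand_dna(2000))))
  corr <- withr::with_seed(10, apply_error_model(big, cfg))
  d <- sum(mapply(function(x, y) utils::adist(x, y), big$sequence, corr$sequence))
  rate <- d / sum(nchar(big$sequence))
  expect_lt(abs(rate - 0.07), 0.005)
})

test_that("homopolymer runs inflate deletions only", {
  hp <- strrep("A", 400)
  mixed <- withr::with_seed(12, rand_dna(400))
  cfg <- simulation_config(error_rates = c(sub = 0, ins = 0, del = 0.02),
                           homopolymer_del_multiplier = 3)
  reads <- plain_reads(c(rep(hp, 30), rep(mixed, 30)))
  corr <- withr::with_seed(13, apply_error_model(reads, cfg))
  del_hp <- 400 - mean(nchar(corr$sequence[1:30]))
  del_mixed <- 400 - mean(nchar(corr$sequence[31:60]))
  expect_gt(del_hp, 1.8 * del_mixed)  # ~3x in expectation
})

test_that("simulated VRF converges to enriched_fraction (binomial property)", {
  pan <- tiny_panel(1)
  for (v in c(0.001, 0.01)) {
    tv <- spike_variant(pan, vaf = v)
    cfg <- simulation_config(true_vaf = tv, enrichment_fold = 500,
                             seed = 20 + round(1000 * v))
    withr::with_seed(cfg$seed, {
      mono <- simulate_monomers(pan, cfg, n_monomers = 5000)
    })
    frac <- mean(nzchar(mono$truth$variants))
    expected <- enriched_fraction(v, 500)
    se <- sqrt(expected * (1 - expected) / 5000)
    expect_lt(abs(frac - expected), 5 * se + 1e-3)
  }
})
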