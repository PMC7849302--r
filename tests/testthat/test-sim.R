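# Synthetic-data generator: construction invariants, determinism, count
# noise model and fixture serialization.

test_that("truth table honors class counts, flags and rate invariants", {
  cfg <- sim_config(n_mrna = 100, n_lnc_cyt = 0, n_lnc_nuc = 0,
                    n_micropeptide = 0, seed = 9)
  tr <- simulate_truth(cfg)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$class == "mRNA"))
  expect_true(all(tr$translated))

  cfg2 <- small_config()
  tr2 <- simulate_truth(cfg2)
  expect_true(all(tr2$translated[tr2$class %in% c("mRNA", "micropeptide")]))
  expect_false(any(tr2$translated[grepl("lncRNA", tr2$class)]))
  expect_true(all(tr2$k_mir[!(tr2$translated & tr2$ago2_bound)] == 0))
  expect_true(all(tr2$k_mir[tr2$translated & tr2$ago2_bound] > 0))
  # k3_ko = comp * k3_base + residual * k_mir; k1_ko = comp * k1_wt
  comp <- cfg2$synthesis_compensation
  k3_base <- tr2$k3_wt - tr2$k_mir
  expect_equal(tr2$k3_ko,
               comp * k3_base + cfg2$residual_mirna_fraction * tr2$k_mir)
  expect_equal(tr2$k1_ko, comp * tr2$k1_wt)
})

test_that("the generator is deterministic given the seed", {
  cfg <- small_config(seed = 77)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$cyt_nuc, b2$cyt_nuc)
  expect_identical(b1$mirnas, b2$mirnas)
})

test_that("miRNA targets lose decay in KO; the k3 fold-change design holds", {
  cfg <- small_config(synthesis_compensation = 1)
  tr <- simulate_truth(cfg)
  targets <- tr$translated & tr$ago2_bound
  expect_true(all(tr$k3_wt[targets] > tr$k3_ko[targets]))
  # with default compensation, the median true fold change is lower for
  # targets than for untranslated genes
  tr2 <- simulate_truth(small_config())
  fc <- log2(tr2$k3_ko / tr2$k3_wt)
  expect_lt(median(fc[tr2$translated & tr2$ago2_bound]),
            median(fc[!tr2$translated]))
})

test_that("count means follow the closed-form expectations", {
  cfg <- sim_config(n_mrna = 12, n_lnc_cyt = 0, n_lnc_nuc = 0,
                    n_micropeptide = 0, depth = 5e4, replicates = 1,
                    seed = 5)
  tr <- simulate_truth(cfg)
  draws <- 400
  rat <- matrix(NA_real_, draws, 4)
  for (i in seq_len(draws)) {
    cfg_i <- cfg; cfg_i$seed <- 10000L + i
    fc <- simulate_fraction_counts(tr, cfg_i)
    keep <- fc$expected > 50
    rat[i, ] <- c(mean(fc$counts[keep] / fc$expected[keep]),
                  sd(fc$counts[keep] / fc$expected[keep]),
                  sum(keep), NA)
  }
  # mean over many draws within 3 standard errors of 1
  m <- mean(rat[, 1])
  se <- sd(rat[, 1]) / sqrt(draws)
  expect_lt(abs(m - 1), 3 * se + 1e-3)
})

test_that("labeled plus pre-existing exonic expectation is the steady state", {
  cfg <- small_config()
  tr <- simulate_truth(cfg)
  fc <- simulate_fraction_counts(tr, cfg)
  sc <- stats::setNames(fc$library_scales$scale, fc$library_scales$library_id)
  s <- fc$samples
  lib <- s$library_id
  flat <- sweep(fc$expected, 2, sc[lib], `/`)
  ex <- s$feature == "exonic" & s$condition == "WT"
  for (tt in cfg$pulse_minutes) {
    cols_lab <- ex & s$fraction == "labeled" & s$pulse_minutes == tt &
      s$replicate == 1
    cols_pre <- ex & s$fraction == "preexisting" & s$pulse_minutes == tt &
      s$replicate == 1
    total <- flat[, cols_lab] + flat[, cols_pre]
    ss <- tr$k1_wt / tr$k2_wt + tr$k1_wt / tr$k3_wt
    expect_equal(unname(total), unname(ss), tolerance = 1e-10)
  }
})

test_that("auxiliary data reflect the truth flags", {
  cfg <- small_config()
  b <- simulate_bundle(cfg)
  tr <- b$truth; ann <- b$annotation

  # micropeptides carry a same-strand positive-score ORF region
  mp <- tr$gene[tr$class == "micropeptide"]
  pos <- b$orf_scores[b$orf_scores$score > 0]
  for (g in mp) {
    i <- match(g, ann$gene)
    hit <- as.character(GenomicRanges::seqnames(pos)) == ann$chrom[i] &
      GenomicRanges::start(pos) <= ann$end[i] &
      GenomicRanges::end(pos) >= ann$start[i] + 1 &
      as.character(GenomicRanges::strand(pos)) == ann$strand[i]
    expect_true(any(hit))
  }

  # untranslated genes have near-zero ribosome-profiling signal
  rp_untr <- b$ribo$rp_count[!tr$translated]
  rp_tr <- b$ribo$rp_count[tr$translated]
  expect_lt(mean(rp_untr > 5), 0.01)
  expect_gt(median(rp_tr), median(rp_untr))

  # cytosolic classes sit above nuclear lncRNAs in cytosolic fraction
  expect_gt(median(tr$cyt_frac[tr$class == "lncRNA_cyt"]),
            median(tr$cyt_frac[tr$class == "mRNA"]))
  expect_lt(median(tr$cyt_frac[tr$class == "lncRNA_nuc"]), 0.5)
})

test_that("about half of mRNAs are called cytosolic by the median threshold", {
  b <- simulate_bundle(small_config())
  biotypes <- stats::setNames(b$annotation$biotype, b$annotation$gene)
  loc <- classify_localization(b$cyt_nuc, biotypes)
  is_m <- loc$calls$biotype == "protein_coding"
  frac_cyt <- mean(loc$calls$class[is_m] == "cytosolic")
  n <- sum(is_m)
  expect_lte(frac_cyt, 0.5)
  expect_gte(frac_cyt, 0.5 - 2 / n)
})

test_that("fixtures round-trip bit-exactly through write and read", {
  b <- simulate_bundle(small_config(seed = 55))
  dir <- withr::local_tempdir()
  manifest <- write_fixture(b, dir)
  expect_equal(manifest$seed, 55)
  b2 <- read_fixture(dir)
  expect_identical(b$counts, b2$counts)
  expect_equal(as.data.frame(b$truth), as.data.frame(b2$truth))
  expect_equal(b$cyt_nuc, b2$cyt_nuc)
  expect_equal(b$ribo, b2$ribo)
  expect_identical(b$mirnas, b2$mirnas)
  # BED round trip preserves coordinates, strand and score
  expect_equal(GenomicRanges::start(b$ago2_peaks),
               GenomicRanges::start(b2$ago2_peaks))
  expect_identical(as.character(GenomicRanges::strand(b$ago2_peaks)),
                   as.character(GenomicRanges::strand(b2$ago2_peaks)))
  expect_equal(b$ago2_peaks$score, b2$ago2_peaks$score)
  expect_equal(b$orf_scores$score, b2$orf_scores$score)
  # a second write of the same bundle is byte-identical
  dir2 <- withr::local_tempdir()
  write_fixture(b, dir2)
  for (f in list.files(dir)) {
    expect_identical(readBin(file.path(dir, f), "raw", 1e7),
                     readBin(file.path(dir2, f), "raw", 1e7))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_mrna = -1), "non-negative")
  expect_error(sim_config(residual_mirna_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(pulse_minutes = c(10, 10)), "distinct")
  expect_error(sim_config(pulse_minutes = c(0, 10)), "positive")
  expect_error(sim_config(replicates = 0), "replicate")
})
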