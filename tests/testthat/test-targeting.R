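# AGO2 peak density, condition-specific cluster filtering and seed-match
# discovery.

test_that("peak density is peaks per kilobase with the bound-only rule", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2500),
                                   name = "r1")
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(10, 500, 2000),
                                                   c(40, 530, 2030)))
  d <- peak_density(peaks, region)
  expect_equal(d$n_peaks, 3L)
  expect_equal(d$density, 3 / 2.5)

  both_regions <- GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(c(1, 1), c(2500, 1000)),
    name = c("r1", "r2"))
  d2 <- peak_density(peaks, both_regions, bound_only = TRUE)
  expect_false(d2$in_comparison[d2$region == "r2"])
  expect_true(d2$in_comparison[d2$region == "r1"])
  d3 <- peak_density(peaks, both_regions, bound_only = FALSE)
  expect_true(all(d3$in_comparison))
})

test_that("peak counting agrees with a brute-force all-pairs scan", {
  set.seed(7)
  for (i in 1:40) {
    peaks <- random_granges(sample(5:60, 1))
    regions <- random_granges(sample(5:40, 1))
    d <- peak_density(peaks, regions, bound_only = FALSE)
    expect_equal(d$n_peaks, as.integer(brute_overlap_count(regions, peaks)))
  }
})

test_that("density is additive over peak-list chunks", {
  set.seed(11)
  peaks <- random_granges(60)
  regions <- random_granges(15)
  whole <- peak_density(peaks, regions, bound_only = FALSE)
  split1 <- peak_density(peaks[1:30], regions, bound_only = FALSE)
  split2 <- peak_density(peaks[31:60], regions, bound_only = FALSE)
  expect_equal(whole$density, split1$density + split2$density)
})

test_that("wild-type-specific cluster filtering removes any overlap", {
  wt <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(100, 500), c(200, 600)))
  expect_length(wt_specific_clusters(wt, wt), 0)

  ko_far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100))
  expect_length(wt_specific_clusters(wt, ko_far), 2)

  ko_touch <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
  kept <- wt_specific_clusters(wt, ko_touch)   # 1-bp overlap with cluster 1
  expect_length(kept, 1)
  expect_equal(GenomicRanges::start(kept), 500)
})

test_that("cluster filtering matches brute force on random sets", {
  set.seed(13)
  for (i in 1:30) {
    wt <- random_granges(sample(5:50, 1), stranded = FALSE)
    ko <- random_granges(sample(5:50, 1), stranded = FALSE)
    kept <- wt_specific_clusters(wt, ko)
    manual <- brute_overlap_count(wt, ko) == 0
    expect_equal(length(kept), sum(manual))
    expect_equal(GenomicRanges::start(kept),
                 GenomicRanges::start(wt)[manual])
  }
})

test_that("seed matching finds the documented 8mer site", {
  hits <- find_seed_matches("UACGGUAACGAUCGAUCGAU", "GGGTTACCGTAGG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 4)
  expect_equal(hits$end, 11)
  expect_equal(hits$site_type, "8mer")
  expect_equal(hits$site, "TTACCGTA")
})

test_that("seed matching handles empty input, case and T/U spelling", {
  mir <- "UACGGUAACGAUCGAUCGAU"
  expect_equal(nrow(find_seed_matches(mir, "")), 0)
  a <- find_seed_matches(mir, "gggttaccgtagg")
  b <- find_seed_matches(mir, "GGGUUACCGUAGG")
  ref <- find_seed_matches(mir, "GGGTTACCGTAGG")
  expect_equal(a, ref)
  expect_equal(b, ref)
  expect_error(find_seed_matches("UACGGUXX", "ACGT"), "invalid")
  expect_error(find_seed_matches("UACGG", "ACGT"), "at least 8")
})

test_that("a full reverse-complement target yields exactly one strongest site", {
  mir <- "UACGGUAACGAUCGAUCGAU"
  target <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("U", "T", mir))))
  hits <- find_seed_matches(mir, target)
  expect_equal(nrow(hits), 1)
  # miRNA position 1 is U, so the target carries the 3' A: strongest type
  expect_equal(hits$site_type, "8mer")
})

test_that("seed matcher agrees with a brute-force scan on random sequences", {
  set.seed(21)
  revcomp <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  for (i in 1:60) {
    mir <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
    tx <- paste(sample(c("A", "C", "G", "T"), sample(30:120, 1), TRUE),
                collapse = "")
    hits <- find_seed_matches(mir, tx)
    # brute force: all 6mer matches, then classify
    mir_dna <- gsub("U", "T", mir)
    m6 <- revcomp(substr(mir_dna, 2, 7))
    m8b <- revcomp(substr(mir_dna, 8, 8))
    manual <- list()
    for (s in seq_len(nchar(tx) - 5)) {
      if (substr(tx, s, s + 5) != m6) next
      hasm8 <- s > 1 && substr(tx, s - 1, s - 1) == m8b
      hasA <- substr(tx, s + 6, s + 6) == "A"
      type <- if (hasm8 && hasA) "8mer" else if (hasm8) "7mer-m8"
              else if (hasA) "7mer-A1" else "6mer"
      st <- if (hasm8) s - 1L else s
      en <- st + c("8mer" = 7L, "7mer-m8" = 6L, "7mer-A1" = 6L,
                   "6mer" = 5L)[[type]]
      manual[[length(manual) + 1]] <- data.frame(
        start = st, end = en, site_type = type, stringsAsFactors = FALSE)
    }
    man <- do.call(rbind, manual)
    if (is.null(man)) {
      expect_equal(nrow(hits), 0)
    } else {
      ord <- c("8mer", "7mer-m8", "7mer-A1", "6mer")
      man <- man[order(man$start, match(man$site_type, ord)), ]
      man <- man[!duplicated(man$start), ]
      expect_equal(hits$start, man$start)
      expect_equal(hits$site_type, man$site_type)
    }
  }
})

test_that("binding annotation recovers the generator truth", {
  b <- simulate_bundle(small_config())
  ann <- b$annotation
  is_m <- ann$biotype == "protein_coding"
  reg_start <- ifelse(is_m, ann$utr3_start, ann$start)
  reg_end <- ifelse(is_m, ann$utr3_end, ann$end)
  regions <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(reg_start + 1, reg_end),
    strand = ann$strand, name = ann$gene)
  part <- data.frame(gene = ann$gene, class = b$truth$class)
  bind <- annotate_binding(part, b$ago2_peaks, regions)
  expect_equal(bind$bound, b$truth$ago2_bound[match(bind$gene,
                                                    b$truth$gene)])
})
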