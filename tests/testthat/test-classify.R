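# Localization thresholding, translation efficiency and the micropeptide
# flag.

test_that("localization threshold is the expressed-mRNA median ratio", {
  expr <- data.frame(
    gene = c("m1", "m2", "m3", "l1", "l2"),
    cyt_expr = c(10, 20, 30, 25, 20),
    nuc_expr = c(10, 10, 10, 10, 10))
  bt <- c(m1 = "protein_coding", m2 = "protein_coding",
          m3 = "protein_coding", l1 = "lincRNA", l2 = "lincRNA")
  loc <- classify_localization(expr, bt, eps = 0)
  expect_equal(loc$threshold, 2)
  expect_equal(loc$calls$class[loc$calls$gene == "l1"], "cytosolic")
  # a ratio exactly at the threshold goes to nuclear (strictly greater)
  expect_equal(loc$calls$class[loc$calls$gene == "l2"], "nuclear")
})

test_that("genes below the expression filter are excluded; no mRNA errors", {
  expr <- data.frame(gene = c("m1", "weak"),
                     cyt_expr = c(5, 0.2), nuc_expr = c(1, 0.3))
  bt <- c(m1 = "protein_coding", weak = "lincRNA")
  loc <- classify_localization(expr, bt)
  expect_false("weak" %in% loc$calls$gene)
  expr_none <- data.frame(gene = "l1", cyt_expr = 5, nuc_expr = 1)
  expect_error(classify_localization(expr_none, c(l1 = "lincRNA")),
               "no expressed mRNAs")
})

test_that("translation efficiency follows the cpm log-ratio with its filters", {
  rp <- c(a = 100L, b = 0L, c = 400L, d = 500L)
  rna <- c(a = 100L, b = 50L, c = 100L, d = 750L)
  te <- translation_efficiency(rp, rna)
  # equal library totals here, so cpm ratio = count ratio
  expect_equal(te$te[te$gene == "a"], 0)
  expect_true(is.na(te$te[te$gene == "b"]))      # zero RP reads
  expect_false(te$defined[te$gene == "b"])
  expect_equal(te$te[te$gene == "c"], 2)

  # shift invariance: common rescaling of both libraries leaves te alone
  te2 <- translation_efficiency(rp * 7L, rna * 7L)
  expect_equal(te2$te, te$te)

  expect_error(translation_efficiency(c(a = 0L), c(a = 0L)), "zero library")
})

test_that("ribosome-bound flag uses a strict threshold on defined TE", {
  profile <- data.frame(gene = c("a", "b", "c"),
                        rp_cpm = 1, rna_cpm = 1,
                        te = c(0.5, NA, 0), defined = c(TRUE, FALSE, TRUE))
  fl <- flag_ribosome_bound(profile)
  expect_true(fl[["a"]])
  expect_false(fl[["b"]])   # undefined
  expect_false(fl[["c"]])   # exactly at the threshold
})

test_that("micropeptide flag needs same-strand positive-score overlap", {
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000),
                               strand = "+", name = "lnc1")
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 5100),
                                strand = "+", name = "o", score = 10)
  expect_false(flag_micropeptide(tx, far)[["lnc1"]])

  opp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1600),
                                strand = "-", name = "o", score = 10)
  expect_false(flag_micropeptide(tx, opp)[["lnc1"]])

  neg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1600),
                                strand = "+", name = "o", score = -3)
  expect_false(flag_micropeptide(tx, neg)[["lnc1"]])

  # single-base overlap on the same strand is enough
  onebp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 2100),
                                  strand = "+", name = "o", score = 2)
  expect_true(flag_micropeptide(tx, onebp)[["lnc1"]])

  nostrand <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1600),
                                     name = "o", score = 2)
  expect_error(flag_micropeptide(tx, nostrand), "strand")
})

test_that("micropeptide flag equals a brute-force scan on random intervals", {
  set.seed(42)
  for (rep in 1:20) {
    n_tx <- 15; n_orf <- 25
    tx_start <- sample(1:5000, n_tx)
    tx <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(tx_start, tx_start + sample(50:500, n_tx)),
      strand = sample(c("+", "-"), n_tx, TRUE),
      name = paste0("t", seq_len(n_tx)))
    o_start <- sample(1:5000, n_orf)
    orf <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(o_start, o_start + sample(10:200, n_orf)),
      strand = sample(c("+", "-"), n_orf, TRUE),
      name = paste0("o", seq_len(n_orf)),
      score = round(runif(n_orf, -10, 10), 2))
    got <- flag_micropeptide(tx, orf)
    for (i in seq_len(n_tx)) {
      manual <- any(
        orf$score > 0 &
          as.character(GenomicRanges::strand(orf)) ==
            as.character(GenomicRanges::strand(tx))[i] &
          GenomicRanges::start(orf) <= GenomicRanges::end(tx)[i] &
          GenomicRanges::end(orf) >= GenomicRanges::start(tx)[i])
      expect_identical(unname(got[i]), manual)
    }
  }
})

test_that("the four-class partition is exclusive, exhaustive and accurate", {
  b <- simulate_bundle(small_config())
  biotypes <- stats::setNames(b$annotation$biotype, b$annotation$gene)
  loc <- classify_localization(b$cyt_nuc, biotypes)
  ann <- b$annotation
  tx <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1, ann$end),
                               strand = ann$strand, name = ann$gene)
  mp <- flag_micropeptide(tx, b$orf_scores)
  cls <- classify_transcripts(loc, mp)

  expect_equal(nrow(cls), nrow(loc$calls))
  expect_false(any(duplicated(cls$gene)))
  expect_true(all(cls$class %in% c("mRNA", "micropeptide",
                                   "lncRNA_cyt_bona_fide", "lncRNA_nuc")))
  # micropeptide calls are cytosolic annotated lncRNAs
  mp_genes <- cls$gene[cls$class == "micropeptide"]
  expect_true(all(biotypes[mp_genes] == "lincRNA"))
  expect_true(all(loc$calls$class[match(mp_genes, loc$calls$gene)] ==
                    "cytosolic"))

  # localization recovers the generator's lncRNA classes almost perfectly
  truth_cls <- b$truth$class[match(cls$gene, b$truth$gene)]
  lnc <- truth_cls %in% c("lncRNA_cyt", "lncRNA_nuc")
  called_cyt <- loc$calls$class[match(cls$gene, loc$calls$gene)] ==
    "cytosolic"
  acc <- mean((truth_cls[lnc] == "lncRNA_cyt") == called_cyt[lnc])
  expect_gte(acc, 0.95)

  # ORF tracks are noise-free, so micropeptide recovery is exact among
  # transcripts that pass the localization step
  mp_truth <- b$truth$gene[b$truth$class == "micropeptide"]
  mp_called_cyt <- intersect(mp_truth,
                             loc$calls$gene[loc$calls$class == "cytosolic"])
  expect_setequal(intersect(mp_genes, mp_called_cyt), mp_called_cyt)
  expect_true(all(mp_genes %in% mp_truth))
})
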