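# Auxiliary data: annotation, compartment expression, ribosome profiling,
# AGO2 peaks, conserved-ORF score intervals and miRNA sequences.

# 0-based half-open rows -> GRanges (1-based inclusive)
.rows_to_granges <- function(df) {
  if (is.null(df) || nrow(df) == 0)
    return(GenomicRanges::GRanges(name = character(0), score = numeric(0)))
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start + 1, df$end), strand = df$strand,
    name = df$name, score = df$score)
}

#' Simulate auxiliary datasets
#'
#' Generates every non-kinetic input of the pipeline from the truth table:
#'
#' * a transcript annotation with invented loci (genes laid out with gaps
#'   along a few chromosomes; mRNAs get a 3'UTR sub-interval),
#' * nuclear/cytosolic steady-state expression (TPM-like), splitting each
#'   gene's steady-state abundance by its true cytosolic fraction with
#'   log-normal measurement noise,
#' * ribosome-profiling (RP) and total-RNA (TR) counts — translated genes
#'   at `rna * 2^te_true`, untranslated genes with near-zero RP signal,
#' * AGO2 peak intervals on bound genes only (within the 3'UTR for mRNAs,
#'   across the locus for lncRNAs), peak count increasing with the
#'   miRNA-dependent decay increment,
#' * one positive conserved-ORF score interval on each micropeptide locus
#'   (same strand), plus negative-score decoys elsewhere,
#' * random mature miRNA sequences.
#'
#' @param truth a [simulate_truth()] table.
#' @param config the matching [sim_config()].
#' @param n_mirnas number of miRNA sequences to emit.
#' @return list: `annotation` (data.frame gene, biotype, chrom, start, end,
#'   strand, utr3_start, utr3_end, length, utr3_length), `cyt_nuc`
#'   (data.frame gene, biotype, cyt_expr, nuc_expr), `ribo` (data.frame
#'   gene, rp_count, rna_count), `ago2_peaks` (GRanges), `orf_scores`
#'   (GRanges with score), `mirnas` (named character of RNA sequences).
#' @export
simulate_aux_data <- function(truth, config, n_mirnas = 10) {
  set.seed(.sub_seed(config$seed, 3L))
  n <- nrow(truth)

  # ---- annotation: genes tiled along chromosomes with 10 kb gaps ----------
  len <- round(ifelse(truth$class == "mRNA",
                      stats::rlnorm(n, log(2500), 0.5),
                      stats::rlnorm(n, log(1200), 0.5)))
  len <- pmax(len, 300)
  chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% 5)
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(1000, len[i][-length(i)] + 10000))
  }
  end <- start + len  # 0-based half-open
  strand <- sample(c("+", "-"), n, replace = TRUE)
  utr3_len <- pmin(pmax(round(stats::rlnorm(n, log(800), 0.4)), 100),
                   round(0.4 * len))
  is_m <- truth$class == "mRNA"
  # 3'UTR at the transcript 3' end: right end on +, left end on -
  utr3_start <- ifelse(is_m, ifelse(strand == "+", end - utr3_len, start),
                       NA_integer_)
  utr3_end <- ifelse(is_m, ifelse(strand == "+", end, start + utr3_len),
                     NA_integer_)
  annotation <- data.frame(
    gene = truth$gene, biotype = truth$biotype, chrom = chrom,
    start = start, end = end, strand = strand,
    utr3_start = utr3_start, utr3_end = utr3_end,
    length = len, utr3_length = ifelse(is_m, utr3_len, NA_integer_),
    stringsAsFactors = FALSE)

  # ---- compartment expression --------------------------------------------
  ss <- truth$k1_wt / truth$k3_wt  # steady-state mature abundance, WT
  tpm <- ss / sum(ss) * 1e6
  noise <- function(k) exp(stats::rnorm(k, 0, 0.2))
  cyt_nuc <- data.frame(
    gene = truth$gene, biotype = truth$biotype,
    cyt_expr = tpm * truth$cyt_frac * noise(n),
    nuc_expr = tpm * (1 - truth$cyt_frac) * noise(n),
    stringsAsFactors = FALSE)

  # ---- ribosome profiling / total RNA ------------------------------------
  depth <- config$depth
  rna_mu <- ss / sum(ss) * depth
  rp_rel <- ifelse(truth$translated, rna_mu * 2^truth$te_true, 0)
  rp_mu <- rp_rel / sum(rp_rel) * depth
  rp_mu[!truth$translated] <- 0.02  # sporadic background footprints
  ribo <- data.frame(
    gene = truth$gene,
    rp_count = .rnb(n, rp_mu, config$nb_dispersion),
    rna_count = .rnb(n, rna_mu, config$nb_dispersion),
    stringsAsFactors = FALSE)

  # ---- AGO2 peaks ---------------------------------------------------------
  peak_rows <- list()
  target_rate <- truth$k_mir / exp(config$k_mir_prior$meanlog)
  for (i in which(truth$ago2_bound)) {
    if (is_m[i]) {
      lo <- utr3_start[i]; hi <- utr3_end[i]
    } else {
      lo <- start[i]; hi <- end[i]
    }
    span_kb <- (hi - lo) / 1000
    lambda <- span_kb * (0.5 + 1.0 * target_rate[i])
    n_pk <- 1L + stats::rpois(1, lambda)  # bound genes always get >= 1 peak
    pk_start <- sort(sample(lo:(hi - 30), n_pk, replace = TRUE))
    peak_rows[[length(peak_rows) + 1L]] <- data.frame(
      chrom = chrom[i], start = pk_start, end = pk_start + 30,
      name = paste0("peak_", truth$gene[i], "_", seq_len(n_pk)),
      score = round(stats::runif(n_pk, 1, 100)), strand = strand[i],
      stringsAsFactors = FALSE)
  }
  ago2_peaks <- .rows_to_granges(do.call(rbind, peak_rows))

  # ---- conserved-ORF score track -----------------------------------------
  orf_rows <- list()
  for (i in which(truth$class == "micropeptide")) {
    w <- min(200, len[i] - 10)
    s <- start[i] + sample.int(len[i] - w, 1)
    orf_rows[[length(orf_rows) + 1L]] <- data.frame(
      chrom = chrom[i], start = s, end = s + w,
      name = paste0("orf_", truth$gene[i]),
      score = round(stats::runif(1, 5, 50), 2), strand = strand[i],
      stringsAsFactors = FALSE)
  }
  # negative-score decoys on a sample of non-micropeptide genes
  decoy <- sample(which(truth$class != "micropeptide"),
                  min(50, sum(truth$class != "micropeptide")))
  for (i in decoy) {
    w <- min(150, len[i] - 10)
    s <- start[i] + sample.int(len[i] - w, 1)
    orf_rows[[length(orf_rows) + 1L]] <- data.frame(
      chrom = chrom[i], start = s, end = s + w,
      name = paste0("neg_", truth$gene[i]),
      score = -round(stats::runif(1, 1, 20), 2), strand = strand[i],
      stringsAsFactors = FALSE)
  }
  orf_scores <- .rows_to_granges(do.call(rbind, orf_rows))

  # ---- miRNA sequences ----------------------------------------------------
  mirnas <- vapply(seq_len(n_mirnas), function(i)
    paste(sample(c("A", "C", "G", "U"), 22, replace = TRUE), collapse = ""),
    character(1))
  names(mirnas) <- sprintf("mir-%03d", seq_len(n_mirnas))

  list(annotation = annotation, cyt_nuc = cyt_nuc, ribo = ribo,
       ago2_peaks = ago2_peaks, orf_scores = orf_scores, mirnas = mirnas)
}
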