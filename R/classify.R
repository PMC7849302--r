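# Transcript classification: subcellular localization, translation
# efficiency, ribosome-bound flag, conserved-ORF micropeptide flag, and the
# four-class partition.

#' Classify transcripts by subcellular localization
#'
#' A transcript is called cytosolic when its cytosolic/nuclear expression
#' ratio is strictly greater than the median ratio of expressed mRNAs
#' (which are predominantly cytoplasmic); ties go to nuclear. Genes below
#' `min_tpm` in both compartments are excluded.
#'
#' @param expr data.frame with columns `gene`, `cyt_expr`, `nuc_expr`
#'   (TPM-like units).
#' @param biotypes named character (gene -> biotype); "protein_coding"
#'   defines the mRNA reference set.
#' @param min_tpm expression filter (default 1): a gene must reach this in
#'   at least one compartment.
#' @param eps pseudocount added to both compartments before the ratio
#'   (default 0.01).
#' @return list: `calls` (data.frame gene, biotype, cyt_expr, nuc_expr,
#'   ratio, class in cytosolic/nuclear) and `threshold` (the mRNA median
#'   ratio).
#' @export
classify_localization <- function(expr, biotypes, min_tpm = 1, eps = 0.01) {
  expr <- as.data.frame(expr)
  stopifnot(all(c("gene", "cyt_expr", "nuc_expr") %in% names(expr)))
  bt <- biotypes[expr$gene]
  keep <- pmax(expr$cyt_expr, expr$nuc_expr) >= min_tpm
  expr <- expr[keep, ]
  bt <- bt[keep]

  ratio <- (expr$cyt_expr + eps) / (expr$nuc_expr + eps)
  is_mrna <- !is.na(bt) & bt == "protein_coding"
  if (!any(is_mrna))
    stop("no expressed mRNAs to define the localization threshold",
         call. = FALSE)
  threshold <- stats::median(ratio[is_mrna])

  calls <- data.frame(
    gene = expr$gene, biotype = bt, cyt_expr = expr$cyt_expr,
    nuc_expr = expr$nuc_expr, ratio = ratio,
    class = ifelse(ratio > threshold, "cytosolic", "nuclear"),
    stringsAsFactors = FALSE)
  list(calls = calls, threshold = threshold)
}

#' Translation efficiency from ribosome-profiling and total-RNA counts
#'
#' TE is the log2 ratio of depth-normalized (counts-per-million) ribosome
#' footprint to total-RNA signal, computed only for genes with total-RNA
#' cpm > 1 and at least one raw ribosome-profiling read.
#'
#' @param rp_counts,rna_counts named integer vectors over the same gene
#'   universe (ribosome footprints, total RNA).
#' @param min_rna_cpm total-RNA cpm filter (default 1).
#' @return data.frame: gene, rp_cpm, rna_cpm, te, defined.
#' @export
translation_efficiency <- function(rp_counts, rna_counts, min_rna_cpm = 1) {
  genes <- names(rna_counts)
  if (is.null(genes) || !identical(sort(genes), sort(names(rp_counts))))
    stop("rp_counts and rna_counts must be named over the same genes",
         call. = FALSE)
  rp <- rp_counts[genes]
  if (sum(rp) == 0 || sum(rna_counts) == 0)
    stop("zero library total", call. = FALSE)
  rp_cpm <- rp / sum(rp) * 1e6
  rna_cpm <- rna_counts / sum(rna_counts) * 1e6
  defined <- rna_cpm > min_rna_cpm & rp > 0
  te <- ifelse(defined, log2(rp_cpm / rna_cpm), NA_real_)
  data.frame(gene = genes, rp_cpm = as.numeric(rp_cpm),
             rna_cpm = as.numeric(rna_cpm), te = as.numeric(te),
             defined = defined, row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag ribosome-bound transcripts
#'
#' Bound means TE is defined and strictly exceeds `threshold` (default 0,
#' i.e. footprint cpm above total-RNA cpm).
#'
#' @param profile data.frame from [translation_efficiency()].
#' @param threshold TE cutoff (default 0; strict inequality).
#' @return named logical vector over `profile$gene`.
#' @export
flag_ribosome_bound <- function(profile, threshold = 0) {
  stats::setNames(profile$defined & !is.na(profile$te) &
                    profile$te > threshold, profile$gene)
}

#' Flag transcripts overlapping conserved-ORF score regions
#'
#' A transcript is flagged as micropeptide-encoding when its locus overlaps
#' (>= 1 bp) a positive-score conserved-ORF region on the same strand, in
#' any reading frame.
#'
#' @param transcripts GRanges of transcript loci (names or `name` column =
#'   gene ids), strand required.
#' @param orf_scores GRanges with a numeric `score` column, strand
#'   required.
#' @return named logical vector per transcript.
#' @export
flag_micropeptide <- function(transcripts, orf_scores) {
  ids <- .granges_ids(transcripts)
  if (any(GenomicRanges::strand(transcripts) == "*") ||
      any(GenomicRanges::strand(orf_scores) == "*"))
    stop("strand is required on transcripts and score regions",
         call. = FALSE)
  pos <- orf_scores[!is.na(orf_scores$score) & orf_scores$score > 0]
  h <- .same_seqlevels(transcripts, pos)
  hits <- GenomicRanges::countOverlaps(h[[1]], h[[2]],
                                       minoverlap = 1L,
                                       ignore.strand = FALSE)
  stats::setNames(hits > 0, ids)
}

.granges_ids <- function(gr) {
  ids <- names(gr)
  if (is.null(ids) && !is.null(gr$name)) ids <- gr$name
  if (is.null(ids)) stop("intervals need names or a `name` column",
                         call. = FALSE)
  ids
}

#' Partition genes into the four analysis classes
#'
#' mRNAs are genes annotated protein-coding; annotated lncRNAs are split by
#' localization, and cytosolic lncRNAs carrying a conserved-ORF flag are
#' reported as micropeptide-encoding rather than bona fide lncRNAs. The
#' partition is mutually exclusive and exhaustive over the localized gene
#' set.
#'
#' @param localization result of [classify_localization()].
#' @param micropeptide named logical vector from [flag_micropeptide()].
#' @return data.frame: gene, class in mRNA / micropeptide /
#'   lncRNA_cyt_bona_fide / lncRNA_nuc.
#' @export
classify_transcripts <- function(localization, micropeptide) {
  calls <- localization$calls
  mp <- micropeptide[calls$gene]
  mp[is.na(mp)] <- FALSE
  cls <- ifelse(calls$biotype == "protein_coding", "mRNA",
         ifelse(calls$class == "nuclear", "lncRNA_nuc",
         ifelse(mp, "micropeptide", "lncRNA_cyt_bona_fide")))
  data.frame(gene = calls$gene, class = cls, stringsAsFactors = FALSE)
}
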