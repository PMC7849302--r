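# miRISC-binding evidence: AGO2 peak density, condition-specific cluster
# filtering and miRNA seed-match (MRE) discovery.

#' AGO2 peak density over regions
#'
#' Counts peaks overlapping (>= 1 bp) each region and reports peaks per
#' kilobase of region length. Regions without peaks are reported but
#' flagged, so that density comparisons can be restricted to regions with
#' binding evidence (> 0 peaks), which is the default.
#'
#' @param peaks GRanges of peaks.
#' @param regions GRanges of scored regions (3'UTRs for mRNAs, transcript
#'   spans for lncRNAs); names or a `name` column identify them.
#' @param bound_only when TRUE (default) the returned `in_comparison`
#'   column is TRUE only for regions with at least one peak.
#' @param ignore.strand passed to the overlap counting (default TRUE;
#'   CLIP peak files are not always stranded consistently).
#' @return data.frame: region, n_peaks, length_kb, density, bound,
#'   in_comparison.
#' @export
peak_density <- function(peaks, regions, bound_only = TRUE,
                         ignore.strand = TRUE) {
  ids <- .granges_ids(regions)
  widths <- GenomicRanges::width(regions)
  if (any(widths <= 0)) stop("zero-length region", call. = FALSE)
  h <- .same_seqlevels(regions, peaks)
  n_pk <- GenomicRanges::countOverlaps(h[[1]], h[[2]], minoverlap = 1L,
                                       ignore.strand = ignore.strand)
  length_kb <- widths / 1000
  out <- data.frame(
    region = ids, n_peaks = as.integer(n_pk), length_kb = length_kb,
    density = n_pk / length_kb, bound = n_pk > 0,
    stringsAsFactors = FALSE)
  out$in_comparison <- if (bound_only) out$bound else TRUE
  out
}

#' Retain clusters specific to the wild-type condition
#'
#' Removes every WT cluster that overlaps (>= 1 bp) any cluster from the
#' comparison (e.g. DICER-null) set, leaving miRNA-dependent binding
#' events. Strand is ignored unless both sets are fully stranded.
#'
#' @param clusters_wt,clusters_ko GRanges.
#' @return GRanges subset of `clusters_wt`.
#' @export
wt_specific_clusters <- function(clusters_wt, clusters_ko) {
  both_stranded <- !any(GenomicRanges::strand(clusters_wt) == "*") &&
    !any(GenomicRanges::strand(clusters_ko) == "*")
  h <- .same_seqlevels(clusters_wt, clusters_ko)
  hits <- GenomicRanges::countOverlaps(h[[1]], h[[2]],
                                       minoverlap = 1L,
                                       ignore.strand = !both_stranded)
  clusters_wt[hits == 0]
}

# canonical site-type strength order
.site_levels <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

# put two GRanges on the union of their chromosome sets so overlap
# counting does not warn about disjoint sequence levels
.same_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

.revcomp_dna <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Find miRNA seed-complementary sites in a transcript
#'
#' Scans the transcript (5'->3') for matches to the reverse complement of
#' the miRNA seed (positions 2-8 of the mature miRNA). Site types follow
#' the canonical hierarchy: 7mer-m8 is complementarity to positions 2-8;
#' 8mer is a 7mer-m8 followed by an A in the target (opposite miRNA
#' position 1); 6mer matches positions 2-7; 7mer-A1 is a 6mer followed by
#' an A. Each target start position is reported once with its strongest
#' type. Matching is case-insensitive and accepts T or U in the
#' transcript.
#'
#' @param mirna mature miRNA sequence (RNA alphabet, length >= 8).
#' @param transcript transcript sequence (DNA or RNA alphabet).
#' @return data.frame: start, end (1-based inclusive positions on the
#'   transcript), site_type, site (matched target sequence).
#' @export
find_seed_matches <- function(mirna, transcript) {
  mirna <- toupper(gsub("T", "U", toupper(mirna)))
  if (!grepl("^[ACGU]*$", mirna))
    stop("invalid characters in miRNA sequence", call. = FALSE)
  if (nchar(mirna) < 8)
    stop("miRNA must be at least 8 nucleotides", call. = FALSE)
  tx <- gsub("U", "T", toupper(transcript))
  if (!grepl("^[ACGT]*$", tx))
    stop("invalid characters in transcript sequence", call. = FALSE)

  empty <- data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), site = character(0),
                      stringsAsFactors = FALSE)
  if (nchar(tx) < 6) return(empty)

  seed_dna <- gsub("U", "T", mirna)
  match6 <- .revcomp_dna(substr(seed_dna, 2, 7))   # complements pos 2-7
  m8_base <- .revcomp_dna(substr(seed_dna, 8, 8))  # target base facing pos 8

  starts6 <- as.integer(gregexpr(match6, tx, fixed = TRUE)[[1]])
  starts6 <- starts6[starts6 > 0]
  if (length(starts6) == 0) return(empty)

  rows <- lapply(starts6, function(s6) {
    # the seed match covers target positions [start, end], 3' A at end + 1;
    # position facing miRNA position 8 is immediately 5' of the 6mer
    has_m8 <- s6 > 1 && substr(tx, s6 - 1, s6 - 1) == m8_base
    a_after <- substr(tx, s6 + 6, s6 + 6) == "A"
    if (has_m8 && a_after)
      data.frame(start = s6 - 1L, end = s6 + 6L, site_type = "8mer",
                 stringsAsFactors = FALSE)
    else if (has_m8)
      data.frame(start = s6 - 1L, end = s6 + 5L, site_type = "7mer-m8",
                 stringsAsFactors = FALSE)
    else if (a_after)
      data.frame(start = s6, end = s6 + 6L, site_type = "7mer-A1",
                 stringsAsFactors = FALSE)
    else
      data.frame(start = s6, end = s6 + 5L, site_type = "6mer",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$site <- substring(tx, out$start, out$end)
  # one record per target position, strongest type first
  out <- out[order(out$start,
                   match(out$site_type, .site_levels)), , drop = FALSE]
  out <- out[!duplicated(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene AGO2 binding flags and density table
#'
#' Joins peak density over each gene's scored region (3'UTR for mRNAs,
#' transcript span for lncRNAs) with the class partition; the bound flag is
#' n_peaks > 0. Genes without a region are flagged missing.
#'
#' @param partition data.frame from [classify_transcripts()] (columns
#'   gene, class), or any data.frame with a `gene` column.
#' @param peaks GRanges of AGO2 peaks.
#' @param regions GRanges named by gene.
#' @return data.frame: gene, class, n_peaks, length_kb, density, bound,
#'   missing_region.
#' @export
annotate_binding <- function(partition, peaks, regions) {
  dens <- peak_density(peaks, regions, bound_only = FALSE)
  i <- match(partition$gene, dens$region)
  out <- data.frame(
    gene = partition$gene,
    class = if ("class" %in% names(partition)) partition$class else NA,
    n_peaks = dens$n_peaks[i], length_kb = dens$length_kb[i],
    density = dens$density[i], bound = dens$bound[i],
    missing_region = is.na(i), stringsAsFactors = FALSE)
  out$bound[out$missing_region] <- FALSE
  out$n_peaks[out$missing_region] <- 0L
  out
}
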