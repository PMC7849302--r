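# End-to-end orchestration: normalize -> fit -> compare -> classify ->
# binding -> class-level statistics.

.median_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_

#' Run the full analysis pipeline on a fixture bundle
#'
#' Normalizes the fraction libraries by steady-state conservation, fits
#' per-gene rates in both conditions (pooled over pulse times, and per
#' pulse for concordance QC), compares rates between conditions with BH
#' FDR, classifies transcripts (localization, translation efficiency,
#' micropeptide), quantifies AGO2 binding, and summarizes degradation-rate
#' and steady-state fold changes per class with Mann-Whitney contrasts.
#'
#' @param bundle a [simulate_bundle()] result, a fixture directory (passed
#'   to [read_fixture()]), or a [sim_config()] (simulated on the fly).
#' @param out_dir optional output directory; when given, rate tables,
#'   comparisons, classes, binding table and `summary.json` are written
#'   there and listed in the returned manifest.
#' @param fdr significance cutoff on q-values (default 0.05).
#' @return list of class `pipeline_report`: `rates` (per condition),
#'   `rates_by_pulse`, `comparisons` (per rate), `pulse_r2`, `classes`,
#'   `te`, `binding`, `class_summary`, `tests`, `pca`, `summary`,
#'   `manifest`.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, fdr = 0.05) {
  if (inherits(bundle, "sim_config")) bundle <- simulate_bundle(bundle)
  if (is.character(bundle)) bundle <- read_fixture(bundle)
  cfg <- bundle$config

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- normalization ------------------------------------------------------
  norm <- stage("normalize",
                normalize_by_conservation(bundle$counts, bundle$samples))
  obs <- norm$observations

  # ---- rate fitting -------------------------------------------------------
  conditions <- unique(bundle$samples$condition)
  rates <- stage("fit", lapply(stats::setNames(conditions, conditions),
                               function(cc) fit_rates_table(obs, cc)))
  pulses <- sort(unique(bundle$samples$pulse_minutes))
  rates_by_pulse <- stage("fit_by_pulse", lapply(
    stats::setNames(as.character(pulses), paste0("t", pulses)),
    function(p) lapply(stats::setNames(conditions, conditions), function(cc)
      fit_rates_table(obs, cc, pulse_minutes = as.numeric(p)))))

  pulse_r2 <- NULL
  if (length(pulses) >= 2) {
    pulse_r2 <- lapply(stats::setNames(conditions, conditions), function(cc)
      pulse_agreement(rates_by_pulse[[1]][[cc]],
                      rates_by_pulse[[2]][[cc]])$r2)
  }

  # ---- condition comparison ----------------------------------------------
  comparisons <- NULL
  if (all(c("WT", "KO") %in% conditions)) {
    comparisons <- stage("compare", lapply(
      stats::setNames(c("k1", "k2", "k3"), c("k1", "k2", "k3")),
      function(r) compare_rates(rates$WT, rates$KO, r)))
  }

  # ---- classification -----------------------------------------------------
  biotypes <- stats::setNames(bundle$annotation$biotype,
                              bundle$annotation$gene)
  loc <- stage("classify", classify_localization(bundle$cyt_nuc, biotypes))
  te <- stage("classify", translation_efficiency(
    stats::setNames(bundle$ribo$rp_count, bundle$ribo$gene),
    stats::setNames(bundle$ribo$rna_count, bundle$ribo$gene)))
  ribo_bound <- flag_ribosome_bound(te)
  ann <- bundle$annotation
  tx_gr <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start + 1, ann$end), strand = ann$strand,
    name = ann$gene)
  mp <- stage("classify", flag_micropeptide(tx_gr, bundle$orf_scores))
  classes <- stage("classify", classify_transcripts(loc, mp))

  # ---- AGO2 binding -------------------------------------------------------
  # mRNAs scored over the 3'UTR, lncRNAs over the transcript span
  reg_start <- ifelse(ann$biotype == "protein_coding", ann$utr3_start,
                      ann$start)
  reg_end <- ifelse(ann$biotype == "protein_coding", ann$utr3_end, ann$end)
  ok <- !is.na(reg_start) & !is.na(reg_end) & reg_end > reg_start
  regions <- GenomicRanges::GRanges(
    ann$chrom[ok], IRanges::IRanges(reg_start[ok] + 1, reg_end[ok]),
    strand = ann$strand[ok], name = ann$gene[ok])
  binding <- stage("targeting",
                   annotate_binding(classes, bundle$ago2_peaks, regions))

  # ---- class-level statistics --------------------------------------------
  gene_tab <- classes
  gene_tab$ribosome_bound <- unname(ribo_bound[gene_tab$gene])
  gene_tab$ago2_bound <- binding$bound[match(gene_tab$gene, binding$gene)]
  gene_tab$density <- binding$density[match(gene_tab$gene, binding$gene)]
  if (!is.null(comparisons)) {
    k3c <- comparisons$k3
    gene_tab$log2_fc_k3 <- k3c$log2_fc[match(gene_tab$gene, k3c$gene)]
    gene_tab$q_k3 <- k3c$q[match(gene_tab$gene, k3c$gene)]
    # steady-state abundance = k1/k3; fold change from the fitted rates
    i_wt <- match(gene_tab$gene, rates$WT$gene)
    i_ko <- match(gene_tab$gene, rates$KO$gene)
    gene_tab$log2_fc_ss <-
      log2((rates$KO$k1[i_ko] / rates$KO$k3[i_ko]) /
             (rates$WT$k1[i_wt] / rates$WT$k3[i_wt]))
  }

  class_summary <- do.call(rbind, lapply(
    split(gene_tab, gene_tab$class), function(d) data.frame(
      class = d$class[1], n = nrow(d),
      median_log2_fc_k3 = .median_or_na(
        d$log2_fc_k3[!is.na(d$log2_fc_k3)]),
      frac_q_lt_cut = if (any(!is.na(d$q_k3)))
        mean(d$q_k3[!is.na(d$q_k3)] < fdr) else NA_real_,
      median_log2_fc_ss = .median_or_na(
        d$log2_fc_ss[is.finite(d$log2_fc_ss)]),
      stringsAsFactors = FALSE)))
  rownames(class_summary) <- NULL

  tests <- list()
  grp <- function(cls, extra = TRUE)
    gene_tab$log2_fc_k3[gene_tab$class == cls & extra &
                          !is.na(gene_tab$log2_fc_k3)]
  target_mrna <- grp("mRNA", gene_tab$ribosome_bound &
                       gene_tab$ago2_bound %in% TRUE)
  lnc_cyt <- grp("lncRNA_cyt_bona_fide")
  if (length(target_mrna) >= 2 && length(lnc_cyt) >= 2)
    tests$k3_fc_mrna_bound_vs_lnc_cyt <-
      mann_whitney_u(target_mrna, lnc_cyt)
  mp_fc <- grp("micropeptide")
  if (length(mp_fc) >= 2 && length(lnc_cyt) >= 2)
    tests$k3_fc_micropeptide_vs_lnc_cyt <- mann_whitney_u(mp_fc, lnc_cyt)
  ss_m <- gene_tab$log2_fc_ss[gene_tab$class == "mRNA" &
                                is.finite(gene_tab$log2_fc_ss)]
  ss_l <- gene_tab$log2_fc_ss[gene_tab$class == "lncRNA_cyt_bona_fide" &
                                is.finite(gene_tab$log2_fc_ss)]
  if (length(ss_m) >= 2 && length(ss_l) >= 2)
    tests$ss_fc_mrna_vs_lnc_cyt <- mann_whitney_u(ss_m, ss_l)
  # density of binding: significantly changed vs unchanged bound mRNAs
  sig <- gene_tab$class == "mRNA" & gene_tab$ago2_bound %in% TRUE &
    !is.na(gene_tab$q_k3)
  d_sig <- gene_tab$density[sig & gene_tab$q_k3 < fdr]
  d_ns <- gene_tab$density[sig & gene_tab$q_k3 >= fdr]
  if (length(d_sig) >= 2 && length(d_ns) >= 2)
    tests$density_sig_vs_unchanged <- mann_whitney_u(d_sig, d_ns)

  # ---- PCA QC on exonic sample profiles ----------------------------------
  ex_cols <- bundle$samples$feature == "exonic"
  cpm <- sweep(bundle$counts[, ex_cols, drop = FALSE], 2,
               colSums(bundle$counts[, ex_cols, drop = FALSE]), `/`) * 1e6
  logmat <- log2(cpm + 1)
  pca <- stage("pca", pca_qc(
    logmat, bundle$samples[ex_cols, c("fraction", "condition", "replicate")]))

  summary <- list(
    seed = cfg$seed,
    n_genes = nrow(bundle$truth),
    n_fitted = lapply(rates, nrow),
    n_shared_norm_genes = norm$n_shared_genes,
    pulse_r2_k3 = pulse_r2,
    frac_k3_lower_ko = if (!is.null(comparisons))
      mean(comparisons$k3$log2_fc[comparisons$k3$tested] < 0) else NULL,
    frac_q_lt_cut = if (!is.null(comparisons))
      mean(comparisons$k3$q[comparisons$k3$tested] < fdr) else NULL,
    class_summary = class_summary,
    tests = lapply(tests, function(t)
      list(method = t$method, statistic = t$statistic, p = t$p,
           sizes = t$sizes)),
    pca_separation = pca$separation,
    localization_threshold = loc$threshold,
    fdr = fdr)

  manifest <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (cc in names(rates)) {
      f <- paste0("rates_", tolower(cc), ".tsv")
      .write_tsv(rates[[cc]], file.path(out_dir, f))
      files[[paste0("rates_", tolower(cc))]] <- f
    }
    if (!is.null(comparisons)) for (r in names(comparisons)) {
      f <- paste0("comparison_", r, ".tsv")
      .write_tsv(comparisons[[r]], file.path(out_dir, f))
      files[[paste0("comparison_", r)]] <- f
    }
    .write_tsv(gene_tab, file.path(out_dir, "classes.tsv"))
    files$classes <- "classes.tsv"
    .write_tsv(binding, file.path(out_dir, "binding.tsv"))
    files$binding <- "binding.tsv"
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    files$summary <- "summary.json"
    manifest <- list(out_dir = out_dir, files = files)
  }

  structure(list(
    rates = rates, rates_by_pulse = rates_by_pulse,
    comparisons = comparisons, pulse_r2 = pulse_r2, classes = classes,
    te = te, binding = binding, gene_table = gene_tab,
    class_summary = class_summary, tests = tests, pca = pca,
    summary = summary, manifest = manifest, config = cfg
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", x$summary$n_genes, "genes, seed",
      x$summary$seed, "\n")
  if (!is.null(x$summary$frac_k3_lower_ko))
    cat(sprintf("  %.1f%% of tested genes have lower k3 in KO; %.1f%% at q < %g\n",
                100 * x$summary$frac_k3_lower_ko,
                100 * x$summary$frac_q_lt_cut, x$summary$fdr))
  if (!is.null(x$pulse_r2))
    cat("  pulse-concordance R2 (log10 k3):",
        paste(sprintf("%s %.3f", names(x$pulse_r2), unlist(x$pulse_r2)),
              collapse = ", "), "\n")
  print(x$class_summary)
  invisible(x)
}
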