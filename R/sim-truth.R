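# Ground-truth generator: per-gene rates, class labels and binding flags.

#' Simulate the ground-truth table
#'
#' Draws per-gene kinetic rates and class structure for both conditions.
#' Wild-type degradation is `k3_wt = k3_base + k_mir` for miRNA targets
#' (translated AND AGO2-bound genes) and `k3_base` otherwise. The knockout
#' retains a residual fraction of miRNA-dependent decay and undergoes a
#' global synthesis-decay compensation:
#' `k1_ko = synthesis_compensation * k1_wt` for every gene and
#' `k3_ko = synthesis_compensation^compensation_coupling * k3_base +
#' residual_mirna_fraction * k_mir`. Processing is condition-independent.
#'
#' mRNAs and micropeptide transcripts are translated; bona fide lncRNAs are
#' not. Cytosolic steady-state fractions (`cyt_frac`) are drawn per class so
#' that cytosolic classes sit above the mRNA median ratio and nuclear
#' lncRNAs below it.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `truth_table`, one row per gene: gene, class,
#'   biotype, translated, ago2_bound, k_mir, k1_wt, k2_wt, k3_wt, k1_ko,
#'   k2_ko, k3_ko, cyt_frac, te_true.
#' @export
simulate_truth <- function(config) {
  validate_sim_config(config)
  set.seed(.sub_seed(config$seed, 1L))

  classes <- rep(c("mRNA", "micropeptide", "lncRNA_cyt", "lncRNA_nuc"),
                 times = c(config$n_mrna, config$n_micropeptide,
                           config$n_lnc_cyt, config$n_lnc_nuc))
  n <- length(classes)
  gene <- sprintf("g%05d", seq_len(n))
  translated <- classes %in% c("mRNA", "micropeptide")
  biotype <- ifelse(classes == "mRNA", "protein_coding", "lincRNA")

  p_bound <- ifelse(translated, config$frac_ago2_bound_translated,
                    config$frac_ago2_bound_untranslated)
  ago2_bound <- stats::runif(n) < p_bound

  draw <- function(prior) stats::rlnorm(n, prior$meanlog, prior$sdlog)
  k1 <- draw(config$rate_priors$k1)
  k2 <- draw(config$rate_priors$k2)
  k3_base <- draw(config$rate_priors$k3_base)
  k_mir <- ifelse(translated & ago2_bound,
                  stats::rlnorm(n, config$k_mir_prior$meanlog,
                                config$k_mir_prior$sdlog), 0)

  comp <- config$synthesis_compensation
  k3_wt <- k3_base + k_mir
  k3_ko <- comp^config$compensation_coupling * k3_base +
    config$residual_mirna_fraction * k_mir

  # subcellular steady-state split: cytosolic classes above, nuclear below,
  # the typical mRNA cytosolic fraction
  cyt_frac <- numeric(n)
  cyt_frac[classes == "mRNA"] <- stats::rbeta(sum(classes == "mRNA"), 14, 6)
  cyt_high <- classes %in% c("micropeptide", "lncRNA_cyt")
  cyt_frac[cyt_high] <- stats::rbeta(sum(cyt_high), 18, 2)
  cyt_frac[classes == "lncRNA_nuc"] <-
    stats::rbeta(sum(classes == "lncRNA_nuc"), 2, 8)

  # true log2 translation efficiency for translated genes
  te_true <- ifelse(translated, stats::rnorm(n, 1, 0.5), -Inf)

  structure(data.frame(
    gene = gene, class = classes, biotype = biotype,
    translated = translated, ago2_bound = ago2_bound, k_mir = k_mir,
    k1_wt = k1, k2_wt = k2, k3_wt = k3_wt,
    k1_ko = comp * k1, k2_ko = k2, k3_ko = k3_ko,
    cyt_frac = cyt_frac, te_true = te_true,
    stringsAsFactors = FALSE
  ), class = c("truth_table", "data.frame"))
}
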