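# Study-design configuration for the synthetic-data generator.

#' Simulation configuration
#'
#' Parameters of the synthetic dual-fraction pulse-labelling study. Defaults
#' emulate a DICER loss-of-function design in mESC-like cells: two pulse
#' durations (10 and 15 min), two biological replicates, a knockout (KO)
#' condition in which ~80% of miRNA activity is lost
#' (`residual_mirna_fraction = 0.2`) together with a mild global
#' transcription-decay compensation (`synthesis_compensation = 0.85`), and
#' four transcript classes: mRNA, micropeptide-encoding transcript,
#' bona fide cytosolic lncRNA and nuclear lncRNA.
#'
#' Rate priors are log-normal, parameterized by `meanlog`/`sdlog`. The
#' defaults give median processing half-lives of a few minutes and median
#' degradation half-lives of roughly four hours, with the miRNA-dependent
#' decay increment `k_mir` (added to `k3` of translated AND AGO2-bound
#' transcripts) comparable in magnitude to basal decay.
#'
#' @param n_mrna,n_lnc_cyt,n_lnc_nuc,n_micropeptide genes per class.
#' @param rate_priors list of `meanlog`/`sdlog` pairs for `k1`
#'   (abundance-units/min), `k2` (1/min) and `k3_base` (1/min).
#' @param k_mir_prior log-normal prior for the miRNA-dependent decay
#'   increment (1/min), applied to translated AND AGO2-bound genes.
#' @param frac_ago2_bound_translated,frac_ago2_bound_untranslated
#'   probability that a translated / untranslated transcript is AGO2-bound.
#' @param residual_mirna_fraction fraction of miRNA activity remaining in
#'   KO (0.2 = ~80% depletion).
#' @param synthesis_compensation multiplicative reduction of `k1` in KO;
#'   the basal decay rate is reduced by the same factor raised to
#'   `compensation_coupling` (global synthesis-decay coupling).
#' @param compensation_coupling coupling exponent (default 1).
#' @param pulse_minutes pulse durations in minutes (strictly positive,
#'   distinct).
#' @param replicates biological replicates per condition and pulse time.
#' @param depth expected sequencing library size (counts).
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson noise.
#' @param seed integer seed; every generator draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 1200, n_lnc_cyt = 300, n_lnc_nuc = 450,
                       n_micropeptide = 50,
                       rate_priors = list(
                         k1 = list(meanlog = log(1), sdlog = 1),
                         k2 = list(meanlog = log(0.25), sdlog = 0.5),
                         k3_base = list(meanlog = log(0.003), sdlog = 0.7)),
                       k_mir_prior = list(meanlog = log(0.003), sdlog = 0.7),
                       frac_ago2_bound_translated = 0.5,
                       frac_ago2_bound_untranslated = 0.3,
                       residual_mirna_fraction = 0.2,
                       synthesis_compensation = 0.85,
                       compensation_coupling = 1,
                       pulse_minutes = c(10, 15),
                       replicates = 2,
                       depth = 5e6,
                       nb_dispersion = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_mrna = n_mrna, n_lnc_cyt = n_lnc_cyt, n_lnc_nuc = n_lnc_nuc,
    n_micropeptide = n_micropeptide, rate_priors = rate_priors,
    k_mir_prior = k_mir_prior,
    frac_ago2_bound_translated = frac_ago2_bound_translated,
    frac_ago2_bound_untranslated = frac_ago2_bound_untranslated,
    residual_mirna_fraction = residual_mirna_fraction,
    synthesis_compensation = synthesis_compensation,
    compensation_coupling = compensation_coupling,
    pulse_minutes = pulse_minutes, replicates = replicates,
    depth = depth, nb_dispersion = nb_dispersion, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_mrna, cfg$n_lnc_cyt, cfg$n_lnc_nuc, cfg$n_micropeptide)
  if (any(counts < 0) || sum(counts) == 0)
    stop("class counts must be non-negative with at least one gene",
         call. = FALSE)
  for (nm in c("k1", "k2", "k3_base"))
    if (!all(c("meanlog", "sdlog") %in% names(cfg$rate_priors[[nm]])))
      stop("rate_priors$", nm, " needs meanlog and sdlog", call. = FALSE)
  probs <- c(cfg$frac_ago2_bound_translated, cfg$frac_ago2_bound_untranslated,
             cfg$residual_mirna_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities and residual_mirna_fraction must lie in [0, 1]",
         call. = FALSE)
  if (any(cfg$pulse_minutes <= 0) || anyDuplicated(cfg$pulse_minutes))
    stop("pulse_minutes must be strictly positive and distinct",
         call. = FALSE)
  if (cfg$replicates < 1) stop("need at least one replicate", call. = FALSE)
  if (cfg$synthesis_compensation <= 0)
    stop("synthesis_compensation must be positive", call. = FALSE)
  if (cfg$nb_dispersion < 0)
    stop("nb_dispersion must be non-negative", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_mrna, "mRNA,", x$n_micropeptide, "micropeptide,",
      x$n_lnc_cyt, "cytosolic lncRNA,", x$n_lnc_nuc, "nuclear lncRNA\n")
  cat("  pulses:", paste(x$pulse_minutes, collapse = "/"), "min,",
      x$replicates, "replicates, depth", format(x$depth, big.mark = ","),
      "\n")
  cat("  KO: residual miRNA", x$residual_mirna_fraction,
      ", synthesis compensation", x$synthesis_compensation, "\n")
  invisible(x)
}

# Sub-seeds for the generator stages, all < 2^31. Keeps stages independent
# so regenerating counts does not perturb the truth table.
.sub_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}
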