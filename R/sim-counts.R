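# Fraction-library count simulation from the closed-form kinetic model.

# negative binomial with variance mu + dispersion*mu^2; dispersion 0 =
# Poisson
.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate fraction-library counts
#'
#' For every (condition, pulse time, replicate) two libraries are produced
#' — labeled (newly synthesized) and pre-existing RNA — each quantified at
#' intronic and exonic features. Expected signal follows the closed forms:
#' intronic is proportional to premature abundance P of the fraction,
#' exonic to P + M. Each library gets a scale factor drawn log-uniform in
#' [0.5, 2] (times a depth factor targeting `config$depth` counts per
#' library), and counts are negative-binomial around the scaled
#' expectation.
#'
#' @param truth a [simulate_truth()] table.
#' @param config the [sim_config()] that produced it.
#' @return list with `counts` (integer matrix genes x samples), `samples`
#'   (sample metadata: sample_id, condition, fraction, feature,
#'   pulse_minutes, replicate, library_id), `library_scales` (data.frame of
#'   true per-library scale factors) and `expected` (matrix of expected
#'   counts, same shape as `counts`).
#' @export
simulate_fraction_counts <- function(truth, config) {
  validate_sim_config(config)
  set.seed(.sub_seed(config$seed, 2L))
  n <- nrow(truth)

  design <- expand.grid(
    feature = c("intronic", "exonic"),
    fraction = c("labeled", "preexisting"),
    replicate = seq_len(config$replicates),
    pulse_minutes = config$pulse_minutes,
    condition = c("WT", "KO"),
    stringsAsFactors = FALSE)
  design$library_id <- paste(design$condition, design$pulse_minutes,
                             design$replicate, design$fraction, sep = "_")
  design$sample_id <- paste(design$library_id, design$feature, sep = "_")

  rate_col <- function(k, cond) truth[[paste0(k, "_", tolower(cond))]]
  abundance <- sapply(seq_len(nrow(design)), function(j) {
    d <- design[j, ]
    .model_abundance(rate_col("k1", d$condition), rate_col("k2", d$condition),
                     rate_col("k3", d$condition), d$pulse_minutes,
                     d$fraction, d$feature)
  })

  lib_ids <- unique(design$library_id)
  jitter <- exp(stats::runif(length(lib_ids), log(0.5), log(2)))
  names(jitter) <- lib_ids
  # depth factor per library so the expected library total is depth*jitter
  scale <- vapply(lib_ids, function(l) {
    tot <- sum(abundance[, design$library_id == l])
    jitter[l] * config$depth / tot
  }, numeric(1))

  expected <- sweep(abundance, 2, scale[design$library_id], `*`)
  counts <- matrix(
    .rnb(length(expected), as.vector(expected), config$nb_dispersion),
    nrow = n)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth$gene, design$sample_id)
  dimnames(expected) <- dimnames(counts)

  list(counts = counts,
       samples = design[, c("sample_id", "condition", "fraction", "feature",
                            "pulse_minutes", "replicate", "library_id")],
       library_scales = data.frame(library_id = lib_ids, scale = scale,
                                   stringsAsFactors = FALSE),
       expected = expected)
}
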