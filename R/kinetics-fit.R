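# Per-gene rate estimation and condition comparison.

#' Fit synthesis, processing and degradation rates for one gene
#'
#' Nonlinear least squares on the log scale: minimizes
#' sum over observations of (log(model + eps) - log(observed + eps))^2
#' over log(k1), log(k2), log(k3). The pseudo-floor eps is the larger of
#' 1e-6 times the median observed abundance and half the smallest positive
#' abundance of the gene; the second term keeps zero-count observations
#' (common for the rapidly decaying pre-existing intronic pool) from
#' dominating the log-scale objective, which would otherwise bias the
#' fitted rates.
#' Optimization by Levenberg-Marquardt; standard errors on the natural-log
#' scale come from the Gauss-Newton approximation of the Hessian.
#'
#' Initial values: k3 from the per-observation pre-existing mature fraction,
#' k3 = -ln(max(M_E/M_total, 1e-3))/t averaged over pre-existing exonic
#' observations; k1 = mean labeled exonic abundance / t; k2 = k1 / mean
#' intronic abundance.
#'
#' @param obs data.frame for one gene and condition with columns `fraction`
#'   ("labeled"/"preexisting"), `feature` ("intronic"/"exonic"),
#'   `pulse_minutes`, `abundance`. At least 4 observations spanning both
#'   fractions.
#' @return A list of class `kinetic_fit`: `k1`, `k2`, `k3`, `se_log_k1`,
#'   `se_log_k2`, `se_log_k3`, `rss`, `n_obs`, `converged`.
#' @export
fit_rates <- function(obs) {
  obs <- as.data.frame(obs)
  stopifnot(all(c("fraction", "feature", "pulse_minutes", "abundance")
                %in% names(obs)))
  if (nrow(obs) < 4 || length(unique(obs$fraction)) < 2)
    stop("need at least 4 observations spanning both fractions",
         call. = FALSE)
  if (any(obs$abundance < 0) || any(!is.finite(obs$abundance)))
    stop("abundances must be finite and non-negative", call. = FALSE)
  lab <- obs$fraction == "labeled"
  if (all(obs$abundance[lab] == 0))
    stop("no signal: all labeled abundances are zero", call. = FALSE)

  eps <- max(1e-6 * stats::median(obs$abundance),
             0.5 * min(obs$abundance[obs$abundance > 0]))

  # --- initialization ------------------------------------------------------
  pre_ex <- obs$fraction == "preexisting" & obs$feature == "exonic"
  pre_in <- obs$fraction == "preexisting" & obs$feature == "intronic"
  lab_ex <- lab & obs$feature == "exonic"
  tot_ex_gene <- mean(obs$abundance[obs$feature == "exonic"]) * 2 # L + E
  k3_0 <- 0.01
  if (any(pre_ex) && tot_ex_gene > 0) {
    # mature pre-existing approximated by pre-existing exonic minus intronic
    me <- pmax(obs$abundance[pre_ex] -
                 mean(obs$abundance[pre_in], na.rm = TRUE), eps)
    mtot <- max(tot_ex_gene - 2 * mean(obs$abundance[pre_in], na.rm = TRUE),
                eps)
    k3_0 <- mean(-log(pmax(pmin(me / mtot, 1), 1e-3)) /
                   obs$pulse_minutes[pre_ex])
    if (!is.finite(k3_0) || k3_0 <= 0) k3_0 <- 0.01
  }
  k1_0 <- mean(obs$abundance[lab_ex] / obs$pulse_minutes[lab_ex])
  if (!is.finite(k1_0) || k1_0 <= 0) k1_0 <- eps / 10
  p_in <- mean(obs$abundance[obs$feature == "intronic"]) * 2
  k2_0 <- if (is.finite(p_in) && p_in > 0) k1_0 / (p_in / 2) else 0.2
  if (!is.finite(k2_0) || k2_0 <= 0) k2_0 <- 0.2

  resid_fn <- function(theta) {
    k <- exp(theta)
    pred <- mapply(function(fr, fe, t)
      .model_abundance(k[1], k[2], k[3], t, fr, fe),
      obs$fraction, obs$feature, obs$pulse_minutes)
    log(pred + eps) - log(obs$abundance + eps)
  }

  fit <- minpack.lm::nls.lm(
    par = log(c(k1_0, k2_0, k3_0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 200, ftol = 1e-14, ptol = 1e-14, gtol = 0))
  theta <- fit$par
  converged <- fit$info %in% 1:4
  rss <- sum(resid_fn(theta)^2)
  n <- nrow(obs)

  # Gauss-Newton covariance: sigma^2 (J'J)^-1 with sigma^2 = rss/(n - 3)
  se <- rep(NA_real_, 3)
  sigma2 <- if (n > 3) rss / (n - 3) else 0
  jtj <- fit$hessian
  cv <- try(solve(jtj) * sigma2, silent = TRUE)
  if (!inherits(cv, "try-error")) {
    d <- diag(cv)
    se <- sqrt(pmax(d, 0))
  }

  structure(list(
    k1 = exp(theta[1]), k2 = exp(theta[2]), k3 = exp(theta[3]),
    se_log_k1 = se[1], se_log_k2 = se[2], se_log_k3 = se[3],
    rss = rss, n_obs = n, converged = converged
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "kinetic_fit: k1 = %.4g /min, k2 = %.4g /min, k3 = %.4g /min (half-life %.3g min)\n",
    x$k1, x$k2, x$k3, log(2) / x$k3))
  cat(sprintf("  n_obs = %d, rss = %.4g, converged = %s\n",
              x$n_obs, x$rss, x$converged))
  invisible(x)
}

#' Fit rates for all genes of one condition
#'
#' Applies [fit_rates()] per gene to a normalized observation table,
#' excluding genes whose labeled signal never reaches the count noise floor.
#'
#' @param observations data.frame as produced by
#'   [normalize_by_conservation()] (optionally pre-filtered to one
#'   condition).
#' @param condition condition to fit; default the single condition present.
#' @param pulse_minutes optional subset of pulse times to use (e.g. a
#'   single-pulse fit for pulse-concordance checks); default all.
#' @param min_labeled minimum labeled (exonic) abundance that must be
#'   reached in at least one labeled library for a gene to be fitted
#'   (noise floor, default 10 on the normalized count scale).
#' @return data.frame, one row per fitted gene: gene, condition, k1, k2,
#'   k3, se_log_k1..se_log_k3, rss, n_obs, converged.
#' @export
fit_rates_table <- function(observations, condition = NULL,
                            pulse_minutes = NULL, min_labeled = 10) {
  obs <- as.data.frame(observations)
  if (is.null(condition)) {
    condition <- unique(obs$condition)
    if (length(condition) != 1)
      stop("multiple conditions present; pass `condition`", call. = FALSE)
  }
  obs <- obs[obs$condition == condition, ]
  if (!is.null(pulse_minutes))
    obs <- obs[obs$pulse_minutes %in% pulse_minutes, ]

  lab_ex <- obs[obs$fraction == "labeled" & obs$feature == "exonic", ]
  keep <- tapply(lab_ex$abundance, lab_ex$gene, max) >= min_labeled
  genes <- names(keep)[keep]

  rows <- lapply(genes, function(g) {
    f <- try(fit_rates(obs[obs$gene == g, ]), silent = TRUE)
    if (inherits(f, "try-error")) return(NULL)
    data.frame(gene = g, condition = condition, k1 = f$k1, k2 = f$k2,
               k3 = f$k3, se_log_k1 = f$se_log_k1, se_log_k2 = f$se_log_k2,
               se_log_k3 = f$se_log_k3, rss = f$rss, n_obs = f$n_obs,
               converged = f$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare one rate between two fitted conditions
#'
#' Per-gene z-test on the natural-log rate difference:
#' z = (ln k_KO - ln k_WT) / sqrt(se_KO^2 + se_WT^2), two-tailed p from the
#' standard normal, Benjamini-Hochberg q across all tested genes. Fold
#' changes are reported as log2(KO/WT). Genes missing or non-converged in
#' either condition are returned with `tested = FALSE`.
#'
#' @param rates_wt,rates_ko data.frames from [fit_rates_table()].
#' @param rate one of "k1", "k2", "k3".
#' @return data.frame: gene, log2_fc, z, p, q, tested.
#' @export
compare_rates <- function(rates_wt, rates_ko, rate = c("k3", "k1", "k2")) {
  rate <- match.arg(rate)
  se_col <- paste0("se_log_", rate)
  genes <- union(rates_wt$gene, rates_ko$gene)
  wt <- rates_wt[match(genes, rates_wt$gene), ]
  ko <- rates_ko[match(genes, rates_ko$gene), ]
  tested <- !is.na(wt$gene) & !is.na(ko$gene) &
    wt$converged & ko$converged &
    is.finite(wt[[se_col]]) & is.finite(ko[[se_col]])

  dln <- log(ko[[rate]]) - log(wt[[rate]])
  se <- sqrt(wt[[se_col]]^2 + ko[[se_col]]^2)
  z <- ifelse(dln == 0, 0, dln / se)  # identical rates -> z = 0 even if se 0
  p <- 2 * stats::pnorm(-abs(z))
  p[tested & dln == 0] <- 1
  out <- data.frame(gene = genes, log2_fc = dln / log(2), z = z, p = p,
                    q = NA_real_, tested = tested, stringsAsFactors = FALSE)
  out$log2_fc[!tested] <- NA_real_
  out$z[!tested] <- NA_real_
  out$p[!tested] <- NA_real_
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out
}

#' Agreement of degradation rates between two single-pulse fits
#'
#' Squared Pearson correlation of log10 degradation rates over genes fitted
#' and converged in both inputs.
#'
#' @param rates_a,rates_b data.frames from [fit_rates_table()] (e.g. the
#'   10-min-only and 15-min-only fits).
#' @param rate rate column to correlate (default "k3").
#' @return list with `r2`, `r` and `n_genes`.
#' @export
pulse_agreement <- function(rates_a, rates_b, rate = "k3") {
  a <- rates_a[rates_a$converged, c("gene", rate)]
  b <- rates_b[rates_b$converged, c("gene", rate)]
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < 3)
    stop("need at least 3 genes fitted in both runs", call. = FALSE)
  x <- log10(a[[rate]][match(shared, a$gene)])
  y <- log10(b[[rate]][match(shared, b$gene)])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in log10 rates; correlation undefined",
         call. = FALSE)
  r <- stats::cor(x, y)
  list(r2 = r^2, r = r, n_genes = length(shared))
}
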