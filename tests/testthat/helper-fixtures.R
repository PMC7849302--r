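# Shared fixtures: small study configurations and closed-form observation
# builders used across test files.

small_config <- function(seed = 101, ...) {
  sim_config(n_mrna = 80, n_lnc_cyt = 25, n_lnc_nuc = 30,
             n_micropeptide = 10, depth = 4e5, seed = seed, ...)
}

# noise-free observations for one gene from the closed forms
closed_form_obs <- function(k1, k2, k3, times = c(10, 15), replicates = 2) {
  grid <- expand.grid(fraction = c("labeled", "preexisting"),
                      feature = c("intronic", "exonic"),
                      pulse_minutes = times,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  grid$abundance <- mapply(function(fr, fe, t) {
    ab <- if (fr == "labeled") labeled_abundance(k1, k2, k3, t)
          else preexisting_abundance(k1, k2, k3, t)
    if (fe == "intronic") ab$P else ab$P + ab$M
  }, grid$fraction, grid$feature, grid$pulse_minutes)
  grid
}

# fourth-order Runge-Kutta integration of the labeled/pre-existing system;
# independent oracle for the closed forms
rk4_abundance <- function(k1, k2, k3, t_end, labeled = TRUE, n_steps = 4000) {
  deriv <- function(t, y, parms) {
    with(as.list(parms), list(c(
      (if (labeled) k1 else 0) - k2 * y[1],
      k2 * y[1] - k3 * y[2]
    )))
  }
  y0 <- if (labeled) c(0, 0) else c(k1 / k2, k1 / k3)
  out <- deSolve::rk4(y0, seq(0, t_end, length.out = n_steps + 1), deriv,
                      c(k1 = k1, k2 = k2, k3 = k3))
  list(P = unname(out[nrow(out), 2]), M = unname(out[nrow(out), 3]))
}

# exact two-tailed Mann-Whitney by enumeration over group assignments
enumerate_mw_p <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  u_obs <- sum(rank(vals)[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx)
    sum(rank(vals)[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# exact two-tailed Fisher by hypergeometric enumeration
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(a)
    dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}


random_granges <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                           stranded = TRUE, scored = FALSE) {
  s <- sample(seq_len(max_pos), n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    sample(chroms, n, TRUE), IRanges::IRanges(s, s + sample(10:300, n, TRUE)),
    strand = if (stranded) sample(c("+", "-"), n, TRUE) else "*",
    name = paste0("iv", seq_len(n)))
  if (scored) gr$score <- runif(n)
  gr
}

brute_overlap_count <- function(query, subject, ignore.strand = TRUE) {
  vapply(seq_along(query), function(i) {
    qi <- query[i]
    sum(vapply(seq_along(subject), function(j) {
      sj <- subject[j]
      same_chr <- as.character(GenomicRanges::seqnames(qi)) ==
        as.character(GenomicRanges::seqnames(sj))
      ovl <- GenomicRanges::start(qi) <= GenomicRanges::end(sj) &&
        GenomicRanges::end(qi) >= GenomicRanges::start(sj)
      str_ok <- ignore.strand ||
        as.character(GenomicRanges::strand(qi)) ==
          as.character(GenomicRanges::strand(sj))
      same_chr && ovl && str_ok
    }, logical(1)))
  }, numeric(1))
}

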