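#' State frequencies of a dominant locus under a frequency model
#'
#' Dominant markers expose only band presence/absence, so two conventions
#' coexist for turning a band frequency p into "allele" frequencies:
#'
#' * `band_state`: treat the two phenotype classes as the states, (p, 1 - p).
#'   This is the convention behind GenAlEx's binary diversity statistics.
#' * `dominant_hwe`: assume a diploid locus in Hardy-Weinberg equilibrium
#'   with the band allele dominant, so the band-absent phenotype frequency
#'   1 - p equals q^2. The recessive allele frequency is estimated as
#'   q-hat = sqrt(1 - p) (`estimator = "sqrt"`) or with the Lynch-Milligan
#'   small-sample Taylor correction q-hat = sqrt(x) / (1 - Var(x) / (8 x^2)),
#'   Var(x) = x(1 - x)/n (`estimator = "lynch_milligan"`, requires `n`).
#'
#' @param p band frequency in \[0, 1\] (vectorised).
#' @param model `"band_state"` or `"dominant_hwe"`.
#' @param estimator recessive-frequency estimator for `dominant_hwe`.
#' @param n scored sample count, used by the Lynch-Milligan correction.
#' @return matrix with columns `f1` (band/dominant state) and `f2`.
#' @export
locus_state_freqs <- function(p, model = c("band_state", "dominant_hwe"),
                              estimator = c("sqrt", "lynch_milligan"), n = Inf) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("band frequency must lie in [0, 1]", call. = FALSE)
  if (model == "band_state") {
    q <- 1 - p
  } else {
    x <- 1 - p
    q <- sqrt(x)
    if (estimator == "lynch_milligan" && is.finite(n)) {
      vx <- x * (1 - x) / n
      corr <- 1 - vx / (8 * x^2)
      q <- ifelse(x > 0, pmin(sqrt(x) / pmax(corr, .Machine$double.eps), 1), 0)
    }
  }
  cbind(f1 = 1 - q, f2 = q)
}

pop_indices <- function(m, pop) {
  idx <- which(m$pops == pop)
  if (length(idx) == 0) stop("unknown population: ", pop, call. = FALSE)
  idx
}

#' Within-population diversity statistics
#'
#' Per-locus state frequencies (f1, f2) under the chosen model give, per
#' locus: Na = number of states with f > 0; Ne = 1 / sum(f^2);
#' I = -sum(f ln f); He = 1 - sum(f^2); uHe = He * 2N / (2N - 1). Reported
#' values are unweighted means over all loci (monomorphic loci included);
#' `pctP` is the percentage of loci with 0 < p < 1 within the population;
#' `hprime` is the mean He recomputed under the `dominant_hwe` model (the
#' POPGene-style Nei gene diversity for dominant data).
#'
#' @param m a [marker_matrix].
#' @param pop population name.
#' @param model frequency model for the main columns; see [locus_state_freqs()].
#' @param estimator passed to [locus_state_freqs()] for `dominant_hwe`.
#' @return one-row data.frame: pop, N, Na, Ne, I, He, uHe, hprime, pctP.
#' @export
pop_diversity <- function(m, pop, model = c("band_state", "dominant_hwe"),
                          estimator = c("sqrt", "lynch_milligan")) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  idx <- pop_indices(m, pop)
  N <- length(idx)
  if (N < 2) stop("population '", pop, "' has fewer than 2 samples", call. = FALSE)
  sub <- m$bands[idx, , drop = FALSE]
  p <- colMeans(sub, na.rm = TRUE)
  p <- p[!is.na(p)]
  f <- locus_state_freqs(p, model, estimator, n = N)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  sumsq <- f[, 1]^2 + f[, 2]^2
  He <- 1 - sumsq
  fh <- locus_state_freqs(p, "dominant_hwe", estimator, n = N)
  data.frame(
    pop = pop, N = N,
    Na = mean((f[, 1] > 0) + (f[, 2] > 0)),
    Ne = mean(1 / sumsq),
    I = mean(-(xlx(f[, 1]) + xlx(f[, 2]))),
    He = mean(He),
    uHe = mean(He) * 2 * N / (2 * N - 1),
    hprime = mean(1 - fh[, 1]^2 - fh[, 2]^2),
    pctP = 100 * mean(p > 0 & p < 1),
    stringsAsFactors = FALSE
  )
}

#' Diversity table over all populations
#'
#' One [pop_diversity()] row per population (order of first appearance) plus
#' a `"Mean"` row of unweighted across-population means.
#'
#' @inheritParams pop_diversity
#' @export
diversity_table <- function(m, model = c("band_state", "dominant_hwe"),
                            estimator = c("sqrt", "lynch_milligan")) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  rows <- do.call(rbind, lapply(unique(m$pops), function(pp)
    pop_diversity(m, pp, model, estimator)))
  mean_row <- data.frame(pop = "Mean", t(colMeans(rows[-1])),
                         stringsAsFactors = FALSE)
  out <- rbind(rows, mean_row)
  attr(out, "model") <- model
  out
}
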