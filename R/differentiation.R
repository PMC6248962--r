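#' Nei diversity partitioning with Hedrick and Jost corrections
#'
#' Per locus, the within-population gene diversity is h_k = 1 - sum(f^2) from
#' the model's state frequencies in population k; HS is the unweighted mean
#' over populations then loci, and HT = 1 - sum(fbar^2) with fbar the
#' unweighted mean of per-population state frequencies, averaged over loci
#' (the POPGene equal-weights convention; `weighted = TRUE` weights
#' populations by sample size instead). Then
#' GST = (HT - HS) / HT, Hedrick's G'ST = GST (K - 1 + HS) / ((K - 1)(1 - HS))
#' and Jost's D = ((HT - HS) / (1 - HS)) * K / (K - 1).
#'
#' @param m a [marker_matrix].
#' @param model frequency model; see [locus_state_freqs()].
#' @param estimator passed to [locus_state_freqs()].
#' @param weighted weight populations by sample size in HS/HT.
#' @return data.frame with HT, HS, GST, GprimeST, D_jost, K and the model.
#' @export
diversity_partition <- function(m, model = c("band_state", "dominant_hwe"),
                                estimator = c("sqrt", "lynch_milligan"),
                                weighted = FALSE) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  pops <- unique(m$pops)
  K <- length(pops)
  if (K < 2) stop("need at least 2 populations", call. = FALSE)
  bf <- band_frequencies(m, "per_population")
  w <- if (weighted) as.numeric(table(m$pops)[pops]) else rep(1, K)
  w <- w / sum(w)
  L <- n_loci(m)
  f1 <- matrix(NA_real_, K, L)  # band/dominant state frequency per pop x locus
  for (k in seq_len(K)) {
    nk <- bf$n_scored[pops[k], ]
    f1[k, ] <- locus_state_freqs(bf$freq[pops[k], ], model, estimator,
                                 n = stats::median(nk))[, 1]
  }
  h_k <- 2 * f1 * (1 - f1)              # 1 - f1^2 - (1-f1)^2
  HS_l <- colSums(w * h_k)
  fbar <- colSums(w * f1)
  HT_l <- 2 * fbar * (1 - fbar)
  HS <- mean(HS_l)
  HT <- mean(HT_l)
  if (HT <= 0) stop("HT = 0: all loci monomorphic, GST undefined", call. = FALSE)
  GST <- (HT - HS) / HT
  GprimeST <- GST * (K - 1 + HS) / ((K - 1) * (1 - HS))
  D_jost <- ((HT - HS) / (1 - HS)) * K / (K - 1)
  data.frame(HT = HT, HS = HS, GST = GST, GprimeST = GprimeST,
             D_jost = D_jost, K = K, model = model, stringsAsFactors = FALSE)
}

#' Island-model gene-flow estimate
#'
#' NM = (1/FST - 1) / 4, the equilibrium number of migrants per generation
#' under Wright's island model.
#'
#' @param fst fixation index in (0, 1\]; values <= 0 give `NA` with a warning.
#' @export
gene_flow <- function(fst) {
  out <- ifelse(!is.na(fst) & fst > 0, (1 / fst - 1) / 4, NA_real_)
  if (any(!is.na(fst) & fst <= 0))
    warning("gene flow undefined for fst <= 0; returning NA")
  out
}

#' Nei (1972) standard genetic distance between two populations
#'
#' I = sum over loci of sum(x_s y_s) / sqrt(sum over loci of sum(x^2) *
#' sum over loci of sum(y^2)) on the model's state frequencies;
#' Ds = -ln I. Identical frequency profiles give 0.
#'
#' @param m a [marker_matrix].
#' @param popA,popB population names.
#' @param model,estimator see [locus_state_freqs()].
#' @export
nei_distance <- function(m, popA, popB, model = c("band_state", "dominant_hwe"),
                         estimator = c("sqrt", "lynch_milligan")) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  bf <- band_frequencies(m, "per_population")
  for (pp in c(popA, popB))
    if (!pp %in% rownames(bf$freq)) stop("unknown population: ", pp, call. = FALSE)
  fx <- locus_state_freqs(bf$freq[popA, ], model, estimator,
                          n = stats::median(bf$n_scored[popA, ]))
  fy <- locus_state_freqs(bf$freq[popB, ], model, estimator,
                          n = stats::median(bf$n_scored[popB, ]))
  jxy <- sum(fx * fy)
  jx <- sum(fx^2)
  jy <- sum(fy^2)
  I <- jxy / sqrt(jx * jy)
  if (I <= 0) {
    warning("zero identity between '", popA, "' and '", popB,
            "': distance undefined")
    return(NA_real_)
  }
  -log(I)
}

#' Matrix of Nei distances over all population pairs
#'
#' @inheritParams nei_distance
#' @export
nei_distance_matrix <- function(m, model = c("band_state", "dominant_hwe"),
                                estimator = c("sqrt", "lynch_milligan")) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  pops <- unique(m$pops)
  K <- length(pops)
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  for (a in seq_len(K - 1)) for (b in seq(a + 1, K))
    out[a, b] <- out[b, a] <- nei_distance(m, pops[a], pops[b], model, estimator)
  out
}

#' Slatkin's linearized fixation index
#'
#' Elementwise FST / (1 - FST); entries equal to 1 map to `NA`.
#'
#' @param fst_matrix matrix (or scalar) of pairwise fixation indices, each < 1.
#' @export
slatkin_linearized <- function(fst_matrix) {
  out <- ifelse(!is.na(fst_matrix) & fst_matrix < 1,
                fst_matrix / (1 - fst_matrix), NA_real_)
  if (is.matrix(fst_matrix)) {
    dimnames(out) <- dimnames(fst_matrix)
    diag(out) <- 0
  }
  out
}

#' Combine two distance matrices into a lower/upper-triangle table
#'
#' The conventional joint report: `lower` below the diagonal (e.g. Nei Ds),
#' `upper` above (e.g. pairwise FST), diagonal `NA`.
#'
#' @param lower,upper K x K matrices with matching labels.
#' @export
combined_triangle <- function(lower, upper) {
  stopifnot(identical(dim(lower), dim(upper)))
  out <- lower
  out[upper.tri(out)] <- upper[upper.tri(upper)]
  diag(out) <- NA_real_
  out
}
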