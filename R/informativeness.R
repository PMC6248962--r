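#' Polymorphic information content of a two-state band locus
#'
#' PIC = 1 - sum(p_i^2) over the two phenotype classes (band present with
#' frequency p, absent with 1 - p), i.e. 2p(1 - p); maximum 0.5 at p = 0.5.
#'
#' @param p band frequency (vectorised), each in \[0, 1\].
#' @return PIC value(s) in \[0, 0.5\].
#' @export
pic_locus <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("band frequency must lie in [0, 1]", call. = FALSE)
  2 * p * (1 - p)
}

#' Band informativeness
#'
#' Ib = 1 - 2|0.5 - p|: 1 for a band present in half the individuals, 0 for a
#' fixed or absent band.
#'
#' @inheritParams pic_locus
#' @export
band_informativeness <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("band frequency must lie in [0, 1]", call. = FALSE)
  1 - 2 * abs(0.5 - p)
}

#' Shannon index of a two-state band locus
#'
#' H = -(p ln p + (1-p) ln(1-p)) with 0 ln 0 := 0 (natural logarithm).
#'
#' @inheritParams pic_locus
#' @export
shannon_locus <- function(p) {
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  -(xlx(p) + xlx(1 - p))
}

primer_loci <- function(m, primer) {
  loci <- names(m$primers)[m$primers == primer]
  if (length(loci) == 0) stop("unknown primer: ", primer, call. = FALSE)
  loci
}

#' Resolving power of a primer
#'
#' RP = sum of band informativeness Ib over all the primer's scored bands.
#'
#' @param m a [marker_matrix].
#' @param primer primer name.
#' @export
resolving_power <- function(m, primer) {
  p <- band_frequencies(m, "pooled")$freq[1, primer_loci(m, primer)]
  sum(band_informativeness(p))
}

#' Marker index and mean resolving power
#'
#' MI = PIC x EMR with the effective multiplex ratio taken as the primer's
#' polymorphic-band count; MRP = RP / PB. Both are undefined (`NA`) when
#' PB = 0.
#'
#' @param pic primer-mean PIC.
#' @param pb polymorphic-band count.
#' @param rp resolving power.
#' @export
marker_index <- function(pic, pb) ifelse(pb > 0, pic * pb, NA_real_)

#' @rdname marker_index
#' @export
mean_resolving_power <- function(rp, pb) ifelse(pb > 0, rp / pb, NA_real_)

#' Mean Shannon index over a primer's bands
#'
#' @inheritParams resolving_power
#' @export
shannon_primer <- function(m, primer) {
  p <- band_frequencies(m, "pooled")$freq[1, primer_loci(m, primer)]
  mean(shannon_locus(p))
}

#' Per-primer informativeness table
#'
#' One row per primer with SB, PB, PPB, PIC (unweighted mean of per-locus
#' two-state PIC over all scored bands), RP, MRP, MI and H' (mean per-locus
#' Shannon index), plus an `"Average"` row of column means. Pearson
#' correlations between the MI~PIC and PIC~RP columns (r, r squared, and the
#' two-sided p-value from [stats::cor.test]) are attached when at least three
#' primers are present and neither column is constant.
#'
#' @param m a [marker_matrix].
#' @param poly_criterion passed to [classify_loci()].
#' @return data.frame with attribute `correlations` (named list with entries
#'   `MI_PIC` and `PIC_RP`, each `list(r, r2, p)`, or `NULL` entries when not
#'   estimable).
#' @export
primer_table <- function(m, poly_criterion = 1) {
  cls <- classify_loci(m, poly_criterion)
  p <- band_frequencies(m, "pooled")$freq[1, ]
  primers <- unique(m$primers)
  rows <- lapply(primers, function(pr) {
    loci <- primer_loci(m, pr)
    pb <- sum(cls$polymorphic[loci])
    pic <- mean(pic_locus(p[loci]))
    rp <- sum(band_informativeness(p[loci]))
    data.frame(primer = pr, SB = length(loci), PB = pb,
               PPB = 100 * pb / length(loci), PIC = pic, RP = rp,
               MRP = mean_resolving_power(rp, pb), MI = marker_index(pic, pb),
               Hp = mean(shannon_locus(p[loci])), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(primer = "Average", t(colMeans(tab[-1], na.rm = TRUE)),
                    stringsAsFactors = FALSE)
  out <- rbind(tab, avg)
  attr(out, "correlations") <- list(
    MI_PIC = column_correlation(tab$MI, tab$PIC),
    PIC_RP = column_correlation(tab$PIC, tab$RP)
  )
  out
}

column_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2, p = ct$p.value)
}
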