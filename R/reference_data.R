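#' Published reference tables from a Kuwaiti *Haloxylon salicornicum* survey
#'
#' Small plain-text tables bundled with the package for worked examples and
#' validation: summary statistics from a published ISSR survey of the desert
#' shrub *Haloxylon salicornicum* (Rimth) sampled in six locations across
#' Kuwait (108 plants, 195 band loci from 16 primers).
#'
#' * `hsal_pairwise_fst()` — 6 x 6 matrix of pairwise fixation indices
#'   between the populations (Arlequin-style pairwise FST).
#' * `hsal_nei_distance()` — 6 x 6 matrix of pairwise Nei genetic distances.
#' * `hsal_primer_stats()` — per-primer informativeness summary (SB, PB,
#'   PPB, PIC, RP, MRP, MI, H') for the 16 ISSR primers.
#'
#' @return a labelled numeric matrix (`hsal_pairwise_fst`,
#'   `hsal_nei_distance`) or a data.frame (`hsal_primer_stats`).
#' @name reference_data
NULL

read_hsal_matrix <- function(file) {
  tab <- utils::read.delim(system.file("extdata", file, package = "dompopgen"),
                           check.names = FALSE)
  out <- as.matrix(tab[, -1])
  rownames(out) <- tab[[1]]
  out
}

#' @rdname reference_data
#' @export
hsal_pairwise_fst <- function() read_hsal_matrix("haloxylon_pairwise_fst.tsv")

#' @rdname reference_data
#' @export
hsal_nei_distance <- function() read_hsal_matrix("haloxylon_nei_distance.tsv")

#' @rdname reference_data
#' @export
hsal_primer_stats <- function() {
  utils::read.delim(system.file("extdata", "haloxylon_primer_stats.tsv",
                                package = "dompopgen"), check.names = FALSE)
}
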