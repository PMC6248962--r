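#' Construct a dominant-marker band matrix
#'
#' `marker_matrix` is the package's single input currency: a samples x loci
#' binary (1/0) band-presence matrix with a population label per sample and a
#' primer assignment per locus. Missing scores are allowed as `NA` but are
#' absent by default in typical gel-scored data.
#'
#' @param bands integer/numeric matrix of 0/1/`NA`, samples in rows, loci in
#'   columns. Row names are taken as sample ids, column names as locus ids;
#'   defaults (`S1..Sn`, `L1..Lm`) are supplied when absent.
#' @param pops character vector of population labels, one per sample.
#' @param primers character vector mapping each locus to a primer name, one
#'   per locus. Defaults to a single primer `"P1"`.
#' @return An object of class `marker_matrix`: a list with elements `bands`
#'   (integer matrix with dimnames), `pops` (named character) and `primers`
#'   (named character, names = locus ids).
#' @examples
#' m <- marker_matrix(rbind(c(1, 0), c(1, 1)), pops = c("A", "A"))
#' n_samples(m)
#' @export
marker_matrix <- function(bands, pops, primers = NULL) {
  bands <- as.matrix(bands)
  if (is.null(rownames(bands))) rownames(bands) <- paste0("S", seq_len(nrow(bands)))
  if (is.null(colnames(bands))) colnames(bands) <- paste0("L", seq_len(ncol(bands)))
  if (is.null(primers)) primers <- rep("P1", ncol(bands))
  storage.mode(bands) <- "integer"
  pops <- as.character(pops)
  primers <- as.character(primers)
  if (length(pops) != nrow(bands))
    stop("need one population label per sample", call. = FALSE)
  if (length(primers) != ncol(bands))
    stop("every locus must map to exactly one primer", call. = FALSE)
  names(pops) <- rownames(bands)
  if (is.null(names(primers))) names(primers) <- colnames(bands)
  m <- structure(list(bands = bands, pops = pops, primers = primers),
                 class = "marker_matrix")
  validate_marker_matrix(m)
  m
}

validate_marker_matrix <- function(m) {
  bands <- m$bands
  bad <- matrix(!is.na(bands) & !(bands %in% c(0L, 1L)), nrow = nrow(bands))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary band value at sample '%s', locus '%s'",
                 rownames(bands)[idx[1]], colnames(bands)[idx[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(bands)))
    stop("duplicate sample id: ", rownames(bands)[duplicated(rownames(bands))][1],
         call. = FALSE)
  if (anyDuplicated(colnames(bands)))
    stop("duplicate locus id: ", colnames(bands)[duplicated(colnames(bands))][1],
         call. = FALSE)
  if (length(m$pops) != nrow(bands))
    stop("need one population label per sample", call. = FALSE)
  if (length(m$primers) != ncol(bands))
    stop("every locus must map to exactly one primer", call. = FALSE)
  if (!setequal(names(m$primers), colnames(bands)))
    stop("primer map names do not match locus ids", call. = FALSE)
  invisible(m)
}

#' @rdname marker_matrix
#' @param m a `marker_matrix`.
#' @export
n_samples <- function(m) nrow(m$bands)

#' @rdname marker_matrix
#' @export
n_loci <- function(m) ncol(m$bands)

#' @rdname marker_matrix
#' @export
pop_sizes <- function(m) table(m$pops)[unique(m$pops)]

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d samples x %d loci, %d populations, %d primers\n",
              nrow(x$bands), ncol(x$bands), length(unique(x$pops)),
              length(unique(x$primers))))
  if (anyNA(x$bands))
    cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$bands)),
                100 * mean(is.na(x$bands))))
  invisible(x)
}

#' Read a binary band matrix from disk
#'
#' Two dialects are supported. `plain_tsv` is a tab-separated table whose
#' first row is `sample<TAB>pop<TAB><locus ids...>`, optionally followed by a
#' `#primer` comment row giving a primer name under each locus column; `NA`
#' marks a missing score. `genalex_csv` is the GenAlEx binary-CSV layout: row
#' 1 holds `n_loci, n_samples, n_pops, size_1, ..., size_K`, row 2 a title
#' followed (from column 4) by population names, row 3 the column header, then
#' one row per sample. The GenAlEx metadata row is cross-checked against the
#' parsed content.
#'
#' @param path file path.
#' @param dialect `"plain_tsv"` or `"genalex_csv"`.
#' @return a validated [marker_matrix].
#' @seealso [write_marker_matrix()], [write_structure()]
#' @export
read_marker_matrix <- function(path, dialect = c("plain_tsv", "genalex_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "plain_tsv") read_plain_tsv(path) else read_genalex_csv(path)
}

read_plain_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || header[1] != "sample" || header[2] != "pop")
    stop("plain TSV header must start with 'sample\\tpop'", call. = FALSE)
  loci <- header[-(1:2)]
  body <- lines[-1]
  primers <- NULL
  is_primer <- startsWith(body, "#primer")
  if (any(is_primer)) {
    prow <- strsplit(body[is_primer][1], "\t", fixed = TRUE)[[1]]
    primers <- prow[-(1:2)]
    if (length(primers) != length(loci))
      stop("#primer row must name a primer for every locus", call. = FALSE)
  }
  body <- body[!startsWith(body, "#")]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header)))
    stop(sprintf("row %d has %d fields, expected %d",
                 which(nf != length(header))[1] + 1,
                 nf[nf != length(header)][1], length(header)), call. = FALSE)
  tab <- do.call(rbind, fields)
  samples <- tab[, 1]
  pops <- tab[, 2]
  cells <- tab[, -(1:2), drop = FALSE]
  bad <- matrix(!(cells %in% c("0", "1", "NA")), nrow = nrow(cells))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell value '%s' at sample '%s', locus '%s'",
                 cells[idx[1], idx[2]], samples[idx[1]], loci[idx[2]]),
         call. = FALSE)
  }
  bands <- matrix(suppressWarnings(as.integer(cells)), nrow = nrow(cells),
                  dimnames = list(samples, loci))
  marker_matrix(bands, pops, primers)
}

read_genalex_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  meta <- suppressWarnings(as.integer(split_csv(lines[[1]])))
  if (length(meta) < 3 || anyNA(meta[1:3]))
    stop("GenAlEx metadata row must give n_loci, n_samples, n_pops", call. = FALSE)
  n_loci_m <- meta[1]; n_samp_m <- meta[2]; n_pop_m <- meta[3]
  sizes_m <- meta[seq(4, length.out = n_pop_m)]
  header <- split_csv(lines[[3]])
  loci <- header[-(1:2)]
  loci <- loci[nzchar(loci)]
  body <- lines[-(1:3)]
  body <- body[nzchar(gsub(",", "", body))]
  fields <- lapply(body, split_csv)
  samples <- vapply(fields, `[`, "", 1)
  pops <- vapply(fields, `[`, "", 2)
  cells <- do.call(rbind, lapply(fields, function(f) f[2 + seq_along(loci)]))
  bad <- matrix(!(cells %in% c("0", "1", "-1", "NA", "")), nrow = nrow(cells))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-binary cell value '%s' at sample '%s', locus '%s'",
                 cells[idx[1], idx[2]], samples[idx[1]], loci[idx[2]]),
         call. = FALSE)
  }
  cells[cells %in% c("-1", "")] <- NA_character_
  bands <- matrix(suppressWarnings(as.integer(cells)), nrow = nrow(cells),
                  dimnames = list(samples, loci))
  m <- marker_matrix(bands, pops)
  if (n_loci_m != n_loci(m) || n_samp_m != n_samples(m) ||
      n_pop_m != length(unique(pops)) ||
      !identical(as.integer(sizes_m), as.integer(unname(pop_sizes(m)))))
    stop("GenAlEx metadata row disagrees with parsed content", call. = FALSE)
  m
}

#' Write a band matrix to disk
#'
#' @inheritParams read_marker_matrix
#' @param m a [marker_matrix].
#' @param title title string stored in the GenAlEx second header row.
#' @return `path`, invisibly.
#' @export
write_marker_matrix <- function(m, path, dialect = c("plain_tsv", "genalex_csv"),
                                title = "dompopgen export") {
  dialect <- match.arg(dialect)
  bands <- m$bands
  if (dialect == "plain_tsv") {
    cells <- ifelse(is.na(bands), "NA", as.character(bands))
    lines <- c(
      paste(c("sample", "pop", colnames(bands)), collapse = "\t"),
      paste(c("#primer", "", unname(m$primers)), collapse = "\t"),
      vapply(seq_len(nrow(bands)), function(i)
        paste(c(rownames(bands)[i], m$pops[i], cells[i, ]), collapse = "\t"), "")
    )
  } else {
    sizes <- pop_sizes(m)
    cells <- ifelse(is.na(bands), "-1", as.character(bands))
    lines <- c(
      paste(c(ncol(bands), nrow(bands), length(sizes), unname(sizes)), collapse = ","),
      paste(c(title, "", "", names(sizes)), collapse = ","),
      paste(c("sample", "pop", colnames(bands)), collapse = ","),
      vapply(seq_len(nrow(bands)), function(i)
        paste(c(rownames(bands)[i], m$pops[i], cells[i, ]), collapse = ","), "")
    )
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a STRUCTURE input file (one row per haploid individual)
#'
#' Bands are coded as haploid observations; missing scores are written as -9.
#' Populations are coded as integers in order of first appearance.
#'
#' @param m a [marker_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(m, path) {
  bands <- m$bands
  popcode <- match(m$pops, unique(m$pops))
  cells <- ifelse(is.na(bands), "-9", as.character(bands))
  lines <- c(paste(colnames(bands), collapse = "\t"),
             vapply(seq_len(nrow(bands)), function(i)
               paste(c(rownames(bands)[i], popcode[i], cells[i, ]), collapse = "\t"), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Band frequencies per population or pooled
#'
#' The band frequency p at a locus is the fraction of non-missing samples in
#' the scope that carry the band. Cells with no scored sample are `NA`.
#'
#' @param m a [marker_matrix].
#' @param scope `"pooled"` (one row) or `"per_population"` (one row per
#'   population, in order of first appearance).
#' @return object of class `band_freq_table`: list with `freq` and `n_scored`
#'   matrices (groups x loci).
#' @export
band_frequencies <- function(m, scope = c("pooled", "per_population")) {
  scope <- match.arg(scope)
  groups <- if (scope == "pooled") list(pooled = seq_len(n_samples(m)))
            else split(seq_len(n_samples(m)), factor(m$pops, levels = unique(m$pops)))
  if (any(lengths(groups) == 0))
    stop("empty group: ", names(groups)[lengths(groups) == 0][1], call. = FALSE)
  freq <- do.call(rbind, lapply(groups, function(idx)
    colMeans(m$bands[idx, , drop = FALSE], na.rm = TRUE)))
  nsc <- do.call(rbind, lapply(groups, function(idx)
    colSums(!is.na(m$bands[idx, , drop = FALSE]))))
  freq[nsc == 0] <- NA_real_
  dimnames(freq) <- dimnames(nsc) <- list(names(groups), colnames(m$bands))
  structure(list(freq = freq, n_scored = nsc), class = "band_freq_table")
}

#' Classify loci as polymorphic and tally per-primer band counts
#'
#' A locus is polymorphic iff its pooled band frequency p satisfies
#' 0 < p < 1 (strict criterion, the default). With `poly_criterion < 1`
#' (e.g. 0.95) the frequency of the commoner band state must not exceed the
#' criterion.
#'
#' @param m a [marker_matrix].
#' @param poly_criterion 1 for the strict criterion, or a threshold in (0.5, 1)
#'   for the commoner-state frequency.
#' @return list with `polymorphic` (named logical per locus), `SB`, `PB`,
#'   `PPB` (totals) and `per_primer` (data.frame: primer, SB, PB, PPB).
#' @export
classify_loci <- function(m, poly_criterion = 1) {
  p <- band_frequencies(m, "pooled")$freq[1, ]
  poly <- if (poly_criterion >= 1) p > 0 & p < 1 else pmax(p, 1 - p) <= poly_criterion
  poly[is.na(poly)] <- FALSE
  primer <- factor(m$primers[colnames(m$bands)], levels = unique(m$primers))
  per <- data.frame(
    primer = levels(primer),
    SB = as.integer(table(primer)),
    PB = as.integer(tapply(poly, primer, sum)),
    stringsAsFactors = FALSE
  )
  per$PPB <- 100 * per$PB / per$SB
  list(polymorphic = poly, SB = n_loci(m), PB = sum(poly),
       PPB = 100 * sum(poly) / n_loci(m), per_primer = per)
}
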