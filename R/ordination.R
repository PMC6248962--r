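#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering B = -1/2 J A J with J = I - 11'/n, followed by an
#' eigendecomposition; coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues, and each axis's percent of variation is
#' its eigenvalue's share of the positive-eigenvalue total.
#'
#' Two centering dialects are implemented because software conventions for
#' distance-like (not guaranteed Euclidean) inputs differ:
#' `"gower_squared"` sets A = D*D elementwise (the classical
#' Torgerson/Gower PCoA of the distances, as in [stats::cmdscale]);
#' `"gower_raw"` centers the matrix entries directly, A = D — the convention
#' GenAlEx-style population ordinations apply to fixation-index matrices.
#'
#' @param d symmetric matrix with zero diagonal, K >= 3.
#' @param dialect `"gower_squared"` (default) or `"gower_raw"`.
#' @return object of class `pcoa_result`: list with `coordinates`
#'   (K x n_positive_axes), `eigenvalues` (all K, decreasing), `percent`
#'   (share of positive-eigenvalue total per positive axis) and `dialect`.
#' @export
pcoa <- function(d, dialect = c("gower_squared", "gower_raw")) {
  dialect <- match.arg(dialect)
  d <- as.matrix(d)
  K <- nrow(d)
  if (K < 3) stop("need at least 3 points", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("input must be symmetric with zero diagonal", call. = FALSE)
  A <- if (dialect == "gower_squared") d * d else d
  J <- diag(K) - matrix(1 / K, K, K)
  B <- -0.5 * J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 percent = 100 * e$values[pos] / sum(e$values[pos]),
                 dialect = dialect),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA (%s): %d positive axes\n", x$dialect, ncol(x$coordinates)))
  cat("percent of variation:", paste(sprintf("%.2f", x$percent), collapse = " "), "\n")
  invisible(x)
}

#' Great-circle distances between population centroids
#'
#' Each population's centroid is the arithmetic mean of its samples' latitude
#' and longitude (WGS84 decimal degrees, no projection); distances are
#' haversine great-circle distances in km (Earth radius 6371.0088 km).
#'
#' @param geo data.frame with columns `sample`, `lat`, `lon`.
#' @param pops named character vector of population labels (names = sample
#'   ids), e.g. the `pops` element of a [marker_matrix].
#' @return K x K symmetric matrix of distances in km.
#' @export
geographic_distance <- function(geo, pops) {
  stopifnot(all(c("sample", "lat", "lon") %in% names(geo)))
  pop_of <- pops[match(geo$sample, names(pops))]
  if (anyNA(pop_of))
    stop("GPS table contains samples absent from the marker matrix", call. = FALSE)
  levels <- unique(pops)
  missing_pop <- setdiff(levels, unique(pop_of))
  if (length(missing_pop))
    stop("no coordinates for population: ", missing_pop[1], call. = FALSE)
  cen <- t(vapply(levels, function(pp) {
    sel <- pop_of == pp
    c(lon = mean(geo$lon[sel]), lat = mean(geo$lat[sel]))
  }, numeric(2)))
  K <- length(levels)
  out <- matrix(0, K, K, dimnames = list(levels, levels))
  for (a in seq_len(K - 1)) for (b in seq(a + 1, K))
    out[a, b] <- out[b, a] <-
      geosphere::distHaversine(cen[a, ], cen[b, ], r = 6371008.8) / 1000
  out
}

#' Mantel test of correlation between two distance matrices
#'
#' r is the Pearson correlation of the vectorized upper triangles; p is the
#' one-tailed (upper) probability from jointly permuting rows and columns of
#' `dy`, with the observed statistic included in the tail.
#'
#' @param dx,dy symmetric matrices with matching labels.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return object of class `mantel_result`: list with `r`, `r2`, `p`,
#'   `n_perm`, `seed`.
#' @export
mantel <- function(dx, dy, n_perm = 10000, seed = NULL) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  stopifnot(identical(dim(dx), dim(dy)))
  if (!is.null(rownames(dx)) && !is.null(rownames(dy)) &&
      !identical(rownames(dx), rownames(dy)))
    stop("matrix labels do not match", call. = FALSE)
  K <- nrow(dx)
  if (K < 4) warning("Mantel test on fewer than 4 units is nearly powerless")
  ut <- upper.tri(dx)
  x <- dx[ut]
  if (stats::sd(x) == 0 || stats::sd(dy[ut]) == 0)
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  r_obs <- stats::cor(x, dy[ut])
  if (!is.null(seed)) set.seed(seed)
  hits <- vapply(seq_len(n_perm), function(i) {
    perm <- sample.int(K)
    stats::cor(x, dy[perm, perm][ut]) >= r_obs
  }, logical(1))
  p <- (sum(hits) + 1) / (n_perm + 1)
  structure(list(r = r_obs, r2 = r_obs^2, p = p, n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (r2 = %.4f), one-tailed P = %.4g (%d permutations)\n",
              x$r, x$r2, x$p, x$n_perm))
  invisible(x)
}
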