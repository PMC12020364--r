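# Alpha diversity, Bray-Curtis distances and principal coordinates.

#' Simpson and Shannon alpha diversity per sample
#'
#' `1 - D = 1 - sum(p_i^2)` and `H = -sum(p_i * ln p_i)` with `p_i` the
#' within-sample proportion of taxon i and `0 * ln 0 = 0`.  Both indices are
#' scale-invariant, so counts and per-mille profiles give identical results.
#'
#' @param x counts or profile matrix (samples x taxa), all row sums > 0.
#' @return data.frame: sample_id, simpson_1mD, shannon_H.
#' @export
alpha_diversity <- function(x) {
  x <- unclass(x)
  if (any(rowSums(x) == 0)) {
    stop("zero-sum sample(s): ",
         paste(rownames(x)[rowSums(x) == 0], collapse = ", "))
  }
  data.frame(sample_id = rownames(x),
             simpson_1mD = vegan::diversity(x, index = "simpson"),
             shannon_H = vegan::diversity(x, index = "shannon"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis distance matrix
#'
#' `BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)`.  A pair of all-zero
#' samples has no defined distance; such pairs are flagged with a warning
#' and returned as `NA`.
#'
#' @param x non-negative matrix (samples x taxa), >= 2 samples.
#' @return symmetric matrix of class `bray_curtis` with zero diagonal.
#' @export
bray_curtis <- function(x) {
  x <- unclass(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (any(x < 0)) stop("abundances must be non-negative")
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (any(!is.finite(d))) warning("all-zero sample pair(s): distance undefined")
  diag(d) <- 0
  class(d) <- c("bray_curtis", "matrix", "array")
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues.  Negative eigenvalues -- expected for non-Euclidean
#' dissimilarities such as Bray-Curtis -- are counted and reported but not
#' corrected or used.
#'
#' @param dm symmetric distance matrix (e.g. [bray_curtis()]).
#' @return list of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all, descending), `prop_explained` (share of positive
#'   eigenvalue mass per retained axis), `n_negative`.
#' @export
pcoa_ordination <- function(dm) {
  dm <- unclass(dm)
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = n - 1, eig = TRUE))
  ev <- fit$eig
  tol <- max(abs(ev)) * 1e-9
  keep <- seq_len(ncol(fit$points))
  keep <- keep[ev[keep] > tol] # cmdscale may retain numerically-zero axes
  coords <- fit$points[, keep, drop = FALSE]
  if (ncol(coords)) colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 prop_explained = ev[keep] / sum(ev[ev > tol]),
                 n_negative = sum(ev < -tol)),
            class = "pcoa_result")
}
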