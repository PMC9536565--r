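#' Representational dissimilarity matrix (RDM)
#'
#' An `rdm` is a square, symmetric, non-negative matrix of pairwise
#' dissimilarities between labeled items, with a zero diagonal. RDMs are the
#' common currency of the package: behavioral pipelines produce them, model
#' conventions produce them, and all comparisons operate on their vectorized
#' lower triangles.
#'
#' @param values square numeric matrix of dissimilarities. Negative entries
#'   are allowed only when `signed = TRUE` (z-scored RT dissimilarities are
#'   stored in negated-z units and may take either sign).
#' @param labels character vector of item identifiers; defaults to the row
#'   names of `values`.
#' @param signed logical; allow negative entries (default `TRUE`, since
#'   behavioral RDMs live on a negated z / negated ms scale).
#' @param tol symmetry tolerance.
#' @return an object of class `rdm`: the matrix with `dimnames` set to the
#'   labels.
#' @examples
#' m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
#' r <- rdm(m, labels = c("a", "b", "c"))
#' lower_triangle(r)
#' @export
rdm <- function(values, labels = rownames(values), signed = TRUE,
                tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("malformed RDM: matrix is not square", call. = FALSE)
  }
  n <- nrow(values)
  if (is.null(labels)) labels <- default_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("malformed RDM: dimension does not equal label count", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("malformed RDM: duplicated labels", call. = FALSE)
  }
  finite <- values[is.finite(values)]
  asym <- abs(values - t(values))
  if (any(asym[is.finite(asym)] > tol)) {
    stop("malformed RDM: asymmetric beyond tolerance", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  if (!signed && any(finite < -tol)) {
    stop("malformed RDM: negative dissimilarities", call. = FALSE)
  }
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("rdm", "matrix", "array"))
}

default_labels <- function(n) {
  if (n <= 26L) letters[seq_len(n)] else paste0("item", seq_len(n))
}

#' @export
#' @method print rdm
print.rdm <- function(x, ...) {
  cat(sprintf("RDM over %d items (%d pairs)\n", nrow(x),
              nrow(x) * (nrow(x) - 1) / 2))
  v <- unclass(x)[lower.tri(x)]
  v <- v[is.finite(v)]
  if (length(v)) {
    cat(sprintf("  dissimilarity range: [%.4g, %.4g]\n", min(v), max(v)))
  }
  cat("  items:", paste(utils::head(rownames(x), 10), collapse = " "),
      if (nrow(x) > 10) "...\n" else "\n")
  invisible(x)
}

#' @export
plot.rdm <- function(x, main = "RDM", ...) {
  n <- nrow(x)
  # flip rows so item 1 plots in the top-left, matrix style
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  axes = FALSE, xlab = "", ylab = "", main = main, ...)
  graphics::axis(1, at = seq_len(n), labels = rownames(x), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(x)), las = 2,
                 cex.axis = 0.6, tick = FALSE)
  invisible(x)
}

#' Canonical pair order for n items
#'
#' Pairs are enumerated row-major over the strict lower triangle:
#' (2,1), (3,1), (3,2), (4,1), ... For lowercase-letter labels this is
#' b-a, c-a, c-b, d-a, ... Serialized pair vectors always use this order,
#' so vectors from different pipelines are comparable entry by entry.
#'
#' @param labels character vector of item labels.
#' @return two-column character matrix (`i`, `j`) with one row per unordered
#'   pair; `i` is the later item, `j` the earlier.
#' @export
canonical_pairs <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2) stop("need at least 2 labels", call. = FALSE)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # row-major
  cbind(i = labels[idx[, 1L]], j = labels[idx[, 2L]])
}

new_pair_vector <- function(entries, pairs) {
  structure(as.numeric(entries), pairs = pairs, class = "pair_vector")
}

#' Vectorize the lower triangle of an RDM
#'
#' @param x an `rdm` (or plain symmetric matrix).
#' @return a `pair_vector`: numeric vector of length n(n-1)/2 in canonical
#'   row-major lower-triangle order, with a `pairs` attribute naming each
#'   unordered pair.
#' @seealso [rdm_from_pairs()] for the inverse.
#' @export
lower_triangle <- function(x) {
  if (!inherits(x, "rdm")) x <- rdm(x)
  labels <- rownames(x)
  m <- unclass(x)
  # t(m)[upper.tri] walks the lower triangle row-major
  new_pair_vector(t(m)[upper.tri(m)], canonical_pairs(labels))
}

#' Rebuild a symmetric RDM from a canonical pair vector
#'
#' @param entries numeric vector of n(n-1)/2 dissimilarities in canonical
#'   order (or a `pair_vector`).
#' @param labels item labels; recovered from the `pairs` attribute when
#'   `entries` is a `pair_vector`.
#' @return an `rdm`.
#' @export
rdm_from_pairs <- function(entries, labels = NULL) {
  if (inherits(entries, "pair_vector") && is.null(labels)) {
    labels <- unique(as.vector(t(attr(entries, "pairs")[, 2:1])))
    labels <- labels[!duplicated(labels)]
  }
  entries <- as.numeric(entries)
  if (is.null(labels)) {
    n <- (1 + sqrt(1 + 8 * length(entries))) / 2
    if (n != round(n)) stop("entry count is not n(n-1)/2", call. = FALSE)
    labels <- default_labels(as.integer(n))
  }
  n <- length(labels)
  if (length(entries) != n * (n - 1) / 2) {
    stop("entry count does not match label count", call. = FALSE)
  }
  m <- matrix(0, n, n)
  tm <- t(m)
  tm[upper.tri(tm)] <- entries
  m <- t(tm)
  m <- m + t(m)
  rdm(m, labels)
}

#' @export
#' @method print pair_vector
print.pair_vector <- function(x, ...) {
  p <- attr(x, "pairs")
  cat(sprintf("pair_vector: %d unordered pairs\n", length(x)))
  k <- min(6L, length(x))
  cat(paste0("  ", p[seq_len(k), 1L], "-", p[seq_len(k), 2L], " = ",
             signif(x[seq_len(k)], 4), collapse = "\n"), "\n")
  if (length(x) > k) cat("  ...\n")
  invisible(x)
}

#' Spearman rank correlation between two pair vectors
#'
#' Ties receive average ranks. Used for every model-behavior and split-half
#' comparison in the package.
#'
#' @param a,b equal-length numeric vectors (or `pair_vector`s) with at least
#'   3 entries.
#' @return the rank correlation in \[-1, 1\], or `NA` (with a warning) when
#'   either input has zero variance and the correlation is undefined.
#' @export
spearman_rdm <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero-variance input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(a), rank(b))
}

#' Spearman-Brown prophecy correction
#'
#' Predicts the reliability of a full sample from the reliability of half
#' the sample: 2 * rho / (1 + rho).
#'
#' @param rho_half split-half correlation(s) in (-1, 1].
#' @return corrected reliability, same length as `rho_half`.
#' @export
spearman_brown <- function(rho_half) {
  rho_half <- as.numeric(rho_half)
  if (any(rho_half[!is.na(rho_half)] <= -1) ||
      any(rho_half[!is.na(rho_half)] > 1)) {
    stop("rho_half must lie in (-1, 1]", call. = FALSE)
  }
  if (any(rho_half[!is.na(rho_half)] < 0)) {
    warning("negative split-half reliability: corrected value is negative")
  }
  2 * rho_half / (1 + rho_half)
}

#' Project an RDM into a low-dimensional configuration (MDS)
#'
#' Metric multidimensional scaling for visualization: classical scaling
#' (`cmdscale`) optionally refined by Sammon stress minimisation. Intended
#' for plots only, never for inference.
#'
#' @param x an `rdm`.
#' @param n_dims number of output dimensions (default 2).
#' @param method `"classical"` (deterministic eigen-decomposition) or
#'   `"sammon"` (stress refinement of the classical start).
#' @param seed unused by the deterministic methods; accepted so callers can
#'   treat all embedding back-ends uniformly.
#' @return matrix of per-item coordinates (items x n_dims), rownames = labels.
#' @export
mds_embed <- function(x, n_dims = 2, method = c("classical", "sammon"),
                      seed = NULL) {
  method <- match.arg(method)
  if (!inherits(x, "rdm")) x <- rdm(x)
  if (n_dims < 1) stop("n_dims must be >= 1", call. = FALSE)
  d <- unclass(x)
  if (all(d == 0)) stop("degenerate all-zero RDM: no embedding", call. = FALSE)
  # classical scaling tolerates signed RDMs after shifting to non-negative
  off <- min(d[lower.tri(d)])
  if (off < 0) {
    d <- d - off
    diag(d) <- 0
  }
  cfg <- stats::cmdscale(stats::as.dist(d), k = n_dims)
  if (ncol(cfg) < n_dims) {
    cfg <- cbind(cfg, matrix(0, nrow(cfg), n_dims - ncol(cfg)))
  }
  if (method == "sammon" && nrow(d) > n_dims + 1) {
    fit <- MASS::sammon(stats::as.dist(d), y = jitter_degenerate(cfg),
                        k = n_dims, trace = FALSE)
    cfg <- fit$points
  }
  rownames(cfg) <- rownames(x)
  cfg
}

# sammon() rejects configurations with duplicated points (exactly
# equidistant items collapse under cmdscale); nudge deterministically.
jitter_degenerate <- function(cfg) {
  if (!anyDuplicated(round(cfg, 10))) return(cfg)
  cfg + 1e-6 * sin(seq_along(cfg))
}

#' Configuration stress against an RDM
#'
#' Kruskal raw stress of a coordinate configuration relative to target
#' dissimilarities; used to sanity-check embeddings.
#'
#' @param coords item x dim coordinate matrix.
#' @param x target `rdm`.
#' @return normalized stress (sqrt(sum((d - dhat)^2) / sum(d^2))).
#' @export
mds_stress <- function(coords, x) {
  if (!inherits(x, "rdm")) x <- rdm(x)
  d <- as.numeric(lower_triangle(x))
  dhat <- as.numeric(stats::dist(coords))
  # dist() walks column-major; reorder to canonical row-major
  n <- nrow(coords)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- dhat
  m <- m + t(m)
  dhat <- as.numeric(lower_triangle(rdm(m, rownames(x))))
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

#' Read / write RDMs as labeled CSV matrices
#'
#' The on-disk format is a plain CSV with a header row and a leading label
#' column, so RDMs round-trip through spreadsheets and other toolchains.
#'
#' @param x an `rdm`.
#' @param path file path.
#' @return `read_rdm` returns an `rdm`; `write_rdm` returns `path`
#'   invisibly.
#' @export
write_rdm <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rdm(m, labels)
}

#' Write a pair vector as two-column CSV (pair, value)
#'
#' @param x a `pair_vector`.
#' @param path file path.
#' @export
write_pair_vector <- function(x, path) {
  stopifnot(inherits(x, "pair_vector"))
  p <- attr(x, "pairs")
  utils::write.csv(data.frame(pair = paste0(p[, 1L], "-", p[, 2L]),
                              value = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_vector
#' @export
read_pair_vector <- function(path) {
  df <- utils::read.csv(path)
  parts <- do.call(rbind, strsplit(as.character(df$pair), "-", fixed = TRUE))
  new_pair_vector(df$value, cbind(i = parts[, 1L], j = parts[, 2L]))
}
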