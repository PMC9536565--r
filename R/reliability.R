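#' Number of equal-size font splits
#'
#' The font-split noise ceiling enumerates every way of putting `half` of
#' the `n_fonts` fonts into one half of the data; this is the binomial
#' coefficient choose(n_fonts, half) (184,756 for 10 of 20 fonts).
#'
#' @param n_fonts total number of fonts.
#' @param half fonts per half (default `n_fonts / 2`).
#' @return the subset count as a double.
#' @export
count_font_splits <- function(n_fonts, half = n_fonts / 2) {
  if (half > n_fonts || half < 0) stop("half must be in [0, n_fonts]",
                                       call. = FALSE)
  choose(n_fonts, half)
}

#' Font-split noise ceiling for the search experiment
#'
#' Splits the fonts into two equal halves, averages each half's per-font
#' pair vectors into a half-RDM, Spearman-correlates the halves, averages
#' the correlation over all splits (exhaustively by default), and applies
#' the Spearman-Brown correction to predict full-sample reliability.
#' Complementary halves give the same correlation, so enumerating all
#' subsets (rather than unordered partitions) double-counts harmlessly.
#'
#' @param per_font either a named list of `rdm`s (one per font, e.g. from
#'   [per_font_rdms()]) or a numeric matrix with one column per font whose
#'   rows are canonical pair entries.
#' @param n_splits `"exhaustive"` (default; requires an even font count) or
#'   a number of random splits.
#' @param seed seed for sampled splits.
#' @return list: `ceiling` (Spearman-Brown corrected reliability),
#'   `mean_rho` (mean split-half correlation), `rho` (per-split
#'   correlations), `n_splits`.
#' @export
font_splithalf_ceiling <- function(per_font, n_splits = "exhaustive",
                                   seed = 1L) {
  mat <- per_font_matrix(per_font)
  nf <- ncol(mat)
  if (nf < 2) stop("need at least 2 fonts", call. = FALSE)
  exhaustive <- identical(n_splits, "exhaustive")
  if (exhaustive) {
    if (nf %% 2 != 0) {
      stop("exhaustive mode requires an even font count", call. = FALSE)
    }
    subsets <- utils::combn(nf, nf / 2)
  } else {
    rng <- seeded_rng(seed)
    half <- floor(nf / 2)
    subsets <- vapply(seq_len(n_splits),
                      function(i) sort(rng$sample_int(nf, half)),
                      integer(half))
    if (is.null(dim(subsets))) subsets <- matrix(subsets, nrow = half)
  }
  rho <- apply(subsets, 2L, function(s) {
    h1 <- rowMeans(mat[, s, drop = FALSE])
    h2 <- rowMeans(mat[, -s, drop = FALSE])
    suppressWarnings(spearman_rdm(h1, h2))
  })
  mean_rho <- mean(rho, na.rm = TRUE)
  list(ceiling = spearman_brown(mean_rho), mean_rho = mean_rho,
       rho = rho, n_splits = ncol(subsets))
}

per_font_matrix <- function(per_font) {
  if (is.matrix(per_font)) return(per_font)
  if (!is.list(per_font) || !length(per_font)) {
    stop("per_font must be a matrix or list of rdm/pair vectors",
         call. = FALSE)
  }
  cols <- lapply(per_font, function(x) {
    if (inherits(x, "rdm")) as.numeric(lower_triangle(x))
    else as.numeric(x)
  })
  len <- unique(vapply(cols, length, integer(1)))
  if (length(len) != 1) stop("per-font vectors differ in length",
                             call. = FALSE)
  do.call(cbind, cols)
}

#' Measurement-split noise ceiling for the categorization experiment
#'
#' Each ordered pair's retained (condition, HIT) measurements are split
#' into two halves of equal size; each half is turned into an RDM with the
#' full mixed-model pipeline, the halves are Spearman-correlated, the
#' correlation is averaged over `n_splits` random splits, and Spearman-
#' Brown corrected. Pairs with an odd number of measurements drop one
#' measurement at random per split so the halves stay balanced.
#'
#' @param pm pair-means table from [pair_means()].
#' @param n_splits number of random splits (default 20; the statistic is a
#'   mean over splits, so tens of splits already estimate it well).
#' @param seed integer seed.
#' @param alphabet item universe.
#' @param method LME criterion for the per-half fits; `"ML"` by default
#'   for speed inside the split loop.
#' @return list: `ceiling`, `mean_rho`, `rho` (per split), `n_splits`.
#' @export
measurement_splithalf_ceiling <- function(pm, n_splits = 20, seed = 1L,
                                          alphabet = NULL,
                                          method = "ML") {
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(pm$target, pm$presented)))
  }
  cond <- paste0(pm$target, ">", pm$presented)
  counts <- table(cond)
  if (any(counts < 2)) {
    stop("every condition needs >= 2 retained measurements", call. = FALSE)
  }
  rng <- seeded_rng(seed)
  idx_by_cond <- split(seq_len(nrow(pm)), cond)
  ctrl <- lme4::lmerControl(
    check.conv.singular = "ignore", check.conv.grad = "ignore",
    optCtrl = list(xtol_abs = 1e-6, ftol_abs = 1e-6))
  rho <- vapply(seq_len(n_splits), function(s) {
    h1 <- integer(0); h2 <- integer(0)
    for (idx in idx_by_cond) {
      k <- length(idx)
      if (k %% 2 == 1) idx <- idx[-rng$sample_int(k, 1L)]
      perm <- idx[rng$sample(length(idx))]
      half <- length(perm) / 2
      h1 <- c(h1, perm[seq_len(half)])
      h2 <- c(h2, perm[half + seq_len(half)])
    }
    r1 <- fit_lme_rdm(pm[h1, , drop = FALSE], alphabet, method = method,
                      control = ctrl)
    r2 <- fit_lme_rdm(pm[h2, , drop = FALSE], alphabet, method = method,
                      control = ctrl)
    suppressWarnings(spearman_rdm(lower_triangle(r1), lower_triangle(r2)))
  }, numeric(1))
  mean_rho <- mean(rho, na.rm = TRUE)
  list(ceiling = spearman_brown(mean_rho), mean_rho = mean_rho,
       rho = rho, n_splits = n_splits)
}
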