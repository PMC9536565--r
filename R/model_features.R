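#' Activation sets: pooled feature vectors for labeled stimuli
#'
#' An `activation_set` holds one model stage's pooled activations: one row
#' per stimulus image, one column per feature, with per-image letter and
#' font labels. A complete letter-by-font grid is required by the RDM
#' conventions.
#'
#' @param activations numeric matrix, images x features.
#' @param letter,font character vectors of per-image labels.
#' @param stage stage label (e.g. "relu3").
#' @return an `activation_set`.
#' @export
activation_set <- function(activations, letter, font,
                           stage = "stage") {
  activations <- as.matrix(activations)
  if (!all(is.finite(activations))) {
    stop("activations must be finite", call. = FALSE)
  }
  if (nrow(activations) != length(letter) ||
      nrow(activations) != length(font)) {
    stop("label length must match image count", call. = FALSE)
  }
  structure(list(activations = activations,
                 letter = as.character(letter),
                 font = as.character(font),
                 stage = as.character(stage)),
            class = "activation_set")
}

#' @export
#' @method print activation_set
print.activation_set <- function(x, ...) {
  cat(sprintf("activation_set '%s': %d images x %d features (%d letters, %d fonts)\n",
              x$stage, nrow(x$activations), ncol(x$activations),
              length(unique(x$letter)), length(unique(x$font))))
  invisible(x)
}

#' Pool spatial feature maps to one scalar per feature
#'
#' Convolutional activations arrive as per-image stacks of spatial maps;
#' pooling sums each map so every feature contributes a single
#' location-abstracted activation per image (a 13x13 map of ones pools to
#' 169). 1x1 maps pass through unchanged.
#'
#' @param maps either a 4-D array (image x feature x h x w) or a list with
#'   one element per image, each a 3-D array (feature x h x w).
#' @param letter,font,stage labels forwarded to [activation_set()].
#' @return an `activation_set` with one pooled column per feature.
#' @export
pool_feature_maps <- function(maps, letter, font, stage = "stage") {
  if (is.list(maps)) {
    dims <- unique(t(vapply(maps, dim, integer(3))))
    if (nrow(dims) != 1) {
      stop("feature map shapes differ across images", call. = FALSE)
    }
    pooled <- t(vapply(maps, function(m) apply(m, 1L, sum),
                       numeric(dims[1, 1])))
  } else if (is.array(maps) && length(dim(maps)) == 4L) {
    pooled <- apply(maps, c(1L, 2L), sum)
  } else {
    stop("maps must be a 4-D array or list of 3-D arrays", call. = FALSE)
  }
  activation_set(pooled, letter, font, stage)
}

feature_distance <- function(x, metric) {
  switch(metric,
    euclidean = as.matrix(stats::dist(x)),
    correlation = 1 - stats::cor(t(x)),
    cosine = {
      nrm <- sqrt(rowSums(x^2))
      s <- (x %*% t(x)) / outer(nrm, nrm)
      1 - s
    },
    stop("unknown metric: ", metric, call. = FALSE))
}

cross_distance <- function(a, b, metric) {
  # distances between rows of a and rows of b
  switch(metric,
    euclidean = {
      aa <- rowSums(a^2); bb <- rowSums(b^2)
      d2 <- outer(aa, bb, "+") - 2 * a %*% t(b)
      sqrt(pmax(d2, 0))
    },
    correlation = 1 - stats::cor(t(a), t(b)),
    cosine = {
      na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
      1 - (a %*% t(b)) / outer(na, nb)
    },
    stop("unknown metric: ", metric, call. = FALSE))
}

check_complete_grid <- function(acts) {
  tab <- table(acts$letter, acts$font)
  if (any(tab != 1)) {
    stop("activation set is not a complete one-image letter x font grid",
         call. = FALSE)
  }
  invisible(acts)
}

#' Model RDM under the visual-search convention
#'
#' Search compares letters rendered in the *same* font, so distances are
#' computed between all letter pairs within each font and then averaged
#' across fonts (a letters x letters x fonts stack collapsed over fonts).
#'
#' @param acts an `activation_set` with a complete letter x font grid.
#' @param metric `"euclidean"` (default), `"correlation"` or `"cosine"`.
#' @return an `rdm` over letters.
#' @export
search_convention_rdm <- function(acts,
                                  metric = c("euclidean", "correlation",
                                             "cosine")) {
  metric <- match.arg(metric)
  check_complete_grid(acts)
  letters_u <- sort(unique(acts$letter))
  fonts_u <- sort(unique(acts$font))
  n <- length(letters_u)
  acc <- matrix(0, n, n)
  for (f in fonts_u) {
    sel <- acts$font == f
    x <- acts$activations[sel, , drop = FALSE][match(letters_u, acts$letter[sel]), ,
                                               drop = FALSE]
    acc <- acc + feature_distance(x, metric)
  }
  m <- acc / length(fonts_u)
  diag(m) <- 0
  rdm((m + t(m)) / 2, letters_u, signed = FALSE)
}

#' Model RDM under the categorization convention
#'
#' Categorization compares a presented font-specific letter against an
#' internal target template. The template of letter j is its mean
#' activation across fonts; D(i, j) is the mean over fonts of the distance
#' between font-specific exemplars of i and the template of j. The two
#' directions D(i, j) and D(j, i) are averaged into a symmetric RDM,
#' mirroring the direction-averaging of the behavioral pipeline. Exemplar
#' spread makes the raw diagonal D(i, i) positive; it is returned as the
#' `self_dissimilarity` attribute while the RDM diagonal is zero by
#' convention.
#'
#' @inheritParams search_convention_rdm
#' @return an `rdm` over letters with attribute `self_dissimilarity`.
#' @export
categ_convention_rdm <- function(acts,
                                 metric = c("euclidean", "correlation",
                                            "cosine")) {
  metric <- match.arg(metric)
  check_complete_grid(acts)
  letters_u <- sort(unique(acts$letter))
  templates <- do.call(rbind, lapply(letters_u, function(l) {
    colMeans(acts$activations[acts$letter == l, , drop = FALSE])
  }))
  d_exemplar <- cross_distance(acts$activations, templates, metric)
  # D[i, j] = mean over fonts of dist(exemplar of letter i, template j)
  D <- do.call(rbind, lapply(letters_u, function(l) {
    colMeans(d_exemplar[acts$letter == l, , drop = FALSE])
  }))
  sym <- (D + t(D)) / 2
  self <- diag(sym)
  names(self) <- letters_u
  diag(sym) <- 0
  out <- rdm(sym, letters_u, signed = FALSE)
  attr(out, "self_dissimilarity") <- self
  out
}

#' All-pairs RDM over individual images
#'
#' @param acts an `activation_set` (no grid requirement).
#' @param metric distance metric.
#' @return an `rdm` over images, labeled "letter.font" when both labels
#'   are available.
#' @export
image_level_rdm <- function(acts,
                            metric = c("euclidean", "correlation",
                                       "cosine")) {
  metric <- match.arg(metric)
  if (nrow(acts$activations) < 2) stop("need >= 2 images", call. = FALSE)
  m <- feature_distance(acts$activations, metric)
  diag(m) <- 0
  labs <- make.unique(paste(acts$letter, acts$font, sep = "."))
  rdm((m + t(m)) / 2, labs, signed = FALSE)
}

#' Purely categorical image-level RDM
#'
#' Represents each image as a one-hot vector over letter identities:
#' same-letter images are at distance 0, different-letter images at the
#' single cross-category Euclidean distance sqrt(2). Any metric monotone
#' in same/different yields the same rank structure.
#'
#' @param labels per-image letter identities.
#' @param image_names optional image labels.
#' @return an `rdm` over images.
#' @export
categorical_rdm <- function(labels, image_names = NULL) {
  labels <- as.character(labels)
  m <- sqrt(2) * (outer(labels, labels, "!=") * 1)
  if (is.null(image_names)) {
    image_names <- make.unique(labels, sep = "#")
  }
  rdm(m, image_names, signed = FALSE)
}

#' Select letter-preferring features
#'
#' Welch two-sample t-test per feature comparing pooled activations to
#' letter images against activations to object images; a feature is kept
#' when its mean activation to letters exceeds its mean to objects with
#' p < alpha. Under a common null distribution the directional filter
#' keeps about alpha/2 of features.
#'
#' @param letters_acts,objects_acts `activation_set`s (or plain matrices)
#'   sharing the feature dimension; rows are images.
#' @param alpha significance level (default 0.05).
#' @return a `feature_mask`: logical `keep` per feature plus per-feature
#'   `statistic`, `p_value`, group means and a `degenerate` flag for
#'   features with undefined variance in both groups (never selected).
#' @export
select_letter_preferring <- function(letters_acts, objects_acts,
                                     alpha = 0.05) {
  A <- if (inherits(letters_acts, "activation_set")) letters_acts$activations else as.matrix(letters_acts)
  B <- if (inherits(objects_acts, "activation_set")) objects_acts$activations else as.matrix(objects_acts)
  if (ncol(A) != ncol(B)) stop("feature dimensions differ", call. = FALSE)
  if (nrow(A) < 2 || nrow(B) < 2) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  na <- nrow(A); nb <- nrow(B)
  ma <- colMeans(A); mb <- colMeans(B)
  va <- colVars(A); vb <- colVars(B)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  keep <- !degenerate & is.finite(p) & (ma > mb) & (p < alpha)
  structure(list(keep = keep, statistic = tstat, p_value = p,
                 mean_letters = ma, mean_objects = mb,
                 degenerate = degenerate,
                 alpha = alpha,
                 stage = if (inherits(letters_acts, "activation_set"))
                   letters_acts$stage else "stage"),
            class = "feature_mask")
}

colVars <- function(x) {
  n <- nrow(x)
  (colSums(x^2) - n * colMeans(x)^2) / (n - 1)
}

#' @export
#' @method print feature_mask
print.feature_mask <- function(x, ...) {
  cat(sprintf("feature_mask '%s': %d of %d features kept (alpha = %g)\n",
              x$stage, sum(x$keep), length(x$keep), x$alpha))
  invisible(x)
}

#' Size-matched random feature masks
#'
#' Draws `n_samples` random masks, each the size of the letter-preferring
#' mask, without replacement from an eligibility pool (features that
#' responded to letters but were not letter-preferring). Used as the
#' control subspace when evaluating letter-preferring subspaces.
#'
#' @param mask a `feature_mask` from [select_letter_preferring()].
#' @param pool logical vector (or integer indices) of eligible features.
#' @param n_samples number of random masks (default 100).
#' @param seed integer seed; fixed seeds reproduce the identical list.
#' @return list of logical keep-vectors, each with `sum == sum(mask$keep)`.
#' @export
random_matched_masks <- function(mask, pool, n_samples = 100, seed = 1L) {
  k <- sum(mask$keep)
  n_feat <- length(mask$keep)
  if (is.logical(pool)) pool <- which(pool)
  pool <- setdiff(as.integer(pool), which(mask$keep))
  if (length(pool) < k) {
    stop("pool smaller than the mask to match", call. = FALSE)
  }
  rng <- seeded_rng(seed)
  lapply(seq_len(n_samples), function(i) {
    keep <- logical(n_feat)
    keep[pool[rng$sample_int(length(pool), k)]] <- TRUE
    keep
  })
}

#' Apply a feature mask to an activation set
#'
#' @param acts an `activation_set`.
#' @param mask a `feature_mask` or logical keep-vector.
#' @return an `activation_set` restricted to the kept features.
#' @export
mask_activations <- function(acts, mask) {
  keep <- if (inherits(mask, "feature_mask")) mask$keep else as.logical(mask)
  if (!any(keep)) stop("mask keeps no features", call. = FALSE)
  activation_set(acts$activations[, keep, drop = FALSE],
                 acts$letter, acts$font, acts$stage)
}

#' RDM from intuitive letter features
#'
#' Builds a model RDM from hand-coded feature counts (straight lines by
#' orientation, curve openings, intersections, terminations, diacritics,
#' symmetry, closed space - 17 columns) using Euclidean distance in count
#' space. With per-font rows the search or categorization convention
#' applies; with one row per letter the RDM is the plain pairwise
#' distance.
#'
#' @param table data.frame with a `letter` column, an optional `font`
#'   column, and numeric feature-count columns (non-negative).
#' @param convention `"plain"`, `"search"` or `"categ"`.
#' @param metric distance metric.
#' @return an `rdm` over letters.
#' @export
intuitive_rdm <- function(table, convention = c("plain", "search", "categ"),
                          metric = "euclidean") {
  convention <- match.arg(convention)
  if (is.null(table$letter)) stop("table needs a letter column", call. = FALSE)
  feat_cols <- setdiff(names(table), c("letter", "font"))
  x <- as.matrix(table[, feat_cols, drop = FALSE])
  if (any(x < 0)) stop("feature counts must be non-negative", call. = FALSE)
  if (convention == "plain") {
    if (anyDuplicated(table$letter)) {
      stop("plain convention needs one row per letter", call. = FALSE)
    }
    m <- feature_distance(x, metric)
    diag(m) <- 0
    ord <- order(table$letter)
    return(rdm(m[ord, ord], sort(table$letter), signed = FALSE))
  }
  if (is.null(table$font)) {
    stop("search/categ conventions need a font column", call. = FALSE)
  }
  acts <- activation_set(x, table$letter, table$font, "intuitive")
  if (convention == "search") search_convention_rdm(acts, metric)
  else categ_convention_rdm(acts, metric)
}
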