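#' Normalize a visual-search trial table
#'
#' Preprocessing for odd-one-out search RTs: incorrect trials are dropped,
#' reaction times are log-transformed (lognormal-skewed RTs become roughly
#' symmetric) and z-scored within each HIT, and trials further than 3 SD
#' from their HIT mean are excluded. Because every HIT tests all letter
#' pairs, within-HIT z-scores make fast and slow sessions commensurable.
#' Z-scores are computed in a single pass and not recomputed after outlier
#' removal.
#'
#' @param trials data.frame with columns `hit_id`, `letter_a`, `letter_b`,
#'   `target`, `font`, `correct` (logical or 0/1), `rt_ms` (positive).
#' @param z_cutoff absolute z-score beyond which trials are excluded
#'   (default 3).
#' @return the retained trials with an added `z` column; attribute
#'   `exclusions` reports the fraction of incorrect trials, the fraction of
#'   correct trials beyond the cutoff, and any degenerate HITs dropped
#'   because their correct-trial log-RTs had zero variance.
#' @export
preprocess_search <- function(trials, z_cutoff = 3) {
  check_search_table(trials)
  n_total <- nrow(trials)
  keep <- as.logical(trials$correct)
  frac_incorrect <- mean(!keep)
  trials <- trials[keep, , drop = FALSE]

  logrt <- log(trials$rt_ms)
  mu <- tapply(logrt, trials$hit_id, mean)
  sdv <- tapply(logrt, trials$hit_id, stats::sd)
  degenerate <- names(sdv)[is.na(sdv) | sdv == 0]
  if (length(degenerate)) {
    warning(sprintf("excluding %d degenerate HIT(s) with zero log-RT variance: %s",
                    length(degenerate),
                    paste(utils::head(degenerate, 5), collapse = ", ")))
  }
  trials$z <- as.numeric((logrt - mu[trials$hit_id]) / sdv[trials$hit_id])
  ok_hit <- !trials$hit_id %in% degenerate
  out_of_range <- ok_hit & abs(trials$z) > z_cutoff
  frac_outlier <- mean(out_of_range[ok_hit])
  trials <- trials[ok_hit & !out_of_range, , drop = FALSE]
  rownames(trials) <- NULL
  attr(trials, "exclusions") <- list(
    frac_incorrect = frac_incorrect,
    frac_outlier = frac_outlier,
    degenerate_hits = degenerate,
    n_input = n_total, n_retained = nrow(trials))
  trials
}

#' Build the search RDM from normalized trials
#'
#' Each pair's dissimilarity is the negated mean z-scored log RT over all
#' retained trials of that pair: pairs searched quickly (dissimilar
#' letters) get high values, pairs searched slowly (similar letters) get
#' low values.
#'
#' @param trials output of [preprocess_search()] (must carry a `z` column).
#' @param alphabet item universe; defaults to the letters present.
#' @return an `rdm` in negated-z units. Unobserved pairs are `NA` and
#'   flagged with a warning, never zero-filled.
#' @export
build_search_rdm <- function(trials, alphabet = NULL) {
  if (is.null(trials$z)) {
    stop("trials must be preprocessed first (missing z column)", call. = FALSE)
  }
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(trials$letter_a, trials$letter_b)))
  }
  agg_pair_matrix(trials, trials$z, alphabet, negate = TRUE)
}

#' Accuracy-based search RDM
#'
#' Mean per-pair accuracy from the raw (unfiltered) trial table. Stored so
#' that larger values mean more dissimilar: errors concentrate on similar,
#' hard-to-discriminate pairs, so accuracy itself is the dissimilarity
#' axis (entries in \[0, 1\]).
#'
#' @param trials raw search trial table (see [preprocess_search()]).
#' @param alphabet item universe.
#' @return an `rdm` of per-pair accuracies.
#' @export
build_accuracy_rdm <- function(trials, alphabet = NULL) {
  check_search_table(trials)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(trials$letter_a, trials$letter_b)))
  }
  agg_pair_matrix(trials, as.numeric(trials$correct), alphabet,
                  negate = FALSE)
}

#' Per-font search RDMs
#'
#' Applies the [build_search_rdm()] rule separately within each font's
#' HITs; used for font-resolved model comparisons and font-split ceilings.
#'
#' @param trials output of [preprocess_search()].
#' @param alphabet item universe.
#' @return named list of `rdm`, one per font present. Fonts whose trials do
#'   not cover every pair are flagged with a warning (missing entries
#'   `NA`).
#' @export
per_font_rdms <- function(trials, alphabet = NULL) {
  if (is.null(trials$font)) stop("trials lack a font column", call. = FALSE)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(trials$letter_a, trials$letter_b)))
  }
  fonts <- sort(unique(trials$font))
  out <- lapply(fonts, function(f) {
    build_search_rdm(trials[trials$font == f, , drop = FALSE], alphabet)
  })
  names(out) <- fonts
  out
}

# shared per-pair aggregation: mean of `values` per unordered pair,
# optionally negated, arranged into an rdm over `alphabet`
agg_pair_matrix <- function(trials, values, alphabet, negate) {
  a <- as.character(trials$letter_a); b <- as.character(trials$letter_b)
  ia <- match(a, alphabet); ib <- match(b, alphabet)
  if (anyNA(ia) || anyNA(ib)) {
    stop("trial letters outside the alphabet", call. = FALSE)
  }
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- (hi - 1L) * length(alphabet) + lo
  means <- tapply(values, key, mean)
  n <- length(alphabet)
  m <- matrix(NA_real_, n, n)
  kk <- as.integer(names(means))
  hi_k <- (kk - 1L) %/% n + 1L; lo_k <- kk - (hi_k - 1L) * n
  vals <- if (negate) -as.numeric(means) else as.numeric(means)
  m[cbind(hi_k, lo_k)] <- vals
  m[cbind(lo_k, hi_k)] <- vals
  diag(m) <- 0
  if (anyNA(m[lower.tri(m)])) {
    miss <- sum(is.na(m[lower.tri(m)]))
    warning(sprintf("incomplete data: %d unobserved pair(s) left NA", miss))
  }
  rdm(m, alphabet)
}

check_search_table <- function(trials) {
  need <- c("hit_id", "letter_a", "letter_b", "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be positive", call. = FALSE)
  invisible(trials)
}
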