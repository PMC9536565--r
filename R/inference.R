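#' Model-behavior correlation curve across stages
#'
#' Spearman-correlates the behavioral RDM's lower triangle with each model
#' stage's, giving the familiar correlation-by-layer curve. An optional
#' bootstrap over letter pairs supplies a confidence band per stage.
#'
#' @param behavior behavioral `rdm`.
#' @param stages named list of model `rdm`s in stage order.
#' @param n_boot bootstrap resamples for the band (0 = point estimates
#'   only).
#' @param level band coverage (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return a `model_curve`: data.frame (`stage`, `rho`, `lower`, `upper`).
#' @export
model_behavior_curve <- function(behavior, stages, n_boot = 0,
                                 level = 0.95, seed = 1L) {
  bv <- as.numeric(check_shared_labels(behavior, stages))
  sv <- lapply(stages, function(s) as.numeric(lower_triangle(s)))
  rho <- vapply(sv, function(v) suppressWarnings(spearman_rdm(bv, v)),
                numeric(1))
  lower <- upper <- rep(NA_real_, length(sv))
  if (n_boot > 0) {
    rng <- seeded_rng(seed)
    idx <- matrix(rng$sample_int(length(bv), length(bv) * n_boot,
                                 replace = TRUE), ncol = n_boot)
    for (k in seq_along(sv)) {
      bs <- boot_spearman(bv, sv[[k]], idx)
      qs <- stats::quantile(bs, c((1 - level) / 2, 1 - (1 - level) / 2),
                            na.rm = TRUE, names = FALSE)
      lower[k] <- qs[1]; upper[k] <- qs[2]
    }
  }
  nm <- names(stages)
  if (is.null(nm)) nm <- paste0("stage", seq_along(stages))
  structure(data.frame(stage = nm, rho = rho, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("model_curve", "data.frame"))
}

#' @export
plot.model_curve <- function(x, main = "Model-behavior correlation", ...) {
  k <- nrow(x)
  ylim <- range(c(x$rho, x$lower, x$upper), na.rm = TRUE)
  graphics::plot(seq_len(k), x$rho, type = "b", pch = 16, xaxt = "n",
                 xlab = "stage", ylab = "Spearman rho", ylim = ylim,
                 main = main, ...)
  graphics::axis(1, at = seq_len(k), labels = x$stage, las = 2,
                 cex.axis = 0.8)
  if (!all(is.na(x$lower))) {
    graphics::arrows(seq_len(k), x$lower, seq_len(k), x$upper,
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}

boot_spearman <- function(bv, mv, idx) {
  apply(idx, 2L, function(ii) {
    b <- bv[ii]; m <- mv[ii]
    if (stats::var(b) == 0 || stats::var(m) == 0) return(NA_real_)
    stats::cor(rank(b), rank(m))
  })
}

#' Bootstrap comparison of two models' behavioral fit
#'
#' Resamples the unordered letter pairs with replacement and recomputes
#' both models' Spearman correlations with behavior in every resample.
#' `kind = "max_layer"` fixes, from the original sample, the stage of each
#' model with the highest correlation and compares those two stages across
#' resamples; `kind = "layerwise"` compares matched stages. The reported
#' `p` is the one-sided proportion of resamples in which the nominally
#' better model (by the original sample) is *not* better; tie resamples
#' count against rejection. `two_sided = TRUE` doubles the smaller tail.
#' Resamples where either vector becomes rank-degenerate are skipped and
#' counted.
#'
#' @param behavior behavioral `rdm`.
#' @param model_a,model_b named lists of stage `rdm`s.
#' @param kind `"max_layer"` or `"layerwise"`.
#' @param n resample count (the full-scale procedure uses 50,000).
#' @param seed integer seed; results are bit-reproducible given (seed, n).
#' @param two_sided double the one-sided proportion (capped at 1).
#' @return a `bootstrap_result` with elements `kind`, `n_resamples`,
#'   `seed`, and a `comparisons` data.frame (`stage_a`, `stage_b`,
#'   `rho_a`, `rho_b`, `direction`, `p`, `n_skipped`).
#' @export
bootstrap_compare <- function(behavior, model_a, model_b,
                              kind = c("max_layer", "layerwise"),
                              n = 1000, seed = 1L, two_sided = FALSE) {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  bv <- as.numeric(check_shared_labels(behavior, c(model_a, model_b)))
  av <- lapply(model_a, function(s) as.numeric(lower_triangle(s)))
  bvv <- lapply(model_b, function(s) as.numeric(lower_triangle(s)))
  rho_a <- vapply(av, function(v) suppressWarnings(spearman_rdm(bv, v)),
                  numeric(1))
  rho_b <- vapply(bvv, function(v) suppressWarnings(spearman_rdm(bv, v)),
                  numeric(1))
  if (kind == "max_layer") {
    ka <- which.max(rho_a); kb <- which.max(rho_b)
    pairs_idx <- cbind(ka, kb)
  } else {
    if (length(av) != length(bvv)) {
      stop("layerwise comparison needs matched stage counts", call. = FALSE)
    }
    pairs_idx <- cbind(seq_along(av), seq_along(bvv))
  }
  rng <- seeded_rng(seed)
  np <- length(bv)
  idx <- matrix(rng$sample_int(np, np * n, replace = TRUE), ncol = n)

  comparisons <- do.call(rbind, lapply(seq_len(nrow(pairs_idx)), function(r) {
    ia <- pairs_idx[r, 1]; ib <- pairs_idx[r, 2]
    da <- av[[ia]]; db <- bvv[[ib]]
    diffs <- apply(idx, 2L, function(ii) {
      b <- bv[ii]
      if (stats::var(b) == 0 || stats::var(da[ii]) == 0 ||
          stats::var(db[ii]) == 0) return(NA_real_)
      rb <- rank(b)
      stats::cor(rb, rank(da[ii])) - stats::cor(rb, rank(db[ii]))
    })
    skipped <- sum(is.na(diffs))
    diffs <- diffs[!is.na(diffs)]
    obs <- rho_a[ia] - rho_b[ib]
    direction <- if (obs > 0) "a" else if (obs < 0) "b" else "tie"
    # ties count toward "not better" on both sides (conservative)
    p_a_not_better <- mean(diffs <= 0)   # evidence against a > b
    p_b_not_better <- mean(diffs >= 0)
    p1 <- switch(direction, a = p_a_not_better, b = p_b_not_better,
                 tie = 1)
    p <- if (two_sided) min(1, 2 * min(p_a_not_better, p_b_not_better))
         else p1
    data.frame(stage_a = stage_name(model_a, ia),
               stage_b = stage_name(model_b, ib),
               rho_a = rho_a[ia], rho_b = rho_b[ib],
               direction = direction, p = p, n_skipped = skipped,
               stringsAsFactors = FALSE)
  }))
  structure(list(kind = kind, n_resamples = n, seed = seed,
                 two_sided = two_sided, comparisons = comparisons),
            class = "bootstrap_result")
}

stage_name <- function(stages, i) {
  nm <- names(stages)
  if (is.null(nm)) paste0("stage", i) else nm[i]
}

#' @export
#' @method print bootstrap_result
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %s comparison, %d resamples (seed %s)\n",
              x$kind, x$n_resamples, format(x$seed)))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Per-font comparison of maximum model-behavior correlations
#'
#' For each font, takes each model's maximum correlation across stages
#' with that font's behavioral RDM, then compares the two models with a
#' paired t-test across fonts (df = n_fonts - 1; 20 fonts gives t(19)).
#'
#' @param behavior_by_font named list of per-font behavioral `rdm`s.
#' @param model_a,model_b either lists of stage `rdm`s (same model RDM for
#'   every font) or per-font lists of stage lists, named by font.
#' @return list: `statistic` (paired t), `df`, `p_value` (two-sided),
#'   `per_font` data.frame (`font`, `max_a`, `max_b`, `diff`).
#' @export
per_font_max_comparison <- function(behavior_by_font, model_a, model_b) {
  fonts <- names(behavior_by_font)
  if (length(fonts) < 2) stop("need at least 2 fonts", call. = FALSE)
  max_rho <- function(beh, stages) {
    max(vapply(stages, function(s) {
      suppressWarnings(spearman_rdm(lower_triangle(beh), lower_triangle(s)))
    }, numeric(1)))
  }
  stages_for <- function(model, f) {
    if (!is.null(names(model)) && f %in% names(model) &&
        is.list(model[[f]]) && !inherits(model[[f]], "rdm")) model[[f]]
    else model
  }
  max_a <- vapply(fonts, function(f)
    max_rho(behavior_by_font[[f]], stages_for(model_a, f)), numeric(1))
  max_b <- vapply(fonts, function(f)
    max_rho(behavior_by_font[[f]], stages_for(model_b, f)), numeric(1))
  d <- max_a - max_b
  if (stats::sd(d) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
               p.value = 1)
  } else {
    tt <- stats::t.test(max_a, max_b, paired = TRUE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       per_font = data.frame(font = fonts, max_a = max_a, max_b = max_b,
                             diff = d, stringsAsFactors = FALSE))
}

check_shared_labels <- function(behavior, stages) {
  if (!inherits(behavior, "rdm")) behavior <- rdm(behavior)
  labs <- rownames(behavior)
  for (s in stages) {
    if (!identical(rownames(s), labs)) {
      stop("label mismatch between behavioral and model RDMs",
           call. = FALSE)
    }
  }
  lower_triangle(behavior)
}
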