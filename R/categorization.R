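#' Per-HIT pair means for the categorization experiment
#'
#' The similarity index in speeded categorization is the time to *reject* a
#' non-matching letter. This step (i) drops whole HITs whose overall trial
#' accuracy falls below `min_hit_accuracy`, (ii) drops incorrect trials,
#' and (iii) averages the remaining non-match RTs per HIT and ordered
#' (target, presented) pair, excluding any cell in which more than half of
#' its scheduled repetitions were answered incorrectly (more than 4 of 8
#' at the default design).
#'
#' @param trials data.frame with columns `hit_id`, `block`, `target`,
#'   `presented`, `font`, `match`, `correct`, `rt_ms`.
#' @param reps_per_pair scheduled repetitions per (pair, HIT) cell
#'   (default 8); a cell is kept while incorrect trials <= reps/2.
#' @param min_hit_accuracy whole-HIT accuracy threshold (default 0.9).
#' @return data.frame (`condition`, `target`, `presented`, `hit_id`,
#'   `mean_rt`, `n_trials`), one row per retained (condition, HIT) cell;
#'   `condition` is the string "target>presented". Attribute `exclusions`
#'   records dropped HITs and cells.
#' @export
pair_means <- function(trials, reps_per_pair = 8, min_hit_accuracy = 0.9) {
  need <- c("hit_id", "target", "presented", "match", "correct", "rt_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(trials$rt_ms <= 0)) stop("rt_ms must be positive", call. = FALSE)
  bad_flag <- xor(as.logical(trials$match),
                  trials$target == trials$presented)
  if (any(bad_flag)) {
    stop("match flag inconsistent with target/presented letters",
         call. = FALSE)
  }

  hit_acc <- tapply(as.numeric(trials$correct), trials$hit_id, mean)
  bad_hits <- names(hit_acc)[hit_acc < min_hit_accuracy]
  trials <- trials[!trials$hit_id %in% bad_hits, , drop = FALSE]

  nm <- trials[!as.logical(trials$match), , drop = FALSE]
  key <- interaction(nm$hit_id, nm$target, nm$presented, drop = TRUE)
  n_wrong <- tapply(!as.logical(nm$correct), key, sum)
  bad_cells <- names(n_wrong)[n_wrong > reps_per_pair / 2]

  ok <- nm[as.logical(nm$correct) & !(as.character(key) %in% bad_cells), ,
           drop = FALSE]
  okey <- interaction(ok$hit_id, ok$target, ok$presented, drop = TRUE)
  first <- !duplicated(okey)
  out <- data.frame(
    condition = paste0(ok$target, ">", ok$presented)[first],
    target = ok$target[first],
    presented = ok$presented[first],
    hit_id = ok$hit_id[first],
    mean_rt = as.numeric(tapply(ok$rt_ms, okey, mean)[as.character(okey[first])]),
    n_trials = as.integer(table(okey)[as.character(okey[first])]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!nrow(out)) warning("pair_means produced an empty table")
  attr(out, "exclusions") <- list(
    dropped_hits = bad_hits,
    dropped_cells = length(bad_cells))
  out
}

#' Estimate the categorization RDM with a linear mixed model
#'
#' Fits `mean_rt ~ condition + (1 | hit_id)`: fixed effects for every
#' ordered (target, presented) condition (dummy coded against the first
#' condition in canonical order) and a random intercept per HIT absorbing
#' between-session speed differences. The reference estimate (the model
#' intercept) is added back to every condition effect to recover estimated
#' RTs per ordered pair; the two directions of each unordered pair are
#' averaged, negated so that slower rejection (more similar letters) means
#' *less* dissimilar, and assembled into the RDM. The result is invariant
#' to the choice of reference condition.
#'
#' With a single HIT (or a single level of the grouping factor) the random
#' intercept is unidentifiable; the model degrades to the fixed-effects
#' fit, whose estimates are the per-condition cell means.
#'
#' @param pm pair-means table from [pair_means()].
#' @param alphabet item universe; defaults to letters present.
#' @param method `"REML"` (default) or `"ML"`.
#' @param control optional [lme4::lmerControl()] object (e.g. relaxed
#'   tolerances for repeated split-half fits).
#' @return an `rdm` in negated-ms units, with attributes
#'   `condition_estimates` (named vector of estimated RTs per ordered
#'   condition) and `fit` diagnostics (`method`, `singular`, `messages`).
#' @export
fit_lme_rdm <- function(pm, alphabet = NULL, method = c("REML", "ML"),
                        control = NULL) {
  method <- match.arg(method)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(pm$target, pm$presented)))
  }
  univ <- ordered_conditions(alphabet)
  present <- unique(paste0(pm$target, ">", pm$presented))
  missing_cond <- setdiff(univ, present)
  if (length(missing_cond)) {
    stop(sprintf("incomplete design: %d unobserved condition(s), e.g. %s",
                 length(missing_cond), missing_cond[1]), call. = FALSE)
  }
  df <- data.frame(
    rt = pm$mean_rt,
    condition = factor(paste0(pm$target, ">", pm$presented), levels = univ),
    hit = factor(pm$hit_id))

  msgs <- character(0)
  singular <- FALSE
  # saturated or near-saturated designs leave no information for the
  # random intercept; degrade to the fixed-effects fit (= cell means)
  if (nlevels(df$hit) < 2 || nrow(df) < nlevels(df$condition) + 2) {
    fit <- stats::lm(rt ~ condition, data = df)
    est <- stats::coef(fit)
    msgs <- "single grouping level: random intercept dropped, fixed-effects fit"
  } else {
    if (is.null(control)) {
      control <- lme4::lmerControl(check.conv.singular = "ignore")
    }
    fit <- withCallingHandlers(
      lme4::lmer(rt ~ condition + (1 | hit), data = df,
                 REML = (method == "REML"), control = control),
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      },
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    singular <- lme4::isSingular(fit)
    est <- lme4::fixef(fit)
  }
  if (anyNA(est)) {
    stop("rank-deficient condition design: unestimable conditions",
         call. = FALSE)
  }
  # dummy coding: intercept is the reference condition; add it back
  rts <- c(est[1], est[1] + est[-1])
  names(rts) <- univ

  n <- length(alphabet)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    m[i, j] <- rts[paste0(alphabet[i], ">", alphabet[j])]
  }
  sym <- -(m + t(m)) / 2
  diag(sym) <- 0
  out <- rdm(sym, alphabet)
  attr(out, "condition_estimates") <- rts
  attr(out, "fit") <- list(method = method, singular = singular,
                           messages = msgs)
  out
}

#' All ordered (target, presented) conditions for an alphabet
#'
#' @param alphabet character vector of letters.
#' @return character vector "target>presented" of length n*(n-1), ordered
#'   target-major in alphabet order.
#' @export
ordered_conditions <- function(alphabet) {
  alphabet <- as.character(alphabet)
  unlist(lapply(alphabet, function(t) {
    paste0(t, ">", setdiff(alphabet, t))
  }))
}
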