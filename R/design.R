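#' Counterbalanced visual-search HIT designs
#'
#' One HIT (session) is generated for each combination of target position,
#' font, and target-distractor assignment. Every HIT contains exactly one
#' trial per unordered letter pair, so fast and slow sessions influence all
#' pairs equally; with 6 positions, 20 fonts and 2 assignments this yields
#' the full 240-HIT design with 325 trials each.
#'
#' @param alphabet character vector of letters (default the 26 lowercase).
#' @param n_positions number of display positions the target cycles over.
#' @param fonts character vector of font identifiers.
#' @param n_assignments number of target-distractor assignments (1 or 2;
#'   assignment 1 targets the alphabetically later letter of the pair,
#'   assignment 2 the earlier).
#' @param seed integer seed for within-HIT trial-order shuffling.
#' @return list of `search_hit_spec` objects, each a list with `hit_id`,
#'   `font`, `position`, `assignment` and a `trials` data.frame
#'   (`letter_a`, `letter_b`, `target`, `position`); `letter_a` is the later
#'   letter of the canonical pair.
#' @export
generate_search_designs <- function(alphabet = letters,
                                    n_positions = 6,
                                    fonts = paste0("font", sprintf("%02d", 1:20)),
                                    n_assignments = 2,
                                    seed = 1L) {
  fonts <- as.character(fonts)
  if (length(fonts) < 1) stop("need at least one font", call. = FALSE)
  if (n_positions < 1) stop("n_positions must be >= 1", call. = FALSE)
  if (!n_assignments %in% 1:2) {
    stop("n_assignments must be 1 or 2", call. = FALSE)
  }
  if (length(alphabet) < 2) stop("need at least 2 letters", call. = FALSE)
  pairs <- canonical_pairs(alphabet)
  grid <- expand.grid(position = seq_len(n_positions), font = fonts,
                      assignment = seq_len(n_assignments),
                      stringsAsFactors = FALSE)
  rng <- seeded_rng(seed)
  hits <- vector("list", nrow(grid))
  for (h in seq_len(nrow(grid))) {
    a <- grid$assignment[h]
    target <- if (a == 1L) pairs[, "i"] else pairs[, "j"]
    trials <- data.frame(letter_a = pairs[, "i"], letter_b = pairs[, "j"],
                         target = target, position = grid$position[h],
                         stringsAsFactors = FALSE)
    trials <- trials[rng$sample(nrow(trials)), , drop = FALSE]
    rownames(trials) <- NULL
    hits[[h]] <- structure(
      list(hit_id = sprintf("S%04d", h), font = grid$font[h],
           position = grid$position[h], assignment = a, trials = trials),
      class = "search_hit_spec")
  }
  hits
}

#' Counterbalanced letter-categorization HIT designs
#'
#' Each HIT has two blocks with distinct target letters; each block assigns
#' a fixed set of non-target letters to its target and repeats every
#' (target, non-target) ordered pair `reps_per_pair` times, interleaved
#' with an equal number of target-match trials. For 26 letters with 13
#' non-targets per block and 8 repetitions this is the 416-trial HIT over
#' the 650-member ordered-pair universe.
#'
#' Ordered pairs are distributed across HITs by round-robin over seeded
#' per-target queues, which keeps per-pair coverage near-uniform
#' (max - min coverage <= 2).
#'
#' @param alphabet character vector of letters (>= 2).
#' @param reps_per_pair non-match repetitions of each assigned ordered pair
#'   within its HIT (default 8).
#' @param n_hits number of HITs to generate.
#' @param pairs_per_block non-target letters per block; default
#'   `ceiling((n-1)/2)` (13 for 26 letters).
#' @param fonts font identifiers sampled per trial (fonts are randomized
#'   within HIT, not counterbalanced).
#' @param seed integer seed.
#' @return list of `categ_hit_spec` objects: `hit_id`, `blocks` (list of
#'   `target` + `nontargets`), and a `trials` data.frame (`block`,
#'   `target`, `presented`, `font`, `match`).
#' @export
generate_categ_designs <- function(alphabet = letters,
                                   reps_per_pair = 8,
                                   n_hits = 664,
                                   pairs_per_block = NULL,
                                   fonts = paste0("font", sprintf("%02d", 1:20)),
                                   seed = 1L) {
  alphabet <- as.character(alphabet)
  n <- length(alphabet)
  if (n < 2) stop("need at least 2 letters", call. = FALSE)
  if (is.null(pairs_per_block)) pairs_per_block <- ceiling((n - 1) / 2)
  pairs_per_block <- min(pairs_per_block, n - 1)
  n_universe <- n * (n - 1)
  if (2 * pairs_per_block * n_hits < n_universe) {
    stop(sprintf(
      "n_hits too small: %d HITs cover at most %d ordered pairs of %d",
      n_hits, 2 * pairs_per_block * n_hits, n_universe), call. = FALSE)
  }
  rng <- seeded_rng(seed)
  # per-target queues of non-target letters, refilled with a fresh shuffle
  queues <- lapply(seq_len(n), function(i) character(0))
  pop_nontargets <- function(ti, k) {
    q <- queues[[ti]]
    out <- character(0)
    while (length(out) < k) {
      if (!length(q)) {
        pool <- setdiff(alphabet, alphabet[ti])
        q <- pool[rng$sample(length(pool))]
        # avoid duplicating a letter within one block across the refill seam
        q <- c(setdiff(q, out), intersect(q, out))
      }
      take <- min(k - length(out), length(q))
      out <- c(out, q[seq_len(take)])
      q <- q[-seq_len(take)]
    }
    queues[[ti]] <<- q
    out
  }
  target_order <- rep(rng$sample(n), length.out = 2 * n_hits)
  hits <- vector("list", n_hits)
  for (h in seq_len(n_hits)) {
    t1 <- target_order[2 * h - 1]; t2 <- target_order[2 * h]
    if (t2 == t1) t2 <- if (t1 == n) 1L else t1 + 1L
    blocks <- list(
      list(target = alphabet[t1],
           nontargets = pop_nontargets(t1, pairs_per_block)),
      list(target = alphabet[t2],
           nontargets = pop_nontargets(t2, pairs_per_block)))
    trial_list <- lapply(1:2, function(b) {
      blk <- blocks[[b]]
      nonmatch <- data.frame(
        block = b, target = blk$target,
        presented = rep(blk$nontargets, each = reps_per_pair),
        match = FALSE, stringsAsFactors = FALSE)
      match <- data.frame(
        block = b, target = blk$target,
        presented = blk$target,
        match = TRUE, stringsAsFactors = FALSE)
      match <- match[rep(1L, nrow(nonmatch)), , drop = FALSE]
      out <- rbind(nonmatch, match)
      out[rng$sample(nrow(out)), , drop = FALSE]
    })
    trials <- do.call(rbind, trial_list)
    trials$font <- fonts[rng$sample_int(length(fonts), nrow(trials),
                                        replace = TRUE)]
    rownames(trials) <- NULL
    hits[[h]] <- structure(
      list(hit_id = sprintf("C%04d", h), blocks = blocks, trials = trials),
      class = "categ_hit_spec")
  }
  hits
}

#' Ordered-pair coverage of a categorization design
#'
#' Counts, for every ordered (target, non-target) pair in the alphabet, the
#' number of HITs whose design assigns it.
#'
#' @param designs list of `categ_hit_spec`.
#' @param alphabet the letter universe.
#' @return data.frame (`target`, `presented`, `n_hits`) covering the full
#'   n*(n-1) ordered-pair universe.
#' @export
categ_pair_coverage <- function(designs, alphabet = NULL) {
  assigned <- do.call(rbind, lapply(designs, function(d) {
    do.call(rbind, lapply(d$blocks, function(b) {
      data.frame(target = b$target, presented = b$nontargets,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(alphabet)) {
    alphabet <- sort(unique(c(assigned$target, assigned$presented)))
  }
  univ <- expand.grid(presented = alphabet, target = alphabet,
                      stringsAsFactors = FALSE)[, 2:1]
  univ <- univ[univ$target != univ$presented, , drop = FALSE]
  key <- paste(assigned$target, assigned$presented)
  counts <- table(key)
  univ$n_hits <- as.integer(counts[paste(univ$target, univ$presented)])
  univ$n_hits[is.na(univ$n_hits)] <- 0L
  rownames(univ) <- NULL
  univ
}

#' Flatten HIT designs to a single trial table
#'
#' @param designs list of HIT specs from [generate_search_designs()] or
#'   [generate_categ_designs()].
#' @return data.frame with one row per trial and a `hit_id` column; search
#'   designs additionally carry a `font` column taken from the HIT.
#' @export
design_trials <- function(designs) {
  do.call(rbind, lapply(designs, function(d) {
    tr <- d$trials
    tr$hit_id <- d$hit_id
    if (!is.null(d$font)) tr$font <- d$font
    tr[, c("hit_id", setdiff(names(tr), "hit_id")), drop = FALSE]
  }))
}

# Local RNG helper: all generators draw from their own stream so package
# randomness never disturbs (or depends on) the caller's .Random.seed.
seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample = function(n) with_state(sample.int(n)),
    sample_int = function(n, size, replace = FALSE)
      with_state(sample.int(n, size, replace = replace)),
    rnorm = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max))
  )
}
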