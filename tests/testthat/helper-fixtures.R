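# Shared in-code fixtures. Everything is generated programmatically and
# cached per test run so expensive simulations happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

small_truth <- function() {
  cached("small_truth", default_ground_truth(alphabet = letters[1:6],
                                             n_fonts = 6, seed = 11))
}

small_search_design <- function() {
  cached("small_search_design",
         generate_search_designs(alphabet = letters[1:6], n_positions = 5,
                                 fonts = paste0("f", 1:6),
                                 n_assignments = 2, seed = 21))
}

small_search_trials <- function() {
  cached("small_search_trials",
         simulate_search(small_truth(), small_search_design(), seed = 31))
}

small_categ_design <- function() {
  cached("small_categ_design",
         generate_categ_designs(alphabet = letters[1:6], reps_per_pair = 8,
                                n_hits = 60, fonts = paste0("f", 1:6),
                                seed = 22))
}

small_categ_trials <- function() {
  cached("small_categ_trials",
         simulate_categ(small_truth(), small_categ_design(), seed = 32))
}

# hand-built search trial table: explicit HITs with given RTs per pair
toy_search_table <- function(hits) {
  do.call(rbind, lapply(names(hits), function(h) {
    d <- hits[[h]]
    data.frame(hit_id = h, letter_a = d$letter_a, letter_b = d$letter_b,
               target = d$letter_a,
               font = if (is.null(d$font)) "f1" else d$font,
               correct = if (is.null(d$correct)) TRUE else d$correct,
               rt_ms = d$rt_ms, stringsAsFactors = FALSE)
  }))
}

# categorization trial block: one (target, presented) cell of n trials
toy_categ_cell <- function(hit, target, presented, rts, correct = TRUE) {
  n <- length(rts)
  data.frame(hit_id = hit, block = 1L, target = target,
             presented = presented, font = "f1",
             match = target == presented,
             correct = rep_len(correct, n), rt_ms = rts,
             stringsAsFactors = FALSE)
}

# fully balanced categorization pair-means table: every ordered condition
# observed once per HIT, values = truth + optional per-HIT offset + noise
balanced_pair_means <- function(alphabet, n_hits, cond_rt,
                                hit_offsets = rep(0, n_hits),
                                noise = NULL) {
  conds <- ordered_conditions(alphabet)
  stopifnot(length(cond_rt) == length(conds))
  df <- expand.grid(condition = conds, hit = seq_len(n_hits),
                    stringsAsFactors = FALSE)
  parts <- strsplit(df$condition, ">", fixed = TRUE)
  df <- data.frame(
    condition = df$condition,
    target = vapply(parts, `[`, "", 1L),
    presented = vapply(parts, `[`, "", 2L),
    hit_id = sprintf("H%03d", df$hit),
    mean_rt = cond_rt[match(df$condition, conds)] + hit_offsets[df$hit],
    n_trials = 8L, stringsAsFactors = FALSE)
  if (!is.null(noise)) df$mean_rt <- df$mean_rt + noise
  df
}

# independent Spearman oracle: explicit average-rank transform followed by
# the product-moment formula
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    sv <- v[o]
    pos <- seq_along(v)
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && sv[j + 1] == sv[i]) j <- j + 1
      r[o[i:j]] <- mean(pos[i:j])
      i <- j + 1
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

random_rdm <- function(labels, seed) {
  set.seed(seed)
  n <- length(labels)
  rdm_from_pairs(stats::rnorm(n * (n - 1) / 2), labels)
}
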