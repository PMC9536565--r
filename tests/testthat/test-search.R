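test_that("preprocessing excludes errors and 3-SD outliers by the direct log-RT oracle", {
  # a HIT over all 15 pairs of 6 letters plus one far-tail repeat trial
  # (with few trials, a single-pass z can never exceed (n-1)/sqrt(n), so
  # the outlier needs enough unremarkable company to stand out)
  cp <- canonical_pairs(letters[1:6])
  hits <- list(H1 = list(letter_a = c(cp[, 1], "b"),
                         letter_b = c(cp[, 2], "a"),
                         rt_ms = c(seq(400, 600, length.out = 15), 20000)))
  tab <- toy_search_table(hits)
  pp <- preprocess_search(tab)
  # oracle: direct mean/SD of the log RTs; only the 20 s trial is beyond 3 SD
  lz <- (log(tab$rt_ms) - mean(log(tab$rt_ms))) / sd(log(tab$rt_ms))
  expect_identical(which(abs(lz) > 3), 16L)
  expect_equal(nrow(pp), 15)
  expect_false(any(pp$rt_ms == 20000))
  expect_equal(pp$z, lz[1:15], tolerance = 1e-12)
  excl <- attr(pp, "exclusions")
  expect_equal(excl$frac_outlier, 1 / 16)
  expect_equal(excl$frac_incorrect, 0)

  # incorrect trials are removed before normalization
  tab2 <- tab
  tab2$correct <- c(TRUE, FALSE, rep(TRUE, 14))
  pp2 <- preprocess_search(tab2)
  expect_equal(attr(pp2, "exclusions")$frac_incorrect, 1 / 16)
  expect_false(any(pp2$rt_ms == tab$rt_ms[2]))
})

test_that("z-scores are invariant to per-HIT multiplicative RT rescaling", {
  tab <- small_search_trials()
  pp1 <- preprocess_search(tab)
  tab2 <- tab
  scale_by <- ifelse(tab2$hit_id %in% unique(tab2$hit_id)[1:5], 3.7, 1)
  tab2$rt_ms <- tab2$rt_ms * scale_by
  pp2 <- preprocess_search(tab2)
  expect_equal(pp1$z, pp2$z, tolerance = 1e-10)
})

test_that("degenerate zero-variance HITs are excluded with a warning", {
  hits <- list(H1 = list(letter_a = c("b", "c", "c"),
                         letter_b = c("a", "a", "b"),
                         rt_ms = c(500, 500, 500)),
               H2 = list(letter_a = c("b", "c", "c"),
                         letter_b = c("a", "a", "b"),
                         rt_ms = c(400, 520, 610)))
  expect_warning(pp <- preprocess_search(toy_search_table(hits)),
                 "degenerate")
  expect_equal(unique(pp$hit_id), "H2")
  expect_equal(attr(pp, "exclusions")$degenerate_hits, "H1")
})

test_that("search RDM equals brute-force per-pair negated mean z on a toy table", {
  hits <- list(H1 = list(letter_a = c("b", "c", "c"),
                         letter_b = c("a", "a", "b"),
                         rt_ms = c(420, 950, 700)),
               H2 = list(letter_a = c("b", "c", "c"),
                         letter_b = c("a", "a", "b"),
                         rt_ms = c(500, 1400, 660)))
  tab <- toy_search_table(hits)
  pp <- preprocess_search(tab)
  r <- build_search_rdm(pp)

  # oracle: per-HIT z of log RT, averaged per pair, negated
  zs <- unlist(lapply(split(tab, tab$hit_id), function(h) {
    l <- log(h$rt_ms); (l - mean(l)) / sd(l)
  }))
  key <- unlist(lapply(split(tab, tab$hit_id), function(h) {
    paste(h$letter_a, h$letter_b)
  }))
  want <- -tapply(zs, key, mean)
  expect_equal(unclass(r)["b", "a"], unname(want["b a"]), tolerance = 1e-12)
  expect_equal(unclass(r)["c", "a"], unname(want["c a"]), tolerance = 1e-12)
  expect_equal(unclass(r)["c", "b"], unname(want["c b"]), tolerance = 1e-12)
  expect_true(isSymmetric(unclass(r)))

  # Latin-square RT rotation: every pair sees every speed rank once, so
  # per-pair mean z is constant
  hits_const <- list(H1 = list(letter_a = c("b", "c", "c"),
                               letter_b = c("a", "a", "b"),
                               rt_ms = c(400, 500, 600)),
                     H2 = list(letter_a = c("b", "c", "c"),
                               letter_b = c("a", "a", "b"),
                               rt_ms = c(500, 600, 400)),
                     H3 = list(letter_a = c("b", "c", "c"),
                               letter_b = c("a", "a", "b"),
                               rt_ms = c(600, 400, 500)))
  rc <- build_search_rdm(preprocess_search(toy_search_table(hits_const)))
  v <- as.numeric(lower_triangle(rc))
  expect_equal(max(v) - min(v), 0, tolerance = 1e-12)
})

test_that("uniformly slowing one pair strictly decreases its dissimilarity entry", {
  tab <- small_search_trials()
  base <- build_search_rdm(preprocess_search(tab))
  slow <- tab
  sel <- (slow$letter_a == "b" & slow$letter_b == "a") |
         (slow$letter_a == "a" & slow$letter_b == "b")
  slow$rt_ms[sel] <- slow$rt_ms[sel] * 1.5
  slowed <- build_search_rdm(preprocess_search(slow))
  expect_lt(unclass(slowed)["b", "a"], unclass(base)["b", "a"])
})

test_that("accuracy RDM counts errors per pair, bounded in [0,1]", {
  tab <- small_search_trials()
  acc <- build_accuracy_rdm(tab)
  v <- as.numeric(lower_triangle(acc))
  expect_true(all(v >= 0 & v <= 1))

  # oracle on a toy table: one error-prone pair is the extreme entry
  hits <- list(H1 = list(letter_a = c("b", "c", "c"),
                         letter_b = c("a", "a", "b"),
                         rt_ms = c(500, 600, 700),
                         correct = c(FALSE, TRUE, TRUE)),
               H2 = list(letter_a = c("b", "c", "c"),
                         letter_b = c("a", "a", "b"),
                         rt_ms = c(520, 610, 720),
                         correct = c(FALSE, TRUE, TRUE)))
  toy <- build_accuracy_rdm(toy_search_table(hits))
  expect_equal(unclass(toy)["b", "a"], 0)
  expect_equal(unclass(toy)["c", "a"], 1)
  expect_equal(which.min(as.numeric(lower_triangle(toy))), 1L)

  all_right <- build_accuracy_rdm(toy_search_table(list(
    H1 = list(letter_a = c("b", "c", "c"), letter_b = c("a", "a", "b"),
              rt_ms = c(1, 2, 3)))))
  expect_equal(max(as.numeric(lower_triangle(all_right))), 1)
  expect_equal(min(as.numeric(lower_triangle(all_right))), 1)
})

test_that("per-font RDMs restrict correctly and average back to the pooled RDM when balanced", {
  tab <- preprocess_search(small_search_trials())
  by_font <- per_font_rdms(tab)
  expect_length(by_font, 6)

  single <- per_font_rdms(tab[tab$font == "f1", , drop = FALSE])
  expect_length(single, 1)
  expect_equal(unclass(single[["f1"]]), unclass(by_font[["f1"]]))

  # balanced HIT counts: mean of per-font RDMs = pooled RDM (exact when
  # nothing is excluded, so simulate with errors and lapses switched off)
  gt0 <- ground_truth(small_truth()$rdm,
                      search = list(error_base = 0, error_slope = 0,
                                    lapse_rate = 0, resid_sd = 0.05))
  tab0 <- preprocess_search(simulate_search(gt0, small_search_design(),
                                            seed = 77), z_cutoff = Inf)
  pooled <- build_search_rdm(tab0)
  avg <- Reduce(`+`, lapply(per_font_rdms(tab0), unclass)) / 6
  expect_lt(max(abs(avg - unclass(pooled))), 1e-10)

  expect_warning(build_search_rdm(tab[1:4, , drop = FALSE]), "unobserved")
})
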