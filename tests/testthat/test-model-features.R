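toy_acts <- function(mat, letter, font, stage = "s") {
  activation_set(mat, letter, font, stage)
}

test_that("spatial pooling sums maps to one scalar per feature", {
  maps <- array(1, dim = c(3, 256, 13, 13))  # 3 images, 256 features
  acts <- pool_feature_maps(maps, letter = c("a", "b", "c"),
                            font = rep("f1", 3))
  expect_equal(dim(acts$activations), c(3, 256))
  expect_true(all(acts$activations == 169))

  lst <- list(array(1:4, dim = c(4, 1, 1)), array(5:8, dim = c(4, 1, 1)))
  acts1 <- pool_feature_maps(lst, letter = c("a", "b"), font = c("f", "f"))
  expect_equal(unname(acts1$activations), rbind(1:4, 5:8))  # 1x1 is identity

  bad <- list(array(1, dim = c(2, 3, 3)), array(1, dim = c(2, 4, 4)))
  expect_error(pool_feature_maps(bad, c("a", "b"), c("f", "f")), "shapes")
})

test_that("search convention averages within-font distances, matching hand arithmetic", {
  # 2 letters x 2 fonts, 2-dim activations
  mat <- rbind(c(0, 0), c(3, 4),    # font f1: a, b  -> distance 5
               c(1, 1), c(1, 6))    # font f2: a, b  -> distance 5... no, 5
  acts <- toy_acts(mat, c("a", "b", "a", "b"), c("f1", "f1", "f2", "f2"))
  r <- search_convention_rdm(acts)
  d1 <- sqrt(sum((c(0, 0) - c(3, 4))^2))
  d2 <- sqrt(sum((c(1, 1) - c(1, 6))^2))
  expect_equal(unclass(r)["b", "a"], (d1 + d2) / 2, tolerance = 1e-12)

  # identical rows in every font -> zero entry
  same <- toy_acts(rbind(c(1, 2), c(1, 2), c(5, 1), c(5, 1)),
                   c("a", "b", "a", "b"), c("f1", "f1", "f2", "f2"))
  expect_equal(unclass(search_convention_rdm(same))["b", "a"], 0)

  # permuting feature columns leaves the RDM unchanged
  perm <- toy_acts(mat[, 2:1], c("a", "b", "a", "b"),
                   c("f1", "f1", "f2", "f2"))
  expect_equal(unclass(search_convention_rdm(perm)), unclass(r))

  # adding all-zero features leaves the Euclidean RDM unchanged
  padded <- toy_acts(cbind(mat, 0, 0), c("a", "b", "a", "b"),
                     c("f1", "f1", "f2", "f2"))
  expect_equal(unclass(search_convention_rdm(padded)), unclass(r))

  expect_error(search_convention_rdm(toy_acts(mat[1:3, ],
                                              c("a", "b", "a"),
                                              c("f1", "f1", "f2"))),
               "complete")
})

test_that("single-font search convention equals plain within-font distances", {
  set.seed(21)
  mat <- matrix(rnorm(4 * 3), 4, 3)
  acts <- toy_acts(mat, letters[1:4], rep("f1", 4))
  r <- search_convention_rdm(acts)
  expect_equal(unclass(r), as.matrix(dist(mat)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("categorization convention matches the exemplar-to-template oracle and differs from the search convention", {
  # 2 letters x 2 fonts, 1-dim activations
  mat <- matrix(c(0, 10,   # f1: a=0,  b=10
                  4, 20),  # f2: a=4,  b=20
                ncol = 1)
  acts <- toy_acts(mat, c("a", "b", "a", "b"), c("f1", "f1", "f2", "f2"))
  r <- categ_convention_rdm(acts)
  # templates: a -> 2, b -> 15
  # D(a,b) = mean(|0-15|, |4-15|) = 13 ; D(b,a) = mean(|10-2|, |20-2|) = 13
  expect_equal(unclass(r)["b", "a"], 13, tolerance = 1e-12)
  # asymmetric directions average: D(a,b)=13, D(b,a)=13 here; build a case
  # where the conventions disagree
  rs <- search_convention_rdm(acts)  # mean(10, 16) = 13 -- equal here
  mat2 <- matrix(c(0, 10, 8, 2), ncol = 1)
  acts2 <- toy_acts(mat2, c("a", "b", "a", "b"), c("f1", "f1", "f2", "f2"))
  v_search <- unclass(search_convention_rdm(acts2))["b", "a"]
  v_categ <- unclass(categ_convention_rdm(acts2))["b", "a"]
  # search: mean(|0-10|, |8-2|) = 8 ; categ templates a=4, b=6:
  # D(a,b)=mean(|0-6|,|8-6|)=4, D(b,a)=mean(|10-4|,|2-4|)=4 -> 4
  expect_equal(v_search, 8, tolerance = 1e-12)
  expect_equal(v_categ, 4, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(v_search, v_categ)))

  # identical fonts: template equals every exemplar, self-dissimilarity 0
  same <- toy_acts(rbind(c(1, 2), c(7, 1), c(1, 2), c(7, 1)),
                   c("a", "b", "a", "b"), c("f1", "f1", "f2", "f2"))
  rsame <- categ_convention_rdm(same)
  expect_equal(unname(attr(rsame, "self_dissimilarity")), c(0, 0))
})

test_that("image-level RDMs are plain all-pairs distances", {
  mat <- rbind(c(0, 0), c(3, 4), c(0, 0))
  acts <- toy_acts(mat, c("a", "b", "a"), c("f1", "f1", "f2"))
  r <- image_level_rdm(acts)
  expect_equal(nrow(r), 3)
  expect_equal(unclass(r)[2, 1], 5)
  expect_equal(unclass(r)[3, 1], 0)   # duplicate images at distance 0
  expect_equal(unclass(r)[3, 2], 5)
  big <- toy_acts(matrix(rnorm(20 * 4), 20, 4),
                  rep(letters[1:5], 4), rep(paste0("f", 1:4), each = 5))
  expect_equal(dim(image_level_rdm(big)), c(20, 20), ignore_attr = TRUE)
  expect_error(image_level_rdm(toy_acts(mat[1, , drop = FALSE], "a", "f")),
               ">= 2")
})

test_that("categorical RDM has one-hot geometry and rank-correlates as expected", {
  labs <- c("a", "a", "b", "c", "b")
  r <- categorical_rdm(labs)
  expect_equal(unclass(r)[2, 1], 0)          # same letter
  expect_equal(unclass(r)[3, 1], sqrt(2))    # different letters
  v <- as.numeric(lower_triangle(r))
  expect_setequal(unique(v), c(0, sqrt(2)))
  expect_equal(spearman_rdm(v, v), 1)
  # complement reverses the ranks
  expect_equal(spearman_rdm(v, max(v) - v), -1)
})

test_that("letter-preferring selection separates signal and flags degenerate features", {
  set.seed(31)
  nL <- 40; nO <- 60
  L <- cbind(rnorm(nL, 5), rnorm(nL, 0), 0)   # f1 letter-preferring
  O <- cbind(rnorm(nO, 0), rnorm(nO, 0), 0)   # f3 all-zero
  mask <- select_letter_preferring(L, O, alpha = 0.05)
  expect_true(mask$keep[1])
  expect_false(mask$keep[3])
  expect_true(mask$degenerate[3])
  # matches R's own Welch test feature-by-feature
  tt <- t.test(L[, 2], O[, 2])
  expect_equal(mask$p_value[2], tt$p.value, tolerance = 1e-10)
  expect_equal(unname(mask$statistic[2]), unname(tt$statistic),
               tolerance = 1e-10)
  expect_error(select_letter_preferring(L[1, , drop = FALSE], O), "2 samples")
})

test_that("random matched masks are size-matched, pool-restricted and seed-stable", {
  keep <- c(rep(TRUE, 5), rep(FALSE, 15))
  mask <- structure(list(keep = keep), class = "feature_mask")
  pool <- c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 5))
  ms <- random_matched_masks(mask, pool, n_samples = 100, seed = 7)
  expect_length(ms, 100)
  expect_true(all(vapply(ms, sum, numeric(1)) == 5))
  expect_true(all(vapply(ms, function(m) all(which(m) %in% 6:15),
                         logical(1))))
  expect_identical(ms, random_matched_masks(mask, pool, 100, seed = 7))
  # pool exactly the mask size: every sample is the whole pool
  small_pool <- c(rep(FALSE, 5), rep(TRUE, 5), rep(FALSE, 10))
  ms2 <- random_matched_masks(mask, small_pool, n_samples = 3, seed = 1)
  expect_true(all(vapply(ms2, function(m) identical(which(m), 6:10),
                         logical(1))))
  expect_error(random_matched_masks(mask, c(rep(TRUE, 4), rep(FALSE, 16)),
                                    1, 1), "pool")
})

test_that("a full-feature mask reproduces the full-space RDMs", {
  set.seed(41)
  mat <- matrix(rnorm(8 * 6), 8, 6)
  acts <- toy_acts(mat, rep(letters[1:4], 2), rep(c("f1", "f2"), each = 4))
  full_mask <- rep(TRUE, 6)
  expect_equal(unclass(search_convention_rdm(mask_activations(acts, full_mask))),
               unclass(search_convention_rdm(acts)))
  expect_equal(unclass(categ_convention_rdm(mask_activations(acts, full_mask))),
               unclass(categ_convention_rdm(acts)))
})

test_that("intuitive feature RDMs follow Euclidean count-space distances", {
  tab <- data.frame(letter = c("a", "b", "c"),
                    rbind(c(1, rep(0, 16)),
                          c(0, 1, rep(0, 15)),
                          c(0, 0, 1, rep(0, 14))))
  r <- intuitive_rdm(tab)
  expect_equal(unclass(r)["b", "a"], sqrt(2), tolerance = 1e-12)

  set.seed(51)
  counts <- matrix(rpois(3 * 17, 1), 3, 17)
  tab2 <- data.frame(letter = c("a", "b", "c"), counts)
  r2 <- intuitive_rdm(tab2)
  expect_equal(unclass(r2)["c", "b"],
               sqrt(sum((counts[3, ] - counts[2, ])^2)), tolerance = 1e-12)
  # identical rows -> zero distance
  tab3 <- data.frame(letter = c("a", "b"), rbind(counts[1, ], counts[1, ]))
  expect_equal(unclass(intuitive_rdm(tab3))["b", "a"], 0)
  expect_error(intuitive_rdm(data.frame(letter = "a", x = -1)),
               "non-negative")
})

test_that("the shipped synthetic intuitive-feature example builds a full-alphabet RDM", {
  path <- system.file("extdata", "intuitive_features_synthetic.csv",
                      package = "lettersim")
  tab <- read.csv(path)
  expect_equal(nrow(tab), 26)
  r <- intuitive_rdm(tab)
  expect_equal(dim(unclass(r)), c(26, 26))
  expect_length(lower_triangle(r), 325)
  expect_true(all(as.numeric(lower_triangle(r)) >= 0))
})
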