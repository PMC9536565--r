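# 5x7 dot-matrix templates for the lowercase alphabet; "fonts" are
# parametric perturbations (scale, slant, stroke, jitter) of these.
glyph_templates <- function() {
  tpl <- c(
    a = ".....|.....|.###.|....#|.####|#...#|.####",
    b = "#....|#....|####.|#...#|#...#|#...#|####.",
    c = ".....|.....|.####|#....|#....|#....|.####",
    d = "....#|....#|.####|#...#|#...#|#...#|.####",
    e = ".....|.....|.###.|#...#|#####|#....|.####",
    f = "..##.|.#...|####.|.#...|.#...|.#...|.#...",
    g = ".....|.####|#...#|#...#|.####|....#|.###.",
    h = "#....|#....|####.|#...#|#...#|#...#|#...#",
    i = "..#..|.....|.##..|..#..|..#..|..#..|.###.",
    j = "...#.|.....|..##.|...#.|...#.|#..#.|.##..",
    k = "#....|#....|#..#.|#.#..|##...|#.#..|#..#.",
    l = ".##..|..#..|..#..|..#..|..#..|..#..|.###.",
    m = ".....|.....|##.#.|#.#.#|#.#.#|#.#.#|#.#.#",
    n = ".....|.....|####.|#...#|#...#|#...#|#...#",
    o = ".....|.....|.###.|#...#|#...#|#...#|.###.",
    p = ".....|####.|#...#|#...#|####.|#....|#....",
    q = ".....|.####|#...#|#...#|.####|....#|....#",
    r = ".....|.....|#.##.|##...|#....|#....|#....",
    s = ".....|.....|.####|#....|.###.|....#|####.",
    t = ".#...|.#...|####.|.#...|.#...|.#..#|..##.",
    u = ".....|.....|#...#|#...#|#...#|#...#|.####",
    v = ".....|.....|#...#|#...#|#...#|.#.#.|..#..",
    w = ".....|.....|#...#|#.#.#|#.#.#|#.#.#|.#.#.",
    x = ".....|.....|#...#|.#.#.|..#..|.#.#.|#...#",
    y = ".....|#...#|#...#|#...#|.####|....#|.###.",
    z = ".....|.....|#####|...#.|..#..|.#...|#####")
  lapply(tpl, function(s) {
    rows <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], "")
    t(vapply(rows, function(r) r == "#", logical(5)))
  })
}

#' Render a synthetic glyph set
#'
#' Rasterizes dot-matrix letter templates at `image_size`, with each
#' "font" a deterministic parametric perturbation: isotropic scale, slant
#' (horizontal shear), stroke width (binary dilation) and sub-pixel
#' translation jitter. Same seed, same pixels. The full behavioral
#' stimulus scale is 26 letters by 20 fonts (520 images).
#'
#' @param alphabet letters to render (subset of a-z).
#' @param n_fonts number of synthetic fonts.
#' @param image_size output raster side length (default 24; must fit the
#'   7-row template, so >= 8).
#' @param seed integer seed.
#' @return a `glyph_set`: list with `alphabet`, `fonts`, `images` (4-D
#'   binary array letter x font x row x col) and `font_params`.
#' @export
render_glyphs <- function(alphabet = letters, n_fonts = 20,
                          image_size = 24, seed = 1L) {
  if (n_fonts < 1) stop("n_fonts must be >= 1", call. = FALSE)
  if (image_size < 8) stop("image size too small to render strokes",
                           call. = FALSE)
  tpl <- glyph_templates()
  alphabet <- as.character(alphabet)
  if (!all(alphabet %in% names(tpl))) {
    stop("alphabet must be lowercase a-z letters", call. = FALSE)
  }
  rng <- seeded_rng(seed)
  fonts <- paste0("font", sprintf("%02d", seq_len(n_fonts)))
  params <- data.frame(
    font = fonts,
    scale = 0.75 + 0.25 * rng$runif(n_fonts),
    slant = -0.25 + 0.5 * rng$runif(n_fonts),
    stroke = 1L + (rng$runif(n_fonts) > 0.5),
    dx = 0.06 * (rng$runif(n_fonts) - 0.5),
    dy = 0.06 * (rng$runif(n_fonts) - 0.5))
  imgs <- array(0,
                dim = c(length(alphabet), n_fonts, image_size, image_size),
                dimnames = list(alphabet, fonts, NULL, NULL))
  px <- (seq_len(image_size) - 0.5) / image_size
  for (f in seq_len(n_fonts)) {
    p <- params[f, ]
    for (a in seq_along(alphabet)) {
      bm <- tpl[[alphabet[a]]]
      # inverse-map each output pixel into template coordinates
      out <- matrix(0, image_size, image_size)
      for (r in seq_len(image_size)) {
        v <- (px[r] - 0.5 - p$dy) / p$scale + 0.5
        u <- (px - 0.5 - p$dx - p$slant * (px[r] - 0.5)) / p$scale + 0.5
        ri <- floor(v * 7) + 1
        ci <- floor(u * 5) + 1
        ok <- ri >= 1 & ri <= 7 & ci >= 1 & ci <= 5
        ric <- pmax(pmin(ri, 7L), 1L)
        cic <- pmax(pmin(ci, 5L), 1L)
        if (any(ok)) out[r, ok] <- bm[cbind(ric, cic)][ok]
      }
      if (p$stroke > 1L) out <- dilate_cross(out)
      imgs[a, f, , ] <- out
    }
  }
  structure(list(alphabet = alphabet, fonts = fonts, images = imgs,
                 font_params = params, image_size = image_size,
                 seed = as.integer(seed)),
            class = "glyph_set")
}

dilate_cross <- function(m) {
  n <- nrow(m)
  out <- m
  out[-1, ] <- pmax(out[-1, ], m[-n, ])
  out[-n, ] <- pmax(out[-n, ], m[-1, ])
  out[, -1] <- pmax(out[, -1], m[, -n])
  out[, -n] <- pmax(out[, -n], m[, -1])
  out
}

#' @export
#' @method print glyph_set
print.glyph_set <- function(x, ...) {
  cat(sprintf("glyph_set: %d letters x %d fonts, %dx%d rasters (seed %d)\n",
              length(x$alphabet), length(x$fonts), x$image_size,
              x$image_size, x$seed))
  invisible(x)
}

#' Pixelwise ground-truth RDM of a glyph set
#'
#' Mean across fonts of within-font Euclidean pixel distances between
#' letters, normalized to \[0, 1\] by the maximum entry. This latent
#' structure is what the behavioral simulators encode into reaction
#' times.
#'
#' @param glyphs a `glyph_set`.
#' @return an `rdm` over the glyph alphabet with entries in \[0, 1\].
#' @export
truth_rdm_from_glyphs <- function(glyphs) {
  nl <- length(glyphs$alphabet); nf <- length(glyphs$fonts)
  acc <- matrix(0, nl, nl)
  for (f in seq_len(nf)) {
    x <- matrix(glyphs$images[, f, , ], nrow = nl)
    acc <- acc + as.matrix(stats::dist(x))
  }
  m <- acc / nf
  mx <- max(m)
  if (mx > 0) m <- m / mx
  rdm(m, glyphs$alphabet, signed = FALSE)
}

#' Ground-truth simulation parameters
#'
#' Bundles a latent similarity structure with the generative parameters of
#' both behavioral simulators. Defaults describe realistic crowdsourced
#' letter RT data: ~600 ms baseline responses, lognormal search RTs with
#' ~25% residual variability and up to ~2x slowing for the most similar
#' pairs, per-session speed offsets, ~1% attentional lapses producing
#' far-tail RTs, and error rates rising with similarity to a ~97% mean
#' accuracy.
#'
#' @param rdm latent `rdm` over the alphabet, entries scaled to \[0, 1\]
#'   (e.g. from [truth_rdm_from_glyphs()]).
#' @param search named list of search RT parameters: `baseline_log_rt`
#'   (log ms), `hit_offset_sd`, `sim_slope`, `resid_sd` (all log-RT
#'   units), `lapse_rate`, `error_base`, `error_slope`.
#' @param categ named list of categorization parameters (ms scale):
#'   `baseline_rt`, `hit_intercept_sd`, `sim_slope`, `resid_sd`,
#'   `error_base`, `error_slope`.
#' @param seed integer seed stored for provenance.
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(rdm,
                         search = list(),
                         categ = list(),
                         seed = 1L) {
  stopifnot(inherits(rdm, "rdm"))
  v <- unclass(rdm)[lower.tri(rdm)]
  if (any(v < 0) || max(v) > 1 + 1e-8) {
    stop("latent RDM entries must lie in [0, 1]", call. = FALSE)
  }
  s_def <- list(baseline_log_rt = log(600), hit_offset_sd = 0.15,
                sim_slope = 0.7, resid_sd = 0.25, lapse_rate = 0.01,
                error_base = 0.01, error_slope = 0.06)
  c_def <- list(baseline_rt = 600, hit_intercept_sd = 60,
                sim_slope = 200, resid_sd = 120,
                error_base = 0.01, error_slope = 0.08)
  search <- utils::modifyList(s_def, search)
  categ <- utils::modifyList(c_def, categ)
  sds <- c(search$hit_offset_sd, search$resid_sd,
           categ$hit_intercept_sd, categ$resid_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0", call. = FALSE)
  if (search$lapse_rate < 0 || search$lapse_rate > 1) {
    stop("lapse_rate must be a probability", call. = FALSE)
  }
  structure(list(rdm = rdm, search = search, categ = categ,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default ground truth built from synthetic glyphs
#'
#' Convenience wrapper: renders a glyph set, derives the pixelwise latent
#' RDM, and attaches default behavioral parameters. The default test
#' scale (6 letters, 6 fonts) keeps mixed-model fits fast; pass the full
#' alphabet and 20 fonts for the behavioral-scale configuration.
#'
#' @param alphabet letters (default first 6).
#' @param n_fonts fonts (default 6).
#' @param image_size raster size.
#' @param seed integer seed.
#' @return a `ground_truth` with an attached `glyphs` attribute.
#' @export
default_ground_truth <- function(alphabet = letters[1:6], n_fonts = 6,
                                 image_size = 24, seed = 1L) {
  glyphs <- render_glyphs(alphabet, n_fonts, image_size, seed)
  gt <- ground_truth(truth_rdm_from_glyphs(glyphs), seed = seed)
  attr(gt, "glyphs") <- glyphs
  gt
}

truth_similarity <- function(truth) {
  1 - unclass(truth$rdm)  # similarity = 1 - normalized dissimilarity
}

#' Simulate a visual-search trial table
#'
#' Generative inverse of the search pipeline: per HIT a Gaussian speed
#' offset; per trial log RT = baseline + offset + slope * similarity +
#' Gaussian residual (similar pairs are searched more slowly), with a
#' small lapse probability replacing the response by a far-tail RT, and
#' error probability increasing with similarity.
#'
#' @param truth a `ground_truth`.
#' @param design list of `search_hit_spec` from
#'   [generate_search_designs()].
#' @param seed integer seed.
#' @return a search trial data.frame (`hit_id`, `letter_a`, `letter_b`,
#'   `target`, `font`, `correct`, `rt_ms`).
#' @export
simulate_search <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  S <- truth_similarity(truth)
  p <- truth$search
  check_design_alphabet(design, rownames(truth$rdm))
  rng <- seeded_rng(seed)
  out <- vector("list", length(design))
  for (h in seq_along(design)) {
    d <- design[[h]]
    nt <- nrow(d$trials)
    offset <- rng$rnorm(1, 0, p$hit_offset_sd)
    sim <- S[cbind(d$trials$letter_a, d$trials$letter_b)]
    logrt <- p$baseline_log_rt + offset + p$sim_slope * sim +
      rng$rnorm(nt, 0, p$resid_sd)
    lapse <- rng$runif(nt) < p$lapse_rate
    if (any(lapse)) {
      logrt[lapse] <- p$baseline_log_rt + offset +
        log(5 + 25 * rng$runif(sum(lapse)))
    }
    p_err <- pmin(pmax(p$error_base + p$error_slope * sim, 0), 0.5)
    correct <- rng$runif(nt) >= p_err
    out[[h]] <- data.frame(
      hit_id = d$hit_id, letter_a = d$trials$letter_a,
      letter_b = d$trials$letter_b, target = d$trials$target,
      font = d$font, correct = correct, rt_ms = exp(logrt),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate a categorization trial table
#'
#' Non-match trials get RT = baseline + HIT intercept + slope *
#' similarity(target, presented) + residual (letters similar to the held
#' target are rejected more slowly); match trials sit at baseline.
#' Errors rise with similarity on non-match trials.
#'
#' @param truth a `ground_truth`.
#' @param design list of `categ_hit_spec` from
#'   [generate_categ_designs()].
#' @param seed integer seed.
#' @return a categorization trial data.frame (`hit_id`, `block`,
#'   `target`, `presented`, `font`, `match`, `correct`, `rt_ms`).
#' @export
simulate_categ <- function(truth, design, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  S <- truth_similarity(truth)
  p <- truth$categ
  rng <- seeded_rng(seed)
  out <- vector("list", length(design))
  for (h in seq_along(design)) {
    d <- design[[h]]
    tr <- d$trials
    nt <- nrow(tr)
    intercept <- rng$rnorm(1, 0, p$hit_intercept_sd)
    sim <- ifelse(tr$match, 0, S[cbind(tr$target, tr$presented)])
    rt <- p$baseline_rt + intercept + p$sim_slope * sim +
      rng$rnorm(nt, 0, p$resid_sd)
    rt <- pmax(rt, 150)
    p_err <- pmin(pmax(p$error_base + p$error_slope * sim, 0), 0.5)
    correct <- rng$runif(nt) >= p_err
    out[[h]] <- data.frame(
      hit_id = d$hit_id, block = tr$block, target = tr$target,
      presented = tr$presented, font = tr$font, match = tr$match,
      correct = correct, rt_ms = rt, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

check_design_alphabet <- function(design, alphabet) {
  ls <- unique(unlist(lapply(design, function(d) {
    c(d$trials$letter_a, d$trials$letter_b)
  })))
  if (!all(ls %in% alphabet)) {
    stop("design alphabet does not match the ground truth", call. = FALSE)
  }
  invisible(design)
}

#' Simulate an untrained feature hierarchy over glyphs
#'
#' A cascade of random local filtering: each stage convolves the previous
#' stage's maps with random 3x3 kernels across channels, applies half-wave
#' rectification (ReLU), and 2x average-downsamples; each stage's maps are
#' then spatially sum-pooled into an `activation_set`. This is a random-
#' weights stand-in for a feature hierarchy: no learning, but the same
#' pooling and RDM conventions apply.
#'
#' @param glyphs a `glyph_set`.
#' @param n_stages number of cascade stages (default 3).
#' @param n_features output channels per stage (default 12).
#' @param seed integer seed; the full hierarchy is reproducible.
#' @return named list of `activation_set`, one per stage.
#' @export
simulate_feature_hierarchy <- function(glyphs, n_stages = 3,
                                       n_features = 12, seed = 1L) {
  if (n_stages < 1) stop("n_stages must be >= 1", call. = FALSE)
  rng <- seeded_rng(seed)
  nl <- length(glyphs$alphabet); nf <- length(glyphs$fonts)
  letter <- rep(glyphs$alphabet, times = nf)
  font <- rep(glyphs$fonts, each = nl)
  # current: list over images of 3-D arrays (channel, h, w)
  current <- vector("list", nl * nf)
  k <- 0L
  for (f in seq_len(nf)) for (a in seq_len(nl)) {
    k <- k + 1L
    current[[k]] <- array(glyphs$images[a, f, , ],
                          dim = c(1, glyphs$image_size, glyphs$image_size))
  }
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    c_in <- dim(current[[1]])[1]
    kernels <- array(rng$rnorm(n_features * c_in * 9, 0, 1 / sqrt(c_in * 9)),
                     dim = c(n_features, c_in, 3, 3))
    current <- lapply(current, function(x) stage_forward(x, kernels))
    stages[[s]] <- pool_feature_maps(current, letter, font,
                                     stage = sprintf("stage%d", s))
  }
  names(stages) <- sprintf("stage%d", seq_len(n_stages))
  stages
}

# one cascade stage: multi-channel 3x3 convolution ("same" padding),
# ReLU, then 2x average pooling
stage_forward <- function(x, kernels) {
  c_in <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  n_out <- dim(kernels)[1]
  out <- array(0, dim = c(n_out, h, w))
  for (o in seq_len(n_out)) {
    acc <- matrix(0, h, w)
    for (ci in seq_len(c_in)) {
      acc <- acc + conv3x3(matrix(x[ci, , ], h, w), kernels[o, ci, , ])
    }
    out[o, , ] <- pmax(acc, 0)
  }
  h2 <- floor(h / 2); w2 <- floor(w / 2)
  ds <- array(0, dim = c(n_out, h2, w2))
  for (o in seq_len(n_out)) {
    m <- matrix(out[o, , ], h, w)
    ds[o, , ] <- (m[seq_len(h2) * 2 - 1, seq_len(w2) * 2 - 1] +
                  m[seq_len(h2) * 2, seq_len(w2) * 2 - 1] +
                  m[seq_len(h2) * 2 - 1, seq_len(w2) * 2] +
                  m[seq_len(h2) * 2, seq_len(w2) * 2]) / 4
  }
  ds
}

conv3x3 <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    out <- out + k[dr + 2, dc + 2] *
      pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  out
}
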