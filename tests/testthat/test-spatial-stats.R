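test_that("Bray-Curtis handles the textbook cases", {
  m <- rbind(a = c(10, 0), b = c(5, 5))
  expect_equal(bray_curtis(m)["a", "b"], 0.5)
  m2 <- rbind(c(10, 5, 0), c(10, 5, 0))
  expect_equal(bray_curtis(m2)[1, 2], 0)
  m3 <- rbind(c(10, 5, 0, 0), c(0, 0, 3, 7))
  expect_equal(bray_curtis(m3)[1, 2], 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "zero total cover")
  # single species at constant cover: all distances zero
  expect_true(all(bray_curtis(matrix(20, 5, 1)) == 0))
})

test_that("Euclidean distance reduces to |difference| for counts", {
  expect_equal(euclidean_dist(rbind(c(0, 0), c(3, 4)))[1, 2], 5)
  expect_equal(euclidean_dist(c(2, 7))[1, 2], 5)
  expect_error(euclidean_dist(c(1, NA, 3)), "missing")
})

test_that("Sturges classing of a 30-point 0.3 m transect gives the
           printed 10 classes", {
  cls <- sturges_classes((0:29) * 0.3)
  expect_equal(cls$k, 10)
  expect_equal(cls$boundaries[1, ], c(lower = 0, upper = 0.72))
  expect_equal(cls$boundaries[2, ], c(lower = 0.72, upper = 1.56))
  expect_equal(cls$boundaries[10, ], c(lower = 7.44, upper = 8.28))
  # the two longest separations (8.4 m, 8.7 m) fall beyond the last class
  excl <- cls$pair_distances[!cls$included]
  expect_true(all(excl > 8.28))
  expect_equal(sort(unique(round(excl, 2))), c(8.4, 8.7))
  expect_error(sturges_classes(rep(1, 5)), "equal")
})

test_that("Sturges boundaries are translation invariant and scale with
           spacing", {
  base <- sturges_classes((0:19) * 0.5)
  shift <- sturges_classes((0:19) * 0.5 + 100)
  expect_equal(base$boundaries, shift$boundaries)
  scaled <- sturges_classes((0:19) * 1.0)
  expect_equal(scaled$boundaries, base$boundaries * 2)
})

test_that("mantel_r equals a brute-force Pearson oracle on small instances", {
  set.seed(21)
  d_self <- as.matrix(dist(rnorm(6)))
  expect_equal(mantel_r(d_self, d_self), 1)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    d1 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    d2 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
    v1 <- d1[lower.tri(d1)]
    v2 <- d2[lower.tri(d2)]
    expect_equal(mantel_r(d1, d2), brute_pearson(v1, v2), tolerance = 1e-12)
    # linear invariance
    expect_equal(mantel_r(d1, 2 + 3 * d1), 1, tolerance = 1e-12)
  }
})

test_that("mantel_r agrees with the vegan Mantel statistic", {
  set.seed(22)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  d2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
  expect_equal(mantel_r(d1, d2), unname(ref$statistic), tolerance = 1e-10)
})

test_that("a monotone gradient yields a positive first class and negative
           far classes", {
  pos <- (0:29) * 0.3
  cls <- sturges_classes(pos)
  d <- as.matrix(dist(pos)) # dissimilarity = separation itself
  set.seed(23)
  cg <- mantel_correlogram(d, cls, n_perm = 199)
  expect_gt(cg$classes$r[1], 0)
  expect_true(cg$classes$significant[1])
  expect_lt(cg$classes$r[10], 0)
  expect_equal(cg$pattern, "patchy")
})

test_that("correlogram r values are permutation-free and p resolution
           follows n_perm", {
  pos <- (0:29) * 0.3
  cls <- sturges_classes(pos)
  set.seed(24)
  d <- as.matrix(dist(rnorm(30)))
  cg1 <- mantel_correlogram(d, cls, n_perm = 99)
  cg2 <- mantel_correlogram(d, cls, n_perm = 199)
  expect_equal(cg1$classes$r, cg2$classes$r)
  expect_true(all(cg1$classes$p >= 1 / 100))
  # degenerate matrix: no coefficients, no pattern
  cg0 <- mantel_correlogram(matrix(1, 30, 30) - diag(30), cls, n_perm = 99)
  expect_true(all(is.na(cg0$classes$r)))
  expect_equal(cg0$pattern, "none")
})

test_that("pattern classification follows the short-distance rule", {
  fake <- function(r, sig) {
    structure(list(classes = data.frame(
      class = seq_along(r), lower = 0, upper = 1, n_pairs = 10,
      r = r, p = 0.5, p_corrected = ifelse(sig, 0.01, 0.5),
      significant = sig
    ), alpha = 0.05), class = "mantel_correlogram")
  }
  r <- c(0.5, 0.2, 0, -0.2, -0.3, -0.4)
  expect_equal(classify_pattern(fake(r, rep(FALSE, 6))), "none")
  expect_equal(classify_pattern(fake(r, c(TRUE, rep(FALSE, 5)))), "patchy")
  # significance only at a long distance is autocorrelation, not patchiness
  expect_equal(classify_pattern(fake(r, c(rep(FALSE, 5), TRUE))),
               "autocorrelated")
  # significant positive head but no decay to zero or below
  expect_equal(classify_pattern(fake(rep(0.3, 6), c(TRUE, rep(FALSE, 5)))),
               "autocorrelated")
})

test_that("Moran's I detects gradients and alternation and matches a
           brute-force oracle", {
  pos <- (0:29) * 0.3
  set.seed(25)
  grad <- global_morans_i(pos + rnorm(30, 0, 0.1), pos, n_perm = 199)
  expect_gt(grad$i, 0)
  expect_lt(grad$p, 0.05)
  alt <- global_morans_i(rep(c(0, 10), 15), pos, n_perm = 99)
  expect_lt(alt$i, -1 / 29)
  # textbook double sum, written out element by element
  moran_oracle <- function(x, p) {
    n <- length(x)
    z <- x - mean(x)
    num <- 0; s0 <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      w <- 1 / abs(p[i] - p[j])
      num <- num + w * z[i] * z[j]
      s0 <- s0 + w
    }
    n / s0 * num / sum(z^2)
  }
  for (k in 1:5) {
    vals <- rnorm(12)
    ours <- global_morans_i(vals, pos[1:12], n_perm = 0)
    expect_equal(ours$i, moran_oracle(vals, pos[1:12]), tolerance = 1e-12)
    expect_equal(ours$expectation, -1 / 11)
  }
  expect_error(global_morans_i(rep(1, 10), 1:10), "constant")
})
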