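#' Bray-Curtis dissimilarity between plots
#'
#' BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i) on raw percent covers; symmetric
#' with zero diagonal, values in \[0, 1\]. Computed with [vegan::vegdist()].
#'
#' @param cover_matrix Plot x species matrix of non-negative covers; every
#'   plot must have positive total cover.
#' @return Square symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(cover_matrix) {
  cover_matrix <- as.matrix(cover_matrix)
  if (any(cover_matrix < 0)) stop("covers must be non-negative")
  if (any(rowSums(cover_matrix) <= 0)) {
    stop("plot(s) with zero total cover: Bray-Curtis undefined")
  }
  as.matrix(vegan::vegdist(cover_matrix, method = "bray"))
}

#' Euclidean distance between plot rows
#'
#' Standard Euclidean distance on a plot x variable matrix. For a single
#' column (e.g. herbivore counts) this reduces to the absolute difference.
#'
#' @param x Numeric matrix or vector (treated as one column); no missing
#'   values allowed in retained rows.
#' @return Square symmetric distance matrix.
#' @export
euclidean_dist <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values in input rows")
  as.matrix(stats::dist(x, method = "euclidean"))
}

#' Sturges-rule distance classes for transect positions
#'
#' The number of classes is K = ceiling(1 + log2(N_pairs)) with N_pairs the
#' number of pairwise distances, n(n-1)/2. Classes have common width
#' w = (d_max - d_min)/K and are centered at d_min + k*w (k = 0..K-1) with
#' half-width w/2; the first class is truncated at 0 and pairs beyond the last
#' upper boundary are excluded. For a 30-plot transect at 0.3 m spacing this
#' yields 10 classes with boundaries 0-0.72 m up to 7.44-8.28 m, dropping the
#' two longest separations.
#'
#' @param positions Numeric vector of plot positions along the transect (m);
#'   at least three, not all equal.
#' @return An object of class `distance_class_set`: list with `k`,
#'   `boundaries` (matrix of lower/upper per class), `pair_distances`,
#'   `membership` (n_pairs x K logical), `included` (pair not beyond the last
#'   class), and the pair index matrix `pairs`.
#' @export
sturges_classes <- function(positions) {
  positions <- as.numeric(positions)
  n <- length(positions)
  if (n < 3L) stop("need at least three positions")
  d <- stats::dist(positions)
  if (max(d) <= 0) stop("all positions equal: no distance structure")
  np <- length(d)
  k <- ceiling(1 + log2(np))
  w <- (max(d) - min(d)) / k
  centers <- min(d) + (seq_len(k) - 1) * w
  lower <- pmax(centers - w / 2, 0)
  upper <- centers + w / 2
  dv <- as.vector(d)
  eps <- 1e-9
  membership <- vapply(seq_len(k), function(j) {
    lo <- if (j == 1L) -eps else lower[j]
    dv > lo + eps * (j > 1) & dv <= upper[j] + eps
  }, logical(np))
  membership <- matrix(membership, nrow = np, ncol = k)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  # dist() unfolds column-wise lower triangle; rebuild matching pair order
  ij <- do.call(rbind, lapply(seq_len(n - 1), function(i) cbind(i, (i + 1):n)))
  ord <- order(ij[, 1], ij[, 2])
  structure(
    list(
      k = k, boundaries = cbind(lower = lower, upper = upper),
      pair_distances = dv, membership = membership,
      included = rowSums(membership) > 0, pairs = ij[ord, , drop = FALSE]
    ),
    class = "distance_class_set"
  )
}

#' @export
print.distance_class_set <- function(x, ...) {
  cat("Sturges distance classes: K =", x$k, "\n")
  b <- round(x$boundaries, 3)
  cat(paste0("  [", b[, 1], ", ", b[, 2], "] m (n_pairs = ",
             colSums(x$membership), ")"), sep = "\n")
  cat("pairs beyond last class:", sum(!x$included), "\n")
  invisible(x)
}

# Unfold the upper triangle of a square matrix in dist() pair order
# (pairs (1,2), (1,3), ..., (1,n), (2,3), ...).
upper_vec <- function(m) {
  m[lower.tri(m)]
}

#' Mantel statistic between two distance matrices
#'
#' Pearson correlation between the unfolded off-diagonal entries of two
#' square symmetric matrices, optionally restricted to a pair mask. This is
#' the raw Mantel r; the correlogram wrapper flips the sign when the second
#' matrix is a binary class-membership indicator so that within-class
#' similarity reads as positive.
#'
#' @param d1,d2 Square symmetric matrices of identical order.
#' @param mask Logical vector over the n(n-1)/2 pairs (dist order), or NULL
#'   for all pairs.
#' @return Mantel r in \[-1, 1\], or `NA` when fewer than 3 pairs are masked
#'   in or either vector is constant.
#' @export
mantel_r <- function(d1, d2, mask = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2)) || nrow(d1) != ncol(d1)) {
    stop("matrices must be square and of identical order")
  }
  v1 <- upper_vec(d1); v2 <- upper_vec(d2)
  if (is.null(mask)) mask <- rep(TRUE, length(v1))
  v1 <- v1[mask]; v2 <- v2[mask]
  if (length(v1) < 3L) return(NA_real_)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Mantel correlogram over Sturges distance classes
#'
#' For each distance class in order of increasing distance, computes the
#' Mantel correlation between the dissimilarity matrix and the binary
#' class-membership indicator (sign flipped, so r > 0 means plots within the
#' class are more similar than average), a two-sided permutation p-value
#' (simultaneous row/column permutation of `d`), and a progressive Holm
#' correction (p of class k multiplied by k, capped at 1). Classes are
#' evaluated in order while they contain at least one pair; pairs beyond the
#' last class boundary are excluded throughout.
#'
#' @param d Square symmetric dissimilarity matrix among plots.
#' @param classes A `distance_class_set` from [sturges_classes()].
#' @param n_perm Number of permutations (>= 99), default 999.
#' @param alpha Significance level for the pattern classification.
#' @return Object of class `mantel_correlogram`: data frame `classes` with
#'   columns class, lower, upper, n_pairs, r, p, p_corrected, significant;
#'   plus `pattern` from [classify_pattern()].
#' @export
mantel_correlogram <- function(d, classes, n_perm = 999, alpha = 0.05) {
  stopifnot(inherits(classes, "distance_class_set"))
  if (n_perm < 99) stop("n_perm must be at least 99")
  d <- as.matrix(d)
  n <- nrow(d)
  if (nrow(classes$membership) != n * (n - 1) / 2) {
    stop("class set does not match matrix order")
  }
  incl <- classes$included
  npair <- colSums(classes$membership)
  # evaluate classes in order while non-empty
  k_eval <- if (any(npair == 0)) min(which(npair == 0)) - 1L else classes$k
  dv <- upper_vec(d)[incl]
  m <- classes$membership[incl, seq_len(k_eval), drop = FALSE]
  r_obs <- suppressWarnings(-as.vector(stats::cor(dv, m)))
  degenerate <- stats::sd(dv) == 0
  if (degenerate) r_obs <- rep(NA_real_, k_eval)

  p <- rep(NA_real_, k_eval)
  if (!degenerate) {
    exceed <- integer(k_eval)
    ut <- lower.tri(d) # upper_vec order
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      dp <- d[perm, perm][ut][incl]
      r_star <- suppressWarnings(-as.vector(stats::cor(dp, m)))
      exceed <- exceed + (abs(r_star) >= abs(r_obs) - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  p_corr <- pmin(1, p * seq_len(k_eval))
  tab <- data.frame(
    class = seq_len(classes$k),
    lower = classes$boundaries[, "lower"],
    upper = classes$boundaries[, "upper"],
    n_pairs = npair,
    r = c(r_obs, rep(NA_real_, classes$k - k_eval)),
    p = c(p, rep(NA_real_, classes$k - k_eval)),
    p_corrected = c(p_corr, rep(NA_real_, classes$k - k_eval))
  )
  tab$significant <- !is.na(tab$p_corrected) & tab$p_corrected <= alpha
  out <- structure(
    list(classes = tab, alpha = alpha, n_perm = n_perm, pattern = "none"),
    class = "mantel_correlogram"
  )
  out$pattern <- classify_pattern(out)
  out
}

#' @export
print.mantel_correlogram <- function(x, ...) {
  cat("Mantel correlogram (", x$n_perm, " permutations), pattern: ",
      x$pattern, "\n", sep = "")
  print(cbind(x$classes[, 1:4], round(x$classes[, 5:7], 4),
              sig = ifelse(x$classes$significant, "*", "")), row.names = FALSE)
  invisible(x)
}

#' @export
plot.mantel_correlogram <- function(x, ...) {
  tab <- x$classes
  mid <- (tab$lower + tab$upper) / 2
  plot(mid, tab$r, type = "b", xlab = "distance class midpoint (m)",
       ylab = "Mantel r", ylim = range(c(tab$r, 0), na.rm = TRUE), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::points(mid[tab$significant], tab$r[tab$significant], pch = 16)
  invisible(x)
}

#' Classify the spatial pattern of a correlogram
#'
#' `"autocorrelated"` when any class is significant after the progressive
#' correction; `"patchy"` when additionally one of the first two classes is
#' significant with a positive coefficient and some later class coefficient
#' drops to zero or below (similarity decaying from patch centers);
#' `"none"` otherwise.
#'
#' @param correlogram A `mantel_correlogram`.
#' @return One of `"patchy"`, `"autocorrelated"`, `"none"`.
#' @export
classify_pattern <- function(correlogram) {
  tab <- correlogram$classes
  sig <- which(tab$significant)
  if (length(sig) == 0) return("none")
  head_pos <- sig[sig <= 2 & tab$r[sig] > 0]
  if (length(head_pos) > 0) {
    later <- tab$r[seq_len(nrow(tab)) > min(head_pos)]
    if (any(!is.na(later) & later <= 0)) return("patchy")
  }
  "autocorrelated"
}

#' Global Moran's I with permutation inference
#'
#' Moran's I with inverse-distance weights w_ij = 1/d_ij (zero diagonal,
#' row-unstandardized). The null expectation is -1/(n-1); the permutation
#' p-value is two-sided around that expectation.
#'
#' @param values Numeric vector (>= 4 values, not all equal).
#' @param positions Plot positions along the transect (m), same length.
#' @param n_perm Number of permutations (default 999); `0` skips the test and
#'   returns `p = NA`.
#' @return List with `i`, `expectation`, `p`, `n_perm`.
#' @export
global_morans_i <- function(values, positions, n_perm = 999) {
  n <- length(values)
  stopifnot(length(positions) == n)
  if (n < 4L) stop("need at least 4 values")
  if (stats::sd(values) == 0) stop("constant values: Moran's I undefined")
  dmat <- as.matrix(stats::dist(positions))
  w <- 1 / dmat
  diag(w) <- 0
  if (any(!is.finite(w))) stop("coincident positions give infinite weights")
  s0 <- sum(w)
  stat <- function(x) {
    z <- x - mean(x)
    n / s0 * sum(w * tcrossprod(z)) / sum(z^2)
  }
  i_obs <- stat(values)
  e_i <- -1 / (n - 1)
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      i_star <- stat(sample(values))
      if (abs(i_star - e_i) >= abs(i_obs - e_i) - 1e-12) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(i = i_obs, expectation = e_i, p = p, n_perm = n_perm)
}
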