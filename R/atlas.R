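# Statistical shape atlas: mean-centred principal component analysis of the
# pooled shape vectors, with mode reconstruction and Bonferroni-corrected
# mode-wise group comparison.  PCA is computed on raw mm coordinates (units
# are homogeneous and size is signal) via the SVD of the centred data
# matrix; mode signs are fixed deterministically.

#' Build a PCA shape atlas
#'
#' Mean-centred principal component analysis of an N x p matrix of shape
#' vectors.  The top-K modes by eigenvalue are retained (K = 10 by default,
#' truncated with a warning when the data rank is lower).  Mode sign is
#' fixed by making the largest-magnitude loading positive.
#'
#' @param X numeric matrix, one shape vector per row.
#' @param K number of anatomical modes to retain.
#' @return A [ShapeAtlas-class].
#' @export
buildAtlas <- function(X, K = 10L) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 3L) stop("at least 3 shapes are required to build an atlas")
  if (any(!is.finite(X))) stop("shape vectors must be finite")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(N - 1L, ncol(X)))
  lambda <- sv$d[seq_len(ncol(sv$v))]^2 / (N - 1L)
  rank <- sum(lambda > max(lambda[1], 0) * 1e-12)
  if (rank < 1L) rank <- 1L
  if (rank < K) {
    warning("data rank ", rank, " is below K = ", K, "; truncating")
    K <- rank
  }
  K <- as.integer(K)
  modes <- sv$v[, seq_len(K), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (k in seq_len(K)) {
    i <- which.max(abs(modes[, k]))
    if (modes[i, k] < 0) modes[, k] <- -modes[, k]
  }
  scores <- Xc %*% modes
  new("ShapeAtlas", mean = mu, modes = modes,
      eigenvalues = lambda[seq_len(K)],
      allEigenvalues = pmax(lambda, 0),
      scores = scores, K = K)
}

#' Explained shape variance of the leading modes
#'
#' Fraction of total population shape variance captured by the first
#' \code{k} anatomical modes.
#'
#' @param atlas a [ShapeAtlas-class].
#' @param k number of leading modes (1 <= k <= K).
#' @return Fraction in [0, 1]; monotone non-decreasing in \code{k}.
#' @export
explainedVariance <- function(atlas, k = atlas@K) {
  if (k < 1L || k > atlas@K) stop("k must be between 1 and K = ", atlas@K)
  sum(atlas@eigenvalues[seq_len(k)]) / sum(atlas@allEigenvalues)
}

#' Project a shape vector onto the atlas modes
#'
#' Mode scores of a shape: \code{t(modes) \%*\% (shape - mean)}.
#'
#' @param atlas a [ShapeAtlas-class].
#' @param shape numeric shape vector of the atlas dimensionality.
#' @return Numeric length-K score vector.
#' @export
projectShape <- function(atlas, shape) {
  if (length(shape) != length(atlas@mean))
    stop("shape vector length ", length(shape), " does not match the atlas (",
         length(atlas@mean), ")")
  as.numeric(crossprod(atlas@modes, shape - atlas@mean))
}

#' Reconstruct a shape from mode scores
#'
#' Either from a full score vector, or along a single mode at \code{k_sd}
#' population standard deviations (the score is then
#' \code{k_sd * sqrt(eigenvalue)}), the convention used to visualise the
#' +/-3 SD range of a mode.
#'
#' @param atlas a [ShapeAtlas-class].
#' @param scores numeric score vector (length <= K); ignored when
#'   \code{mode} is given.
#' @param mode single mode index for the (mode, k_sd) form.
#' @param k_sd number of standard deviations along \code{mode}.
#' @return Numeric shape vector.
#' @export
reconstructShape <- function(atlas, scores = NULL, mode = NULL, k_sd = 0) {
  if (!is.null(mode)) {
    if (mode < 1L || mode > atlas@K) stop("invalid mode index ", mode)
    if (abs(k_sd) > 5)
      warning("|k_sd| > 5: extrapolating far outside the population range")
    scores <- numeric(atlas@K)
    scores[mode] <- k_sd * sqrt(atlas@eigenvalues[mode])
  }
  if (is.null(scores)) scores <- numeric(atlas@K)
  if (length(scores) > atlas@K) stop("more scores than retained modes")
  s <- numeric(atlas@K)
  s[seq_along(scores)] <- scores
  as.numeric(atlas@mean + atlas@modes %*% s)
}

# one-way ANOVA F and p, with a seeded permutation fallback for degenerate
# zero-variance groups
.onewayF <- function(y, g, nPerm = 10000L, permSeed = 1L) {
  g <- factor(g)
  ni <- tapply(y, g, length)
  mi <- tapply(y, g, mean)
  gm <- mean(y)
  dfb <- nlevels(g) - 1L
  dfw <- length(y) - nlevels(g)
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((y - mi[g])^2)
  if (ssw < 1e-12 * max(ssb, 1e-300)) {
    # a group with zero variance: permutation p-value
    if (ssb < 1e-300) return(list(F = 0, p = 1))
    obs <- ssb
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(permSeed))
    cnt <- 0L
    for (b in seq_len(nPerm)) {
      gp <- sample(g)
      mp <- tapply(y, gp, mean)
      if (sum(ni * (mp - gm)^2) >= obs - 1e-12) cnt <- cnt + 1L
    }
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    return(list(F = Inf, p = (cnt + 1) / (nPerm + 1)))
  }
  Fst <- (ssb / dfb) / (ssw / dfw)
  list(F = Fst, p = pf(Fst, dfb, dfw, lower.tail = FALSE))
}

#' Mode-wise group comparison with Bonferroni correction
#'
#' Per-mode one-way ANOVA of the atlas scores across groups, with the raw
#' p-values Bonferroni-multiplied by the number of retained modes (capped at
#' 1).  Subgroup (e.g. stage-stratified) comparisons are obtained by passing
#' the corresponding subset of scores and labels.
#'
#' @param scores N x K score matrix (or a [ShapeAtlas-class], whose training
#'   scores are used).
#' @param groups group labels, length N.
#' @param alpha significance level for the flags (default 0.05).
#' @return Data frame with one row per mode: F statistic, raw and adjusted
#'   p, per-group score means and the significance flag.
#' @export
compareModes <- function(scores, groups, alpha = 0.05) {
  if (is(scores, "ShapeAtlas")) scores <- scores@scores
  scores <- as.matrix(scores)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("at least two groups are required")
  if (any(table(g) < 2L)) stop("each group needs n >= 2")
  K <- ncol(scores)
  res <- lapply(seq_len(K), function(k) .onewayF(scores[, k], g, permSeed = k))
  Fv <- vapply(res, `[[`, numeric(1), "F")
  p <- vapply(res, `[[`, numeric(1), "p")
  padj <- pmin(1, p * K)
  means <- t(vapply(seq_len(K),
                    function(k) tapply(scores[, k], g, mean),
                    numeric(nlevels(g))))
  colnames(means) <- paste0("mean_", levels(g))
  out <- data.frame(mode = seq_len(K), F = Fv, p = p, p_adj = padj,
                    significant = padj < alpha)
  cbind(out, means)
}
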