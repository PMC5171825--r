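#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used throughout the package to compare inferred clusters with
#' ground-truth clone or cluster assignments.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

# Pooled-variance two-sample t-test, two-sided.
# Conventions for degenerate input: zero variance in both groups with equal
# means -> p = 1; zero variance with unequal means -> p = 0.
pooled_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  mx <- mean(x); my <- mean(y)
  s2 <- (sum((x - mx)^2) + sum((y - my)^2)) / (nx + ny - 2)
  if (s2 <= 0) {
    if (mx == my) return(list(t = 0, p = 1, df = nx + ny - 2))
    return(list(t = sign(mx - my) * Inf, p = 0, df = nx + ny - 2))
  }
  tt <- (mx - my) / sqrt(s2 * (1 / nx + 1 / ny))
  list(t = tt, p = 2 * pt(-abs(tt), df = nx + ny - 2), df = nx + ny - 2)
}

# Welch (unequal-variance) two-sample t-test, two-sided, with the same
# degenerate-input conventions as pooled_t_test.
welch_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  mx <- mean(x); my <- mean(y)
  vx <- var(x); vy <- var(y)
  if (vx <= 0 && vy <= 0) {
    if (mx == my) return(list(t = 0, p = 1, df = nx + ny - 2))
    return(list(t = sign(mx - my) * Inf, p = 0, df = nx + ny - 2))
  }
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tt, p = 2 * pt(-abs(tt), df = df), df = df)
}

# Centered rolling mean with shrinking windows at the edges.
rolling_mean <- function(x, window) {
  n <- length(x)
  window <- max(1L, as.integer(window))
  if (window <= 1L || n <= 2L) return(x)
  half <- window %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Orient a PC1 score vector so that its correlation with per-row variance is
# negative (high-variance rows score low).  Exposed for testing the
# sign-invariance of the germline filter.
orient_pc1 <- function(scores, row_vars) {
  if (length(unique(scores)) > 1 && length(unique(row_vars)) > 1 &&
      cor(scores, row_vars) > 0) {
    -scores
  } else {
    scores
  }
}

# Small symmetric fastICA (logcosh nonlinearity) on pre-whitened data.
# X: n x p whitened matrix (unit covariance).  Returns n x n_comp sources.
# Deterministic given the RNG state (seeded random orthogonal init).
fast_ica <- function(X, n_comp = 2, max_iter = 200, tol = 1e-6) {
  p <- ncol(X)
  n <- nrow(X)
  W <- matrix(rnorm(n_comp * p), n_comp, p)
  sym_orth <- function(W) {
    s <- W %*% t(W)
    e <- eigen(s, symmetric = TRUE)
    solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                     n_comp) %*% t(e$vectors)
    solve_sqrt %*% W
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WX <- X %*% t(W)                     # n x n_comp
    g <- tanh(WX)
    gp <- 1 - g^2
    W1 <- t(g) %*% X / n - diag(colMeans(gp), n_comp) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  # fix sign: largest-|weight| entry of each unmixing row positive
  for (k in seq_len(n_comp)) {
    j <- which.max(abs(W[k, ]))
    if (W[k, j] < 0) W[k, ] <- -W[k, ]
  }
  X %*% t(W)
}
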