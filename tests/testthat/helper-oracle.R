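# Brute-force quantile-regression oracle: the check-loss LP attains its
# minimum at a vertex, i.e. a coefficient vector interpolating p of the n
# observations.  Enumerating all p-subsets gives the exact optimal objective
# for desk-scale instances, independently of the interior-point solver.
qr_brute_objective <- function(y, X, tau) {
  n <- length(y)
  p <- ncol(X)
  best <- Inf
  for (idx in asplit(combn(n, p), 2)) {
    Xi <- X[idx, , drop = FALSE]
    if (abs(det(Xi)) < 1e-10) next
    b <- solve(Xi, y[idx])
    obj <- sum(check_loss(y - X %*% b, tau))
    if (obj < best) best <- obj
  }
  best
}

# random small QR instance for oracle comparisons
random_qr_instance <- function(n_max = 25, p_max = 3) {
  n <- sample(8:n_max, 1)
  p <- sample(1:p_max, 1)
  X <- if (p == 1) matrix(1, n, 1) else cbind(1, matrix(rnorm(n * (p - 1)), n))
  list(y = rnorm(n, sd = sample(c(0.5, 5), 1)), X = X,
       tau = runif(1, 0.05, 0.95))
}

# small circulant nearest-neighbour weight matrix for non-multiple-of-10
# cross sections (each unit's two ring neighbours get weight 1/2)
ring_weights <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w[i, if (i == 1) n else i - 1] <- 0.5
    w[i, if (i == n) 1 else i + 1] <- 0.5
  }
  spatial_weights(w, row_normalized = TRUE)
}
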