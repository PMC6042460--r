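# Independent brute-force lasso oracle.
#
# For min (1/2n)||y - X b||^2 + lambda ||b||_1 the KKT conditions are
# sufficient (convex problem): enumerate all 3^p sign patterns, solve the
# stationarity system on each candidate active set, and accept the first
# solution whose signs and inactive subgradients are consistent. Shares no
# code with the package's coordinate-descent solver.
oracle_lasso <- function(x, y, lambda, tol = 1e-8) {
  n <- nrow(x); p <- ncol(x)
  G <- crossprod(x) / n
  b <- as.numeric(crossprod(x, y)) / n
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    act <- which(s != 0)
    beta <- numeric(p)
    if (length(act)) {
      sol <- tryCatch(solve(G[act, act, drop = FALSE],
                            b[act] - lambda * s[act]),
                      error = function(e) NULL)
      if (is.null(sol) || any(sign(sol) != s[act])) next
      beta[act] <- sol
    }
    grad <- b - as.numeric(G %*% beta)
    inact <- setdiff(seq_len(p), act)
    if (all(abs(grad[act] - lambda * s[act]) <= tol) &&
        all(abs(grad[inact]) <= lambda + tol)) {
      return(beta)
    }
  }
  stop("oracle: no sign pattern satisfied the optimality conditions")
}

# random standardised regression instance with a sparse true signal
random_instance <- function(n, p, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * stats::rbinom(p, 1, 0.5)
  y <- as.numeric(x %*% beta + rnorm(n))
  std <- standardize_columns(x)
  yc <- y - mean(y)
  list(x = std$x, y = yc / sqrt(mean(yc^2)))
}
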