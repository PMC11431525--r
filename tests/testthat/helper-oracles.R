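# Independent brute-force oracles used to validate the Gram-based engines.
# These deliberately work from the raw design matrix with dense least squares
# (lm.fit) and explicit enumeration, sharing no code with the package's
# search path.

# dense least-squares fit of intercept + X[, active]
oracle_fit <- function(X, y, active = integer(0)) {
  Xa <- cbind(1, X[, active, drop = FALSE])
  fit <- lm.fit(Xa, y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  list(coef = unname(fit$coefficients), rss = rss,
       neg2ll = n * (log(2 * pi * rss / n) + 1))
}

oracle_q <- function(X, y, active, lambda) {
  oracle_fit(X, y, active)$neg2ll + lambda * length(active)
}

# TRUE if sorted index vector a precedes b lexicographically
lex_less <- function(a, b) {
  k <- which(a != b)
  length(k) > 0 && a[k[1]] < b[k[1]]
}

# all-subsets minimiser with the package's documented tie-break
# (fewer variables, then lexicographically smallest index sequence)
oracle_best_subset <- function(X, y, lambda,
                               forced_in = integer(0),
                               forced_out = integer(0)) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), c(forced_in, forced_out))
  best <- NULL
  for (m in 0:(2^length(free) - 1)) {
    take <- free[bitwAnd(m, as.integer(2^(seq_along(free) - 1))) > 0L]
    act <- sort(as.integer(c(forced_in, take)))
    q <- oracle_q(X, y, act, lambda)
    if (is.null(best)) {
      best <- list(q = q, active = act)
    } else if (q < best$q - 1e-9) {
      best <- list(q = q, active = act)
    } else if (abs(q - best$q) <= 1e-9) {
      if (length(act) < length(best$active) ||
          (length(act) == length(best$active) && lex_less(act, best$active))) {
        best <- list(q = q, active = act)
      }
    }
  }
  best
}

# VI by enumeration: split all subsets by group membership
oracle_vi <- function(X, y, lambda, group) {
  p <- ncol(X)
  q_exc <- Inf
  q_inc <- Inf
  for (m in 0:(2^p - 1)) {
    act <- which(bitwAnd(m, as.integer(2^(0:(p - 1)))) > 0L)
    q <- oracle_q(X, y, act, lambda)
    if (all(group %in% act)) q_inc <- min(q_inc, q)
    if (!any(group %in% act)) q_exc <- min(q_exc, q)
  }
  list(vi = q_exc - q_inc, mvi = q_exc - q_inc + lambda * length(group),
       q_excluded = q_exc, q_included = q_inc)
}

# random regression instance with a sparse signal; returns a data frame
rand_instance <- function(n, p, seed, rho = 0) {
  set.seed(seed)
  Sigma <- matrix(rho, p, p) + diag(1 - rho, p)
  X <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
  colnames(X) <- paste0("x", seq_len(p))
  k <- sample.int(p, 1)
  beta <- numeric(p)
  beta[sample.int(p, k)] <- rnorm(k)
  y <- as.numeric(X %*% beta) + rnorm(n)
  data.frame(y = y, X)
}

pred_names <- function(d) setdiff(names(d), "y")
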