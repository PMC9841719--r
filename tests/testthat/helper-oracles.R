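# Independent oracles used by the test suite. These implement the checked
# quantities from first principles and stay independent of the package's
# own computation paths.

# Proximal-gradient (FISTA with restarts) minimizer of
#   -(1/n) * binomial loglik(b0 + X b)  +  sum_j ( a_j |b_j| + c_j b_j^2 )
# with an unpenalized intercept. Generic convex oracle: any per-coordinate
# L1/L2 penalty can be expressed through (a, c).
fista_logistic_oracle <- function(X, y, a, cvec, iters = 2e6, tol = 1e-15) {
  n <- nrow(X); p <- ncol(X)
  Xi <- cbind(1, X)
  L <- max(eigen(crossprod(Xi) / (4 * n), symmetric = TRUE,
                 only.values = TRUE)$values)
  t_step <- 1 / L
  b <- z <- numeric(p + 1L)
  tk <- 1; prev <- Inf
  objective <- function(b) {
    eta <- drop(Xi %*% b)
    mean(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      sum(a * abs(b[-1L])) + sum(cvec * b[-1L]^2)
  }
  for (it in seq_len(iters)) {
    mu <- stats::plogis(drop(Xi %*% z))
    g <- drop(crossprod(Xi, mu - y)) / n
    w <- z - t_step * g
    bn <- w
    bn[-1L] <- sign(w[-1L]) * pmax(0, abs(w[-1L]) - t_step * a) /
      (1 + 2 * t_step * cvec)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + ((tk - 1) / tn) * (bn - b)
    if (it %% 500 == 0) {
      o <- objective(bn)
      if (o > prev) { z <- bn; tk <- 1 } else tk <- tn
      if (abs(prev - o) < tol * max(1, abs(o))) { b <- bn; break }
      prev <- o
    } else tk <- tn
    b <- bn
  }
  b
}

# Two-sided Fisher exact p by explicit enumeration of the hypergeometric
# support with fixed margins (minimum-likelihood convention).
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form Welch t-test p-value.
welch_oracle <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Log-rank chi-square by direct evaluation of the observed-minus-expected
# sums over distinct event times.
logrank_oracle <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1L]
  U <- 0; V <- 0
  for (tj in sort(unique(time[event]))) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(event & time == tj)
    d1j <- sum(event & time == tj & group == g1)
    U <- U + d1j - dj * n1j / nj
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  U^2 / V
}

# Kaplan-Meier product-limit survival at each distinct event time.
km_oracle <- function(time, event) {
  s <- 1
  out <- numeric(0)
  for (tj in sort(unique(time))) {
    nj <- sum(time >= tj)
    dj <- sum(event & time == tj)
    s <- s * (1 - dj / nj)
    out <- c(out, s)
  }
  data.frame(time = sort(unique(time)), surv = out)
}

# Pearson correlation of two vectors from the raw definition.
pearson_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
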