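# Independent oracles used to cross-check the fitters.  These deliberately
# avoid stats::lm so that agreement is a two-route check.

# simple linear regression y = a + b*u via the covariance closed form
ols_closed_form <- function(u, y) {
  b <- sum((u - mean(u)) * (y - mean(y))) / sum((u - mean(u))^2)
  c(a = mean(y) - b * mean(u), b = b)
}

# multiple linear regression via explicitly solved normal equations with
# iterative refinement (the raw normal equations square the condition
# number; refinement recovers the least-squares solution to ~1e-12)
normal_equations_fit <- function(X, y, refinements = 3L) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  for (k in seq_len(refinements))
    beta <- beta + solve(XtX, crossprod(X, y - X %*% beta))
  as.numeric(beta)
}

# shrinking grid search minimizing SSE of ln x = a + b/T.  The search runs
# in the decorrelated parametrization (alpha, b) with
# a = alpha - b*mean(1/T), where the SSE surface is separable and the
# argmin cannot escape the shrinking window.
grid_search_vant_hoff <- function(T, x, n = 201L) {
  u <- 1 / T; y <- log(x)
  uc <- u - mean(u)
  b0 <- (y[length(y)] - y[1L]) / (u[length(u)] - u[1L])
  al0 <- mean(y)
  sse <- function(al, b) sum((y - al - b * uc)^2)
  wa <- max(abs(al0), 1) * 0.5; wb <- max(abs(b0), 1) * 0.5
  for (round in 1:4) {
    als <- seq(al0 - wa, al0 + wa, length.out = n)
    bs <- seq(b0 - wb, b0 + wb, length.out = n)
    S <- outer(als, bs, Vectorize(sse))
    ix <- arrayInd(which.min(S), dim(S))
    al0 <- als[ix[1L]]; b0 <- bs[ix[2L]]
    wa <- wa * 4 / n; wb <- wb * 4 / n
  }
  c(a = al0 - b0 * mean(u), b = b0)
}

# direct mole bookkeeping for the saturated ternary composition: dissolve
# n1 moles of solute into 1 g of solvent blend and count moles
composition_by_mole_count <- function(x_e, m, masses) {
  n2 <- m / masses$cosolvent
  n3 <- (1 - m) / masses$water
  n1 <- x_e * (n2 + n3) / (1 - x_e)
  tot <- n1 + n2 + n3
  c(x1 = n1 / tot, x2 = n2 / tot, x3 = n3 / tot)
}

# a small noiseless van't Hoff series
vh_series <- function(a, b, T = c(298.2, 303.2, 308.2, 313.2, 318.2)) {
  list(T = T, x = exp(a + b / T))
}
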