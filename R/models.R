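#' Percent root-mean-square relative deviation
#'
#' The model-comparison metric used throughout:
#' \deqn{\%RMSD = 100\sqrt{\frac{1}{N}\sum_i
#'   \left(\frac{x^{obs}_i - x^{pred}_i}{x^{obs}_i}\right)^2}}
#'
#' @param x_obs observed solubilities, positive.
#' @param x_pred predicted solubilities, same length.
#' @return Percent RMSD, a single non-negative number.
#' @export
rmsd_percent <- function(x_obs, x_pred) {
  if (length(x_obs) != length(x_pred))
    stop("observed and predicted series differ in length", call. = FALSE)
  if (any(!is.finite(x_obs)) || any(x_obs <= 0))
    stop("observations must be positive", call. = FALSE)
  100 * sqrt(mean(((x_obs - x_pred) / x_obs)^2))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} on the supplied response scale.  Fit
#' statistics in this package report it on the `ln x` regression scale.
#'
#' @param y_obs observed responses, at least 2 values with non-zero
#'   variance.
#' @param y_fit fitted responses, same length.
#' @return `R^2`, at most 1.
#' @export
r_squared <- function(y_obs, y_fit) {
  if (length(y_obs) != length(y_fit))
    stop("observed and fitted series differ in length", call. = FALSE)
  if (length(y_obs) < 2L)
    stop("need at least two points", call. = FALSE)
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  if (ss_tot == 0)
    stop("zero variance in y_obs", call. = FALSE)
  1 - sum((y_obs - y_fit)^2) / ss_tot
}

#' Fit the van't Hoff solubility model
#'
#' Ordinary least squares of `ln x` on `1/T`:
#' \eqn{\ln x = a + b/T}.  `R^2` is reported on the `ln x` scale and %RMSD
#' on the back-transformed solubility scale.
#'
#' @param T temperatures, K; at least 3 distinct values.
#' @param x mole-fraction solubilities, positive.
#' @param m optional cosolvent mass fraction the series belongs to
#'   (metadata only).
#' @return An object of class `"vant_hoff_fit"`: list with `a` (intercept),
#'   `b` (slope, K), `r2`, `rmsd_pct`, `n`, `m`.
#' @examples
#' ds <- ppn_fixture()
#' pure <- subset(ds$data, m == 1)
#' fit_vant_hoff(pure$T_K, pure$x_e)
#' @export
fit_vant_hoff <- function(T, x, m = NA_real_) {
  if (length(T) != length(x) || length(T) < 3L)
    stop("need at least 3 (T, x) points", call. = FALSE)
  if (length(unique(T)) < 2L)
    stop("temperatures are degenerate", call. = FALSE)
  if (any(x <= 0)) stop("solubilities must be positive", call. = FALSE)
  fit <- stats::lm(log(x) ~ I(1 / T))
  a <- unname(stats::coef(fit)[1L]); b <- unname(stats::coef(fit)[2L])
  lnhat <- a + b / T
  structure(list(a = a, b = b,
                 r2 = r_squared(log(x), lnhat),
                 rmsd_pct = rmsd_percent(x, exp(lnhat)),
                 n = length(T), m = m),
            class = "vant_hoff_fit")
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit%s: ln x = %.4f + %.2f/T  (R2 = %.4f, RMSD = %.2f%%)\n",
              if (is.na(x$m)) "" else sprintf(" (m = %g)", x$m),
              x$a, x$b, x$r2, x$rmsd_pct))
  invisible(x)
}

#' @param object a `"vant_hoff_fit"`.
#' @param T temperatures, K.
#' @param ... unused.
#' @return Predicted mole-fraction solubilities `exp(a + b/T)`.
#' @rdname fit_vant_hoff
#' @export
predict.vant_hoff_fit <- function(object, T, ...) {
  if (any(T <= 0)) stop("temperatures must be positive", call. = FALSE)
  exp(object$a + object$b / T)
}

#' Fit the Apelblat solubility model
#'
#' \eqn{\ln x = A + B/T + C\ln T}, linear in its coefficients, fit by least
#' squares on the regressors `{1, 1/T, ln T}`.  Over a narrow temperature
#' window this design is severely collinear, so individual coefficients are
#' poorly determined even when predictions are excellent; the condition
#' number of the design matrix is reported as a diagnostic.
#'
#' @param T temperatures, K; at least 4 points.
#' @param x mole-fraction solubilities, positive.
#' @param m optional cosolvent mass fraction (metadata only).
#' @return An object of class `"apelblat_fit"`: list with `A`, `B` (K),
#'   `C`, `r2`, `rmsd_pct`, `condition_number`, `n`, `m`.
#' @export
fit_apelblat <- function(T, x, m = NA_real_) {
  if (length(T) != length(x) || length(T) < 4L)
    stop("need at least 4 (T, x) points", call. = FALSE)
  if (any(x <= 0)) stop("solubilities must be positive", call. = FALSE)
  X <- cbind(1, 1 / T, log(T))
  if (qr(X)$rank < 3L)
    stop("design is rank deficient (too few distinct temperatures)",
         call. = FALSE)
  fit <- stats::lm(log(x) ~ I(1 / T) + log(T))
  cf <- unname(stats::coef(fit))
  lnhat <- cf[1L] + cf[2L] / T + cf[3L] * log(T)
  structure(list(A = cf[1L], B = cf[2L], C = cf[3L],
                 r2 = r_squared(log(x), lnhat),
                 rmsd_pct = rmsd_percent(x, exp(lnhat)),
                 condition_number = kappa(X, exact = TRUE),
                 n = length(T), m = m),
            class = "apelblat_fit")
}

#' @export
print.apelblat_fit <- function(x, ...) {
  cat(sprintf(
    "Apelblat fit%s: ln x = %.2f + %.2f/T + %.2f ln T  (R2 = %.4f, RMSD = %.2f%%, cond = %.2g)\n",
    if (is.na(x$m)) "" else sprintf(" (m = %g)", x$m),
    x$A, x$B, x$C, x$r2, x$rmsd_pct, x$condition_number))
  invisible(x)
}

#' @param object an `"apelblat_fit"`.
#' @param T temperatures, K.
#' @param ... unused.
#' @rdname fit_apelblat
#' @export
predict.apelblat_fit <- function(object, T, ...) {
  if (any(T <= 0)) stop("temperatures must be positive", call. = FALSE)
  exp(object$A + object$B / T + object$C * log(T))
}

#' Yalkowsky-Roseman log-linear mixture rule
#'
#' Predicts the mixture log-solubility as the mass-fraction-weighted blend
#' of the pure-solvent log-solubilities,
#' \eqn{\log_{10} x = m_1\log_{10}x_1 + m_2\log_{10}x_2} with
#' \eqn{m_2 = 1 - m_1}.  No parameters are fitted.
#'
#' @param m1 cosolvent mass fraction(s) in \[0, 1\].
#' @param x1 solubility in pure cosolvent at the same temperature, positive.
#' @param x2 solubility in pure water at the same temperature, positive.
#' @return Predicted `log10` mole-fraction solubility.
#' @examples
#' yalkowsky_roseman(0.2, 8.44e-2, 1.31e-5)  # -4.12
#' @export
yalkowsky_roseman <- function(m1, x1, x2) {
  check_mass_fraction(m1)
  if (any(x1 <= 0) || any(x2 <= 0))
    stop("pure-solvent solubilities must be positive", call. = FALSE)
  m1 * log10(x1) + (1 - m1) * log10(x2)
}

#' Yalkowsky-Roseman predictions over a dataset
#'
#' Applies [yalkowsky_roseman()] at every mixture point of a complete grid,
#' using the measured pure-solvent solubilities at each temperature, and
#' reports per-`m` %RMSD.
#'
#' @param dataset a complete-grid [solubility_dataset()].
#' @return A list with `table` (data frame `m`, `T_K`, `log10_x_pred`,
#'   `x_pred`, `x_e`), `rmsd_by_m` (data frame `m`, `rmsd_pct`) and
#'   `rmsd_pct` (average over `m` levels).
#' @export
yalkowsky_table <- function(dataset) {
  assert_complete_grid(dataset)
  d <- dataset$data
  px <- pure_lookup(d)
  mix <- d[d$m > 0 & d$m < 1, ]
  l10 <- yalkowsky_roseman(mix$m, px$x1[match(mix$T_K, px$T_K)],
                           px$x2[match(mix$T_K, px$T_K)])
  tab <- data.frame(m = mix$m, T_K = mix$T_K, log10_x_pred = l10,
                    x_pred = 10^l10, x_e = mix$x_e)
  by_m <- do.call(rbind, lapply(split(tab, tab$m), function(s)
    data.frame(m = s$m[1L], rmsd_pct = rmsd_percent(s$x_e, s$x_pred))))
  rownames(by_m) <- NULL
  list(table = tab, rmsd_by_m = by_m, rmsd_pct = mean(by_m$rmsd_pct))
}

## measured pure-solvent solubilities per temperature (x1 cosolvent, x2 water)
pure_lookup <- function(d) {
  Ts <- sort(unique(d$T_K))
  data.frame(T_K = Ts,
             x1 = d$x_e[match(paste(1, Ts), paste(d$m, d$T_K))],
             x2 = d$x_e[match(paste(0, Ts), paste(d$m, d$T_K))])
}

## Jouyban-Acree interaction regressors m1*m2*(m1-m2)^i / T for i = 0..order
ja_regressors <- function(m1, T, order = 2L) {
  m2 <- 1 - m1
  base <- m1 * m2 / T
  sapply(0:order, function(i) base * (m1 - m2)^i)
}

## No-intercept least squares with single-pass p > p_drop term deletion.
## Near-perfect fits (residual variance at floating-point noise level) make
## t-based p-values meaningless; terms are then retained iff their
## coefficient is numerically nonzero (threshold 1e-6 K, far below any
## physically meaningful interaction coefficient).
fit_no_intercept_select <- function(W, y, p_drop = 0.05, term_names,
                                    scale = max(abs(y), 1)) {
  colnames(W) <- term_names
  df <- as.data.frame(W)
  df$.y <- y
  full <- stats::lm(.y ~ . + 0, data = df)
  smr <- summary(full)
  sm <- smr$coefficients
  coefs <- stats::setNames(sm[, "Estimate"], rownames(sm))
  pvals <- stats::setNames(sm[, "Pr(>|t|)"], rownames(sm))
  perfect <- !is.finite(smr$sigma) || smr$sigma <= 1e-10 * scale
  if (perfect) pvals <- ifelse(abs(coefs) > 1e-6, 0, 1)
  keep <- names(coefs)[pvals <= p_drop]
  if (length(keep) == 0L) {
    J <- stats::setNames(numeric(0), character(0))
    fitted_y <- rep(0, length(y))
  } else if (setequal(keep, term_names)) {
    J <- coefs
    fitted_y <- as.numeric(stats::fitted(full))
  } else {
    red <- stats::lm(stats::reformulate(c("0", sprintf("`%s`", keep)), ".y"),
                     data = df)
    J <- stats::setNames(unname(stats::coef(red)), keep)
    fitted_y <- as.numeric(stats::fitted(red))
  }
  list(J = J, fitted = fitted_y, full_summary = sm)
}

#' Fit the Jouyban-Acree mixture model
#'
#' \deqn{\ln x_{m,T} = m_1\ln x_{1,T} + m_2\ln x_{2,T} +
#'   \frac{m_1 m_2}{T}\sum_{i=0}^{2} J_i (m_1-m_2)^i}
#' The pure-solvent terms use the *measured* solubilities at each
#' temperature, so the interaction response
#' `y = ln x - m1 ln x1 - m2 ln x2` is regressed without intercept on the
#' regressors `m1 m2 (m1-m2)^i / T`.  Terms with p > `p_drop` are dropped
#' in a single pass and the model refit; %RMSD is computed over the
#' mixture points.
#'
#' @param dataset a complete-grid [solubility_dataset()] containing both
#'   pure solvents.
#' @param p_drop significance threshold for retaining interaction terms;
#'   set to 1 to keep all terms.
#' @param order highest power of `(m1 - m2)` (default 2, i.e. up to three
#'   `J` coefficients).
#' @return An object of class `"jouyban_acree_fit"`: list with `J` (named
#'   numeric, retained coefficients in K), `retained_terms` (integer powers
#'   kept), `rmsd_pct`, `pure` (per-temperature pure-solvent solubilities
#'   used), `n`.
#' @export
fit_jouyban_acree <- function(dataset, p_drop = 0.05, order = 2L) {
  assert_complete_grid(dataset)
  d <- dataset$data
  px <- pure_lookup(d)
  mix <- d[d$m > 0 & d$m < 1, ]
  if (nrow(mix) == 0L)
    stop("no mixture points to fit", call. = FALSE)
  ix <- match(mix$T_K, px$T_K)
  y <- log(mix$x_e) - mix$m * log(px$x1[ix]) - (1 - mix$m) * log(px$x2[ix])
  W <- ja_regressors(mix$m, mix$T_K, order)
  sel <- fit_no_intercept_select(W, y, p_drop, paste0("J", 0:order),
                                 scale = max(abs(log(mix$x_e))))
  pred <- exp(log(mix$x_e) - y + sel$fitted)
  structure(list(J = sel$J,
                 retained_terms = as.integer(sub("^J", "", names(sel$J))),
                 rmsd_pct = rmsd_percent(mix$x_e, pred),
                 pure = px, n = nrow(mix)),
            class = "jouyban_acree_fit")
}

#' @export
print.jouyban_acree_fit <- function(x, ...) {
  cat("Jouyban-Acree fit: ",
      if (length(x$J)) paste(sprintf("%s = %.2f K", names(x$J), x$J),
                             collapse = ", ")
      else "no significant interaction terms",
      sprintf("  (RMSD = %.2f%% over %d mixture points)\n", x$rmsd_pct, x$n),
      sep = "")
  invisible(x)
}

#' @param object a `"jouyban_acree_fit"`.
#' @param m cosolvent mass fraction(s).
#' @param T temperatures, K; must be temperatures present in the fitted
#'   grid (the model anchors on measured pure-solvent solubilities).
#' @param ... unused.
#' @rdname fit_jouyban_acree
#' @export
predict.jouyban_acree_fit <- function(object, m, T, ...) {
  check_mass_fraction(m)
  ix <- match(T, object$pure$T_K)
  if (anyNA(ix))
    stop("prediction temperatures must match the fitted grid", call. = FALSE)
  lnx <- m * log(object$pure$x1[ix]) + (1 - m) * log(object$pure$x2[ix]) +
    ja_interaction(object$J, m, T)
  exp(lnx)
}

ja_interaction <- function(J, m1, T) {
  if (length(J) == 0L) return(rep(0, max(length(m1), length(T))))
  pow <- as.integer(sub("^J", "", names(J)))
  m2 <- 1 - m1
  out <- 0
  for (k in seq_along(J))
    out <- out + J[[k]] * m1 * m2 * (m1 - m2)^pow[k] / T
  out
}

#' Fit the Jouyban-Acree-van't Hoff mixture model
#'
#' Two-stage fit of
#' \deqn{\ln x_{m,T} = m_1(A_1 + B_1/T) + m_2(A_2 + B_2/T) +
#'   \frac{m_1 m_2}{T}\sum_i J_i (m_1-m_2)^i.}
#' Stage 1 fits van't Hoff lines to the two pure solvents; stage 2 fits the
#' `J` coefficients by no-intercept regression of the residuals of the
#' van't Hoff-smoothed log-linear blend at the mixture points.  %RMSD is
#' reported over the full grid (pure-solvent predictions come from the
#' stage-1 lines).
#'
#' @inheritParams fit_jouyban_acree
#' @return An object of class `"ja_vant_hoff_fit"`: list with `A1`, `B1`
#'   (pure cosolvent), `A2`, `B2` (pure water), `J`, `retained_terms`,
#'   `rmsd_pct`, `n`.
#' @export
fit_ja_vant_hoff <- function(dataset, p_drop = 0.05, order = 2L) {
  assert_complete_grid(dataset)
  d <- dataset$data
  vh1 <- fit_vant_hoff(d$T_K[d$m == 1], d$x_e[d$m == 1], m = 1)
  vh2 <- fit_vant_hoff(d$T_K[d$m == 0], d$x_e[d$m == 0], m = 0)
  base <- d$m * (vh1$a + vh1$b / d$T_K) + (1 - d$m) * (vh2$a + vh2$b / d$T_K)
  mixsel <- d$m > 0 & d$m < 1
  y <- log(d$x_e[mixsel]) - base[mixsel]
  W <- ja_regressors(d$m[mixsel], d$T_K[mixsel], order)
  sel <- fit_no_intercept_select(W, y, p_drop, paste0("J", 0:order),
                                 scale = max(abs(log(d$x_e))))
  obj <- structure(list(A1 = vh1$a, B1 = vh1$b, A2 = vh2$a, B2 = vh2$b,
                        J = sel$J,
                        retained_terms = as.integer(sub("^J", "", names(sel$J))),
                        rmsd_pct = NA_real_, n = nrow(d)),
                   class = "ja_vant_hoff_fit")
  obj$rmsd_pct <- rmsd_percent(d$x_e, predict(obj, d$m, d$T_K))
  obj
}

#' @export
print.ja_vant_hoff_fit <- function(x, ...) {
  cat(sprintf(
    "Jouyban-Acree-van't Hoff fit: A1 = %.4f, B1 = %.2f, A2 = %.4f, B2 = %.2f\n",
    x$A1, x$B1, x$A2, x$B2))
  cat("  ",
      if (length(x$J)) paste(sprintf("%s = %.2f K", names(x$J), x$J),
                             collapse = ", ")
      else "no significant interaction terms",
      sprintf("  (RMSD = %.2f%% over %d grid points)\n", x$rmsd_pct, x$n),
      sep = "")
  invisible(x)
}

#' @param object a `"ja_vant_hoff_fit"`.
#' @param m cosolvent mass fraction(s).
#' @param T temperatures, K (any positive value; the model is closed-form).
#' @param ... unused.
#' @rdname fit_ja_vant_hoff
#' @export
predict.ja_vant_hoff_fit <- function(object, m, T, ...) {
  check_mass_fraction(m)
  if (any(T <= 0)) stop("temperatures must be positive", call. = FALSE)
  lnx <- m * (object$A1 + object$B1 / T) +
    (1 - m) * (object$A2 + object$B2 / T) +
    ja_interaction(object$J, m, T)
  exp(lnx)
}

#' Per-composition van't Hoff fits over a dataset
#'
#' @param dataset a [solubility_dataset()].
#' @return A data frame with one row per `m` level: `m`, `a`, `b`, `r2`,
#'   `rmsd_pct`.
#' @export
vant_hoff_table <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  d <- dataset$data
  out <- do.call(rbind, lapply(split(d, d$m), function(s) {
    f <- fit_vant_hoff(s$T_K, s$x_e, m = s$m[1L])
    data.frame(m = f$m, a = f$a, b = f$b, r2 = f$r2, rmsd_pct = f$rmsd_pct)
  }))
  rownames(out) <- NULL
  out
}

#' Per-composition Apelblat fits over a dataset
#'
#' @param dataset a [solubility_dataset()].
#' @return A data frame with one row per `m` level: `m`, `A`, `B`, `C`,
#'   `r2`, `rmsd_pct`, `condition_number`.
#' @export
apelblat_table <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  d <- dataset$data
  out <- do.call(rbind, lapply(split(d, d$m), function(s) {
    f <- fit_apelblat(s$T_K, s$x_e, m = s$m[1L])
    data.frame(m = f$m, A = f$A, B = f$B, C = f$C, r2 = f$r2,
               rmsd_pct = f$rmsd_pct, condition_number = f$condition_number)
  }))
  rownames(out) <- NULL
  out
}
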