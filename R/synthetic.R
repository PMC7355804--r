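#' Configuration for the synthetic solubility-grid generator
#'
#' Defines the generative law for synthetic datasets: the
#' Jouyban-Acree-van't Hoff surface
#' \deqn{\ln x_{m,T} = m_1(A_1 + B_1/T) + m_2(A_2 + B_2/T) +
#'   \frac{m_1 m_2}{T}\sum_i J_i(m_1-m_2)^i}
#' plus additive Gaussian noise on `ln x` (multiplicative lognormal on
#' `x`), matching the relative-error structure of the %RMSD metric.
#'
#' Defaults mirror the piperine / Transcutol-HP + water study: the grid is
#' m = 0 to 1 by 0.1 and T = 298.2 to 318.2 K by 5 K, the van't Hoff
#' parameters are the fitted pure-solvent lines and `J` the trained
#' interaction coefficient of that system, and the noise sigma of 0.01 on
#' `ln x` corresponds to about 1% relative measurement error.
#'
#' @param m_levels cosolvent mass fractions; must include 0 and 1.
#' @param T_levels temperatures, K.
#' @param A1,B1 van't Hoff intercept and slope (K) of the pure cosolvent.
#' @param A2,B2 van't Hoff intercept and slope (K) of pure water.
#' @param J numeric vector of up to three interaction coefficients
#'   (`J0`, `J1`, `J2`), K.
#' @param noise_sigma standard deviation of the Gaussian noise on `ln x`;
#'   non-negative.
#' @param seed integer seed making generation reproducible.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(m_levels = seq(0, 1, by = 0.1),
                             T_levels = seq(298.2, 318.2, by = 5),
                             A1 = -0.21, B1 = -696.21,
                             A2 = -4.45, B2 = -2093.60,
                             J = -16.42,
                             noise_sigma = 0.01,
                             seed = 1L) {
  if (!any(m_levels == 0) || !any(m_levels == 1))
    stop("m_levels must include the pure solvents 0 and 1", call. = FALSE)
  check_mass_fraction(m_levels)
  if (any(T_levels <= 0)) stop("temperatures must be positive", call. = FALSE)
  if (length(J) < 1L || length(J) > 3L)
    stop("J must hold 1 to 3 coefficients", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  structure(list(m_levels = sort(unique(m_levels)),
                 T_levels = sort(unique(T_levels)),
                 A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                 J = J, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "generator_config")
}

ja_vh_surface <- function(cfg, m, T) {
  J <- stats::setNames(cfg$J, paste0("J", seq_along(cfg$J) - 1L))
  m * (cfg$A1 + cfg$B1 / T) + (1 - m) * (cfg$A2 + cfg$B2 / T) +
    ja_interaction(J, m, T)
}

#' Generate a synthetic solubility grid
#'
#' Evaluates the configured Jouyban-Acree-van't Hoff surface on the full
#' `(m, T)` grid and applies multiplicative lognormal noise,
#' `x = exp(ln x + eps)`, `eps ~ N(0, noise_sigma^2)`.  Generation is
#' deterministic for a fixed config (the seed is applied locally and the
#' caller's random state restored).
#'
#' @param cfg a [generator_config()].
#' @return A [solubility_dataset()] covering the complete grid.
#' @examples
#' ds <- generate_solubility_grid(generator_config(noise_sigma = 0))
#' fit_ja_vant_hoff(ds)  # recovers the generating coefficients
#' @export
generate_solubility_grid <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  grid <- expand.grid(T_K = cfg$T_levels, m = cfg$m_levels)[, c("m", "T_K")]
  lnx <- ja_vh_surface(cfg, grid$m, grid$T_K)
  eps <- with_local_seed(cfg$seed,
                         stats::rnorm(nrow(grid), 0, cfg$noise_sigma))
  x <- exp(lnx + if (cfg$noise_sigma > 0) eps else 0)
  bad <- which(x >= 1)
  if (length(bad))
    stop(sprintf(
      "generated solubility >= 1 at m = %g, T = %g K; adjust parameters",
      grid$m[bad[1L]], grid$T_K[bad[1L]]), call. = FALSE)
  solubility_dataset(data.frame(m = grid$m, T_K = grid$T_K, x_e = x),
                     labels = c(solute = "synthetic solute",
                                cosolvent = "cosolvent", water = "water"))
}

#' Perturb a dataset with multiplicative lognormal noise
#'
#' Multiplies every solubility by `exp(eps)`, `eps ~ N(0, sigma^2)`; used
#' for robustness and recovery studies of the fitters.  `sigma = 0` returns
#' the dataset unchanged.
#'
#' @param dataset a [solubility_dataset()].
#' @param sigma noise standard deviation on `ln x`; non-negative.
#' @param seed integer seed.
#' @return A [solubility_dataset()] with perturbed solubilities.
#' @export
perturb_fixture <- function(dataset, sigma, seed = 1L) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(dataset)
  d <- dataset$data
  eps <- with_local_seed(seed, stats::rnorm(nrow(d), 0, sigma))
  d$x_e <- d$x_e * exp(eps)
  if (any(d$x_e >= 1))
    stop("perturbation pushed a solubility to 1 or above; reduce sigma",
         call. = FALSE)
  solubility_dataset(d, masses = dataset$masses, labels = dataset$labels)
}

## run expr under a fixed seed without disturbing the caller's RNG state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
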