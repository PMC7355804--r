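#' Hansen solubility parameter components
#'
#' The total cohesive-energy solubility parameter decomposes into
#' dispersion, polar and hydrogen-bonding contributions:
#' \eqn{\delta^2 = \delta_d^2 + \delta_p^2 + \delta_h^2}.  When both the
#' components and a total are supplied they must be consistent.
#'
#' @param delta_d,delta_p,delta_h component parameters, MPa^0.5,
#'   non-negative.  May be `NULL` if only `delta_total` is known.
#' @param delta_total optional total parameter, MPa^0.5.
#' @return An object of class `"hsp_components"` with fields `delta_d`,
#'   `delta_p`, `delta_h`, `delta_total` (computed from the components when
#'   not supplied).
#' @export
hsp_components <- function(delta_d = NULL, delta_p = NULL, delta_h = NULL,
                           delta_total = NULL) {
  comps <- list(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h)
  have_comps <- !any(vapply(comps, is.null, logical(1L)))
  if (!have_comps && is.null(delta_total))
    stop("supply either all three components or delta_total", call. = FALSE)
  if (have_comps) {
    v <- unlist(comps)
    if (any(!is.finite(v)) || any(v < 0))
      stop("HSP components must be finite and non-negative", call. = FALSE)
    total <- sqrt(sum(v^2))
    if (!is.null(delta_total) &&
        abs(delta_total^2 - total^2) > 1e-9 * max(1, total^2))
      stop("delta_total is inconsistent with the components", call. = FALSE)
    delta_total <- if (is.null(delta_total)) total else delta_total
  }
  structure(list(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h,
                 delta_total = delta_total),
            class = "hsp_components")
}

#' Total Hansen solubility parameter from components
#'
#' @param c an [hsp_components()] object with all three components present.
#' @return Total parameter \eqn{\sqrt{\delta_d^2+\delta_p^2+\delta_h^2}},
#'   MPa^0.5.
#' @examples
#' total_hsp(hsp_components(3, 4, 12))  # 13
#' @export
total_hsp <- function(c) {
  stopifnot(inherits(c, "hsp_components"))
  if (is.null(c$delta_d) || is.null(c$delta_p) || is.null(c$delta_h))
    stop("component parameters are missing; only a total is available",
         call. = FALSE)
  sqrt(c$delta_d^2 + c$delta_p^2 + c$delta_h^2)
}

#' Solubility parameter of a binary solvent blend
#'
#' Linear blending rule \eqn{\delta_{mix} = \alpha\delta_1 +
#' (1-\alpha)\delta_2}.  By default `alpha` is taken as the cosolvent mass
#' fraction `m`; supply volume fractions instead if densities are known.
#'
#' @param alpha cosolvent fraction(s) in \[0, 1\].
#' @param delta1 parameter of the pure cosolvent, MPa^0.5.
#' @param delta2 parameter of pure water, MPa^0.5.
#' @return Blend parameter(s), bounded by `delta1` and `delta2`.
#' @examples
#' mixture_hsp(0.9, 21.40, 47.80)  # 24.04
#' @export
mixture_hsp <- function(alpha, delta1, delta2) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("alpha must lie in [0, 1]", call. = FALSE)
  alpha * delta1 + (1 - alpha) * delta2
}

#' Rank candidate solvents by solubility-parameter proximity
#'
#' Solvents whose solubility parameter lies close to the solute's tend to
#' dissolve it better; this sorts candidates by `|delta - delta_solute|`
#' ascending, preserving input order on ties.
#'
#' @param solute_delta total parameter of the solute, MPa^0.5.
#' @param candidates a data frame with columns `label` and `delta`.
#' @return The candidates data frame with an added `distance` column,
#'   sorted by proximity.
#' @export
proximity_rank <- function(solute_delta, candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L ||
      !all(c("label", "delta") %in% names(candidates)))
    stop("candidates must be a non-empty data frame with label and delta",
         call. = FALSE)
  out <- candidates
  out$distance <- abs(out$delta - solute_delta)
  out <- out[order(out$distance), , drop = FALSE]   # stable in base R
  rownames(out) <- NULL
  out
}

#' Read a table of Hansen solubility parameters
#'
#' CSV with columns `substance` and any of `delta_d`, `delta_p`, `delta_h`,
#' `delta_total`; totals are derived from components where absent.
#'
#' @param path path to the CSV file.
#' @return A data frame with columns `substance`, `delta_d`, `delta_p`,
#'   `delta_h`, `delta_total`.
#' @export
read_hsp_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  if (!("substance" %in% names(d)))
    stop("HSP table needs a substance column", call. = FALSE)
  for (cn in c("delta_d", "delta_p", "delta_h", "delta_total"))
    if (!(cn %in% names(d))) d[[cn]] <- NA_real_
  derive <- is.na(d$delta_total)
  if (any(derive)) {
    comp_ok <- !is.na(d$delta_d) & !is.na(d$delta_p) & !is.na(d$delta_h)
    if (any(derive & !comp_ok))
      stop("rows with neither delta_total nor full components: ",
           paste(d$substance[derive & !comp_ok], collapse = ", "),
           call. = FALSE)
    d$delta_total[derive] <- sqrt(d$delta_d[derive]^2 + d$delta_p[derive]^2 +
                                    d$delta_h[derive]^2)
  }
  d[, c("substance", "delta_d", "delta_p", "delta_h", "delta_total")]
}
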