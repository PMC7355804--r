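#' Molar masses of the three species
#'
#' Bundle of molar masses for the solute (1), cosolvent (2) and water (3),
#' used in every mass-to-mole conversion.  Defaults are the piperine /
#' Transcutol-HP / water values of the packaged dataset.
#'
#' @param solute,cosolvent,water molar masses in g/mol; all strictly positive.
#' @return An object of class `"molar_masses"`: a named list with elements
#'   `solute`, `cosolvent`, `water`.
#' @examples
#' molar_masses()
#' molar_masses(solute = 180.16, cosolvent = 46.07, water = 18.02)
#' @export
molar_masses <- function(solute = 285.34, cosolvent = 134.17, water = 18.07) {
  mm <- list(solute = solute, cosolvent = cosolvent, water = water)
  for (nm in names(mm)) {
    v <- mm[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("molar mass of ", nm, " must be a single positive number",
           call. = FALSE)
  }
  structure(mm, class = "molar_masses")
}

#' @export
print.molar_masses <- function(x, ...) {
  cat(sprintf("Molar masses (g/mol): solute %.2f, cosolvent %.2f, water %.2f\n",
              x$solute, x$cosolvent, x$water))
  invisible(x)
}

as_molar_masses <- function(x) {
  if (inherits(x, "molar_masses")) return(x)
  if (is.list(x) && all(c("solute", "cosolvent", "water") %in% names(x)))
    return(molar_masses(x$solute, x$cosolvent, x$water))
  stop("cannot interpret object as molar masses", call. = FALSE)
}

#' Convert raw gravimetric solubility to mole fraction
#'
#' Converts a solubility expressed as mg of solute per gram of solute-free
#' solvent blend into a mole fraction.  Per gram of solvent the blend holds
#' `m` g cosolvent and `1 - m` g water, so
#' \deqn{x_e = \frac{m_1/M_1}{m_1/M_1 + m/M_2 + (1-m)/M_3}}
#' with \eqn{m_1} the solute mass in grams.  At `m = 0` or `m = 1` this
#' reduces to the two-species (binary) form.
#'
#' @param mg_per_g raw solubility, mg solute per g solvent; non-negative.
#' @param m cosolvent mass fraction of the solute-free solvent blend, in
#'   \[0, 1\].
#' @param masses a [molar_masses()] object.
#' @return Mole-fraction solubility, same length as the longer of
#'   `mg_per_g` and `m`.
#' @examples
#' to_mole_fraction(185.29, m = 1)   # pure cosolvent: 8.01e-2
#' to_mole_fraction(0.164, m = 0)    # pure water:     1.04e-5
#' @seealso [from_mole_fraction()] for the inverse.
#' @export
to_mole_fraction <- function(mg_per_g, m, masses = molar_masses()) {
  masses <- as_molar_masses(masses)
  if (any(!is.finite(mg_per_g)) || any(mg_per_g < 0))
    stop("raw solubility must be finite and non-negative", call. = FALSE)
  check_mass_fraction(m)
  n1 <- mg_per_g * 1e-3 / masses$solute
  n_solvent <- m / masses$cosolvent + (1 - m) / masses$water
  out <- n1 / (n1 + n_solvent)
  out[n1 == 0] <- 0
  out
}

#' Convert mole-fraction solubility back to mg per g of solvent
#'
#' Exact inverse of [to_mole_fraction()].
#'
#' @inheritParams to_mole_fraction
#' @param x_e mole-fraction solubility in \[0, 1).
#' @return Raw solubility in mg solute per g solvent.
#' @export
from_mole_fraction <- function(x_e, m, masses = molar_masses()) {
  masses <- as_molar_masses(masses)
  if (any(!is.finite(x_e)) || any(x_e < 0) || any(x_e >= 1))
    stop("x_e must lie in [0, 1)", call. = FALSE)
  check_mass_fraction(m)
  n_solvent <- m / masses$cosolvent + (1 - m) / masses$water
  1000 * masses$solute * x_e * n_solvent / (1 - x_e)
}

check_mass_fraction <- function(m) {
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("cosolvent mass fraction m must lie in [0, 1]", call. = FALSE)
  invisible(m)
}

#' Composition of the saturated ternary solution
#'
#' Mole fractions of solute (`x1`), cosolvent (`x2`) and water (`x3`) in the
#' saturated solution: `x1` equals the measured solubility and the remaining
#' `1 - x1` is split between cosolvent and water in the mole ratio of the
#' solute-free blend, `(m/M2) : ((1-m)/M3)`.
#'
#' @param x_e mole-fraction solubility of the solute.
#' @inheritParams to_mole_fraction
#' @return A data frame with columns `x1`, `x2`, `x3` summing to 1 row-wise.
#' @export
saturated_composition <- function(x_e, m, masses = molar_masses()) {
  masses <- as_molar_masses(masses)
  if (any(!is.finite(x_e)) || any(x_e < 0) || any(x_e >= 1))
    stop("x_e must lie in [0, 1)", call. = FALSE)
  check_mass_fraction(m)
  n2 <- m / masses$cosolvent
  n3 <- (1 - m) / masses$water
  frac2 <- n2 / (n2 + n3)
  data.frame(x1 = x_e, x2 = (1 - x_e) * frac2, x3 = (1 - x_e) * (1 - frac2))
}

#' Assemble and validate a solubility dataset
#'
#' The central container of the package: a set of `(m, T)` solubility
#' records together with the molar masses and species labels.  Input rows
#' may carry solubility either as mole fraction (`x_e`) or as raw
#' `mg_per_g`; raw values are converted on construction.
#'
#' Validation enforces: `m` in \[0, 1\], `T_K > 0`, `x_e` in (0, 1), and
#' uniqueness of `(m, T_K)` pairs.  Completeness of the rectangular grid is
#' only required by operations that need it (mixture-model fits); see
#' [assert_complete_grid()].
#'
#' @param data a data frame with columns `m`, `T_K` and one of `x_e` or
#'   `mg_per_g`.
#' @param masses a [molar_masses()] object.
#' @param labels named character vector or list with entries `solute`,
#'   `cosolvent`, `water`.
#' @return An object of class `"solubility_dataset"`: a list with elements
#'   `data` (data frame `m`, `T_K`, `x_e`, sorted by `m` then `T_K`),
#'   `masses` and `labels`.
#' @export
solubility_dataset <- function(data, masses = molar_masses(),
                               labels = c(solute = "solute",
                                          cosolvent = "cosolvent",
                                          water = "water")) {
  masses <- as_molar_masses(masses)
  if (!is.data.frame(data))
    stop("`data` must be a data frame", call. = FALSE)
  if (!all(c("m", "T_K") %in% names(data)))
    stop("`data` must have columns m and T_K", call. = FALSE)
  if (nrow(data) == 0L)
    stop("dataset is empty", call. = FALSE)
  if (!("x_e" %in% names(data))) {
    if (!("mg_per_g" %in% names(data)))
      stop("`data` must have a solubility column: x_e or mg_per_g",
           call. = FALSE)
    data$x_e <- to_mole_fraction(data$mg_per_g, data$m, masses)
  }
  bad <- which(!is.finite(data$m) | data$m < 0 | data$m > 1)
  if (length(bad))
    stop("invalid mass fraction m in row ", bad[1L], call. = FALSE)
  bad <- which(!is.finite(data$T_K) | data$T_K <= 0)
  if (length(bad))
    stop("invalid temperature T_K in row ", bad[1L], call. = FALSE)
  bad <- which(!is.finite(data$x_e) | data$x_e <= 0 | data$x_e >= 1)
  if (length(bad))
    stop("mole-fraction solubility outside (0, 1) in row ", bad[1L],
         call. = FALSE)
  key <- paste(format(data$m, digits = 12), format(data$T_K, digits = 12))
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (m, T) pair in row %d: m = %g, T = %g K",
                 i, data$m[i], data$T_K[i]), call. = FALSE)
  }
  d <- data[order(data$m, data$T_K), c("m", "T_K", "x_e")]
  rownames(d) <- NULL
  structure(list(data = d, masses = masses, labels = as.list(labels)),
            class = "solubility_dataset")
}

#' @export
print.solubility_dataset <- function(x, ...) {
  d <- x$data
  cat(sprintf("Solubility dataset: %s in %s + %s\n",
              x$labels$solute, x$labels$cosolvent, x$labels$water))
  cat(sprintf("  %d records; m levels: %s; T range: %.1f-%.1f K\n",
              nrow(d), paste(sort(unique(d$m)), collapse = ", "),
              min(d$T_K), max(d$T_K)))
  cat(sprintf("  x_e range: %.3g-%.3g\n", min(d$x_e), max(d$x_e)))
  invisible(x)
}

#' Levels of a dataset
#'
#' Sorted unique cosolvent mass fractions and temperatures.
#' @param dataset a [solubility_dataset()].
#' @return A list with elements `m` and `T_K`.
#' @export
grid_levels <- function(dataset) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  list(m = sort(unique(dataset$data$m)), T_K = sort(unique(dataset$data$T_K)))
}

#' Require a complete rectangular (m x T) grid
#'
#' Mixture-model fits need every `(m, T)` cell present plus both pure
#' solvents (`m = 0` and `m = 1`).  Errors name the first missing cell.
#'
#' @param dataset a [solubility_dataset()].
#' @return Invisibly, the dataset.
#' @export
assert_complete_grid <- function(dataset) {
  lv <- grid_levels(dataset)
  if (!any(lv$m == 0) || !any(lv$m == 1))
    stop("grid must contain both pure solvents (m = 0 and m = 1)",
         call. = FALSE)
  d <- dataset$data
  for (mi in lv$m) for (ti in lv$T_K) {
    if (!any(d$m == mi & d$T_K == ti))
      stop(sprintf("incomplete grid: missing cell m = %g, T = %g K", mi, ti),
           call. = FALSE)
  }
  invisible(dataset)
}

#' Read a solubility dataset from CSV
#'
#' Expects a comma-separated file with a header row and columns `m`, `T_K`
#' and one of `x_e` or `mg_per_g`; lines starting with `#` are comments.
#' Raw `mg_per_g` values are converted to mole fractions with `masses`.
#'
#' @param path path to the CSV file.
#' @inheritParams solubility_dataset
#' @return A [solubility_dataset()].
#' @export
read_solubility_csv <- function(path, masses = molar_masses(),
                                labels = c(solute = "solute",
                                           cosolvent = "cosolvent",
                                           water = "water")) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, comment.char = "#", strip.white = TRUE)
  need <- c("m", "T_K")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!any(c("x_e", "mg_per_g") %in% names(d)))
    stop("missing solubility column (x_e or mg_per_g) in ", path,
         call. = FALSE)
  for (cn in intersect(c("m", "T_K", "x_e", "mg_per_g"), names(d))) {
    if (!is.numeric(d[[cn]])) {
      i <- which(is.na(suppressWarnings(as.numeric(d[[cn]]))))[1L]
      stop(sprintf("unparseable number in column %s, row %d of %s",
                   cn, if (is.na(i)) NA_integer_ else i, path), call. = FALSE)
    }
  }
  solubility_dataset(d, masses = masses, labels = labels)
}

#' Write a solubility dataset to CSV
#'
#' Writes columns `m`, `T_K`, `x_e` in the dialect read by
#' [read_solubility_csv()].
#'
#' @param dataset a [solubility_dataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_solubility_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "solubility_dataset"))
  utils::write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

constants_file <- function() {
  system.file("extdata", "piperine_constants.json", package = "cosolvr",
              mustWork = TRUE)
}

#' Physical constants of the piperine / Transcutol-HP / water system
#'
#' Reads the packaged constants table: molar masses of the three species,
#' fusion properties of piperine (fusion temperature, fusion enthalpy,
#' solid-to-liquid heat-capacity difference), and total Hansen solubility
#' parameters of the three pure substances.
#'
#' @return A list with elements `labels`, `molar_masses`, `fusion`,
#'   `hsp_total`.
#' @export
ppn_constants <- function() {
  jsonlite::read_json(constants_file(), simplifyVector = TRUE)
}

#' Fusion properties of piperine
#'
#' @return A [fusion_properties()] object with `T_fus` = 404.88 K,
#'   `dH_fus` = 32690 J/mol, `dC_p` = 80.74 J/(mol K).
#' @export
ppn_fusion_properties <- function() {
  f <- ppn_constants()$fusion
  fusion_properties(f$T_fus, f$dH_fus, f$dC_p)
}

#' Total Hansen solubility parameters of the piperine system
#'
#' @return Named numeric vector (MPa^0.5) with entries `solute`,
#'   `cosolvent`, `water`.
#' @export
ppn_hsp_totals <- function() {
  unlist(ppn_constants()$hsp_total)
}

#' The packaged piperine solubility grid
#'
#' Mole-fraction solubility of piperine in Transcutol-HP + water at 11
#' cosolvent mass fractions (0 to 1 by 0.1) and 5 temperatures (298.2 to
#' 318.2 K by 5 K), with the system's molar masses attached.
#'
#' @return A [solubility_dataset()] with 55 records.
#' @examples
#' ds <- ppn_fixture()
#' subset(ds$data, m == 1)
#' @export
ppn_fixture <- function() {
  cst <- ppn_constants()
  path <- system.file("extdata", "piperine_thp_water_solubility.csv",
                      package = "cosolvr", mustWork = TRUE)
  read_solubility_csv(path,
                      masses = as_molar_masses(cst$molar_masses),
                      labels = cst$labels)
}
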