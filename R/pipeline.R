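#' Rank cosolvency models by parsimony-aware fit quality
#'
#' Orders models by ascending average %RMSD; ties are broken by the smaller
#' number of fitted coefficients, then alphabetically by name.
#'
#' @param fits a data frame with columns `model`, `rmsd_pct`, `n_coef`.
#' @return The same data frame sorted into ranking order, with a `rank`
#'   column prepended.
#' @export
rank_models <- function(fits) {
  if (!is.data.frame(fits) || nrow(fits) == 0L ||
      !all(c("model", "rmsd_pct", "n_coef") %in% names(fits)))
    stop("fits must be a non-empty data frame with model, rmsd_pct, n_coef",
         call. = FALSE)
  out <- fits[order(fits$rmsd_pct, fits$n_coef, fits$model), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

model_names <- c("vant_hoff", "apelblat", "yalkowsky_roseman",
                 "jouyban_acree", "ja_vant_hoff")

#' Run the full cosolvency analysis
#'
#' Orchestrates every pipeline stage on a solubility dataset: ideal
#' solubility and activity coefficients, mixing thermodynamics, Hansen
#' solubility parameter blending (when HSP totals are supplied), the five
#' cosolvency model fits, and a parsimony-aware model ranking.  When
#' `out_dir` is given, all result tables are written there as CSV and the
#' model fits as JSON.
#'
#' @param dataset a complete-grid [solubility_dataset()].
#' @param fusion a [fusion_properties()] object for the solute.
#' @param hsp optional named numeric vector of total solubility parameters
#'   with entries `solute`, `cosolvent`, `water` (MPa^0.5), as returned by
#'   [ppn_hsp_totals()].
#' @param models character vector of models to fit (subset of
#'   `"vant_hoff"`, `"apelblat"`, `"yalkowsky_roseman"`, `"jouyban_acree"`,
#'   `"ja_vant_hoff"`), or `"all"`.
#' @param out_dir optional output directory for report artifacts.
#' @param strict logical; if `TRUE`, analysis warnings (for example dropped
#'   interaction terms) are raised as errors.
#' @return An object of class `"analysis_report"`: a list with elements
#'   `summary`, `ideal` (per-temperature ideal solubility), `thermo` (the
#'   [mixing_thermo()] table, including activity coefficients), `hsp`
#'   (blend table and proximity ranking, or `NULL`), `fits` (per-model
#'   results), `ranking`, `warnings`.
#' @examples
#' rep <- run_analysis(ppn_fixture(), ppn_fusion_properties(),
#'                     hsp = ppn_hsp_totals())
#' rep$ranking
#' @export
run_analysis <- function(dataset, fusion, hsp = NULL, models = "all",
                         out_dir = NULL, strict = FALSE) {
  stopifnot(inherits(dataset, "solubility_dataset"),
            inherits(fusion, "fusion_properties"))
  if (identical(models, "all")) models <- model_names
  unknown <- setdiff(models, model_names)
  if (length(unknown))
    stop("unknown model(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  needs_grid <- any(models %in% c("yalkowsky_roseman", "jouyban_acree",
                                  "ja_vant_hoff"))
  if (needs_grid) assert_complete_grid(dataset)
  warnings <- character(0)
  note <- function(msg) {
    if (strict) stop(msg, call. = FALSE)
    warnings <<- c(warnings, msg)
  }

  lv <- grid_levels(dataset)
  summary_tab <- data.frame(
    n_records = nrow(dataset$data),
    n_m_levels = length(lv$m), n_T_levels = length(lv$T_K),
    T_min = min(lv$T_K), T_max = max(lv$T_K))

  ideal <- data.frame(T_K = lv$T_K,
                      x_idl = ideal_solubility(lv$T_K, fusion))
  thermo <- mixing_thermo(dataset, fusion)

  hsp_out <- NULL
  if (!is.null(hsp)) {
    if (!all(c("solute", "cosolvent", "water") %in% names(hsp)))
      stop("hsp must name solute, cosolvent and water totals", call. = FALSE)
    blends <- data.frame(m = lv$m,
                         delta_mix = mixture_hsp(lv$m, hsp[["cosolvent"]],
                                                 hsp[["water"]]))
    cand <- data.frame(label = c("cosolvent", "water",
                                 sprintf("mixture m=%g", lv$m)),
                       delta = c(hsp[["cosolvent"]], hsp[["water"]],
                                 blends$delta_mix))
    hsp_out <- list(totals = hsp, blends = blends,
                    ranking = proximity_rank(hsp[["solute"]], cand))
  }

  fits <- list()
  comparison <- data.frame(model = character(0), rmsd_pct = numeric(0),
                           n_coef = integer(0))
  add_cmp <- function(model, rmsd, n_coef)
    comparison <<- rbind(comparison,
                         data.frame(model = model, rmsd_pct = rmsd,
                                    n_coef = n_coef))

  if ("vant_hoff" %in% models) {
    tab <- vant_hoff_table(dataset)
    fits$vant_hoff <- tab
    add_cmp("vant_hoff", mean(tab$rmsd_pct), 2L)
  }
  if ("apelblat" %in% models) {
    tab <- apelblat_table(dataset)
    fits$apelblat <- tab
    add_cmp("apelblat", mean(tab$rmsd_pct), 3L)
  }
  if ("yalkowsky_roseman" %in% models) {
    yl <- yalkowsky_table(dataset)
    fits$yalkowsky_roseman <- yl
    add_cmp("yalkowsky_roseman", yl$rmsd_pct, 0L)
  }
  if ("jouyban_acree" %in% models) {
    ja <- fit_jouyban_acree(dataset)
    if (length(ja$J) < 3L)
      note(sprintf(
        "jouyban_acree: interaction terms retained after selection: %s",
        if (length(ja$J)) paste(names(ja$J), collapse = ", ") else "none"))
    fits$jouyban_acree <- ja
    add_cmp("jouyban_acree", ja$rmsd_pct, length(ja$J))
  }
  if ("ja_vant_hoff" %in% models) {
    jv <- fit_ja_vant_hoff(dataset)
    if (length(jv$J) < 3L)
      note(sprintf(
        "ja_vant_hoff: interaction terms retained after selection: %s",
        if (length(jv$J)) paste(names(jv$J), collapse = ", ") else "none"))
    fits$ja_vant_hoff <- jv
    add_cmp("ja_vant_hoff", jv$rmsd_pct, 4L + length(jv$J))
  }

  report <- structure(list(summary = summary_tab, ideal = ideal,
                           thermo = thermo, hsp = hsp_out, fits = fits,
                           ranking = rank_models(comparison),
                           warnings = warnings),
                      class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, dataset, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Cosolvency analysis report\n")
  cat(sprintf("  %d records over %d m-levels x %d temperatures (%.1f-%.1f K)\n",
              x$summary$n_records, x$summary$n_m_levels, x$summary$n_T_levels,
              x$summary$T_min, x$summary$T_max))
  cat("  Ideal solubility: ",
      paste(sprintf("%.3g (%.1f K)", x$ideal$x_idl, x$ideal$T_K),
            collapse = ", "), "\n", sep = "")
  cat("  Model ranking (by average %RMSD, ties to fewer coefficients):\n")
  for (i in seq_len(nrow(x$ranking)))
    cat(sprintf("    %d. %-18s RMSD = %.2f%%  (%d coefficients)\n",
                x$ranking$rank[i], x$ranking$model[i], x$ranking$rmsd_pct[i],
                x$ranking$n_coef[i]))
  if (length(x$warnings))
    cat("  Warnings:\n", paste0("    - ", x$warnings, "\n"), sep = "")
  invisible(x)
}

## serialize the report tables as CSV + the fits as JSON
write_report <- function(report, dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  write_solubility_csv(dataset, file.path(out_dir, "dataset.csv"))
  wcsv(report$ideal, "ideal_solubility.csv")
  wcsv(report$thermo, "mixing_thermodynamics.csv")
  wcsv(report$ranking, "model_ranking.csv")
  if (!is.null(report$hsp)) {
    wcsv(report$hsp$blends, "hsp_blends.csv")
    wcsv(report$hsp$ranking, "hsp_proximity.csv")
  }
  if (!is.null(report$fits$vant_hoff))
    wcsv(report$fits$vant_hoff, "vant_hoff_fits.csv")
  if (!is.null(report$fits$apelblat))
    wcsv(report$fits$apelblat, "apelblat_fits.csv")
  if (!is.null(report$fits$yalkowsky_roseman)) {
    wcsv(report$fits$yalkowsky_roseman$table, "yalkowsky_predictions.csv")
    wcsv(report$fits$yalkowsky_roseman$rmsd_by_m, "yalkowsky_rmsd.csv")
  }
  serial <- list()
  for (nm in intersect(c("jouyban_acree", "ja_vant_hoff"),
                       names(report$fits))) {
    f <- report$fits[[nm]]
    serial[[nm]] <- list(
      coefficients = as.list(f$J),
      retained_terms = f$retained_terms, rmsd_pct = f$rmsd_pct)
    if (nm == "ja_vant_hoff")
      serial[[nm]]$pure_solvent <- list(A1 = f$A1, B1 = f$B1,
                                        A2 = f$A2, B2 = f$B2)
  }
  serial$warnings <- report$warnings
  jsonlite::write_json(serial, file.path(out_dir, "mixture_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
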