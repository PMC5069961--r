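#' Analysis configuration
#'
#' Bundles the thresholds and constants used across the pipeline: the marker
#' panel for growth-state scoring, the fold-change gates of the three report
#' filters, the significance level, the per-cell sulfur quota used in the DMSP
#' mass balance, and the pseudo-floor applied before log2 transforms.
#'
#' @param marker_genes Character vector of marker locus tags used for the
#'   growth-state score. Defaults to the 21 ribosomal-protein genes plus the
#'   elongation factor *fusA* (see [marker_panel()]).
#' @param fold_thresholds Named list with elements `table1` (any-condition
#'   filter, default 6), `table2` (stationary contrast filter, default 4) and
#'   `fig2_box` (scatter-plot box, default 5). All must exceed 1.
#' @param alpha Significance level for raw and corrected tests, in (0, 1).
#' @param sulfur_quota Per-cell sulfur requirement in attomoles/cell
#'   (1 amol = 1e-18 mol). Default 6.67.
#' @param pseudo_floor Positive value substituted for zeros before log2; if
#'   `NULL` (default) it is derived per matrix as half the smallest positive
#'   entry.
#' @param seed Integer seed recorded with the configuration.
#'
#' @return An object of class `sulfurlim_config` (a named list).
#' @examples
#' cfg <- analysis_config()
#' cfg$fold_thresholds$table1
#' @export
analysis_config <- function(marker_genes = marker_panel(),
                            fold_thresholds = list(table1 = 6, table2 = 4, fig2_box = 5),
                            alpha = 0.05,
                            sulfur_quota = 6.67,
                            pseudo_floor = NULL,
                            seed = 1L) {
  stopifnot(is.character(marker_genes), length(marker_genes) >= 1)
  for (nm in c("table1", "table2", "fig2_box")) {
    if (is.null(fold_thresholds[[nm]]) || fold_thresholds[[nm]] <= 1) {
      abort(sprintf("fold_thresholds$%s must be > 1", nm))
    }
  }
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  if (sulfur_quota <= 0) abort("sulfur_quota must be positive")
  if (!is.null(pseudo_floor) && pseudo_floor <= 0) abort("pseudo_floor must be positive")
  structure(
    list(
      marker_genes = marker_genes,
      fold_thresholds = fold_thresholds,
      alpha = alpha,
      sulfur_quota = sulfur_quota,
      pseudo_floor = pseudo_floor,
      seed = as.integer(seed)
    ),
    class = "sulfurlim_config"
  )
}

#' Default growth-state marker panel
#'
#' The 21 ribosomal-protein / elongation-factor genes whose transcript levels
#' drop sharply on entry to stationary phase: rpsC/E/G/H/J/L/N/S,
#' rplB/C/D/E/F/N/O/P/R/V/W/X and fusA. Returned as symbolic gene names;
#' [simulate_study()] and the scoring functions use these tags as locus ids.
#'
#' @return Character vector of 21 locus tags.
#' @export
marker_panel <- function() {
  c(
    paste0("rps", c("C", "E", "G", "H", "J", "L", "N", "S")),
    paste0("rpl", c("B", "C", "D", "E", "F", "N", "O", "P", "R", "V", "W", "X")),
    "fusA"
  )
}

# Unit conversions are centralized here.
# densities: cells/ml; concentrations: nM; quota: amol/cell (1e-18 mol/cell).

#' Sulfur consumed by a cell population
#'
#' Converts a cell density and a per-cell sulfur quota into the equivalent
#' dissolved-sulfur concentration:
#' `consumed [nM] = density [cells/ml] * 1000 [ml/L] * quota * 1e-18 [mol/cell] * 1e9 [nM per mol/L]`.
#'
#' @param density Cell density in cells/ml (vectorized, `>= 0`).
#' @param quota Per-cell sulfur quota in amol/cell (`> 0`).
#' @return Consumed sulfur concentration in nM.
#' @examples
#' consumed_sulfur(1e7, 6.67) # 66.7 nM
#' @export
consumed_sulfur <- function(density, quota = 6.67) {
  if (any(density < 0)) abort("density must be nonnegative")
  if (quota <= 0) abort("quota must be positive")
  density * 1000 * quota * 1e-18 * 1e9
}

#' Cell density supportable by a sulfur dose
#'
#' Inverse of [consumed_sulfur()]: the carrying capacity (cells/ml) set by an
#' initial DMSP dose at a given per-cell quota.
#'
#' @param dmsp_nM Initial DMSP concentration in nM (`> 0`).
#' @param quota Per-cell sulfur quota in amol/cell (`> 0`).
#' @return Density in cells/ml.
#' @examples
#' sulfur_capacity(100, 6.67) # about 1.5e7 cells/ml
#' @export
sulfur_capacity <- function(dmsp_nM, quota = 6.67) {
  if (any(dmsp_nM <= 0)) abort("dmsp_nM must be positive")
  if (quota <= 0) abort("quota must be positive")
  dmsp_nM * 1e-9 / (quota * 1e-18) / 1000
}

# half the smallest positive entry; used to floor zeros ahead of log2
default_pseudo_floor <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  if (length(pos) == 0) abort("matrix has no positive entries; cannot derive pseudo_floor")
  min(pos) / 2
}

floor_positive <- function(x, pseudo_floor = NULL) {
  pf <- if (is.null(pseudo_floor)) default_pseudo_floor(x) else pseudo_floor
  pmax(x, pf)
}

#' Read / write an analysis configuration file
#'
#' Plain-text YAML serialization of [analysis_config()], so a run's thresholds
#' and constants can be versioned alongside its data.
#'
#' @param path File path.
#' @param config An `sulfurlim_config` object.
#' @return `read_analysis_config()`: an `sulfurlim_config`;
#'   `write_analysis_config()`: `path`, invisibly.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  analysis_config(
    marker_genes = raw$marker_genes %||% marker_panel(),
    fold_thresholds = raw$fold_thresholds %||% list(table1 = 6, table2 = 4, fig2_box = 5),
    alpha = raw$alpha %||% 0.05,
    sulfur_quota = raw$sulfur_quota %||% 6.67,
    pseudo_floor = raw$pseudo_floor,
    seed = raw$seed %||% 1L
  )
}

#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "sulfurlim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
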