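#' Correlation between one gene's mRNA and protein series
#'
#' Pearson correlation of the log2 mRNA and log2 protein abundances across
#' paired time points from a single culture. Undefined (`NA`) with fewer than
#' 3 paired points or when either series is constant.
#'
#' @param mrna_series,protein_series Positive abundances at matched time
#'   points; pairs with a missing protein value are dropped.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
gene_correlation <- function(mrna_series, protein_series) {
  keep <- !is.na(mrna_series) & !is.na(protein_series)
  x <- log2(mrna_series[keep])
  y <- log2(protein_series[keep])
  if (length(x) < 3) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Per-gene mRNA-protein correlation across a culture's time course
#'
#' For every locus, correlates log2 transcript abundance with log2 protein
#' abundance (mean of the locus's observed peptide abundances per sample)
#' across the harvests of one culture, ordered by harvest day. Defaults to
#' the culture with the most time points (the five-point control culture in
#' the standard design). Loci with fewer than 3 complete pairs or a constant
#' series are dropped.
#'
#' @param study A `sulfurlim_study` (or supply `mrna`, `peptides`, `samples`).
#' @param culture Culture id; default the culture with most samples.
#' @param mrna,peptides,samples Components when not passing a study.
#' @return Tibble with `locus`, `r`, `n_timepoints`,
#'   `max_abs_log2_mrna_change` (log2 of the max/min transcript ratio across
#'   the series) and `culture_id`.
#' @export
correlate_layers <- function(study = NULL, culture = NULL,
                             mrna = NULL, peptides = NULL, samples = NULL) {
  if (inherits(study, "sulfurlim_study")) {
    mrna <- study$mrna
    peptides <- study$peptides
    samples <- study$samples
  }
  if (is.null(peptides)) abort("a peptide table is required to correlate layers")
  if (is.null(culture)) {
    culture <- samples %>%
      dplyr::count(.data$culture_id) %>%
      arrange(dplyr::desc(.data$n), .data$culture_id) %>%
      dplyr::slice(1) %>%
      dplyr::pull("culture_id")
  }
  smp <- samples %>%
    filter(.data$culture_id == culture) %>%
    arrange(.data$harvest_day)
  if (nrow(smp) < 3) abort(sprintf("culture %s has fewer than 3 time points", culture))
  m <- expr_matrix(mrna)[, smp$sample_id, drop = FALSE]
  prot <- peptides %>%
    filter(.data$sample_id %in% smp$sample_id, !is.na(.data$abundance)) %>%
    group_by(.data$locus, .data$sample_id) %>%
    summarise(abundance = mean(.data$abundance), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "abundance")
  out <- purrr::map(seq_len(nrow(prot)), function(i) {
    loc <- prot$locus[i]
    if (!loc %in% rownames(m)) return(NULL)
    pr <- unlist(prot[i, smp$sample_id[smp$sample_id %in% names(prot)]])
    pr <- setNames(rep(NA_real_, nrow(smp)), smp$sample_id) %>%
      replace(names(pr), pr)
    mr <- m[loc, ]
    keep <- !is.na(pr)
    r <- gene_correlation(mr, pr)
    if (is.na(r)) return(NULL)
    lg <- log2(mr[keep])
    tibble(
      locus = loc, r = r, n_timepoints = sum(keep),
      max_abs_log2_mrna_change = max(lg) - min(lg),
      culture_id = culture
    )
  })
  bind_rows(out)
}

#' Stratified summary of correlation by mRNA fold magnitude
#'
#' Splits correlation records at a transcript-change threshold (default
#' eightfold across the series) and reports the median mRNA-protein
#' correlation per stratum and their difference — large transcriptional
#' changes are expected to sit near the high end of the correlation axis.
#'
#' @param records Tibble from [correlate_layers()].
#' @param fold_cutoff Fold-change threshold defining the large-change stratum
#'   (default 8).
#' @return Tibble with one row per non-empty stratum (`stratum`, `n`,
#'   `median_r`); the difference (large minus small) is in attribute
#'   `"median_difference"` (`NA` when a stratum is absent).
#' @export
magnitude_correlation_summary <- function(records, fold_cutoff = 8) {
  if (nrow(records) == 0) abort("no correlation records")
  strat <- records %>%
    mutate(stratum = ifelse(.data$max_abs_log2_mrna_change >= log2(fold_cutoff),
                            "large_change", "small_change")) %>%
    group_by(.data$stratum) %>%
    summarise(n = dplyr::n(), median_r = median(.data$r), .groups = "drop")
  d <- if (all(c("large_change", "small_change") %in% strat$stratum)) {
    strat$median_r[strat$stratum == "large_change"] -
      strat$median_r[strat$stratum == "small_change"]
  } else {
    NA_real_
  }
  attr(strat, "median_difference") <- d
  strat
}

#' Correlation-versus-magnitude plot
#'
#' Scatter of per-gene mRNA-protein correlation against the magnitude of the
#' gene's transcript change across the time course, with the large-change
#' threshold marked.
#'
#' @param records Tibble from [correlate_layers()].
#' @param fold_cutoff Threshold line (default 8).
#' @return A ggplot object.
#' @export
plot_correlation_magnitude <- function(records, fold_cutoff = 8) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$max_abs_log2_mrna_change, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = log2(fold_cutoff), linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "max |log2 mRNA change| across time points",
                  y = "mRNA-protein correlation (Pearson, log2)") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
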