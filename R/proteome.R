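#' Peptide group mean
#'
#' Arithmetic mean of a peptide's non-missing observations within a sample
#' group; `NA` if the peptide was never observed in the group. Replicate
#' instrument runs are assumed to have been averaged into one observation per
#' (peptide, sample) upstream — the peptide table enforces uniqueness of that
#' pair.
#'
#' @param peptides Peptide table.
#' @param peptide_id Peptide identifier.
#' @param group Character vector of sample ids.
#' @return Nonnegative scalar, or `NA` when unobserved.
#' @export
peptide_group_mean <- function(peptides, peptide_id, group) {
  if (length(group) == 0) abort("group must be nonempty")
  v <- peptides$abundance[peptides$peptide_id == peptide_id &
                            peptides$sample_id %in% group]
  v <- v[!is.na(v)]
  if (length(v) == 0) NA_real_ else mean(v)
}

#' Peptide fold change with detection sentinels
#'
#' Ratio of a peptide's treatment-group mean to its reference-group mean.
#' When the peptide is detected in only one of the two groups the ratio is a
#' sentinel: `"POS_INF"` (treatment only) or `"INV_INF"` (reference only,
#' rendered "1/inf" in reports). Detected in neither: the peptide contributes
#' nothing (`"none"`).
#'
#' @param mean_b Treatment-group mean (or `NA`).
#' @param mean_a Reference-group mean (or `NA`).
#' @return List with `fold` (numeric or `NA`) and `sentinel`
#'   (`"finite"`, `"POS_INF"`, `"INV_INF"` or `"none"`).
#' @export
peptide_fold <- function(mean_b, mean_a) {
  if (!is.na(mean_b) && !is.na(mean_a)) {
    list(fold = mean_b / mean_a, sentinel = "finite")
  } else if (!is.na(mean_b)) {
    list(fold = NA_real_, sentinel = "POS_INF")
  } else if (!is.na(mean_a)) {
    list(fold = NA_real_, sentinel = "INV_INF")
  } else {
    list(fold = NA_real_, sentinel = "none")
  }
}

#' Protein fold change from peptide fold changes
#'
#' Averages finite peptide fold changes arithmetically into a protein fold
#' change. With no finite folds, a unanimous sentinel propagates; mixed
#' contradictory sentinels yield an undefined record with a warning.
#'
#' @param folds Numeric vector of finite peptide folds (may be empty).
#' @param sentinels Character vector of sentinels for peptides without a
#'   finite fold (`"POS_INF"`/`"INV_INF"`).
#' @return List with `fold`, `sentinel` (`"finite"`, `"POS_INF"`,
#'   `"INV_INF"`, `"undefined"`) and `n_peptides_used`.
#' @export
protein_fold <- function(folds, sentinels = character()) {
  folds <- folds[is.finite(folds)]
  sentinels <- sentinels[sentinels %in% c("POS_INF", "INV_INF")]
  if (length(folds) == 0 && length(sentinels) == 0) {
    abort("protein_fold needs at least one finite fold or sentinel")
  }
  if (length(folds) > 0) {
    return(list(fold = mean(folds), sentinel = "finite", n_peptides_used = length(folds)))
  }
  u <- unique(sentinels)
  if (length(u) == 1) {
    list(fold = NA_real_, sentinel = u, n_peptides_used = 0L)
  } else {
    warn("contradictory detection sentinels for one protein; fold undefined")
    list(fold = NA_real_, sentinel = "undefined", n_peptides_used = 0L)
  }
}

# one-sample two-sided t of log2 fold changes against 0; constant-data
# conventions: all-zero log folds -> 1, constant nonzero -> 0
log_fold_test_p <- function(log2_folds) {
  log2_folds <- log2_folds[is.finite(log2_folds)]
  if (length(log2_folds) < 2) return(NA_real_)
  if (sd(log2_folds) == 0) {
    return(if (all(log2_folds == 0)) 1 else 0)
  }
  t.test(log2_folds, mu = 0)$p.value
}

#' Protein-level significance from peptide fold changes
#'
#' Two-sided one-sample t test of the per-peptide log2 fold changes against 0,
#' using peptide multiplicity as replication. Undefined (`NA`) with fewer than
#' two finite peptide folds.
#'
#' @param peptides Peptide table.
#' @param locus Locus tag.
#' @param group_b,group_a Treatment and reference sample-id vectors.
#' @return p-value in \[0, 1\] or `NA`.
#' @export
protein_test_p <- function(peptides, locus, group_b, group_a) {
  rec <- protein_quant(peptides, group_b, group_a, loci = locus)
  rec$p_value[1]
}

#' Roll peptide observations up to protein fold changes
#'
#' For each locus: per-peptide group means in the treatment and reference
#' groups, per-peptide fold changes (with detection sentinels), arithmetic
#' averaging into a protein fold change, and a one-sample t test of the
#' per-peptide log2 folds. Loci with no observation in either group of the
#' comparison are `"undefined"`; loci supplied via `loci` but absent from the
#' table entirely are `"ND"` (never detected).
#'
#' @param peptides Peptide table.
#' @param group_b,group_a Treatment and reference sample-id vectors.
#' @param loci Optional locus universe; defaults to loci present in the table.
#' @return Tibble with `locus`, `fold`, `sentinel`, `n_peptides_used`,
#'   `p_value`.
#' @export
protein_quant <- function(peptides, group_b, group_a, loci = NULL) {
  if (length(group_a) == 0 || length(group_b) == 0) abort("groups must be nonempty")
  if (is.null(loci)) loci <- unique(peptides$locus)
  sub <- peptides %>%
    filter(.data$locus %in% loci, .data$sample_id %in% c(group_a, group_b)) %>%
    mutate(grp = ifelse(.data$sample_id %in% group_b, "b", "a"))
  means <- sub %>%
    group_by(.data$locus, .data$peptide_id, .data$grp) %>%
    summarise(m = if (all(is.na(.data$abundance))) NA_real_ else
      mean(.data$abundance, na.rm = TRUE), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "grp", values_from = "m")
  if (!"a" %in% names(means)) means$a <- NA_real_
  if (!"b" %in% names(means)) means$b <- NA_real_
  folds <- means %>%
    mutate(
      sentinel = case_when(
        !is.na(.data$b) & !is.na(.data$a) ~ "finite",
        !is.na(.data$b) ~ "POS_INF",
        !is.na(.data$a) ~ "INV_INF",
        TRUE ~ "none"
      ),
      fold = ifelse(.data$sentinel == "finite", .data$b / .data$a, NA_real_)
    ) %>%
    filter(.data$sentinel != "none")
  # vectorized rollup; equivalent to protein_fold()/log_fold_test_p() per
  # locus (consistency enforced by tests on hand-built fixtures)
  roll <- folds %>%
    mutate(lf = ifelse(.data$sentinel == "finite", log2(.data$fold), NA_real_)) %>%
    group_by(.data$locus) %>%
    summarise(
      n_fin = sum(.data$sentinel == "finite"),
      n_pos = sum(.data$sentinel == "POS_INF"),
      n_inv = sum(.data$sentinel == "INV_INF"),
      fold = mean(.data$fold[.data$sentinel == "finite"]), # NaN when none finite
      m_lf = mean(.data$lf, na.rm = TRUE),
      s_lf = sd(.data$lf[!is.na(.data$lf)]),
      .groups = "drop"
    ) %>%
    mutate(
      sentinel = case_when(
        .data$n_fin > 0 ~ "finite",
        .data$n_pos > 0 & .data$n_inv > 0 ~ "undefined",
        .data$n_pos > 0 ~ "POS_INF",
        TRUE ~ "INV_INF"
      ),
      fold = ifelse(.data$sentinel == "finite", .data$fold, NA_real_),
      n_peptides_used = ifelse(.data$sentinel == "finite", .data$n_fin, 0L),
      p_value = dplyr::case_when(
        sentinel != "finite" | n_fin < 2 ~ NA_real_,
        s_lf == 0 & m_lf == 0 ~ 1,
        s_lf == 0 ~ 0,
        TRUE ~ 2 * stats::pt(-abs(m_lf / (s_lf / sqrt(n_fin))), n_fin - 1)
      )
    )
  if (any(roll$sentinel == "undefined" & (roll$n_pos + roll$n_inv) > 0)) {
    warn("contradictory detection sentinels for some protein(s); fold undefined")
  }
  roll <- roll %>% select("locus", "fold", "sentinel", "n_peptides_used", "p_value")
  detected_anywhere <- unique(peptides$locus[!is.na(peptides$abundance)])
  all_out <- tibble(locus = loci) %>%
    left_join(roll, by = "locus") %>%
    mutate(
      sentinel = case_when(
        !is.na(.data$sentinel) ~ .data$sentinel,
        .data$locus %in% detected_anywhere ~ "undefined",
        TRUE ~ "ND"
      ),
      n_peptides_used = ifelse(is.na(.data$n_peptides_used), 0L, .data$n_peptides_used)
    )
  all_out
}

#' Census of never-detected proteins
#'
#' A locus is `ND` when it has zero non-missing peptide observations across
#' all samples (never detected by mass spectrometry at any time point).
#'
#' @param peptides Peptide table.
#' @param loci Locus universe to report on.
#' @return Tibble with `locus`, `detected` (logical), `n_observations`.
#' @export
nd_census <- function(peptides, loci) {
  obs <- peptides %>%
    filter(!is.na(.data$abundance)) %>%
    group_by(.data$locus) %>%
    summarise(n_observations = dplyr::n(), .groups = "drop")
  tibble(locus = loci) %>%
    left_join(obs, by = "locus") %>%
    mutate(
      n_observations = ifelse(is.na(.data$n_observations), 0L, as.integer(.data$n_observations)),
      detected = .data$n_observations > 0
    ) %>%
    select("locus", "detected", "n_observations")
}

#' Render a fold/sentinel pair the way reports print it
#'
#' @param fold Numeric fold (or `NA`).
#' @param sentinel Sentinel code.
#' @return Character: the fold, `"ND"`, `"Inf"`, `"1/Inf"` or `""`.
#' @export
render_fold <- function(fold, sentinel) {
  fold <- as.numeric(fold)
  dplyr::case_when(
    sentinel == "finite" ~ formatC(fold, format = "fg", digits = 4),
    sentinel == "POS_INF" ~ "Inf",
    sentinel == "INV_INF" ~ "1/Inf",
    sentinel == "ND" ~ "ND",
    TRUE ~ ""
  )
}
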