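#' Sample groups for the standard contrasts
#'
#' Maps samples to the four analysis groups — LE (sulfur-limited exponential),
#' LS (limited stationary), CE (control exponential, the reference), CS
#' (control stationary) — using assigned growth phases when a
#' [growth_state()] fit is given, otherwise nominal phases. Transitioning
#' samples belong to no group (they are excluded from the headline
#' contrasts).
#'
#' @param samples Sample metadata.
#' @param state Optional [growth_state()] fit; its assigned phases override
#'   the nominal ones.
#' @return Named list of sample-id character vectors (`LE`, `LS`, `CE`, `CS`).
#' @export
condition_groups <- function(samples, state = NULL) {
  phase <- samples$nominal_phase
  if (!is.null(state)) {
    a <- state$assignments
    phase <- a$phase[match(samples$sample_id, a$sample_id)]
    phase[is.na(phase)] <- samples$nominal_phase[is.na(phase)]
  }
  grp <- function(tr, ph) samples$sample_id[samples$treatment == tr & phase == ph]
  list(
    LE = grp("limited", "exponential"),
    LS = grp("limited", "stationary"),
    CE = grp("control", "exponential"),
    CS = grp("control", "stationary")
  )
}

#' Mean fold change between sample groups
#'
#' Ratio of arithmetic group means of linear-scale abundances:
#' `fold = mean(treatment) / mean(reference)`. Values below 1 denote lower
#' expression under treatment.
#'
#' @param mrna Expression table.
#' @param group_b Treatment sample ids.
#' @param group_a Reference sample ids.
#' @param loci Optional locus subset (default: all).
#' @return Tibble with `locus` and `fold`.
#' @export
mean_fold_change <- function(mrna, group_b, group_a, loci = NULL) {
  if (length(group_a) == 0 || length(group_b) == 0) abort("groups must be nonempty")
  if (length(intersect(group_a, group_b)) > 0) abort("groups must be disjoint")
  m <- expr_matrix(mrna)
  if (!is.null(loci)) {
    missing <- setdiff(loci, rownames(m))
    if (length(missing) > 0) abort(sprintf("locus not in matrix: %s", paste(missing, collapse = ", ")))
    m <- m[loci, , drop = FALSE]
  }
  bad <- setdiff(c(group_a, group_b), colnames(m))
  if (length(bad) > 0) abort(sprintf("sample not in matrix: %s", paste(bad, collapse = ", ")))
  ref <- rowMeans(m[, group_a, drop = FALSE])
  trt <- rowMeans(m[, group_b, drop = FALSE])
  if (any(ref == 0)) {
    abort(sprintf("zero reference mean for locus %s (apply a pseudo_floor upstream)",
                  rownames(m)[which(ref == 0)[1]]))
  }
  tibble(locus = rownames(m), fold = unname(trt / ref))
}

#' Welch test between two groups of abundances
#'
#' Two-sided Welch unequal-variance t test on log2-transformed abundances.
#' Conventions for degenerate input: both groups constant and equal gives
#' p = 1; constant and unequal gives p = 0; a group smaller than 2 gives
#' `NA` (flagged, excluded from multiple-testing correction).
#'
#' @param values_a,values_b Linear-scale abundances (positive).
#' @return p-value in \[0, 1\] or `NA`.
#' @export
group_test_p <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) return(NA_real_)
  la <- log2(values_a)
  lb <- log2(values_b)
  if (sd(la) == 0 && sd(lb) == 0) {
    return(if (la[1] == lb[1]) 1 else 0)
  }
  t.test(la, lb, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate correction at level `alpha` within one family
#' of tests. `NA` p-values are excluded from the correction and flagged
#' `FALSE`.
#'
#' @param p_values Numeric vector of p-values (`NA` allowed).
#' @param alpha Family FDR level.
#' @return Logical vector: corrected significance per entry.
#' @export
adjust_multiple <- function(p_values, alpha = 0.05) {
  adj <- p.adjust(p_values, method = "BH")
  !is.na(adj) & adj <= alpha
}

# Vectorized Welch p per locus between two sample groups; identical to
# group_test_p() applied row-wise (a consistency test enforces this).
mrna_group_p <- function(m, group_b, group_a) {
  la <- log2(m[, group_a, drop = FALSE])
  lb <- log2(m[, group_b, drop = FALSE])
  na <- ncol(la)
  nb <- ncol(lb)
  if (na < 2 || nb < 2) return(rep(NA_real_, nrow(m)))
  ma <- rowMeans(la)
  mb <- rowMeans(lb)
  va <- rowSums((la - ma)^2) / (na - 1)
  vb <- rowSums((lb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs((ma - mb) / sqrt(se2)), df)
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  unname(p)
}

#' Dual-layer differential expression
#'
#' Computes, for every locus, fold changes and significance on both layers and
#' all standard contrasts: mRNA and protein LE/LS/CS versus the
#' control-exponential reference, plus the direct stationary contrast
#' (`LSvsCS`, limited-stationary over control-stationary). The mRNA layer uses
#' arithmetic group-mean ratios and Welch tests on log2 abundances; the
#' protein layer uses the peptide-to-protein rollup of [protein_quant()].
#' Benjamini-Hochberg correction is applied within each (comparison x layer)
#' family.
#'
#' @param study A `sulfurlim_study`, or an expression table (then supply
#'   `samples` and optionally `peptides`).
#' @param state Optional [growth_state()] fit used to assign phases; by
#'   default one is fitted from the study (set `state = NA` to use nominal
#'   phases).
#' @param config [analysis_config()].
#' @param samples,peptides Used when `study` is a plain expression table.
#' @return Object of class `omics_de`: list with `records` (tibble: `locus`,
#'   `layer`, `comparison`, `fold`, `sentinel`, `p_value`, `significant_raw`,
#'   `significant_corrected`), `groups`, and `config`. [tidy()] returns the
#'   records, [glance()] per-family counts, [autoplot()] the exponential-phase
#'   mRNA-vs-protein scatter.
#' @examples
#' study <- simulate_study(seed = 1, peptides = FALSE)
#' de <- diff_expression(study)
#' head(tidy(de))
#' @export
diff_expression <- function(study, state = NULL, config = analysis_config(),
                            samples = NULL, peptides = NULL) {
  if (inherits(study, "sulfurlim_study")) {
    mrna <- study$mrna
    samples <- study$samples
    peptides <- study$peptides
    if (is.null(state)) state <- growth_state(study)
  } else {
    mrna <- study
    if (is.null(samples)) abort("samples metadata required")
  }
  if (length(state) == 1 && is.na(state)) state <- NULL
  groups <- condition_groups(samples, state)
  for (g in c("LE", "LS", "CE", "CS")) {
    if (length(groups[[g]]) == 0) abort(sprintf("empty sample group: %s", g))
  }
  m <- expr_matrix(mrna)
  comparisons <- list(
    LE = list(b = groups$LE, a = groups$CE),
    LS = list(b = groups$LS, a = groups$CE),
    CS = list(b = groups$CS, a = groups$CE),
    LSvsCS = list(b = groups$LS, a = groups$CS)
  )
  mrna_rec <- purrr::imap(comparisons, function(cmp, nm) {
    fc <- mean_fold_change(mrna, cmp$b, cmp$a)
    tibble(
      locus = fc$locus, layer = "mRNA", comparison = nm,
      fold = fc$fold, sentinel = "finite",
      p_value = mrna_group_p(m, cmp$b, cmp$a)
    )
  }) %>% bind_rows()
  prot_rec <- NULL
  if (!is.null(peptides)) {
    prot_rec <- purrr::imap(comparisons, function(cmp, nm) {
      protein_quant(peptides, cmp$b, cmp$a, loci = mrna$locus) %>%
        mutate(layer = "protein", comparison = nm) %>%
        select("locus", "layer", "comparison", "fold", "sentinel", "p_value")
    }) %>% bind_rows()
  }
  records <- bind_rows(mrna_rec, prot_rec) %>%
    group_by(.data$layer, .data$comparison) %>%
    mutate(
      significant_raw = !is.na(.data$p_value) & .data$p_value <= config$alpha,
      significant_corrected = adjust_multiple(.data$p_value, config$alpha)
    ) %>%
    ungroup()
  structure(
    list(records = records, groups = groups, config = config),
    class = "omics_de"
  )
}

de_records <- function(x) {
  if (inherits(x, "omics_de")) x$records else x
}

# A protein seen only in the treatment group (POS_INF) is an unbounded
# increase and passes any fold gate; a reference-only record ("1/Inf") is
# reported but does not by itself establish membership.
fold_passes <- function(fold, sentinel, threshold) {
  sentinel == "POS_INF" |
    (sentinel == "finite" & (fold >= threshold | fold <= 1 / threshold))
}

#' Any-condition sixfold filter
#'
#' Loci with a significant difference — at least a `threshold`-fold change
#' (default 6) supported by raw p <= alpha — in mRNA or protein expression
#' between the control-exponential reference and any other condition
#' (LE, LS or CS). A protein detected in only one group of a contrast
#' (sentinel Inf or 1/Inf) counts as passing the fold criterion.
#'
#' @param de An `omics_de` object or its records tibble.
#' @param threshold Fold gate (default 6).
#' @param alpha Raw-p gate (default 0.05).
#' @return Sorted character vector of locus tags.
#' @export
table1_filter <- function(de, threshold = 6, alpha = 0.05) {
  rec <- de_records(de) %>% filter(.data$comparison %in% c("LE", "LS", "CS"))
  hit <- fold_passes(rec$fold, rec$sentinel, threshold) &
    (rec$sentinel != "finite" | (!is.na(rec$p_value) & rec$p_value <= alpha))
  sort(unique(rec$locus[hit]))
}

#' Stationary-phase fourfold filter
#'
#' Loci with at least a `threshold`-fold difference (default 4) and p <= alpha
#' in mRNA or protein expression between sulfur-limited stationary and control
#' stationary samples (the direct `LSvsCS` contrast). Detection sentinels
#' count as passing the fold criterion.
#'
#' @inheritParams table1_filter
#' @param threshold Fold gate (default 4).
#' @return Sorted character vector of locus tags.
#' @export
table2_filter <- function(de, threshold = 4, alpha = 0.05) {
  rec <- de_records(de) %>% filter(.data$comparison == "LSvsCS")
  hit <- fold_passes(rec$fold, rec$sentinel, threshold) &
    (rec$sentinel != "finite" | (!is.na(rec$p_value) & rec$p_value <= alpha))
  sort(unique(rec$locus[hit]))
}

#' Exponential-phase fold-change scatter table
#'
#' The per-locus table behind the exponential-phase scatter: log10 mRNA and
#' protein fold changes (sulfur-limited over control), restricted to loci with
#' raw p <= alpha on either layer, flagging loci outside the `box`-fold box
#' (|log10 fold| > log10(box) on either axis).
#'
#' @param de An `omics_de` object or its records tibble.
#' @param box Fold box (default 5).
#' @param alpha Raw-p gate (default 0.05).
#' @return Tibble with `locus`, `log10_mrna_fold`, `log10_protein_fold`,
#'   `significant_mrna`, `significant_protein`, `outside_box`.
#' @export
fig2_scatter <- function(de, box = 5, alpha = 0.05) {
  rec <- de_records(de) %>% filter(.data$comparison == "LE")
  wide <- rec %>%
    mutate(lf = ifelse(.data$sentinel == "finite", log10(.data$fold), NA_real_),
           sig = !is.na(.data$p_value) & .data$p_value <= alpha) %>%
    select("locus", "layer", "lf", "sig") %>%
    tidyr::pivot_wider(names_from = "layer", values_from = c("lf", "sig"))
  if (!"lf_protein" %in% names(wide)) {
    wide$lf_protein <- NA_real_
    wide$sig_protein <- FALSE
  }
  wide %>%
    mutate(sig_protein = ifelse(is.na(.data$sig_protein), FALSE, .data$sig_protein)) %>%
    filter(.data$sig_mRNA | .data$sig_protein) %>%
    mutate(outside_box = (!is.na(.data$lf_mRNA) & abs(.data$lf_mRNA) > log10(box)) |
             (!is.na(.data$lf_protein) & abs(.data$lf_protein) > log10(box))) %>%
    rename(log10_mrna_fold = "lf_mRNA", log10_protein_fold = "lf_protein",
           significant_mrna = "sig_mRNA", significant_protein = "sig_protein")
}

#' @rdname diff_expression
#' @param x,object An `omics_de` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.omics_de <- function(x, ...) x$records

#' @rdname diff_expression
#' @exportS3Method generics::glance
glance.omics_de <- function(x, ...) {
  x$records %>%
    group_by(.data$layer, .data$comparison) %>%
    summarise(
      n_loci = dplyr::n(),
      n_significant_raw = sum(.data$significant_raw, na.rm = TRUE),
      n_significant_corrected = sum(.data$significant_corrected, na.rm = TRUE),
      .groups = "drop"
    )
}

#' @rdname diff_expression
#' @exportS3Method ggplot2::autoplot
autoplot.omics_de <- function(object, ...) {
  box <- object$config$fold_thresholds$fig2_box
  sc <- fig2_scatter(object, box = box, alpha = object$config$alpha)
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$log10_mrna_fold, y = .data$log10_protein_fold,
                                   colour = .data$outside_box)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::annotate("rect", xmin = -log10(box), xmax = log10(box),
                      ymin = -log10(box), ymax = log10(box),
                      fill = NA, colour = "grey40", linetype = 2) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = "log10 fold change, mRNA (limited/control, exponential)",
      y = "log10 fold change, protein",
      colour = sprintf("> %g-fold", box)
    ) +
    ggplot2::theme_minimal()
}

#' @export
print.omics_de <- function(x, ...) {
  cat("<omics_de>\n")
  print(glance(x))
  invisible(x)
}
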