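#' Min-max normalize marker-gene transcripts
#'
#' For each marker gene, abundances are log2 transformed and rescaled to
#' span \[0, 1\] across the samples:
#' `n(g, s) = (log2 x(g,s) - min_s log2 x) / (max_s log2 x - min_s log2 x)`,
#' so every marker row attains both 0 (its minimum observed abundance) and 1
#' (its maximum).
#'
#' @param mrna Expression table containing all panel loci.
#' @param panel Character vector of marker locus tags (default
#'   [marker_panel()]).
#' @param pseudo_floor Positive floor applied before log2; default half the
#'   smallest positive value in the marker submatrix.
#' @return Numeric matrix (markers x samples) of values in \[0, 1\].
#' @export
normalize_markers <- function(mrna, panel = marker_panel(), pseudo_floor = NULL) {
  validate_expression(mrna)
  missing <- setdiff(panel, mrna$locus)
  if (length(missing) > 0) {
    abort(sprintf("marker(s) absent from expression table: %s", paste(missing, collapse = ", ")))
  }
  m <- expr_matrix(mrna)[panel, , drop = FALSE]
  if (ncol(m) < 2) abort("need at least 2 samples to normalize markers")
  lg <- log2(floor_positive(m, pseudo_floor))
  rng <- apply(lg, 1, range)
  flat <- which(rng[2, ] - rng[1, ] == 0)
  if (length(flat) > 0) {
    abort(sprintf("marker constant across samples (normalization undefined): %s",
                  paste(panel[flat], collapse = ", ")))
  }
  (lg - rng[1, ]) / (rng[2, ] - rng[1, ])
}

#' Growth-state score
#'
#' Per-sample mean of the min-max-normalized log2 marker expression. A score
#' of 1 means every marker is at its maximum observed abundance in that sample
#' (deep exponential growth); 0 means every marker is at its minimum (deep
#' stationary phase).
#'
#' @param normalized Marker x sample matrix from [normalize_markers()].
#' @return Named numeric vector of scores in \[0, 1\], one per sample.
#' @export
growth_state_score <- function(normalized) {
  if (any(normalized < 0 | normalized > 1)) abort("normalized values must lie in [0, 1]")
  colMeans(normalized)
}

# Exact SSE-optimal clustering of 1-D scores into 3 groups. Any optimum is
# contiguous in sorted order, so it suffices to scan the two split points;
# the global optimum is a fixed point of Lloyd's k-means. Ties at a boundary
# go to the lower-score cluster.
cluster_scores_3 <- function(scores) {
  n <- length(scores)
  if (length(unique(scores)) < 3) abort("need at least 3 distinct scores to form three clusters")
  ord <- order(scores, method = "radix")
  x <- scores[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse <- function(i, j) { # segment [i, j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  best <- Inf
  cut <- c(1L, 2L)
  for (a in 1:(n - 2)) {
    for (b in (a + 1):(n - 1)) {
      tot <- sse(1, a) + sse(a + 1, b) + sse(b + 1, n)
      if (tot < best - 1e-12) {
        best <- tot
        cut <- c(a, b)
      }
    }
  }
  grp <- integer(n)
  grp[ord] <- rep(1:3, c(cut[1], cut[2] - cut[1], n - cut[2]))
  grp # 1 = lowest-score cluster
}

#' Classify samples into growth phases from their scores
#'
#' Clusters the 1-D growth-state scores into three groups (exact
#' sum-of-squares-optimal 3-partition, the converged k-means solution) and
#' labels them by mean score: lowest = stationary, middle = transitioning,
#' highest = exponential. If nominal phases are supplied, samples whose
#' cluster label differs are flagged `reclassified`; reclassification only
#' relabels, it never drops samples.
#'
#' @param scores Named numeric vector of growth-state scores (>= 3 samples
#'   spanning >= 3 distinct values).
#' @param nominal_phase Optional character vector of nominal phase labels,
#'   parallel to `scores`.
#' @return Tibble with `sample_id`, `score`, `phase`, `nominal_phase`,
#'   `reclassified`.
#' @export
classify_phases <- function(scores, nominal_phase = NULL) {
  grp <- cluster_scores_3(scores)
  phase <- c("stationary", "transitioning", "exponential")[grp]
  out <- tibble(
    sample_id = if (is.null(names(scores))) as.character(seq_along(scores)) else names(scores),
    score = unname(scores),
    phase = phase
  )
  if (!is.null(nominal_phase)) {
    out$nominal_phase <- nominal_phase
    out$reclassified <- out$phase != nominal_phase
  } else {
    out$nominal_phase <- NA_character_
    out$reclassified <- NA
  }
  out
}

#' Growth-state classification of a study
#'
#' Runs the full growth-state procedure on a study: normalize the marker
#' panel, average into per-sample scores, cluster into three phases, and
#' compare with the nominal harvest labels.
#'
#' @param study A `sulfurlim_study`, or an expression table.
#' @param samples Sample metadata (ignored when `study` is a
#'   `sulfurlim_study`).
#' @param markers Marker locus tags; defaults to the study's marker set or
#'   [marker_panel()].
#' @param pseudo_floor Passed to [normalize_markers()].
#' @return Object of class `growth_state` with elements `assignments`
#'   (tibble), `normalized` (marker matrix) and `centers` (per-phase mean
#'   scores). [tidy()] returns the assignments; [glance()] a one-row summary;
#'   [autoplot()] a score dot plot.
#' @examples
#' study <- simulate_study(seed = 1, peptides = FALSE)
#' fit <- growth_state(study)
#' glance(fit)
#' @export
growth_state <- function(study, samples = NULL, markers = NULL, pseudo_floor = NULL) {
  if (inherits(study, "sulfurlim_study")) {
    mrna <- study$mrna
    samples <- study$samples
    if (is.null(markers)) markers <- study$markers
  } else {
    mrna <- study
    if (is.null(samples)) abort("samples metadata required when not passing a sulfurlim_study")
    if (is.null(markers)) markers <- marker_panel()
  }
  norm <- normalize_markers(mrna, markers, pseudo_floor)
  scores <- growth_state_score(norm)
  nominal <- samples$nominal_phase[match(names(scores), samples$sample_id)]
  assignments <- classify_phases(scores, nominal)
  centers <- assignments %>%
    group_by(.data$phase) %>%
    summarise(mean_score = mean(.data$score), n = dplyr::n(), .groups = "drop")
  structure(
    list(assignments = assignments, normalized = norm, centers = centers),
    class = "growth_state"
  )
}

#' @export
print.growth_state <- function(x, ...) {
  cat("<growth_state>\n")
  print(x$centers)
  cat(sprintf("  %d sample(s) reclassified\n", sum(x$assignments$reclassified, na.rm = TRUE)))
  invisible(x)
}

#' @rdname growth_state
#' @param x A `growth_state` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.growth_state <- function(x, ...) x$assignments

#' @rdname growth_state
#' @exportS3Method generics::glance
glance.growth_state <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_samples = nrow(a),
    n_exponential = sum(a$phase == "exponential"),
    n_transitioning = sum(a$phase == "transitioning"),
    n_stationary = sum(a$phase == "stationary"),
    n_reclassified = sum(a$reclassified, na.rm = TRUE)
  )
}

#' @rdname growth_state
#' @param object A `growth_state` object.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_state <- function(object, ...) {
  a <- object$assignments %>%
    mutate(phase = factor(.data$phase, c("stationary", "transitioning", "exponential")))
  ggplot2::ggplot(a, ggplot2::aes(x = .data$phase, y = .data$score, colour = .data$reclassified)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
                                 na.value = "grey30") +
    ggplot2::labs(x = "assigned phase", y = "growth state score",
                  colour = "reclassified") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
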