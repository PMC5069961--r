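#' DMSP mass balance for a set of replicate cultures
#'
#' Per-cell sulfur-quota bookkeeping: each culture's late-stationary density
#' implies a consumed DMSP concentration ([consumed_sulfur()]); the remainder
#' of the initial dose is unaccounted for by biomass. Consumption exceeding
#' the dose is floored at zero with a warning (conservation then no longer
#' holds exactly for that culture). The across-culture spread is the sample
#' (n-1) standard deviation.
#'
#' @param initial Initial DMSP dose, nM (> 0).
#' @param densities Late-stationary densities, cells/ml, one per culture.
#' @param quota Per-cell sulfur quota, amol/cell.
#' @param treatment Optional treatment label carried into the result.
#' @return Object of class `dmsp_budget`: list with `per_culture` (tibble:
#'   `culture`, `density`, `consumed`, `unaccounted`), `initial_dmsp`,
#'   `mean_unaccounted`, `sd_unaccounted`, `treatment`.
#' @examples
#' unaccounted_dmsp(100, c(9.1e6, 9.3e6), quota = 6.67)
#' @export
unaccounted_dmsp <- function(initial, densities, quota = 6.67, treatment = NA_character_) {
  if (initial <= 0) abort("initial DMSP must be positive")
  if (length(densities) == 0) abort("at least one culture density is required")
  consumed <- consumed_sulfur(densities, quota)
  un <- initial - consumed
  if (any(un < 0)) {
    warn("consumed sulfur exceeds the initial dose for some culture(s); flooring at 0")
    un <- pmax(un, 0)
  }
  per_culture <- tibble(
    culture = if (is.null(names(densities))) as.character(seq_along(densities)) else names(densities),
    density = unname(densities),
    consumed = unname(consumed),
    unaccounted = unname(un)
  )
  structure(
    list(
      per_culture = per_culture,
      initial_dmsp = initial,
      mean_unaccounted = mean(un),
      sd_unaccounted = if (length(un) > 1) sd(un) else NA_real_,
      treatment = treatment
    ),
    class = "dmsp_budget"
  )
}

#' @export
print.dmsp_budget <- function(x, ...) {
  cat(sprintf("<dmsp_budget>%s initial %g nM: unaccounted %.3g nM (SD %.3g) over %d culture(s)\n",
              if (is.na(x$treatment)) "" else paste0(" [", x$treatment, "]"),
              x$initial_dmsp, x$mean_unaccounted, x$sd_unaccounted,
              nrow(x$per_culture)))
  invisible(x)
}

#' @rdname unaccounted_dmsp
#' @param x A `dmsp_budget` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dmsp_budget <- function(x, ...) {
  x$per_culture %>%
    mutate(treatment = x$treatment, initial_dmsp = x$initial_dmsp)
}

#' @rdname unaccounted_dmsp
#' @exportS3Method generics::glance
glance.dmsp_budget <- function(x, ...) {
  tibble(
    treatment = x$treatment, initial_dmsp = x$initial_dmsp,
    n_cultures = nrow(x$per_culture),
    mean_unaccounted = x$mean_unaccounted, sd_unaccounted = x$sd_unaccounted
  )
}

#' Sulfur budget of a study, by treatment
#'
#' Applies [unaccounted_dmsp()] to each treatment's stationary-phase harvest
#' densities (one per culture), using the study's DMSP doses.
#'
#' @param samples Sample metadata (or a `sulfurlim_study`).
#' @param doses Named numeric: initial DMSP dose (nM) per treatment.
#' @param quota Per-cell sulfur quota, amol/cell.
#' @return Tibble with one row per treatment: `treatment`, `initial_dmsp`,
#'   `n_cultures`, `mean_unaccounted`, `sd_unaccounted`.
#' @export
sulfur_budget <- function(samples, doses = c(limited = 100, control = 1000),
                          quota = 6.67) {
  if (inherits(samples, "sulfurlim_study")) samples <- samples$samples
  stn <- samples %>%
    filter(.data$nominal_phase == "stationary") %>%
    group_by(.data$treatment, .data$culture_id) %>%
    summarise(density = .data$density[which.max(.data$harvest_day)], .groups = "drop")
  purrr::map(unique(stn$treatment), function(tr) {
    d <- stn %>% filter(.data$treatment == tr)
    glance(unaccounted_dmsp(doses[[tr]], setNames(d$density, d$culture_id),
                            quota, treatment = tr))
  }) %>% bind_rows()
}

#' Growth curves with harvest points
#'
#' @param object A `sulfurlim_study`.
#' @param ... Unused.
#' @return A ggplot of daily densities per culture, coloured by treatment,
#'   with harvest samples overplotted.
#' @exportS3Method ggplot2::autoplot
autoplot.sulfurlim_study <- function(object, ...) {
  ggplot2::ggplot(object$growth,
                  ggplot2::aes(x = .data$day, y = .data$density,
                               group = .data$culture_id,
                               colour = grepl("^L", .data$culture_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$samples,
                        ggplot2::aes(x = .data$harvest_day, y = .data$density,
                                     shape = .data$nominal_phase),
                        inherit.aes = FALSE, size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "goldenrod3", `FALSE` = "steelblue"),
                                 labels = c(`TRUE` = "limited", `FALSE` = "control")) +
    ggplot2::labs(x = "day", y = "cells/ml", colour = "treatment", shape = "harvest") +
    ggplot2::theme_minimal()
}
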