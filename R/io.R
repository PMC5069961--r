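#' Expression tables, peptide tables and sample metadata
#'
#' The pipeline works on three plain tibbles:
#'
#' * **expression table** — one row per locus: a character `locus` column
#'   followed by one numeric column per sample, holding nonnegative
#'   linear-scale abundances. Complete by construction: a missing transcript
#'   value is a validation error (missingness is a proteomics-only concept).
#' * **peptide table** — long form, one row per (peptide, sample) observation:
#'   `peptide_id`, `locus`, `sample_id`, `abundance` (nonnegative double,
#'   `NA` = not detected).
#' * **sample metadata** — one row per harvest sample: `sample_id`,
#'   `culture_id`, `treatment` (`"limited"`/`"control"`), `harvest_day`,
#'   `density` (cells/ml), `nominal_phase`
#'   (`"exponential"`/`"transitioning"`/`"stationary"`/`"unassigned"`).
#'
#' @name sulfurlim-tables
NULL

expr_loci <- function(mrna) mrna$locus

expr_samples <- function(mrna) setdiff(names(mrna), "locus")

# numeric matrix view (loci x samples) of an expression tibble
expr_matrix <- function(mrna) {
  m <- as.matrix(mrna[, expr_samples(mrna), drop = FALSE])
  rownames(m) <- mrna$locus
  m
}

#' Validate an expression table
#'
#' Checks the invariants of the expression table: a character `locus` column
#' with no duplicates, at least one sample column, all values finite,
#' nonnegative and non-missing.
#'
#' @param mrna Expression table (see [sulfurlim-tables]).
#' @return `mrna`, invisibly, if valid; otherwise an error naming the
#'   offending locus or cell.
#' @export
validate_expression <- function(mrna) {
  if (!is.data.frame(mrna) || !"locus" %in% names(mrna)) {
    abort("expression table must be a data frame with a 'locus' column")
  }
  dup <- unique(mrna$locus[duplicated(mrna$locus)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate locus tag(s): %s", paste(dup, collapse = ", ")))
  }
  smp <- expr_samples(mrna)
  if (length(smp) == 0) abort("expression table has no sample columns")
  for (s in smp) {
    v <- mrna[[s]]
    if (!is.numeric(v)) abort(sprintf("sample column '%s' is not numeric", s))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("missing value at locus '%s', sample '%s': expression tables must be complete",
                    mrna$locus[bad[1]], s))
    }
    neg <- which(v < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative abundance at locus '%s', sample '%s'",
                    mrna$locus[neg[1]], s))
    }
  }
  invisible(mrna)
}

#' Read / write an expression table
#'
#' Tab-separated, first column locus tags, header row of sample ids, values
#' linear-scale abundances. `read_expression_matrix()` validates on read;
#' `write_expression_matrix()` writes with full double precision so that a
#' write/read round trip reproduces values bit-identically.
#'
#' @param path File path.
#' @param mrna Expression table to write.
#' @return `read_expression_matrix()`: a validated expression tibble.
#'   `write_expression_matrix()`: `path`, invisibly.
#' @export
read_expression_matrix <- function(path) {
  mrna <- readr::read_tsv(path, col_types = readr::cols(
    locus = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  names(mrna)[1] <- "locus"
  validate_expression(mrna)
  mrna
}

#' @rdname read_expression_matrix
#' @export
write_expression_matrix <- function(mrna, path) {
  validate_expression(mrna)
  readr::write_tsv(mrna, path, progress = FALSE)
  invisible(path)
}

#' Validate a peptide table
#'
#' Checks the long-form peptide table: required columns present, abundances
#' nonnegative or `NA` (= not detected), and no duplicated
#' (`peptide_id`, `sample_id`) pair.
#'
#' @param peptides Peptide table (see [sulfurlim-tables]).
#' @return `peptides`, invisibly, if valid.
#' @export
validate_peptides <- function(peptides) {
  need <- c("peptide_id", "locus", "sample_id", "abundance")
  miss <- setdiff(need, names(peptides))
  if (length(miss) > 0) abort(sprintf("peptide table lacks column(s): %s", paste(miss, collapse = ", ")))
  if (any(peptides$abundance < 0, na.rm = TRUE)) abort("peptide abundances must be nonnegative")
  key <- paste(peptides$peptide_id, peptides$sample_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate peptide observation: peptide '%s' in sample '%s'",
                  peptides$peptide_id[dup[1]], peptides$sample_id[dup[1]]))
  }
  invisible(peptides)
}

#' Read / write a peptide table
#'
#' Long format with columns `peptide_id`, `locus`, `sample_id`, `abundance`;
#' comma- or tab-separated (sniffed from the header line). Missing
#' observations may be encoded as an empty field or `NA` on read and are
#' written as empty fields.
#'
#' @param path File path.
#' @param peptides Peptide table to write.
#' @return `read_peptide_table()`: a validated peptide tibble.
#'   `write_peptide_table()`: `path`, invisibly.
#' @export
read_peptide_table <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  peptides <- readr::read_delim(
    path, delim = delim, na = c("", "NA"), progress = FALSE,
    col_types = readr::cols(
      peptide_id = readr::col_character(),
      locus = readr::col_character(),
      sample_id = readr::col_character(),
      abundance = readr::col_double()
    )
  )
  validate_peptides(peptides)
  peptides
}

#' @rdname read_peptide_table
#' @export
write_peptide_table <- function(peptides, path) {
  validate_peptides(peptides)
  readr::write_csv(peptides, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Tab-separated with columns `sample_id`, `culture_id`, `treatment`,
#' `harvest_day`, `density`, `nominal_phase`.
#'
#' @param path File path.
#' @param samples Sample metadata tibble to write.
#' @return A validated tibble (read) or `path`, invisibly (write).
#' @export
read_sample_metadata <- function(path) {
  samples <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    culture_id = readr::col_character(),
    treatment = readr::col_character(),
    harvest_day = readr::col_double(),
    density = readr::col_double(),
    nominal_phase = readr::col_character()
  ), progress = FALSE)
  validate_samples(samples)
  samples
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(samples, path) {
  validate_samples(samples)
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Validate sample metadata
#'
#' @param samples Sample metadata tibble.
#' @return `samples`, invisibly, if valid.
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "culture_id", "treatment", "harvest_day", "density", "nominal_phase")
  miss <- setdiff(need, names(samples))
  if (length(miss) > 0) abort(sprintf("sample metadata lacks column(s): %s", paste(miss, collapse = ", ")))
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  if (length(dup) > 0) abort(sprintf("duplicate sample_id(s): %s", paste(dup, collapse = ", ")))
  if (!all(samples$treatment %in% c("limited", "control"))) {
    abort("treatment must be 'limited' or 'control'")
  }
  ok_phase <- c("exponential", "transitioning", "stationary", "unassigned")
  if (!all(samples$nominal_phase %in% ok_phase)) {
    abort(sprintf("nominal_phase must be one of: %s", paste(ok_phase, collapse = ", ")))
  }
  if (any(samples$density <= 0)) abort("density must be positive")
  if (any(samples$harvest_day < 0)) abort("harvest_day must be nonnegative")
  bad <- samples %>%
    arrange(.data$culture_id, .data$harvest_day) %>%
    group_by(.data$culture_id) %>%
    summarise(ok = !is.unsorted(.data$harvest_day), .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0) {
    abort(sprintf("harvest_day not nondecreasing within culture(s): %s",
                  paste(bad$culture_id, collapse = ", ")))
  }
  invisible(samples)
}

#' Cross-validate a study's three inputs
#'
#' Cross-references sample ids across metadata, expression table and peptide
#' table. Samples present in one input but absent from another are reported as
#' orphans; an empty intersection between metadata and expression samples is
#' fatal.
#'
#' @param samples Sample metadata tibble.
#' @param mrna Expression table.
#' @param peptides Peptide table (optional; `NULL` to skip).
#' @return A tibble of orphans with columns `sample_id`, `present_in`,
#'   `missing_from`; zero rows when fully consistent.
#' @export
validate_study <- function(samples, mrna, peptides = NULL) {
  validate_samples(samples)
  validate_expression(mrna)
  meta_ids <- samples$sample_id
  expr_ids <- expr_samples(mrna)
  report <- list()
  orphan <- function(ids, present_in, missing_from) {
    if (length(ids) == 0) return(NULL)
    tibble(sample_id = ids, present_in = present_in, missing_from = missing_from)
  }
  report$a <- orphan(setdiff(expr_ids, meta_ids), "expression", "metadata")
  report$b <- orphan(setdiff(meta_ids, expr_ids), "metadata", "expression")
  if (length(intersect(meta_ids, expr_ids)) == 0) {
    abort("no samples shared between metadata and expression table")
  }
  if (!is.null(peptides)) {
    validate_peptides(peptides)
    pep_ids <- unique(peptides$sample_id)
    report$c <- orphan(setdiff(pep_ids, meta_ids), "peptides", "metadata")
    if (length(intersect(meta_ids, pep_ids)) == 0) {
      abort("no samples shared between metadata and peptide table")
    }
  }
  out <- bind_rows(report)
  if (nrow(out) == 0) {
    tibble(sample_id = character(), present_in = character(), missing_from = character())
  } else {
    out
  }
}
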