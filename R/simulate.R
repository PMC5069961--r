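#' Growth model parameters
#'
#' Parameters of the nutrient-quota batch-growth model. The effective carrying
#' capacity is the smaller of the density supportable by the initial DMSP dose
#' (dose / per-cell quota, see [sulfur_capacity()]) and a non-sulfur carrying
#' capacity `k_other` standing in for whatever else (carbon, space) caps the
#' culture.
#'
#' @param initial_density Inoculum density, cells/ml (> 0).
#' @param growth_rate Per-day logistic rate (> 0).
#' @param dmsp_initial Initial DMSP dose, nM (> 0).
#' @param sulfur_quota Per-cell sulfur quota, amol/cell (> 0).
#' @param k_other Non-sulfur carrying capacity, cells/ml (> 0).
#' @return A `growth_params` list with the fields above plus `capacity`, the
#'   effective carrying capacity in cells/ml.
#' @examples
#' growth_params(dmsp_initial = 100)$capacity # sulfur-capped at 1.5e7
#' @export
growth_params <- function(initial_density = 4e5,
                          growth_rate = 0.55,
                          dmsp_initial = 100,
                          sulfur_quota = 6.67,
                          k_other = 3.5e7) {
  vals <- c(initial_density, growth_rate, dmsp_initial, sulfur_quota, k_other)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all growth parameters must be positive and finite")
  }
  capacity <- min(sulfur_capacity(dmsp_initial, sulfur_quota), k_other)
  structure(
    list(
      initial_density = initial_density, growth_rate = growth_rate,
      dmsp_initial = dmsp_initial, sulfur_quota = sulfur_quota,
      k_other = k_other, capacity = capacity
    ),
    class = "growth_params"
  )
}

#' Simulate a batch-culture growth curve
#'
#' Deterministic discrete-day logistic map toward the effective carrying
#' capacity: `N[t+1] = N[t] + r * N[t] * (1 - N[t]/K)`. Emulates daily flow
#' cytometry counts of a batch culture growing to a nutrient-set plateau.
#'
#' @param params A [growth_params()] object.
#' @param days Number of days to simulate (>= 1).
#' @param culture_id Optional culture label carried into the output.
#' @return Tibble with columns `culture_id`, `day` (0..days), `density`
#'   (cells/ml).
#' @export
simulate_growth <- function(params, days, culture_id = "culture") {
  if (!inherits(params, "growth_params")) abort("params must be a growth_params object")
  if (days < 1) abort("days must be >= 1")
  n <- numeric(days + 1)
  n[1] <- params$initial_density
  for (t in seq_len(days)) {
    n[t + 1] <- n[t] + params$growth_rate * n[t] * (1 - n[t] / params$capacity)
  }
  tibble(culture_id = culture_id, day = 0:days, density = n)
}

#' Assay noise model
#'
#' Multiplicative lognormal noise (chosen for positivity) with coefficient of
#' variation `cv`; `sigma^2 = log(1 + cv^2)` and the mean is fixed at 1 so
#' noise is unbiased on the linear scale. Peptide-level parameters control
#' how many peptides a protein emits, the spread of their fixed ionization
#' efficiencies, and missingness (detection limit and random dropout).
#'
#' @param cv_mrna Transcript assay coefficient of variation (default 0.2).
#' @param cv_protein Peptide observation coefficient of variation (default 0.3).
#' @param peptides_per_protein Integer range (length-2) of peptides per
#'   protein, inclusive.
#' @param peptide_efficiency_sd Lognormal sdlog of per-peptide fixed
#'   efficiencies.
#' @param detection_limit Observations below this abundance are censored to
#'   missing (0 disables).
#' @param dropout_rate Probability that an otherwise-detected observation is
#'   missing.
#' @return A `noise_model` list.
#' @export
noise_model <- function(cv_mrna = 0.2,
                        cv_protein = 0.3,
                        peptides_per_protein = c(2L, 5L),
                        peptide_efficiency_sd = 0.3,
                        detection_limit = 0,
                        dropout_rate = 0.05) {
  stopifnot(cv_mrna >= 0, cv_protein >= 0, peptide_efficiency_sd >= 0,
            detection_limit >= 0, dropout_rate >= 0, dropout_rate <= 1,
            length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            peptides_per_protein[2] >= peptides_per_protein[1])
  structure(
    list(
      cv_mrna = cv_mrna, cv_protein = cv_protein,
      peptides_per_protein = as.integer(peptides_per_protein),
      peptide_efficiency_sd = peptide_efficiency_sd,
      detection_limit = detection_limit, dropout_rate = dropout_rate
    ),
    class = "noise_model"
  )
}

# lognormal multiplier with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

# ---------------------------------------------------------------------------
# Planted effect configuration

table1_effect_rows <- function() {
  # Per-condition multiplicative effects relative to control exponential
  # phase (CE = 1). Hidden (non-significant) cells default to 1; the few
  # cells planted at other values reconcile the per-condition effects with
  # the stationary-contrast report (see vignette, "Planted effects").
  tibble::tribble(
    ~locus,        ~gene,   ~m_LE, ~m_LS,  ~m_CS, ~p_LE, ~p_LS, ~p_CS, ~detect,
    "SAR11_0181", "ibpA",       1,     1,   3.69,     1,  3.74,  7.63, "all",
    "SAR11_0254", "trmD",       1,  0.51,   0.44,     1,   0.3,  0.15, "all",
    "SAR11_0259", NA,           1,  7.38,   3.69,     1,     1,     1, "never",
    "SAR11_0287", "ccmC",       1, 10.35,   2.18,     1,     1,     1, "never",
    "SAR11_0641", "recA",       1,  7.31,   3.11,     1,  2.65,     1, "all",
    "SAR11_0750", "mmuM",    6.08,  1.73,   5.22,     1,     1,  2.89, "all",
    "SAR11_1019", "xerD",       1,  8.50,   7.63,     1,     1,     1, "never",
    "SAR11_1030", "metY",    7.14,  6.37,   9.78,  2.24,  1.81,  3.19, "all",
    "SAR11_1040", "hppA",       1,  0.12,   0.27,     1,     1,     1, "all",
    "SAR11_1093", "rpoA",       1,  0.13,   0.42,  1.15,  1.21,     1, "all",
    "SAR11_1102", "rplF",       1,  0.16,   0.26,     1,     1,     1, "all",
    "SAR11_1104", "rpsN",       1, 0.165,   0.29,     1,     1,     1, "all",
    "SAR11_1122", "rpoC",       1,  0.11,   0.26,     1,     1,     1, "all",
    "SAR11_1129", NA,           1,  0.16,   0.60,     1,     1,     1, "never",
    "SAR11_1130", "tufB",       1,  0.16,   0.62,     1,     1,     1, "all",
    "SAR11_1163", NA,           1,  6.11, 1.3028,     1,     1,     1, "never",
    "SAR11_1164", NA,           1, 11.13, 1.4512,     1,     1,     1, "never",
    "SAR11_1171", "ordL",   17.28,  4.88,  11.29,     1,     1,  2.10, "all",
    "SAR11_1172", "osmC",   50.04,  9.56,  40.72,  4.48, 10.42,  2.16, "all",
    "SAR11_1173", "bhmT",   33.77,  8.91,  29.19,  3.58,   2.0,  6.20, "all",
    "SAR11_1264", "metF",       1,  0.20,   0.12,  1.38,  1.46,     1, "all",
    "SAR11_1265", NA,           1,  0.10,   0.10,  1.29,  1.30,     1, "all",
    "SAR11_1274", "cspL",       1,  0.07,   0.39,  1.58,     1,  0.78, "all"
  )
}

table2_only_effect_rows <- function() {
  # Loci reported only in the stationary contrast (limited-stationary vs
  # control-stationary ratio r). The ratio is split symmetrically between the
  # two stationary conditions: LS = sqrt(r), CS = 1/sqrt(r), keeping both
  # within the any-condition sixfold gate.
  base <- tibble::tribble(
    ~locus,        ~gene,    ~m_r, ~p_r,  ~detect,
    "SAR11_0007", "hflC",    0.20, 1.34,  "all",
    "SAR11_0162", "groEL",   0.18, NA,    "all",
    "SAR11_0173", NA,        0.64, NA,    "not_cs",
    "SAR11_0399", "rbr",     0.17, 2.24,  "all",
    "SAR11_0756", "aldA",    0.23, 0.63,  "all",
    "SAR11_0864", NA,        0.22, 0.62,  "all",
    "SAR11_0865", NA,        0.19, NA,    "all",
    "SAR11_1302", "opuAC",   0.22, 0.62,  "all",
    "SAR11_1305", "glnT",    0.19, 0.78,  "all",
    "SAR11_1361", "livJ2",   0.23, NA,    "all"
  )
  base %>%
    mutate(
      m_LE = 1, m_LS = sqrt(.data$m_r), m_CS = 1 / sqrt(.data$m_r),
      p_LE = 1,
      p_LS = ifelse(is.na(.data$p_r), 1, sqrt(.data$p_r)),
      p_CS = ifelse(is.na(.data$p_r), 1, 1 / sqrt(.data$p_r))
    ) %>%
    select("locus", "gene", "m_LE", "m_LS", "m_CS", "p_LE", "p_LS", "p_CS", "detect")
}

#' Default planted-effect configuration
#'
#' Builds the generator's ground-truth effect table: one row per locus with
#' multiplicative mRNA and protein effects for the sulfur-limited exponential
#' (LE), sulfur-limited stationary (LS) and control stationary (CS) conditions,
#' all relative to control exponential growth (CE = 1). Effects are the
#' published per-condition fold changes for the differentially expressed loci,
#' the assimilatory sulfate reduction subunits aprA/aprB, and a stationary
#' decrease for the 21 ribosomal-protein/elongation-factor marker genes; every
#' other locus is null (effect 1 in every condition).
#'
#' Columns: `locus`, `gene`, `baseline` (linear-scale transcript baseline),
#' `marker` (coupled to growth phase), `detect` (protein detectability:
#' `"all"`, `"never"`, `"ls_only"`), `m_LE`, `m_LS`, `m_CS` (mRNA effects),
#' `p_LE`, `p_LS`, `p_CS` (protein effects).
#'
#' @param n_loci Total number of loci (default 1354, genome scale). The extra
#'   loci beyond the configured ones are null fillers named `NULL_Sxxxx`.
#' @param marker_stationary_effect Stationary-phase transcript effect applied
#'   to marker genes without a published per-condition value (default 0.3, a
#'   significant but sub-sixfold decrease).
#' @return Tibble as described; attribute `"marker_loci"` holds the locus tags
#'   flagged as markers.
#' @examples
#' fx <- default_effect_config()
#' fx[fx$gene %in% "osmC", "m_LE"] # 50.04
#' @export
default_effect_config <- function(n_loci = 1354, marker_stationary_effect = 0.3) {
  t1 <- table1_effect_rows()
  t2 <- table2_only_effect_rows()
  apr <- tibble::tribble(
    ~locus,  ~gene,  ~m_LE,      ~m_LS, ~m_CS, ~p_LE, ~p_LS, ~p_CS, ~detect,
    "aprA",  "aprA", 1,     1 / 5.88,  0.5,     1,   1.2,     1, "all",
    "aprB",  "aprB", 1,     1 / 3.13,  1.0,     1,     1,     1, "all"
  )
  other_markers <- setdiff(marker_panel(), c("rplF", "rpsN"))
  mk <- tibble(
    locus = other_markers, gene = other_markers,
    m_LE = 1, m_LS = marker_stationary_effect, m_CS = marker_stationary_effect,
    p_LE = 1, p_LS = 1, p_CS = 1, detect = "all"
  )
  fx <- bind_rows(t1, t2, apr, mk) %>%
    mutate(marker = .data$locus %in% c("SAR11_1102", "SAR11_1104") |
             .data$gene %in% marker_panel())
  n_fill <- n_loci - nrow(fx)
  if (n_fill < 0) abort(sprintf("n_loci must be at least %d", nrow(fx)))
  if (n_fill > 0) {
    fill <- tibble(
      locus = sprintf("NULL_S%04d", seq_len(n_fill)), gene = NA_character_,
      m_LE = 1, m_LS = 1, m_CS = 1, p_LE = 1, p_LS = 1, p_CS = 1,
      detect = "all", marker = FALSE
    )
    fx <- bind_rows(fx, fill)
  }
  # deterministic spread of transcript baselines across ~2 decades
  fx$baseline <- 100 * 2^(seq_len(nrow(fx)) %% 8)
  attr(fx, "marker_loci") <- fx$locus[fx$marker]
  fx
}

# effect of each locus in each of the six treatment-by-phase conditions;
# transitioning gets the geometric mean of exponential and stationary
effect_by_condition <- function(fx, layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  p <- if (layer == "mrna") "m_" else "p_"
  LE <- fx[[paste0(p, "LE")]]
  LS <- fx[[paste0(p, "LS")]]
  CS <- fx[[paste0(p, "CS")]]
  cbind(
    LE = LE, LT = sqrt(LE * LS), LS = LS,
    CE = rep(1, nrow(fx)), CT = sqrt(CS), CS = CS
  )
}

sample_condition <- function(samples) {
  phase <- if ("true_phase" %in% names(samples)) samples$true_phase else samples$nominal_phase
  if (any(phase == "unassigned")) abort("samples must carry a resolvable phase")
  paste0(
    ifelse(samples$treatment == "limited", "L", "C"),
    c(exponential = "E", transitioning = "T", stationary = "S")[phase]
  )
}

#' Simulate the study's sample layout and growth curves
#'
#' Builds the nine-culture design: five sulfur-limited cultures (100 nM DMSP)
#' and four controls (1 uM DMSP), each harvested at exponential, transitioning
#' and stationary phase, with two extra pre-stationary harvests of the first
#' control culture (29 samples). Two limited cultures are harvested late for
#' their "exponential" sample (the cell-mass requirement of proteomics pushes
#' harvests toward stationary), so their true phase is transitioning — these
#' are the samples the growth-state classifier is expected to reclassify.
#'
#' True phases are derived from the harvest density as a fraction of the
#' culture's carrying capacity: exponential <= 0.5 < transitioning < 0.95 <=
#' stationary.
#'
#' @param limited,control [growth_params()] for each treatment. Defaults:
#'   limited 100 nM DMSP with non-sulfur cap 1.2e7 cells/ml; control 1000 nM
#'   with cap 3.5e7.
#' @param days Days of growth simulated (default 21).
#' @return List with `samples` (29-row metadata tibble including `true_phase`)
#'   and `growth` (daily densities per culture).
#' @export
simulate_design <- function(limited = growth_params(dmsp_initial = 100, k_other = 1.2e7),
                            control = growth_params(dmsp_initial = 1000, k_other = 3.5e7),
                            days = 21) {
  cultures <- tibble(
    culture_id = c(paste0("L", 1:5), paste0("C", 1:4)),
    treatment = rep(c("limited", "control"), c(5, 4))
  )
  growth <- purrr::map2(
    cultures$culture_id, cultures$treatment,
    function(id, tr) simulate_growth(if (tr == "limited") limited else control, days, id)
  ) %>% bind_rows()

  crossing_day <- function(curve, frac, K) {
    hit <- which(curve$density >= frac * K)
    if (length(hit) == 0) abort("culture never reaches requested harvest fraction")
    curve$day[hit[1]]
  }
  harvest <- function(id, tr, slot, frac) {
    K <- if (tr == "limited") limited$capacity else control$capacity
    curve <- growth %>% filter(.data$culture_id == id)
    day <- if (is.infinite(frac)) max(curve$day) else crossing_day(curve, frac, K)
    dens <- curve$density[curve$day == day]
    f <- dens / K
    tibble(
      sample_id = paste0(id, "_", slot), culture_id = id, treatment = tr,
      harvest_day = day, density = dens,
      nominal_phase = c(exp = "exponential", trn = "transitioning",
                        pre = "transitioning",
                        stn = "stationary")[[sub("[0-9]*$", "", slot)]],
      true_phase = if (f <= 0.5) "exponential" else if (f < 0.95) "transitioning" else "stationary"
    )
  }
  plan <- list(
    # limited: L1-L3 harvested mid-exponential, L4-L5 late (truly transitioning)
    purrr::map(paste0("L", 1:3), ~ harvest(.x, "limited", "exp", 0.35)),
    purrr::map(paste0("L", 4:5), ~ harvest(.x, "limited", "exp", 0.80)),
    purrr::map(paste0("L", 1:5), ~ harvest(.x, "limited", "trn", 0.90)),
    purrr::map(paste0("L", 1:5), ~ harvest(.x, "limited", "stn", Inf)),
    purrr::map(paste0("C", 1:4), ~ harvest(.x, "control", "exp", 0.286)),
    purrr::map(paste0("C", 1:4), ~ harvest(.x, "control", "trn", 0.80)),
    list(harvest("C1", "control", "pre1", 0.84), harvest("C1", "control", "pre2", 0.90)),
    purrr::map(paste0("C", 1:4), ~ harvest(.x, "control", "stn", Inf))
  )
  samples <- bind_rows(purrr::flatten(plan)) %>%
    arrange(.data$culture_id, .data$harvest_day)
  validate_samples(samples)
  list(samples = samples, growth = growth)
}

#' Simulate a transcript abundance matrix
#'
#' Each abundance is `baseline * effect(condition) * lognormal(cv)`, where the
#' condition (LE/LT/LS/CE/CT/CS) comes from the sample's treatment and true
#' phase. Marker-flagged loci carry their phase effect in the effect table, so
#' exponential samples score high and stationary samples low in the
#' growth-state procedure.
#'
#' @param effects Effect table from [default_effect_config()].
#' @param samples Sample metadata (with `true_phase`).
#' @param noise A [noise_model()]; only `cv_mrna` is used here.
#' @param seed Integer seed; same seed, same matrix.
#' @return Expression tibble (see [sulfurlim-tables]).
#' @export
simulate_transcriptome <- function(effects, samples, noise = noise_model(), seed = 1L) {
  cond <- sample_condition(samples)
  eff <- effect_by_condition(effects, "mrna")[, cond, drop = FALSE]
  vals <- effects$baseline * eff
  withr::with_seed(seed, {
    vals <- vals * matrix(rlnorm_cv(length(vals), noise$cv_mrna), nrow = nrow(vals))
  })
  out <- as_tibble(vals, .name_repair = "minimal")
  names(out) <- samples$sample_id
  bind_cols(tibble(locus = effects$locus), out)
}

#' Simulate a peptide observation table
#'
#' Protein abundance is `baseline * protein effect(condition) * lognormal(cv)`
#' per sample; each protein emits `k` peptides (drawn from the configured
#' range) with fixed per-peptide efficiencies, and each observation gets its
#' own lognormal noise. Observations below the detection limit or hit by
#' random dropout are missing (`NA`). Loci whose `detect` flag is `"never"`
#' yield no rows (never seen by mass spectrometry); `"not_cs"` loci are
#' observed everywhere except in control stationary samples (so they appear
#' as a detection sentinel only in the stationary contrast).
#'
#' @inheritParams simulate_transcriptome
#' @param noise A [noise_model()]; peptide fields and `cv_protein` are used.
#' @return Peptide tibble (see [sulfurlim-tables]).
#' @export
simulate_peptides <- function(effects, samples, noise = noise_model(), seed = 1L) {
  cond <- sample_condition(samples)
  eff <- effect_by_condition(effects, "protein")[, cond, drop = FALSE]
  keep <- effects$detect != "never"
  fx <- effects[keep, ]
  eff <- eff[keep, , drop = FALSE]
  n_s <- nrow(samples)
  out <- withr::with_seed(seed, {
    k <- sample(seq(noise$peptides_per_protein[1], noise$peptides_per_protein[2]),
                nrow(fx), replace = TRUE)
    pep_locus <- rep(seq_len(nrow(fx)), k)            # locus index per peptide
    pep_no <- sequence(k)
    n_pep <- length(pep_locus)
    effic <- if (noise$peptide_efficiency_sd == 0) rep(1, n_pep) else
      rlnorm(n_pep, 0, noise$peptide_efficiency_sd)
    protein <- fx$baseline * eff                      # loci x samples
    il <- rep(pep_locus, each = n_s)                  # row index per observation
    is <- rep(seq_len(n_s), times = n_pep)            # sample index per observation
    obs <- protein[cbind(il, is)] * rep(effic, each = n_s) *
      rlnorm_cv(n_pep * n_s, noise$cv_protein)
    miss <- (noise$detection_limit > 0 & obs < noise$detection_limit) |
      runif(n_pep * n_s) < noise$dropout_rate |
      (fx$detect[il] == "not_cs" & cond[is] == "CS")
    obs[miss] <- NA_real_
    tibble(
      peptide_id = rep(sprintf("%s_pep%02d", fx$locus[pep_locus], pep_no), each = n_s),
      locus = fx$locus[il],
      sample_id = samples$sample_id[is],
      abundance = obs
    )
  })
  validate_peptides(out)
  out
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator: sample layout and growth curves
#' ([simulate_design()]), transcript matrix ([simulate_transcriptome()]) and
#' peptide table ([simulate_peptides()]), with the planted ground truth
#' attached. Defaults emulate the sulfur-limitation study design: 9 cultures,
#' 29 samples, published effect sizes, lognormal noise with cv 0.2 (mRNA) and
#' 0.3 (peptides).
#'
#' @param effects Effect table (default [default_effect_config()]).
#' @param noise [noise_model()].
#' @param seed Integer seed controlling every random draw.
#' @param design Optional precomputed [simulate_design()] output.
#' @param peptides Logical; set `FALSE` to skip the (slower) peptide layer.
#' @return An object of class `sulfurlim_study`: list with `samples`, `mrna`,
#'   `peptides` (or `NULL`), `growth`, `effects`, `markers`, `seed`.
#' @examples
#' study <- simulate_study(seed = 42, peptides = FALSE)
#' dim(study$mrna)
#' @export
simulate_study <- function(effects = default_effect_config(),
                           noise = noise_model(),
                           seed = 1L,
                           design = simulate_design(),
                           peptides = TRUE) {
  mrna <- simulate_transcriptome(effects, design$samples, noise, seed)
  pep <- if (peptides) simulate_peptides(effects, design$samples, noise, seed + 1L) else NULL
  structure(
    list(
      samples = design$samples, mrna = mrna, peptides = pep,
      growth = design$growth, effects = effects,
      markers = effects$locus[effects$marker], seed = as.integer(seed)
    ),
    class = "sulfurlim_study"
  )
}

#' @export
print.sulfurlim_study <- function(x, ...) {
  cat("<sulfurlim_study>\n")
  cat(sprintf("  %d samples, %d cultures, %d loci%s, seed %d\n",
              nrow(x$samples), length(unique(x$samples$culture_id)),
              nrow(x$mrna),
              if (is.null(x$peptides)) " (no peptide layer)" else
                sprintf(", %d peptide observations", nrow(x$peptides)),
              x$seed))
  invisible(x)
}
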