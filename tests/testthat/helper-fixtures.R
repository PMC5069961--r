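# Small in-code fixtures and independent oracles shared across tests.

expr_tbl <- function(loci, values, samples = NULL) {
  values <- matrix(values, nrow = length(loci))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  out <- tibble::as_tibble(as.data.frame(values), .name_repair = "minimal")
  names(out) <- samples
  dplyr::bind_cols(tibble::tibble(locus = loci), out)
}

pep_tbl <- function(...) {
  tibble::tribble(~peptide_id, ~locus, ~sample_id, ~abundance, ...)
}

samples_tbl <- function(n_per_phase = 1, treatment = "control") {
  phases <- rep(c("exponential", "transitioning", "stationary"), each = n_per_phase)
  tibble::tibble(
    sample_id = paste0("s", seq_along(phases)),
    culture_id = "c1",
    treatment = treatment,
    harvest_day = seq_along(phases),
    density = 1e6 * seq_along(phases),
    nominal_phase = phases
  )
}

# Brute-force optimal 3-partition of 1-D points: enumerate every labeling
# into 3 nonempty groups (all 3^n assignments, vectorized) and minimize the
# total within-group sum of squares.
brute_force_3cluster_sse <- function(x) {
  n <- length(x)
  lab <- as.matrix(expand.grid(rep(list(1:3), n)))
  total <- 0
  valid <- rep(TRUE, nrow(lab))
  for (g in 1:3) {
    ind <- lab == g
    cnt <- rowSums(ind)
    valid <- valid & cnt > 0
    s1 <- ind %*% x
    s2 <- ind %*% x^2
    sse_g <- ifelse(cnt > 0, s2 - s1^2 / pmax(cnt, 1), 0)
    total <- total + sse_g
  }
  min(total[valid])
}

cluster_sse <- function(x, grp) {
  sum(unlist(lapply(split(x, grp), function(v) sum((v - mean(v))^2))))
}

# Two-sided permutation test for a difference in means of log2 values;
# independent check on the parametric group test.
permutation_p <- function(a, b, n_perm = 2000, seed = 1) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    hits <- replicate(n_perm, {
      idx <- sample(length(pool), length(a))
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12
    })
    (sum(hits) + 1) / (n_perm + 1)
  })
}

# Hand implementation of Benjamini-Hochberg step-up flags.
bh_flags_by_hand <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  flagged <- logical(m)
  k <- which(p[ord] <= alpha * seq_len(m) / m)
  if (length(k) > 0) flagged[ord[seq_len(max(k))]] <- TRUE
  flagged
}

zero_noise <- function() {
  noise_model(cv_mrna = 0, cv_protein = 0, peptide_efficiency_sd = 0,
              dropout_rate = 0)
}

# the 15 loci of the stationary-contrast report
stationary_report_loci <- function() {
  sort(c("SAR11_0007", "SAR11_0162", "SAR11_0173", "SAR11_0287", "SAR11_0399",
         "SAR11_0756", "SAR11_0864", "SAR11_0865", "SAR11_1163", "SAR11_1164",
         "SAR11_1172", "SAR11_1274", "SAR11_1302", "SAR11_1305", "SAR11_1361"))
}

# the 23 loci of the any-condition report
any_condition_report_loci <- function() {
  sort(c("SAR11_0181", "SAR11_0254", "SAR11_0259", "SAR11_0287", "SAR11_0641",
         "SAR11_0750", "SAR11_1019", "SAR11_1030", "SAR11_1040", "SAR11_1093",
         "SAR11_1102", "SAR11_1104", "SAR11_1122", "SAR11_1129", "SAR11_1130",
         "SAR11_1163", "SAR11_1164", "SAR11_1171", "SAR11_1172", "SAR11_1173",
         "SAR11_1264", "SAR11_1265", "SAR11_1274"))
}
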