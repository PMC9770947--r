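# Shared fixtures and independent oracles used across the suite.

# a small, fast simulation configuration; ... overrides the defaults
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_proteins = 40L, proteoforms_per_protein = 1,
         n_differential = 6L, n_saav_proteoforms = 3L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# all stochastic effects off: exact masses, no isotope errors, no noise
# PrSMs, detection always succeeds
noise_free_cfg <- function(seed = 1L, ...) {
  sim_config(n_proteins = 20L, proteoforms_per_protein = 1,
             mass_error_ppm_sd = 0, isotope_error_prob = 0,
             true_hit_fraction = 1,
             detect_logistic_params = c(midpoint = -50, slope = 1),
             n_differential = 0L, n_saav_proteoforms = 0L,
             seed = seed, ...)
}

# minimal PrSM data.frame for unit tests of FDR / clustering
make_prsms <- function(e_value, is_decoy = rep(FALSE, length(e_value)),
                       mass = rep(10000, length(e_value)),
                       acc = rep("P1", length(e_value)),
                       id = sprintf("S%03d", seq_along(e_value))) {
  acc <- ifelse(is_decoy & !startsWith(acc, "DECOY_"),
                paste0("DECOY_", acc), acc)
  data.frame(spectrum_id = id, protein_accession = acc,
             is_decoy = is_decoy, precursor_mass = mass, e_value = e_value,
             stringsAsFactors = FALSE)
}

# O(n^2) brute-force D/T q-value oracle: at every rank recompute decoy and
# target counts from scratch, then take the minimum raw FDR at or below
# each item's score
brute_force_q <- function(e_value, is_decoy) {
  n <- length(e_value)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    at_or_better <- e_value <= e_value[i]
    d <- sum(is_decoy & at_or_better)
    t <- sum(!is_decoy & at_or_better)
    raw[i] <- d / max(1, t)
  }
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(raw[e_value >= e_value[i]])
  }
  q
}

# slow re-execution of greedy best-E-value seeding, written independently:
# scans for the minimum at every step instead of sorting
brute_force_clusters <- function(prsms, mass_tol) {
  assign_to <- rep(NA_integer_, nrow(prsms))
  cl <- 0L
  repeat {
    open <- which(is.na(assign_to))
    if (!length(open)) break
    best <- open[1]
    for (i in open) {
      if (prsms$e_value[i] < prsms$e_value[best] ||
          (prsms$e_value[i] == prsms$e_value[best] &&
           prsms$spectrum_id[i] < prsms$spectrum_id[best])) best <- i
    }
    cl <- cl + 1L
    for (i in open) {
      if (prsms$protein_accession[i] == prsms$protein_accession[best] &&
          abs(prsms$precursor_mass[i] - prsms$precursor_mass[best]) <=
          mass_tol) {
        assign_to[i] <- cl
      }
    }
  }
  # canonical form: sorted member-id sets
  canon_sets(unname(lapply(split(prsms$spectrum_id, assign_to), sort)))
}

# canonicalize a list of member-id sets: sort within, order by first id
canon_sets <- function(s) {
  s <- lapply(s, sort)
  s[order(vapply(s, `[`, "", 1L))]
}

# canonical member sets of a cluster_prsms() result, for comparison
member_sets <- function(clusters) {
  canon_sets(clusters$members)
}
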