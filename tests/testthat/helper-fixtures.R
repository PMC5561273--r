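# Small study configurations and hand-built containers shared across tests.

small_config <- function(...) {
  synthetic_config(n_species = 6, n_medicago = 3, plants_per_species = 4,
                   aphids_per_cell = 6, n_epg_vars = 30, n_dup_pairs = 4,
                   n_null_compounds = 40, ...)
}

# profile_matrix built directly from a numeric matrix (rows = plants)
make_profile_matrix <- function(values, species, fraction = "polar") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("plant%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("%.1f", 100 + 0.2 * seq_len(ncol(values)))
  }
  structure(list(values = values,
                 meta = data.frame(plant_id = rownames(values),
                                   species = species,
                                   stringsAsFactors = FALSE),
                 fraction = fraction, binning = binning_config()),
            class = "profile_matrix")
}

# score_table built directly from per-species means and SEs
make_score_table <- function(species, mean_MS, mean_TP, se_MS = 0,
                             se_TP = 0, profile = "E2") {
  se <- sqrt(se_MS^2 + se_TP^2)
  out <- data.frame(species = species, mean_MS = mean_MS, mean_TP = mean_TP,
                    se_MS = se_MS, se_TP = se_TP,
                    discrimination = mean_MS - mean_TP,
                    acceptability = mean_MS + mean_TP,
                    se_discrimination = se, se_acceptability = se,
                    profile = profile, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

# bin labels of the planted compounds of one class in one fraction
planted_bins <- function(truth, classes, fraction,
                         binning = binning_config()) {
  comp <- truth$compounds
  sel <- comp$class %in% classes & comp$fraction == fraction
  sprintf("%.1f", bin_left_edge(comp$mz[sel], binning))
}

# per-recording E2 profile data.frame ready for summarize_profiles()
e2_profiles <- function(epg) {
  e2 <- extract_e2(epg)
  names(e2)[names(e2) == "e2_min"] <- "value"
  e2
}
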