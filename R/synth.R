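#' Configuration for the synthetic study generator
#'
#' Encodes the study design the generator emulates: 19 legume species (9
#' *Medicago*, 10 *Trifolium*), two aphid host races (MS, TP) of two clones
#' each, ~119 EPG behavioural variables per recording, and triplicate
#' MALDI-TOF spectra per plant in 50-1000 Da with planted discriminative,
#' acceptability-linked and nuisance compounds.
#'
#' @param n_species number of plant species (default 19).
#' @param n_medicago how many of them are *Medicago* (default 9); the rest are
#'   *Trifolium*.
#' @param plants_per_species biological replicates per species (default 6).
#' @param tech_reps technical (spotting) replicates per extract (default 3).
#' @param aphids_per_cell EPG recordings per species x race cell (default 8).
#' @param clones_per_race aphid clones per race (default 2).
#' @param n_epg_vars number of behavioural variables (default 119).
#' @param frac_informative fraction of variables linearly loaded on the latent
#'   acceptance score (default 0.3).
#' @param frac_zero_inflated fraction of variables with >= 50% zeros in
#'   expectation (default 0.2).
#' @param n_dup_pairs number of near-duplicate variable pairs, population
#'   correlation > 0.9 (default 10).
#' @param miss_rate MCAR missingness rate over behavioural cells (default
#'   0.02); the E2 column is never missing.
#' @param sigma_a,sigma_d SDs of the species acceptability and discrimination
#'   latents (defaults 1).
#' @param delta_genus genus shift of the discrimination latent: +delta for
#'   *Medicago*, -delta for *Trifolium* (default 1.5).
#' @param sigma_clone,sigma_aphid clone and within-cell aphid noise SDs
#'   (defaults 0.2, 0.8).
#' @param n_disc_compounds,n_acc_compounds,n_null_compounds planted compound
#'   counts: discriminative (half positive, half negative direction),
#'   acceptability-linked, and nuisance (defaults 4, 4, 400).
#' @param gamma_disc,gamma_acc log-abundance effect sizes per unit latent
#'   (defaults 0.8).
#' @param sigma_species reference SD of the species-level random log-abundance
#'   effect given to every nuisance compound (default 0.4, about a 1.5-fold
#'   1-SD difference between species). Nuisance compounds are defined by
#'   species-to-species variation unrelated to behaviour, which this effect
#'   realises; without it they would be flat across species and the null
#'   model of the importance ranking would be degenerate. Per-compound SDs
#'   are uniform between 0.25 and 2.5 times `sigma_species`, heterogeneous
#'   as in real metabolomes but bounded so no single compound can swamp a
#'   species' total ion count. Planted compounds carry no extra species
#'   effect: their species structure is exactly the planted behavioural
#'   signal.
#' @param cv_bio,cv_tech biological and technical coefficients of variation of
#'   compound intensity (defaults 0.3, 0.1).
#' @param mz_jitter_sd SD of the observed m/z around the true compound m/z, Da
#'   (default 0.03).
#' @param mz_range mass range in Da (default c(50, 1000)).
#' @param edge_stress if TRUE, planted compound m/z values are placed on
#'   0.2-Da bin edges to stress bin-splitting; by default they are kept at
#'   least 2 x mz_jitter_sd away from any edge.
#' @param seed RNG seed for the whole dataset.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 19, n_medicago = 9,
                             plants_per_species = 6, tech_reps = 3,
                             aphids_per_cell = 8, clones_per_race = 2,
                             n_epg_vars = 119, frac_informative = 0.3,
                             frac_zero_inflated = 0.2, n_dup_pairs = 10,
                             miss_rate = 0.02,
                             sigma_a = 1, sigma_d = 1, delta_genus = 1.5,
                             sigma_clone = 0.2, sigma_aphid = 0.8,
                             n_disc_compounds = 4, n_acc_compounds = 4,
                             n_null_compounds = 400,
                             gamma_disc = 0.8, gamma_acc = 0.8,
                             sigma_species = 0.4,
                             cv_bio = 0.3, cv_tech = 0.1,
                             mz_jitter_sd = 0.03, mz_range = c(50, 1000),
                             edge_stress = FALSE, seed = 1) {
  cfg <- list(n_species = n_species, n_medicago = n_medicago,
              plants_per_species = plants_per_species, tech_reps = tech_reps,
              aphids_per_cell = aphids_per_cell,
              clones_per_race = clones_per_race, n_epg_vars = n_epg_vars,
              frac_informative = frac_informative,
              frac_zero_inflated = frac_zero_inflated,
              n_dup_pairs = n_dup_pairs, miss_rate = miss_rate,
              sigma_a = sigma_a, sigma_d = sigma_d,
              delta_genus = delta_genus, sigma_clone = sigma_clone,
              sigma_aphid = sigma_aphid,
              n_disc_compounds = n_disc_compounds,
              n_acc_compounds = n_acc_compounds,
              n_null_compounds = n_null_compounds,
              gamma_disc = gamma_disc, gamma_acc = gamma_acc,
              sigma_species = sigma_species,
              cv_bio = cv_bio, cv_tech = cv_tech,
              mz_jitter_sd = mz_jitter_sd, mz_range = mz_range,
              edge_stress = edge_stress, seed = seed)
  counts <- c("n_species", "n_medicago", "plants_per_species", "tech_reps",
              "aphids_per_cell", "clones_per_race", "n_epg_vars")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop(sprintf("configuration error: %s must be an integer >= 1", f))
    }
  }
  props <- c("frac_informative", "frac_zero_inflated", "miss_rate")
  for (f in props) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("configuration error: %s must be in [0, 1]", f))
    }
  }
  if (cfg$n_medicago >= cfg$n_species) {
    stop("configuration error: n_medicago must be < n_species")
  }
  if (length(cfg$mz_range) != 2L || cfg$mz_range[1] >= cfg$mz_range[2]) {
    stop("configuration error: mz_range lower bound must be < upper bound")
  }
  if (cfg$n_dup_pairs < 0 ||
      cfg$n_dup_pairs > floor(cfg$n_epg_vars / 2)) {
    stop("configuration error: n_dup_pairs must fit twice into n_epg_vars")
  }
  structure(cfg, class = "synthetic_config")
}

# lognormal noise with mean 1 and the given coefficient of variation
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw the latent species structure and compound registry
#'
#' Species latents: acceptability a_j ~ Normal(0, sigma_a^2) and
#' discrimination d_j ~ Normal(+delta_genus, sigma_d^2) for *Medicago*,
#' Normal(-delta_genus, sigma_d^2) for *Trifolium*, reproducing a
#' genus-separated discrimination pattern. Race mean scores are
#' m_MS = (a + d)/2 and m_TP = (a - d)/2, so their sum and difference recover
#' a_j and d_j exactly. The compound registry assigns every planted compound a
#' true m/z, a class (disc_pos/disc_neg/acc/null), a signed log-abundance
#' effect and a fraction (polar/nonpolar, balanced within class); nuisance
#' compounds additionally receive a per-compound, per-species random
#' log-abundance effect so their baseline chemistry differs among species.
#'
#' @param config a [synthetic_config()].
#' @return object of class `ground_truth`: list with `species` (data.frame
#'   species, genus, a, d, m_MS, m_TP) and `compounds` (data.frame
#'   compound_id, class, mz, effect, fraction, base_abundance).
#' @export
generate_latents <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_species
  genus <- rep(c("Medicago", "Trifolium"),
               c(config$n_medicago, n - config$n_medicago))
  species <- sprintf("%s_sp%02d", ifelse(genus == "Medicago", "M", "T"),
                     seq_len(n))
  a <- stats::rnorm(n, 0, config$sigma_a)
  d <- stats::rnorm(n, ifelse(genus == "Medicago", config$delta_genus,
                              -config$delta_genus), config$sigma_d)
  m_MS <- (a + d) / 2
  m_TP <- (a - d) / 2
  # store the latents recovered from the race means so that sum and
  # difference reproduce a and d exactly, not just to rounding error
  species_tab <- data.frame(species = species, genus = genus,
                            a = m_MS + m_TP, d = m_MS - m_TP,
                            m_MS = m_MS, m_TP = m_TP,
                            stringsAsFactors = FALSE)

  n_disc <- config$n_disc_compounds
  n_acc <- config$n_acc_compounds
  n_null <- config$n_null_compounds
  cls <- c(rep(c("disc_pos", "disc_neg"), length.out = n_disc),
           rep("acc", n_acc), rep("null", n_null))
  n_comp <- length(cls)
  fraction <- character(n_comp)
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    fraction[idx] <- rep(c("polar", "nonpolar"), length.out = length(idx))
  }
  mz <- stats::runif(n_comp, config$mz_range[1], config$mz_range[2])
  bw <- 0.2
  if (config$edge_stress) {
    mz <- config$mz_range[1] + round((mz - config$mz_range[1]) / bw) * bw
    mz <- pmin(pmax(mz, config$mz_range[1]), config$mz_range[2] - bw)
  } else {
    # keep true m/z at least 2*mz_jitter_sd from any 0.2-Da bin edge
    margin <- min(2 * config$mz_jitter_sd, bw / 2 * 0.9)
    off <- (mz - config$mz_range[1]) %% bw
    mz <- mz + ifelse(off < margin, margin - off,
                      ifelse(off > bw - margin, (bw - margin) - off, 0))
  }
  effect <- ifelse(cls == "disc_pos", config$gamma_disc,
            ifelse(cls == "disc_neg", -config$gamma_disc,
            ifelse(cls == "acc", config$gamma_acc, 0)))
  compounds <- data.frame(
    compound_id = sprintf("cmp_%04d", seq_len(n_comp)),
    class = cls, mz = mz, effect = effect, fraction = fraction,
    base_abundance = stats::rlnorm(n_comp, meanlog = log(1000), sdlog = 0.5),
    stringsAsFactors = FALSE
  )
  # nuisance compounds vary among species for reasons unrelated to
  # behaviour, with heterogeneous but bounded per-compound spread (an
  # unbounded tail lets a single compound dominate a species' entire ion
  # count, which no real %TIC spectrum shows); planted compounds' species
  # structure is exactly their behavioural effect
  sigma_k <- stats::runif(n_comp, 0.25 * config$sigma_species,
                          2.5 * config$sigma_species)
  sigma_k[cls != "null"] <- 0
  compounds$sigma_species <- sigma_k
  species_effects <- matrix(
    stats::rnorm(n_comp * n, 0, rep(sigma_k, n)), n_comp, n,
    dimnames = list(compounds$compound_id, species_tab$species))
  structure(list(species = species_tab, compounds = compounds,
                 species_effects = species_effects, config = config),
            class = "ground_truth")
}

#' Generate a per-recording EPG feature table
#'
#' Each aphid of race r and clone c on species j has a latent acceptance
#' s = m_rj + u_c + Normal(0, sigma_aphid^2), with clone effects
#' u_c ~ Normal(0, sigma_clone^2). Its total E2 duration is 360 * logistic(s)
#' minutes, bounded by the 6-hour recording. Behavioural variables are a mix
#' of informative (affine in s plus noise), zero-inflated (>= 50% zeros in
#' expectation), pure-noise and near-duplicate columns; missingness is MCAR at
#' `miss_rate` except for E2, which is always observed.
#'
#' @param truth a `ground_truth` from [generate_latents()].
#' @param config the [synthetic_config()] used to build `truth`.
#' @return data.frame with columns `recording_id`, `race`, `clone`, `species`,
#'   `genus`, `var_001`..`var_NNN`, `E2_total_min`.
#' @export
generate_epg_table <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  races <- c("MS", "TP")
  clones <- lapply(races, function(r) {
    paste0(r, seq_len(config$clones_per_race))
  })
  names(clones) <- races
  clone_eff <- stats::setNames(
    stats::rnorm(2 * config$clones_per_race, 0, config$sigma_clone),
    unlist(clones)
  )
  per_clone <- diff(round(seq(0, config$aphids_per_cell,
                              length.out = config$clones_per_race + 1L)))

  rows <- list()
  for (j in seq_len(nrow(truth$species))) {
    for (r in races) {
      m_rj <- truth$species[[paste0("m_", r)]][j]
      for (ci in seq_len(config$clones_per_race)) {
        n_i <- per_clone[ci]
        if (n_i == 0L) next
        cl <- clones[[r]][ci]
        s <- m_rj + clone_eff[[cl]] + stats::rnorm(n_i, 0, config$sigma_aphid)
        rows[[length(rows) + 1L]] <- data.frame(
          race = r, clone = cl, species = truth$species$species[j],
          genus = truth$species$genus[j], s = s, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  n_rec <- nrow(tab)
  tab$recording_id <- sprintf("rec_%04d", seq_len(n_rec))
  s <- tab$s

  nv <- config$n_epg_vars
  n_inf <- round(config$frac_informative * nv)
  n_zi <- round(config$frac_zero_inflated * nv)
  n_dup <- config$n_dup_pairs
  if (n_inf + n_zi + n_dup > nv) {
    stop("configuration error: informative + zero-inflated + duplicate variables exceed n_epg_vars")
  }
  role <- rep("noise", nv)
  role[seq_len(n_inf)] <- "informative"
  if (n_zi > 0) role[n_inf + seq_len(n_zi)] <- "zero_inflated"
  if (n_dup > 0) role[nv - n_dup + seq_len(n_dup)] <- "duplicate"

  vars <- matrix(NA_real_, n_rec, nv,
                 dimnames = list(NULL, sprintf("var_%03d", seq_len(nv))))
  alpha <- stats::rnorm(nv, 0, 1)
  beta <- sample(c(-1, 1), nv, replace = TRUE) * stats::runif(nv, 0.5, 1.5)
  p_zero <- stats::runif(nv, 0.55, 0.8)
  for (k in seq_len(nv)) {
    vars[, k] <- switch(role[k],
      informative = alpha[k] + beta[k] * s + stats::rnorm(n_rec, 0, 0.5),
      zero_inflated = ifelse(stats::runif(n_rec) < p_zero[k], 0,
                             abs(stats::rnorm(n_rec, 1, 0.5))),
      noise = stats::rnorm(n_rec, alpha[k], 1),
      duplicate = NA_real_  # filled after sources exist
    )
  }
  dup_src <- seq_len(n_dup)  # duplicates copy the first n_dup columns
  for (i in seq_len(n_dup)) {
    k <- nv - n_dup + i
    src <- vars[, dup_src[i]]
    vars[, k] <- src + stats::rnorm(n_rec, 0, 0.3 * stats::sd(src))
  }
  if (config$miss_rate > 0) {
    miss <- stats::runif(length(vars)) < config$miss_rate
    vars[miss] <- NA_real_
  }
  e2 <- 360 * stats::plogis(s)
  out <- data.frame(recording_id = tab$recording_id, race = tab$race,
                    clone = tab$clone, species = tab$species,
                    genus = tab$genus, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(vars))
  out$E2_total_min <- e2
  attr(out, "latent") <- s
  attr(out, "roles") <- stats::setNames(role, colnames(vars))
  out
}

#' Generate triplicate MALDI-TOF peak lists for every plant
#'
#' Each compound's expected abundance in a plant of species j is
#' base * exp(effect * latent_j), with latent_j = d_j for discriminative
#' compounds, a_j for acceptability-linked compounds and 0 for nuisance
#' compounds. Biological lognormal noise (cv_bio) applies per plant, technical
#' lognormal noise (cv_tech) and a global lognormal TIC scale factor apply per
#' replicate, and every observed peak m/z is jittered by
#' Normal(0, mz_jitter_sd^2). The TIC factor must cancel under %TIC
#' normalisation.
#'
#' @inheritParams generate_epg_table
#' @return list with `peaklists` (list of `peaklist` objects) and `manifest`
#'   (data.frame file, species, plant_id, replicate, fraction).
#' @export
generate_spectra <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 2L)
  binning <- binning_config(0.2, config$mz_range[1], config$mz_range[2])
  comp <- truth$compounds
  latent_for <- function(j) {
    ifelse(comp$class %in% c("disc_pos", "disc_neg"), truth$species$d[j],
           ifelse(comp$class == "acc", truth$species$a[j], 0))
  }
  peaklists <- list()
  manifest <- list()
  for (j in seq_len(nrow(truth$species))) {
    sp <- truth$species$species[j]
    mu_all <- comp$base_abundance *
      exp(comp$effect * latent_for(j) + truth$species_effects[, j])
    for (p in seq_len(config$plants_per_species)) {
      plant_id <- sprintf("%s_plant%02d", sp, p)
      bio <- .rlnorm_cv(nrow(comp), config$cv_bio)
      for (fr in c("polar", "nonpolar")) {
        idx <- which(comp$fraction == fr)
        for (rep_i in seq_len(config$tech_reps)) {
          tic_scale <- stats::rlnorm(1, 0, 0.5)
          intensity <- mu_all[idx] * bio[idx] *
            .rlnorm_cv(length(idx), config$cv_tech) * tic_scale
          mz <- comp$mz[idx] +
            stats::rnorm(length(idx), 0, config$mz_jitter_sd)
          keep <- mz >= config$mz_range[1] & mz < config$mz_range[2]
          pl <- structure(
            list(mz = mz[keep], intensity = intensity[keep],
                 meta = list(species = sp, plant_id = plant_id,
                             replicate = rep_i, fraction = fr)),
            class = "peaklist")
          file <- sprintf("%s_rep%d_%s.tsv", plant_id, rep_i, fr)
          peaklists[[file]] <- pl
          manifest[[length(manifest) + 1L]] <- data.frame(
            file = file, species = sp, plant_id = plant_id,
            replicate = rep_i, fraction = fr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(peaklists = peaklists,
       manifest = do.call(rbind, manifest),
       binning = binning)
}

#' Generate an aphid fecundity (performance) table
#'
#' Fecundity of one replicate of race r on species j is
#' Poisson(exp(eta0 + eta1 * m_rj)): the number of live young produced by a
#' single adult aphid on the test plant.
#'
#' @inheritParams generate_epg_table
#' @param eta0,eta1 intercept and slope of the log fecundity rate (defaults
#'   1.5 and 0.5).
#' @param reps_per_cell replicates per species x race cell; defaults to
#'   `config$aphids_per_cell`.
#' @return data.frame `species`, `race`, `clone`, `replicate`, `live_young`.
#' @export
generate_performance <- function(truth, config, eta0 = 1.5, eta1 = 0.5,
                                 reps_per_cell = config$aphids_per_cell) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "synthetic_config"))
  set.seed(config$seed + 3L)
  races <- c("MS", "TP")
  per_clone <- diff(round(seq(0, reps_per_cell,
                              length.out = config$clones_per_race + 1L)))
  rows <- list()
  for (j in seq_len(nrow(truth$species))) {
    for (r in races) {
      m_rj <- truth$species[[paste0("m_", r)]][j]
      lambda <- exp(eta0 + eta1 * m_rj)
      for (ci in seq_len(config$clones_per_race)) {
        n_i <- per_clone[ci]
        if (n_i == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          species = truth$species$species[j], race = r,
          clone = paste0(r, ci), replicate = seq_len(n_i),
          live_young = stats::rpois(n_i, lambda), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a full synthetic dataset, optionally writing it to disk
#'
#' Orchestrates [generate_latents()], [generate_epg_table()],
#' [generate_spectra()] and [generate_performance()]. When `dir` is given,
#' writes `epg.csv`, `performance.csv`, per-replicate peak-list TSVs under
#' `spectra/` with a `manifest.csv`, and the ground truth as `truth.json`;
#' output files are byte-identical across runs with the same config.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @return list with `truth`, `epg`, `spectra`, `performance` (invisible when
#'   writing to disk).
#' @export
generate_dataset <- function(config = synthetic_config(), dir = NULL) {
  truth <- generate_latents(config)
  epg <- generate_epg_table(truth, config)
  spectra <- generate_spectra(truth, config)
  performance <- generate_performance(truth, config)
  out <- list(truth = truth, epg = epg, spectra = spectra,
              performance = performance)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "spectra"), recursive = TRUE,
               showWarnings = FALSE)
    utils::write.csv(epg, file.path(dir, "epg.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(performance, file.path(dir, "performance.csv"),
                     row.names = FALSE)
    utils::write.csv(spectra$manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    for (f in names(spectra$peaklists)) {
      pl <- spectra$peaklists[[f]]
      utils::write.table(
        data.frame(mz = sprintf("%.6f", pl$mz),
                   intensity = sprintf("%.6f", pl$intensity)),
        file.path(dir, "spectra", f), sep = "\t", row.names = FALSE,
        col.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(species = truth$species, compounds = truth$compounds),
      file.path(dir, "truth.json"), dataframe = "columns", digits = NA)
  }
  invisible(out)
}
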