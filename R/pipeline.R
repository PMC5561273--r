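#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a master seed for an end-to-end
#' run on synthetic data (or on files laid out as the generator writes them).
#'
#' @param out_dir output directory for all stage outputs and the run report.
#' @param synthetic a [synthetic_config()]; when `simulate = TRUE` the
#'   pipeline generates its input data from it.
#' @param cleaning a [cleaning_config()].
#' @param rf an [rf_run_config()].
#' @param profile acceptance profile to analyse: "E2" or "LD1".
#' @param responses which scores to rank against (default both
#'   "discrimination" and "acceptability").
#' @param seed master seed; overrides the seeds inside `synthetic` and `rf`.
#' @param simulate generate the input data (default TRUE).
#' @param data_dir directory holding `epg.csv`, `manifest.csv`, `spectra/`,
#'   `performance.csv` when `simulate = FALSE`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("hostdiscrim_run_"),
                            synthetic = synthetic_config(),
                            cleaning = cleaning_config(),
                            rf = rf_run_config(),
                            profile = c("E2", "LD1"),
                            responses = c("discrimination", "acceptability"),
                            seed = 1, simulate = TRUE, data_dir = NULL) {
  profile <- match.arg(profile)
  stopifnot(is.numeric(seed), seed == round(seed))
  synthetic$seed <- seed
  rf$seed <- seed
  structure(list(out_dir = out_dir, synthetic = synthetic,
                 cleaning = cleaning, rf = rf, profile = profile,
                 responses = responses, seed = seed, simulate = simulate,
                 data_dir = data_dir),
            class = "pipeline_config")
}

.read_dataset <- function(data_dir, binning) {
  epg <- utils::read.csv(file.path(data_dir, "epg.csv"),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(data_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop(sprintf("spectra manifest not found: %s", manifest_path))
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  peaklists <- lapply(seq_len(nrow(manifest)), function(i) {
    parse_peaklist(file.path(data_dir, "spectra", manifest$file[i]),
                   binning = binning,
                   species = manifest$species[i],
                   plant_id = manifest$plant_id[i],
                   replicate = manifest$replicate[i],
                   fraction = manifest$fraction[i])
  })
  names(peaklists) <- manifest$file
  perf_path <- file.path(data_dir, "performance.csv")
  performance <- if (file.exists(perf_path)) {
    utils::read.csv(perf_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  list(epg = epg, spectra = list(peaklists = peaklists, manifest = manifest),
       performance = performance)
}

.matrices_from_spectra <- function(spectra, binning) {
  manifest <- spectra$manifest
  out <- list()
  for (fr in unique(manifest$fraction)) {
    sub <- manifest[manifest$fraction == fr, ]
    combined <- lapply(split(seq_len(nrow(sub)), sub$plant_id), function(idx) {
      profs <- lapply(sub$file[idx], function(f) {
        bin_spectrum(spectra$peaklists[[f]], binning)
      })
      combine_replicates(profs)$profile
    })
    out[[fr]] <- build_matrix(unname(combined), fraction = fr)
  }
  out
}

#' Run the analysis pipeline end-to-end
#'
#' Executes simulate (optional), EPG cleaning and profiling, score
#' derivation, spectral binning, random-forest ranking and annotation,
#' writing per-stage CSV outputs and a JSON run report to
#' `config$out_dir`. Any stage error aborts the run naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return the run report (invisibly), a list with per-stage summaries.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, profile = config$profile,
                 stages = list(), warnings = character(0))
  log_warning <- function(w) {
    report$warnings <<- c(report$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = log_warning),
             error = function(e) {
               stop(sprintf("stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  binning <- binning_config(0.2, config$synthetic$mz_range[1],
                            config$synthetic$mz_range[2])

  data <- run_stage("simulate", {
    if (config$simulate) {
      d <- generate_dataset(config$synthetic,
                            dir = file.path(config$out_dir, "data"))
      report$stages$simulate <- list(
        n_species = nrow(d$truth$species),
        n_recordings = nrow(d$epg),
        n_peaklists = length(d$spectra$peaklists))
      d
    } else {
      d <- .read_dataset(config$data_dir, binning)
      report$stages$simulate <- list(skipped = TRUE,
                                      data_dir = config$data_dir)
      d
    }
  })

  profiles <- run_stage("epg", {
    cleaned <- clean_epg(data$epg, config$cleaning, seed = config$seed)
    prof <- if (config$profile == "E2") {
      e2 <- extract_e2(cleaned$table)
      names(e2)[names(e2) == "e2_min"] <- "value"
      e2
    } else {
      races <- lapply(c("MS", "TP"), function(r) {
        ld <- compute_ld1(cleaned$table, r)
        out <- ld$scores
        out$clone <- cleaned$table$clone[cleaned$table$race == r]
        names(out)[names(out) == "ld1"] <- "value"
        out
      })
      do.call(rbind, races)
    }
    jsonlite::write_json(cleaned$report,
                         file.path(config$out_dir, "cleaning_report.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$epg <- list(
      n_recordings = nrow(prof),
      n_variables_remaining = length(cleaned$report$remaining))
    prof
  })

  scores <- run_stage("scores", {
    pt <- summarize_profiles(profiles, value_col = "value",
                             profile = config$profile)
    # LD1 axes are race-arbitrary in gain; equalise scales before combining
    st <- discrimination_acceptability(pt,
                                       scale_races = config$profile == "LD1")
    utils::write.csv(pt, file.path(config$out_dir, "profile_table.csv"),
                     row.names = FALSE)
    utils::write.csv(st, file.path(config$out_dir, "score_table.csv"),
                     row.names = FALSE)
    report$stages$scores <- list(n_species = nrow(st))
    list(profile_table = pt, score_table = st)
  })

  matrices <- run_stage("spectra", {
    mats <- .matrices_from_spectra(data$spectra, binning)
    for (fr in names(mats)) {
      m <- mats[[fr]]
      utils::write.csv(
        data.frame(m$meta, m$values, check.names = FALSE),
        file.path(config$out_dir, sprintf("profile_matrix_%s.csv", fr)),
        row.names = FALSE)
    }
    report$stages$spectra <- lapply(mats, function(m) {
      list(n_plants = nrow(m$values), n_bins = ncol(m$values))
    })
    mats
  })

  ranking <- run_stage("rank", {
    rank_rows <- list()
    top_rows <- list()
    r2 <- list()
    for (fr in names(matrices)) {
      for (resp in config$responses) {
        rd <- resampled_ranking(matrices[[fr]], scores$score_table,
                                response = resp, cfg = config$rf)
        rank_rows[[paste(fr, resp)]] <- data.frame(
          bin = rd$bins, median_rank = rd$median_rank, iqr = rd$iqr,
          fraction = fr, response = resp, stringsAsFactors = FALSE)
        top <- select_top_bins(rd, min(config$rf$top_k, length(rd$bins)))
        top$fraction <- fr
        top$response <- resp
        top_rows[[paste(fr, resp)]] <- top
        n_r2 <- min(nrow(top), nrow(scores$score_table) - 2L)
        r2[[fr]][[resp]] <- top_bins_r2(scores$score_table, matrices[[fr]],
                                        top$bin[seq_len(n_r2)],
                                        response = resp)
      }
    }
    rank_table <- do.call(rbind, c(rank_rows, list(make.row.names = FALSE)))
    top_bins <- do.call(rbind, c(top_rows, list(make.row.names = FALSE)))
    utils::write.csv(rank_table, file.path(config$out_dir, "rank_table.csv"),
                     row.names = FALSE)
    utils::write.csv(top_bins, file.path(config$out_dir, "top_bins.csv"),
                     row.names = FALSE)
    jsonlite::write_json(r2, file.path(config$out_dir, "r2.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$rank <- list(n_rank_rows = nrow(rank_table),
                                r2 = r2)
    list(rank_table = rank_table, top_bins = top_bins, r2 = r2)
  })

  run_stage("annotate", {
    nominal <- unique(floor(as.numeric(ranking$top_bins$bin)))
    hits <- annotate_bins(nominal)
    if (is.null(hits)) {
      hits <- data.frame(compound = character(0), adduct = character(0),
                         theoretical_mz = numeric(0), bin = character(0),
                         nominal_bin = integer(0),
                         mass_error_da = numeric(0),
                         query_bin = integer(0))
    }
    utils::write.csv(hits, file.path(config$out_dir, "annotation.csv"),
                     row.names = FALSE)
    report$stages$annotate <- list(n_bins_queried = length(nominal),
                                    n_hits = nrow(hits))
    hits
  })

  report$completed_stages <- names(report$stages)
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
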