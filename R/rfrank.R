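#' Configuration for the resampled random-forest ranking
#'
#' @param n_trees trees per forest (default 1000).
#' @param n_resamples number of response draws / forest refits (default 500).
#' @param top_k how many top bins to carry forward (default 8).
#' @param mtry predictors tried per split; default `floor(M/3)` at fit time,
#'   the regression-forest convention.
#' @param min_node minimum node size (default 5).
#' @param seed master seed; per-resample sub-seeds are spawned from it.
#' @return object of class `rf_run_config`.
#' @export
rf_run_config <- function(n_trees = 1000, n_resamples = 500, top_k = 8,
                          mtry = NULL, min_node = 5, seed = 1) {
  stopifnot(n_trees >= 1, n_resamples >= 1, top_k >= 1, min_node >= 1)
  structure(list(n_trees = n_trees, n_resamples = n_resamples, top_k = top_k,
                 mtry = mtry, min_node = min_node, seed = seed),
            class = "rf_run_config")
}

.score_cols <- function(response = c("discrimination", "acceptability")) {
  response <- match.arg(response)
  list(mean = response, se = paste0("se_", response), response = response)
}

#' Draw per-species responses from score means and standard errors
#'
#' One independent Normal(mean_j, SE_j^2) draw per species; a zero SE returns
#' the mean exactly. Species with a missing SE (single-recording cells) are an
#' error unless `pool_se` replaces missing SEs by the mean of the available
#' ones.
#'
#' @param scores a `score_table` from [discrimination_acceptability()].
#' @param response which score to draw: "discrimination" or "acceptability".
#' @param seed RNG seed.
#' @param pool_se replace missing SEs by the mean available SE (default
#'   FALSE).
#' @return named numeric vector of draws, one per species.
#' @export
draw_responses <- function(scores, response = "discrimination", seed = NULL,
                           pool_se = FALSE) {
  cols <- .score_cols(response)
  mu <- scores[[cols$mean]]
  se <- scores[[cols$se]]
  if (anyNA(se)) {
    if (!pool_se) {
      stop(paste("missing SE for species:",
                 paste(scores$species[is.na(se)], collapse = ", "),
                 "- exclude these species or set pool_se = TRUE"))
    }
    if (all(is.na(se))) stop("no SE available to pool")
    se[is.na(se)] <- mean(se, na.rm = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  stats::setNames(stats::rnorm(length(mu), mu, se), scores$species)
}

#' Random-forest importance of every m/z bin for a response
#'
#' Fits a regression forest (bootstrap rows, `mtry` features per split) of the
#' plants x bins %TIC matrix on a per-plant response and returns the
#' node-impurity importance: the total decrease in residual sum of squares
#' attributable to splits on each bin, summed over nodes and averaged over
#' trees (the IncNodePurity convention). Importances are non-negative. The
#' forest is fitted single-threaded by ranger so results are reproducible
#' from the R random seed alone.
#'
#' @param X numeric matrix, rows = plants, columns = bins.
#' @param y numeric response, one value per row of X.
#' @param cfg an [rf_run_config()].
#' @return named numeric vector of importances per bin.
#' @export
forest_importance <- function(X, y, cfg = rf_run_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (nrow(X) < 10L) stop("need at least 10 rows")
  if (stats::sd(y) == 0) stop("constant response")
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(ncol(X) / 3)) else cfg$mtry
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("bin%04d", seq_len(ncol(X)))
  }
  fit <- ranger::ranger(
    x = X, y = y, num.trees = cfg$n_trees, mtry = mtry,
    min.node.size = cfg$min_node, importance = "impurity",
    num.threads = 1, seed = sample.int(.Machine$integer.max - 1L, 1L))
  stats::setNames(as.numeric(fit$variable.importance), colnames(X))
}

.rank_importance <- function(imp) {
  # rank 1 = most important; ties get average ranks
  rank(-imp, ties.method = "average")
}

.spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.plant_responses <- function(m, draws) {
  missing <- setdiff(unique(m$meta$species), names(draws))
  if (length(missing) > 0L) {
    stop(sprintf("no score for species: %s", paste(missing, collapse = ", ")))
  }
  as.numeric(draws[m$meta$species])
}

.new_rank_distribution <- function(ranks, response, fraction) {
  structure(list(ranks = ranks,
                 median_rank = apply(ranks, 1, stats::median),
                 iqr = apply(ranks, 1, stats::IQR),
                 bins = rownames(ranks),
                 response = response, fraction = fraction),
            class = "rank_distribution")
}

#' @export
print.rank_distribution <- function(x, ...) {
  cat(sprintf("rank_distribution: %d bins x %d resamples (%s)\n",
              nrow(x$ranks), ncol(x$ranks), x$response))
  invisible(x)
}

#' Importance-rank distribution under response uncertainty
#'
#' The uncertainty-propagating core: for each of R resamples, draws one
#' response per species from Normal(mean, SE^2), assigns every plant its
#' species' draw, fits a regression forest and ranks bins by descending
#' importance (rank 1 = most important, ties averaged). Median and
#' inter-quartile range of the R ranks summarise each bin's importance and
#' its consistency.
#'
#' @param m a `profile_matrix` (plants x bins %TIC).
#' @param scores a `score_table`.
#' @param response "discrimination" or "acceptability".
#' @param cfg an [rf_run_config()]; `cfg$n_resamples` is R.
#' @param exclude_plants optional plant_ids dropped before fitting (the
#'   outlier-exclusion robustness rerun).
#' @param pool_se passed to [draw_responses()].
#' @return object of class `rank_distribution`.
#' @export
resampled_ranking <- function(m, scores, response = "discrimination",
                              cfg = rf_run_config(), exclude_plants = NULL,
                              pool_se = FALSE) {
  stopifnot(inherits(m, "profile_matrix"))
  keep <- !(m$meta$plant_id %in% exclude_plants)
  X <- m$values[keep, , drop = FALSE]
  meta <- m$meta[keep, , drop = FALSE]
  sub <- list(values = X, meta = meta, fraction = m$fraction,
              binning = m$binning)
  class(sub) <- "profile_matrix"
  R <- cfg$n_resamples
  seeds <- .spawn_seeds(cfg$seed, R)
  ranks <- matrix(NA_real_, ncol(X), R,
                  dimnames = list(colnames(X), NULL))
  for (r in seq_len(R)) {
    draws <- draw_responses(scores, response, seed = seeds[r],
                            pool_se = pool_se)
    y <- .plant_responses(sub, draws)
    imp <- forest_importance(X, y, cfg)
    ranks[, r] <- .rank_importance(imp)
  }
  .new_rank_distribution(ranks, response, m$fraction)
}

#' Select the top-k bins by median importance rank
#'
#' Bins are ordered by smallest median rank; ties are broken by smaller IQR,
#' then by bin label ascending.
#'
#' @param rd a `rank_distribution`.
#' @param k number of bins (default 8).
#' @return data.frame `bin`, `median_rank`, `iqr`, ordered.
#' @export
select_top_bins <- function(rd, k = 8) {
  stopifnot(inherits(rd, "rank_distribution"))
  if (k > length(rd$bins)) stop("k exceeds the number of bins")
  ord <- order(rd$median_rank, rd$iqr, as.numeric(rd$bins))
  idx <- ord[seq_len(k)]
  data.frame(bin = rd$bins[idx], median_rank = rd$median_rank[idx],
             iqr = rd$iqr[idx], row.names = NULL, stringsAsFactors = FALSE)
}

.species_mean_matrix <- function(m, bins) {
  X <- m$values[, bins, drop = FALSE]
  rowsplit <- split(seq_len(nrow(X)), m$meta$species)
  res <- vapply(rowsplit, function(idx) colMeans(X[idx, , drop = FALSE]),
                numeric(length(bins)))
  matrix(res, nrow = length(rowsplit), ncol = length(bins), byrow = TRUE,
         dimnames = list(names(rowsplit), bins))
}

#' Variance in a score explained by selected bins
#'
#' Ordinary least squares of the species-level score on the species-mean %TIC
#' of the selected bins; returns the coefficient of determination.
#'
#' @param scores a `score_table`.
#' @param m a `profile_matrix`.
#' @param bins character vector of bin labels (columns of the matrix).
#' @param response "discrimination" or "acceptability".
#' @return R-squared in \[0, 1\].
#' @export
top_bins_r2 <- function(scores, m, bins, response = "discrimination") {
  stopifnot(inherits(m, "profile_matrix"))
  cols <- .score_cols(response)
  Xs <- .species_mean_matrix(m, bins)
  common <- intersect(scores$species, rownames(Xs))
  if (length(common) <= length(bins) + 1L) {
    stop("need more species than bins + 1 for the regression")
  }
  Xs <- Xs[common, , drop = FALSE]
  y <- scores[[cols$mean]][match(common, scores$species)]
  kap <- kappa(cbind(1, Xs), exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    stop(sprintf("collinear design: condition number %.3g", kap))
  }
  fit <- stats::lm(y ~ Xs)
  summary(fit)$r.squared
}

#' Spearman screen of bins against a score, with FDR correction
#'
#' Per bin: Spearman correlation of the species-mean %TIC with the
#' species-level score, with Benjamini-Hochberg q-values over the tested set.
#' Constant bins get NA with a warning.
#'
#' @inheritParams top_bins_r2
#' @return data.frame `bin`, `rho`, `p_value`, `q_value`.
#' @export
spearman_screen_fdr <- function(scores, m, bins, response = "discrimination") {
  stopifnot(inherits(m, "profile_matrix"))
  cols <- .score_cols(response)
  Xs <- .species_mean_matrix(m, bins)
  common <- intersect(scores$species, rownames(Xs))
  if (length(common) < 4L) stop("need at least 4 species")
  Xs <- Xs[common, , drop = FALSE]
  y <- scores[[cols$mean]][match(common, scores$species)]
  res <- lapply(seq_along(bins), function(i) {
    x <- Xs[, i]
    if (stats::sd(x) == 0) {
      warning(sprintf("bin %s is constant across species; rho undefined",
                      bins[i]))
      return(c(rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman",
                      exact = length(common) <= 10))
    c(rho = unname(ct$estimate), p = ct$p.value)
  })
  rho <- vapply(res, `[[`, numeric(1), "rho")
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(bin = bins, rho = rho, p_value = p, q_value = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Jack-knife stability of the importance ranking
#'
#' Creates `n_jack` jack-knifed behavioural datasets by deleting one random
#' recording from every species x cell (race by default, optionally race x
#' clone), recomputes the species-level point-estimate scores, fits one
#' forest per dataset (no SE draw) and aggregates the bin ranks' median and
#' IQR.
#'
#' @param profiles per-recording profile data.frame (`species`, `race`,
#'   optional `clone`, and a value column as in [summarize_profiles()]).
#' @param m a `profile_matrix`.
#' @param response "discrimination" or "acceptability".
#' @param cfg an [rf_run_config()].
#' @param n_jack number of jack-knife datasets (default 500).
#' @param cell "race" (species x race cells) or "clone" (species x race x
#'   clone cells).
#' @param value_col passed to [summarize_profiles()].
#' @return object of class `rank_distribution`.
#' @export
jackknife_ranking <- function(profiles, m, response = "discrimination",
                              cfg = rf_run_config(), n_jack = 500,
                              cell = c("race", "clone"), value_col = NULL) {
  cell <- match.arg(cell)
  stopifnot(inherits(m, "profile_matrix"))
  key <- if (cell == "race") {
    paste(profiles$species, profiles$race, sep = " x ")
  } else {
    paste(profiles$species, profiles$race, profiles$clone, sep = " x ")
  }
  sizes <- table(key)
  if (any(sizes < 2L)) {
    stop(sprintf("cell(s) with fewer than 2 recordings: %s",
                 paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  groups <- split(seq_len(nrow(profiles)), key)
  seeds <- .spawn_seeds(cfg$seed, n_jack)
  ranks <- matrix(NA_real_, ncol(m$values), n_jack,
                  dimnames = list(colnames(m$values), NULL))
  for (b in seq_len(n_jack)) {
    set.seed(seeds[b])
    drop_idx <- vapply(groups, function(idx) idx[sample.int(length(idx), 1L)],
                       integer(1))
    sub <- profiles[-drop_idx, , drop = FALSE]
    prof <- summarize_profiles(sub, value_col = value_col)
    sc <- suppressWarnings(discrimination_acceptability(prof))
    point <- stats::setNames(sc[[response]], sc$species)
    y <- .plant_responses(m, point)
    # common forest seed: rank variability reflects the deleted recordings,
    # not forest randomness, so identical jack-knife datasets rank identically
    set.seed(cfg$seed)
    imp <- forest_importance(m$values, y, cfg)
    ranks[, b] <- .rank_importance(imp)
  }
  .new_rank_distribution(ranks, response, m$fraction)
}
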