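#' Summarise per-recording profiles to species x race means
#'
#' Computes the sample mean, SD, SE = SD/sqrt(n) and n of a per-recording
#' acceptance profile (E2 or LD1) for every species x race cell. The SE is NA
#' for single-recording cells.
#'
#' @param profiles data.frame with columns `species`, `race` and `value` (or a
#'   column named by `value_col`).
#' @param value_col name of the value column; defaults to the first of
#'   `value`, `e2_min`, `ld1` present.
#' @param profile label for the profile kind ("E2" or "LD1"), carried through.
#' @return data.frame of class `profile_table`: `species`, `race`, `n`,
#'   `mean`, `sd`, `se`, `profile`.
#' @export
summarize_profiles <- function(profiles, value_col = NULL, profile = NULL) {
  stopifnot(is.data.frame(profiles),
            all(c("species", "race") %in% names(profiles)))
  if (is.null(value_col)) {
    value_col <- intersect(c("value", "e2_min", "ld1"), names(profiles))[1]
    if (is.na(value_col)) stop("no value column found")
  }
  if (is.null(profile)) {
    profile <- switch(value_col, e2_min = "E2", ld1 = "LD1", "profile")
  }
  v <- profiles[[value_col]]
  if (anyNA(v)) stop("profile values must not be missing")
  cells <- interaction(profiles$species, profiles$race, drop = FALSE,
                       sep = " x ")
  full <- expand.grid(species = unique(profiles$species),
                      race = unique(profiles$race),
                      stringsAsFactors = FALSE)
  have <- paste(profiles$species, profiles$race, sep = " x ")
  want <- paste(full$species, full$race, sep = " x ")
  empty <- setdiff(want, have)
  if (length(empty) > 0L) {
    stop(sprintf("empty species x race cell(s): %s",
                 paste(empty, collapse = ", ")))
  }
  agg <- lapply(split(v, have), function(x) {
    n <- length(x)
    s <- if (n >= 2L) stats::sd(x) else NA_real_
    c(n = n, mean = mean(x), sd = s,
      se = if (n >= 2L) s / sqrt(n) else NA_real_)
  })
  key <- names(agg)
  parts <- strsplit(key, " x ", fixed = TRUE)
  out <- data.frame(
    species = vapply(parts, `[[`, character(1), 1L),
    race = vapply(parts, `[[`, character(1), 2L),
    n = vapply(agg, `[[`, numeric(1), "n"),
    mean = vapply(agg, `[[`, numeric(1), "mean"),
    sd = vapply(agg, `[[`, numeric(1), "sd"),
    se = vapply(agg, `[[`, numeric(1), "se"),
    profile = profile, row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$species, out$race), ]
  rownames(out) <- NULL
  class(out) <- c("profile_table", "data.frame")
  out
}

#' Discrimination and overall acceptability per plant species
#'
#' Discrimination is the difference of the two race means (MS - TP; positive
#' values mean greater acceptance by MS aphids) and overall acceptability is
#' their sum. Standard errors propagate as sqrt(SE_MS^2 + SE_TP^2). By
#' construction discrimination + acceptability = 2 * mean_MS exactly.
#'
#' When the profile is expressed in race-arbitrary units — LD1 axes are
#' fitted per race, so their gains differ — summing raw race means yields a
#' gain-weighted mixture that leaks discrimination into acceptability.
#' `scale_races = TRUE` divides each race's means and SEs by the standard
#' deviation of its species means first, putting both races on a common
#' among-species scale. Leave it FALSE for profiles in shared physical units
#' such as E2 minutes.
#'
#' @param profiles a `profile_table` from [summarize_profiles()].
#' @param on_missing what to do with a species lacking one race: "drop" (with
#'   a warning, the default) or "error".
#' @param scale_races standardise each race's among-species scale before
#'   combining (default FALSE; recommended for LD1 profiles).
#' @return data.frame of class `score_table`: `species`, `mean_MS`,
#'   `mean_TP`, `se_MS`, `se_TP`, `discrimination`, `acceptability`,
#'   `se_discrimination`, `se_acceptability`, `profile`.
#' @export
discrimination_acceptability <- function(profiles,
                                         on_missing = c("drop", "error"),
                                         scale_races = FALSE) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(profiles),
            all(c("species", "race", "mean") %in% names(profiles)))
  ms <- profiles[profiles$race == "MS", ]
  tp <- profiles[profiles$race == "TP", ]
  common <- intersect(ms$species, tp$species)
  missing <- setdiff(union(ms$species, tp$species), common)
  if (length(missing) > 0L) {
    msg <- sprintf("species missing one race: %s",
                   paste(missing, collapse = ", "))
    if (on_missing == "error") stop(msg)
    warning(paste(msg, "- dropped from score table"))
  }
  ms <- ms[match(common, ms$species), ]
  tp <- tp[match(common, tp$species), ]
  if (scale_races) {
    for (r in c("ms", "tp")) {
      tab <- get(r)
      s <- stats::sd(tab$mean)
      if (s == 0) stop("cannot scale a race with constant species means")
      tab$mean <- tab$mean / s
      tab$se <- tab$se / s
      assign(r, tab)
    }
  }
  se <- sqrt(ms$se^2 + tp$se^2)
  out <- data.frame(
    species = common,
    mean_MS = ms$mean, mean_TP = tp$mean,
    se_MS = ms$se, se_TP = tp$se,
    discrimination = ms$mean - tp$mean,
    acceptability = ms$mean + tp$mean,
    se_discrimination = se, se_acceptability = se,
    profile = ms$profile, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Correlate two per-species vectors
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided P
#' value. Pearson uses the t distribution; Spearman uses the exact permutation
#' distribution for n <= 10 (t approximation if ties make the exact
#' distribution unavailable) and the t approximation for larger n.
#'
#' @param x,y numeric vectors of equal length (n >= 3), typically species
#'   means.
#' @param method "pearson" or "spearman".
#' @param pair optional description of what is being correlated.
#' @return list with `estimate`, `n`, `p_value`, `method`, `pair`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"), pair = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite and non-missing")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  n <- length(x)
  ct <- if (method == "spearman") {
    suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                     exact = n <= 10))
  } else {
    stats::cor.test(x, y, method = "pearson")
  }
  list(estimate = unname(ct$estimate), n = n, p_value = ct$p.value,
       method = method, pair = pair)
}

#' Correlate species-level profile scores with aphid performance
#'
#' Aggregates the performance table to species x race mean fecundity and
#' correlates it with the per-species race-mean profile, separately per race.
#'
#' @param profiles a `profile_table`.
#' @param performance data.frame `species`, `race`, `live_young` (replicate
#'   rows).
#' @param method correlation method, default "pearson".
#' @return data.frame with one row per race: `race`, `r`, `n`, `p_value`.
#' @export
performance_correlation <- function(profiles, performance,
                                    method = "pearson") {
  stopifnot(all(c("species", "race", "live_young") %in% names(performance)))
  out <- lapply(c("MS", "TP"), function(r) {
    prof <- profiles[profiles$race == r, ]
    perf <- performance[performance$race == r, ]
    perf_mean <- tapply(perf$live_young, perf$species, mean)
    common <- intersect(prof$species, names(perf_mean))
    res <- correlate(prof$mean[match(common, prof$species)],
                     as.numeric(perf_mean[common]), method = method,
                     pair = sprintf("%s profile vs fecundity", r))
    data.frame(race = r, r = res$estimate, n = res$n, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
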