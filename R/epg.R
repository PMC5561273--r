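#' Cleaning configuration for EPG feature tables
#'
#' @param zero_frac_threshold drop a variable when the fraction of zero values
#'   reaches this proportion (default 0.50; the rule is "50% or more").
#' @param corr_threshold drop one variable of any pair with Pearson |r|
#'   strictly above this value (default 0.80; a pair at exactly 0.80 is kept).
#' @return object of class `cleaning_config`.
#' @export
cleaning_config <- function(zero_frac_threshold = 0.50, corr_threshold = 0.80) {
  stopifnot(zero_frac_threshold >= 0, zero_frac_threshold <= 1,
            corr_threshold >= 0, corr_threshold <= 1)
  structure(list(zero_frac_threshold = zero_frac_threshold,
                 corr_threshold = corr_threshold),
            class = "cleaning_config")
}

.epg_label_cols <- c("recording_id", "race", "clone", "species", "genus")

# behavioural variable columns: everything numeric except labels and E2
.epg_var_cols <- function(table, include_e2 = FALSE) {
  cols <- setdiff(names(table), .epg_label_cols)
  if (!include_e2) cols <- setdiff(cols, "E2_total_min")
  cols[vapply(table[cols], is.numeric, logical(1))]
}

.check_epg_table <- function(table) {
  stopifnot(is.data.frame(table))
  missing <- setdiff(c("race", "species"), names(table))
  if (length(missing) > 0L) {
    stop(sprintf("EPG table lacks column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (!all(table$race %in% c("MS", "TP"))) {
    stop("race labels must be 'MS' or 'TP'")
  }
  if (any(!nzchar(table$species) | is.na(table$species))) {
    stop("species labels must be non-empty")
  }
  invisible(table)
}

#' Impute missing EPG values by proximity-weighted tree-ensemble imputation
#'
#' Missing behavioural cells are filled by median-start iterative
#' random-forest proximity imputation (the rfImpute scheme: start at column
#' medians, then repeatedly refit a forest on the species grouping and replace
#' each missing cell by the proximity-weighted average of the observed
#' values), run for 3 iterations of 300 trees. Non-missing cells are never
#' changed and the result is deterministic for a fixed seed.
#'
#' @param table an EPG feature table (see [generate_epg_table()] for the
#'   schema).
#' @param seed RNG seed (default 1).
#' @param iter,ntree imputation iterations and trees per forest.
#' @return the table with no missing numeric cells.
#' @export
impute_missing <- function(table, seed = 1, iter = 3, ntree = 300) {
  .check_epg_table(table)
  vars <- .epg_var_cols(table, include_e2 = TRUE)
  all_na <- vars[vapply(table[vars], function(x) all(is.na(x)), logical(1))]
  if (length(all_na) > 0L) {
    stop(sprintf("variable(s) entirely missing: %s",
                 paste(all_na, collapse = ", ")))
  }
  few <- vars[vapply(table[vars], function(x) sum(!is.na(x)) < 2L, logical(1))]
  if (length(few) > 0L) {
    stop(sprintf("variable(s) with fewer than 2 observed values: %s",
                 paste(few, collapse = ", ")))
  }
  if (!anyNA(table[vars])) return(table)
  x <- as.data.frame(table[vars])
  y <- factor(table$species)
  set.seed(seed)
  utils::capture.output(imputed <- suppressWarnings(
    randomForest::rfImpute(x = x, y = y, iter = iter, ntree = ntree)
  ))
  imputed$y <- NULL
  # rfImpute may mangle names; restore by position
  names(imputed) <- vars
  out <- table
  out[vars] <- imputed
  out
}

#' Remove zero-inflated behavioural variables
#'
#' Drops every behavioural variable whose fraction of values equal to zero is
#' at least `zero_frac_threshold` (50% or more by default). The E2 column and
#' the label columns are never removed.
#'
#' @param table an imputed EPG feature table.
#' @param config a [cleaning_config()].
#' @return list with `table` (filtered) and `report` (list with
#'   `dropped_zero`, `remaining`).
#' @export
filter_zero_inflated <- function(table, config = cleaning_config()) {
  .check_epg_table(table)
  vars <- .epg_var_cols(table)
  zero_frac <- vapply(table[vars], function(x) mean(x == 0, na.rm = TRUE),
                      numeric(1))
  dropped <- vars[zero_frac >= config$zero_frac_threshold]
  out <- table[setdiff(names(table), dropped)]
  list(table = out,
       report = list(dropped_zero = dropped,
                     zero_fraction = zero_frac,
                     remaining = setdiff(vars, dropped)))
}

#' Prune one variable from every highly correlated pair
#'
#' Greedy pass over variable pairs in column order: for each pair with Pearson
#' |r| strictly above `corr_threshold` in which both variables are still
#' present, the later column is dropped. The comparison carries a 1e-10
#' numerical guard so a pair at exactly the threshold is kept (the rule is
#' strictly "greater than"). Afterwards no remaining pair exceeds the
#' threshold (asserted). Zero-variance variables are excluded from the
#' correlation computation and kept, with a warning.
#'
#' @param table a zero-filtered EPG feature table.
#' @param config a [cleaning_config()].
#' @return list with `table` (pruned) and `report` (data.frame of
#'   kept/dropped/r decisions plus `remaining`).
#' @export
prune_correlated <- function(table, config = cleaning_config()) {
  .check_epg_table(table)
  vars <- .epg_var_cols(table)
  const <- vars[vapply(table[vars],
                       function(x) stats::sd(x, na.rm = TRUE) == 0,
                       logical(1))]
  if (length(const) > 0L) {
    warning(sprintf("zero-variance variable(s) kept, excluded from pruning: %s",
                    paste(const, collapse = ", ")))
  }
  active <- setdiff(vars, const)
  decisions <- list()
  if (length(active) >= 2L) {
    cm <- stats::cor(as.matrix(table[active]),
                     use = "pairwise.complete.obs")
    alive <- rep(TRUE, length(active))
    for (i in seq_along(active)[-length(active)]) {
      if (!alive[i]) next
      for (j in seq((i + 1L), length(active))) {
        if (!alive[j]) next
        r <- cm[i, j]
        if (is.finite(r) && abs(r) > config$corr_threshold + 1e-10) {
          alive[j] <- FALSE
          decisions[[length(decisions) + 1L]] <- data.frame(
            kept = active[i], dropped = active[j], r = r,
            stringsAsFactors = FALSE)
        }
      }
    }
    dropped <- active[!alive]
  } else {
    dropped <- character(0)
  }
  out <- table[setdiff(names(table), dropped)]
  remaining <- setdiff(vars, dropped)
  surv <- setdiff(remaining, const)
  if (length(surv) >= 2L) {
    cm2 <- abs(stats::cor(as.matrix(out[surv]),
                          use = "pairwise.complete.obs"))
    diag(cm2) <- 0
    stopifnot(max(cm2, na.rm = TRUE) <= config$corr_threshold + 1e-10)
  }
  report <- if (length(decisions) > 0L) {
    do.call(rbind, decisions)
  } else {
    data.frame(kept = character(0), dropped = character(0), r = numeric(0))
  }
  list(table = out, report = list(pruned_pairs = report,
                                  remaining = remaining,
                                  zero_variance_kept = const))
}

#' Clean an EPG table: impute, filter zero-inflated, prune correlated
#'
#' @inheritParams impute_missing
#' @inheritParams filter_zero_inflated
#' @return list with `table` and a combined `report`.
#' @export
clean_epg <- function(table, config = cleaning_config(), seed = 1) {
  imputed <- impute_missing(table, seed = seed)
  zf <- filter_zero_inflated(imputed, config)
  pr <- prune_correlated(zf$table, config)
  list(table = pr$table,
       report = list(dropped_zero = zf$report$dropped_zero,
                     pruned_pairs = pr$report$pruned_pairs,
                     zero_variance_kept = pr$report$zero_variance_kept,
                     remaining = pr$report$remaining))
}

#' First linear-discriminant scores of the cleaned EPG variables
#'
#' Fisher LDA of all cleaned behavioural variables (including E2) for one
#' aphid race, with plant species as the grouping factor. Uses the pooled
#' within-species covariance with a small ridge (1e-8 * trace/p on the
#' diagonal) and scales the discriminant so the pooled within-species variance
#' of the scores is 1, which makes scores invariant (up to sign) to affine
#' rescaling of any input variable.
#'
#' The axis orientation of Fisher LDA is arbitrary, and because the two races
#' are analysed separately their axes need a common anchor before race means
#' can be summed or differenced. With `orient = "e2"` (the default) the axis
#' is flipped, if needed, so the scores correlate non-negatively with the E2
#' duration: LD1 then reads as an acceptance score for either race.
#' `orient = "loading"` instead makes the largest-magnitude loading positive,
#' a purely mechanical convention used automatically when E2 is absent.
#'
#' @param table cleaned EPG feature table.
#' @param race which race to analyse, "MS" or "TP".
#' @param ridge ridge coefficient relative to trace/p (default 1e-8).
#' @param orient axis orientation rule, "e2" (default) or "loading".
#' @return list with `scores` (data.frame recording_id, species, ld1),
#'   `proportion` (share of among-species variance explained by LD1),
#'   `loadings` (named vector), `race`.
#' @export
compute_ld1 <- function(table, race, ridge = 1e-8,
                        orient = c("e2", "loading")) {
  orient <- match.arg(orient)
  .check_epg_table(table)
  stopifnot(race %in% c("MS", "TP"))
  sub <- table[table$race == race, , drop = FALSE]
  vars <- .epg_var_cols(sub, include_e2 = TRUE)
  groups <- factor(sub$species)
  if (nlevels(groups) < 2L) stop("need at least 2 species for LDA")
  if (any(table(groups) < 2L)) {
    stop("every species needs at least 2 recordings for LDA")
  }
  X <- as.matrix(sub[vars])
  if (anyNA(X)) stop("LDA requires a fully imputed table")
  p <- ncol(X)
  n <- nrow(X)
  g <- nlevels(groups)
  grand <- colMeans(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (lev in levels(groups)) {
    Xg <- X[groups == lev, , drop = FALSE]
    ng <- nrow(Xg)
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2, mg))
    B <- B + ng * tcrossprod(mg - grand)
  }
  W <- W / (n - g)
  B <- B / (g - 1)
  Wr <- W + diag(ridge * sum(diag(W)) / p, p)
  # whiten with the Cholesky factor so the eigenproblem is symmetric,
  # which is numerically far better conditioned than eigen(W^-1 B)
  L <- tryCatch(chol(Wr), error = function(e) {
    stop("singular within-species covariance even after ridge regularisation")
  })
  Bw <- backsolve(L, t(backsolve(L, t(B), transpose = TRUE)),
                  transpose = TRUE)
  eig <- eigen((Bw + t(Bw)) / 2, symmetric = TRUE)
  vals <- eig$values
  vals[vals < 0] <- 0
  v <- backsolve(L, eig$vectors[, 1])
  # scale so pooled within-species variance of scores is 1
  v <- v / sqrt(drop(t(v) %*% Wr %*% v))
  if (v[which.max(abs(v))] < 0) v <- -v
  scores <- drop(sweep(X, 2, grand) %*% v)
  if (orient == "e2" && "E2_total_min" %in% vars &&
      stats::sd(sub$E2_total_min) > 0 &&
      stats::cor(scores, sub$E2_total_min) < 0) {
    v <- -v
    scores <- -scores
  }
  proportion <- if (sum(vals) > 0) vals[1] / sum(vals) else 0
  proportion <- min(max(proportion, 0), 1)
  list(scores = data.frame(
         recording_id = if ("recording_id" %in% names(sub)) {
           sub$recording_id
         } else {
           seq_len(nrow(sub))
         },
         species = sub$species, race = race, ld1 = scores,
         stringsAsFactors = FALSE),
       proportion = proportion,
       loadings = stats::setNames(v, vars),
       race = race)
}

#' Extract per-recording E2 durations
#'
#' Returns the total E2 (passive phloem ingestion) duration per recording, in
#' minutes. Values must lie within the 6-hour recording window \[0, 360\].
#'
#' @param table an EPG feature table with an `E2_total_min` column.
#' @return data.frame `recording_id`, `race`, `clone`, `species`, `e2_min`.
#' @export
extract_e2 <- function(table) {
  .check_epg_table(table)
  if (!"E2_total_min" %in% names(table)) {
    stop("column 'E2_total_min' absent")
  }
  e2 <- table$E2_total_min
  if (anyNA(e2)) stop("E2 column must not contain missing values")
  if (any(e2 < 0 | e2 > 360)) {
    stop("E2 durations must lie in [0, 360] minutes for a 6-hour recording")
  }
  data.frame(
    recording_id = if ("recording_id" %in% names(table)) {
      table$recording_id
    } else {
      seq_len(nrow(table))
    },
    race = table$race,
    clone = if ("clone" %in% names(table)) table$clone else NA_character_,
    species = table$species,
    e2_min = e2, stringsAsFactors = FALSE)
}
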