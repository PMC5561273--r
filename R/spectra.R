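#' Binning configuration for MALDI-TOF peak lists
#'
#' Bins are half-open intervals `[edge, edge + bin_width)` anchored at
#' `range_min`, so a peak at exactly a bin edge falls in the bin to its right.
#' Bin labels are the left edge printed to one decimal; the nominal bin is the
#' integer part of the m/z, the convention used when bins are reported by
#' integer mass (e.g. "bin 166").
#'
#' @param bin_width bin width in Da (default 0.2).
#' @param range_min,range_max mass range in Da (defaults 50 and 1000).
#' @return object of class `binning_config`.
#' @export
binning_config <- function(bin_width = 0.2, range_min = 50, range_max = 1000) {
  stopifnot(bin_width > 0, range_min < range_max)
  n_bins <- round((range_max - range_min) / bin_width)
  if (abs(n_bins * bin_width - (range_max - range_min)) > 1e-9) {
    stop("mass range must be an integer number of bins")
  }
  structure(list(bin_width = bin_width, range_min = range_min,
                 range_max = range_max, n_bins = n_bins),
            class = "binning_config")
}

#' Left edge of the bin containing an m/z value
#' @param mz numeric m/z values within the binning range.
#' @param binning a [binning_config()].
#' @return numeric left edges, rounded to the label precision.
#' @export
bin_left_edge <- function(mz, binning = binning_config()) {
  idx <- floor((mz - binning$range_min) / binning$bin_width + 1e-12)
  idx <- pmin(pmax(idx, 0), binning$n_bins - 1)
  round(binning$range_min + idx * binning$bin_width, 6)
}

.bin_label <- function(edge) sprintf("%.1f", edge)

#' Read a two-column m/z-intensity peak list
#'
#' Parses a tab-separated file with columns m/z and intensity. Peaks outside
#' the configured mass range are dropped and their count reported with a
#' message; negative intensities and non-numeric lines are errors.
#'
#' @param file path to the TSV file.
#' @param binning a [binning_config()] supplying the mass range.
#' @param species,plant_id,replicate,fraction optional metadata attached to
#'   the peak list.
#' @return object of class `peaklist`: list with `mz`, `intensity`, `meta`.
#' @export
parse_peaklist <- function(file, binning = binning_config(),
                           species = NA_character_, plant_id = NA_character_,
                           replicate = NA_integer_, fraction = NA_character_) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty peak list file: %s", file))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected two tab-separated fields",
                 bad[1], file))
  }
  mz <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  bad <- which(is.na(mz) | is.na(intensity))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: non-numeric value", bad[1], file))
  }
  if (any(intensity < 0)) {
    stop(sprintf("negative intensity in %s", file))
  }
  peaklist(mz, intensity, species = species, plant_id = plant_id,
           replicate = replicate, fraction = fraction, binning = binning)
}

#' Construct a peak list from vectors
#'
#' @param mz,intensity numeric vectors of equal length.
#' @inheritParams parse_peaklist
#' @return object of class `peaklist`. Peaks outside the binning range are
#'   dropped with a message giving the count.
#' @export
peaklist <- function(mz, intensity, species = NA_character_,
                     plant_id = NA_character_, replicate = NA_integer_,
                     fraction = NA_character_, binning = binning_config()) {
  stopifnot(length(mz) == length(intensity), all(is.finite(intensity)),
            all(intensity >= 0))
  keep <- mz >= binning$range_min & mz < binning$range_max
  if (any(!keep)) {
    message(sprintf("dropped %d peak(s) outside [%g, %g) Da",
                    sum(!keep), binning$range_min, binning$range_max))
  }
  structure(list(mz = mz[keep], intensity = intensity[keep],
                 meta = list(species = species, plant_id = plant_id,
                             replicate = replicate, fraction = fraction)),
            class = "peaklist")
}

#' Bin a peak list into %TIC per 0.2-Da m/z bin
#'
#' Sums intensity within half-open bins, then converts to percent of total
#' ion count so the profile sums to 100. Only occupied bins are stored; a
#' downstream matrix treats absent bins as 0.
#'
#' @param p a `peaklist`.
#' @param binning a [binning_config()].
#' @return object of class `binned_profile`: named numeric vector of %TIC
#'   (names = bin labels), with attributes `edges`, `nominal_bin`, `meta`,
#'   `binning`.
#' @export
bin_spectrum <- function(p, binning = binning_config()) {
  stopifnot(inherits(p, "peaklist"))
  if (length(p$mz) == 0L) stop("empty peak list")
  total <- sum(p$intensity)
  if (total <= 0) stop("zero total intensity")
  edges <- bin_left_edge(p$mz, binning)
  agg <- tapply(p$intensity, edges, sum)
  edge_vals <- as.numeric(names(agg))
  ord <- order(edge_vals)
  tic <- as.numeric(agg)[ord] / total * 100
  edge_vals <- edge_vals[ord]
  structure(stats::setNames(tic, .bin_label(edge_vals)),
            edges = edge_vals,
            nominal_bin = floor(edge_vals),
            meta = p$meta, binning = binning,
            class = "binned_profile")
}

#' Combine technical replicate profiles of one plant
#'
#' Averages replicate %TIC per bin and renormalises the mean profile to sum
#' to 100. Bins whose replicate coefficient of variation exceeds
#' `concordance_cv` while the mean %TIC exceeds 0.01 are flagged in the
#' concordance report; they are reported, never removed.
#'
#' @param profiles list of >= 2 `binned_profile` objects of the same plant and
#'   fraction.
#' @param concordance_cv CV threshold for flagging discordant bins
#'   (default 0.5).
#' @return list with `profile` (combined `binned_profile`) and `report`
#'   (data.frame of flagged bins with mean and CV).
#' @export
combine_replicates <- function(profiles, concordance_cv = 0.5) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, logical(1), "binned_profile")))
  metas <- lapply(profiles, attr, "meta")
  key <- vapply(metas, function(m) {
    paste(m$species, m$plant_id, m$fraction, sep = "\r")
  }, character(1))
  if (length(unique(key)) != 1L) {
    stop("replicate metadata mismatch: all profiles must share species, plant_id and fraction")
  }
  bins <- sort(unique(unlist(lapply(profiles, names))))
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(bins)), bins)
    v[names(p)] <- as.numeric(p)
    v
  }, numeric(length(bins)))
  mat <- matrix(mat, nrow = length(bins),
                dimnames = list(bins, NULL))
  means <- rowMeans(mat)
  sds <- apply(mat, 1, stats::sd)
  cv <- ifelse(means > 0, sds / means, 0)
  flagged <- which(cv > concordance_cv & means > 0.01)
  report <- data.frame(bin = bins[flagged], mean_tic = means[flagged],
                       cv = cv[flagged], row.names = NULL,
                       stringsAsFactors = FALSE)
  combined <- means / sum(means) * 100
  binning <- attr(profiles[[1]], "binning")
  edges <- as.numeric(bins)
  meta <- metas[[1]]
  meta$replicate <- NA_integer_
  profile <- structure(stats::setNames(combined, bins),
                       edges = edges, nominal_bin = floor(edges),
                       meta = meta, binning = binning,
                       class = "binned_profile")
  list(profile = profile, report = report)
}

#' Assemble combined plant profiles into a plants x bins %TIC matrix
#'
#' Aligns all profiles on the union of occupied bins (absent bins are 0) and
#' stacks them into a matrix with one row per plant individual.
#'
#' @param profiles list of combined `binned_profile` objects, one per plant.
#' @param fraction fraction tag carried on the matrix ("polar"/"nonpolar").
#' @return object of class `profile_matrix`: list with `values` (matrix, rows
#'   = plants, columns = bin labels), `meta` (data.frame plant_id, species),
#'   `fraction`, `binning`.
#' @export
build_matrix <- function(profiles, fraction = NA_character_) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "binned_profile")))
  metas <- lapply(profiles, attr, "meta")
  plant_ids <- vapply(metas, function(m) as.character(m$plant_id), character(1))
  if (anyDuplicated(plant_ids)) {
    stop(sprintf("duplicate plant_id: %s",
                 plant_ids[duplicated(plant_ids)][1]))
  }
  bins <- unique(unlist(lapply(profiles, names)))
  bins <- bins[order(as.numeric(bins))]
  values <- t(vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(bins)), bins)
    v[names(p)] <- as.numeric(p)
    v
  }, numeric(length(bins))))
  rownames(values) <- plant_ids
  meta <- data.frame(
    plant_id = plant_ids,
    species = vapply(metas, function(m) as.character(m$species), character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, meta = meta, fraction = fraction,
                 binning = attr(profiles[[1]], "binning")),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d plants x %d m/z bins (%s fraction)\n",
              nrow(x$values), ncol(x$values),
              ifelse(is.na(x$fraction), "unknown", x$fraction)))
  invisible(x)
}

#' PCA overview of a %TIC profile matrix with outlier flags
#'
#' Column-centred principal component analysis (via [stats::prcomp()]) of the
#' plants x bins matrix. Plants whose score distance on the first two
#' components has a robust z-score (median/MAD) above `z_cut` are flagged as
#' candidate outliers; flags are informational, rows are never removed.
#'
#' @param m a `profile_matrix`.
#' @param n_components number of components to return (default 5).
#' @param z_cut robust z threshold for the outlier flag (default 3.5).
#' @return list with `scores`, `loadings`, `variance_fraction`,
#'   `outlier_flag` (logical per plant), `score_distance`.
#' @export
pca_overview <- function(m, n_components = 5, z_cut = 3.5) {
  stopifnot(inherits(m, "profile_matrix"))
  if (nrow(m$values) < 3L) stop("need at least 3 plants for PCA")
  n_components <- min(n_components, nrow(m$values) - 1L, ncol(m$values))
  fit <- stats::prcomp(m$values, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  d <- sqrt(rowSums(fit$x[, seq_len(min(2L, ncol(fit$x))), drop = FALSE]^2))
  mad_d <- stats::mad(d)
  z <- if (mad_d > 0) (d - stats::median(d)) / mad_d else rep(0, length(d))
  list(scores = scores,
       loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
       variance_fraction = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(n_components)],
       outlier_flag = stats::setNames(z > z_cut, rownames(m$values)),
       score_distance = stats::setNames(d, rownames(m$values)))
}

#' PLS discriminant analysis of a profile matrix by species
#'
#' NIPALS PLS2 regression of the column-centred %TIC matrix on a centred
#' one-hot species indicator matrix, returning latent scores, loadings and
#' per-bin VIP (variable importance in projection). Successive X-scores are
#' orthogonal; VIP is scaled so the mean of squared VIP over bins is 1.
#'
#' @param m a `profile_matrix`.
#' @param groups factor or character vector of group labels, one per plant;
#'   defaults to the species column of the matrix metadata.
#' @param n_components number of latent components (default 2).
#' @param max_iter,tol NIPALS iteration controls.
#' @return list with `scores` (plants x components), `x_loadings`,
#'   `x_weights`, `y_loadings`, `vip` (per bin), `groups`.
#' @export
plsda <- function(m, groups = NULL, n_components = 2, max_iter = 500,
                  tol = 1e-10) {
  stopifnot(inherits(m, "profile_matrix"))
  if (is.null(groups)) groups <- m$meta$species
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 plants")
  X <- scale(m$values, center = TRUE, scale = FALSE)
  Y <- stats::model.matrix(~ groups - 1)
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n_components <- min(n_components, ncol(X), nrow(X) - 1L)
  M <- ncol(X)
  Tm <- matrix(0, nrow(X), n_components)
  W <- matrix(0, M, n_components)
  P <- matrix(0, M, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, nrow(X))
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      w <- w / sqrt(sum(w^2))
      t_vec <- drop(X %*% w)
      q <- drop(crossprod(Y, t_vec)) / sum(t_vec^2)
      u <- drop(Y %*% q) / sum(q^2)
      if (sum((t_vec - t_old)^2) < tol * sum(t_vec^2)) break
      t_old <- t_vec
    }
    p <- drop(crossprod(X, t_vec)) / sum(t_vec^2)
    X <- X - tcrossprod(t_vec, p)
    Y <- Y - tcrossprod(t_vec, q)
    Tm[, a] <- t_vec
    W[, a] <- w
    P[, a] <- p
    Q[, a] <- q
    ssy[a] <- sum(q^2) * sum(t_vec^2)
  }
  vip <- sqrt(M * drop(W^2 %*% ssy) / sum(ssy))
  dimnames(Tm) <- list(rownames(m$values), paste0("comp", seq_len(n_components)))
  rownames(W) <- rownames(P) <- colnames(m$values)
  list(scores = Tm, x_loadings = P, x_weights = W, y_loadings = Q,
       vip = stats::setNames(vip, colnames(m$values)), groups = groups)
}
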