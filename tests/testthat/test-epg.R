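# EPG cleaning (imputation, zero filter, correlation pruning) and the two
# per-recording acceptance summaries.

# table with three species, two races, constructed variables
toy_epg <- function(vars, races = NULL) {
  n <- nrow(vars)
  data.frame(
    recording_id = sprintf("r%02d", seq_len(n)),
    race = if (is.null(races)) rep(c("MS", "TP"), length.out = n) else races,
    clone = "MS1",
    species = rep(c("spA", "spB"), each = n / 2),
    genus = "Medicago",
    vars,
    E2_total_min = seq(10, 300, length.out = n),
    stringsAsFactors = FALSE)
}

test_that("imputation returns tables without missing values unchanged elsewhere", {
  cfg <- small_config(miss_rate = 0.05, seed = 31)
  epg <- generate_epg_table(generate_latents(cfg), cfg)
  expect_true(anyNA(epg))
  imp <- impute_missing(epg, seed = 1)
  vars <- grep("^var_", names(imp), value = TRUE)
  expect_false(anyNA(imp[vars]))
  # observed cells are untouched
  for (v in vars) {
    obs <- !is.na(epg[[v]])
    expect_equal(imp[[v]][obs], epg[[v]][obs])
  }
  # a complete table passes through identically
  cfg0 <- small_config(miss_rate = 0)
  epg0 <- generate_epg_table(generate_latents(cfg0), cfg0)
  expect_identical(impute_missing(epg0), epg0)
  # determinism
  expect_identical(imp, impute_missing(epg, seed = 1))
})

test_that("a missing cell in an otherwise constant column is imputed to that constant", {
  set.seed(2)
  vars <- data.frame(var_a = c(NA, rep(5, 11)),
                     var_b = stats::rnorm(12),
                     var_c = stats::rnorm(12))
  tab <- toy_epg(vars)
  imp <- impute_missing(tab, seed = 1)
  expect_equal(imp$var_a[1], 5)
})

test_that("an entirely missing variable is an error naming it", {
  vars <- data.frame(var_a = rep(NA_real_, 8), var_b = stats::rnorm(8))
  expect_error(impute_missing(toy_epg(vars)), "var_a")
})

test_that("tree-ensemble imputation beats global-mean imputation on masked cells", {
  rmse_rf <- numeric(20)
  rmse_mean <- numeric(20)
  for (sd in 1:20) {
    cfg <- small_config(miss_rate = 0, seed = sd)
    epg <- generate_epg_table(generate_latents(cfg), cfg)
    vars <- grep("^var_", names(epg), value = TRUE)
    set.seed(sd + 500)
    mask <- matrix(stats::runif(nrow(epg) * length(vars)) < 0.05,
                   nrow(epg), length(vars))
    masked <- epg
    truth_vals <- list()
    for (k in seq_along(vars)) {
      masked[[vars[k]]][mask[, k]] <- NA
    }
    imp <- impute_missing(masked, seed = sd)
    err_rf <- c()
    err_mu <- c()
    for (k in seq_along(vars)) {
      idx <- mask[, k]
      if (!any(idx)) next
      err_rf <- c(err_rf, imp[[vars[k]]][idx] - epg[[vars[k]]][idx])
      err_mu <- c(err_mu, mean(masked[[vars[k]]], na.rm = TRUE) -
                    epg[[vars[k]]][idx])
    }
    rmse_rf[sd] <- sqrt(mean(err_rf^2))
    rmse_mean[sd] <- sqrt(mean(err_mu^2))
  }
  expect_lt(mean(rmse_rf), mean(rmse_mean))
  expect_gte(mean(rmse_rf < rmse_mean), 0.75)
})

test_that("zero-inflation filter drops at 50% zeros but not below", {
  vars <- data.frame(var_half = c(rep(0, 5), 1:5),      # exactly 50%
                     var_four = c(rep(0, 4), 1:6),      # 40%
                     var_all0 = rep(0, 10),
                     var_ok = 1:10)
  tab <- toy_epg(vars)
  res <- filter_zero_inflated(tab)
  expect_true(all(c("var_half", "var_all0") %in% res$report$dropped_zero))
  expect_true(all(c("var_four", "var_ok") %in% names(res$table)))
  expect_true("E2_total_min" %in% names(res$table))
})

test_that("correlation pruning drops the later column and keeps r = 0.80 pairs", {
  # u and v are centred, orthogonal, equal-norm integer vectors, so
  # cor(u, 4u + 3v) = 4/5 exactly and cor(u, 9u + v) = 9/sqrt(82) > 0.8
  u <- c(3, -3, 1, -1, 3, -3, 1, -1)
  v <- c(1, -1, -3, 3, 1, -1, -3, 3)
  vars <- data.frame(var_a = u,
                     var_b = 4 * u + 3 * v,      # r = 0.80 with var_a: kept
                     var_c = u + 0.001 * v,      # r ~ 1 with var_a: dropped
                     var_d = v)                  # r = 0 with var_a: kept
  tab <- toy_epg(vars)
  res <- prune_correlated(tab)
  expect_equal(res$report$pruned_pairs$dropped, "var_c")
  expect_equal(res$report$pruned_pairs$kept, "var_a")
  expect_setequal(res$report$remaining, c("var_a", "var_b", "var_d"))
})

test_that("exact duplicate columns lose the later copy only", {
  set.seed(5)
  x <- stats::rnorm(10)
  tab <- toy_epg(data.frame(var_a = x, var_b = x, var_c = stats::rnorm(10)))
  res <- prune_correlated(tab)
  expect_equal(res$report$pruned_pairs$dropped, "var_b")
  expect_true("var_a" %in% names(res$table))
  expect_false("var_b" %in% names(res$table))
})

test_that("a correlation chain is pruned by the greedy column-order pass", {
  # target correlations A~B = 0.85, B~C = 0.85, A~C = 0.5 (positive definite);
  # the pass sees (A,B) first and drops B, then keeps C against A
  R <- matrix(c(1, 0.85, 0.5,
                0.85, 1, 0.85,
                0.5, 0.85, 1), 3, 3)
  set.seed(8)
  E <- qr.Q(qr(cbind(1, matrix(stats::rnorm(20 * 3), 20, 3))))[, 2:4]
  X <- E %*% chol(R)
  expect_equal(stats::cor(X)[1, 2], 0.85, tolerance = 1e-10)
  tab <- toy_epg(data.frame(var_a = X[, 1], var_b = X[, 2], var_c = X[, 3]))
  res <- prune_correlated(tab)
  expect_equal(res$report$pruned_pairs$dropped, "var_b")
  expect_setequal(res$report$remaining, c("var_a", "var_c"))
})

test_that("zero-variance variables are kept with a warning and pruning still runs", {
  set.seed(9)
  x <- stats::rnorm(10)
  tab <- toy_epg(data.frame(var_a = x, var_b = x + stats::rnorm(10, 0, 1e-4),
                            var_const = rep(3, 10)))
  expect_warning(res <- prune_correlated(tab), "zero-variance")
  expect_true("var_const" %in% names(res$table))
  expect_equal(res$report$pruned_pairs$dropped, "var_b")
})

test_that("cleaning is idempotent and leaves no pair above the threshold", {
  cfg <- small_config(miss_rate = 0, seed = 41)
  epg <- generate_epg_table(generate_latents(cfg), cfg)
  first <- prune_correlated(filter_zero_inflated(epg)$table)
  again <- prune_correlated(filter_zero_inflated(first$table)$table)
  expect_identical(again$table, first$table)
  expect_equal(nrow(again$report$pruned_pairs), 0)
  vars <- grep("^var_", names(first$table), value = TRUE)
  cm <- abs(stats::cor(as.matrix(first$table[vars])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.80 + 1e-10)
})

test_that("LD1 separates separable species and rejects degenerate input", {
  set.seed(12)
  n <- 10
  vars <- data.frame(var_a = c(stats::rnorm(n, 0, 0.1), stats::rnorm(n, 10, 0.1)),
                     var_b = c(stats::rnorm(n, 0, 0.1), stats::rnorm(n, -6, 0.1)))
  tab <- data.frame(recording_id = sprintf("r%02d", 1:(2 * n)),
                    race = "MS", clone = "MS1",
                    species = rep(c("spA", "spB"), each = n),
                    genus = "g", vars,
                    E2_total_min = c(stats::runif(n, 10, 50),
                                     stats::runif(n, 200, 300)),
                    stringsAsFactors = FALSE)
  ld <- compute_ld1(tab, "MS")
  sA <- ld$scores$ld1[tab$species == "spA"]
  sB <- ld$scores$ld1[tab$species == "spB"]
  expect_true(max(sA) < min(sB) || min(sA) > max(sB))
  expect_gte(ld$proportion, 0)
  expect_lte(ld$proportion, 1)
  one_species <- tab[tab$species == "spA", ]
  expect_error(compute_ld1(one_species, "MS"), "at least 2 species")
})

test_that("LD1 scores are invariant up to sign under affine variable rescaling", {
  cfg <- small_config(miss_rate = 0, seed = 43)
  epg <- generate_epg_table(generate_latents(cfg), cfg)
  cl <- prune_correlated(filter_zero_inflated(epg)$table)$table
  base <- compute_ld1(cl, "MS")
  rescaled <- cl
  v <- grep("^var_", names(rescaled), value = TRUE)[1]
  rescaled[[v]] <- rescaled[[v]] * 37 - 4
  alt <- compute_ld1(rescaled, "MS")
  agree <- max(abs(alt$scores$ld1 - base$scores$ld1))
  flip <- max(abs(alt$scores$ld1 + base$scores$ld1))
  # the ridge scales with trace(W)/p, so rescaling perturbs the axis at
  # the ridge magnitude; invariance holds to far below the score scale
  expect_lt(min(agree, flip), 1e-3 * stats::sd(base$scores$ld1))
})

test_that("LD1 agrees with an independent discriminant fit up to sign and scale", {
  cfg <- small_config(miss_rate = 0, seed = 44)
  epg <- generate_epg_table(generate_latents(cfg), cfg)
  cl <- prune_correlated(filter_zero_inflated(epg)$table)$table
  ours <- compute_ld1(cl, "MS")
  sub <- cl[cl$race == "MS", ]
  vars <- c(grep("^var_", names(sub), value = TRUE), "E2_total_min")
  fit <- MASS::lda(x = sub[vars], grouping = factor(sub$species))
  ref <- drop(as.matrix(sub[vars]) %*% fit$scaling[, 1])
  expect_gt(abs(stats::cor(ours$scores$ld1, ref)), 0.999)
})

test_that("species-mean LD1 recovers the planted race-mean latent", {
  # strong informative loading, as the recovery claim assumes
  hits <- vapply(1:20, function(sd) {
    cfg <- small_config(miss_rate = 0, frac_informative = 0.5, seed = sd)
    truth <- generate_latents(cfg)
    epg <- generate_epg_table(truth, cfg)
    cl <- prune_correlated(filter_zero_inflated(epg)$table)$table
    ld <- compute_ld1(cl, "MS")
    mu <- tapply(ld$scores$ld1, ld$scores$species, mean)
    abs(stats::cor(as.numeric(mu[truth$species$species]),
                   truth$species$m_MS))
  }, numeric(1))
  expect_gt(stats::median(hits), 0.8)
  expect_gte(mean(hits > 0.8), 0.85)
  expect_gt(min(hits), 0.7)
})

test_that("E2 extraction validates the recording window", {
  cfg <- small_config(seed = 45)
  epg <- generate_epg_table(generate_latents(cfg), cfg)
  e2 <- extract_e2(epg)
  expect_true(all(e2$e2_min > 0 & e2$e2_min < 360))
  bad <- epg
  bad$E2_total_min[1] <- 400
  expect_error(extract_e2(bad), "360")
  noe2 <- epg[setdiff(names(epg), "E2_total_min")]
  expect_error(extract_e2(noe2), "absent")
})
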