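# The uncertainty-propagating random-forest ranking: response draws, forest
# importance, rank aggregation, top-bin selection, regression R2, Spearman
# screen and jack-knife stability.

test_that("response draws follow the stated Normal(mean, SE^2) law", {
  st <- make_score_table(c("A", "B", "C"), mean_MS = c(2, 0, -1),
                         mean_TP = c(1, 0, 1), se_MS = c(0.3, 0, 0.4),
                         se_TP = c(0.4, 0, 0.3))
  # zero SE species draw their mean exactly
  d <- draw_responses(st, "discrimination", seed = 1)
  expect_equal(unname(d["B"]), 0)
  expect_identical(d, draw_responses(st, "discrimination", seed = 1))
  expect_false(identical(d, draw_responses(st, "discrimination", seed = 2)))
  # Monte-Carlo moments for one species
  draws <- vapply(1:10000, function(i) {
    draw_responses(st, "discrimination", seed = i)[["A"]]
  }, numeric(1))
  se_a <- st$se_discrimination[1]
  expect_lt(abs(mean(draws) - st$discrimination[1]), 4 * se_a / 100)
  expect_lt(abs(stats::sd(draws) - se_a) / se_a, 0.05)
})

test_that("missing SEs error with guidance unless pooled", {
  st <- make_score_table(c("A", "B"), mean_MS = c(1, 2), mean_TP = c(0, 0),
                         se_MS = c(NA, 0.3), se_TP = c(0, 0.1))
  expect_error(draw_responses(st, "discrimination"), "pool_se")
  d <- draw_responses(st, "discrimination", seed = 3, pool_se = TRUE)
  expect_equal(length(d), 2)
  expect_true(all(is.finite(d)))
})

test_that("forest importance puts an exact-signal bin first", {
  set.seed(31)
  X <- matrix(stats::rnorm(40 * 15), 40, 15,
              dimnames = list(NULL, sprintf("b%02d", 1:15)))
  y <- X[, 7]
  imp <- forest_importance(X, y, rf_run_config(n_trees = 300, seed = 1))
  expect_true(all(imp >= 0))
  expect_equal(names(which.max(imp)), "b07")
  expect_error(forest_importance(X, rep(1, 40)), "constant response")
  expect_error(forest_importance(X[1:5, ], y[1:5]), "at least 10 rows")
})

test_that("permuting the response destroys the signal bin's rank", {
  set.seed(32)
  X <- matrix(stats::rnorm(40 * 20), 40, 20,
              dimnames = list(NULL, sprintf("b%02d", 1:20)))
  y <- X[, 5] + stats::rnorm(40, 0, 0.3)
  cfg <- rf_run_config(n_trees = 150)
  ranks <- vapply(1:50, function(i) {
    set.seed(i)
    yp <- sample(y)
    imp <- forest_importance(X, yp, cfg)
    rank(-imp)[["b05"]]
  }, numeric(1))
  med <- stats::median(ranks)
  expect_gt(med, 20 / 4)          # nowhere near the top...
  expect_lt(med, 20 * 3 / 4)      # ...nor pinned to the bottom
  # while with the intact response the bin is rank 1
  imp0 <- forest_importance(X, y, cfg)
  expect_equal(unname(rank(-imp0)["b05"]), 1)
})

test_that("rank multisets average to (M+1)/2 and R=1 gives zero IQR", {
  set.seed(33)
  M <- 12
  values <- matrix(stats::rexp(30 * M), 30, M)
  values <- values / rowSums(values) * 100
  m <- make_profile_matrix(values, species = rep(letters[1:10], each = 3))
  st <- make_score_table(letters[1:10], mean_MS = stats::rnorm(10),
                         mean_TP = stats::rnorm(10), se_MS = 0.2, se_TP = 0.2)
  rd <- resampled_ranking(m, st, "discrimination",
                          rf_run_config(n_trees = 50, n_resamples = 7, seed = 4))
  expect_equal(dim(rd$ranks), c(M, 7))
  expect_equal(unname(colMeans(rd$ranks)), rep((M + 1) / 2, 7))
  rd1 <- resampled_ranking(m, st, "discrimination",
                           rf_run_config(n_trees = 50, n_resamples = 1, seed = 4))
  expect_true(all(rd1$iqr == 0))
  # determinism in the master seed
  rd_same <- resampled_ranking(m, st, "discrimination",
                               rf_run_config(n_trees = 50, n_resamples = 7,
                                             seed = 4))
  expect_identical(rd$ranks, rd_same$ranks)
})

test_that("top-bin selection breaks ties by IQR then label", {
  rd <- hostdiscrim:::.new_rank_distribution(
    matrix(c(2, 2, 2,
             2, 3, 1,
             5, 5, 5,
             1, 1, 1), nrow = 4, byrow = TRUE,
           dimnames = list(c("300.0", "100.0", "200.0", "400.0"), NULL)),
    "discrimination", "polar")
  # medians: 300.0 -> 2 (IQR 0), 100.0 -> 2 (IQR 1), 200.0 -> 5, 400.0 -> 1
  top <- select_top_bins(rd, 3)
  expect_equal(top$bin, c("400.0", "300.0", "100.0"))
  all_bins <- select_top_bins(rd, 4)
  expect_equal(nrow(all_bins), 4)
  expect_error(select_top_bins(rd, 9), "exceeds")
})

test_that("tied medians and IQRs fall back to ascending bin label", {
  rd <- hostdiscrim:::.new_rank_distribution(
    matrix(c(1, 1,
             1, 1,
             3, 3), nrow = 3, byrow = TRUE,
           dimnames = list(c("500.0", "120.0", "130.0"), NULL)),
    "discrimination", "polar")
  top <- select_top_bins(rd, 2)
  expect_equal(top$bin, c("120.0", "500.0"))
})

test_that("R2 is exact for a perfectly explanatory bin and monotone in bins", {
  set.seed(34)
  n_sp <- 12
  values <- matrix(stats::rexp(n_sp * 3 * 6), n_sp * 3, 6)
  values <- values / rowSums(values) * 100
  colnames(values) <- sprintf("%.1f", 100 + 0.2 * (1:6))
  species <- rep(sprintf("sp%02d", 1:n_sp), each = 3)
  m <- make_profile_matrix(values, species = species)
  sp_means <- hostdiscrim:::.species_mean_matrix(m, colnames(values))
  resp <- sp_means[, 2]
  st <- make_score_table(rownames(sp_means), mean_MS = resp,
                         mean_TP = rep(0, n_sp), se_MS = 0, se_TP = 0)
  expect_equal(suppressWarnings(top_bins_r2(st, m, colnames(values)[2])),
               1, tolerance = 1e-10)
  r2_one <- top_bins_r2(st, m, colnames(values)[3])
  r2_two <- top_bins_r2(st, m, colnames(values)[3:4])
  expect_gte(r2_two, r2_one - 1e-12)
  # collinear design is rejected
  m2 <- m
  m2$values <- cbind(m$values, "999.8" = 2 * m$values[, 3])
  expect_error(top_bins_r2(st, m2, c(colnames(values)[3], "999.8")),
               "collinear|condition")
})

test_that("null R2 of one random bin across 19 species averages about 1/18", {
  set.seed(35)
  r2 <- vapply(1:300, function(i) {
    values <- matrix(stats::rexp(19 * 2), 19, 2,
                     dimnames = list(NULL, c("100.0", "100.2")))
    values <- values / rowSums(values) * 100
    m <- make_profile_matrix(values, species = sprintf("sp%02d", 1:19))
    st <- make_score_table(sprintf("sp%02d", 1:19),
                           mean_MS = stats::rnorm(19), mean_TP = 0,
                           se_MS = 0, se_TP = 0)
    top_bins_r2(st, m, "100.0")
  }, numeric(1))
  expect_lt(abs(mean(r2) - 1 / 18), 0.02)
})

test_that("the Spearman screen flags a proportional bin and applies BH", {
  set.seed(36)
  n_sp <- 10
  score <- stats::rnorm(n_sp)
  values <- matrix(stats::rexp(n_sp * 4), n_sp, 4,
                   dimnames = list(NULL, sprintf("%.1f", 200 + 0.2 * (1:4))))
  values[, 1] <- exp(score)         # monotone in the score
  m <- make_profile_matrix(values, species = sprintf("sp%02d", 1:n_sp))
  st <- make_score_table(sprintf("sp%02d", 1:n_sp), mean_MS = score,
                         mean_TP = 0, se_MS = 0, se_TP = 0)
  res <- spearman_screen_fdr(st, m, colnames(values))
  expect_equal(res$rho[1], 1)
  expect_equal(which.min(res$q_value), 1L)
  # constant bin reports NA with a warning
  m$values[, 2] <- 1
  expect_warning(res2 <- spearman_screen_fdr(st, m, colnames(values)),
                 "constant")
  expect_true(is.na(res2$rho[2]))
})

test_that("jack-knife ranking is stable, cell-checked and noise-free at zero noise", {
  cfg <- small_config(sigma_aphid = 0, sigma_clone = 0, miss_rate = 0,
                      seed = 37)
  truth <- generate_latents(cfg)
  epg <- generate_epg_table(truth, cfg)
  prof <- e2_profiles(epg)
  spec <- generate_spectra(truth, cfg)
  m <- hostdiscrim:::.matrices_from_spectra(spec, spec$binning)$polar
  rd <- jackknife_ranking(prof, m, "discrimination",
                          rf_run_config(n_trees = 60, seed = 5), n_jack = 6)
  # identical recordings in each cell: every jack-knife dataset is identical
  expect_true(all(rd$iqr == 0))
  # a cell with one recording is rejected by name
  small <- prof[-which(prof$species == prof$species[1] &
                         prof$race == "MS")[-1], ]
  expect_error(jackknife_ranking(small, m, "discrimination", n_jack = 2),
               "fewer than 2")
})

test_that("scaled recovery: planted discriminative bins rank top for discrimination only", {
  cfg <- small_config(seed = 38)
  truth <- generate_latents(cfg)
  epg <- generate_epg_table(truth, cfg)
  spec <- generate_spectra(truth, cfg)
  st <- discrimination_acceptability(summarize_profiles(e2_profiles(epg)))
  m <- hostdiscrim:::.matrices_from_spectra(spec, spec$binning)$polar
  rf <- rf_run_config(n_trees = 150, n_resamples = 20, seed = 39)
  disc_bins <- planted_bins(truth, c("disc_pos", "disc_neg"), "polar")
  rd_d <- resampled_ranking(m, st, "discrimination", rf)
  expect_true(all(rd_d$median_rank[disc_bins] <= 10))
  rd_a <- resampled_ranking(m, st, "acceptability", rf)
  acc_bins <- planted_bins(truth, "acc", "polar")
  # at this desk scale (6 species) the contrast is directional, not sharp:
  # disc bins rank clearly worse for acceptability than for discrimination
  expect_true(all(rd_a$median_rank[disc_bins] >= 10))
  expect_gt(mean(rd_a$median_rank[disc_bins]), 10)
  expect_true(all(rd_a$median_rank[disc_bins] > rd_d$median_rank[disc_bins]))
  expect_true(all(rd_a$median_rank[acc_bins] <= 20))
})

test_that("excluding plants reruns the ranking on the reduced matrix", {
  set.seed(40)
  M <- 8
  values <- matrix(stats::rexp(24 * M), 24, M)
  values <- values / rowSums(values) * 100
  m <- make_profile_matrix(values, species = rep(letters[1:8], each = 3))
  st <- make_score_table(letters[1:8], mean_MS = stats::rnorm(8),
                         mean_TP = stats::rnorm(8), se_MS = 0.1, se_TP = 0.1)
  cfg <- rf_run_config(n_trees = 50, n_resamples = 3, seed = 6)
  full <- resampled_ranking(m, st, "discrimination", cfg)
  reduced <- resampled_ranking(m, st, "discrimination", cfg,
                               exclude_plants = m$meta$plant_id[1:3])
  expect_equal(dim(reduced$ranks), dim(full$ranks))
  expect_false(identical(full$ranks, reduced$ranks))
})
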