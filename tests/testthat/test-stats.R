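test_that("permutation importance recovers a planted signal", {
  set.seed(31)
  n <- 400
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- X$x1
  imp <- ensemble_importance(X, y)
  expect_gt(imp$importance[["x1"]], 10 * max(abs(imp$importance[c("x2", "x3")])))
  expect_gt(imp$oob_r2, 0.5)
  # cross-check the planted ranking with an independent forest engine
  skip_if_not_installed("randomForest")
  rf <- randomForest::randomForest(X, y, mtry = 2, ntree = 200,
                                   nodesize = 5, importance = TRUE)
  ri <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  expect_equal(names(which.max(ri)), "x1")
})

test_that("importance on pure noise gives negligible explained variance", {
  r2 <- vapply(1:8, function(s) {
    X <- local({set.seed(200 + s); data.frame(a = rnorm(150), b = rnorm(150))})
    y <- local({set.seed(300 + s); rnorm(150)})
    ensemble_importance(X, y, seed = s)$oob_r2
  }, numeric(1))
  expect_lt(mean(pmax(r2, 0)), 0.05)
  expect_error(ensemble_importance(data.frame(a = rnorm(10)), rep(1, 10)),
               "constant")
})

test_that("shadow-feature selection confirms signal and rejects noise", {
  set.seed(7)
  n <- 400
  X <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  y <- X$signal + rnorm(n, 0, 0.3)
  sel <- shadow_feature_selection(X, y, seed = 99)
  expect_equal(as.character(sel$decisions[["signal"]]), "confirmed")
  expect_true(all(sel$decisions[c("n1", "n2", "n3")] == "rejected"))
  expect_gt(sel$model_r2, 0.7)
  expect_output(print(sel), "confirmed")
  expect_equal(nrow(summary(sel)), 4)
  # a duplicated confirmed feature is also confirmed
  X2 <- X
  X2$signal_copy <- X$signal + rnorm(n, 0, 0.01)
  sel2 <- shadow_feature_selection(X2, y, seed = 5)
  expect_equal(as.character(sel2$decisions[["signal_copy"]]), "confirmed")
  expect_error(shadow_feature_selection(X, y, max_runs = 4), "max_runs")
  expect_error(shadow_feature_selection(X["signal"], y), "2 features")
})

test_that("shadow hits are chance-level when the response is pure noise", {
  # with 3 features + 3 shadows, exchangeability puts a noise feature above
  # the shadow maximum in about 1/4 of runs
  X <- local({set.seed(401); data.frame(a = rnorm(500), b = rnorm(500),
                                        c = rnorm(500))})
  y <- local({set.seed(501); rnorm(500)})
  sel <- shadow_feature_selection(X, y, seed = 11)
  hit_rate <- sum(sel$hits) / (3 * sel$n_runs)
  expect_gt(hit_rate, 0.05)
  expect_lt(hit_rate, 0.5)
  expect_false(any(sel$decisions == "confirmed"))
})

test_that("collinear model comparison prefers the generating covariate", {
  s <- sim_season(seed = 55, with_tide = TRUE)
  recs <- subsample_on_hour(s$records)
  ann <- attach_covariates(recs, s$env, s$tide)
  ann$rainfall_mm <- local({set.seed(1); runif(nrow(ann), 0, 20)})
  cmp <- compare_collinear_models(
    ann, response = "spl_high_dB",
    base_factors = c("lunar", "tidal", "day_night"),
    variants = c("temperature_C", "day_length_h", "rainfall_mm"),
    max_runs = 15, seed = 3)
  expect_equal(cmp$best, "temperature_C")
  # day length co-varies with season so it beats pure-noise rainfall too
  expect_gt(cmp$r2[["day_length_h"]], cmp$r2[["rainfall_mm"]])
  expect_error(compare_collinear_models(ann, variants = "absent_col"),
               "missing covariate")
})

test_that("DTK pairwise comparisons control sign, count and degeneracy", {
  set.seed(77)
  g <- list(a = rnorm(30), b = rnorm(30, 5), c = rnorm(25, 5.2))
  out <- dtk_pairwise(g)
  expect_equal(nrow(out), 3)  # k(k-1)/2
  ab <- out[out$group1 == "a" & out$group2 == "b", ]
  expect_true(ab$significant)
  expect_lt(ab$upr, 0)
  # identical groups: centred at zero, not significant
  same <- dtk_pairwise(list(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4)))
  expect_equal(same$diff, 0)
  expect_false(same$significant)
  expect_error(dtk_pairwise(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("DTK reduces to classical Tukey-Kramer under equal variances", {
  set.seed(42)
  k <- 3; n <- 40
  # standardize so the groups have exactly equal sample variances: the
  # remaining width difference is only the per-pair degrees of freedom
  vals <- lapply(1:k, function(i) {
    v <- rnorm(n)
    (v - mean(v)) / sd(v) + i * 0.5
  })
  names(vals) <- letters[1:k]
  mine <- dtk_pairwise(vals)
  df <- data.frame(y = unlist(vals),
                   g = factor(rep(names(vals), each = n)))
  tk <- TukeyHSD(aov(y ~ g, data = df))$g
  for (i in seq_len(nrow(mine))) {
    key <- paste(mine$group2[i], mine$group1[i], sep = "-")
    expect_equal(mine$diff[i], -tk[key, "diff"], tolerance = 1e-9)
    w_mine <- mine$upr[i] - mine$lwr[i]
    w_tk <- tk[key, "upr"] - tk[key, "lwr"]
    expect_equal(w_mine / w_tk, 1, tolerance = 0.01)
  }
})

test_that("diversity metrics match closed forms and the vegan oracle", {
  u <- diversity_metrics(c(a = 5, b = 5, c = 5, d = 5), 1)
  expect_equal(u$shannon_per_area, log(4), tolerance = 1e-12)
  expect_equal(diversity_metrics(c(a = 17), 1)$shannon_per_area, 0)
  m <- diversity_metrics(c(a = 3, b = 1), 2)
  h_exact <- -(0.75 * log(0.75) + 0.25 * log(0.25))
  expect_equal(m$shannon_per_area * 2, h_exact, tolerance = 1e-12)
  expect_equal(m$shannon_per_area, 0.2812, tolerance = 1e-3)
  expect_message(z <- diversity_metrics(c(a = 0, b = 0), 10), "all-zero")
  expect_equal(z$richness_per_area, 0)
  expect_error(diversity_metrics(c(a = 1), 0), "positive")
  skip_if_not_installed("vegan")
  set.seed(3)
  for (i in 1:5) {
    cnt <- rpois(6, 8)
    if (sum(cnt) == 0) next
    expect_equal(diversity_metrics(cnt, 1)$shannon_per_area,
                 unname(vegan::diversity(cnt, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("monthly summaries average per-seine per-area metrics", {
  samples <- data.frame(
    station_id = "9M",
    date = as.Date(c("2017-05-01", "2017-05-01", "2017-05-15", "2017-06-02")),
    site_type = "tidal_pool",
    area_m2 = c(10, 10, 5, 20),
    species = c("a", "b", "a", "a"),
    count = c(4, 4, 2, 10))
  out <- monthly_summaries(samples)
  expect_equal(nrow(out), 2)  # two months
  may <- out[out$month == "2017-05", ]
  expect_equal(may$n_seines, 2)
  expect_equal(may$richness_per_area, mean(c(2 / 10, 1 / 5)))
  expect_equal(may$shannon_per_area, mean(c(log(2) / 10, 0)))
  expect_equal(may$abundance_per_area, mean(c(8 / 10, 2 / 5)))
})

test_that("soundscape-biodiversity correlation matches hand computations", {
  expect_equal(cor(c(1, 2, 3), c(6, 4, 5)), -0.5)  # oracle for the fixture
  div <- data.frame(station_id = "S", month = sprintf("2017-%02d", 1:6),
                    richness_per_area = c(1, 2, 3, 4, 5, 6) / 10,
                    shannon_per_area = c(1, 2, 3, 4, 5, 6) / 20,
                    abundance_per_area = c(6, 4, 5, 7, 9, 11))
  spl <- data.frame(station_id = "S", month = sprintf("2017-%02d", 1:6),
                    spl_high_dB = 100 + c(1, 2, 3, 4, 5, 6),
                    spl_low_dB = 90 + c(6, 4, 5, 7, 9, 11),
                    spl_broad_dB = rep(101, 6))
  expect_message(
    rep_ <- correlate_soundscape_biodiversity(div, spl),
    "insufficient")  # broadband column is constant -> skipped
  rich_high <- rep_$correlations[
    rep_$correlations$metric == "richness_per_area" &
      rep_$correlations$band == "high", ]
  expect_equal(rich_high$r, 1, tolerance = 1e-12)
  temp <- data.frame(station_id = "S", month = sprintf("2017-%02d", 1:6),
                     temperature_C = c(10, 12, 15, 19, 24, 28))
  rep2 <- correlate_soundscape_biodiversity(div, spl, temp)
  rich_reg <- rep2$regressions[rep2$regressions$metric == "richness_per_area", ]
  expect_gt(rich_reg$slope, 0)
  expect_gt(rich_reg$r2, 0.9)
})
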