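# Variable-importance modelling of SPL drivers (shadow-feature wrapper over
# a permutation-importance random forest), Dunnett-Tukey-Kramer pairwise
# comparisons, seine diversity metrics, and the soundscape-biodiversity
# correlation/regression tables.

#' Permutation importance from a random-forest ensemble
#'
#' Fits a regression random forest (via \pkg{ranger}) and returns the
#' permutation importance of each feature (mean increase in out-of-bag
#' error when the feature is permuted) and the out-of-bag R^2
#' (1 - OOB MSE / var(y)). The default hyperparameters are the analysis
#' defaults used throughout this package: mtry 2, 200 trees, node size 5,
#' seed 42.
#'
#' @param X data.frame of features (no missing values; factors allowed).
#' @param y numeric response (SPL values).
#' @param mtry,ntree,nodesize forest hyperparameters.
#' @param seed RNG seed passed to the forest.
#' @return list with `importance` (named numeric) and `oob_r2`.
#' @export
ensemble_importance <- function(X, y, mtry = 2, ntree = 200, nodesize = 5,
                                seed = 42) {
  stopifnot(is.data.frame(X), nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in features or response")
  if (stats::sd(y) == 0) stop("constant response")
  dat <- cbind(X, .response = y)
  fit <- ranger::ranger(
    dependent.variable.name = ".response", data = dat,
    mtry = min(mtry, ncol(X)), num.trees = ntree, min.node.size = nodesize,
    importance = "permutation", seed = seed, num.threads = 1
  )
  list(importance = fit$variable.importance, oob_r2 = fit$r.squared)
}

#' Shadow-feature all-relevant selection
#'
#' A wrapper feature-selection algorithm: each run appends a permuted
#' "shadow" copy of every feature to the design, fits the permutation-
#' importance forest, and scores a *hit* for every real feature whose
#' importance exceeds the maximum shadow importance. After each run a
#' two-sided binomial test (null hit probability 0.5) at `p_threshold`
#' confirms features hitting significantly more than half the runs and
#' rejects those hitting significantly fewer. The loop continues until all
#' features are decided or `max_runs` is reached; undecided features are
#' reported as tentative, never silently confirmed.
#'
#' @param X data.frame of features (at least 2).
#' @param y numeric response.
#' @param p_threshold two-sided significance level of the binomial decision
#'   (default 0.01).
#' @param max_runs maximum number of forest runs (default 100; values < 5
#'   cannot reach significance and are an error).
#' @param mtry,ntree,nodesize,seed engine settings, see
#'   [ensemble_importance()]. `mtry` applies to the shadow-augmented design.
#' @return object of class `shadow_select`: `decisions` (named factor:
#'   confirmed/rejected/tentative), `hits`, `n_runs`,
#'   `importance_history` (runs x features matrix, plus a `shadow_max`
#'   column), `model_r2` (OOB R^2 of a final forest on the original
#'   features), `settings`.
#' @export
shadow_feature_selection <- function(X, y, p_threshold = 0.01,
                                     max_runs = 100, mtry = 2, ntree = 200,
                                     nodesize = 5, seed = 42) {
  stopifnot(is.data.frame(X))
  if (ncol(X) < 2) stop("need at least 2 features")
  if (max_runs < 5) stop("max_runs < 5: binomial test cannot reach significance")
  feats <- names(X)
  decisions <- stats::setNames(rep("tentative", length(feats)), feats)
  hits <- stats::setNames(integer(length(feats)), feats)
  hist <- matrix(NA_real_, 0, length(feats) + 1,
                 dimnames = list(NULL, c(feats, "shadow_max")))
  run <- 0L
  while (run < max_runs && any(decisions == "tentative")) {
    run <- run + 1L
    run_seed <- seed + run
    shadow <- local_seed(run_seed, as.data.frame(lapply(X, sample)))
    names(shadow) <- paste0("shadow_", feats)
    imp <- ensemble_importance(cbind(X, shadow), y, mtry = mtry,
                               ntree = ntree, nodesize = nodesize,
                               seed = run_seed)$importance
    smax <- max(imp[paste0("shadow_", feats)])
    hit <- imp[feats] > smax
    hits <- hits + as.integer(hit)
    hist <- rbind(hist, c(imp[feats], shadow_max = smax))
    for (f in feats[decisions == "tentative"]) {
      p_ge <- stats::pbinom(hits[[f]] - 1L, run, 0.5, lower.tail = FALSE)
      p_le <- stats::pbinom(hits[[f]], run, 0.5)
      p2 <- min(1, 2 * min(p_ge, p_le))
      if (p2 < p_threshold) {
        decisions[f] <- if (hits[[f]] > run / 2) "confirmed" else "rejected"
      }
    }
  }
  final <- ensemble_importance(X, y, mtry = mtry, ntree = ntree,
                               nodesize = nodesize, seed = seed)
  structure(list(
    decisions = factor(decisions, levels = c("confirmed", "rejected",
                                             "tentative")),
    hits = hits, n_runs = run, importance_history = hist,
    model_r2 = final$oob_r2, final_importance = final$importance,
    settings = list(p_threshold = p_threshold, mtry = mtry, ntree = ntree,
                    nodesize = nodesize, seed = seed, max_runs = max_runs)
  ), class = "shadow_select")
}

#' @export
print.shadow_select <- function(x, ...) {
  cat("Shadow-feature selection (", x$n_runs, " forest runs)\n", sep = "")
  for (lev in levels(x$decisions)) {
    f <- names(x$decisions)[x$decisions == lev]
    if (length(f)) cat(sprintf("  %-9s: %s\n", lev, paste(f, collapse = ", ")))
  }
  cat(sprintf("  model OOB R^2 = %.3f\n", x$model_r2))
  invisible(x)
}

#' @export
summary.shadow_select <- function(object, ...) {
  data.frame(feature = names(object$decisions),
             decision = as.character(object$decisions),
             hits = as.integer(object$hits),
             n_runs = object$n_runs,
             mean_importance = colMeans(
               object$importance_history[, names(object$decisions),
                                         drop = FALSE]),
             row.names = NULL)
}

#' Compare collinear model variants
#'
#' Temperature, day length and rainfall are mutually collinear seasonal
#' covariates; including them together biases importance. This fits one
#' shadow-selection model per variant (base factors + exactly one of the
#' collinear covariates) and reports the out-of-bag R^2 of each, selecting
#' the variant with the highest R^2 (ties broken by listed order).
#'
#' @param data annotated SPL data.frame.
#' @param response column name of the SPL response (e.g. `"spl_high_dB"`).
#' @param base_factors shared factor columns.
#' @param variants candidate collinear covariate columns, in priority order.
#' @param ... engine settings passed to [shadow_feature_selection()].
#' @return list with `r2` (named per variant), `best` (variant name), and
#'   `fits` (the shadow_select objects).
#' @export
compare_collinear_models <- function(data, response = "spl_high_dB",
                                     base_factors = c("station_id", "year",
                                                      "lunar", "tidal",
                                                      "day_night"),
                                     variants = c("temperature_C",
                                                  "day_length_h",
                                                  "rainfall_mm"), ...) {
  missing_cols <- setdiff(c(response, base_factors, variants), names(data))
  if (length(missing_cols)) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  }
  fits <- lapply(variants, function(v) {
    X <- data[, c(base_factors, v), drop = FALSE]
    X <- as.data.frame(lapply(X, function(col) {
      if (is.character(col)) factor(col) else col
    }))
    keep <- stats::complete.cases(X) & is.finite(data[[response]])
    shadow_feature_selection(X[keep, , drop = FALSE], data[[response]][keep],
                             ...)
  })
  names(fits) <- variants
  r2 <- vapply(fits, function(f) f$model_r2, numeric(1))
  list(r2 = r2, best = variants[which.max(r2)], fits = fits)
}

#' Dunnett-Tukey-Kramer pairwise comparisons
#'
#' All pairwise mean differences with simultaneous confidence intervals
#' adjusted for unequal variances and unequal sample sizes (Dunnett's C /
#' Tukey-Kramer form): for groups i, j the half-width is
#' q * sqrt(s_i^2/n_i + s_j^2/n_j) / sqrt(2), with q the studentized-range
#' quantile at the given confidence for k groups and per-pair
#' Welch-Satterthwaite degrees of freedom. A pair is significant when its
#' interval excludes zero.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param conf confidence level, default 0.95.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `lwr`, `upr`, `significant`.
#' @export
dtk_pairwise <- function(groups, conf = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("every group needs n >= 2")
  k <- length(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / ns[i] + v[j] / ns[j]
    df <- if (se2 == 0) ns[i] + ns[j] - 2 else
      se2^2 / ((v[i] / ns[i])^2 / (ns[i] - 1) + (v[j] / ns[j])^2 / (ns[j] - 1))
    q <- stats::qtukey(conf, nmeans = k, df = df)
    hw <- q * sqrt(se2) / sqrt(2)
    d <- m[i] - m[j]
    data.frame(group1 = names(groups)[i], group2 = names(groups)[j],
               diff = d, lwr = d - hw, upr = d + hw,
               significant = (d - hw) > 0 | (d + hw) < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-area diversity metrics for one seine haul
#'
#' Species richness, Shannon-Wiener diversity H' = -sum p_i ln p_i (nats)
#' and total abundance, each standardized by the seined area. An all-zero
#' haul yields all three metrics 0 (with a message), not an error.
#'
#' @param counts non-negative species counts (named or not).
#' @param area_m2 seined area (> 0).
#' @return list with `richness_per_area`, `shannon_per_area`,
#'   `abundance_per_area`.
#' @examples
#' diversity_metrics(c(a = 5, b = 5, c = 5, d = 5), 1)$shannon_per_area
#' # log(4) = 1.3863
#' @export
diversity_metrics <- function(counts, area_m2) {
  if (area_m2 <= 0) stop("area must be positive")
  counts <- counts[!is.na(counts)]
  total <- sum(counts)
  if (total == 0) {
    message("all-zero counts: diversity metrics are 0")
    return(list(richness_per_area = 0, shannon_per_area = 0,
                abundance_per_area = 0))
  }
  p <- counts[counts > 0] / total
  h <- -sum(p * log(p)) + 0  # + 0 normalises IEEE negative zero
  list(richness_per_area = sum(counts > 0) / area_m2,
       shannon_per_area = h / area_m2,
       abundance_per_area = total / area_m2)
}

#' Monthly per-station diversity summaries
#'
#' Per-seine per-area metrics averaged within station x calendar month
#' (each haul standardized by its own area first, then averaged), the
#' convention the per-seine wording of field methods implies.
#'
#' @param samples long-format SeineSample data.frame (`station_id`, `date`,
#'   `area_m2`, `species`, `count`).
#' @return data.frame: `station_id`, `month` ("YYYY-MM"),
#'   `richness_per_area`, `shannon_per_area`, `abundance_per_area`,
#'   `n_seines`.
#' @export
monthly_summaries <- function(samples) {
  stopifnot(all(c("station_id", "date", "area_m2", "species", "count") %in%
                  names(samples)))
  haul_id <- paste(samples$station_id, samples$date)
  hauls <- lapply(split(samples, haul_id), function(h) {
    met <- suppressMessages(
      diversity_metrics(stats::setNames(h$count, h$species), h$area_m2[1]))
    data.frame(station_id = h$station_id[1],
               month = format(as.Date(h$date[1]), "%Y-%m"),
               richness_per_area = met$richness_per_area,
               shannon_per_area = met$shannon_per_area,
               abundance_per_area = met$abundance_per_area)
  })
  hd <- do.call(rbind, hauls)
  agg <- stats::aggregate(
    hd[, c("richness_per_area", "shannon_per_area", "abundance_per_area")],
    by = list(station_id = hd$station_id, month = hd$month), FUN = mean)
  nsein <- stats::aggregate(list(n_seines = hd$richness_per_area),
                            by = list(station_id = hd$station_id,
                                      month = hd$month), FUN = length)
  out <- merge(agg, nsein, by = c("station_id", "month"))
  out[order(out$station_id, out$month), ]
}

#' Correlate monthly soundscape levels with seine diversity
#'
#' Pearson correlations (two-sided t-test) between monthly averages of each
#' diversity metric and monthly mean SPL per band, paired by station-month
#' across all stations combined; plus ordinary least-squares regressions of
#' each metric on monthly mean temperature. Pairs with fewer than 3 months
#' or zero variance are skipped with a message.
#'
#' @param diversity_monthly output of [monthly_summaries()].
#' @param spl_monthly data.frame: `station_id`, `month`, plus one column per
#'   band of monthly mean SPL (`spl_high_dB`, `spl_low_dB`, `spl_broad_dB`).
#' @param temp_monthly optional data.frame: `station_id`, `month`,
#'   `temperature_C`.
#' @return list with `correlations` (metric, band, r, p, n) and
#'   `regressions` (metric, slope, intercept, r2, p, n; empty without
#'   temperatures).
#' @export
correlate_soundscape_biodiversity <- function(diversity_monthly, spl_monthly,
                                              temp_monthly = NULL) {
  metrics <- c("richness_per_area", "shannon_per_area", "abundance_per_area")
  band_cols <- c(high = "spl_high_dB", low = "spl_low_dB",
                 broadband = "spl_broad_dB")
  d <- merge(diversity_monthly, spl_monthly, by = c("station_id", "month"))
  cors <- list()
  for (met in metrics) {
    for (b in names(band_cols)) {
      if (!band_cols[[b]] %in% names(d)) next
      x <- d[[met]]; y <- d[[band_cols[[b]]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        message(sprintf("skipping %s ~ %s band (insufficient data/variance)",
                        met, b))
        next
      }
      ct <- stats::cor.test(x[ok], y[ok])
      cors[[length(cors) + 1]] <- data.frame(
        metric = met, band = b, r = unname(ct$estimate), p = ct$p.value,
        n = sum(ok))
    }
  }
  regs <- list()
  if (!is.null(temp_monthly)) {
    dt <- merge(diversity_monthly, temp_monthly,
                by = c("station_id", "month"))
    for (met in metrics) {
      x <- dt$temperature_C; y <- dt[[met]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
        message(sprintf("skipping regression for %s", met))
        next
      }
      fit <- stats::lm(y[ok] ~ x[ok])
      sm <- summary(fit)
      regs[[length(regs) + 1]] <- data.frame(
        metric = met, slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        r2 = sm$r.squared, p = sm$coefficients[2, 4], n = sum(ok))
    }
  }
  list(correlations = if (length(cors)) do.call(rbind, cors) else
    data.frame(),
    regressions = if (length(regs)) do.call(rbind, regs) else data.frame())
}
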