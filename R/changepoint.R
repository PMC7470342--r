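#' Bayesian change-point analysis via the Barry-Hartigan product partition model
#'
#' Fits the Barry-Hartigan change-point model to a (daily) series of values
#' with a Gibbs sampler, returning for every position the posterior
#' probability (PP) that an abrupt change in mean occurs there, together with
#' the posterior mean of the underlying signal.
#'
#' The model partitions the series into contiguous blocks of constant mean.
#' Conditional on a partition with \eqn{b} change points, observations are
#' Gaussian around their block mean; block means are themselves Gaussian
#' around a grand mean. The nuisance ratio \eqn{w} of within- to total
#' variance carries a Uniform(0, \code{w0}) prior and the per-position change
#' probability \eqn{p} a Uniform(0, \code{p0}) prior; both are integrated out
#' analytically, leaving a marginal posterior over partitions that depends on
#' the data only through the within-block (W) and between-block (B) sums of
#' squares. Each Gibbs sweep resamples every interior change indicator from
#' its conditional odds (the ratio of marginal likelihoods with and without a
#' block boundary at that position). PP at a position is the fraction of
#' post-burn-in sweeps in which a boundary was present there; the posterior
#' mean is the across-sweep average of conditional block means.
#'
#' Missing values (`NA`) are allowed and are compacted out of the series
#' before sampling: the sampler sees consecutive observed days, and results
#' map back to the original dates. No interpolation is performed, so gaps in
#' acoustic coverage cannot manufacture spurious changes.
#'
#' @param y numeric series (e.g. daily mean SPL in dB). `NA`s are dropped
#'   with their dates; `NaN`/`Inf` are errors. At least 5 observed values and
#'   some variation are required.
#' @param dates optional vector of `Date`s parallel to `y` (defaults to
#'   `1:length(y)` positions).
#' @param p0,w0 upper limits of the uniform priors on the change probability
#'   and the within/total variance ratio. Defaults 0.2 each.
#' @param burnin,mcmc number of discarded and retained Gibbs sweeps.
#' @param seed optional integer; fixes the sampler RNG without disturbing the
#'   caller's RNG state.
#' @return An object of class `bcp_ppm`: a list with `dates`, `values`,
#'   `posterior_mean`, `pp` (PP per position; the first position is 0 since
#'   no change is possible at the first observation), and `settings`.
#' @seealso [first_positive_change()], [day_anomalies()],
#'   [bcp_posterior_exact()] for the brute-force enumeration usable at tiny n.
#' @examples
#' y <- c(rnorm(30, 0), rnorm(30, 5))
#' fit <- bcp_ppm(y, seed = 1)
#' which.max(fit$pp)   # near the step at position 31
#' plot(fit)
#' @export
bcp_ppm <- function(y, dates = NULL, p0 = 0.2, w0 = 0.2,
                    burnin = 50, mcmc = 500, seed = NULL) {
  if (any(is.nan(y)) || any(is.infinite(y))) {
    stop("non-finite (NaN/Inf) values in series; use NA for missing days")
  }
  if (is.null(dates)) dates <- seq_along(y)
  if (length(dates) != length(y)) stop("'dates' and 'y' lengths differ")
  keep <- !is.na(y)
  y_obs <- as.numeric(y[keep])
  d_obs <- dates[keep]
  n <- length(y_obs)
  if (n < 5L) stop("need at least 5 observed values for change-point analysis")
  if (stats::sd(y_obs) == 0) stop("constant series: change-point model is degenerate")
  stopifnot(p0 > 0, p0 <= 1, w0 > 0, w0 <= 1, burnin >= 0, mcmc >= 1)

  res <- local_seed(seed, bcp_gibbs(y_obs, p0, w0, burnin, mcmc))

  structure(list(
    dates = d_obs,
    values = y_obs,
    posterior_mean = res$posterior_mean,
    pp = res$pp,
    settings = list(p0 = p0, w0 = w0, burnin = burnin, mcmc = mcmc,
                    seed = seed, n_dropped = sum(!keep))
  ), class = "bcp_ppm")
}

# ---- marginal-likelihood components -------------------------------------
#
# Partition with b change points (b+1 blocks), W/B within/between sums of
# squares, n observations:
#   m(rho) = [ int_0^p0 p^b (1-p)^(n-1-b) dp ] *
#            [ int_0^w0 w^(b/2) (W + B w)^(-(n-1)/2) dw ]
# The p-integral is an incomplete beta; the w-integral reduces to one via
# t = Bw/(W+Bw) unless the second shape parameter is non-positive, where we
# fall back on quadrature.

log_p_integral <- function(b, n, p0) {
  stats::pbeta(p0, b + 1, n - b, log.p = TRUE) + lbeta(b + 1, n - b)
}

log_w_integral <- function(b, n, W, B, w0) {
  k <- b / 2
  m <- (n - 1) / 2
  if (B <= .Machine$double.eps * max(W, 1)) {
    # all block means equal (or single block): integrand w^k * W^-m
    return(-m * log(W) + (k + 1) * log(w0) - log(k + 1))
  }
  if (W <= 0) {
    # perfect within-block fit; only proper when every block is a singleton
    if (k - m > -1) {
      return(-m * log(B) + (k - m + 1) * log(w0) - log(k - m + 1))
    }
    stop("degenerate partition: zero within-block variance")
  }
  t0 <- B * w0 / (W + B * w0)
  s2 <- m - k - 1
  if (s2 > 0) {
    (k - m + 1) * log(W) - (k + 1) * log(B) +
      lbeta(k + 1, s2) + stats::pbeta(t0, k + 1, s2, log.p = TRUE)
  } else {
    f <- function(w) exp(k * log(w) - m * log(W + B * w))
    val <- stats::integrate(f, 0, w0, rel.tol = 1e-10)$value
    log(val)
  }
}

# Q = sum over blocks of S_j^2 / n_j for a vector of block start positions
block_q <- function(cs, starts, n) {
  ends <- c(starts[-1] - 1L, n)
  s <- cs[ends + 1L] - cs[starts]
  sum(s^2 / (ends - starts + 1L))
}

# Full log marginal posterior (up to a constant) of a partition given by the
# change-indicator vector u (length n, u[1] ignored). Used by the
# enumeration oracle and kept deliberately simple.
log_marginal_partition <- function(y, u, p0, w0) {
  n <- length(y)
  starts <- c(1L, which(u[-1] == 1L) + 1L)
  cs <- c(0, cumsum(y))
  q <- block_q(cs, starts, n)
  Bss <- q - sum(y)^2 / n
  Bss <- max(Bss, 0)
  Tss <- sum((y - mean(y))^2)
  Wss <- max(Tss - Bss, 0)
  b <- length(starts) - 1L
  log_p_integral(b, n, p0) + log_w_integral(b, n, Wss, Bss, w0)
}

#' Exact change-point posterior by partition enumeration
#'
#' Computes the posterior probability of a change at every position by
#' enumerating all \eqn{2^{n-1}} partitions of the series and weighting each
#' by its marginal posterior under the product partition model. Feasible only
#' for very short series (n <= 20 or so); its purpose is to provide ground
#' truth against which the Gibbs sampler in [bcp_ppm()] can be validated.
#'
#' @inheritParams bcp_ppm
#' @return numeric vector of exact change probabilities (first entry 0).
#' @export
bcp_posterior_exact <- function(y, p0 = 0.2, w0 = 0.2) {
  n <- length(y)
  if (n < 2L || n > 20L) stop("enumeration supported for 2 <= n <= 20")
  if (any(!is.finite(y))) stop("non-finite values")
  m <- n - 1L
  logw <- numeric(2^m)
  ind <- matrix(0L, 2^m, n)
  for (code in 0:(2^m - 1L)) {
    u <- c(0L, as.integer(intToBits(code))[seq_len(m)])
    ind[code + 1L, ] <- u
    logw[code + 1L] <- log_marginal_partition(y, u, p0, w0)
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  as.numeric(colSums(ind * w))
}

# ---- Gibbs sampler -------------------------------------------------------

bcp_gibbs <- function(y, p0, w0, burnin, mcmc) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  tot <- sum(y)
  Tss <- sum((y - mean(y))^2)
  lp <- vapply(0:(n - 1L), log_p_integral, numeric(1), n = n, p0 = p0)

  u <- integer(n)            # u[i] = 1: block boundary before position i
  is_start <- c(TRUE, rep(FALSE, n - 1L))
  b_cur <- 0L
  q_cur <- tot^2 / n

  pp_count <- numeric(n)
  mu_sum <- numeric(n)
  total <- burnin + mcmc

  for (sweep in seq_len(total)) {
    for (i in 2:n) {
      # block neighbourhood of position i under "no boundary at i"
      prev <- i - 1L
      while (!is_start[prev]) prev <- prev - 1L
      nxt <- if (i < n) i + which(is_start[(i + 1L):n])[1L] else NA_integer_
      if (is.na(nxt)) nxt <- n + 1L
      s_all <- cs[nxt] - cs[prev]
      n_all <- nxt - prev
      s_l <- cs[i] - cs[prev]; n_l <- i - prev
      s_r <- s_all - s_l;      n_r <- n_all - n_l
      q_merged <- s_all^2 / n_all
      q_split <- s_l^2 / n_l + s_r^2 / n_r
      q_base <- q_cur - if (u[i] == 1L) q_split else q_merged

      b0 <- b_cur - u[i]
      grand <- tot^2 / n
      B0 <- max(q_base + q_merged - grand, 0)
      B1 <- max(q_base + q_split - grand, 0)
      W0 <- max(Tss - B0, 0)
      W1 <- max(Tss - B1, 0)

      log_odds <- (lp[b0 + 2L] - lp[b0 + 1L]) +
        (log_w_integral(b0 + 1L, n, W1, B1, w0) -
           log_w_integral(b0, n, W0, B0, w0))
      p1 <- 1 / (1 + exp(-log_odds))
      new_u <- as.integer(stats::runif(1) < p1)
      if (new_u != u[i]) {
        u[i] <- new_u
        is_start[i] <- new_u == 1L
        b_cur <- b0 + new_u
        q_cur <- q_base + if (new_u == 1L) q_split else q_merged
      }
    }
    if (sweep > burnin) {
      pp_count <- pp_count + u
      starts <- which(is_start)
      ends <- c(starts[-1] - 1L, n)
      means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
      mu_sum <- mu_sum + rep(means, ends - starts + 1L)
    }
  }
  list(pp = pp_count / mcmc, posterior_mean = mu_sum / mcmc)
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.bcp_ppm <- function(x, ...) {
  cat("Bayesian change-point fit (product partition model)\n")
  cat(sprintf("  n = %d observed positions (%d dropped as missing)\n",
              length(x$values), x$settings$n_dropped))
  cat(sprintf("  priors: p0 = %g, w0 = %g; sweeps: %d burn-in + %d retained\n",
              x$settings$p0, x$settings$w0, x$settings$burnin, x$settings$mcmc))
  k <- sum(x$pp >= 0.5)
  cat(sprintf("  positions with PP >= 0.5: %d (max PP = %.3f)\n",
              k, max(x$pp)))
  invisible(x)
}

#' @export
summary.bcp_ppm <- function(object, threshold = 0.5, ...) {
  hits <- which(object$pp >= threshold)
  out <- data.frame(
    position = hits,
    date = object$dates[hits],
    pp = object$pp[hits],
    posterior_mean = object$posterior_mean[hits]
  )
  structure(list(changes = out, threshold = threshold,
                 settings = object$settings),
            class = "summary.bcp_ppm")
}

#' @export
print.summary.bcp_ppm <- function(x, ...) {
  cat(sprintf("Positions with posterior change probability >= %g:\n",
              x$threshold))
  if (nrow(x$changes) == 0) cat("  (none)\n") else print(x$changes, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.bcp_ppm <- function(object, ...) object$posterior_mean

#' @export
residuals.bcp_ppm <- function(object, ...) object$values - object$posterior_mean

#' @export
as.data.frame.bcp_ppm <- function(x, ...) {
  data.frame(date = x$dates, value = x$values,
             posterior_mean = x$posterior_mean, pp = x$pp)
}

#' Plot a change-point fit
#'
#' Two stacked panels: the series with its posterior mean, and the posterior
#' probability of change per position with the 0.5 significance line.
#'
#' @param x a [bcp_ppm()] fit.
#' @param ... passed to the upper panel's `plot`.
#' @export
plot.bcp_ppm <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$dates, x$values, type = "p", pch = 16, cex = 0.5,
       xlab = "", ylab = "value (dB)", ...)
  graphics::lines(x$dates, x$posterior_mean, col = "steelblue", lwd = 2)
  plot(x$dates, x$pp, type = "h", ylim = c(0, 1), xlab = "",
       ylab = "PP of change")
  graphics::abline(h = 0.5, lty = 2, col = "grey40")
  invisible(x)
}

# ---- phenology rules -----------------------------------------------------

#' First positive change within the spring window
#'
#' Applies the onset rule: scanning dates inside the spring window in order,
#' return the first whose posterior probability of change meets the
#' threshold *and* whose posterior mean is higher immediately after the
#' change than immediately before (an increase in acoustic activity, not a
#' decrease). A tie at exactly the threshold counts as significant.
#'
#' @param cpr a [bcp_ppm()] fit whose `dates` are `Date`s.
#' @param window a [spring_window()] (list with `start_date`, `end_date`) or
#'   any list/data.frame with those fields.
#' @param threshold minimum posterior probability, default 0.5.
#' @return A one-row data.frame with `date`, `day_of_year`, `pp_value`, or
#'   `NULL` when no qualifying change exists (e.g. the window has no data).
#' @export
first_positive_change <- function(cpr, window, threshold = 0.5) {
  stopifnot(inherits(cpr, "bcp_ppm"))
  d <- as.Date(cpr$dates)
  in_win <- which(d >= as.Date(window$start_date) & d <= as.Date(window$end_date))
  if (length(in_win) == 0) {
    message("no dates intersect the spring window; no onset reported")
    return(NULL)
  }
  for (i in in_win) {
    if (i == 1L) next  # no change possible at the first observation
    if (cpr$pp[i] >= threshold &&
        cpr$posterior_mean[i] > cpr$posterior_mean[i - 1L]) {
      return(data.frame(date = d[i], day_of_year = day_of_year(d[i]),
                        pp_value = cpr$pp[i]))
    }
  }
  NULL
}

#' Day-of-year anomalies of onset events across years
#'
#' For one station/band series of yearly onset events, computes the
#' leap-aware day of year of each onset and its anomaly: day of year minus
#' the multi-year mean day of year. Negative anomalies mean earlier than
#' average.
#'
#' @param events data.frame with columns `year` and `date` (one row per
#'   year); other columns are carried through.
#' @return The input with `day_of_year`, `anomaly_days` (signed, fractional)
#'   and `anomaly_label` ("8 days earlier" style, rounded magnitude) added;
#'   attribute `mean_doy` holds the multi-year mean day of year.
#' @examples
#' ev <- data.frame(year = 2013:2018,
#'                  date = as.Date(c("2013-04-09", "2014-04-03", "2015-04-01",
#'                                   "2016-03-25", "2017-03-23", "2018-03-29")))
#' day_anomalies(ev)   # 2017: 8 days earlier; 2013: 9 days later
#' @export
day_anomalies <- function(events) {
  stopifnot(is.data.frame(events), all(c("year", "date") %in% names(events)))
  if (anyDuplicated(events$year)) stop("duplicate year in events")
  if (nrow(events) < 2L) stop("need at least 2 years to define an anomaly")
  doy <- day_of_year(events$date)
  m <- mean(doy)
  events$day_of_year <- doy
  events$anomaly_days <- doy - m
  mag <- round(abs(events$anomaly_days))
  dir <- ifelse(events$anomaly_days < 0, "earlier", "later")
  events$anomaly_label <- ifelse(mag == 0, "on average",
                                 sprintf("%d day%s %s", mag,
                                         ifelse(mag == 1, "", "s"), dir))
  attr(events, "mean_doy") <- m
  events
}

#' Relationship between mean spring temperature and onset timing
#'
#' Pearson correlation and least-squares regression of onset day of year on
#' mean spring water temperature across station-years. Warmer springs with
#' earlier onsets yield a negative correlation.
#'
#' @param doy onset day of year per station-year.
#' @param temp mean spring water temperature (deg C) per station-year.
#' @return list with `pearson_r`, `p_value`, `slope`, `intercept`, `n`.
#' @export
onset_temperature_relation <- function(doy, temp) {
  ok <- is.finite(doy) & is.finite(temp)
  doy <- doy[ok]; temp <- temp[ok]
  if (length(doy) < 3L) stop("need at least 3 (year, station) pairs")
  if (stats::sd(temp) == 0) stop("zero temperature variance")
  if (stats::sd(doy) == 0) stop("onset constant across years: correlation undefined")
  ct <- stats::cor.test(temp, doy)
  fit <- stats::lm(doy ~ temp)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(doy))
}
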