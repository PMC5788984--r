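#' Mismatch distribution of a sample
#'
#' Histogram of pairwise difference counts over all unordered sequence pairs,
#' with a simple modality diagnostic: the number of local maxima of the
#' relative-frequency vector after unit smoothing (moving average of window
#' 3 with zero boundaries).
#'
#' @param x A difference matrix restricted to the group, or an
#'   [mt_alignment()] (differences computed under `policy`).
#' @param policy Missing-data policy when `x` is an alignment.
#' @return Object of class `mismatch_hist`: list with `counts` (named vector
#'   over difference classes `0:max`), `n`, `n_pairs`, `modality`.
#' @export
mismatch_histogram <- function(x, policy = "complete_deletion") {
  d <- if (is.matrix(x) && !inherits(x, "mt_alignment")) x else pairwise_diff_matrix(x, policy)
  n <- nrow(d)
  if (n < 2) abort("Mismatch distribution needs at least 2 sequences.")
  v <- d[upper.tri(d)]
  counts <- tabulate(v + 1, nbins = max(v) + 1)
  names(counts) <- 0:max(v)
  structure(
    list(counts = counts, n = n, n_pairs = length(v),
         modality = count_modes(counts / length(v))),
    class = "mismatch_hist"
  )
}

# Modality diagnostic: local maxima of the relative-frequency vector with a
# minimum prominence of delta (1% of pairs by default), so sampling jitter
# does not register as extra modes while adjacent true modes (e.g. two
# haplotype clusters two steps apart) still do.
count_modes <- function(x, delta = 0.01) {
  if (sum(x) <= 0) return(0L)
  x <- x / sum(x)
  z <- c(0, x, 0)
  n <- length(z)
  peaks <- which(z[2:(n - 1)] > z[1:(n - 2)] & z[2:(n - 1)] >= z[3:n])
  if (!length(peaks)) return(0L)
  ord <- peaks[order(-x[peaks])]
  kept <- ord[1]
  for (p in ord[-1]) {
    higher <- kept[x[kept] >= x[p]]
    valley <- max(vapply(higher, function(k) min(x[min(p, k):max(p, k)]),
                         numeric(1)))
    if (x[p] - valley >= delta) kept <- c(kept, p)
  }
  length(kept)
}

#' @export
print.mismatch_hist <- function(x, ...) {
  cat(sprintf("<mismatch_hist> n=%d, %d pairs, max diff %s, %d mode(s)\n",
              x$n, x$n_pairs, names(x$counts)[length(x$counts)], x$modality))
  invisible(x)
}

#' @export
tidy.mismatch_hist <- function(x, ...) {
  tibble(differences = as.integer(names(x$counts)),
         count = as.integer(x$counts),
         freq = x$counts / x$n_pairs)
}

#' Expected mismatch distribution under sudden expansion
#'
#' Expected relative frequencies of pairwise difference counts under the
#' sudden-expansion model: a population at scaled size theta0 that changed to
#' theta1 at time tau (in mutational time units, tau = 2ut) before present.
#' Computed from the exact piecewise-exponential density of the pair
#' coalescence time: with `Feq(i, th) = th^i/(1+th)^(i+1)` and
#' `lambda = (theta1+1)/theta1`,
#' `F_i = Feq(i, theta1) * P(Gamma(i+1, lambda) <= tau) +
#'        exp(-lambda*tau) * sum_j tau^j/j! * Feq(i-j, theta0)`.
#' The equal-size limit reduces to the geometric equilibrium and tau = 0
#' reduces to equilibrium at theta0.
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled population sizes (>= 0).
#' @param i_max Largest difference class to report.
#' @param renormalize If TRUE, rescale the truncated vector to sum to 1.
#' @return Numeric vector of length `i_max + 1` (classes 0..i_max) with
#'   attributes `mass` (untruncated probability captured) and `renormalized`.
#' @export
expected_mismatch <- function(tau, theta0, theta1, i_max, renormalize = FALSE) {
  stopifnot(i_max >= 0)
  if (!all(is.finite(c(tau, theta0, theta1))) || any(c(tau, theta0, theta1) < 0)) {
    abort("Parameters must be finite and non-negative.")
  }
  i <- 0:i_max
  feq <- function(th) {
    if (th == 0) as.numeric(i == 0) else exp(i * log(th) - (i + 1) * log1p(th))
  }
  if (theta1 == 0 && tau > 0) {
    f <- as.numeric(i == 0)  # immediate coalescence in the present population
  } else if (tau == 0) {
    f <- feq(theta0)
  } else {
    lam <- (theta1 + 1) / theta1
    f1 <- feq(theta1) * stats::pgamma(tau, shape = i + 1, rate = lam)
    cj <- exp(i * log(tau) - lgamma(i + 1))  # tau^j / j!
    f0 <- feq(theta0)
    conv <- vapply(i, function(k) sum(cj[1:(k + 1)] * f0[(k + 1):1]), numeric(1))
    f <- f1 + exp(-lam * tau) * conv
  }
  mass <- sum(f)
  if (renormalize && mass > 0) f <- f / mass
  structure(f, mass = mass, renormalized = renormalize)
}

#' Raggedness index of a mismatch distribution
#'
#' Sum of squared differences between successive relative frequencies,
#' including the zero boundary classes on both sides; low for the smooth,
#' unimodal distributions expected under demographic expansion.
#'
#' @param x A `mismatch_hist`, or a numeric vector of relative frequencies
#'   over classes `0:d`.
#' @return Non-negative numeric.
#' @export
raggedness <- function(x) {
  if (inherits(x, "mismatch_hist")) x <- x$counts / x$n_pairs
  sum(diff(c(0, x, 0))^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the expected mismatch curve to the observed relative
#' frequencies: minimizes the sum of squared deviations (SSD) over
#' `(tau, theta0, theta1)` with a multistart grid followed by local
#' refinement (L-BFGS-B on `(tau, theta0/theta1, theta1)`), under the bounds
#' tau in `[0, 2*i_max]`, `0 <= theta0 <= theta1 <= 1e4`.
#'
#' @param h A `mismatch_hist` (or raw counts vector over classes `0:d`).
#' @param i_max Largest class used in the fit; defaults to the observed
#'   maximum difference class.
#' @return Object of class `expansion_fit`: tau, theta0, theta1, ssd, the
#'   observed relative frequencies, and a `degenerate` flag (all mass at 0).
#' @export
fit_sudden_expansion <- function(h, i_max = NULL) {
  counts <- if (inherits(h, "mismatch_hist")) h$counts else h
  n <- if (inherits(h, "mismatch_hist")) h$n else NA_integer_
  obs <- counts / sum(counts)
  if (is.null(i_max)) i_max <- length(obs) - 1
  if (length(obs) < i_max + 1) obs <- c(obs, rep(0, i_max + 1 - length(obs)))
  obs <- obs[1:(i_max + 1)]

  if (sum(counts[-1]) == 0) {
    return(structure(
      list(tau = 0, theta0 = 0, theta1 = 0, ssd = 0, obs = obs, i_max = i_max,
           n = n, degenerate = TRUE),
      class = "expansion_fit"
    ))
  }

  ssd_of <- function(par) {  # par = (tau, ratio, theta1)
    f <- expected_mismatch(par[1], par[2] * par[3], par[3], i_max)
    sum((obs - f)^2)
  }
  mean_obs <- sum((0:i_max) * obs)
  taus <- unique(pmin(c(0.25, 0.5, 1, 2, 4, 8, 16, mean_obs, mean_obs / 2), 2 * i_max))
  th1s <- c(0.5, 2, 10, 50, 200, 1000)
  ratios <- c(0.001, 0.05, 0.5, 1)
  grid <- expand.grid(tau = taus, r = ratios, th1 = th1s)
  vals <- apply(grid, 1, ssd_of)
  starts <- grid[order(vals)[1:6], , drop = FALSE]
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(
        as.numeric(starts[k, ]), ssd_of, method = "L-BFGS-B",
        lower = c(0, 0, 1e-6), upper = c(2 * i_max, 1, 1e4),
        control = list(maxit = 500, factr = 1e4)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  par <- best$par
  structure(
    list(tau = par[1], theta0 = par[2] * par[3], theta1 = par[3],
         ssd = best$value, obs = obs, i_max = i_max, n = n, degenerate = FALSE),
    class = "expansion_fit"
  )
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("<expansion_fit> tau=%.3f theta0=%.4f theta1=%.2f ssd=%.3g%s\n",
              x$tau, x$theta0, x$theta1, x$ssd,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' @export
tidy.expansion_fit <- function(x, ...) {
  tibble(term = c("tau", "theta0", "theta1"),
         estimate = c(x$tau, x$theta0, x$theta1))
}

#' @export
glance.expansion_fit <- function(x, ...) {
  tibble(ssd = x$ssd, i_max = x$i_max, n = x$n, degenerate = x$degenerate)
}

#' Parametric-bootstrap goodness of fit of the expansion model
#'
#' Simulates `n_boot` coalescent samples of the same size under the fitted
#' sudden-expansion demography, refits the model to each and compares the
#' replicate SSD and raggedness with the observed values:
#' `p = Pr(statistic_rep >= statistic_obs)`. Non-significant values mean the
#' data do not deviate from the expansion expectation.
#'
#' @param a Group alignment (supplies n and L for the replicates).
#' @param fit An [fit_sudden_expansion()] result for this group.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Master seed.
#' @return Tibble with ssd, p_ssd, rg, p_rg, n_boot.
#' @export
expansion_gof <- function(a, fit, n_boot = 100, seed = NULL) {
  if (n_boot < 10) warn("n_boot < 10 gives very coarse p-values.")
  n <- nrow(a)
  L <- ncol(a)
  h_obs <- mismatch_histogram(a)
  rg_obs <- raggedness(h_obs)
  ssd_obs <- fit$ssd
  seeds <- spawn_seeds(seed, n_boot)
  stats <- purrr::map_dfr(seq_len(n_boot), function(b) {
    sim <- sim_sudden_expansion(fit$theta0, fit$theta1, fit$tau, n, L, seed = seeds[b])
    hb <- mismatch_histogram(sim$alignment)
    fb <- fit_sudden_expansion(hb)
    tibble(ssd = fb$ssd, rg = raggedness(hb))
  })
  tibble(
    ssd = ssd_obs,
    p_ssd = mean(stats$ssd >= ssd_obs),
    rg = rg_obs,
    p_rg = mean(stats$rg >= rg_obs),
    n_boot = n_boot
  )
}

#' Plot an observed mismatch distribution with its fitted expectation
#'
#' @param h A `mismatch_hist`.
#' @param fit Optional [fit_sudden_expansion()] result; its expected curve is
#'   overlaid when supplied.
#' @return A ggplot object.
#' @export
plot_mismatch <- function(h, fit = NULL) {
  df <- tidy.mismatch_hist(h)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$differences, .data$freq)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = "pairwise differences", y = "relative frequency") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    ef <- expected_mismatch(fit$tau, fit$theta0, fit$theta1, max(df$differences))
    p <- p + ggplot2::geom_line(
      data = tibble(differences = 0:max(df$differences), freq = as.numeric(ef)),
      colour = "darkgreen", linetype = 2
    )
  }
  p
}
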