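#' Prior specification for ABC
#'
#' Uniform priors on haploid effective sizes, event times (generations) and
#' the per-site mutation rate. The mutation-rate prior may optionally be
#' log-uniform.
#'
#' @param ne Bounds for every Ne (default 10..10000).
#' @param t Bounds for t1/t2 in generations (default 10..10000).
#' @param mu Bounds for the per-site per-generation mutation rate
#'   (default 1e-8..1e-6).
#' @param mu_log Draw mu log-uniformly instead of uniformly.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(ne = c(10, 10000), t = c(10, 10000),
                       mu = c(1e-8, 1e-6), mu_log = FALSE) {
  for (b in list(ne, t, mu)) {
    if (length(b) != 2 || b[1] >= b[2]) abort("Each prior needs lower < upper.")
  }
  structure(list(ne = ne, t = t, mu = mu, mu_log = mu_log), class = "prior_spec")
}

#' Draw scenario parameters from the priors
#'
#' Independent uniform draws within bounds; for the gradual scenarios the
#' pair (t1, t2) is drawn jointly conditional on t1 < t2 by rejection. Each
#' of the three sampled populations and the ancestral population receives an
#' independent Ne draw.
#'
#' @param spec A [prior_spec()].
#' @param kind Scenario kind (see [scenario()]).
#' @param n Number of draws.
#' @param seed Seed.
#' @return Tibble with columns Ne1, Ne2, Ne3, Ne_anc, t1, t2 (NA for the
#'   trifurcation) and mu.
#' @export
sample_priors <- function(spec, kind, n = 1, seed = NULL) {
  with_seed_(seed, {
    runif2 <- function(b, m = n) stats::runif(m, b[1], b[2])
    mu <- if (spec$mu_log) {
      exp(stats::runif(n, log(spec$mu[1]), log(spec$mu[2])))
    } else {
      runif2(spec$mu)
    }
    if (kind == "sudden_trifurcation") {
      t1 <- runif2(spec$t)
      t2 <- rep(NA_real_, n)
    } else {
      t1 <- numeric(n); t2 <- numeric(n)
      need <- seq_len(n)
      while (length(need)) {  # joint rejection until t1 < t2
        a <- runif2(spec$t, length(need))
        b <- runif2(spec$t, length(need))
        ok <- a < b
        t1[need[ok]] <- a[ok]
        t2[need[ok]] <- b[ok]
        need <- need[!ok]
      }
    }
    tibble(
      Ne1 = runif2(spec$ne), Ne2 = runif2(spec$ne), Ne3 = runif2(spec$ne),
      Ne_anc = runif2(spec$ne), t1 = t1, t2 = t2, mu = mu
    )
  })
}

# Summary statistics from an integer variant-state matrix (rows = samples,
# columns = variant sites, values 1..4) and a group factor. Monomorphic
# columns contribute nothing, so working on variant sites only is exact.
summary_stats_variants <- function(states, grp, group_order) {
  grp <- as.character(grp)
  ns <- ncol(states)
  G <- length(group_order)
  n_g <- vapply(group_order, function(g) sum(grp == g), numeric(1))
  # per-site per-group base counts: list of G matrices (ns x 4)
  cnt <- lapply(group_order, function(g) {
    sub <- states[grp == g, , drop = FALSE]
    if (ns == 0) return(matrix(0, 0, 4))
    t(apply(sub, 2, tabulate, nbins = 4))
  })
  names(cnt) <- group_order
  within_pairs <- function(g) {  # per-site count of differing within-group pairs
    cm <- cnt[[g]]
    if (ns == 0) return(numeric(0))
    choose(n_g[[g]], 2) - rowSums(choose(cm, 2))
  }
  seg_in <- function(g) {
    cm <- cnt[[g]]
    if (ns == 0) return(logical(0))
    rowSums(cm > 0) > 1
  }
  out <- list()
  wd <- lapply(group_order, within_pairs)
  sg <- lapply(group_order, seg_in)
  names(wd) <- names(sg) <- group_order
  for (g in group_order) {
    sub <- states[grp == g, , drop = FALSE]
    nh <- if (ns == 0) 1 else length(unique(apply(sub, 1, paste, collapse = ",")))
    others <- setdiff(group_order, g)
    priv <- if (ns == 0) 0 else sum(sg[[g]] & !Reduce(`|`, sg[others], rep(FALSE, ns)))
    out[[paste0("nhap_", g)]] <- nh
    out[[paste0("S_", g)]] <- sum(sg[[g]])
    out[[paste0("kbar_", g)]] <- sum(wd[[g]]) / choose(n_g[[g]], 2)
    out[[paste0("priv_", g)]] <- priv
  }
  if (G >= 2) {
    for (i in seq_len(G - 1)) for (j in (i + 1):G) {
      g1 <- group_order[i]; g2 <- group_order[j]
      n1 <- n_g[[g1]]; n2 <- n_g[[g2]]
      between <- if (ns == 0) 0 else {
        sum(n1 * n2 - rowSums(cnt[[g1]] * cnt[[g2]])) / (n1 * n2)
      }
      within <- (sum(wd[[g1]]) + sum(wd[[g2]])) / (choose(n1, 2) + choose(n2, 2))
      fst <- if (between == 0) 0 else min(max(1 - within / between, 0), 1)
      out[[paste0("W_", g1, "_", g2)]] <- within
      out[[paste0("B_", g1, "_", g2)]] <- between
      out[[paste0("FST_", g1, "_", g2)]] <- fst
    }
  }
  as_tibble(out)
}

#' Summary statistics for ABC
#'
#' The seven statistics used for scenario comparison, computed per group and
#' per group pair: number of haplotypes, number of segregating sites, mean
#' pairwise differences and private segregating sites for each group; mean
#' within-pair pairwise differences (W), mean between-population pairwise
#' differences (B) and `FST = 1 - W/B` (clipped to `[0, 1]`, 0 by convention
#' when B = 0) for each pair. A private segregating site of a group is a
#' usable column segregating within that group and monomorphic within every
#' other group. Column order is fixed: group statistics in group order, then
#' pairs (1,2), (1,3), (2,3).
#'
#' @param a An [mt_alignment()] (complete-deletion mask applied), or the
#'   `variants` matrix returned by [simulate_scenario()].
#' @param s Sample table aligned with `a` (ignored for a variants matrix).
#' @param partition Grouping column of `s`.
#' @param group_order Optional explicit group order; defaults to order of
#'   appearance.
#' @return One-row tibble of named statistics.
#' @export
summary_statistics <- function(a, s = NULL, partition = "group", group_order = NULL) {
  if (inherits(a, "mt_alignment")) {
    if (is.null(s)) abort("A sample table is required for an alignment input.")
    s <- s[s$sample_id %in% rownames(a), , drop = FALSE]
    a <- a[s$sample_id, , drop = FALSE]
    grp <- s[[partition]]
    mask <- usable_sites(a)
    m <- unclass(a)[, mask, drop = FALSE]
    states <- matrix(match(m, .DNA_STRICT), nrow = nrow(m))
    poly <- apply(states, 2, function(x) length(unique(x)) > 1)
    states <- states[, poly, drop = FALSE]
  } else {
    states <- a
    grp <- attr(a, "pop")
  }
  if (is.null(group_order)) group_order <- unique(grp)
  if (length(group_order) < 2) abort("At least two groups are required.")
  n_g <- table(grp)[group_order]
  if (any(is.na(n_g)) || any(n_g < 2)) abort("Every group needs n >= 2.")
  summary_stats_variants(states, grp, group_order)
}

#' Build an ABC reference table
#'
#' For each scenario kind: `n_sims` independent rows of (parameter draw ->
#' coalescent simulation -> summary statistics). Fully seeded (one sub-seed
#' per row) and processed in chunks; a failed simulation is skipped with a
#' warning, never silently retried.
#'
#' @param kinds Character vector of scenario kinds (default the three
#'   divergence scenarios).
#' @param spec A [prior_spec()].
#' @param n_sims Simulations per scenario.
#' @param sample_sizes Sample sizes for the three populations.
#' @param populations Population names.
#' @param L Sequence length (default 866).
#' @param seed Master seed.
#' @return Tibble: `scenario` (1-based id), `kind`, parameter columns,
#'   statistic columns.
#' @export
build_reference_table <- function(kinds = c("gradual_north_derived",
                                            "gradual_south_derived",
                                            "sudden_trifurcation"),
                                  spec = prior_spec(),
                                  n_sims = 1000,
                                  sample_sizes = c(25, 25, 25),
                                  populations = c("P1", "P2", "P3"),
                                  L = 866, seed = NULL) {
  stopifnot(n_sims >= 1)
  seeds <- spawn_seeds(seed, length(kinds) * 2)
  rows <- purrr::map_dfr(seq_along(kinds), function(si) {
    kind <- kinds[si]
    pars <- sample_priors(spec, kind, n = n_sims, seed = seeds[2 * si - 1])
    row_seeds <- spawn_seeds(seeds[2 * si], n_sims)
    purrr::map_dfr(seq_len(n_sims), function(r) {
      p <- pars[r, ]
      res <- tryCatch({
        scn <- scenario(kind, populations,
                        Ne = c(p$Ne1, p$Ne2, p$Ne3), Ne_anc = p$Ne_anc,
                        t1 = p$t1, t2 = if (is.na(p$t2)) NULL else p$t2)
        sim <- simulate_scenario(scn, mu = p$mu, n = sample_sizes, L = L,
                                 seed = row_seeds[r])
        summary_stats_variants(sim$variants, attr(sim$variants, "pop"), populations)
      }, error = function(e) {
        warn(paste0("Simulation failed (", kind, ", row ", r, "): ",
                    conditionMessage(e)))
        NULL
      })
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble(scenario = si, kind = kind), p, res)
    })
  })
  rows
}

# Standardize reference-table statistics and compute Euclidean distances to
# the observed vector. Constant columns are dropped.
abc_distances <- function(ref, obs) {
  stat_cols <- intersect(names(obs), names(ref))
  if (!length(stat_cols)) abort("No shared statistic columns between obs and table.")
  X <- as.matrix(ref[stat_cols])
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X <- sweep(X[, keep, drop = FALSE], 2, sds[keep], "/")
  xo <- as.numeric(obs[1, stat_cols])[keep] / sds[keep]
  list(d = sqrt(colSums((t(X) - xo)^2)), X = X, xobs = xo)
}

#' ABC scenario choice by weighted multinomial logistic regression
#'
#' Statistics are standardized by the reference-table scale; the `n_closest`
#' rows by Euclidean distance to the observed vector are retained with
#' Epanechnikov weights `1 - (d/d_max)^2`, and the scenario id is regressed
#' on the (observation-centred) statistics by multinomial logistic
#' regression. Posterior scenario probabilities are the fitted probabilities
#' at the observed point; 95% CIs come from the regression's asymptotic
#' variance by the delta method.
#'
#' @param obs Observed summary statistics ([summary_statistics()]).
#' @param ref Reference table ([build_reference_table()]).
#' @param n_closest Number of accepted rows; defaults to 1% of the table.
#' @return Object of class `abc_model_choice`: tibble `posterior`
#'   (scenario, kind, prob, lo, hi), `selected`, accepted row indices and
#'   weights.
#' @export
model_choice <- function(obs, ref, n_closest = NULL) {
  if (is.null(n_closest)) n_closest <- max(2, ceiling(0.01 * nrow(ref)))
  if (n_closest > nrow(ref)) abort("n_closest exceeds the reference table size.")
  dd <- abc_distances(ref, obs)
  sel <- order(dd$d)[seq_len(n_closest)]
  dmax <- max(dd$d[sel])
  w <- 1 - (dd$d[sel] / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-6) / 2  # keep boundary rows in the fit
  scn_levels <- sort(unique(ref$scenario))
  kinds <- ref$kind[match(scn_levels, ref$scenario)]
  present <- sort(unique(ref$scenario[sel]))
  missing <- setdiff(scn_levels, present)
  if (length(missing)) {
    warn(paste0("Scenario(s) ", paste(missing, collapse = ", "),
                " absent from the ", n_closest,
                " closest rows; probability floored at 0."))
  }
  Z <- sweep(dd$X[sel, , drop = FALSE], 2, dd$xobs, "-")
  y <- factor(ref$scenario[sel], levels = present)
  if (length(present) == 1) {
    post <- tibble(scenario = scn_levels, kind = kinds,
                   prob = as.numeric(scn_levels == present),
                   lo = as.numeric(scn_levels == present),
                   hi = as.numeric(scn_levels == present))
  } else {
    dat <- data.frame(y = y, Z)
    fit <- nnet::multinom(y ~ ., data = dat, weights = w, trace = FALSE,
                          Hess = TRUE, maxit = 500)
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list(present[-1], names(cf)))
    b0 <- cf[, "(Intercept)"]
    eta <- c(0, b0)
    p <- exp(eta - logsumexp(eta))
    se <- tryCatch(delta_se_softmax(fit, length(present), ncol(Z)),
                   error = function(e) rep(NA_real_, length(present)))
    post <- tibble(scenario = present, prob = p,
                   lo = pmax(0, p - 1.96 * se), hi = pmin(1, p + 1.96 * se))
    if (length(missing)) {
      post <- dplyr::bind_rows(post, tibble(scenario = missing, prob = 0, lo = 0, hi = 0))
      post <- dplyr::arrange(post, .data$scenario)
      post$prob <- post$prob / sum(post$prob)
    }
    post$kind <- kinds[match(post$scenario, scn_levels)]
    post <- post[, c("scenario", "kind", "prob", "lo", "hi")]
  }
  structure(
    list(posterior = post,
         selected = post$scenario[which.max(post$prob)],
         selected_kind = post$kind[which.max(post$prob)],
         n_closest = n_closest, accepted = sel, weights = w),
    class = "abc_model_choice"
  )
}

# Delta-method standard errors of softmax probabilities at the observed
# point (intercept coordinates only).
delta_se_softmax <- function(fit, K, p_stats) {
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(V)) return(rep(NA_real_, K))
  # coefficient order in vcov: per outcome class 2..K, (Intercept) then slopes
  idx_int <- seq(1, by = p_stats + 1, length.out = K - 1)
  Vi <- V[idx_int, idx_int, drop = FALSE]
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  eta <- c(0, cf[, 1])
  p <- exp(eta - logsumexp(eta))
  se <- numeric(K)
  for (k in seq_len(K)) {
    # d p_k / d b0_j = p_k (1[k=j] - p_j), j = 2..K
    g <- p[k] * ((seq_len(K) == k) - p)[-1]
    se[k] <- sqrt(drop(t(g) %*% Vi %*% g))
  }
  se
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat(sprintf("<abc_model_choice> selected scenario %s (%s), n_closest=%d\n",
              x$selected, x$selected_kind, x$n_closest))
  print(x$posterior)
  invisible(x)
}

#' @export
tidy.abc_model_choice <- function(x, ...) x$posterior

#' @export
glance.abc_model_choice <- function(x, ...) {
  tibble(selected = x$selected, selected_kind = x$selected_kind,
         n_closest = x$n_closest)
}

#' ABC parameter estimation by local-linear regression adjustment
#'
#' Restricts the reference table to the selected scenario, accepts the
#' `n_closest` rows by standardized Euclidean distance, log-transforms the
#' parameters and adjusts each accepted draw by a weighted local-linear
#' regression on the (observation-centred) statistics (Beaumont-style).
#' Posterior summaries are the weighted median and 2.5/97.5 percentiles on
#' the back-transformed scale. A singular regression falls back to the
#' unadjusted rejection posterior with a warning.
#'
#' @param ref Reference table restricted (or restrictable) to one scenario.
#' @param obs Observed summary statistics.
#' @param scenario_id Scenario to estimate (default: the only one present).
#' @param n_closest Accepted rows (default 1% of the scenario's rows).
#' @param g Generation time in years for the year-scale columns (default 10).
#' @return Tibble: parameter, median, lo, hi (natural scale), plus
#'   median_years/lo_years/hi_years for the time parameters.
#' @export
estimate_parameters <- function(ref, obs, scenario_id = NULL, n_closest = NULL,
                                g = 10) {
  if (!is.null(scenario_id)) ref <- ref[ref$scenario == scenario_id, , drop = FALSE]
  if (length(unique(ref$scenario)) != 1) {
    abort("Reference table must be restricted to a single scenario.")
  }
  if (is.null(n_closest)) n_closest <- max(2, ceiling(0.01 * nrow(ref)))
  if (nrow(ref) < n_closest) abort("Selected scenario has fewer rows than n_closest.")
  par_cols <- intersect(c("Ne1", "Ne2", "Ne3", "Ne_anc", "t1", "t2", "mu"), names(ref))
  par_cols <- par_cols[vapply(par_cols, function(p) !all(is.na(ref[[p]])), logical(1))]
  dd <- abc_distances(ref, obs)
  sel <- order(dd$d)[seq_len(n_closest)]
  dmax <- max(dd$d[sel])
  w <- 1 - (dd$d[sel] / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-6) / 2
  Z <- sweep(dd$X[sel, , drop = FALSE], 2, dd$xobs, "-")
  out <- purrr::map_dfr(par_cols, function(pc) {
    y <- log(ref[[pc]][sel])
    adj <- tryCatch({
      fit <- stats::lm.wfit(cbind(1, Z), y, w)
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      y - drop(Z %*% beta)
    }, error = function(e) {
      warn(paste0("Singular local-linear regression for ", pc,
                  "; using rejection posterior."))
      y
    })
    q <- weighted_quantile(exp(adj), w, c(0.025, 0.5, 0.975))
    tibble(parameter = pc, median = q[2], lo = q[1], hi = q[3])
  })
  times <- out$parameter %in% c("t1", "t2")
  out$median_years <- ifelse(times, to_years(out$median, g), NA_real_)
  out$lo_years <- ifelse(times, to_years(out$lo, g), NA_real_)
  out$hi_years <- ifelse(times, to_years(out$hi, g), NA_real_)
  out
}

#' Convert generations to years
#'
#' @param generations Number of generations (>= 0).
#' @param g Generation time in years (default 10).
#' @return `generations * g`.
#' @export
to_years <- function(generations, g = 10) {
  stopifnot(all(generations >= 0, na.rm = TRUE))
  generations * g
}

#' Plot ABC scenario posteriors
#' @param x An `abc_model_choice`.
#' @return ggplot object.
#' @export
plot_model_choice <- function(x) {
  ggplot2::ggplot(x$posterior,
                  ggplot2::aes(factor(.data$scenario), .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.2) +
    ggplot2::labs(x = "scenario", y = "posterior probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
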