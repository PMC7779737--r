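#' Specification of the Besag-York-Mollie model fit
#'
#' Priors and backend settings for [bym_fit]. The precision of each
#' random effect gets a Gamma prior (equivalently log-gamma on the
#' log-precision); the default `(shape 1, rate 0.001)` is the minimally
#' informative setting common in disease-mapping software. The intercept
#' is flat.
#'
#' @param prior_unstructured `c(shape, rate)` Gamma prior on the
#'   precision of the exchangeable effect.
#' @param prior_structured `c(shape, rate)` Gamma prior on the precision
#'   of the intrinsic-CAR spatial effect.
#' @param credible_level width of the equal-tailed posterior interval
#'   used for high-risk classification.
#' @param chains number of independent MCMC chains.
#' @param iter_warmup,iter_sample burn-in and retained sweeps per chain.
#' @param thin thinning interval.
#' @return a list of class `bym_spec`.
#' @export
bym_spec <- function(prior_unstructured = c(1, 0.001),
                     prior_structured = c(1, 0.001),
                     credible_level = 0.95,
                     chains = 4, iter_warmup = 1000, iter_sample = 1000,
                     thin = 1) {
  stopifnot(credible_level > 0, credible_level < 1,
            all(prior_unstructured > 0), all(prior_structured > 0),
            chains >= 1, iter_warmup >= 0, iter_sample >= 1, thin >= 1)
  structure(list(prior_unstructured = prior_unstructured,
                 prior_structured = prior_structured,
                 credible_level = credible_level,
                 chains = as.integer(chains),
                 iter_warmup = as.integer(iter_warmup),
                 iter_sample = as.integer(iter_sample),
                 thin = as.integer(thin)),
            class = "bym_spec")
}

#' Fit the Besag-York-Mollie disease-mapping model
#'
#' Hierarchical Poisson model `c_i ~ Poisson(e_i * RR_i)` with
#' `log RR_i = mu + s_i + v_i`: an intercept, an intrinsic-CAR spatially
#' structured effect `s` (conditional mean equal to the neighbour
#' average, conditional variance inversely proportional to the neighbour
#' count, sum-to-zero per connected component) and an exchangeable effect
#' `v`. Fit by adaptive Metropolis-within-Gibbs MCMC (conjugate Gibbs
#' updates for the two precisions and the intercept). Deterministic given
#' `seed` and the backend settings.
#'
#' On maps with several connected components the ICAR constraint is
#' applied per component and a warning is emitted; island districts
#' (no neighbours) carry no spatial effect.
#'
#' @param map a [district_map].
#' @param cases a [case_vector].
#' @param spec a [bym_spec].
#' @param seed integer seed.
#' @return object of class `bym_posterior`: per-district `summary`
#'   data.frame (mean, median, lower, upper of RR), `params` (posterior
#'   summaries of mu and the two precisions), `diagnostics` (effective
#'   sample sizes, split-chain R-hat for mu, acceptance rates),
#'   `credible_level`, and the retained `draws` of log RR.
#' @export
bym_fit <- function(map, cases, spec = bym_spec(), seed = 1L) {
  stopifnot(inherits(map, "district_map"), inherits(cases, "case_vector"),
            all(cases$expected > 0))
  g <- map_graph(map)
  comp <- igraph::components(g)$membership
  if (max(comp) > 1L)
    warning("map has several components; ICAR sum-to-zero applied per component")
  nbr <- neighbor_list(map)
  runs <- with_seed(seed, lapply(seq_len(spec$chains), function(ch) {
    bym_mcmc(cases$cases, cases$expected, nbr, as.integer(comp),
             spec$iter_warmup, spec$iter_sample, spec$thin,
             spec$prior_structured[1], spec$prior_structured[2],
             spec$prior_unstructured[1], spec$prior_unstructured[2])
  }))
  logrr <- do.call(cbind, lapply(runs, `[[`, "logrr"))
  mu_d <- unlist(lapply(runs, `[[`, "mu"))
  tau_s <- unlist(lapply(runs, `[[`, "tau_s"))
  tau_v <- unlist(lapply(runs, `[[`, "tau_v"))
  a <- (1 - spec$credible_level) / 2
  rr <- exp(logrr)
  smry <- data.frame(
    district_id = map$ids,
    rr_mean = rowMeans(rr),
    rr_median = apply(rr, 1, median),
    rr_lower = apply(rr, 1, quantile, probs = a),
    rr_upper = apply(rr, 1, quantile, probs = 1 - a))
  params <- data.frame(
    parameter = c("mu", "tau_structured", "tau_unstructured"),
    mean = c(mean(mu_d), mean(tau_s), mean(tau_v)),
    median = c(median(mu_d), median(tau_s), median(tau_v)),
    lower = c(quantile(mu_d, a), quantile(tau_s, a), quantile(tau_v, a)),
    upper = c(quantile(mu_d, 1 - a), quantile(tau_s, 1 - a),
              quantile(tau_v, 1 - a)))
  diagnostics <- list(
    ess_mu = ess(mu_d), ess_tau_s = ess(tau_s), ess_tau_v = ess(tau_v),
    rhat_mu = split_rhat(mu_d, spec$chains),
    accept_s = mean(vapply(runs, `[[`, numeric(1), "accept_s")),
    accept_v = mean(vapply(runs, `[[`, numeric(1), "accept_v")),
    converged = TRUE)
  diagnostics$converged <- is.na(diagnostics$rhat_mu) ||
    diagnostics$rhat_mu < 1.1
  if (!diagnostics$converged)
    warning(sprintf("possible non-convergence: split R-hat(mu) = %.3f",
                    diagnostics$rhat_mu))
  structure(list(summary = smry, params = params,
                 diagnostics = diagnostics,
                 credible_level = spec$credible_level, draws = rr),
            class = "bym_posterior")
}

# effective sample size from the autocorrelation function, truncated at
# the first negative lag (initial positive sequence estimator, simplified)
ess <- function(x, max_lag = 100) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(max_lag, n - 1), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  n / (1 + 2 * sum(rho))
}

split_rhat <- function(x, chains) {
  n <- length(x)
  m <- chains * 2
  if (n < m * 4) return(NA_real_)
  len <- floor(n / m)
  xs <- matrix(x[seq_len(m * len)], nrow = len)
  bm <- colMeans(xs)
  W <- mean(apply(xs, 2, stats::var))
  B <- len * stats::var(bm)
  if (W == 0) return(NA_real_)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' @export
print.bym_posterior <- function(x, ...) {
  cat(sprintf("BYM posterior: %d districts, %d draws, %.0f%% credible level\n",
              nrow(x$summary), ncol(x$draws), 100 * x$credible_level))
  cat(sprintf("  RR medians in [%.3f, %.3f]; ESS(mu) = %.0f, R-hat(mu) = %.3f\n",
              min(x$summary$rr_median), max(x$summary$rr_median),
              x$diagnostics$ess_mu, x$diagnostics$rhat_mu))
  invisible(x)
}

#' Classify high-risk districts from a BYM posterior
#'
#' A district is labeled high-risk when the lower bound of the
#' equal-tailed credible interval for its relative risk exceeds 1.
#'
#' @param posterior a `bym_posterior` from [bym_fit].
#' @param credible_level optional level to re-extract from the stored
#'   draws (defaults to the level used at fit time).
#' @return object of classes `bym_result` and `detection_result` with
#'   logical `labels` and the per-district `table`.
#' @export
bym_detect <- function(posterior, credible_level = NULL) {
  stopifnot(inherits(posterior, "bym_posterior"))
  smry <- posterior$summary
  if (!is.null(credible_level) &&
      credible_level != posterior$credible_level) {
    a <- (1 - credible_level) / 2
    smry$rr_lower <- apply(posterior$draws, 1, quantile, probs = a)
    smry$rr_upper <- apply(posterior$draws, 1, quantile, probs = 1 - a)
  } else {
    credible_level <- posterior$credible_level
  }
  labels <- smry$rr_lower > 1
  structure(list(
    method = "bym",
    table = cbind(smry, labeled = as.integer(labels)),
    labels = labels,
    parameters = list(credible_level = credible_level),
    diagnostics = posterior$diagnostics),
    class = c("bym_result", "detection_result"))
}

#' @export
print.bym_result <- function(x, ...) {
  cat(sprintf("BYM detection: %d district(s) labeled high-risk at the %.0f%% credible level\n",
              sum(x$labels), 100 * x$parameters$credible_level))
  invisible(x)
}
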