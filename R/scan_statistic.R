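#' Enumerate circular scan zones under a population cap
#'
#' For each centre district, nested zones are grown by adding
#' next-nearest centroids while the cumulative population stays within
#' `max_frac * N`. The centre itself is always admissible (the
#' zero-radius circle). Zones are kept in the compact nested
#' representation: a distance ordering per centre plus the number of
#' admissible members.
#'
#' @param map a [district_map].
#' @param max_frac maximum fraction of the total population inside a
#'   zone, `0 < max_frac <= 1` (the study uses 0.10).
#' @return object of class `sss_zones` with `ord` (H x H index matrix,
#'   row i = centre i followed by the other districts by increasing
#'   distance), `mlen` (admissible members per centre), `n_zones`.
#' @export
sss_zones <- function(map, max_frac = 0.1) {
  stopifnot(max_frac > 0, max_frac <= 1)
  nb_ord <- bn_neighbor_order(map)
  ord <- cbind(seq_len(map$H), nb_ord)
  cap <- max_frac * map$N
  cum_pop <- t(apply(ord, 1, function(o) cumsum(map$populations[o])))
  mlen <- pmax(1L, rowSums(cum_pop <= cap))
  structure(list(ord = unname(ord), mlen = as.integer(mlen),
                 n_zones = sum(mlen), max_frac = max_frac, H = map$H),
            class = "sss_zones")
}

#' Members of one scan zone
#'
#' @param zones an `sss_zones` object.
#' @param center centre district index.
#' @param size number of zone members (prefix length).
#' @return integer vector of member district indices.
#' @export
zone_members <- function(zones, center, size) {
  zones$ord[center, seq_len(size)]
}

#' Poisson log-likelihood ratio of a scan zone
#'
#' `LLR = D*log(D/E) + (C-D)*log((C-D)/(C-E))` with `E = U*C/N` the
#' expected zone count under the null, when the zone is in excess
#' (`D > E`); 0 otherwise (one-sided high-risk indicator). Vectorized.
#'
#' @param D zone case count(s).
#' @param U zone population(s).
#' @param C total cases.
#' @param N total population.
#' @return numeric LLR value(s).
#' @export
#' @examples
#' sss_llr(D = 5, U = 100, C = 10, N = 1000)  # 5*log(5) + 5*log(5/9)
sss_llr <- function(D, U, C, N) {
  E <- U * C / N
  llr <- numeric(length(D))
  hot <- D > E & D > 0
  if (any(hot)) {
    Dh <- D[hot]; Eh <- E[hot]
    term2 <- ifelse(C - Dh > 0, (C - Dh) * log((C - Dh) / (C - Eh)), 0)
    llr[hot] <- Dh * log(Dh / Eh) + term2
  }
  llr
}

#' Kulldorff circular spatial scan with Monte Carlo inference
#'
#' Finds the zone maximizing the Poisson likelihood ratio over all
#' population-capped circles, and assesses significance by conditional
#' Monte Carlo: the `C` observed cases are redistributed multinomially
#' with probabilities `u_i / N`, and `p = (1 + #\{T* >= T\}) / (1 + n_mc)`.
#' When `include_secondary` is on, non-overlapping zones whose own LLR is
#' significant against the replicate max-statistic distribution are also
#' reported and labeled (SaTScan convention).
#'
#' @param map a [district_map].
#' @param cases a [case_vector].
#' @param max_frac population cap per zone (fraction of N).
#' @param n_mc number of null replicates.
#' @param alpha significance level.
#' @param include_secondary label significant secondary clusters too.
#' @return object of classes `sss_result` and `detection_result`:
#'   `most_likely` (member indices), `llr_max`, `p_value`, `secondary`
#'   (list of zones with their LLRs and p-values), logical `labels`.
#' @export
sss_detect <- function(map, cases, max_frac = 0.1, n_mc = 999,
                       alpha = 0.05, include_secondary = TRUE) {
  stopifnot(n_mc >= 1)
  zones <- sss_zones(map, max_frac)
  labels <- logical(map$H)
  if (cases$C == 0) {
    return(structure(list(
      method = "scan", most_likely = integer(0), llr_max = 0,
      p_value = 1, secondary = list(), labels = labels,
      parameters = list(max_frac = max_frac, n_mc = n_mc, alpha = alpha,
                        include_secondary = include_secondary)),
      class = c("sss_result", "detection_result")))
  }
  best <- scan_best_zones(zones$ord - 1L, zones$mlen, map$populations,
                          cases$cases, cases$C, map$N)
  t_obs <- max(best$llr)
  center <- which.max(best$llr)
  ml_members <- zone_members(zones, center, best$size[center])
  null_max <- scan_null_max(zones$ord - 1L, zones$mlen, map$populations,
                            cases$C, map$N, n_mc)
  mc_p <- function(llr) (1 + sum(null_max >= llr)) / (1 + n_mc)
  p <- mc_p(t_obs)
  secondary <- list()
  if (p < alpha) {
    labels[ml_members] <- TRUE
    if (include_secondary) {
      taken <- labels
      o <- order(best$llr, decreasing = TRUE)
      for (i in o) {
        if (i == center || best$llr[i] <= 0) next
        p_i <- mc_p(best$llr[i])
        if (p_i >= alpha) break           # ordered by LLR: no later zone passes
        mem <- zone_members(zones, i, best$size[i])
        if (any(taken[mem])) next         # overlaps an accepted cluster
        taken[mem] <- TRUE
        labels[mem] <- TRUE
        secondary[[length(secondary) + 1]] <-
          list(center = i, members = mem, llr = best$llr[i], p_value = p_i)
      }
    }
  }
  structure(list(
    method = "scan", most_likely = ml_members, center = center,
    llr_max = t_obs, p_value = p, secondary = secondary, labels = labels,
    parameters = list(max_frac = max_frac, n_mc = n_mc, alpha = alpha,
                      include_secondary = include_secondary)),
    class = c("sss_result", "detection_result"))
}

#' @export
print.sss_result <- function(x, ...) {
  cat(sprintf("spatial scan: max LLR = %.3f, p = %.4f (n_mc = %d); %d labeled, %d secondary cluster(s)\n",
              x$llr_max, x$p_value, x$parameters$n_mc, sum(x$labels),
              length(x$secondary)))
  invisible(x)
}
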