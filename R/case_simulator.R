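#' Scenario configuration for case simulation
#'
#' Bundles the incidence model of a simulation scenario: the annual
#' baseline rate per person (7 per million for nephroblastoma, 140 per
#' million for all childhood malignancies), the aggregation period in
#' years, the relative-risk grid, the cluster-size grid, and the number
#' of Monte Carlo iterations per cell.
#'
#' @param baseline_rate annual incidence per person at risk.
#' @param years aggregation period (cases are summed over this window).
#' @param rr_levels relative risks applied inside the true cluster.
#' @param cluster_sizes numbers of adjacent districts per true cluster.
#' @param iterations simulation replicates per (size, RR) cell.
#' @param master_seed root seed for all substreams.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(baseline_rate = 7e-6, years = 10,
                            rr_levels = c(1, 1.1, 1.2, 1.3, 1.4, 1.5,
                                          2, 5, 10, 100),
                            cluster_sizes = c(1, 2, 3, 5, 10, 20, 50),
                            iterations = 2000, master_seed = 1L) {
  stopifnot(baseline_rate > 0, years >= 1, iterations >= 1,
            all(rr_levels >= 0), all(cluster_sizes >= 1))
  structure(list(baseline_rate = baseline_rate, years = years,
                 rr_levels = rr_levels, cluster_sizes = cluster_sizes,
                 iterations = as.integer(iterations),
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

#' Expected case counts per district
#'
#' Under the null (RR = 1) the expected count in district i over the
#' aggregation window is `e_i = rate * u_i * years`, so that
#' `sum(e) = rate * N * years`.
#'
#' @param map a [district_map].
#' @param rate annual incidence per person.
#' @param years aggregation period.
#' @return named numeric vector of expected counts.
#' @export
#' @examples
#' # a district of 100,000 children at 7 per million over 10 years
#' # expects 7 cases
expected_cases <- function(map, rate = 7e-6, years = 10) {
  stopifnot(rate > 0, years >= 1)
  rate * map$populations * years
}

#' Simulate aggregated case counts under a cluster scenario
#'
#' Draws `c_i ~ Poisson(RR_i * e_i)` independently per district, with
#' `RR_i` equal to the cluster's relative risk for members and 1
#' elsewhere. A single Poisson draw with mean `years * rate * u_i`
#' replaces the sum of annual draws (the two are distributionally
#' identical). Uses the current RNG state.
#'
#' @param map a [district_map].
#' @param cluster a `true_cluster`, or `NULL` for a pure null surface.
#' @param rate annual baseline incidence per person.
#' @param years aggregation period.
#' @return an object of class `case_vector`: `cases` (integer counts),
#'   `expected` (`e_i`), `C` (total cases).
#' @export
simulate_cases <- function(map, cluster = NULL, rate = 7e-6, years = 10) {
  e <- expected_cases(map, rate, years)
  rr_vec <- rep(1, map$H)
  if (!is.null(cluster)) {
    stopifnot(inherits(cluster, "true_cluster"),
              all(cluster$members >= 1), all(cluster$members <= map$H))
    rr_vec[cluster$members] <- cluster$rr
  }
  cases <- rpois(map$H, rr_vec * e)
  case_vector(cases, e, ids = map$ids)
}

#' Construct a case vector
#'
#' @param cases non-negative integer counts per district.
#' @param expected strictly positive expected counts per district.
#' @param ids optional district ids.
#' @return an object of class `case_vector`.
#' @export
case_vector <- function(cases, expected, ids = NULL) {
  stopifnot(length(cases) == length(expected),
            all(cases >= 0), all(cases == round(cases)),
            all(expected > 0))
  cases <- as.integer(cases)
  if (!is.null(ids)) { names(cases) <- ids; names(expected) <- ids }
  structure(list(cases = cases, expected = as.numeric(expected),
                 C = sum(cases)),
            class = "case_vector")
}

#' @export
print.case_vector <- function(x, ...) {
  cat(sprintf("case_vector: %d districts, C = %d cases (expected %.1f)\n",
              length(x$cases), x$C, sum(x$expected)))
  invisible(x)
}

#' Crude incidence rates per million per year
#'
#' `rate_i = c_i / (u_i * years) * 1e6`: the observed annual incidence
#' per million persons, aggregated counts divided back by the window.
#'
#' @param cases a [case_vector].
#' @param map a [district_map].
#' @param years the aggregation period the counts were summed over.
#' @return numeric vector of rates per million per year.
#' @export
crude_rate <- function(cases, map, years = 10) {
  cases$cases / (map$populations * years) * 1e6
}

#' District cumulative relative risk estimand
#'
#' The simulation estimand: `rr_hat_i = c_i / e_i`, the ratio of observed
#' to expected counts over the aggregation window.
#'
#' @param cases a [case_vector].
#' @return numeric vector of per-district cumulative RR estimates.
#' @export
cumulative_rr <- function(cases) {
  cases$cases / cases$expected
}

#' Write a case vector as CSV
#'
#' @param cases a [case_vector].
#' @param path output CSV path (`district_id, cases, expected`).
#' @export
write_case_csv <- function(cases, path) {
  write.csv(data.frame(
    district_id = names(cases$cases) %||% seq_along(cases$cases),
    cases = cases$cases, expected = cases$expected),
    path, row.names = FALSE)
  invisible(path)
}
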