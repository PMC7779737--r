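#' Specification for a synthetic lattice geography
#'
#' Describes a rook-adjacency lattice whose district populations are drawn
#' from a truncated log-normal, emulating the statistical structure of the
#' German district system (402 districts; under-15 populations between
#' 3,594 and 492,448 summing to roughly 11 million).
#'
#' @param rows,cols lattice dimensions (`rows * cols >= 2`).
#' @param n_districts number of districts kept; when smaller than
#'   `rows * cols`, cells are trimmed from the end of the last row (the
#'   lattice stays connected).
#' @param log_mean,log_sd parameters of the log-normal population model.
#' @param min_pop,max_pop truncation bounds (persons).
#' @return a list of class `lattice_spec`.
#' @export
lattice_spec <- function(rows, cols, n_districts = rows * cols,
                         log_mean = log(20000), log_sd = 1,
                         min_pop = 3594, max_pop = 492448) {
  stopifnot(rows >= 1, cols >= 1, rows * cols >= 2,
            min_pop >= 1, max_pop >= min_pop,
            n_districts >= 2, n_districts <= rows * cols)
  if (n_districts < (rows - 1) * cols + 1)
    stop("n_districts would remove more than the last row")
  structure(list(rows = rows, cols = cols, n_districts = n_districts,
                 log_mean = log_mean, log_sd = log_sd,
                 min_pop = min_pop, max_pop = max_pop),
            class = "lattice_spec")
}

#' Default German-like lattice specification
#'
#' A 21 x 20 lattice trimmed to 402 districts with a truncated log-normal
#' population model (`meanlog = log(20000)`, `sdlog = 1`, bounds
#' `[3594, 492448]`), mirroring the size and population range of the 402
#' German NUTS-3 districts.
#'
#' @return a `lattice_spec`.
#' @export
german_lattice_spec <- function() {
  lattice_spec(rows = 21, cols = 20, n_districts = 402)
}

#' Generate a synthetic lattice district map
#'
#' Rook (edge-sharing) adjacency; centroids at integer grid coordinates;
#' populations i.i.d. truncated log-normal by rejection sampling.
#' Deterministic given `seed`.
#'
#' @param spec a [lattice_spec].
#' @param seed integer RNG seed.
#' @return a [district_map].
#' @export
#' @examples
#' map <- make_lattice_map(lattice_spec(3, 3), seed = 1)
#' validate_map(map)
make_lattice_map <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lattice_spec"))
  rows <- spec$rows; cols <- spec$cols; H <- spec$n_districts
  # row-major cell order; trimming drops trailing cells of the last row
  rr <- rep(seq_len(rows), each = cols)[seq_len(H)]
  cc <- rep(seq_len(cols), times = rows)[seq_len(H)]
  idx <- function(r, c) (r - 1) * cols + c
  edges <- list()
  for (i in seq_len(H)) {
    if (cc[i] < cols && idx(rr[i], cc[i] + 1) <= H)
      edges[[length(edges) + 1]] <- c(i, idx(rr[i], cc[i] + 1))
    if (rr[i] < rows && idx(rr[i] + 1, cc[i]) <= H)
      edges[[length(edges) + 1]] <- c(i, idx(rr[i] + 1, cc[i]))
  }
  em <- do.call(rbind, edges)
  adj <- matrix(0L, H, H)
  adj[em] <- 1L
  adj[em[, 2:1]] <- 1L
  pops <- with_seed(seed, rtrunc_lnorm(H, spec$log_mean, spec$log_sd,
                                       spec$min_pop, spec$max_pop))
  district_map(adj, pops, cbind(cc, rr),
               ids = sprintf("g%03d", seq_len(H)),
               coord_type = "euclidean")
}

# truncated log-normal by rejection; truncation bounds are respected
# with probability 1
rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(2 * (n - length(out)) + 10, meanlog, sdlog)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  round(out[seq_len(n)])
}
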