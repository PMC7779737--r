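# Test fixtures and independent oracles. Oracles deliberately avoid the
# package's own code paths (no igraph, no ppois-based shortcuts).

# independent rook-adjacency builder (double loop, no reuse of package code)
rook_adjacency <- function(rows, cols) {
  H <- rows * cols
  adj <- matrix(0L, H, H)
  id <- function(r, c) (r - 1) * cols + c
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { adj[id(r, c), id(r, c + 1)] <- 1L
                    adj[id(r, c + 1), id(r, c)] <- 1L }
    if (r < rows) { adj[id(r, c), id(r + 1, c)] <- 1L
                    adj[id(r + 1, c), id(r, c)] <- 1L }
  }
  adj
}

# lattice district_map with chosen populations (uniform by default)
make_test_map <- function(rows, cols, pops = NULL) {
  H <- rows * cols
  if (is.null(pops)) pops <- rep(1e5, H)
  cen <- cbind(rep(seq_len(cols), times = rows),
               rep(seq_len(rows), each = cols))
  district_map(rook_adjacency(rows, cols), pops, cen)
}

# connected components by breadth-first search (graph-search oracle)
components_oracle <- function(adj) {
  H <- nrow(adj)
  comp <- integer(H)
  k <- 0
  for (s in seq_len(H)) {
    if (comp[s] != 0) next
    k <- k + 1
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & comp == 0)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

is_connected_subset <- function(adj, members) {
  sub <- adj[members, members, drop = FALSE]
  all(components_oracle(sub) == 1)
}

# Poisson upper tail P(X >= k) by direct pmf summation (term recursion,
# no ppois / dpois)
poisson_tail_oracle <- function(k, mu) {
  term <- exp(-mu)
  cdf <- term
  if (k >= 2) for (s in seq_len(k - 1)) {
    term <- term * mu / s
    cdf <- cdf + term
  }
  1 - cdf
}

# scan LLR via the printed likelihood-ratio expression, powers first
llr_oracle <- function(D, U, C, N) {
  E <- U * C / N
  if (D <= E) return(0)
  lr <- (D / E)^D
  if (C - D > 0) lr <- lr * (((C - D) / (C - E))^(C - D))
  log(lr)
}

# exhaustive scan maximization from the raw distance matrix
scan_max_oracle <- function(map, cases, max_frac) {
  d <- as.matrix(dist(map$centroids))
  best <- 0
  for (i in seq_len(map$H)) {
    o <- order(d[i, ], map$ids)
    o <- c(i, o[o != i])
    U <- unname(cumsum(map$populations[o]))
    D <- unname(cumsum(cases$cases[o]))
    for (j in seq_len(map$H)) {
      if (j > 1 && U[j] > max_frac * map$N) break
      llr <- llr_oracle(D[j], U[j], cases$C, map$N)
      if (llr > best) best <- llr
    }
  }
  best
}

# one enclosure-filling pass (the fixed-point oracle applies it until
# nothing changes)
fill_once_oracle <- function(adj, in_set) {
  for (i in seq_len(nrow(adj))) {
    nb <- which(adj[i, ] > 0)
    if (!in_set[i] && length(nb) > 0 && all(in_set[nb])) in_set[i] <- TRUE
  }
  in_set
}

fill_fixed_point_oracle <- function(adj, members) {
  in_set <- logical(nrow(adj))
  in_set[members] <- TRUE
  repeat {
    nxt <- fill_once_oracle(adj, in_set)
    if (identical(nxt, in_set)) break
    in_set <- nxt
  }
  which(in_set)
}

# German-like 402-district lattice fixture, built once per test run
german_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_lattice_map(german_lattice_spec(),
                                                   seed = 20)
    cache
  }
})

# uniform-population 402-district lattice (e_i = 7 at the nephroblastoma
# rate over 10 years)
uniform_402_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- lattice_spec(21, 20, n_districts = 402)
      m <- make_lattice_map(spec, seed = 1)
      cache <<- district_map(m$adjacency, rep(1e5, m$H), m$centroids,
                             ids = m$ids)
    }
    cache
  }
})

# small random planar-ish maps for oracle comparisons
random_map <- function(H, seed) {
  set.seed(seed)
  rows <- max(2, floor(sqrt(H)))
  cols <- ceiling(H / rows)
  m <- make_lattice_map(lattice_spec(rows, cols, n_districts = H,
                                     log_mean = log(5e4), log_sd = 0.5),
                        seed = seed)
  # jitter centroids so distance ties are rare
  cen <- m$centroids + matrix(runif(2 * H, -0.3, 0.3), ncol = 2)
  district_map(m$adjacency, m$populations, cen, ids = m$ids)
}

random_cases <- function(map, seed, rate = 2e-5) {
  set.seed(seed)
  simulate_cases(map, NULL, rate = rate, years = 10)
}
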