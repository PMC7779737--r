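test_that("zone enumeration with max_frac = 1 yields all nested prefixes", {
  map <- make_test_map(1, 3)
  zones <- sss_zones(map, max_frac = 1)
  expect_equal(zones$mlen, rep(3L, 3))
  expect_equal(zones$n_zones, 9)
  expect_equal(zone_members(zones, 1, 2), c(1L, 2L))
})

test_that("the population cap is respected by every zone", {
  map <- german_fixture()
  zones <- sss_zones(map, max_frac = 0.1)
  for (i in seq_len(map$H)) {
    mem <- zone_members(zones, i, zones$mlen[i])
    if (zones$mlen[i] > 1)
      expect_lte(sum(map$populations[mem]), 0.1 * map$N)
    # maximality: the next district would break the cap
    if (zones$mlen[i] < map$H) {
      nxt <- zones$ord[i, zones$mlen[i] + 1]
      expect_gt(sum(map$populations[mem]) + map$populations[nxt],
                0.1 * map$N)
    }
  }
})

test_that("zone membership matches brute-force recomputation", {
  for (s in 1:10) {
    map <- random_map(16, seed = 400 + s)
    zones <- sss_zones(map, max_frac = 0.3)
    d <- as.matrix(dist(map$centroids))
    for (i in seq_len(map$H)) {
      o <- order(d[i, ], map$ids)
      o <- c(i, o[o != i])
      U <- cumsum(map$populations[o])
      expected_len <- max(1, sum(U <= 0.3 * map$N))
      expect_equal(zones$mlen[i], expected_len)
      expect_equal(zone_members(zones, i, expected_len),
                   o[seq_len(expected_len)], ignore_attr = TRUE)
    }
  }
})

test_that("the log likelihood ratio follows the printed formula", {
  # D = E gives a likelihood ratio of 1; deficits are zeroed
  expect_equal(sss_llr(D = 1, U = 100, C = 10, N = 1000), 0)
  expect_equal(sss_llr(D = 0.5, U = 100, C = 10, N = 1000), 0)
  # direct substitution: 5*log(5) + 5*log(5/9)
  expect_equal(sss_llr(D = 5, U = 100, C = 10, N = 1000),
               5 * log(5) + 5 * log(5 / 9), tolerance = 1e-12)
  # all cases inside the zone: second term vanishes
  expect_equal(sss_llr(D = 10, U = 100, C = 10, N = 1000),
               10 * log(10), tolerance = 1e-12)
  # random instances against the powers-first oracle
  set.seed(31)
  for (r in 1:200) {
    N <- runif(1, 1e3, 1e6)
    U <- runif(1, 1, N - 1)
    C <- sample(1:50, 1)
    D <- sample(0:C, 1)
    expect_equal(sss_llr(D, U, C, N), llr_oracle(D, U, C, N),
                 tolerance = 1e-9)
  }
})

test_that("max statistic equals exhaustive zone enumeration", {
  for (s in 1:15) {
    map <- random_map(25, seed = 500 + s)
    cv <- random_cases(map, seed = 600 + s)
    if (cv$C == 0) next
    set.seed(700 + s)
    res <- sss_detect(map, cv, max_frac = 0.5, n_mc = 19)
    expect_equal(res$llr_max, scan_max_oracle(map, cv, 0.5),
                 tolerance = 1e-9)
  }
})

test_that("a case pile on one district is the most likely cluster", {
  map <- make_test_map(4, 4)
  cases <- rep(0L, 16); cases[6] <- 30L
  cv <- case_vector(cases, rep(2, 16), ids = map$ids)
  set.seed(1)
  res <- sss_detect(map, cv, max_frac = 0.5, n_mc = 99)
  expect_true(6 %in% res$most_likely)
  expect_lt(res$p_value, 0.05)
  expect_true(res$labels[6])
})

test_that("zero cases gives a defined no-detection result", {
  map <- make_test_map(3, 3)
  cv <- case_vector(rep(0, 9), rep(1, 9), ids = map$ids)
  res <- sss_detect(map, cv, n_mc = 19)
  expect_equal(res$p_value, 1)
  expect_false(any(res$labels))
  expect_equal(res$llr_max, 0)
})

test_that("the statistic is invariant to scaling all populations", {
  map <- random_map(16, seed = 801)
  cv <- random_cases(map, seed = 802)
  map2 <- district_map(map$adjacency, map$populations * 13,
                       map$centroids, ids = map$ids)
  cv2 <- case_vector(cv$cases, cv$expected, ids = map$ids)
  set.seed(1); a <- sss_detect(map, cv, n_mc = 19)
  set.seed(1); b <- sss_detect(map2, cv2, n_mc = 19)
  expect_equal(a$llr_max, b$llr_max, tolerance = 1e-10)
  expect_equal(a$most_likely, b$most_likely)
})

test_that("adding a case to the most likely zone cannot lower its LLR", {
  set.seed(41)
  for (r in 1:100) {
    N <- 1e5; U <- runif(1, 1e3, 5e4)
    C <- sample(5:100, 1); D <- sample(1:C, 1)
    if (D <= U * C / N) next
    expect_gte(sss_llr(D + 1, U, C + 1, N), sss_llr(D, U, C, N) - 1e-12)
  }
})

test_that("Monte Carlo p-values live on the discrete grid and are null-uniform", {
  map <- make_test_map(5, 5)
  n_mc <- 99
  set.seed(51)
  ps <- vapply(1:300, function(i) {
    cv <- simulate_cases(map, NULL, rate = 2e-5, years = 10)
    if (cv$C == 0) return(NA_real_)
    sss_detect(map, cv, max_frac = 0.3, n_mc = n_mc)$p_value
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_true(all(ps >= 1 / (n_mc + 1) & ps <= 1))
  expect_true(all(abs(ps * (n_mc + 1) - round(ps * (n_mc + 1))) < 1e-9))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("secondary clusters are disjoint and only significant ones count", {
  # two far-apart case piles; secondary labeling should capture both
  map <- make_test_map(9, 9)
  cases <- rep(0L, 81)
  cases[1] <- 40L          # corner (1,1)
  cases[81] <- 40L         # opposite corner (9,9)
  cv <- case_vector(cases, rep(1, 81), ids = map$ids)
  set.seed(61)
  res <- sss_detect(map, cv, max_frac = 0.2, n_mc = 99,
                    include_secondary = TRUE)
  expect_lt(res$p_value, 0.05)
  expect_true(res$labels[1] && res$labels[81])
  if (length(res$secondary)) {
    for (sec in res$secondary) {
      expect_length(intersect(sec$members, res$most_likely), 0)
      expect_lt(sec$p_value, 0.05)
    }
  }
  set.seed(61)
  strict <- sss_detect(map, cv, max_frac = 0.2, n_mc = 99,
                       include_secondary = FALSE)
  expect_lte(sum(strict$labels), sum(res$labels))
})
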