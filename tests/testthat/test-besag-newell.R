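test_that("neighbour ordering follows distance with id tie-breaks", {
  map1x3 <- make_test_map(1, 3)              # centroids at x = 1, 2, 3
  ord <- bn_neighbor_order(map1x3)
  expect_equal(ord[1, ], c(2L, 3L))
  expect_equal(ord[3, ], c(2L, 1L))
  # symmetric pair equidistant from the centre: lower id first
  suppressWarnings(map_tie <- district_map(
    rook_adjacency(1, 3), rep(10, 3), cbind(c(0, -1, 1), c(0, 0, 0)),
    ids = c("d1", "d2", "d3")))
  ord_tie <- bn_neighbor_order(map_tie)
  expect_equal(ord_tie[1, ], c(2L, 3L))
})

test_that("neighbour ranking matches a from-scratch distance sort", {
  map <- german_fixture()
  ord <- bn_neighbor_order(map)
  for (i in c(1, 57, 201, 402)) {
    d <- sqrt(colSums((t(map$centroids) - map$centroids[i, ])^2))
    o <- order(d, map$ids)
    expect_equal(ord[i, ], o[o != i])
  }
})

test_that("tail probabilities reproduce Poisson closed forms", {
  # mu = U*C/N = 1 with k = 1: p = 1 - exp(-1)
  map <- make_test_map(2, 2, pops = c(25, 25, 25, 25))
  cv <- case_vector(c(1, 0, 0, 3), rep(1, 4), ids = map$ids)
  r <- bn_pvalue(1, k = 1, cv, map)
  expect_equal(r$m_obs, 0L)
  expect_equal(r$p_value, 1 - exp(-1), tolerance = 1e-12)
  # mu = 1 with k = 5: p = 1 - e^-1 (1 + 1 + 1/2 + 1/6 + 1/24)
  map2 <- make_test_map(2, 2, pops = c(20, 20, 20, 40))
  cv2 <- case_vector(c(5, 0, 0, 0), rep(1, 4), ids = map2$ids)
  r2 <- bn_pvalue(1, k = 5, cv2, map2)
  expect_equal(r2$m_obs, 0L)
  expect_equal(r2$p_value, 1 - exp(-1) * (1 + 1 + 1/2 + 1/6 + 1/24),
               tolerance = 1e-12)
})

test_that("accumulation rule and plus-one dialect differ by one case", {
  map <- make_test_map(1, 4)
  cv <- case_vector(c(1, 1, 1, 1), rep(1, 4), ids = map$ids)
  r <- bn_pvalue(1, k = 3, cv, map)          # needs districts 1..3
  expect_equal(r$m_obs, 2L)
  r1 <- bn_pvalue(1, k = 3, cv, map, plus_one = TRUE)  # D_j + 1 >= 3
  expect_equal(r1$m_obs, 1L)
})

test_that("too few total cases flags the degenerate accumulation", {
  map <- make_test_map(2, 2)
  cv <- case_vector(c(1, 0, 0, 0), rep(1, 4), ids = map$ids)
  r <- bn_pvalue(1, k = 10, cv, map)
  expect_false(r$reached)
  expect_equal(r$p_value, 1)
  expect_equal(r$m_obs, map$H - 1L)
})

test_that("p-values match the independent summation oracle", {
  for (s in 1:60) {
    map <- random_map(9, seed = s)
    cv <- random_cases(map, seed = 1000 + s)
    if (cv$C == 0) next
    ord <- bn_neighbor_order(map)
    k <- sample(1:6, 1)
    for (i in seq_len(map$H)) {
      got <- bn_pvalue(i, k, cv, map, ord, expected = "observed")
      # oracle: rebuild the accumulation from the raw distance matrix
      d <- sqrt(colSums((t(map$centroids) - map$centroids[i, ])^2))
      o <- order(d, map$ids)
      o <- c(i, o[o != i])
      cum <- cumsum(cv$cases[o])
      hit <- which(cum >= k)
      if (length(hit) == 0) {
        expect_equal(got$p_value, 1)
      } else {
        U <- sum(map$populations[o[seq_len(hit[1])]])
        p_oracle <- poisson_tail_oracle(k, U * cv$C / map$N)
        expect_equal(got$p_value, p_oracle, tolerance = 1e-12)
        expect_equal(got$m_obs, unname(hit[1]) - 1L)
      }
    }
  }
})

test_that("no cases means no significant districts and no labels", {
  map <- make_test_map(3, 3)
  cv <- case_vector(rep(0, 9), rep(1, 9), ids = map$ids)
  res <- bn_detect(map, cv, k = 5)
  expect_equal(res$R, 0)
  expect_false(any(res$labels))
})

test_that("a district holding all cases is detected and labeled", {
  map <- make_test_map(6, 6)
  cases <- rep(0L, 36); cases[15] <- 50L
  cv <- case_vector(cases, rep(0.5, 36), ids = map$ids)
  res <- bn_detect(map, cv, k = 5)
  expect_gt(res$R, 0)
  expect_true(res$labels[15])
  # baseline dialect: mu is the circle's cumulative expected count
  expect_equal(res$table$p_value[15], poisson_tail_oracle(5, 0.5),
               tolerance = 1e-12)
  # observed-total dialect: mu = U*C/N = 50/36
  res_o <- bn_detect(map, cv, k = 5, expected = "observed")
  expect_equal(res_o$table$p_value[15], poisson_tail_oracle(5, 50 / 36),
               tolerance = 1e-12)
  # centre-only labeling is a subset of circle labeling
  res_c <- bn_detect(map, cv, k = 5, label = "centers")
  expect_true(all(which(res_c$labels) %in% which(res$labels)))
})

test_that("R is invariant under district relabeling", {
  map <- german_fixture()
  set.seed(21)
  cl <- grow_cluster(map, 5, rr = 10)
  set.seed(22)
  cv <- simulate_cases(map, cl)
  res <- bn_detect(map, cv, k = 5)
  perm <- sample(map$H)
  pmap <- district_map(map$adjacency[perm, perm], map$populations[perm],
                       map$centroids[perm, ], ids = map$ids[perm])
  pcv <- case_vector(cv$cases[perm], cv$expected[perm], ids = pmap$ids)
  pres <- bn_detect(pmap, pcv, k = 5)
  expect_equal(pres$R, res$R)
  expect_equal(sum(pres$labels), sum(res$labels))
})

test_that("k beyond the total case count gives R = 0", {
  map <- make_test_map(3, 3)
  cv <- case_vector(c(2, 1, 0, 0, 3, 0, 0, 0, 1), rep(1, 9),
                    ids = map$ids)
  res <- bn_detect(map, cv, k = cv$C + 1)
  expect_equal(res$R, 0)
  expect_false(any(res$labels))
})

test_that("moving cases toward the centre cannot increase the p-value", {
  # with C fixed, concentrating cases near i shrinks the accumulation
  # circle, hence its population and the Poisson mean
  for (s in 1:40) {
    map <- random_map(12, seed = 200 + s)
    cv <- random_cases(map, seed = 300 + s)
    if (cv$C < 2) next
    ord <- bn_neighbor_order(map)
    i <- sample(map$H, 1)
    p_before <- bn_pvalue(i, 3, cv, map, ord)$p_value
    # move one case from the farthest case-carrying district to i
    seq_i <- c(i, ord[i, ])
    donors <- seq_i[cv$cases[seq_i] > 0]
    donor <- donors[length(donors)]
    if (donor == i) next
    cases2 <- cv$cases
    cases2[donor] <- cases2[donor] - 1L
    cases2[i] <- cases2[i] + 1L
    cv2 <- case_vector(cases2, cv$expected, ids = map$ids)
    p_after <- bn_pvalue(i, 3, cv2, map, ord)$p_value
    expect_lte(p_after, p_before + 1e-12)
  }
})
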