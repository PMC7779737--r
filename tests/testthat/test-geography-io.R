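test_that("minimal two-district map validates and reports H and N", {
  map <- district_map(matrix(c(0, 1, 1, 0), 2), c(10, 20),
                      cbind(c(0, 1), c(0, 0)))
  expect_equal(map$H, 2)
  expect_equal(map$N, 30)
  diag <- validate_map(map)
  expect_equal(diag$n_components, 1)
  expect_true(all(rowSums(map$adjacency) == 1))
})

test_that("contract violations are rejected with informative errors", {
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- 1L                      # asymmetric
  expect_error(district_map(adj, rep(10, 3), cbind(1:3, 1:3),
                            ids = c("a", "b", "c")),
               "not symmetric.*\\((a, b|b, a)\\)")
  expect_error(district_map(matrix(c(0, 1, 1, 0), 2), c(10, 0),
                            cbind(1:2, 1:2)),
               "positive")
  bad_diag <- matrix(c(1, 1, 1, 0), 2)
  expect_error(district_map(bad_diag, c(1, 1), cbind(1:2, 1:2)),
               "diagonal")
  expect_error(district_map(matrix(c(0, 2, 2, 0), 2), c(1, 1),
                            cbind(1:2, 1:2)),
               "binary")
})

test_that("3x3 lattice diagnostics show rook neighbour structure", {
  map <- make_test_map(3, 3)
  nbr <- rowSums(map$adjacency)
  expect_equal(nbr[c(1, 3, 7, 9)], rep(2, 4), ignore_attr = TRUE) # corners
  expect_equal(nbr[5], 4, ignore_attr = TRUE)                     # centre
  expect_true(validate_map(map)$connected)
})

test_that("isolated districts are flagged as extra components", {
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1L        # district 3 is an island
  expect_warning(
    map <- district_map(adj, rep(10, 3), cbind(c(0, 1, 5), c(0, 0, 5))),
    "not connected")
  diag <- validate_map(map)
  expect_equal(diag$n_components, 2)
  expect_equal(diag$zero_neighbor_districts, map$ids[3])
  # matches the BFS components oracle
  expect_equal(diag$n_components, max(components_oracle(adj)))
})

test_that("map bundle round-trips exactly", {
  map <- make_test_map(3, 4, pops = c(3594, 5000, 7000, 9000, 11000,
                                      13000, 15000, 17000, 19000,
                                      21000, 23000, 492448))
  dir <- file.path(tempdir(), "bundle-roundtrip")
  write_map_bundle(map, dir)
  back <- load_map_bundle(dir)
  expect_identical(back$adjacency, map$adjacency)
  expect_equal(back$populations, map$populations)
  expect_equal(back$centroids, map$centroids)
  expect_equal(back$N, map$N)
})

test_that("sources are joined by district id, not row order", {
  map <- make_test_map(2, 2, pops = c(100, 200, 300, 400))
  dir <- file.path(tempdir(), "bundle-perm")
  write_map_bundle(map, dir)
  # permute the adjacency and centroid files; population order defines
  # the canonical ordering
  adj <- read.csv(file.path(dir, "adjacency.csv"), row.names = 1,
                  check.names = FALSE)
  perm <- c(3, 1, 4, 2)
  write.csv(adj[perm, perm], file.path(dir, "adjacency.csv"))
  cen <- read.csv(file.path(dir, "centroids.csv"))
  write.csv(cen[perm, ], file.path(dir, "centroids.csv"),
            row.names = FALSE)
  back <- load_map_bundle(dir)
  expect_identical(back$adjacency, map$adjacency)
  expect_equal(back$populations, map$populations)
})

test_that("edge-list adjacency dialect loads and misalignment errors name ids", {
  dir <- file.path(tempdir(), "edgelist")
  dir.create(dir, showWarnings = FALSE)
  write.csv(data.frame(district_id = c("a", "b", "c"), u = c(10, 20, 30)),
            file.path(dir, "pop.csv"), row.names = FALSE)
  write.csv(data.frame(id_a = c("a", "b"), id_b = c("b", "c")),
            file.path(dir, "adj.csv"), row.names = FALSE)
  write.csv(data.frame(district_id = c("a", "b", "c"),
                       x = c(0, 1, 2), y = c(0, 0, 0)),
            file.path(dir, "cen.csv"), row.names = FALSE)
  map <- load_district_map(file.path(dir, "adj.csv"),
                           file.path(dir, "pop.csv"),
                           file.path(dir, "cen.csv"))
  expect_equal(map$H, 3)
  expect_equal(map$adjacency["a", "b"], 1L, ignore_attr = TRUE)
  expect_equal(map$adjacency["a", "c"], 0L, ignore_attr = TRUE)
  # centroid file missing a district -> alignment error naming it
  write.csv(data.frame(district_id = c("a", "b"), x = c(0, 1), y = c(0, 0)),
            file.path(dir, "cen.csv"), row.names = FALSE)
  expect_error(load_district_map(file.path(dir, "adj.csv"),
                                 file.path(dir, "pop.csv"),
                                 file.path(dir, "cen.csv")),
               "centroid.*missing \\[c\\]")
})

test_that("GeoJSON point centroids load with lon/lat distances", {
  dir <- file.path(tempdir(), "geojson")
  dir.create(dir, showWarnings = FALSE)
  gj <- list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = list(district_id = "a"),
         geometry = list(type = "Point", coordinates = list(10.0, 50.0))),
    list(type = "Feature", properties = list(district_id = "b"),
         geometry = list(type = "Point", coordinates = list(10.5, 50.0)))))
  jsonlite::write_json(gj, file.path(dir, "cen.geojson"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(district_id = c("a", "b"), u = c(10, 20)),
            file.path(dir, "pop.csv"), row.names = FALSE)
  write.csv(data.frame(id_a = "a", id_b = "b"),
            file.path(dir, "adj.csv"), row.names = FALSE)
  map <- load_district_map(file.path(dir, "adj.csv"),
                           file.path(dir, "pop.csv"),
                           file.path(dir, "cen.geojson"))
  expect_equal(map$coord_type, "lonlat")
  d <- map_distances(map)
  # ~0.5 degrees of longitude at 50N is roughly 36 km
  expect_gt(d["a", "b"], 30e3)
  expect_lt(d["a", "b"], 42e3)
})

test_that("RData import path extracts a square matrix", {
  f <- file.path(tempdir(), "adj.RData")
  deposited_adjacency <- matrix(c(0, 1, 1, 0), 2)
  save(deposited_adjacency, file = f)
  got <- import_rdata_object(f)
  expect_equal(got, deposited_adjacency)
  expect_error(import_rdata_object(f, "nope"), "not found")
})
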