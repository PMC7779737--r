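#' Construct a district map
#'
#' The central data model: a set of administrative districts with a
#' symmetric binary adjacency relation (the neighbourhood matrix W), an
#' under-15 population count per district, and one planar or lon/lat
#' centroid per district.
#'
#' @param adjacency square 0/1 matrix, symmetric with zero diagonal.
#' @param populations numeric vector of strictly positive population
#'   counts, one per district.
#' @param centroids two-column numeric matrix (x, y) or (lon, lat).
#' @param ids character vector of district identifiers; defaults to the
#'   dimnames of `adjacency`, else `"d1" ... "dH"`.
#' @param coord_type `"euclidean"` for projected planar coordinates or
#'   `"lonlat"` for geographic coordinates (distances then use the
#'   great-circle metric).
#' @return an object of class `district_map` with elements `ids`,
#'   `adjacency`, `populations`, `centroids`, `coord_type`, `H` (number of
#'   districts) and `N` (total population).
#' @export
district_map <- function(adjacency, populations, centroids, ids = NULL,
                         coord_type = c("euclidean", "lonlat")) {
  coord_type <- match.arg(coord_type)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  H <- nrow(adjacency)
  if (is.null(ids)) ids <- rownames(adjacency) %||% paste0("d", seq_len(H))
  ids <- as.character(ids)
  if (length(ids) != H || anyDuplicated(ids))
    stop("district ids must be unique and match the adjacency dimension")
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L)))
    stop("adjacency must be binary 0/1")
  if (any(diag(adjacency) != 0L))
    stop("adjacency must have a zero diagonal")
  asym <- which(adjacency != t(adjacency), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    stop(sprintf("adjacency is not symmetric: first asymmetric pair (%s, %s)",
                 ids[asym[1, 1]], ids[asym[1, 2]]))
  }
  populations <- as.numeric(populations)
  if (length(populations) != H)
    stop(sprintf("population vector length %d does not match %d districts",
                 length(populations), H))
  if (any(!is.finite(populations)) || any(populations <= 0))
    stop("every district population must be a positive number")
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != H || ncol(centroids) != 2)
    stop("centroids must be an H x 2 coordinate matrix")
  if (anyDuplicated(centroids) > 0)
    warning("duplicate centroids present; distance ties are broken by district id")
  dimnames(adjacency) <- list(ids, ids)
  names(populations) <- ids
  dimnames(centroids) <- list(ids, c("x", "y"))
  map <- structure(
    list(ids = ids, adjacency = adjacency, populations = populations,
         centroids = centroids, coord_type = coord_type,
         H = H, N = sum(populations)),
    class = "district_map")
  if (n_components(map) > 1L)
    warning("adjacency graph is not connected; islands are present")
  map
}

#' @export
print.district_map <- function(x, ...) {
  cat(sprintf("district_map: %d districts, total population %s (%s coordinates)\n",
              x$H, format(x$N, big.mark = ","), x$coord_type))
  cat(sprintf("  population range: %s - %s; edges: %d\n",
              format(min(x$populations), big.mark = ","),
              format(max(x$populations), big.mark = ","),
              sum(x$adjacency) / 2))
  invisible(x)
}

map_graph <- function(map) {
  igraph::graph_from_adjacency_matrix(map$adjacency, mode = "undirected")
}

n_components <- function(map) {
  igraph::count_components(map_graph(map))
}

# per-district list of neighbour indices
neighbor_list <- function(map) {
  apply(map$adjacency > 0, 1, which, simplify = FALSE)
}

#' Pairwise centroid distances for a district map
#'
#' Euclidean distances for projected coordinates; great-circle (Haversine)
#' distances in metres for lon/lat coordinates.
#'
#' @param map a [district_map].
#' @return an H x H numeric distance matrix.
#' @export
map_distances <- function(map) {
  if (map$coord_type == "lonlat") {
    d <- geosphere::distm(map$centroids, fun = geosphere::distHaversine)
  } else {
    d <- as.matrix(stats::dist(map$centroids))
  }
  dimnames(d) <- list(map$ids, map$ids)
  d
}

#' Load a district map from plain-text sources
#'
#' Joins three sources by district id (never by row order): an adjacency
#' source (square 0/1 CSV with id header row and column, or a two-column
#' edge-list CSV), a population CSV (`district_id,u`), and a centroid CSV
#' (`district_id,x,y`) or GeoJSON FeatureCollection.
#'
#' @param adjacency_source path to the adjacency CSV.
#' @param population_source path to the population CSV.
#' @param centroid_source path to the centroid CSV or `.geojson` file.
#' @param coord_type `"auto"` guesses `"lonlat"` when all coordinates lie
#'   within valid longitude/latitude bounds, else `"euclidean"`.
#' @return a validated [district_map]; district order follows the
#'   population source.
#' @export
load_district_map <- function(adjacency_source, population_source,
                              centroid_source,
                              coord_type = c("auto", "euclidean", "lonlat")) {
  coord_type <- match.arg(coord_type)

  pop <- read.csv(population_source, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (ncol(pop) < 2)
    stop("population source must have columns: district_id, population")
  ids <- as.character(pop[[1]])
  populations <- as.numeric(pop[[2]])

  adj <- read_adjacency(adjacency_source, ids)
  cen <- read_centroids(centroid_source)

  check_alignment(ids, rownames(adj), "adjacency")
  check_alignment(ids, rownames(cen), "centroid")
  adj <- adj[ids, ids]
  cen <- cen[ids, , drop = FALSE]

  if (coord_type == "auto") {
    lonlat_ok <- all(abs(cen[, 1]) <= 180) && all(abs(cen[, 2]) <= 90)
    coord_type <- if (lonlat_ok) "lonlat" else "euclidean"
  }
  district_map(adj, populations, cen, ids = ids, coord_type = coord_type)
}

check_alignment <- function(ids, other, what) {
  missing_ids <- setdiff(ids, other)
  extra_ids <- setdiff(other, ids)
  if (length(missing_ids) || length(extra_ids)) {
    stop(sprintf(
      "%s source does not align with population ids: missing [%s], unmatched [%s]",
      what,
      paste(head(missing_ids, 5), collapse = ", "),
      paste(head(extra_ids, 5), collapse = ", ")))
  }
}

read_adjacency <- function(path, ids) {
  first <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(first) == 2) {
    # edge list id_a,id_b
    a <- as.character(first[[1]]); b <- as.character(first[[2]])
    all_ids <- ids
    unknown <- setdiff(union(a, b), all_ids)
    if (length(unknown))
      stop(sprintf("edge list refers to unknown districts: [%s]",
                   paste(head(unknown, 5), collapse = ", ")))
    m <- matrix(0L, length(all_ids), length(all_ids),
                dimnames = list(all_ids, all_ids))
    m[cbind(a, b)] <- 1L
    m[cbind(b, a)] <- 1L
    m
  } else {
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    storage.mode(m) <- "integer"
    m
  }
}

read_centroids <- function(path) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    read_centroids_geojson(path)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 3)
      stop("centroid CSV must have columns: district_id, x, y")
    m <- cbind(as.numeric(df[[2]]), as.numeric(df[[3]]))
    rownames(m) <- as.character(df[[1]])
    m
  }
}

# Point features are taken as-is; polygon features get the vertex average
# of their outer ring (full point-on-surface extraction is out of scope).
read_centroids_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("GeoJSON source must be a FeatureCollection")
  coords <- t(vapply(gj$features, function(f) {
    g <- f$geometry
    if (identical(g$type, "Point")) {
      c(as.numeric(g$coordinates[[1]]), as.numeric(g$coordinates[[2]]))
    } else if (identical(g$type, "Polygon")) {
      ring <- do.call(rbind, lapply(g$coordinates[[1]], function(p)
        c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
      colMeans(ring)
    } else {
      stop(sprintf("unsupported GeoJSON geometry type: %s", g$type))
    }
  }, numeric(2)))
  ids <- vapply(gj$features, function(f) {
    p <- f$properties
    id <- p$district_id %||% p$id %||% p$name %||% f$id
    if (is.null(id)) stop("GeoJSON feature without an id property")
    as.character(id)
  }, character(1))
  rownames(coords) <- ids
  coords
}

#' Diagnostics report for a district map
#'
#' A pure report (never errors): counts of districts and connected
#' components, the neighbour-count distribution, population quantiles, and
#' flags for zero-neighbour districts.
#'
#' @param map a [district_map].
#' @return a list of class `map_diagnostics`.
#' @export
validate_map <- function(map) {
  g <- map_graph(map)
  comp <- igraph::components(g)
  nbr_counts <- rowSums(map$adjacency)
  structure(list(
    H = map$H,
    N = map$N,
    n_components = comp$no,
    component_sizes = sort(comp$csize, decreasing = TRUE),
    connected = comp$no == 1L,
    neighbor_counts = table(nbr_counts),
    zero_neighbor_districts = map$ids[nbr_counts == 0],
    population_quantiles = quantile(map$populations,
                                    c(0, .25, .5, .75, 1))
  ), class = "map_diagnostics")
}

#' @export
print.map_diagnostics <- function(x, ...) {
  cat(sprintf("map diagnostics: H = %d, N = %s, %d component(s)%s\n",
              x$H, format(x$N, big.mark = ","), x$n_components,
              if (x$connected) "" else "  [NOT CONNECTED]"))
  if (length(x$zero_neighbor_districts))
    cat("  zero-neighbour districts:",
        paste(x$zero_neighbor_districts, collapse = ", "), "\n")
  cat("  neighbour counts:\n")
  print(x$neighbor_counts)
  cat("  population quantiles:\n")
  print(round(x$population_quantiles))
  invisible(x)
}

#' Write a district map as a canonical plain-text bundle
#'
#' Writes `adjacency.csv` (square 0/1 with id headers), `populations.csv`,
#' `centroids.csv` and `metadata.json` (H, N, coordinate type, md5
#' checksums of the three CSVs) into a directory.
#'
#' @param map a [district_map].
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_map_bundle <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adj_path <- file.path(dir, "adjacency.csv")
  pop_path <- file.path(dir, "populations.csv")
  cen_path <- file.path(dir, "centroids.csv")
  write.csv(as.data.frame(map$adjacency), adj_path)
  write.csv(data.frame(district_id = map$ids, u = map$populations),
            pop_path, row.names = FALSE)
  write.csv(data.frame(district_id = map$ids,
                       x = map$centroids[, 1], y = map$centroids[, 2]),
            cen_path, row.names = FALSE)
  meta <- list(H = map$H, N = map$N, coord_type = map$coord_type,
               checksums = as.list(tools::md5sum(c(adj_path, pop_path,
                                                   cen_path))))
  names(meta$checksums) <- c("adjacency.csv", "populations.csv",
                             "centroids.csv")
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a district map from a canonical bundle directory
#'
#' @param dir directory produced by [write_map_bundle].
#' @return a [district_map].
#' @export
load_map_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  load_district_map(file.path(dir, "adjacency.csv"),
                    file.path(dir, "populations.csv"),
                    file.path(dir, "centroids.csv"),
                    coord_type = meta$coord_type %||% "auto")
}

#' Import objects from a deposited RData file
#'
#' Optional import path for legacy `.RData` deposits (e.g. an adjacency
#' matrix stored as a square matrix object). Returns the named object, or
#' the first square matrix found when `name` is `NULL`. The core pipeline
#' never reads RData; convert once with this helper and
#' [write_map_bundle].
#'
#' @param path an `.RData` file.
#' @param name optional object name inside the file.
#' @return the extracted object.
#' @export
import_rdata_object <- function(path, name = NULL) {
  env <- new.env(parent = emptyenv())
  loaded <- load(path, envir = env)
  if (!is.null(name)) {
    if (!name %in% loaded) stop(sprintf("object '%s' not found in %s", name, path))
    return(get(name, envir = env))
  }
  for (nm in loaded) {
    obj <- get(nm, envir = env)
    if (is.matrix(obj) && nrow(obj) == ncol(obj)) return(obj)
  }
  stop(sprintf("no square matrix object found in %s; available: %s",
               path, paste(loaded, collapse = ", ")))
}
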