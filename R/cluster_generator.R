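#' Grow a random connected high-risk cluster
#'
#' Starting from a uniformly random district, repeatedly adds a district
#' chosen uniformly at random among all non-members adjacent to the
#' current member set, until `size` districts are reached. Any district
#' completely enclosed by the grown cluster ("donut" hole) is then added
#' by [fill_enclosures] (disable with `fill_donuts = FALSE`).
#'
#' Uses the current RNG state; seed with `set.seed()` for
#' reproducibility. If growth stalls inside a component smaller than
#' `size`, a new random start is drawn, up to `max_retries` times.
#'
#' @param map a [district_map].
#' @param size requested cluster size, `1 <= size <= H`.
#' @param rr relative risk assigned to cluster members.
#' @param fill_donuts apply the enclosure rule after growth.
#' @param max_retries bounded restarts before erroring.
#' @return an object of class `true_cluster`: `members` (district
#'   indices), `ids`, `target_size`, `rr`.
#' @export
grow_cluster <- function(map, size, rr = 1, fill_donuts = TRUE,
                         max_retries = 100L) {
  stopifnot(inherits(map, "district_map"))
  if (size < 1 || size > map$H)
    stop(sprintf("cluster size must be in [1, %d]", map$H))
  nbrs <- neighbor_list(map)
  for (attempt in seq_len(max_retries)) {
    start <- sample.int(map$H, 1L)
    members <- start
    in_set <- logical(map$H)
    in_set[start] <- TRUE
    frontier <- setdiff(nbrs[[start]], members)
    ok <- TRUE
    while (length(members) < size) {
      if (length(frontier) == 0) { ok <- FALSE; break }
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members <- c(members, nxt)
      in_set[nxt] <- TRUE
      frontier <- unique(c(frontier, nbrs[[nxt]]))
      frontier <- frontier[!in_set[frontier]]
    }
    if (ok) {
      if (fill_donuts) members <- fill_enclosures(map, members)
      return(structure(list(members = sort(members),
                            ids = map$ids[sort(members)],
                            target_size = as.integer(size), rr = rr),
                       class = "true_cluster"))
    }
  }
  stop(sprintf("could not grow a connected cluster of size %d in %d attempts",
               size, max_retries))
}

#' Fill districts enclosed by a cluster
#'
#' Adds every non-member district all of whose neighbours lie inside the
#' member set (a graph-theoretic "donut" hole), iterating to a fixed
#' point so nested enclosures are filled too. Idempotent. Districts with
#' no neighbours at all are never added.
#'
#' @param map a [district_map].
#' @param members integer vector of member district indices.
#' @return the augmented (sorted) member index vector.
#' @export
fill_enclosures <- function(map, members) {
  if (inherits(members, "true_cluster")) members <- members$members
  nbrs <- neighbor_list(map)
  in_set <- logical(map$H)
  in_set[members] <- TRUE
  repeat {
    enclosed <- which(!in_set & vapply(seq_len(map$H), function(i) {
      length(nbrs[[i]]) > 0 && all(in_set[nbrs[[i]]])
    }, logical(1)))
    if (length(enclosed) == 0) break
    in_set[enclosed] <- TRUE
  }
  sort(which(in_set))
}

#' @export
print.true_cluster <- function(x, ...) {
  cat(sprintf("true_cluster: %d districts (target %d), RR = %g\n",
              length(x$members), x$target_size, x$rr))
  cat("  members:", paste(x$ids, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a true cluster to JSON
#'
#' @param cluster a `true_cluster`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @param seed optional seed to record alongside the members.
#' @return the path (invisibly) or a JSON string.
#' @export
write_cluster_json <- function(cluster, path = NULL, seed = NULL) {
  obj <- list(seed = seed, size = cluster$target_size, rr = cluster$rr,
              member_ids = cluster$ids)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
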