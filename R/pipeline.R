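#' Configuration of a full factorial detection experiment
#'
#' Binds a map, a [scenario_config] and per-method settings into a
#' reproducible experiment: every (cluster size, RR) cell runs
#' `iterations` independent draws of (true cluster, case vector), each
#' scored by every enabled method.
#'
#' @param map a [district_map].
#' @param scenario a [scenario_config].
#' @param methods named list of per-method settings; enable a method by
#'   including its entry. Recognized: `bn = list(k, alpha, label,
#'   plus_one)`, `sss = list(max_frac, n_mc, alpha, include_secondary)`,
#'   `bym = list(spec = bym_spec(...))`.
#' @param paired_clusters reuse the same per-iteration cluster stream
#'   across RR levels within a cluster size (lower-variance RR
#'   comparisons; the deposited layout of one cluster list per size);
#'   `FALSE` draws fully independent clusters per cell.
#' @param output_dir optional checkpoint directory; completed (size, RR)
#'   cells are written as CSV and skipped on resume.
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(map, scenario = scenario_config(),
                              methods = default_methods(),
                              paired_clusters = TRUE,
                              output_dir = NULL) {
  stopifnot(inherits(map, "district_map"),
            inherits(scenario, "scenario_config"),
            length(methods) >= 1)
  unknown <- setdiff(names(methods), c("bn", "sss", "bym"))
  if (length(unknown))
    stop("unknown methods: ", paste(unknown, collapse = ", "))
  structure(list(map = map, scenario = scenario, methods = methods,
                 paired_clusters = isTRUE(paired_clusters),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Default method settings
#'
#' Besag-Newell with k = 5, the scan statistic with a 10% population cap
#' and 999 null replicates, and the BYM model at its default backend
#' settings; all at the 0.05 level / 95% credible level.
#'
#' @return named list suitable for [experiment_config].
#' @export
default_methods <- function() {
  list(bn = list(k = 5, alpha = 0.05, label = "circles", plus_one = FALSE),
       sss = list(max_frac = 0.1, n_mc = 999, alpha = 0.05,
                  include_secondary = TRUE),
       bym = list(spec = bym_spec()))
}

#' Run the factorial detection experiment
#'
#' For every (cluster size, RR) cell: grows `iterations` random true
#' clusters, simulates case vectors, runs every enabled method, scores
#' each against the truth, and aggregates one metric row per method.
#' Fully reproducible from `scenario$master_seed` via per-purpose
#' substream seeds ([mix_seed]), so any cell re-run in isolation
#' reproduces its rows from a full run. A method failure in an iteration
#' is logged and that iteration is dropped for that method only.
#'
#' @param config an [experiment_config].
#' @param verbose print one progress line per cell.
#' @return a data.frame of metric rows (method x cluster_size x rr),
#'   also written to `output_dir/metrics.csv` when checkpointing.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  map <- config$map
  sc <- config$scenario
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  rows <- list()
  for (si in seq_along(sc$cluster_sizes)) {
    size <- sc$cluster_sizes[si]
    for (ri in seq_along(sc$rr_levels)) {
      rr <- sc$rr_levels[ri]
      cell_file <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("cell_size%d_rr%g.csv", size, rr))
      if (!is.null(out_dir) && file.exists(cell_file)) {
        rows[[length(rows) + 1]] <- read.csv(cell_file,
                                             stringsAsFactors = FALSE)
        next
      }
      t0 <- proc.time()[3]
      cell <- run_cell(map, sc, config$methods, size, rr,
                       config$paired_clusters)
      if (verbose)
        message(sprintf("cell size=%d rr=%g: n=%d, %d method failure(s), %.1fs",
                        size, rr, sc$iterations, cell$n_failures,
                        proc.time()[3] - t0))
      rows[[length(rows) + 1]] <- cell$metrics
      if (!is.null(out_dir))
        write.csv(cell$metrics, cell_file, row.names = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(master_seed = sc$master_seed,
           iterations = sc$iterations,
           paired_clusters = config$paired_clusters,
           methods = names(config$methods)),
      file.path(out_dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  }
  metrics
}

# one (size, rr) cell; substreams are keyed by the cell's values (not
# grid indices) so the cell reproduces in isolation from any grid
run_cell <- function(map, sc, methods, size, rr, paired) {
  n <- sc$iterations
  conf <- lapply(methods, function(m) vector("list", n))
  estimand <- numeric(n)
  truth_sizes <- integer(n)
  n_failures <- 0L
  for (it in seq_len(n)) {
    cluster_seed <- if (paired) mix_seed(sc$master_seed, size, it, "cluster")
                    else mix_seed(sc$master_seed, size, rr, it, "cluster")
    truth <- with_seed(cluster_seed,
                       grow_cluster(map, size, rr = rr))
    cases <- with_seed(mix_seed(sc$master_seed, size, rr, it, "cases"),
                       simulate_cases(map, truth, sc$baseline_rate,
                                      sc$years))
    estimand[it] <- mean(cumulative_rr(cases)[truth$members])
    truth_sizes[it] <- length(truth$members)
    for (m in names(methods)) {
      res <- tryCatch(
        run_method(m, methods[[m]], map, cases,
                   mix_seed(sc$master_seed, size, rr, it, m)),
        error = function(e) {
          warning(sprintf("%s failed in cell size=%d rr=%g iter=%d: %s",
                          m, size, rr, it, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) n_failures <- n_failures + 1L
      else conf[[m]][[it]] <- confusion(res, truth, map)
    }
  }
  # donut fill can enlarge individual truths; score against the modal
  # realized size (equal to `size` unless an enclosure occurred)
  metrics <- do.call(rbind, lapply(names(methods), function(m) {
    keep <- !vapply(conf[[m]], is.null, logical(1))
    if (!any(keep)) return(NULL)      # method failed in every iteration
    cs <- conf[[m]][keep]
    # group by realized truth size (almost always a single group)
    groups <- split(seq_along(cs), truth_sizes[keep])
    main <- groups[[which.max(lengths(groups))]]
    row <- metrics_from_confusions(cs[main],
                                   truth_size = truth_sizes[keep][main[1]],
                                   H = map$H,
                                   estimand_samples = estimand[keep][main])
    cbind(data.frame(method = m, cluster_size = size, rr = rr), row)
  }))
  list(metrics = metrics, n_failures = n_failures)
}

run_method <- function(name, settings, map, cases, seed) {
  switch(name,
    bn = bn_detect(map, cases,
                   k = settings$k %||% 5,
                   alpha = settings$alpha %||% 0.05,
                   label = settings$label %||% "circles",
                   plus_one = settings$plus_one %||% FALSE,
                   expected = settings$expected %||% "baseline"),
    sss = with_seed(seed, sss_detect(map, cases,
                   max_frac = settings$max_frac %||% 0.1,
                   n_mc = settings$n_mc %||% 999,
                   alpha = settings$alpha %||% 0.05,
                   include_secondary = settings$include_secondary %||% TRUE)),
    bym = bym_detect(bym_fit(map, cases,
                             spec = settings$spec %||% bym_spec(),
                             seed = seed)),
    stop("unknown method: ", name))
}

#' Read an experiment configuration from YAML
#'
#' Minimal YAML front-end: a `map` section (`type: lattice` with
#' rows/cols/n_districts, or `type: bundle` with a path), a `scenario`
#' section mirroring [scenario_config], a `methods` section and optional
#' `paired_clusters` / `output_dir` keys.
#'
#' @param path YAML file.
#' @return an [experiment_config].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  map <- switch(y$map$type %||% "lattice",
    lattice = make_lattice_map(
      lattice_spec(y$map$rows, y$map$cols,
                   n_districts = y$map$n_districts %||%
                     (y$map$rows * y$map$cols)),
      seed = y$map$seed %||% 1L),
    bundle = load_map_bundle(y$map$path),
    stop("map type must be 'lattice' or 'bundle'"))
  sc_args <- y$scenario %||% list()
  scenario <- do.call(scenario_config, sc_args)
  methods <- y$methods %||% default_methods()
  if (!is.null(methods$bym) && !is.null(methods$bym$spec))
    methods$bym$spec <- do.call(bym_spec, methods$bym$spec)
  else if (!is.null(methods$bym))
    methods$bym$spec <- bym_spec()
  experiment_config(map, scenario, methods,
                    paired_clusters = y$paired_clusters %||% TRUE,
                    output_dir = y$output_dir)
}

#' Plot a performance measure against relative risk
#'
#' Plain metrics-vs-RR line plot (log-scaled RR axis), one line per
#' method, faceted implicitly by filtering to one cluster size first.
#'
#' @param metrics metric table from [run_experiment].
#' @param measure column to plot (e.g. `"sens"`, `"spec"`, `"ppv"`).
#' @param cluster_size which cluster size to display.
#' @return invisibly, the plotted subset.
#' @export
plot_metrics <- function(metrics, measure = "sens",
                         cluster_size = unique(metrics$cluster_size)[1]) {
  sub <- metrics[metrics$cluster_size == cluster_size, ]
  methods <- unique(sub$method)
  cols <- seq_along(methods)
  graphics::plot(NULL, xlim = range(sub$rr), ylim = c(0, 100), log = "x",
                 xlab = "relative risk", ylab = paste0(measure, " (%)"),
                 main = sprintf("cluster size %d", cluster_size))
  for (i in seq_along(methods)) {
    mi <- sub[sub$method == methods[i], ]
    mi <- mi[order(mi$rr), ]
    graphics::lines(mi$rr, mi[[measure]], col = cols[i], type = "b",
                    pch = 19)
  }
  graphics::legend("bottomright", legend = methods, col = cols, lty = 1,
                   pch = 19, bty = "n")
  invisible(sub)
}
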