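#' Confusion counts for one detection result
#'
#' District-level 2x2 table of a detection result against the true
#' cluster: TP = labeled true-cluster districts, FP = labeled
#' normal-risk districts, FN = missed cluster districts, TN = the rest.
#'
#' @param result a `detection_result` (from [bn_detect], [sss_detect] or
#'   [bym_detect]), or a logical label vector.
#' @param truth a `true_cluster`.
#' @param map the [district_map] both refer to.
#' @return a list of class `confusion` with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(result, truth, map) {
  labels <- if (is.logical(result)) result else result$labels
  if (length(labels) != map$H)
    stop("detection result and map refer to different district sets")
  truth_set <- logical(map$H)
  truth_set[truth$members] <- TRUE
  TP <- sum(labels & truth_set)
  FP <- sum(labels & !truth_set)
  FN <- sum(!labels & truth_set)
  TN <- map$H - TP - FP - FN
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN), class = "confusion")
}

#' Aggregate performance measures over simulation iterations
#'
#' Computes the full metric battery for one (method, cluster size, RR)
#' cell from per-iteration confusion counts, on the percent scale:
#' sensitivity, specificity, PPV, NPV, correct classification (CC),
#' exact power (EP: the whole true cluster found with no false
#' positives), minimum power (MP: at least one true district found),
#' positive/negative diagnostic likelihood (PDL = sens/(1-spec),
#' NDL = (1-sens)/spec, from the aggregated means), false positive rate
#' (100 - PPV) and false negative rate (100 - NPV). Per-iteration ratios
#' that are undefined (PPV with nothing labeled; NPV with everything
#' labeled) are excluded from their means and counted. Mean, SD,
#' and the 95% confidence bounds `mean +/- 1.96 * SD/sqrt(n)` are
#' reported for each simple proportion.
#'
#' @param confusions list of `confusion` objects, one per iteration.
#' @param truth_size number of districts in the true cluster.
#' @param H number of districts in the map.
#' @param estimand_samples optional per-iteration values of the
#'   cumulative-RR estimand inside the true cluster; their SD across
#'   iterations is reported as the Monte Carlo error `mce_rr`.
#' @param averaging `"per_iteration"` (average the per-iteration ratios)
#'   or `"pooled"` (pool the confusion counts, then divide).
#' @return a one-row data.frame (a metric row).
#' @export
metrics_from_confusions <- function(confusions, truth_size, H,
                                    estimand_samples = NULL,
                                    averaging = c("per_iteration",
                                                  "pooled")) {
  averaging <- match.arg(averaging)
  n <- length(confusions)
  stopifnot(n >= 1)
  if (truth_size < 1)
    stop("truth_size must be >= 1: the design always designates a cluster")
  TP <- vapply(confusions, `[[`, numeric(1), "TP")
  FP <- vapply(confusions, `[[`, numeric(1), "FP")
  FN <- vapply(confusions, `[[`, numeric(1), "FN")
  TN <- vapply(confusions, `[[`, numeric(1), "TN")
  if (any(TP + FN != truth_size))
    stop("confusion counts inconsistent with truth_size")

  pct <- function(x) 100 * x
  summarize <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0)
      return(c(mean = NA_real_, sd = NA_real_, lci = NA_real_,
               uci = NA_real_))
    m <- mean(pct(x)); s <- sd(pct(x))
    if (length(x) == 1) s <- 0
    se <- s / sqrt(length(x))
    c(mean = m, sd = s, lci = m - 1.96 * se, uci = m + 1.96 * se)
  }

  if (averaging == "per_iteration") {
    sens <- TP / (TP + FN)
    spec <- TN / (TN + FP)
    cc <- (TP + TN) / H
    ppv <- ifelse(TP + FP > 0, TP / (TP + FP), NA_real_)
    npv <- ifelse(TN + FN > 0, TN / (TN + FN), NA_real_)
  } else {
    sens <- sum(TP) / sum(TP + FN)
    spec <- sum(TN) / sum(TN + FP)
    cc <- sum(TP + TN) / (n * H)
    ppv <- if (sum(TP + FP) > 0) sum(TP) / sum(TP + FP) else NA_real_
    npv <- if (sum(TN + FN) > 0) sum(TN) / sum(TN + FN) else NA_real_
  }
  mp <- as.numeric(TP >= 1)
  ep <- as.numeric(TP == truth_size & FP == 0)

  s_sens <- summarize(sens); s_spec <- summarize(spec)
  s_ppv <- summarize(ppv);   s_npv <- summarize(npv)
  s_cc <- summarize(cc); s_mp <- summarize(mp); s_ep <- summarize(ep)

  # diagnostic likelihoods from the aggregated means (per-iteration
  # ratios are frequently undefined under the null)
  pdl <- if (s_spec["mean"] < 100) s_sens["mean"] / (100 - s_spec["mean"]) else Inf
  ndl <- if (s_spec["mean"] > 0) (100 - s_sens["mean"]) / s_spec["mean"] else Inf

  row <- data.frame(
    n_iter = n, truth_size = truth_size,
    sens = s_sens["mean"], sens_sd = s_sens["sd"],
    sens_lci = s_sens["lci"], sens_uci = s_sens["uci"],
    spec = s_spec["mean"], spec_sd = s_spec["sd"],
    spec_lci = s_spec["lci"], spec_uci = s_spec["uci"],
    ppv = s_ppv["mean"], ppv_sd = s_ppv["sd"],
    ppv_lci = s_ppv["lci"], ppv_uci = s_ppv["uci"],
    npv = s_npv["mean"], npv_sd = s_npv["sd"],
    npv_lci = s_npv["lci"], npv_uci = s_npv["uci"],
    ep = s_ep["mean"], ep_sd = s_ep["sd"],
    ep_lci = s_ep["lci"], ep_uci = s_ep["uci"],
    mp = s_mp["mean"], mp_sd = s_mp["sd"],
    mp_lci = s_mp["lci"], mp_uci = s_mp["uci"],
    cc = s_cc["mean"], cc_sd = s_cc["sd"],
    cc_lci = s_cc["lci"], cc_uci = s_cc["uci"],
    pdl = unname(pdl), ndl = unname(ndl),
    fpr = 100 - s_ppv["mean"], fnr = 100 - s_npv["mean"],
    cp = NA_real_,   # "correct proportion": no published definition; left empty
    mce_rr = if (is.null(estimand_samples)) NA_real_
             else sd(estimand_samples),
    n_undefined_ppv = if (averaging == "per_iteration") sum(is.na(ppv)) else 0L,
    n_undefined_npv = if (averaging == "per_iteration") sum(is.na(npv)) else 0L,
    averaging = averaging,
    row.names = NULL)
  rownames(row) <- NULL
  row
}
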