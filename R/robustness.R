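## Generic bracketed binary search for the smallest positive value of a
## monotone-ish predicate over [0, max_x] at the given resolution.
## predicate(0) TRUE -> status "zero"; predicate(max_x) FALSE -> "not_found";
## else halve [largest-negative, smallest-positive] until within `precision`
## and report the positive end.
.bracketed_threshold_search <- function(predicate, max_x, precision) {
  if (predicate(0)) return(list(status = "zero", threshold = 0))
  if (!predicate(max_x)) return(list(status = "not_found",
                                     threshold = NA_real_))
  lo <- 0          # predicate-negative
  hi <- max_x      # predicate-positive
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (predicate(mid)) hi <- mid else lo <- mid
  }
  list(status = "found", threshold = hi)
}

#' IKr reduction threshold
#'
#' Minimal fractional reduction of the maximal IKr conductance that triggers
#' an early afterdepolarization, found by binary search over
#' \[0, 99.99\]\% at 0.01\% precision (coarser \code{precision} available
#' for quick runs).  Each probe applies the candidate reduction on top of
#' the drugged parameters, paces 100 beats from the supplied drugged steady
#' state and checks the final beat for an EAD in the APD30--APD90 plateau
#' window.  The first probe is at the maximal tested reduction (99.99\%) to
#' settle the \code{not_found} status quickly, and 0\% is probed to detect
#' the \code{zero} status (EAD with no perturbation).
#'
#' @param params drugged [ord_params()] (any \code{ikr_reduction} already
#'   present is an error).
#' @param state drugged steady state to probe from (e.g. the terminal state
#'   of a 1000-beat drugged run).
#' @param cl cycle length (ms), 2000 by default.
#' @param precision search resolution in percent (default 0.01).
#' @param n_beats beats paced per probe (default 100).
#' @param max_reduction largest reduction tested, in percent.
#' @return Object of class \code{"threshold_result"}: list with
#'   \code{threshold} (percent, \code{NA} unless status \code{"found"}),
#'   \code{status} (\code{"found"}, \code{"zero"} or \code{"not_found"}),
#'   \code{cl}, \code{precision}, \code{probes} (data frame of every probe),
#'   \code{anomaly} (\code{TRUE} when the probe set is not monotone in the
#'   reduction, logged rather than fatal).
#' @export
ikr_reduction_threshold <- function(params, state, cl = 2000,
                                    precision = 0.01, n_beats = 100,
                                    max_reduction = 99.99) {
  stopifnot(inherits(params, "ord_params"))
  if (params$ikr_reduction != 0)
    stop("params must carry no prior ikr_reduction", call. = FALSE)
  protocol <- pacing_protocol(cl = cl, n_beats = n_beats)
  probes <- data.frame(reduction = numeric(), ead = logical())

  probe <- function(red_pct) {
    p <- params
    p$ikr_reduction <- red_pct / 100
    res <- tryCatch(pace_to_steady_state(state, p, protocol),
                    error = function(e)
                      stop(sprintf("EAD-indeterminate probe at %.4f%%: %s",
                                   red_pct, conditionMessage(e)),
                           call. = FALSE))
    b <- res$beats[[length(res$beats)]]
    e <- detect_ead(b, window = "plateau")
    # a depolarized, never-repolarizing beat counts as a repolarization
    # failure, i.e. EAD-positive for thresholding purposes
    if (is.na(e)) e <- b$V[length(b$V)] > -40
    probes[nrow(probes) + 1L, ] <<- list(red_pct, e)
    e
  }

  res <- .bracketed_threshold_search(probe, max_reduction, precision)
  status <- res$status
  threshold <- res$threshold
  pos <- probes$reduction[probes$ead]
  neg <- probes$reduction[!probes$ead]
  anomaly <- length(pos) > 0 && length(neg) > 0 && min(pos) < max(neg)
  if (anomaly)
    warning("non-monotone EAD window across probes; reporting the smallest ",
            "EAD-positive boundary", call. = FALSE)
  structure(list(threshold = threshold, status = status, cl = cl,
                 precision = precision, probes = probes, anomaly = anomaly),
            class = "threshold_result")
}

#' Threshold table across drugs and doses
#'
#' Runs a drugged 1000-beat steady state followed by
#' [ikr_reduction_threshold()] for each (drug, dose) pair.
#'
#' @param drugs named list of [drug_profile()]s.
#' @param doses concentration multiples.
#' @param cl cycle length (ms).
#' @param params baseline parameters.
#' @param precision,n_probe_beats passed to [ikr_reduction_threshold()].
#' @param n_steady_beats drugged pre-beats before the search.
#' @param quiet suppress progress messages.
#' @return \code{data.frame} with columns \code{drug}, \code{conc_multiple},
#'   \code{cl}, \code{threshold}, \code{status}.
#' @export
threshold_table <- function(drugs, doses, cl = 2000, params = ord_params(),
                            precision = 0.01, n_probe_beats = 100,
                            n_steady_beats = 1000, quiet = TRUE) {
  control <- control_steady_state(cl, params)
  rows <- list()
  for (dn in names(drugs)) {
    for (dose in doses) {
      if (!quiet) message("threshold: ", dn, " @ ", dose, "x")
      drugged <- apply_drug(params, drugs[[dn]], dose)
      res <- pace_to_steady_state(control$state, drugged,
                                  pacing_protocol(cl = cl,
                                                  n_beats = n_steady_beats))
      th <- ikr_reduction_threshold(drugged, res$state, cl = cl,
                                    precision = precision,
                                    n_beats = n_probe_beats)
      rows[[length(rows) + 1]] <-
        data.frame(drug = dn, conc_multiple = dose, cl = cl,
                   threshold = th$threshold, status = th$status,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between a metric and the IKr reduction threshold
#'
#' Correlates a drug's metric values (steady state, no added reduction)
#' with its thresholds across a concentration series.  Pairs whose status
#' is \code{zero} or \code{not_found} are excluded; fewer than 3 remaining
#' pairs raise an insufficient-data error.
#'
#' @param metric numeric metric series (same order as \code{threshold}).
#' @param threshold numeric threshold series (percent).
#' @param status character status series.
#' @return Pearson correlation coefficient.
#' @export
metric_threshold_correlation <- function(metric, threshold, status) {
  if (length(metric) != length(threshold) ||
      length(metric) != length(status))
    stop("series must have equal length", call. = FALSE)
  keep <- status == "found" & !is.na(metric) & !is.na(threshold)
  if (sum(keep) < 3)
    stop("insufficient data: need >= 3 valid (found) pairs, have ",
         sum(keep), call. = FALSE)
  stats::cor(metric[keep], threshold[keep], method = "pearson")
}

#' Correlation table across drugs
#'
#' Joins a metric panel table with a threshold table by (drug, dose) and
#' computes the per-drug Pearson correlation of each requested metric with
#' the IKr reduction threshold.  Drugs with fewer than 3 valid pairs get
#' \code{NA} with a note.
#'
#' @param panel_table output of [metric_panel_table()].
#' @param thresholds output of [threshold_table()].
#' @param metrics metric column names to correlate.
#' @return \code{data.frame}: drug, one column per metric, \code{n_valid}.
#' @export
threshold_correlation_table <- function(panel_table, thresholds,
                                        metrics = c("qNet", "APD90",
                                                    "cqInward")) {
  drugs <- unique(thresholds$drug)
  rows <- lapply(drugs, function(dn) {
    th <- thresholds[thresholds$drug == dn, ]
    pm <- panel_table[panel_table$drug == dn, ]
    m <- merge(th, pm, by = c("drug", "conc_multiple"))
    vals <- lapply(metrics, function(mc) {
      tryCatch(metric_threshold_correlation(m[[mc]], m$threshold, m$status),
               error = function(e) NA_real_)
    })
    out <- data.frame(drug = dn, stringsAsFactors = FALSE)
    for (k in seq_along(metrics)) out[[metrics[k]]] <- vals[[k]]
    out$n_valid <- sum(m$status == "found")
    out
  })
  do.call(rbind, rows)
}
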