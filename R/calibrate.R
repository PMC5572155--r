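#' Calibration targets
#'
#' One target row per (condition, cycle length, APD fraction): the desired
#' APD value, its experimental SD (optional) and a weight.  When SDs are
#' supplied, weights default to \code{1/SD^2}; otherwise equal weights.
#'
#' @param condition label, \code{"control"} or a name from
#'   [calibration_block_conditions()].
#' @param cl cycle length (ms).
#' @param fraction repolarization fraction (0.3/0.5/0.7/0.9).
#' @param apd_ms target APD (ms).
#' @param sd_ms experimental SD (ms), \code{NA} for unweighted.
#' @param weight explicit weights; default \code{1/sd_ms^2} or 1.
#' @return \code{data.frame} of class \code{"calibration_targets"}.
#' @export
calibration_targets <- function(condition, cl, fraction, apd_ms,
                                sd_ms = NA, weight = NULL) {
  n <- length(apd_ms)
  sd_ms <- rep_len(sd_ms, n)
  if (is.null(weight))
    weight <- ifelse(is.na(sd_ms), 1, 1 / sd_ms^2)
  if (any(!is.na(sd_ms) & sd_ms <= 0))
    stop("sd_ms must be > 0 when supplied", call. = FALSE)
  if (any(cl <= 0)) stop("cycle lengths must be positive", call. = FALSE)
  structure(data.frame(condition = condition, cl = cl, fraction = fraction,
                       apd_ms = apd_ms, sd_ms = sd_ms, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("calibration_targets", "data.frame"))
}

#' Read / write calibration target CSVs
#'
#' Column layout: \code{condition, cl, fraction, apd_ms, sd_ms, weight}.
#'
#' @param path CSV file path.
#' @param targets a [calibration_targets()] table.
#' @return \code{read_calibration_targets} returns the targets table.
#' @export
read_calibration_targets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  calibration_targets(df$condition, df$cl, df$fraction, df$apd_ms,
                      if ("sd_ms" %in% names(df)) df$sd_ms else NA,
                      if ("weight" %in% names(df)) df$weight else NULL)
}

#' @rdname read_calibration_targets
#' @export
write_calibration_targets <- function(targets, path) {
  utils::write.csv(targets, path, row.names = FALSE)
  invisible(path)
}

#' Simulated APDs for a scaler set over the target conditions
#'
#' Paces the model to steady state once per (condition, CL) and measures
#' every APD fraction the targets request.
#'
#' @param scaling a [conductance_scaling()] object (or coercible vector).
#' @param targets a [calibration_targets()] table.
#' @param n_beats pacing beats per condition (reduced inside the optimizer
#'   loop for tractability).
#' @return The targets table with columns \code{apd_sim} and \code{failed}
#'   (EAD/alternans/no-repolarization at that condition).
#' @export
simulate_calibration_apds <- function(scaling, targets, n_beats = 200) {
  if (!inherits(scaling, "conductance_scaling"))
    scaling <- do.call(conductance_scaling, as.list(scaling))
  conds <- calibration_block_conditions()
  out <- targets
  out$apd_sim <- NA_real_
  out$failed <- FALSE
  combos <- unique(targets[, c("condition", "cl")])
  for (r in seq_len(nrow(combos))) {
    cond <- combos$condition[r]
    cl <- combos$cl[r]
    if (!cond %in% names(conds))
      stop("unknown block condition: ", cond, call. = FALSE)
    p <- ord_params(scaling = scaling)
    if (length(conds[[cond]])) p <- apply_block_condition(p, conds[[cond]])
    res <- tryCatch(
      pace_to_steady_state(ord_initial_state(), p,
                           pacing_protocol(cl = cl, n_beats = n_beats)),
      error = function(e) NULL)
    sel <- targets$condition == cond & targets$cl == cl
    if (is.null(res)) { out$failed[sel] <- TRUE; next }
    b2 <- res$beats[[length(res$beats)]]
    b1 <- res$beats[[1]]
    bad <- isTRUE(detect_ead(b2, "repolarization")) ||
      detect_alternans(b1, b2) || is.na(apd(b2, 0.9))
    if (bad) { out$failed[sel] <- TRUE; next }
    for (i in which(sel)) out$apd_sim[i] <- apd(b2, targets$fraction[i])
  }
  out
}

#' Calibration objective
#'
#' Weighted sum of squared errors between simulated and target APDs,
#' \eqn{\sum_i w_i (APD_{sim,i} - APD_{target,i})^2}.  Conditions where the
#' model fails (EAD, alternans, failed repolarization, solver failure)
#' contribute a large penalty per affected target and are logged with a
#' warning.
#'
#' @inheritParams simulate_calibration_apds
#' @param penalty cost added per failed target row.
#' @return Scalar cost.
#' @export
calibration_objective <- function(scaling, targets, n_beats = 200,
                                  penalty = 1e6) {
  sim <- simulate_calibration_apds(scaling, targets, n_beats)
  if (any(sim$failed))
    warning("calibration: ", sum(sim$failed),
            " target(s) failed (EAD/alternans/no repolarization); ",
            "penalized", call. = FALSE)
  ok <- !sim$failed & !is.na(sim$apd_sim)
  sum(sim$weight[ok] * (sim$apd_sim[ok] - sim$apd_ms[ok])^2) +
    penalty * sum(!ok)
}

#' Optimizer configuration
#'
#' @param lower,upper per-scaler search bounds (default \[0.001, 9\]).
#' @param pop_size population size.
#' @param f differential-mutation weight.
#' @param cr crossover probability.
#' @param max_generations generation budget.
#' @param conv_tol,conv_window convergence rule: stop when the minimum cost
#'   improves by less than \code{conv_tol} (relative, default 5\%) over the
#'   last \code{conv_window} generations (default 30).
#' @param seed random seed (recorded; all randomness flows through it).
#' @return List of class \code{"optimizer_config"}.
#' @export
optimizer_config <- function(lower = rep(0.001, 5), upper = rep(9, 5),
                             pop_size = 40, f = 0.7, cr = 0.9,
                             max_generations = 200, conv_tol = 0.05,
                             conv_window = 30, seed = 1) {
  if (any(lower <= 0) || any(upper <= lower))
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  if (pop_size < 4) stop("pop_size must be >= 4", call. = FALSE)
  structure(list(lower = lower, upper = upper, pop_size = pop_size,
                 f = f, cr = cr, max_generations = max_generations,
                 conv_tol = conv_tol, conv_window = conv_window,
                 seed = seed),
            class = "optimizer_config")
}

#' Evolutionary calibration of the five conductance scalers
#'
#' Differential-evolution-style search (rand/1/bin mutation and
#' recombination with elitist replacement) minimizing
#' [calibration_objective()] within the configured bounds.  Converges when
#' the minimum cost improves by less than the configured relative tolerance
#' over the trailing window of generations; if the generation budget runs
#' out first, the best-so-far point is returned with a warning.  Seeded runs
#' are reproducible.
#'
#' @param targets a [calibration_targets()] table.
#' @param config an [optimizer_config()].
#' @param n_beats pacing beats per objective evaluation.
#' @param objective objective function \code{f(scalers, targets, n_beats)};
#'   replaceable for testing with cheap surrogates.
#' @param quiet suppress per-generation messages.
#' @return List of class \code{"calibration_result"}: \code{scaling}
#'   (best [conductance_scaling()]), \code{cost}, \code{trace}
#'   (per-generation minimum cost, non-increasing), \code{converged},
#'   \code{generations}, \code{config}.
#' @export
optimize_conductances <- function(targets, config = optimizer_config(),
                                  n_beats = 200,
                                  objective = calibration_objective,
                                  quiet = TRUE) {
  stopifnot(inherits(config, "optimizer_config"))
  set.seed(config$seed)
  d <- length(config$lower)
  np <- config$pop_size
  lo <- config$lower
  hi <- config$upper
  # Latin-hypercube initial population, always including all-ones
  pop <- sapply(seq_len(d), function(j)
    lo[j] + (hi[j] - lo[j]) * (sample(np) - stats::runif(np)) / np)
  pop[1, ] <- pmin(pmax(rep(1, d), lo), hi)
  cost <- apply(pop, 1, function(x) objective(x, targets, n_beats))
  trace <- min(cost)
  converged <- FALSE
  gen <- 0
  while (gen < config$max_generations) {
    gen <- gen + 1
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3)
      trial <- pop[idx[1], ] + config$f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < config$cr
      cross[sample(d, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lo), hi)
      tc <- objective(trial, targets, n_beats)
      if (tc <= cost[i]) {       # elitist: never lose the incumbent best
        pop[i, ] <- trial
        cost[i] <- tc
      }
    }
    trace <- c(trace, min(cost))
    if (!quiet) message("generation ", gen, " min cost ", min(cost))
    w <- config$conv_window
    if (gen >= w) {
      prev <- trace[length(trace) - w]
      now <- trace[length(trace)]
      if (prev == 0 || (prev - now) / max(prev, .Machine$double.eps) <
            config$conv_tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("generation budget exhausted without convergence; ",
            "returning best-so-far", call. = FALSE)
  best <- which.min(cost)
  sc <- stats::setNames(pop[best, ],
                        c("IKr", "IKs", "IK1", "ICaL", "INaL")[seq_len(d)])
  structure(list(scaling = if (d == 5) do.call(conductance_scaling,
                                               as.list(sc)) else sc,
                 cost = cost[best], trace = trace, converged = converged,
                 generations = gen, config = config),
            class = "calibration_result")
}
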