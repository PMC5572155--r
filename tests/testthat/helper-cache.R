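## Shared memoization for expensive simulations so that independent test
## blocks can reuse the same steady states and drug runs.  Everything is
## deterministic, so caching cannot change outcomes.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

## control steady state (snapshot + 2 top-up beats)
ctrl2000 <- function() cached("ctrl2000", control_steady_state(2000))
ctrl1000 <- function() cached("ctrl1000", control_steady_state(1000))

ctrl_beat2000 <- function() {
  r <- ctrl2000()
  r$beats[[length(r$beats)]]
}

drug_panel <- function() cached("panel", fixture_drug_panel())

## one drugged condition at CL 2000, memoized by drug/dose
drug_run <- function(drug_name, dose, n_beats = 1000) {
  cached(sprintf("run_%s_%g_%d", drug_name, dose, n_beats),
         simulate_drug_condition(drug_panel()[[drug_name]], dose,
                                 cl = 2000, control = ctrl2000(),
                                 n_beats = n_beats))
}

## metric panel over a dose set (classification-scale), memoized
panel_at_doses <- function(doses, n_beats = 1000) {
  rows <- list(cached("ctrl_panel_row", {
    cb <- ctrl_beat2000()
    cbind(data.frame(drug = "control", conc_multiple = 0, cl = 2000,
                     stringsAsFactors = FALSE),
          metric_panel(cb, cb, prev_beat = ctrl2000()$beats[[1]]))
  }))
  for (dn in names(drug_panel()))
    for (ds in doses)
      rows[[length(rows) + 1]] <- drug_run(dn, ds, n_beats)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## drugged steady state + IKr-reduction threshold, memoized (coarse
## precision and reduced pre-beats keep the suite inside its time budget)
drug_threshold <- function(drug_name, dose, precision = 0.5,
                           n_steady_beats = 500) {
  cached(sprintf("thr_%s_%g_%g_%d", drug_name, dose, precision,
                 n_steady_beats), {
    drugged <- apply_drug(ord_params(), drug_panel()[[drug_name]], dose)
    ss <- pace_to_steady_state(ctrl2000()$state, drugged,
                               pacing_protocol(cl = 2000,
                                               n_beats = n_steady_beats))
    ikr_reduction_threshold(drugged, ss$state, cl = 2000,
                            precision = precision)
  })
}
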