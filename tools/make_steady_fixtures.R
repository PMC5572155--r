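#!/usr/bin/env Rscript
## Regenerates inst/extdata/steady_state_cl{1000,2000,4000}.csv:
## the optimized control model paced for 1000 beats at each cycle length.
## Run from the package root after installing the package.
library(cipaord)
params <- ord_params()   # optimized scaling, no drug
for (cl in c(1000, 2000, 4000)) {
  res <- pace_to_steady_state(ord_initial_state(), params,
                              pacing_protocol(cl = cl, n_beats = 1000))
  out <- data.frame(state = names(res$state),
                    value = sprintf("%.17g", res$state))
  write.csv(out, sprintf("inst/extdata/steady_state_cl%d.csv", cl),
            row.names = FALSE, quote = FALSE)
  message("CL ", cl, " done")
}
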