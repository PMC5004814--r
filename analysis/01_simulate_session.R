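#!/usr/bin/env Rscript
# Stage 1 — generate the default synthetic recording session.
#
# Builds one session of the FFF/FMS/SMF/SSS discrimination task: 50 trials
# per sequence, 28 units spanning the five response archetypes (9 Fast,
# 3 Medium, 3 SlowPos, 3 SlowNeg, 10 Unmodulated), behavior driven by a
# logistic psychometric of mean panel speed. Writes the session tables
# under results/session/ for the downstream stages.

suppressPackageStartupMessages(library(vibrotact))

out_dir <- "results"
cfg <- session_config(seed = 1L)
session <- generate_session(cfg)
write_session(session, file.path(out_dir, "session"))

cat("Generated synthetic session:\n")
cat(sprintf("  %d trials (%d per stimulus), %d units\n",
            nrow(session$trials), cfg$n_trials_per_stimulus,
            nrow(session$units)))
print(table(session$units$true_class))
cat("Right-choice fraction by stimulus:\n")
print(round(tapply(session$trials$choice == "right",
                   session$trials$stimulus, mean), 3))
cat(sprintf("  %d spikes total; written to %s/session/\n",
            nrow(session$spikes), out_dir))
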