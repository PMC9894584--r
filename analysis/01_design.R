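#!/usr/bin/env Rscript
# Stimulus geometry and session design: builds the 8-dot layout, enumerates
# the constrained sequences, generates one main-task session and the
# localizer schedule, and checks the deterministic design numbers.

suppressPackageStartupMessages(library(srmap))
dir.create("results", showWarnings = FALSE)

layout <- build_layout(radius = 7, n_locations = 8)
cat("Dot angles (deg, clockwise from vertical):",
    paste(layout$angles, collapse = ", "), "\n")
cat(sprintf("Neighbouring dots are %.1f dva apart; quadrant-separated dots %.1f dva; opposite dots %.1f dva.\n",
            chord_distance(layout, 1, 2), chord_distance(layout, 1, 3),
            chord_distance(layout, 1, 5)))

specs <- enumerate_sequences(layout)
cat(length(specs), "constrained sequences; start 1 visits locations:",
    paste(specs[[1]]$sequence_indices, collapse = "-"), "\n")

scale <- calibrate_iti_scale(2, 10.9, 3.72)
cat(sprintf("Calibrated ITI scale: %.4f s (truncated exponential on [2, 10.9] s, mean 3.72 s)\n",
            scale))

design <- build_session(specs[[1]], n_runs = 3, seed = 20260101)
ev <- design$events
cat(sprintf("Session: %d trials (%d full / %d partial), %d delayed; runs last %s min.\n",
            nrow(ev), sum(ev$trial_type == "full"),
            sum(ev$trial_type != "full"), sum(ev$delayed),
            paste(sprintf("%.1f", design$run_duration_s / 60),
                  collapse = ", ")))
stopifnot(all(ev$iti_s >= 2 & ev$iti_s <= 10.9))
write_events(ev, "results/session_events.tsv")

localizer <- build_localizer_schedule(layout, seed = 20260102)
cat(sprintf("Localizer: %d stimulation blocks, total %.0f s (%.1f min).\n",
            sum(!localizer$blocks$rest), localizer$total_duration_s,
            localizer$total_duration_s / 60))
write_events(localizer$blocks, "results/localizer_blocks.tsv")

jsonlite::write_json(
  list(radius_dva = layout$radius, angles_deg = layout$angles,
       dot_diameter_dva = layout$dot_diameter,
       sequence_starts = vapply(specs, function(s) s$sequence_indices[1],
                                integer(1))),
  "results/layout.json", auto_unbox = TRUE, digits = NA, pretty = TRUE
)
cat("Wrote results/session_events.tsv, results/localizer_blocks.tsv, results/layout.json\n")
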