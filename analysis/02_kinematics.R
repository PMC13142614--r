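#!/usr/bin/env Rscript
# Kinematic processing: recover movement onsets/offsets from the simulated
# motion capture, apply the 4-SD trial-exclusion rules, and derive rest
# segments for the self-paced joint session.

library(msom)
ges <- load_session("results/data/gesture")
jnt <- load_session("results/data/joint")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

speed <- sensor_speed(ges$kinematics)
bounds <- detect_movement_bounds(
  speed, ges$trials$visual_cue_t, threshold_fraction = 0.1,
  sensors = intersect(c("hand_index", "hand_pinky"), speed$sensor_labels))
err_on <- bounds$onset_t - ges$trials$onset_t
cat(sprintf("Detected %d/%d movements; median |onset error| %.0f ms\n",
            sum(!bounds$no_movement), nrow(bounds),
            1000 * median(abs(err_on), na.rm = TRUE)))

hand <- structure(list(time_s = speed$time_s,
                       speed = speed$speed["hand", , drop = FALSE],
                       sensor_labels = "hand"), class = "msom_speed")
wrist <- structure(list(time_s = speed$time_s,
                        speed = speed$speed["wrist", , drop = FALSE],
                        sensor_labels = "wrist"), class = "msom_speed")
trials <- exclude_trials(ges$trials, hand, wrist)
cat(sprintf("Excluded %d/%d trials (%s)\n", sum(trials$excluded),
            nrow(trials),
            paste(unique(trials$exclusion_reason[trials$excluded]),
                  collapse = ", ")))
write.table(trials, "results/tables/gesture_trials.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

jspeed <- sensor_speed(jnt$kinematics)
rest <- find_rest_segments(jspeed,
                           movements = cbind(jnt$trials$onset_t,
                                             jnt$trials$offset_t))
cat(sprintf("Joint session: %d rest windows of 0.5 s\n", nrow(rest)))
write.table(as.data.frame(rest), "results/tables/joint_rest_windows.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
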