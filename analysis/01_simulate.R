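#!/usr/bin/env Rscript
# Generate the synthetic study data: a cued gesture-transition session with a
# planted motor footprint, a self-paced isolated-joint session with a nested
# distal-to-proximal footprint hierarchy, and matching motion-capture traces.
# Everything downstream (02-06) reads the session directories written here.

library(msom)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
set.seed(100)

geometry <- build_default_geometry(16, 16)   # desk-scale grid, 400 um pitch

## gesture session: a hand-area footprint responding to every transition,
## plus extra drive on extension transitions (hand opening recruits more
## cortex than closing) so the flexion/extension comparison has signal.
## iti 1.2 s stands in for the task's 1 s feedback display, keeping
## adjacent movements out of each trial's +/- 2 s exclusion epoch.
gesture_schedule <- make_gesture_schedule(48, "balanced_random", seed = 101,
                                          iti_s = 1.2)
hand_fp <- footprint("all", c(7.5, 7.5), spatial_scale_cells = 3,
                     amplitude_db = 3)
# one sub-territory per transition (extensions stronger than flexions)
class_fps <- list(
  footprint("rock->paper",    c(5.5, 5.5), 1.5, amplitude_db = 2.5),
  footprint("rock->scissors", c(5.5, 9.5), 1.5, amplitude_db = 2.5),
  footprint("paper->rock",    c(9.5, 5.5), 1.5, amplitude_db = 1.5),
  footprint("scissors->rock", c(9.5, 9.5), 1.5, amplitude_db = 1.5))
ges <- simulate_session(geometry, c(list(hand_fp), class_fps),
                        gesture_schedule, seed = 102)
ges$session$kinematics <- simulate_kinematics(gesture_schedule, seed = 103,
                                              noise_amp = 2e-4, tail_s = 2.5)
save_session(ges$session, file.path(out, "gesture"))

## joint session: concentric territories, digits out to shoulder
effectors <- c("digits", "wrist", "forearm", "elbow", "shoulder")
nested <- make_nested_footprints(geometry, effectors, base_scale = 0.6,
                                 growth = 1.6, amplitude_db = 6)
joint_schedule <- make_joint_schedule(effectors, reps = 10, gap_s = 2.6,
                                      block_gap_s = 4, seed = 104)
jnt <- simulate_session(geometry, nested, joint_schedule, seed = 105)
jnt$session$kinematics <- simulate_kinematics(
  joint_schedule, sensors = c(effectors, "hand", "wrist_arm"),
  noise_amp = 0, seed = 106)
save_session(jnt$session, file.path(out, "joint"))

## ground truth sidecars
jsonlite::write_json(
  list(gesture = list(center = hand_fp$center_cell,
                      scale_cells = hand_fp$spatial_scale_cells,
                      amplitude_db = hand_fp$amplitude_db,
                      true_mask_cells = sum(true_mask(hand_fp, geometry))),
       joint = lapply(nested, function(f)
         list(effector = f$effector_label,
              scale_cells = f$spatial_scale_cells,
              true_mask_cells = sum(true_mask(f, geometry))))),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE, digits = NA)

cat("Wrote gesture session:", nrow(ges$session$trials), "trials,",
    nrow(ges$session$voltage), "channels\n")
cat("Wrote joint session:", nrow(jnt$session$trials), "movements over",
    length(effectors), "effectors\n")
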