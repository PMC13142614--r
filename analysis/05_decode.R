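#!/usr/bin/env Rscript
# Temporal-generalization decoding of the four gesture transitions and the
# coupling between encoding strength (EoA) and decoding performance.

library(msom)
ges <- load_session("results/data/gesture")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

hg <- epoched_hg_db(ges, t_range = c(-1.1, 1.0), hop_s = 0.01)
w <- causal_windows(hg, t_range = c(-1, 1), step = 0.05)
labs <- hg$trials$label
kept <- balance_classes(labs, seed = 501)
cat(sprintf("Balancing kept %d/%d trials over %d classes\n",
            length(kept), length(labs), length(unique(labs))))
w$features <- lapply(w$features, function(f) f[kept, , drop = FALSE])
tg <- temporal_generalization(w, labs[kept], seed = 502)

diag_acc <- diag(tg$accuracy)
cat(sprintf("Chance %.3f; peak diagonal accuracy %.2f at %+.0f ms\n",
            tg$chance, max(diag_acc), 1000 * w$times[which.max(diag_acc)]))
write.table(data.frame(time_s = w$times, accuracy = diag_acc,
                       auc = diag(tg$auc)),
            "results/tables/decode_diagonal.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(round(tg$accuracy, 4), "results/tables/decode_tgm.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sc <- symmetric_confusion(tg$confusion)
cat("Most confused pair:",
    paste(rownames(sc)[which(sc == max(sc, na.rm = TRUE),
                             arr.ind = TRUE)[1, ]], collapse = " vs "),
    sprintf("(rate %.2f)\n", max(sc, na.rm = TRUE)))

## encoding-decoding coupling
tcs <- read.table("results/tables/gesture_eoa_timecourse.tsv", header = TRUE,
                  sep = "\t")
cc <- encode_decode_coupling(tcs$time_s, tcs$eoa, w$times, diag(tg$auc))
cat(sprintf("EoA vs diagonal AUC: r = %.2f (p = %.3g)\n", cc$r, cc$p))
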