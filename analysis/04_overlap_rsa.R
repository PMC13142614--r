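#!/usr/bin/env Rscript
# Somatotopic overlap and representational similarity on the joint session:
# per-effector effect maps against the kinematic rest pool, Dice/area/
# non-overlap matrix, Euclidean RDM over grid-flattened dB maps, metric MDS
# with Kruskal stress, Ward dendrogram, and the population PCA.

library(msom)
jnt <- load_session("results/data/joint")
rest <- as.matrix(read.table("results/tables/joint_rest_windows.tsv",
                             header = TRUE, sep = "\t"))
effectors <- c("digits", "wrist", "forearm", "elbow", "shoulder")
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

ems <- map_effectors(jnt, rest_windows = rest, labels = effectors,
                     n_perm = 1000, seed = 401)
masks <- lapply(seq_along(ems), function(i)
  activation_mask(ems[[i]], label = effectors[i]))
sizes <- vapply(masks, function(m) sum(m$cells), 0)
cat("Active electrodes per effector:",
    paste(effectors, sizes, sep = "=", collapse = ", "), "\n")
nested_ok <- all(vapply(1:4, function(i)
  all(!masks[[i]]$channels | masks[[i + 1]]$channels), TRUE))
cat("Strict distal-to-proximal mask containment:", nested_ok, "\n")

om <- overlap_matrix(masks)
write.table(data.frame(label = rownames(om), round(om, 4)),
            "results/tables/joint_overlap_matrix.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Dice(digits, wrist) = %.2f; Dice(digits, shoulder) = %.2f\n",
            om["digits", "wrist"], om["digits", "shoulder"]))

## RSA on trial-averaged dB maps
mr <- movement_rest_power(jnt, rest_windows = rest)
dbs <- vapply(effectors, function(e) {
  mov <- which(mr$labels == 1)[mr$trials$label == e]
  10 * log10(rowMeans(mr$power[, mov, drop = FALSE]) /
               rowMeans(mr$power[, mr$labels == 0, drop = FALSE]))
}, numeric(nrow(mr$power)))
fv <- feature_vectors(dbs, jnt$geometry)
rdm <- rdm_euclidean(fv)
save_results(rdm, "results/tables/joint_rdm.tsv")

mds <- mds_embed(rdm, dims = 2, seed = 402)
cat(sprintf("2-D MDS Kruskal stress: %.3f\n", mds$stress))
write.table(data.frame(effector = effectors, round(mds$coords, 4)),
            "results/tables/joint_mds.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tree <- ward_tree(fv)
save_results(tree, "results/tables/joint_tree.nwk")
cat("Ward dendrogram:", tree_newick(tree), "\n")

## population PCA of the trial-averaged response
hg <- epoched_hg_db(jnt, t_range = c(-0.5, 0.8), hop_s = 0.02,
                    baseline = "onset")
avg <- apply(hg$db, c(2, 3), mean)           # channels x time
pca <- population_pca(avg, k = 5)
cat("Population PCA explained variance:",
    round(pca$explained_variance, 3), "\n")
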