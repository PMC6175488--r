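#!/usr/bin/env Rscript
# Stage 2: landmark QC, user averaging, Procrustes alignment with
# semi-landmark sliding, and the PCA / phylogenetic-PCA trait spaces.

library(beakrates)

inp <- "results/01_simulate"
out <- "results/02_shapespace"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tree <- read_newick(file.path(inp, "tree.nwk"))
markups <- read_markups(file.path(inp, "markups.csv"))
ledger <- read.csv(file.path(inp, "corruption_ledger.csv"))

# ---- QC every specimen -------------------------------------------------
qc <- lapply(markups, qc_markups, d_max = 0.2)
qc_df <- do.call(rbind, lapply(names(qc), function(sp) {
  df <- qc[[sp]]$users
  cbind(specimen = sp, df,
        measurement_error = qc[[sp]]$measurement_error)
}))
write.csv(qc_df, file.path(out, "qc_report.csv"), row.names = FALSE)

truly_bad <- paste(ledger$specimen, paste0("u", ledger$user))
flagged <- paste(qc_df$specimen, qc_df$user)[!qc_df$accepted]
cat("QC rejected", length(flagged), "of", nrow(qc_df), "markups;",
    sum(truly_bad %in% flagged), "of", length(truly_bad),
    "known-corrupted users caught;",
    sum(!(flagged %in% truly_bad)), "honest users rejected.\n")

# ---- user averaging and alignment -------------------------------------
averaged <- lapply(names(markups), function(sp) {
  keep <- qc[[sp]]$users$accepted
  if (!any(keep)) keep <- rep(TRUE, length(keep))
  average_markups(markups[[sp]]$users[keep])
})
names(averaged) <- names(markups)

ali <- gpa(averaged)
ali <- slide_semilandmarks(ali, n_iter = 3)
cat("GPA + sliding: total Procrustes SS", format(ali$ss, digits = 4),
    "; bending energy per pass (before -> after):\n")
print(round(ali$bending, 5))

# ---- trait spaces ------------------------------------------------------
sub_tree <- ape::keep.tip(tree, names(markups))
pca <- shape_pca(ali)
ppca <- shape_ppca(ali, sub_tree)
write_shape_space(pca, out, "pca")
write_shape_space(ppca, out, "ppca")

scores <- select_axes(pca, cum_var = 0.99)
cat("PCA:", ncol(scores), "axes explain 99% of shape variance",
    sprintf("(leading axis %.1f%%).\n", 100 * pca$var_fraction[1]))
write.csv(data.frame(species = rownames(scores), scores),
          file.path(out, "selected_scores.csv"), row.names = FALSE)
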