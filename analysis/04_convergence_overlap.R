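#!/usr/bin/env Rscript
# Stage 4: protein-level convergence filter and three-way evidence overlap.
#
# Keeps genes with omega_c >= 3 in any2spe mode on branch pairs touching
# each ecomorph's foreground, then cross-references selection, rate
# association, and omega_c evidence per ecomorph.

suppressMessages(library(ecoconv))

dir <- "results/study"
out <- "results"
tree <- read_time_tree(file.path(dir, "timetree.nwk"))
map <- read_tsv_schema(file.path(dir, "species_map.tsv"))
meta <- make_branch_metadata(tree, map)
omega <- read_omega_c(file.path(dir, "omega_c.tsv"))

rows <- list()
for (e in c("trawler", "gleaner", "aerial_hawker")) {
  fg <- foreground_branches(meta, e)
  selected <- read_gene_set(file.path(out, paste0("selected_", e, ".txt")))
  assoc <- read_tsv_schema(file.path(out, paste0("rer_assoc_", e, ".tsv")))
  rer_sig <- assoc$gene[assoc$significant]
  omega_sig <- filter_omega_c(omega, threshold = 3, mode = "any2spe",
                              foreground = fg)
  ov <- overlap_evidence(selected, rer_sig, omega_sig)
  cat(sprintf(
    "%-14s selected=%d rer=%d omega=%d | sel&rer=%.3f sel&omega=%.3f rer&omega(J)=%.3f\n",
    e, length(selected), length(rer_sig), length(omega_sig),
    ov$overlap_fractions["selected_in_rer"],
    ov$overlap_fractions["selected_in_omega"],
    ov$overlap_fractions["rer_omega_jaccard"]))
  rows[[e]] <- data.frame(ecomorph = e, n_selected = length(selected),
                          n_rer = length(rer_sig), n_omega = length(omega_sig),
                          t(ov$overlap_fractions))
}
write_tsv_schema(do.call(rbind, rows), file.path(out, "evidence_overlap.tsv"))
cat("Per-ecomorph overlap table written to results/evidence_overlap.tsv\n")
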