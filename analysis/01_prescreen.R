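#!/usr/bin/env Rscript
# Stage 1 of the synthetic screening walk-through: build a small toy
# library, require a carboxylic acid, and filter by Gaussian shape overlap
# against a retinoid-like query, mimicking the ligand-based prescreen of a
# carboxylate-directed virtual screen.  Writes results/01_prescreen.tsv.

suppressMessages(library(consdock))
set.seed(101)

dir.create("results", showWarnings = FALSE)

query <- gen_toy_ligand("retinoid_like")
lib <- list(
  benzoic_acid = gen_toy_ligand("benzoic_acid"),
  phthalimide  = gen_toy_ligand("isoindoline_dione"),
  hybrid       = gen_toy_ligand("n_butyl_isoindoline_benzoate"),
  query_twin   = query
)
# jittered decoys around the query, plus compact blobs
for (k in 1:4) {
  x <- graph_coords(query) + matrix(rnorm(3 * n_atoms(query), sd = 0.15),
                                    ncol = 3)
  lib[[sprintf("near%02d", k)]] <- set_graph_coords(query, x)
}

res <- run_pipeline(pipeline_config(), library = lib, query = query)
print(res$stage_reports)
cat("\nsubstructure survivors:",
    paste(res$survivors$substructure, collapse = ", "), "\n")
cat("shape survivors:", paste(res$survivors$shape, collapse = ", "), "\n")

desc <- basic_descriptors(lib[res$survivors$substructure])
dl <- druglike_check(desc)
cat("\nRule-of-Five screen:\n"); print(dl)

write.table(res$stage_reports, "results/01_prescreen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nwrote results/01_prescreen.tsv\n")
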