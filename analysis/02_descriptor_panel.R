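#!/usr/bin/env Rscript
# Stage 2: compute the chemical descriptor panel for a molecule set.
# The generated molecules span a polarity gradient (0-4 polar groups on an
# alkyl scaffold); point the read_smiles() call at a real .smi file to run
# on database structures.

suppressMessages(library(metabochem))
dir.create("results/descriptors", recursive = TRUE, showWarnings = FALSE)

mols <- gen_molecule_set(300, seed = 202)
writeLines(paste(mols$smiles, mols$id), "results/descriptors/molecules.smi")

panel <- build_panel(read_smiles("results/descriptors/molecules.smi"))
write_panel(panel, "results/descriptors/panel.tsv")

cat(sprintf("computed %d descriptor panels (%d failures)\n",
            nrow(panel), length(attr(panel, "failures"))))
means <- tapply(panel$logp, mols$n_polar[match(panel$id, mols$id)], mean)
cat("mean logP by polar-group count:",
    paste(sprintf("%d:%.2f", as.integer(names(means)), means), collapse = "  "),
    "\n")
cat("monotone polarity gradient:", all(diff(means) < 0), "\n")
cat("stage 2 outputs in results/descriptors/\n")
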