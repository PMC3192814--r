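#!/usr/bin/env Rscript
# Stage 5: concentration-governed network expansion.  Twenty replicate
# runs at the reference parameters (and a second series with ten edges per
# step) show the scale-free degree organisation emerging from the
# concentration rules alone.

suppressMessages(library(metabochem))
dir.create("results/simulation", recursive = TRUE, showWarnings = FALSE)

for (m_edges in c(5, 10)) {
  cfg <- sim_config(m = m_edges)
  tab <- summarize_replicates(cfg, seeds = 1:20)
  utils::write.table(tab, sprintf("results/simulation/replicates_m%d.tsv",
                                  m_edges),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("m = %2d: mean nodes %.1f, mean edges %.0f, exponent b %.2f +/- %.2f, r^2 >= 0.8 in %d/20 runs\n",
              m_edges, mean(tab$n_nodes), mean(tab$n_edges), mean(tab$b),
              sd(tab$b), sum(tab$r_squared >= 0.8)))
}

# one exemplar run kept in full for inspection
res <- run_simulation(sim_config(seed = 505))
write_network_graphml(res$network, "results/simulation/run_seed505.graphml")
utils::write.table(res$histogram, "results/simulation/run_seed505_histogram.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_power_law_fit(res$powerlaw, "results/simulation/run_seed505_powerlaw.json")
print(res)
cat("stage 5 outputs in results/simulation/\n")
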