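#!/usr/bin/env Rscript
# Stage 1: reconstruct a substrate-product network from a screened
# reaction list.  Uses a generated reaction set with known ground truth so
# the screening arithmetic is verifiable end to end; swap in a real
# reaction TSV + annotation TSV to run on database extracts.

suppressMessages(library(metabochem))
dir.create("results/network", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(n_metabolites = 120, n_reactions = 90, seed = 101)
gen <- gen_reaction_set(cfg)
write_reactions(gen$reactions, "results/network/reactions.tsv")
write_annotations(gen$annotations, "results/network/annotations.tsv")

reactions <- parse_reactions("results/network/reactions.tsv")
annotations <- read_annotations("results/network/annotations.tsv")
filtered <- filter_reactions(reactions, annotations)
net <- build_network(filtered)
deg <- compute_degrees(net)
hist <- degree_histogram(deg)

cat(sprintf("parsed %d reactions; %d survive screening (expected %d)\n",
            length(reactions), length(filtered), gen$truth$n_surviving))
cat(sprintf("network: %d nodes, %d edges (expected %d / %d)\n",
            length(net$nodes), nrow(net$edges),
            gen$truth$n_nodes, gen$truth$n_edges))

write_edge_list(net, "results/network/edges.tsv")
write_network_graphml(net, "results/network/network.graphml")
write_degree_table(deg, "results/network/degrees.tsv")

if (length(unique(hist$degree[hist$degree > 0])) >= 3) {
  fit <- fit_power_law(hist)
  print(fit)
  write_power_law_fit(fit, "results/network/powerlaw.json")
}
cat("stage 1 outputs in results/network/\n")
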