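#!/usr/bin/env Rscript
# Stage 3: relate network degree to metabolite chemistry.  A degree-linked
# synthetic network (hubs carry polar molecules) stands in for a database
# extract; the statistics are the ones used on real networks: per-group
# mean +/- SE, Kruskal-Wallis across degree groups, Pearson correlation of
# bin means against bin rank, and an early/late metabolome comparison.

suppressMessages(library(metabochem))
dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

gen <- gen_degree_linked_network(400, strength = 0.9, seed = 303)
panel <- build_panel(gen$molecules[, c("id", "smiles")])
write_panel(panel, "results/stats/panel.tsv")
write_degree_table(gen$degree_table, "results/stats/degrees.tsv")

scheme <- degree_scheme(c("1-2", "3-5", "6-10", ">10"),
                        c(1, 3, 6, 11), c(2, 5, 10, Inf))
summary_tab <- descriptor_group_summary(gen$degree_table, panel, scheme,
                                        descriptors = c("logp", "logs",
                                                        "fpsa3", "fnsa3",
                                                        "rpcg"))
utils::write.table(summary_tab, "results/stats/group_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cors <- lapply(c("logp", "logs", "fpsa3"), function(d) {
  merged <- merge(gen$degree_table, panel, by = "id")
  gs <- group_by_degree(data.frame(degree = merged$degree,
                                   value = merged[[d]]), scheme)
  r <- binned_correlation(gs)
  cat(sprintf("degree-%s binned correlation: R = %.3f (p = %.2g, %d bins)\n",
              d, r$R, r$p, r$n_bins))
  c(descriptor = d, r)
})
jsonlite::write_json(cors, "results/stats/binned_correlations.json",
                     auto_unbox = TRUE, digits = NA)

# early/late comparison.  Early metabolites are those of the oldest enzyme
# class; here the oldest enzymes are attached to the network hubs (the
# evolutionary reading of preferential attachment), so polar chemistry
# should concentrate in the early set.
by_degree <- gen$degree_table$id[order(-gen$degree_table$degree)]
old_mets <- by_degree[1:160]
young_mets <- setdiff(gen$network$nodes, old_mets)
emap <- list(E_ancient = old_mets, E_recent = young_mets)
cls <- classify_age(gen$network$nodes, emap,
                    c(E_ancient = "1", E_recent = "4"))
lp <- setNames(panel$logp, panel$id)
mw <- mann_whitney(lp[cls$early], lp[cls$late])
cat(sprintf("early (n=%d) vs late (n=%d) logP: U = %.1f, p = %.3g\n",
            length(cls$early), length(cls$late), mw$U, mw$p))
jsonlite::write_json(list(n_early = length(cls$early),
                          n_late = length(cls$late),
                          logp_mean_early = mean(lp[cls$early]),
                          logp_mean_late = mean(lp[cls$late]),
                          U = mw$U, p = mw$p),
                     "results/stats/early_late.json",
                     auto_unbox = TRUE, digits = NA)
cat("stage 3 outputs in results/stats/\n")
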