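#!/usr/bin/env Rscript
# Stage 4: model metabolite concentrations from chemistry.  Concentrations
# are generated from the published polarity equation plus noise, then
# recovered by stepwise regression; an epsilon-SVR over the full feature
# set is scored by leave-one-out cross validation, and descriptor-deletion
# importance ranks the features.

suppressMessages(library(metabochem))
dir.create("results/models", recursive = TRUE, showWarnings = FALSE)

mols <- gen_molecule_set(200, seed = 404)
panel <- build_panel(mols[, c("id", "smiles")])
d <- gen_concentration_data(panel, noise_sigma = 0.5, n_decoys = 16,
                            seed = 405)
write_concentrations(d$concentrations, "results/models/concentrations.tsv")

# stepwise multiple linear regression over 4 true + 16 decoy descriptors
m <- stepwise_mlr(d$features, d$concentrations$neg_log_c)
cat("stepwise selection recovered: ")
print(m)
write_linear_model(m, "results/models/stepwise_model.json")

# the published equation as a fixed evaluator on the same molecules
pub <- published_concentration_model()
pred_pub <- apply_linear_model(pub, d$features)
cat(sprintf("published-equation fit on generated data: r^2 = %.3f\n",
            cor(pred_pub, d$concentrations$neg_log_c)^2))

# epsilon-SVR at the published parameters, scored by LOOCV
feat <- d$features[, c("ClogP", "FNSA3", "FPSA3", "RPCG")]
cv <- loocv(svr_spec(), feat, d$concentrations$neg_log_c)
print(cv)
jsonlite::write_json(list(squared_correlation = cv$squared_correlation,
                          total_mse = cv$total_mse,
                          identity_slope = cv$identity_slope),
                     "results/models/svr_loocv.json",
                     auto_unbox = TRUE, digits = NA)

# small grid search around the published optimum, then deletion importance
gs <- grid_search(svr_spec(), feat, d$concentrations$neg_log_c,
                  gamma_grid = c(0.003, 0.01, 0.03, 0.1),
                  epsilon_grid = c(0.1, 0.22, 0.34),
                  cost_grid = c(2, 7.9, 20))
cat(sprintf("grid search best: gamma = %g, epsilon = %g, cost = %g (r^2 = %.3f)\n",
            gs$spec$gamma, gs$spec$epsilon, gs$spec$cost,
            gs$report$squared_correlation))

imp <- descriptor_importance(svr_spec(), feat, d$concentrations$neg_log_c,
                             gamma_grid = c(0.01, 0.1),
                             epsilon_grid = 0.22, cost_grid = 7.9)
print(imp)
utils::write.table(imp, "results/models/descriptor_importance.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("stage 4 outputs in results/models/\n")
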