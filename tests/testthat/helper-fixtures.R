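# Shared fixtures, built in code at test time.

write_reaction_file <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

simple_annotations <- function(ids, macro = character(0), rgroup = character(0),
                               currency = character(0)) {
  data.frame(id = ids,
             is_macromolecule = ids %in% macro,
             has_r_group = ids %in% rgroup,
             is_currency = ids %in% currency,
             stringsAsFactors = FALSE)
}

# random reaction lists for property-style tests
random_reactions <- function(n_rxn, n_met, seed) {
  set.seed(seed)
  mets <- sprintf("X%02d", seq_len(n_met))
  lapply(seq_len(n_rxn), function(i) {
    ns <- sample(1:3, 1); np <- sample(1:3, 1)
    reaction(paste0("R", i), sample(mets, ns), sample(mets, np))
  })
}

# n-alkanols C1..C8 (monotone polarity series)
alkanols <- paste0(vapply(1:8, function(k) strrep("C", k), character(1)), "O")

# ordinary least squares on (x, y) via explicit normal equations -- the
# independent oracle for every regression-slope check
ols_by_hand <- function(x, y) {
  n <- length(x)
  sxx <- n * sum(x^2) - sum(x)^2
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / sxx
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}
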