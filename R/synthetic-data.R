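# Seeded generators that emulate the statistical structure every pipeline
# stage assumes: reaction lists with currency/macromolecule/R-group members,
# molecule sets spanning a polarity gradient, concentrations that are linear
# in polarity descriptors on the -Log10 scale, degree-linked chemistry, and
# enzyme-age annotations.  Each generator is a pure function of its
# arguments + seed and emits its own ground truth for self-validation.

#' Bundle synthetic-data generation parameters
#'
#' @param n_metabolites,n_reactions Sizes of the generated reaction system.
#' @param frac_currency,frac_macromolecule,frac_rgroup Fractions of
#'   metabolites flagged as currency / macromolecule / R-group carriers
#'   (must sum to < 1).
#' @param mlr_beta Generating model for concentrations: a
#'   [linear_model()] (default: the published polarity equation).
#' @param noise_sigma Gaussian noise sd on the -Log10 concentration scale.
#' @param n_descriptor_decoys Number of pure-noise decoy descriptors.
#' @param seed Integer seed.
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(n_metabolites = 60, n_reactions = 40,
                         frac_currency = 0.15, frac_macromolecule = 0.10,
                         frac_rgroup = 0.05,
                         mlr_beta = published_concentration_model(),
                         noise_sigma = 0.5, n_descriptor_decoys = 16,
                         seed = 1) {
  fr <- c(frac_currency, frac_macromolecule, frac_rgroup)
  stopifnot(all(fr >= 0), sum(fr) < 1, noise_sigma >= 0,
            n_metabolites >= 4, n_reactions >= 1)
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_reactions = as.integer(n_reactions),
                 frac_currency = frac_currency,
                 frac_macromolecule = frac_macromolecule,
                 frac_rgroup = frac_rgroup,
                 mlr_beta = mlr_beta, noise_sigma = noise_sigma,
                 n_descriptor_decoys = as.integer(n_descriptor_decoys),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Write a reaction list in the package's TSV format
#'
#' @param reactions List of reaction objects.
#' @param path Output path.
#' @export
write_reactions <- function(reactions, path) {
  lines <- vapply(reactions, function(r) {
    paste0(r$id, "\t", paste(r$substrates, collapse = " + "), " = ",
           paste(r$products, collapse = " + "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a metabolite annotation table
#'
#' @param annotations Data frame as produced by [gen_reaction_set()].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate a reaction set with known screening outcome
#'
#' Builds a reaction list embedding four reaction categories: clean
#' small-molecule reactions (possibly decorated with currency metabolites on
#' both sides), reactions containing a macromolecule member, reactions
#' containing an R-group member, and currency-only reactions. Category
#' counts are deterministic functions of the config fractions
#' (`floor(n_reactions * frac)` for macromolecule and R-group reactions,
#' `floor(n_reactions * frac_currency / 2)` currency-only), so the expected
#' screening outcome is known by construction: macromolecule/R-group
#' reactions are deleted, currency-only reactions empty out, and clean
#' reactions survive with their currency decorations stripped.
#'
#' The emitted `truth` element records the expected surviving reactions and
#' the expected deduplicated substrate-product edge set, computed directly
#' from the generator's own bookkeeping (not by calling the screening
#' functions), so the screening pipeline can be validated against it.
#'
#' @param config A [synth_config()].
#' @return List with `reactions` (list of reaction objects), `annotations`
#'   (data frame), and `truth` (list: `n_surviving`, `n_deleted_macro_rgroup`,
#'   `n_emptied_currency`, `n_edges`, `n_nodes`, `edges` data frame).
#' @export
gen_reaction_set <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_metabolites
  ids <- sprintf("M%04d", seq_len(n))
  n_cur <- round(config$frac_currency * n)
  n_mac <- round(config$frac_macromolecule * n)
  n_rg <- round(config$frac_rgroup * n)
  n_clean <- n - n_cur - n_mac - n_rg
  if (n_clean < 4) stop("infeasible config: too few clean metabolites")
  pool <- sample(ids)
  currency <- pool[seq_len(n_cur)]
  macromol <- pool[n_cur + seq_len(n_mac)]
  rgroup <- pool[n_cur + n_mac + seq_len(n_rg)]
  clean <- pool[(n_cur + n_mac + n_rg + 1):n]

  nr <- config$n_reactions
  n_mac_rxn <- if (n_mac > 0) floor(nr * config$frac_macromolecule) else 0
  n_rg_rxn <- if (n_rg > 0) floor(nr * config$frac_rgroup) else 0
  n_cur_rxn <- if (n_cur >= 2) floor(nr * config$frac_currency / 2) else 0
  n_clean_rxn <- nr - n_mac_rxn - n_rg_rxn - n_cur_rxn
  if (n_clean_rxn < 1) stop("infeasible config: no clean reactions left")

  draw_clean_sides <- function() {
    ns <- sample(1:min(3, n_clean - 1), 1)
    np <- sample(1:min(3, n_clean - ns), 1)
    picked <- sample(clean, ns + np)
    list(subs = picked[seq_len(ns)], prods = picked[ns + seq_len(np)])
  }
  decorate <- function(side) {
    if (n_cur > 0 && stats::runif(1) < 0.5) c(side, sample(currency, 1)) else side
  }

  reactions <- list()
  survivors <- list()  # post-screen substrate/product sets, by construction
  rid <- 0
  for (i in seq_len(n_clean_rxn)) {
    rid <- rid + 1
    s <- draw_clean_sides()
    reactions[[rid]] <- reaction(sprintf("R%04d", rid),
                                 decorate(s$subs), decorate(s$prods))
    survivors[[length(survivors) + 1]] <- s
  }
  for (i in seq_len(n_mac_rxn)) {
    rid <- rid + 1
    s <- draw_clean_sides()
    subs <- c(s$subs, sample(macromol, 1))
    reactions[[rid]] <- reaction(sprintf("R%04d", rid), subs, s$prods)
  }
  for (i in seq_len(n_rg_rxn)) {
    rid <- rid + 1
    s <- draw_clean_sides()
    prods <- c(s$prods, sample(rgroup, 1))
    reactions[[rid]] <- reaction(sprintf("R%04d", rid), s$subs, prods)
  }
  for (i in seq_len(n_cur_rxn)) {
    rid <- rid + 1
    picked <- sample(currency, 2)
    reactions[[rid]] <- reaction(sprintf("R%04d", rid), picked[1], picked[2])
  }

  annotations <- data.frame(
    id = ids,
    is_macromolecule = ids %in% macromol,
    has_r_group = ids %in% rgroup,
    is_currency = ids %in% currency,
    stringsAsFactors = FALSE)

  # expected edge set from the generator's own clean reaction sides
  froms <- character(0); tos <- character(0)
  for (s in survivors) {
    pairs <- expand.grid(a = s$subs, b = s$prods, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    froms <- c(froms, pmin(pairs$a, pairs$b))
    tos <- c(tos, pmax(pairs$a, pairs$b))
  }
  edges <- unique(data.frame(from = froms, to = tos, stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  list(reactions = reactions, annotations = annotations,
       truth = list(n_surviving = length(survivors),
                    n_deleted_macro_rgroup = n_mac_rxn + n_rg_rxn,
                    n_emptied_currency = n_cur_rxn,
                    n_edges = nrow(edges),
                    n_nodes = length(unique(c(edges$from, edges$to))),
                    edges = edges))
}

# Polar decorations by charge asymmetry: donor-rich groups put positive
# partial charge on exchangeable hydrogens, acceptor-only groups carry
# negative heteroatom charge without N-H/O-H hydrogens.
.donor_groups <- c(hydroxyl = "O", amine = "N", acid = "C(=O)O",
                   phosphate = "OP(=O)(O)O", amide = "C(N)=O",
                   urea = "NC(N)=O", carbamate = "OC(N)=O",
                   guanidine = "NC(=N)N")
.acceptor_groups <- c(ketone = "C(C)=O", nitrile = "C#N",
                      nitro = "[N+](=O)[O-]", ester = "C(=O)OC",
                      acetoxy = "OC(C)=O")
.apolar_groups <- c(methyl = "C", chloro = "Cl", fluoro = "F",
                    thiol = "S", trifluoromethyl = "C(F)(F)F",
                    thioether = "SC", dimethylamine = "N(C)C")

#' Generate a molecule set spanning a polarity gradient
#'
#' Molecules are built from a small fragment grammar: an alkyl chain of 2-8
#' carbons decorated with 0-4 polar substituents and 0-2 weakly polar or
#' apolar ones (chloro, fluoro, methyl). Each molecule is drawn from one of
#' three chemical archetypes that differ in charge asymmetry -- donor-rich
#' (hydroxyl, amine, acid, phosphate, amide: positive charge on
#' exchangeable hydrogens), acceptor-only (tertiary amine, ketone, ether,
#' nitrile, ester: negative heteroatom charge with no N-H/O-H), or mixed --
#' mirroring the way real metabolomes split into amine-, acid- and
#' sugar-like classes. This makes the charged-partial-surface-area
#' descriptors vary independently rather than along a single polarity axis.
#' The polar-group count is recorded per molecule, giving a known polarity
#' ordering: group means of the computed logP decrease as it rises.
#'
#' @param n Number of molecules (>= 4).
#' @param seed Integer seed.
#' @param max_chain Maximum chain length (default 8).
#' @param max_polar Maximum number of polar substituents (default 4).
#' @return Data frame `id`, `smiles`, `n_polar`, `chain_length`.
#' @export
gen_molecule_set <- function(n, seed = 1, max_chain = 8, max_polar = 4) {
  stopifnot(n >= 4, max_chain >= 2)
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    L <- sample(2:max_chain, 1)
    k <- sample(0:min(max_polar, L), 1)
    k2 <- sample(0:min(2, L - k), 1)
    pool <- switch(sample(c("donor", "acceptor", "mixed"), 1),
                   donor = .donor_groups,
                   acceptor = .acceptor_groups,
                   mixed = c(.donor_groups, .acceptor_groups))
    groups <- c(if (k > 0) sample(pool, k, replace = TRUE),
                if (k2 > 0) sample(.apolar_groups, k2, replace = TRUE))
    pos <- if (length(groups) > 0) sample(seq_len(L), length(groups)) else integer(0)
    atoms <- rep("C", L)
    for (j in seq_along(pos)) {
      atoms[pos[j]] <- paste0("C(", groups[j], ")")
    }
    data.frame(id = sprintf("S%04d", i), smiles = paste(atoms, collapse = ""),
               n_polar = k, chain_length = L, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate concentrations linear in polarity descriptors
#'
#' Emulates the structure assumed by the concentration regression:
#' `-LogC_i = beta0 + sum(beta * x_i) + eps_i` with Gaussian noise on the
#' -Log10 scale (log-normal concentrations, consistent with metabolite
#' concentrations spanning orders of magnitude). The generating
#' coefficients default to the published polarity equation, so recovery
#' studies are a direct analogue of the real regression. Decoy descriptors
#' are appended as independent standard-normal noise columns.
#'
#' @param panel Descriptor panel ([build_panel()]) covering the generating
#'   model's descriptors via the mapping ClogP = `logp`, FNSA3 = `fnsa3`,
#'   FPSA3 = `fpsa3`, RPCG = `rpcg`.
#' @param beta Generating [linear_model()] (default
#'   [published_concentration_model()]).
#' @param noise_sigma Gaussian noise sd (default 0.5).
#' @param n_decoys Number of decoy descriptors (default 16).
#' @param seed Integer seed.
#' @return List with `features` (data frame: true descriptors under the
#'   model's names + `decoy_01` ...), `concentrations` (data frame `id`,
#'   `concentration`, `neg_log_c`), and `beta` (the generating model).
#' @export
gen_concentration_data <- function(panel, beta = published_concentration_model(),
                                   noise_sigma = 0.5, n_decoys = 16, seed = 1) {
  set.seed(seed)
  map <- c(ClogP = "logp", FNSA3 = "fnsa3", FPSA3 = "fpsa3", RPCG = "rpcg")
  nm <- names(beta$terms)
  X <- data.frame(row.names = seq_len(nrow(panel)))
  for (term in nm) {
    col <- if (term %in% names(map)) map[[term]] else term
    if (!col %in% names(panel)) stop("panel lacks descriptor for term ", term)
    X[[term]] <- panel[[col]]
  }
  keep <- stats::complete.cases(X)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " molecule(s) with undefined descriptors")
    X <- X[keep, , drop = FALSE]
    panel <- panel[keep, , drop = FALSE]
  }
  n <- nrow(X)
  for (d in seq_len(n_decoys)) {
    X[[sprintf("decoy_%02d", d)]] <- stats::rnorm(n)
  }
  neg_log_c <- apply_linear_model(beta, X) + stats::rnorm(n, 0, noise_sigma)
  conc <- data.frame(id = panel$id, concentration = 10^(-neg_log_c),
                     neg_log_c = neg_log_c, stringsAsFactors = FALSE)
  rownames(X) <- NULL
  list(features = X, concentrations = conc, beta = beta)
}

#' Generate a network whose hubs carry polar chemistry
#'
#' Grows a preferential-attachment network (igraph's Barabasi-Albert
#' sampler) and assigns molecules from [gen_molecule_set()] to its nodes so
#' that polarity rank tracks degree rank with configurable strength:
#' at `strength = 1` the most polar molecules sit on the highest-degree
#' nodes; at `strength = 0` the assignment is random.
#'
#' @param n Number of nodes (>= 20).
#' @param strength Rank-coupling strength in `[0, 1]`.
#' @param seed Integer seed.
#' @param m Edges added per node in the attachment process (default 2).
#' @return List with `network` (`"metabolic_network"`), `degree_table`, and
#'   `molecules` (data frame `id`, `smiles`, `n_polar`, node-aligned).
#' @export
gen_degree_linked_network <- function(n, strength = 1, seed = 1, m = 2) {
  stopifnot(n >= 20, strength >= 0, strength <= 1)
  set.seed(seed)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  ids <- sprintf("N%04d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(from = ids[pmin(el[, 1], el[, 2])],
                      to = ids[pmax(el[, 1], el[, 2])],
                      stringsAsFactors = FALSE)
  edges <- unique(edges[edges$from != edges$to, , drop = FALSE])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  network <- structure(list(nodes = ids, edges = edges),
                       class = "metabolic_network")
  degree_table <- compute_degrees(network)

  mols <- gen_molecule_set(n, seed = seed + 1)
  # couple polarity rank to degree rank: nodes are scored by a blend of
  # their degree rank and independent noise, then the molecules (sorted by
  # polarity) are laid onto nodes in score order
  z_deg <- scale(rank(degree_table$degree, ties.method = "random"))[, 1]
  score <- strength * z_deg +
    sqrt(max(0, 1 - strength^2)) * stats::rnorm(n)
  mol_order <- order(mols$n_polar, -mols$chain_length)  # least polar first
  node_order <- order(score)                            # lowest degree-score first
  molecules <- mols[mol_order, , drop = FALSE]
  molecules$id <- ids[node_order]
  molecules <- molecules[order(molecules$id), , drop = FALSE]
  rownames(molecules) <- NULL
  list(network = network, degree_table = degree_table, molecules = molecules)
}

#' Generate enzyme-age annotations with known early/late partition
#'
#' Emits an enzyme-to-metabolite map, enzyme age classes (ordinal `"1"`
#' oldest to `"5"` youngest), an aerobic-metabolite set, and the expected
#' early/late partition of the network nodes, constructed so that
#' [classify_age()] must reproduce it: the chosen early nodes are attached
#' to oldest-class enzymes, aerobic metabolites are additional oldest-class
#' metabolites excluded from the early set, and every other node belongs to
#' younger enzyme classes (or none).
#'
#' @param network_nodes Character vector of network metabolite ids.
#' @param frac_early Fraction of nodes made early (default 0.4).
#' @param frac_aerobic Fraction of nodes made aerobic oldest-class
#'   metabolites (default 0.1).
#' @param seed Integer seed.
#' @return List with `enzyme_metabolite_map`, `enzyme_ages`, `aerobic`,
#'   `expected_early`, `expected_late`.
#' @export
gen_age_annotations <- function(network_nodes, frac_early = 0.4,
                                frac_aerobic = 0.1, seed = 1) {
  stopifnot(length(network_nodes) >= 5, frac_early >= 0, frac_aerobic >= 0,
            frac_early + frac_aerobic <= 1)
  set.seed(seed)
  n <- length(network_nodes)
  shuffled <- sample(network_nodes)
  n_early <- round(frac_early * n)
  n_aer <- round(frac_aerobic * n)
  early <- shuffled[seq_len(n_early)]
  aerobic <- shuffled[n_early + seq_len(n_aer)]
  rest <- shuffled[-(seq_len(n_early + n_aer))]

  old_mets <- c(early, aerobic)
  enzyme_metabolite_map <- list()
  enzyme_ages <- character(0)
  e <- 0
  add_enzyme <- function(mets, age) {
    e <<- e + 1
    id <- sprintf("E%04d", e)
    enzyme_metabolite_map[[id]] <<- mets
    enzyme_ages[id] <<- age
  }
  # oldest-class enzymes cover the early + aerobic metabolites
  i <- 1
  while (i <= length(old_mets)) {
    take <- min(sample(1:3, 1), length(old_mets) - i + 1)
    add_enzyme(old_mets[i:(i + take - 1)], "1")
    i <- i + take
  }
  # younger enzymes over the remaining nodes
  i <- 1
  while (i <= length(rest)) {
    take <- min(sample(1:3, 1), length(rest) - i + 1)
    add_enzyme(rest[i:(i + take - 1)], as.character(sample(2:5, 1)))
    i <- i + take
  }
  list(enzyme_metabolite_map = enzyme_metabolite_map,
       enzyme_ages = enzyme_ages, aerobic = aerobic,
       expected_early = sort(early),
       expected_late = sort(setdiff(network_nodes, early)))
}
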