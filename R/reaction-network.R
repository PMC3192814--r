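#' Parse a reaction list file
#'
#' Reads a tab-separated reaction list in the format used throughout this
#' package to emulate small-molecule reaction databases: one reaction per
#' line, `"RID<TAB>A + B = C + D"`, where `" + "` separates species within a
#' side and `" = "` separates substrates from products. Lines starting with
#' `#` and blank lines are skipped. Stoichiometric coefficients are not part
#' of the format: duplicate mentions of a metabolite on one side collapse to
#' a set, and reversibility is ignored (every reaction is treated as an
#' undirected substrate-product relation).
#'
#' @param path Path to the reaction file.
#' @return A list of reaction objects, each a list with elements `id`,
#'   `substrates` (character vector) and `products` (character vector).
#' @seealso [filter_reactions()], [build_network()]
#' @export
parse_reactions <- function(path) {
  if (!file.exists(path)) stop("reaction file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  reactions <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    line <- lines[i]
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2 || !nzchar(trimws(parts[1]))) {
      stop("malformed reaction line ", i, ": expected 'id<TAB>equation'")
    }
    rid <- trimws(parts[1])
    eq <- paste(parts[-1], collapse = "\t")
    sides <- strsplit(eq, " = ", fixed = TRUE)[[1]]
    if (length(sides) != 2) {
      stop("malformed reaction line ", i, ": equation must contain one ' = '")
    }
    split_side <- function(s) {
      sp <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
      sp <- sp[nzchar(sp)]
      unique(sp)
    }
    subs <- split_side(sides[1])
    prods <- split_side(sides[2])
    if (length(subs) == 0 || length(prods) == 0) {
      stop("malformed reaction line ", i, ": empty reaction side")
    }
    reactions[[k]] <- reaction(rid, subs, prods)
  }
  reactions
}

#' Construct a reaction object
#'
#' @param id Reaction identifier (non-blank string).
#' @param substrates,products Character vectors of metabolite ids; duplicates
#'   are collapsed (reactions are over sets, not multisets).
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, substrates, products) {
  id <- as.character(id)
  if (length(id) != 1 || !nzchar(trimws(id))) stop("reaction id must be a non-blank string")
  substrates <- unique(as.character(substrates))
  products <- unique(as.character(products))
  if (any(!nzchar(substrates)) || any(!nzchar(products))) {
    stop("blank metabolite id in reaction ", id)
  }
  structure(list(id = id, substrates = substrates, products = products),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  cat(x$id, ": ", paste(x$substrates, collapse = " + "), " = ",
      paste(x$products, collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Read a metabolite annotation table
#'
#' Annotations drive reaction screening: macromolecule and R-group flags
#' cause whole-reaction deletion, currency flags cause per-metabolite
#' removal. Flags must be explicit for every metabolite referenced by the
#' reaction list; a missing annotation is an error, never treated as TRUE.
#'
#' @param path TSV with header columns `id`, `is_macromolecule`,
#'   `has_r_group`, `is_currency` and optionally `smiles`.
#' @return A data frame with logical flag columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "is_macromolecule", "has_r_group", "is_currency")
  missing_cols <- setdiff(required, names(ann))
  if (length(missing_cols) > 0) {
    stop("annotation file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in required[-1]) ann[[col]] <- as.logical(ann[[col]])
  if (anyNA(ann[required[-1]])) stop("annotation flags must be explicit TRUE/FALSE")
  if (anyDuplicated(ann$id)) stop("duplicate metabolite ids in annotation file")
  ann
}

#' Screen reactions for network reconstruction
#'
#' Applies the three screening rules used to reduce a raw reaction list to
#' small-molecule chemistry: (i) any reaction containing a macromolecule
#' (polymer, protein, nucleic acid) or a metabolite with an unspecified
#' R-group residue is deleted entirely; (ii) currency metabolites (gases,
#' metal ions, ubiquitous cofactors such as ATP or NAD) are removed from the
#' substrate and product sets of the remaining reactions, so that they do not
#' create spurious shortcut edges; (iii) reactions left with an empty side
#' are dropped. The screen is idempotent.
#'
#' A currency metabolite that genuinely is the chemistry of a particular
#' reaction can be kept there via `currency_overrides`, a named list mapping
#' reaction id to the currency ids to retain in that reaction only.
#'
#' @param reactions List of reaction objects.
#' @param annotations Data frame as returned by [read_annotations()]; every
#'   metabolite mentioned in `reactions` must have a row.
#' @param currency_overrides Optional named list: reaction id -> character
#'   vector of currency metabolite ids to keep in that reaction.
#' @return The filtered list of reaction objects.
#' @export
filter_reactions <- function(reactions, annotations, currency_overrides = NULL) {
  mentioned <- unique(unlist(lapply(reactions, function(r) c(r$substrates, r$products))))
  unknown <- setdiff(mentioned, annotations$id)
  if (length(unknown) > 0) {
    stop("no annotation for metabolite(s): ", paste(unknown, collapse = ", "))
  }
  macro <- annotations$id[annotations$is_macromolecule | annotations$has_r_group]
  currency <- annotations$id[annotations$is_currency]
  out <- list()
  for (r in reactions) {
    members <- c(r$substrates, r$products)
    if (any(members %in% macro)) next
    keep <- currency_overrides[[r$id]]
    drop_ids <- setdiff(currency, keep)
    subs <- setdiff(r$substrates, drop_ids)
    prods <- setdiff(r$products, drop_ids)
    if (length(subs) == 0 || length(prods) == 0) next
    out[[length(out) + 1L]] <- reaction(r$id, subs, prods)
  }
  out
}

#' Build the undirected substrate-product network
#'
#' Every substrate of a reaction is connected to every product of the same
#' reaction (complete bipartite expansion per reaction). Self-pairs are
#' dropped, edges are deduplicated across reactions, and the result is a
#' simple undirected graph. Metabolites that appear only in degenerate
#' edge-less reactions are excluded from the node set.
#'
#' @param reactions List of (already filtered) reaction objects.
#' @return An object of class `"metabolic_network"`: a list with `nodes`
#'   (character vector) and `edges` (two-column data frame `from`/`to`,
#'   each pair ordered lexicographically, rows sorted).
#' @export
build_network <- function(reactions) {
  froms <- character(0)
  tos <- character(0)
  for (r in reactions) {
    if (length(r$substrates) == 0 || length(r$products) == 0) next
    pairs <- expand.grid(s = r$substrates, p = r$products,
                         stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    pairs <- pairs[pairs$s != pairs$p, , drop = FALSE]
    froms <- c(froms, pmin(pairs$s, pairs$p))
    tos <- c(tos, pmax(pairs$s, pairs$p))
  }
  if (length(froms) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- unique(data.frame(from = froms, to = tos, stringsAsFactors = FALSE))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a metabolic network to an igraph object
#'
#' @param network A `"metabolic_network"`.
#' @return An undirected [igraph::graph] with the same nodes and edges.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' Node degrees of a metabolic network
#'
#' Degree is the number of distinct edges incident to a node; the table
#' always satisfies the handshake identity (sum of degrees = twice the edge
#' count) and lists every network node exactly once.
#'
#' @param network A `"metabolic_network"`.
#' @return Data frame with columns `id` and `degree`, in node order.
#' @export
compute_degrees <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  counts <- table(factor(c(network$edges$from, network$edges$to),
                         levels = network$nodes))
  data.frame(id = network$nodes, degree = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Degree histogram
#'
#' @param degree_table Data frame with a `degree` column ([compute_degrees()]).
#' @return Data frame `degree`/`count`, ascending in degree; degrees with
#'   zero count are omitted. Counts sum to the number of nodes.
#' @export
degree_histogram <- function(degree_table) {
  if (nrow(degree_table) == 0) stop("empty degree table")
  tab <- table(degree_table$degree)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab),
             row.names = NULL)
}

#' Fit a power law N = a * D^-b to a degree histogram
#'
#' Ordinary least squares of log10(count) on log10(degree), the conventional
#' straight-line fit of a degree histogram on doubly logarithmic axes. The
#' returned exponent is `b = -slope`, the prefactor `a = 10^intercept`, and
#' `r_squared` is the coefficient of determination of the log-log regression.
#' Only degrees with nonzero counts enter the fit (zero-count degrees never
#' appear in [degree_histogram()] output); degree 0 rows, which have no
#' logarithm, are excluded.
#'
#' @param hist Data frame `degree`/`count` with at least 3 distinct positive
#'   degrees.
#' @return An object of class `"power_law_fit"`: list with `a`, `b`,
#'   `r_squared` and `degrees_used`.
#' @export
fit_power_law <- function(hist) {
  hist <- hist[hist$degree > 0 & hist$count > 0, , drop = FALSE]
  if (length(unique(hist$degree)) < 3) {
    stop("insufficient data: need at least 3 distinct positive degrees")
  }
  x <- log10(hist$degree)
  y <- log10(hist$count)
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate
  structure(list(a = 10^unname(stats::coef(fit)[1]),
                 b = -unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 degrees_used = hist$degree),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law N = %.4g * D^-%.4g  (r^2 = %.4f, %d degree bins)\n",
              x$a, x$b, x$r_squared, length(x$degrees_used)))
  invisible(x)
}

#' Write network, degree and fit outputs
#'
#' `write_edge_list` writes a two-column TSV of lexicographically ordered
#' pairs; `write_degree_table` a TSV of `id`/`degree`;
#' `write_network_graphml` a GraphML file (via igraph); and
#' `write_power_law_fit` a JSON object with `a`, `b`, `r_squared`.
#'
#' @param network A `"metabolic_network"`.
#' @param path Output file path.
#' @name network-io
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname network-io
#' @param degree_table Data frame from [compute_degrees()].
#' @export
write_degree_table <- function(degree_table, path) {
  utils::write.table(degree_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @param fit A `"power_law_fit"`.
#' @export
write_power_law_fit <- function(fit, path) {
  jsonlite::write_json(list(a = fit$a, b = fit$b, r_squared = fit$r_squared),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
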