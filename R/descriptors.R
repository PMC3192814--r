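# Chemical descriptor panel from SMILES.
#
# Structure handling (SMILES parsing, explicit hydrogens, Gasteiger partial
# charges, Wildman-Crippen logP) is delegated to OpenBabel's `obabel` CLI.
# Per-atom charges are read back from mol2 output; surface areas are an
# approximate 2D scheme (see atom_surface_areas) so every descriptor is
# deterministic -- no conformer generation.

`%||%` <- function(a, b) if (is.null(a)) b else a

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("OpenBabel 'obabel' executable not found on PATH")
  p
}

.run_obabel <- function(in_lines, out_format, extra = character(0)) {
  inf <- tempfile(fileext = ".smi")
  outf <- tempfile(fileext = paste0(".", out_format))
  errf <- tempfile(fileext = ".err")
  on.exit(unlink(c(inf, outf, errf)), add = TRUE)
  writeLines(in_lines, inf)
  system2(.obabel_path(), c(inf, paste0("-o", out_format), "-O", outf, extra),
          stdout = FALSE, stderr = errf)
  if (!file.exists(outf)) return(character(0))
  readLines(outf, warn = FALSE)
}

# Parse the ATOM/BOND records of a (possibly multi-molecule) mol2 file into
# a named list of molecules: $atoms (element, type, charge), $bonds (a1, a2,
# type).  Only the fields this package uses are read.
.parse_mol2 <- function(lines) {
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  mols <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[bounds[i]:(bounds[i + 1L] - 1L)]
    title <- trimws(block[2])
    atom_at <- grep("^@<TRIPOS>ATOM", block)[1]
    bond_at <- grep("^@<TRIPOS>BOND", block)[1]
    sec_ends <- c(grep("^@<TRIPOS>", block), length(block) + 1L)
    next_sec <- function(at) min(sec_ends[sec_ends > at]) - 1L
    atoms <- data.frame(element = character(0), type = character(0),
                        charge = numeric(0))
    if (!is.na(atom_at) && next_sec(atom_at) > atom_at) {
      rows <- block[(atom_at + 1L):next_sec(atom_at)]
      rows <- rows[nzchar(trimws(rows))]
      f <- strsplit(trimws(rows), "\\s+")
      type <- vapply(f, `[[`, "", 6L)
      atoms <- data.frame(
        element = sub("\\..*$", "", type),
        type = type,
        charge = as.numeric(vapply(f, function(x) x[[length(x)]], "")),
        stringsAsFactors = FALSE)
    }
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), type = character(0))
    if (!is.na(bond_at) && next_sec(bond_at) > bond_at) {
      rows <- block[(bond_at + 1L):next_sec(bond_at)]
      rows <- rows[nzchar(trimws(rows))]
      f <- strsplit(trimws(rows), "\\s+")
      bonds <- data.frame(a1 = as.integer(vapply(f, `[[`, "", 2L)),
                          a2 = as.integer(vapply(f, `[[`, "", 3L)),
                          type = vapply(f, `[[`, "", 4L),
                          stringsAsFactors = FALSE)
    }
    mols[[title]] <- list(atoms = atoms, bonds = bonds)
  }
  mols
}

# Convert SMILES to per-atom structures with explicit hydrogens and
# Gasteiger charges.  A malformed SMILES aborts the remainder of an obabel
# batch, so missing ids trigger a one-by-one retry to pinpoint failures.
.smiles_to_mols <- function(ids, smiles) {
  stopifnot(length(ids) == length(smiles))
  if (any(grepl("\\s", ids))) stop("metabolite ids must not contain whitespace")
  lines <- paste(smiles, ids)
  got <- .parse_mol2(.run_obabel(lines, "mol2",
                                 c("-h", "--partialcharge", "gasteiger")))
  missing <- setdiff(ids, names(got))
  failed <- character(0)
  if (length(missing) > 0) {
    for (id in missing) {
      one <- .parse_mol2(.run_obabel(paste(smiles[ids == id][1], id), "mol2",
                                     c("-h", "--partialcharge", "gasteiger")))
      if (length(one) == 1) got[[id]] <- one[[1]] else failed <- c(failed, id)
    }
  }
  list(mols = got[ids[ids %in% names(got)]], failed = failed)
}

# Batch Wildman-Crippen logP via obabel's logP descriptor.
.ob_logp <- function(ids, smiles) {
  lines <- paste(smiles, ids)
  out <- .run_obabel(lines, "smi", c("--append", "logP"))
  vals <- rep(NA_real_, length(ids))
  names(vals) <- ids
  for (line in out) {
    rest <- sub("^[^\t]*\t", "", line)
    tok <- strsplit(trimws(rest), "\\s+")[[1]]
    if (length(tok) >= 2 && tok[1] %in% ids) {
      vals[tok[1]] <- suppressWarnings(as.numeric(tok[length(tok)]))
    }
  }
  miss <- is.na(vals)
  if (any(miss)) {
    for (id in ids[miss]) {
      out1 <- .run_obabel(paste(smiles[ids == id][1], id), "smi",
                          c("--append", "logP"))
      if (length(out1) == 1) {
        tok <- strsplit(trimws(sub("^[^\t]*\t", "", out1)), "\\s+")[[1]]
        vals[id] <- suppressWarnings(as.numeric(tok[length(tok)]))
      }
    }
  }
  vals
}

# Bondi van der Waals radii and single-bond covalent radii (Angstrom), plus
# standard atomic masses, for the elements common in metabolites.  Unlisted
# elements fall back to carbon-like values.
.vdw_radius <- function(el) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
         S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10)
  out <- r[el]; out[is.na(out)] <- 1.70; unname(out)
}
.cov_radius <- function(el) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07,
         S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Si = 1.11)
  out <- r[el]; out[is.na(out)] <- 0.76; unname(out)
}
.atomic_mass <- function(el) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
         P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
         B = 10.81, Si = 28.085)
  out <- m[el]; out[is.na(out)] <- 12.011; unname(out)
}

#' Approximate per-atom accessible surface areas
#'
#' A deterministic 2D scheme: each atom is a van der Waals sphere, and every
#' bonded neighbour occludes the spherical cap it would cover when placed at
#' the idealised bond length (sum of covalent radii). No 3D embedding or
#' conformer search is involved, so repeated calls are bit-identical.
#' Occlusion by non-bonded atoms is ignored; areas are floored at zero and
#' the total molecular surface area is always positive for real molecules.
#'
#' @param mol Internal molecule structure (atoms + bonds).
#' @return Numeric vector of areas (Angstrom^2), one per atom.
#' @keywords internal
atom_surface_areas <- function(mol) {
  el <- mol$atoms$element
  R <- .vdw_radius(el)
  area <- 4 * pi * R^2
  if (nrow(mol$bonds) > 0) {
    cr <- .cov_radius(el)
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
      d <- cr[i] + cr[j]
      cap <- function(Ri, Rj) {
        if (d >= Ri + Rj) return(0)
        if (d + Ri <= Rj) return(4 * pi * Ri^2)
        h <- Ri - (d^2 + Ri^2 - Rj^2) / (2 * d)
        h <- min(max(h, 0), 2 * Ri)
        2 * pi * Ri * h
      }
      area[i] <- area[i] - cap(R[i], R[j])
      area[j] <- area[j] - cap(R[j], R[i])
    }
  }
  pmax(area, 0)
}

.cpsa_from_mol <- function(mol) {
  q <- mol$atoms$charge
  sa <- atom_surface_areas(mol)
  tmsa <- sum(sa)
  if (!(tmsa > 0)) stop("descriptor error: zero total molecular surface area")
  pos <- q > 0
  neg <- q < 0
  ppsa3 <- sum(q[pos] * sa[pos])
  pnsa3 <- sum(q[neg] * sa[neg])
  rpcg <- if (any(pos)) max(q[pos]) / sum(q[pos]) else NA_real_
  list(ppsa3 = ppsa3, pnsa3 = pnsa3,
       fpsa3 = ppsa3 / tmsa, fnsa3 = pnsa3 / tmsa,
       rpcg = rpcg, tmsa = tmsa)
}

# Count simple cycles of length exactly k in an adjacency list (heavy atoms
# only; molecules are small so a depth-limited DFS is adequate).  Each cycle
# is anchored at its smallest vertex and traversed in both directions, hence
# the final division by two.
.count_k_cycles <- function(adj, k) {
  n <- length(adj)
  total <- 0L
  dfs <- function(start, v, depth, visited) {
    for (w in adj[[v]]) {
      if (w == start && depth == k) {
        total <<- total + 1L
      } else if (depth < k && w > start && !visited[w]) {
        visited[w] <- TRUE
        dfs(start, w, depth + 1L, visited)
        visited[w] <- FALSE
      }
    }
  }
  visited <- logical(n)
  for (s in seq_len(n)) {
    if (length(adj[[s]]) < 2) next
    visited[s] <- TRUE
    dfs(s, s, 1L, visited)
    visited[s] <- FALSE
  }
  total %/% 2L
}

.heavy_adjacency <- function(mol) {
  heavy <- which(mol$atoms$element != "H")
  idx <- match(seq_len(nrow(mol$atoms)), heavy)  # atom -> heavy index or NA
  adj <- rep(list(integer(0)), length(heavy))
  in_ring_bond <- logical(nrow(mol$bonds))
  for (b in seq_len(nrow(mol$bonds))) {
    i <- idx[mol$bonds$a1[b]]; j <- idx[mol$bonds$a2[b]]
    if (!is.na(i) && !is.na(j)) {
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  list(heavy = heavy, idx = idx, adj = adj)
}

# Bonds that lie on a cycle of the heavy-atom graph = non-bridge edges.
.ring_bonds <- function(mol, hv) {
  n_heavy <- length(hv$heavy)
  out <- logical(nrow(mol$bonds))
  if (n_heavy < 3 || nrow(mol$bonds) == 0) return(out)
  el <- igraph::make_empty_graph(n_heavy, directed = FALSE)
  bond_rows <- integer(0)
  ep <- integer(0)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- hv$idx[mol$bonds$a1[b]]; j <- hv$idx[mol$bonds$a2[b]]
    if (!is.na(i) && !is.na(j)) {
      bond_rows <- c(bond_rows, b)
      ep <- c(ep, i, j)
    }
  }
  if (length(bond_rows) == 0) return(out)
  g <- igraph::add_edges(el, ep)
  br <- igraph::bridges(g)
  is_bridge <- seq_along(bond_rows) %in% as.integer(br)
  out[bond_rows] <- !is_bridge
  out
}

.feature_counts <- function(mol, logp) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  el <- atoms$element
  n_atoms <- nrow(atoms)
  nb <- rep(list(integer(0)), n_atoms)
  for (b in seq_len(nrow(bonds))) {
    nb[[bonds$a1[b]]] <- c(nb[[bonds$a1[b]]], bonds$a2[b])
    nb[[bonds$a2[b]]] <- c(nb[[bonds$a2[b]]], bonds$a1[b])
  }
  has_h_neighbour <- vapply(nb, function(x) any(el[x] == "H"), logical(1))
  hbd <- sum(el %in% c("N", "O") & has_h_neighbour)
  n_count <- sum(el == "N")
  hba <- sum(el %in% c("N", "O"))

  # amide linkages: C-N single (or sybyl 'am') bonds where the carbon also
  # carries a C=O double bond
  carbonyl_c <- rep(FALSE, n_atoms)
  for (b in seq_len(nrow(bonds))) {
    if (bonds$type[b] == "2") {
      i <- bonds$a1[b]; j <- bonds$a2[b]
      if (el[i] == "C" && el[j] == "O") carbonyl_c[i] <- TRUE
      if (el[j] == "C" && el[i] == "O") carbonyl_c[j] <- TRUE
    }
  }
  amide <- 0L
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$a1[b]; j <- bonds$a2[b]
    cn <- (el[i] == "C" && el[j] == "N") || (el[i] == "N" && el[j] == "C")
    if (!cn) next
    if (bonds$type[b] == "am" ||
        (bonds$type[b] == "1" && ((el[i] == "C" && carbonyl_c[i]) ||
                                  (el[j] == "C" && carbonyl_c[j])))) {
      amide <- amide + 1L
    }
  }

  hv <- .heavy_adjacency(mol)
  ring6 <- .count_k_cycles(hv$adj, 6L)

  # hydrophobic atoms: carbon or halogen with no N/O/S/P neighbour
  hetero <- c("N", "O", "S", "P")
  hydrophobe <- sum(vapply(seq_len(n_atoms), function(a) {
    el[a] %in% c("C", "F", "Cl", "Br", "I") && !any(el[nb[[a]]] %in% hetero)
  }, logical(1)))

  # rotatable bonds: acyclic single bonds between non-terminal heavy atoms,
  # amide C-N excluded (ESOL's RB definition)
  ring_bond <- .ring_bonds(mol, hv)
  heavy_deg <- vapply(nb, function(x) sum(el[x] != "H"), integer(1))
  rotatable <- 0L
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$a1[b]; j <- bonds$a2[b]
    if (bonds$type[b] != "1") next
    if (el[i] == "H" || el[j] == "H") next
    if (ring_bond[b]) next
    if (heavy_deg[i] < 2 || heavy_deg[j] < 2) next
    cn <- (el[i] == "C" && el[j] == "N") || (el[i] == "N" && el[j] == "C")
    if (cn && (carbonyl_c[i] || carbonyl_c[j])) next
    rotatable <- rotatable + 1L
  }

  aromatic_atom <- grepl("\\.ar$", atoms$type)
  for (b in seq_len(nrow(bonds))) {
    if (bonds$type[b] == "ar") {
      aromatic_atom[bonds$a1[b]] <- TRUE
      aromatic_atom[bonds$a2[b]] <- TRUE
    }
  }
  n_heavy <- sum(el != "H")
  aromatic_prop <- if (n_heavy > 0) sum(aromatic_atom & el != "H") / n_heavy else 0
  mw <- sum(.atomic_mass(el))

  lscore <- lipinski_score(mw, logp, hbd, hba)

  list(hbd_count = hbd, n_count = n_count, amide_count = amide,
       ring6_count = ring6, hydrophobe_count = hydrophobe,
       lscore = lscore, mw = mw, rotatable = rotatable,
       aromatic_prop = aromatic_prop, hba_count = hba)
}

#' Floating-point Lipinski measure
#'
#' A continuous drug-likeness penalty: the summed fractional excess over
#' each of the four rule-of-five bounds (molecular weight 500, logP 5,
#' hydrogen-bond donors 5, acceptors 10). Zero for fully compliant
#' molecules; each violated bound contributes `(value - bound)/bound`.
#' This is this package's documented stand-in for a "floating point
#' Lipinski measure" -- commercial engines do not publish theirs.
#'
#' @param mw,logp,hbd,hba The four rule-of-five quantities.
#' @return Non-negative numeric penalty.
#' @export
lipinski_score <- function(mw, logp, hbd, hba) {
  bounds <- c(500, 5, 5, 10)
  vals <- c(mw, logp, hbd, hba)
  sum(pmax(0, (vals - bounds) / bounds))
}

.require_mol <- function(smiles) {
  res <- .smiles_to_mols("mol", smiles)
  if (length(res$failed) > 0 || length(res$mols) == 0) {
    stop("structure error: SMILES could not be parsed: ", smiles)
  }
  res$mols[[1]]
}

#' Crippen-type octanol/water partition coefficient
#'
#' Atomic-contribution logP following the Ghose-Crippen/Wildman-Crippen
#' scheme, computed by OpenBabel. Serves as the single open partition
#' coefficient wherever a commercial ClogP/ALogP would be used; downstream
#' analyses depend on the polarity ordering, not on engine-exact values.
#'
#' @param smiles A single SMILES string.
#' @return Numeric logP (dimensionless).
#' @export
compute_logp <- function(smiles) {
  v <- .ob_logp("mol", smiles)
  if (is.na(v)) stop("structure error: SMILES could not be parsed: ", smiles)
  unname(v)
}

#' Charged-partial-surface-area descriptors
#'
#' Gasteiger partial charges (hydrogens explicit) combined with the
#' approximate per-atom surface areas of [atom_surface_areas()]:
#' `ppsa3 = sum(q_i * SA_i)` over positively charged atoms,
#' `pnsa3` the analogue over negative atoms, `fpsa3 = ppsa3/TMSA`,
#' `fnsa3 = pnsa3/TMSA` (TMSA = total molecular surface area), and
#' `rpcg` = largest positive charge / sum of positive charges. `rpcg` is
#' `NA` (undefined) when no atom carries positive partial charge.
#'
#' @param smiles A single SMILES string.
#' @return Named list `ppsa3`, `pnsa3`, `fpsa3`, `fnsa3`, `rpcg`, `tmsa`.
#' @export
compute_cpsa <- function(smiles) {
  .cpsa_from_mol(.require_mol(smiles))
}

#' ESOL coefficients for aqueous solubility estimation
#'
#' @return Named numeric vector of the published ESOL regression
#'   coefficients (intercept, logP, molecular weight, rotatable bonds,
#'   aromatic proportion).
#' @export
esol_coefficients <- function() {
  c(intercept = 0.16, logp = -0.63, mw = -0.0062, rotatable = 0.066,
    aromatic_prop = -0.74)
}

#' Estimated aqueous solubility (logS)
#'
#' ESOL-style estimate of log10 aqueous solubility (mol/L) from logP,
#' molecular weight, rotatable-bond count and aromatic proportion:
#' `logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`.
#'
#' @param smiles A single SMILES string.
#' @return Numeric logS (log10 mol/L).
#' @seealso [esol_coefficients()] for the coefficient vector.
#' @export
estimate_logs <- function(smiles) {
  mol <- .require_mol(smiles)
  logp <- compute_logp(smiles)
  fc <- .feature_counts(mol, logp)
  esol_equation(logp, fc$mw, fc$rotatable, fc$aromatic_prop)
}

#' @rdname estimate_logs
#' @param logp,mw,rotatable,aromatic_prop Precomputed inputs to the ESOL
#'   equation; with all-zero inputs the model intercept is returned.
#' @export
esol_equation <- function(logp, mw, rotatable, aromatic_prop) {
  co <- esol_coefficients()
  unname(co["intercept"] + co["logp"] * logp + co["mw"] * mw +
           co["rotatable"] * rotatable + co["aromatic_prop"] * aromatic_prop)
}

#' Substructure and rule-of-five feature counts
#'
#' Integer substructure counts used by the concentration models:
#' hydrogen-bond donors (N or O bearing at least one hydrogen), nitrogen
#' atoms, amide linkages (C(=O)-N), six-membered rings (simple cycles of
#' length 6 in the heavy-atom graph), hydrophobic atoms (carbon or halogen
#' with no N/O/S/P neighbour), plus the continuous Lipinski measure of
#' [lipinski_score()].
#'
#' @param smiles A single SMILES string.
#' @return Named list `hbd_count`, `n_count`, `amide_count`, `ring6_count`,
#'   `hydrophobe_count`, `lscore`.
#' @export
count_features <- function(smiles) {
  mol <- .require_mol(smiles)
  logp <- compute_logp(smiles)
  fc <- .feature_counts(mol, logp)
  fc[c("hbd_count", "n_count", "amide_count", "ring6_count",
       "hydrophobe_count", "lscore")]
}

#' Compute the full descriptor panel for a table of SMILES
#'
#' One row per parseable structure with the fixed column order used by all
#' downstream statistics. Structures that fail to parse are reported in the
#' `"failures"` attribute (and via a warning), never silently dropped.
#'
#' @param smiles_table Data frame with columns `id` (unique, no whitespace)
#'   and `smiles`.
#' @return Data frame with columns `id`, `logp`, `logs`, `ppsa3`, `pnsa3`,
#'   `fpsa3`, `fnsa3`, `rpcg`, `hbd_count`, `n_count`, `amide_count`,
#'   `ring6_count`, `hydrophobe_count`, `lscore`; attribute `failures`
#'   holds the ids that could not be processed.
#' @export
build_panel <- function(smiles_table) {
  stopifnot(is.data.frame(smiles_table),
            all(c("id", "smiles") %in% names(smiles_table)))
  if (nrow(smiles_table) == 0) stop("empty SMILES table")
  ids <- as.character(smiles_table$id)
  if (anyDuplicated(ids)) stop("duplicate ids in SMILES table")
  smiles <- as.character(smiles_table$smiles)
  conv <- .smiles_to_mols(ids, smiles)
  logps <- .ob_logp(ids, smiles)
  ok <- ids[ids %in% names(conv$mols) & !is.na(logps[ids])]
  failed <- setdiff(ids, ok)
  rows <- lapply(ok, function(id) {
    mol <- conv$mols[[id]]
    logp <- unname(logps[id])
    cp <- .cpsa_from_mol(mol)
    fc <- .feature_counts(mol, logp)
    data.frame(id = id, logp = logp,
               logs = esol_equation(logp, fc$mw, fc$rotatable, fc$aromatic_prop),
               ppsa3 = cp$ppsa3, pnsa3 = cp$pnsa3,
               fpsa3 = cp$fpsa3, fnsa3 = cp$fnsa3, rpcg = cp$rpcg,
               hbd_count = fc$hbd_count, n_count = fc$n_count,
               amide_count = fc$amide_count, ring6_count = fc$ring6_count,
               hydrophobe_count = fc$hydrophobe_count, lscore = fc$lscore,
               stringsAsFactors = FALSE)
  })
  panel <- do.call(rbind, rows)
  if (is.null(panel)) stop("no SMILES could be processed")
  rownames(panel) <- NULL
  if (length(failed) > 0) {
    warning("failed to compute descriptors for: ", paste(failed, collapse = ", "))
  }
  attr(panel, "failures") <- failed
  panel
}

#' Read and write descriptor panels
#'
#' TSV with one row per metabolite, fixed column order, missing values
#' written as `NA`.
#'
#' @param panel Data frame from [build_panel()].
#' @param path File path.
#' @name panel-io
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname panel-io
#' @export
read_panel <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a SMILES (.smi) file
#'
#' One molecule per line, `SMILES<whitespace>id`; `#` comments skipped.
#'
#' @param path File path.
#' @return Data frame with columns `id`, `smiles`.
#' @export
read_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  f <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(f, length, integer(1)) < 2
  if (any(bad)) stop("malformed .smi line(s): ", paste(which(bad), collapse = ", "))
  data.frame(id = vapply(f, `[[`, "", 2L),
             smiles = vapply(f, `[[`, "", 1L), stringsAsFactors = FALSE)
}
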