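# Concentration-governed network growth: new metabolites appear with
# steadily lower concentrations, and reaction partners are drawn with
# probability proportional to current concentration, so abundant (old)
# metabolites accumulate edges -- a chemical reading of preferential
# attachment that yields scale-free degree distributions.

#' Configure a growth simulation
#'
#' Defaults are the reference conditions of the concentration-governed
#' expansion model: a single seed metabolite at concentration 1,000,000,
#' termination once a newly assigned concentration falls to 10 or below
#' (the five-orders-of-magnitude span of measured metabolite
#' concentrations), a per-step concentration decline of 1,000 with a
#' uniform fluctuation of total width 1,500, one new metabolite and five
#' new edges per step.
#'
#' @param n_per_step New metabolites added per step (default 1).
#' @param c_init Initial (seed) concentration (default 1e6).
#' @param c_final Termination threshold: the run stops once a newly
#'   assigned concentration is `<= c_final` (default 10).
#' @param decline_d Mean per-step concentration decline (default 1000).
#' @param fluctuation_f Total width of the uniform fluctuation around the
#'   declining ramp (default 1500; 0 = deterministic).
#' @param m Edges added per step (default 5).
#' @param seed Integer seed for the run's single pseudo-random stream.
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(n_per_step = 1, c_init = 1e6, c_final = 10,
                       decline_d = 1000, fluctuation_f = 1500, m = 5,
                       seed = 1) {
  stopifnot(n_per_step >= 1, c_init > c_final, c_final > 0, decline_d > 0,
            fluctuation_f >= 0, m >= 1)
  structure(list(n_per_step = as.integer(n_per_step), c_init = c_init,
                 c_final = c_final, decline_d = decline_d,
                 fluctuation_f = fluctuation_f, m = as.integer(m),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Concentration assigned to the metabolite added at step k
#'
#' `C_k = max(1, c_init - k * decline_d + U)` with
#' `U ~ Uniform(-f/2, +f/2)` drawn from the current random stream; the
#' floor of 1 keeps sampling weights positive near termination. With
#' `fluctuation_f = 0` the sequence is the deterministic ramp
#' `c_init - k * decline_d`.
#'
#' @param k Step index (>= 1).
#' @param config A [sim_config()].
#' @return Numeric concentration.
#' @export
assign_concentration <- function(k, config) {
  stopifnot(k >= 1)
  u <- if (config$fluctuation_f > 0) {
    stats::runif(1, -config$fluctuation_f / 2, config$fluctuation_f / 2)
  } else 0
  max(1, config$c_init - k * config$decline_d + u)
}

# Draw one edge endpoint pair: both endpoints sampled without replacement
# with probability proportional to concentration.
.draw_pair <- function(conc) {
  sample.int(length(conc), 2, replace = FALSE, prob = conc)
}

#' Sample concentration-weighted edges for a growth step
#'
#' Draws up to `m` edges among the current metabolites, each endpoint
#' chosen with probability proportional to its concentration (endpoints
#' without replacement within an edge, so no self-loops). The first edge
#' has `new_node` forced as one endpoint -- the connectivity guard that
#' ties every newly added metabolite into the network; the remaining
#' edges are sampled freely. An edge duplicating an existing or
#' just-sampled edge is resampled up to `retry_cap` times, then skipped,
#' so tiny graphs may yield fewer than `m` edges.
#'
#' @param conc Numeric vector of current concentrations (index = node id).
#' @param existing Environment used as a hash set of existing edge keys
#'   (`"i-j"`, i < j); updated in place.
#' @param m Number of edges to attempt.
#' @param new_node Index of the newly added node.
#' @param retry_cap Resampling attempts per edge (default 20).
#' @return Integer matrix with columns `from`, `to` (0 rows possible).
#' @export
sample_edges <- function(conc, existing, m, new_node, retry_cap = 20) {
  n <- length(conc)
  if (n < 2) return(matrix(integer(0), ncol = 2,
                           dimnames = list(NULL, c("from", "to"))))
  out <- matrix(NA_integer_, nrow = m, ncol = 2,
                dimnames = list(NULL, c("from", "to")))
  got <- 0L
  for (e in seq_len(m)) {
    placed <- FALSE
    for (try in seq_len(retry_cap)) {
      if (e == 1L) {
        other <- if (n == 2L) setdiff(1:2, new_node) else {
          idx <- setdiff(seq_len(n), new_node)
          idx[sample.int(length(idx), 1, prob = conc[idx])]
        }
        pair <- c(new_node, other)
      } else {
        pair <- .draw_pair(conc)
      }
      key <- paste0(min(pair), "-", max(pair))
      if (!exists(key, envir = existing, inherits = FALSE)) {
        assign(key, TRUE, envir = existing)
        got <- got + 1L
        out[got, ] <- c(min(pair), max(pair))
        placed <- TRUE
        break
      }
    }
    if (!placed && e == 1L) break  # two-node graph already saturated
  }
  out[seq_len(got), , drop = FALSE]
}

#' Run a concentration-governed growth simulation
#'
#' Starts from one metabolite at `c_init`. Each step adds `n_per_step`
#' metabolites whose concentrations follow the declining ramp of
#' [assign_concentration()], then adds `m` concentration-weighted edges
#' (the first anchored at the newest metabolite). The run terminates at
#' the end of the step in which a newly assigned concentration first
#' reaches `c_final` or below; that metabolite is kept. The final degree
#' histogram is fitted by [fit_power_law()] when it spans at least three
#' positive degrees.
#'
#' The whole run consumes a single pseudo-random stream seeded from the
#' config, so identical configs give bit-identical results.
#'
#' @param config A [sim_config()].
#' @return Object of class `"sim_result"`: list with `network`
#'   (a `"metabolic_network"` over node ids `"M1"..`), `concentrations`
#'   (named numeric), `n_steps`, `n_nodes`, `histogram` and `powerlaw`
#'   (a `"power_law_fit"` or NULL when the histogram is too narrow).
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  conc <- config$c_init
  edges_env <- new.env(hash = TRUE, parent = emptyenv())
  from <- integer(0)
  to <- integer(0)
  k <- 0L
  repeat {
    k <- k + 1L
    stop_after_step <- FALSE
    for (j in seq_len(config$n_per_step)) {
      ck <- assign_concentration(k, config)
      conc <- c(conc, ck)
      new_node <- length(conc)
      if (ck <= config$c_final) stop_after_step <- TRUE
      ee <- sample_edges(conc, edges_env, config$m, new_node)
      if (nrow(ee) > 0) {
        from <- c(from, ee[, 1])
        to <- c(to, ee[, 2])
      }
    }
    if (stop_after_step) break
  }
  n_nodes <- length(conc)
  ids <- paste0("M", seq_len(n_nodes))
  deg <- tabulate(c(from, to), nbins = n_nodes)
  edges <- data.frame(from = ids[from], to = ids[to], stringsAsFactors = FALSE)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  network <- structure(list(nodes = ids, edges = edges),
                       class = "metabolic_network")
  degree_table <- data.frame(id = ids, degree = deg, stringsAsFactors = FALSE)
  hist <- degree_histogram(degree_table[degree_table$degree > 0, , drop = FALSE])
  pl <- if (length(unique(hist$degree)) >= 3) fit_power_law(hist) else NULL
  structure(list(network = network,
                 concentrations = stats::setNames(conc, ids),
                 n_steps = k, n_nodes = n_nodes,
                 degree_table = degree_table, histogram = hist,
                 powerlaw = pl, config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("growth simulation: %d steps, %d metabolites, %d edges\n",
              x$n_steps, x$n_nodes, nrow(x$network$edges)))
  if (!is.null(x$powerlaw)) print(x$powerlaw)
  invisible(x)
}

#' Summarise replicate growth simulations
#'
#' Runs the simulation once per seed and tabulates node count, edge count
#' and the power-law fit of each run; a mean/sd summary is attached as the
#' `"summary"` attribute and the per-run histograms as `"histograms"` so
#' every fit can be recomputed from stored data.
#'
#' @param config A [sim_config()] (its `seed` field is ignored).
#' @param seeds Integer vector of seeds, one replicate per seed.
#' @return Data frame `seed`, `n_nodes`, `n_edges`, `a`, `b`, `r_squared`.
#' @export
summarize_replicates <- function(config, seeds) {
  stopifnot(length(seeds) >= 1)
  hists <- list()
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    res <- run_simulation(cfg)
    hists[[as.character(s)]] <<- res$histogram
    data.frame(seed = as.integer(s), n_nodes = res$n_nodes,
               n_edges = nrow(res$network$edges),
               a = if (is.null(res$powerlaw)) NA_real_ else res$powerlaw$a,
               b = if (is.null(res$powerlaw)) NA_real_ else res$powerlaw$b,
               r_squared = if (is.null(res$powerlaw)) NA_real_ else res$powerlaw$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  num <- out[, -1, drop = FALSE]
  attr(out, "summary") <- data.frame(
    statistic = c("mean", "sd"),
    rbind(colMeans(num), vapply(num, stats::sd, numeric(1))))
  attr(out, "histograms") <- hists
  out
}
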