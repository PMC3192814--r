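# Degree/age grouping, rank tests and binned correlations: the statistics
# that relate network topology to metabolite chemistry.

#' Define a degree grouping scheme
#'
#' An ordered list of degree intervals with inclusive integer bounds; the
#' upper bound of the last group may be `Inf` (an open-ended "hub" group).
#' Intervals must be disjoint and in increasing order.
#'
#' @param labels Character vector of group labels.
#' @param lower,upper Integer vectors of inclusive bounds (upper may end
#'   with `Inf`).
#' @return An object of class `"group_scheme"`.
#' @examples
#' degree_scheme(c("1", "2-6", ">6"), c(1, 2, 7), c(1, 6, Inf))
#' @export
degree_scheme <- function(labels, lower, upper) {
  stopifnot(length(labels) == length(lower), length(lower) == length(upper))
  if (any(upper < lower)) stop("group upper bound below lower bound")
  if (length(lower) > 1 && any(lower[-1] <= upper[-length(upper)])) {
    stop("group intervals must be disjoint and increasing")
  }
  structure(list(labels = as.character(labels), lower = lower, upper = upper),
            class = "group_scheme")
}

#' @export
print.group_scheme <- function(x, ...) {
  cat("degree groups:",
      paste(sprintf("%s [%g,%g]", x$labels, x$lower, x$upper), collapse = "  "),
      "\n")
  invisible(x)
}

#' Assign degrees to scheme groups
#'
#' @param degree Integer vector of degrees.
#' @param scheme A [degree_scheme()].
#' @return Factor of group labels (NA for degrees outside every interval).
#' @export
assign_groups <- function(degree, scheme) {
  lab <- rep(NA_character_, length(degree))
  for (g in seq_along(scheme$labels)) {
    lab[degree >= scheme$lower[g] & degree <= scheme$upper[g]] <- scheme$labels[g]
  }
  factor(lab, levels = scheme$labels)
}

#' Per-group mean and standard error of a metabolite property
#'
#' Groups metabolites by degree interval and summarises a property as
#' n / mean / standard error of the mean (se = sd/sqrt(n)), the "mean
#' +/- SE" presentation used for degree-vs-descriptor comparisons. Missing
#' property values are excluded pairwise. A single-member group gets
#' `se = 0` by convention and is flagged `degenerate`; an empty group is
#' reported with `n = 0` and NA mean so that callers can exclude it from
#' downstream correlation.
#'
#' @param data Data frame with columns `degree` and `value` (one row per
#'   metabolite).
#' @param scheme A [degree_scheme()].
#' @return Data frame `label`, `n`, `mean`, `se`, `degenerate`, in scheme
#'   order.
#' @export
group_by_degree <- function(data, scheme) {
  stopifnot(all(c("degree", "value") %in% names(data)))
  keep <- !is.na(data$value) & !is.na(data$degree)
  data <- data[keep, , drop = FALSE]
  grp <- assign_groups(data$degree, scheme)
  out <- lapply(seq_along(scheme$labels), function(g) {
    v <- data$value[!is.na(grp) & grp == scheme$labels[g]]
    n <- length(v)
    data.frame(label = scheme$labels[g], n = n,
               mean = if (n > 0) mean(v) else NA_real_,
               se = if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
               degenerate = n <= 1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square approximation on k-1
#' degrees of freedom (wraps [stats::kruskal.test()]).
#'
#' @param groups A list of two or more non-empty numeric vectors.
#' @return Named list `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need total n >= 3")
  if (length(unique(x)) == 1) {
    # every observation tied: no rank variation, H = 0 by convention
    return(list(H = 0, p = 1, df = length(groups) - 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value),
       df = unname(kt$parameter))
}

#' Mann-Whitney U test for two groups
#'
#' Reports `U = min(U_a, U_b)` with the conventional half-count for ties
#' and a two-sided normal-approximation p-value without continuity
#' correction (wraps [stats::wilcox.test()]; `W` there equals `U_a`).
#'
#' @param a,b Non-empty numeric vectors.
#' @return Named list `U`, `p`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  u_a <- unname(wt$statistic)
  u <- min(u_a, length(a) * length(b) - u_a)
  list(U = u, p = unname(wt$p.value))
}

#' Correlation between degree-bin rank and bin mean
#'
#' Pearson correlation of the per-bin mean property against the ordinal bin
#' index 1..k (the open-ended top bin has no midpoint, so rank is the
#' x-coordinate), with a t-distribution p-value. Degenerate input (constant
#' bin means) yields `R = 0` with a warning rather than NaN.
#'
#' @param summaries Data frame from [group_by_degree()] (or any frame with
#'   columns `n` and `mean`); empty bins (`n = 0`) are dropped first.
#' @return Named list `R`, `p`, `n_bins`.
#' @export
binned_correlation <- function(summaries) {
  s <- summaries[summaries$n > 0 & !is.na(summaries$mean), , drop = FALSE]
  k <- nrow(s)
  if (k < 3) stop("insufficient data: need >= 3 non-empty bins")
  x <- seq_len(k)
  y <- s$mean
  if (stats::sd(y) == 0) {
    warning("bin means have zero variance; correlation undefined, reported 0")
    return(list(R = 0, p = 1, n_bins = k))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = unname(ct$p.value), n_bins = k)
}

#' Classify network metabolites as early or late
#'
#' Early metabolites are those associated with enzymes of the oldest age
#' class, minus metabolites that require molecular oxygen (aerobic
#' metabolites cannot predate oxygenic conditions); the early set is the
#' intersection of these candidates with the network's nodes, and every
#' remaining node is late. The two sets always partition the node set.
#'
#' @param network_nodes Character vector of network metabolite ids.
#' @param enzyme_metabolite_map Named list: enzyme id -> character vector of
#'   associated metabolite ids.
#' @param enzyme_ages Named vector: enzyme id -> age class label.
#' @param aerobic Character vector of aerobic metabolite ids.
#' @param oldest_class The age class label regarded as oldest.
#' @return Named list `early`, `late` (character vectors) and
#'   `candidates` (the pre-intersection early-candidate set).
#' @export
classify_age <- function(network_nodes, enzyme_metabolite_map, enzyme_ages,
                         aerobic = character(0), oldest_class = "1") {
  unknown <- setdiff(names(enzyme_metabolite_map), names(enzyme_ages))
  if (length(unknown) > 0) {
    stop("unknown enzyme id(s): ", paste(unknown, collapse = ", "))
  }
  old_enzymes <- names(enzyme_ages)[enzyme_ages == oldest_class]
  old_mets <- unique(unlist(enzyme_metabolite_map[
    names(enzyme_metabolite_map) %in% old_enzymes], use.names = FALSE))
  if (is.null(old_mets)) old_mets <- character(0)
  candidates <- setdiff(old_mets, aerobic)
  early <- intersect(network_nodes, candidates)
  late <- setdiff(network_nodes, early)
  list(early = early, late = late, candidates = candidates)
}

#' Table-style descriptor summary across degree groups
#'
#' For each descriptor column, computes the per-group n/mean/se and the
#' Kruskal-Wallis test across groups -- the summary layout used when
#' comparing descriptor means between low-degree and hub metabolites.
#'
#' @param degree_table Data frame `id`/`degree` ([compute_degrees()]).
#' @param panel Descriptor panel ([build_panel()]).
#' @param scheme A [degree_scheme()].
#' @param descriptors Character vector of panel columns to summarise.
#' @return Data frame with one row per descriptor x group plus `H` and `p`
#'   of the across-group Kruskal-Wallis test (repeated within descriptor).
#' @export
descriptor_group_summary <- function(degree_table, panel, scheme,
                                     descriptors = c("logp", "logs", "fpsa3",
                                                     "fnsa3", "rpcg")) {
  merged <- merge(degree_table, panel, by = "id")
  out <- list()
  for (d in descriptors) {
    if (!d %in% names(merged)) stop("descriptor not in panel: ", d)
    dat <- data.frame(degree = merged$degree, value = merged[[d]])
    gs <- group_by_degree(dat, scheme)
    grp <- assign_groups(merged$degree, scheme)
    vals <- split(merged[[d]][!is.na(merged[[d]])],
                  droplevels(grp[!is.na(merged[[d]])]))
    vals <- vals[vapply(vals, length, integer(1)) > 0]
    kw <- if (length(vals) >= 2 && sum(lengths(vals)) >= 3) {
      kruskal_wallis(vals)
    } else {
      list(H = NA_real_, p = NA_real_)
    }
    gs$descriptor <- d
    gs$H <- kw$H
    gs$p <- kw$p
    out[[d]] <- gs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("descriptor", "label", "n", "mean", "se", "degenerate", "H", "p")]
}
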