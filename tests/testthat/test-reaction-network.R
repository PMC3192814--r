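test_that("reaction files parse into substrate/product sets", {
  path <- write_reaction_file(c("R1\tA + B = C",
                                "# a comment line",
                                "R2\tC = C",
                                "R3\tA + A = B + B"))
  rx <- parse_reactions(path)
  expect_length(rx, 3)
  expect_equal(rx[[1]]$id, "R1")
  expect_setequal(rx[[1]]$substrates, c("A", "B"))
  expect_equal(rx[[1]]$products, "C")
  # identity reactions are accepted (they just yield no edges)
  expect_equal(rx[[2]]$substrates, rx[[2]]$products)
  # duplicate mentions collapse to sets
  expect_equal(rx[[3]]$substrates, "A")
  expect_equal(rx[[3]]$products, "B")
})

test_that("malformed reaction lines are rejected with the line number", {
  expect_error(parse_reactions(write_reaction_file(c("R1\tA = B", "R2\tA + B"))),
               "line 2")
  expect_error(parse_reactions(write_reaction_file("R1\t = B")), "line 1")
  expect_error(parse_reactions(write_reaction_file("no_tab_here")), "line 1")
})

test_that("screening deletes macromolecule/R-group reactions and strips currency", {
  rx <- list(reaction("X", "A", "P"),
             reaction("Y", c("ATP", "G"), c("ADP", "G6P")),
             reaction("Z", "H2O", "Hplus"))
  ann <- simple_annotations(c("A", "P", "ATP", "G", "ADP", "G6P", "H2O", "Hplus"),
                            macro = "A",
                            currency = c("ATP", "ADP", "H2O", "Hplus"))
  out <- filter_reactions(rx, ann)
  # macromolecule reaction deleted entirely; currency-only reaction emptied
  expect_length(out, 1)
  expect_equal(out[[1]]$id, "Y")
  expect_equal(out[[1]]$substrates, "G")
  expect_equal(out[[1]]$products, "G6P")
  # missing annotation is an error naming the metabolite
  expect_error(filter_reactions(list(reaction("Q", "Unknown", "P")), ann),
               "Unknown")
})

test_that("currency overrides keep a currency metabolite in a named reaction only", {
  rx <- list(reaction("R1", c("ATP", "G"), "G6P"),
             reaction("R2", c("ATP", "F"), "F6P"))
  ann <- simple_annotations(c("ATP", "G", "G6P", "F", "F6P"), currency = "ATP")
  out <- filter_reactions(rx, ann, currency_overrides = list(R1 = "ATP"))
  expect_setequal(out[[1]]$substrates, c("ATP", "G"))
  expect_equal(out[[2]]$substrates, "F")
})

test_that("screening is idempotent", {
  for (seed in 1:5) {
    rx <- random_reactions(15, 12, seed)
    ids <- sprintf("X%02d", 1:12)
    ann <- simple_annotations(ids, macro = ids[1], rgroup = ids[2],
                              currency = ids[3:4])
    once <- filter_reactions(rx, ann)
    twice <- filter_reactions(once, ann)
    expect_identical(once, twice)
  }
})

test_that("the substrate-product expansion builds the expected simple graph", {
  net <- build_network(list(reaction("1", c("A", "B"), "C"),
                            reaction("2", "C", "D")))
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("A C", "B C", "C D"))
  deg <- compute_degrees(net)
  expect_equal(deg$degree[deg$id == "C"], 3)
  expect_equal(sort(deg$degree), c(1, 1, 1, 3))
  # self-pairs excluded: identity reaction yields an empty network
  expect_length(build_network(list(reaction("1", "A", "A")))$nodes, 0)
  # edges deduplicate across reactions
  net2 <- build_network(list(reaction("1", "A", "C"), reaction("2", "C", "A")))
  expect_equal(nrow(net2$edges), 1)
})

test_that("network construction is order-invariant and obeys the handshake identity", {
  for (seed in 1:5) {
    rx <- random_reactions(20, 10, seed)
    net <- build_network(rx)
    deg <- compute_degrees(net)
    expect_equal(sum(deg$degree), 2 * nrow(net$edges))
    # edge bound: complete bipartite expansion per reaction
    bound <- sum(vapply(rx, function(r) length(r$substrates) * length(r$products),
                        numeric(1)))
    expect_lte(nrow(net$edges), bound)
    perm <- build_network(rx[sample(length(rx))])
    expect_identical(net$edges, perm$edges)
  }
})

test_that("degree histograms omit zero counts and conserve node totals", {
  expect_equal(degree_histogram(data.frame(degree = c(1, 1, 1, 3))),
               data.frame(degree = c(1L, 3L), count = c(3L, 1L)))
  expect_equal(degree_histogram(data.frame(degree = rep(2, 4))),
               data.frame(degree = 2L, count = 4L))
  star <- build_network(list(reaction("1", "H", c("L1", "L2", "L3", "L4", "L5"))))
  h <- degree_histogram(compute_degrees(star))
  expect_equal(h, data.frame(degree = c(1L, 5L), count = c(5L, 1L)))
  expect_equal(sum(h$count), length(star$nodes))
})

test_that("power-law fitting recovers exact and noisy log-log lines", {
  d <- c(1, 2, 4, 8)
  fit <- fit_power_law(data.frame(degree = d, count = 100 * d^-2))
  expect_equal(fit$b, 2, tolerance = 1e-10)
  expect_equal(fit$a, 100, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # flat counts give exponent zero
  expect_equal(fit_power_law(data.frame(degree = 1:5, count = 7))$b, 0,
               tolerance = 1e-12)
  # noisy histogram must agree with the normal-equations oracle
  set.seed(42)
  h <- data.frame(degree = c(1, 2, 3, 5, 9, 17),
                  count = round(200 * c(1, 2, 3, 5, 9, 17)^-1.6 *
                                  exp(rnorm(6, 0, 0.2))) + 1)
  fit <- fit_power_law(h)
  oracle <- ols_by_hand(log10(h$degree), log10(h$count))
  expect_equal(fit$b, -unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(fit$a, 10^unname(oracle["intercept"]), tolerance = 1e-9)
  expect_error(fit_power_law(data.frame(degree = c(1, 2), count = c(3, 1))),
               "insufficient")
})

test_that("network export files round-trip nodes, edges and fits", {
  net <- build_network(list(reaction("1", c("A", "B"), "C")))
  ep <- tempfile(fileext = ".tsv")
  write_edge_list(net, ep)
  back <- utils::read.delim(ep, stringsAsFactors = FALSE)
  expect_equal(back, net$edges)
  gp <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gp)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 2)
  fp <- tempfile(fileext = ".json")
  write_power_law_fit(fit_power_law(data.frame(degree = c(1, 2, 4),
                                               count = c(9, 4, 1))), fp)
  obj <- jsonlite::read_json(fp, simplifyVector = TRUE)
  expect_named(obj, c("a", "b", "r_squared"))
})
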