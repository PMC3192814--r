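test_that("degree grouping reproduces hand-computed group means", {
  scheme <- degree_scheme(c("1", "2-6", ">6"), c(1, 2, 7), c(1, 6, Inf))
  dat <- data.frame(degree = c(1, 1, 5, 9), value = c(2, 4, 6, 8))
  gs <- group_by_degree(dat, scheme)
  expect_equal(gs$mean, c(3, 6, 8))
  expect_equal(gs$n, c(2, 1, 1))
  expect_equal(gs$se[1], sd(c(2, 4)) / sqrt(2))
  # single-member groups get se = 0 and are flagged
  expect_equal(gs$se[2:3], c(0, 0))
  expect_true(all(gs$degenerate[2:3]))
  # one group covering everything is just the overall mean
  all_in <- group_by_degree(dat, degree_scheme("all", 1, Inf))
  expect_equal(all_in$mean, mean(dat$value))
  # missing property values are excluded pairwise
  dat$value[2] <- NA
  expect_equal(group_by_degree(dat, scheme)$n, c(1, 1, 1))
  expect_error(degree_scheme(c("a", "b"), c(1, 2), c(3, 9)),
               "disjoint")
})

test_that("Kruskal-Wallis H matches the hand rank-sum formula", {
  # 12/(N(N+1)) * sum(R^2/n) - 3(N+1) with ranks 1..9 = 7.2
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # no rank variation -> H = 0
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5, 5)))$H, 0)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("two-group Kruskal-Wallis agrees with the Mann-Whitney approximation", {
  set.seed(11)
  for (i in 1:5) {
    a <- sample(1:8, 6, replace = TRUE)
    b <- sample(3:10, 7, replace = TRUE)
    kw <- kruskal_wallis(list(a, b))
    mw <- mann_whitney(a, b)
    expect_equal(kw$p, mw$p, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U equals exhaustive pairwise counting", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)  # complete separation
  expect_equal(mann_whitney(1:4, 1:4)$U, 16 / 2)     # identical samples
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:5, 5, replace = TRUE)
    b <- sample(1:5, 5, replace = TRUE)
    wins <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    expect_equal(mann_whitney(a, b)$U, min(wins, 25 - wins))
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(3)
  a <- rnorm(8); b <- rnorm(9, 1); c3 <- rnorm(7, 2)
  f <- function(x) exp(x) + x^3  # strictly increasing
  expect_equal(kruskal_wallis(list(a, b, c3)),
               kruskal_wallis(list(f(a), f(b), f(c3))))
  expect_equal(mann_whitney(a, b), mann_whitney(f(a), f(b)))
})

test_that("binned correlation uses ordinal bin rank and hand Pearson arithmetic", {
  lin <- data.frame(n = rep(5, 4), mean = c(1, 2, 3, 4))
  expect_equal(binned_correlation(lin)$R, 1)
  expect_warning(out <- binned_correlation(data.frame(n = rep(2, 3),
                                                      mean = rep(1, 3))),
                 "zero variance")
  expect_equal(out$R, 0)
  means <- c(3, 2, 1, 0.5, 0.2)
  x <- 1:5
  r_hand <- (5 * sum(x * means) - sum(x) * sum(means)) /
    sqrt((5 * sum(x^2) - sum(x)^2) * (5 * sum(means^2) - sum(means)^2))
  expect_equal(binned_correlation(data.frame(n = rep(3, 5), mean = means))$R,
               r_hand, tolerance = 1e-12)
  # empty bins are dropped before the bin-count check
  expect_error(binned_correlation(data.frame(n = c(3, 0, 3), mean = c(1, NA, 2))),
               "insufficient")
})

test_that("early/late classification partitions the network", {
  nodes <- sprintf("N%02d", 1:12)
  emap <- list(E1 = nodes[1:4], E2 = nodes[5:6], E3 = c(nodes[7:8], "OFFNET"))
  ages <- c(E1 = "1", E2 = "3", E3 = "1")
  res <- classify_age(nodes, emap, ages, aerobic = nodes[2])
  expect_setequal(res$early, c(nodes[c(1, 3, 4)], nodes[7:8]))
  expect_setequal(res$late, setdiff(nodes, res$early))
  expect_length(intersect(res$early, res$late), 0)
  expect_setequal(union(res$early, res$late), nodes)
  # all enzymes oldest and no aerobic exclusions -> nothing is late
  all_old <- classify_age(nodes[1:6], list(E = nodes[1:6]), c(E = "1"))
  expect_length(all_old$late, 0)
  expect_error(classify_age(nodes, list(EX = nodes[1]), ages), "EX")
})

test_that("degree-linked chemistry surfaces as a negative degree-logP correlation", {
  gen <- gen_degree_linked_network(150, strength = 1, seed = 5)
  panel <- build_panel(gen$molecules[, c("id", "smiles")])
  merged <- merge(gen$degree_table, panel, by = "id")
  scheme <- degree_scheme(c("1-2", "3-5", "6-10", ">10"),
                          c(1, 3, 6, 11), c(2, 5, 10, Inf))
  gs <- group_by_degree(data.frame(degree = merged$degree, value = merged$logp),
                        scheme)
  res <- binned_correlation(gs)
  expect_lte(res$R, -0.9)
})

test_that("descriptor summaries tabulate group means with rank-test columns", {
  gen <- gen_degree_linked_network(80, strength = 1, seed = 2)
  panel <- build_panel(gen$molecules[, c("id", "smiles")])
  scheme <- degree_scheme(c("1-2", "3-6", ">6"), c(1, 3, 7), c(2, 6, Inf))
  tab <- descriptor_group_summary(gen$degree_table, panel, scheme,
                                  descriptors = c("logp", "fpsa3"))
  expect_equal(nrow(tab), 6)
  expect_true(all(c("descriptor", "label", "n", "mean", "se", "H", "p") %in%
                    names(tab)))
  # group sizes partition the metabolites with non-missing values
  expect_equal(sum(tab$n[tab$descriptor == "logp"]), nrow(panel))
})
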