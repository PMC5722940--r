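# Topology statistics against brute-force oracles and closed forms.

edge_df <- function(a, b) {
  data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
}

test_that("degree distribution is an exact census (self-loops count once)", {
  tri <- edge_df(c("a", "b", "a"), c("b", "c", "c"))
  expect_equal(degree_distribution(tri), c("2" = 3L))
  star <- edge_df(rep("h", 4), sprintf("l%d", 1:4))
  expect_equal(degree_distribution(star), c("1" = 4L, "4" = 1L))
  loop <- edge_df(c("x", "x"), c("x", "y"))
  expect_equal(degree_distribution(loop), c("1" = 1L, "2" = 1L))

  set.seed(3)
  for (rep in 1:10) {
    g <- random_edge_df(sample(10:50, 1), sample(10:40, 1))
    census <- table(table(c(g$protein_a, g$protein_b)))
    got <- degree_distribution(g)
    expect_equal(got, stats::setNames(as.integer(census), names(census)))
  }
})

test_that("power-law fit recovers exact exponents to machine precision", {
  k <- 1:32
  expect_equal(fit_power_law(stats::setNames(1000 * k^-2, k)), 2,
               tolerance = 1e-9)
  expect_equal(fit_power_law(stats::setNames(1000 * k^-3, k)), 3,
               tolerance = 1e-9)
  expect_error(fit_power_law(c("1" = 5, "2" = 3)), "at least 3")
})

test_that("preferential-attachment networks fit in the scale-free exponent range", {
  set.seed(107)
  g <- igraph::sample_pa(10000, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- edge_df(sprintf("p%05d", el[, 1]), sprintf("p%05d", el[, 2]))
  gamma <- fit_power_law(degree_distribution(edges))
  expect_gt(gamma, 1.8)
  expect_lt(gamma, 3.5)
  # independent fit: direct least squares on the log-log points
  hist <- degree_distribution(edges)
  kk <- log10(as.numeric(names(hist)))
  pp <- log10(as.numeric(hist) / sum(hist))
  slope <- sum((kk - mean(kk)) * (pp - mean(pp))) / sum((kk - mean(kk))^2)
  expect_equal(gamma, -slope, tolerance = 1e-9)
})

test_that("average path length matches enumerable cases and the BFS oracle", {
  tri <- edge_df(c("a", "b", "a"), c("b", "c", "c"))
  expect_equal(average_path_length(tri), 1)
  path <- edge_df(c("a", "b"), c("b", "c"))
  expect_equal(average_path_length(path), 4 / 3)
  two <- edge_df(c("a", "c"), c("b", "d"))
  expect_equal(average_path_length(two), 1)  # cross-component pairs excluded
  # only self-loops: two nodes but no connected distinct pair
  expect_error(average_path_length(edge_df(c("a", "b"), c("a", "b"))),
               "connected pair")
})

test_that("clustering coefficient matches hand enumeration and conventions", {
  tri <- edge_df(c("a", "b", "a"), c("b", "c", "c"))
  expect_equal(clustering_coefficient(tri), 1)
  star <- edge_df(rep("h", 4), sprintf("l%d", 1:4))
  expect_equal(clustering_coefficient(star), 0)
  # triangle plus pendant: a-b-c triangle, c-d pendant
  toy <- edge_df(c("a", "b", "a", "c"), c("b", "c", "c", "d"))
  expect_equal(clustering_coefficient(toy), mean(c(1, 1, 1 / 3, 0)))
})

test_that("L and C agree with brute-force BFS/triangle oracles on random graphs", {
  set.seed(59)
  for (rep in 1:15) {
    n <- sample(5:60, 1)
    m <- sample(n:min(3 * n, n * (n - 1) / 2), 1)
    g <- random_edge_df(n, m)
    expect_equal(average_path_length(g), oracle_avg_path_length(g),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient(g), oracle_clustering(g),
                 tolerance = 1e-12)
  }
})

test_that("the G(n,m) reference is exact, seeded and feasibility-checked", {
  k4 <- random_reference(4, 6, seed = 1)
  expect_equal(nrow(k4), 6L)
  expect_equal(average_path_length(k4), 1)  # saturated -> complete graph

  a <- random_reference(100, 300, seed = 9)
  b <- random_reference(100, 300, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, random_reference(100, 300, seed = 10)))

  big <- random_reference(1000, 3000, seed = 2)
  expect_equal(nrow(big), 3000L)
  deg <- degree_distribution(big)
  expect_equal(sum(as.numeric(names(deg)) * deg), 2 * 3000)  # degree sum 2m
  expect_equal(2 * nrow(big) / 1000, 6)                      # mean degree 2m/n

  expect_error(random_reference(4, 7, seed = 1), "infeasible")
})

test_that("small-world comparison behaves on known generators", {
  set.seed(71)
  # clustered network: preferential attachment + triadic closure surrogate
  g <- igraph::sample_smallworld(1, 200, 4, 0.05)
  el <- igraph::as_edgelist(g)
  edges <- unique(edge_df(sprintf("n%03d", pmin(el[, 1], el[, 2])),
                          sprintf("n%03d", pmax(el[, 1], el[, 2]))))
  edges <- edges[edges$protein_a != edges$protein_b, ]
  rep1 <- small_world_report(edges, seed = 5, n_reference = 5)
  expect_true(rep1$L_ge_random)
  expect_true(rep1$C_exceeds_random)
  expect_gt(rep1$C_ratio, 1)

  # an ER graph against its own distribution shows no clustering excess
  er <- random_reference(200, 800, seed = 77)
  rep2 <- small_world_report(er, seed = 6, n_reference = 5)
  expect_false(rep2$C_exceeds_random)

  # complete graph: L = L_random = 1
  k5 <- random_reference(5, 10, seed = 1)
  rep3 <- small_world_report(k5, seed = 2, n_reference = 3)
  expect_equal(rep3$L, 1)
  expect_equal(rep3$L_random, 1)
})

test_that("network_stats aggregates the component statistics coherently", {
  set.seed(83)
  g <- random_edge_df(30, 45)
  s <- network_stats(g)
  expect_equal(s$n_nodes, sum(s$degree_histogram))
  expect_equal(s$n_edges, 45L)
  expect_equal(s$avg_path_length, oracle_avg_path_length(g))
  d <- oracle_dist_matrix(g)
  expect_equal(s$diameter, max(d[is.finite(d)]))
})
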