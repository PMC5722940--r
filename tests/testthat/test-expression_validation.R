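# Expression support, Pearson co-expression and component classification.

ts_dataset <- function(m, id = "ts1", kind = "time_series") {
  expression_dataset(id, kind, m)
}

test_that("high-expression filter keeps genes strictly above the percentile cutoff", {
  m <- matrix(rep(1:10, each = 3), ncol = 3, byrow = TRUE,
              dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2", "s3")))
  expect_setequal(high_expression_set(ts_dataset(m, kind = "gene_matrix")),
                  c("g09", "g10"))
  # all-equal summaries: nothing is strictly above
  flat <- matrix(5, nrow = 4, ncol = 3,
                 dimnames = list(sprintf("g%d", 1:4), c("a", "b", "c")))
  expect_length(high_expression_set(ts_dataset(flat, kind = "gene_matrix")), 0)
  # a single gene never exceeds its own rank
  one <- matrix(1:3, nrow = 1, dimnames = list("g1", c("a", "b", "c")))
  expect_length(high_expression_set(ts_dataset(one, kind = "gene_matrix")), 0)
  expect_error(
    high_expression_set(expression_dataset("e", "gene_matrix",
      matrix(numeric(), 0, 3, dimnames = list(NULL, c("a", "b", "c"))))),
    "empty")
})

test_that("expressed_protein_set unions presence lists and high-expression genes", {
  pres <- expression_dataset("p1", "protein_presence", c("a", "b"))
  m <- matrix(c(1, 1, 1, 9, 9, 9, 2, 2, 2, 1, 1, 1, 1, 1, 1), ncol = 3,
              byrow = TRUE,
              dimnames = list(c("x1", "c", "x2", "x3", "x4"),
                              c("s1", "s2", "s3")))
  mat <- ts_dataset(m, "m1", "gene_matrix")
  got <- expressed_protein_set(list(pres, mat))
  expect_setequal(got, c("a", "b", "c"))
  expect_length(expressed_protein_set(list()), 0)
})

test_that("edge expression support requires both endpoints", {
  net <- data.frame(protein_a = c("a", "a", "c", "d"),
                    protein_b = c("b", "c", "d", "e"),
                    stringsAsFactors = FALSE)
  out <- flag_edge_expression(net, c("a", "b"))
  expect_equal(out$expression_supported, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(attr(out, "fraction_supported"), 0.25)
})

test_that("pearson_with_p matches its closed forms and the t-test oracle", {
  expect_equal(pearson_with_p(1:4, c(2, 4, 6, 8)),
               list(pcc = 1, p_value = 0, n_points = 4L))
  expect_equal(pearson_with_p(1:4, c(4, 3, 2, 1))$pcc, -1)

  # hand-computable near-linear case, checked against cor.test
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  got <- pearson_with_p(x, y)
  ct <- cor.test(x, y)
  expect_equal(got$pcc, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)

  set.seed(19)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_with_p(x, y)
    # independent oracle: covariance formula + t transform
    r0 <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t0 <- r0 * sqrt((n - 2) / (1 - r0^2))
    expect_equal(got$pcc, r0, tolerance = 1e-12)
    expect_equal(got$p_value, 2 * pt(-abs(t0), n - 2), tolerance = 1e-12)
    # invariance under positive affine maps; sign flip under negation
    expect_equal(pearson_with_p(2 * x + 3, y)$pcc, r0, tolerance = 1e-12)
    expect_equal(pearson_with_p(-x, y)$pcc, -r0, tolerance = 1e-12)
  }

  expect_error(pearson_with_p(1:2, 1:2), "at least 3")
  expect_error(pearson_with_p(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("co-expression uses strict thresholds with the any-dataset rule", {
  m1 <- rbind(a = c(1, 2, 3, 4), b = c(1.5, 1, 3.4, 2))
  colnames(m1) <- sprintf("t%d", 1:4)
  m2 <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  colnames(m2) <- sprintf("t%d", 1:4)
  net <- data.frame(protein_a = "a", protein_b = "b",
                    stringsAsFactors = FALSE)
  res <- find_coexpressed_edges(net, list(ts_dataset(m1, "d1"),
                                          ts_dataset(m2, "d2")))
  expect_equal(res$coexpressed, c(FALSE, TRUE))  # dataset 2 only
  flagged <- flag_coexpression(net, res)
  expect_true(flagged$coexpressed)

  # a PCC exactly at the threshold is rejected (strict >): with pcc_min = 1
  # the perfectly correlated pair (pcc == 1, p == 0) must not qualify
  res3 <- find_coexpressed_edges(net, list(ts_dataset(m2, "d2")),
                                 pcc_min = 1)
  expect_equal(res3$pcc, 1)
  expect_false(res3$coexpressed)

  # zero-variance endpoint: recorded, not co-expressed
  m4 <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4))
  colnames(m4) <- sprintf("t%d", 1:4)
  res4 <- find_coexpressed_edges(net, list(ts_dataset(m4)))
  expect_false(res4$coexpressed)
  expect_true(is.na(res4$pcc))

  # missing profile: dataset skipped for that edge
  m5 <- rbind(a = c(1, 2, 3, 4)); colnames(m5) <- sprintf("t%d", 1:4)
  expect_equal(nrow(find_coexpressed_edges(net, list(ts_dataset(m5)))), 0L)
})

test_that("co-expression groups classify by size and cycle structure", {
  single <- data.frame(protein_a = "M3", protein_b = "SUMO1",
                       stringsAsFactors = FALSE)
  expect_equal(classify_coexpression_groups(single)$shape, "heterodimeric")

  path3 <- data.frame(protein_a = c("a", "b"), protein_b = c("b", "c"),
                      stringsAsFactors = FALSE)
  expect_equal(classify_coexpression_groups(path3)$shape, "linear_multimeric")

  tri <- data.frame(protein_a = c("NOC2P", "RRB", "NOC2P"),
                    protein_b = c("RRB", "PES", "PES"),
                    stringsAsFactors = FALSE)
  expect_equal(classify_coexpression_groups(tri)$shape, "circular_multimeric")

  # branched tree reported linear with a warning flag
  star <- data.frame(protein_a = "h", protein_b = c("x", "y", "z"),
                     stringsAsFactors = FALSE)
  expect_warning(got <- classify_coexpression_groups(star), "branched")
  expect_equal(got$shape, "linear_multimeric")
  expect_true(got$branched)

  # multiple components classified independently
  multi <- rbind(single, path3, tri)
  got2 <- suppressWarnings(classify_coexpression_groups(multi))
  expect_setequal(got2$shape, c("heterodimeric", "linear_multimeric",
                                "circular_multimeric"))
})

test_that("classification matches the cycle-detection oracle on small graphs", {
  set.seed(29)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    m <- sample(1:min(10, n * (n - 1) / 2), 1)
    edges <- random_edge_df(n, m)
    groups <- suppressWarnings(classify_coexpression_groups(edges))
    for (k in seq_len(nrow(groups))) {
      members <- groups$members[[k]]
      sub <- edges[edges$protein_a %in% members &
                     edges$protein_b %in% members, , drop = FALSE]
      cyc <- oracle_has_cycle(sub)
      if (cyc) {
        expect_equal(groups$shape[k], "circular_multimeric")
      } else if (length(members) == 2) {
        expect_equal(groups$shape[k], "heterodimeric")
      } else {
        expect_equal(groups$shape[k], "linear_multimeric")
      }
    }
    # permutation invariance
    perm <- edges[sample.int(nrow(edges)), , drop = FALSE]
    got_p <- suppressWarnings(classify_coexpression_groups(perm))
    expect_setequal(vapply(got_p$members, paste, character(1), collapse = ","),
                    vapply(groups$members, paste, character(1), collapse = ","))
  }
})
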