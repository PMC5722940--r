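# Interolog transfer, provenance merging, and hub/subnetwork queries.

orthomap_from <- function(...) {
  pairs <- list(...)
  data.frame(template_id = rep(names(pairs), lengths(pairs)),
             target_id = unlist(pairs), stringsAsFactors = FALSE)
}

test_that("transfer enumerates ortholog combinations and merges provenance", {
  # minimal 1:1 transfer
  p1 <- transfer_interactions(make_template(a = "A", b = "B"),
                              orthomap_from(A = "a", B = "b"))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$n_species, 1L)

  # many-to-one cross-product
  p2 <- transfer_interactions(make_template(a = "A", b = "B"),
                              orthomap_from(A = c("a1", "a2"), B = "b"))
  expect_setequal(paste(p2$protein_a, p2$protein_b),
                  c("a1 b", "a2 b"))

  # two species witnessing the same pair merge into one prediction
  tpl <- rbind(make_template("ath", "A", "B", "computational"),
               make_template("osa", "A2", "B2", "experimental"))
  p3 <- transfer_interactions(tpl, orthomap_from(A = "a", B = "b",
                                                 A2 = "a", B2 = "b"))
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$n_species, 2L)
  expect_setequal(p3$provenance[[1]]$species, c("ath", "osa"))
  expect_setequal(p3$provenance[[1]]$evidence_method,
                  c("computational", "experimental"))

  # shared ortholog yields a retained self-pair
  p4 <- transfer_interactions(make_template(a = "A", b = "B"),
                              orthomap_from(A = "a", B = "a"))
  expect_equal(p4$protein_a, "a")
  expect_equal(p4$protein_b, "a")

  # unmapped endpoints are skipped and counted
  tpl5 <- rbind(make_template(a = "A", b = "B"),
                make_template(a = "X", b = "B"))
  p5 <- transfer_interactions(tpl5, orthomap_from(A = "a", B = "b"))
  expect_equal(nrow(p5), 1L)
  expect_equal(attr(p5, "n_skipped"), 1L)
})

test_that("predicted pair set equals nested-loop enumeration on random instances", {
  set.seed(7)
  for (rep in 1:10) {
    n_t <- sample(50:200, 1)
    tpl_prot <- sprintf("A%02d", 1:25)
    tpl <- data.frame(
      species = sample(c("ath", "osa"), n_t, replace = TRUE),
      protein_a = sample(tpl_prot, n_t, replace = TRUE),
      protein_b = sample(tpl_prot, n_t, replace = TRUE),
      evidence_method = sample(c("experimental", "computational"), n_t,
                               replace = TRUE),
      source_db = "dbA", stringsAsFactors = FALSE)
    mapped <- sample(tpl_prot, 15)
    om <- orthomap_from()
    om <- data.frame(
      template_id = rep(mapped, sample(1:3, 15, replace = TRUE)),
      stringsAsFactors = FALSE)
    om$target_id <- sprintf("t%02d", sample.int(30, nrow(om), replace = TRUE))
    om <- unique(om)
    got <- transfer_interactions(tpl, om)
    expect_identical(sort(pkey(got$protein_a, got$protein_b)),
                     oracle_transfer_keys(tpl, om))
  }
})

test_that("every provenance witness maps to exactly one input template interaction", {
  set.seed(11)
  tpl <- unique(data.frame(
    species = sample(c("ath", "osa", "stu"), 60, replace = TRUE),
    protein_a = sample(sprintf("A%d", 1:10), 60, replace = TRUE),
    protein_b = sample(sprintf("A%d", 1:10), 60, replace = TRUE),
    evidence_method = sample(c("experimental", "computational"), 60,
                             replace = TRUE),
    source_db = sample(c("dbA", "dbB"), 60, replace = TRUE),
    stringsAsFactors = FALSE))
  om <- data.frame(template_id = sprintf("A%d", 1:10),
                   target_id = sprintf("t%d", 1:10),
                   stringsAsFactors = FALSE)  # 1:1 map: witnesses conserved
  got <- transfer_interactions(tpl, om)
  witnesses <- do.call(rbind, got$provenance)
  tpl_key <- paste(tpl$species, pmin(tpl$protein_a, tpl$protein_b),
                   pmax(tpl$protein_a, tpl$protein_b), tpl$evidence_method,
                   tpl$source_db)
  wit_key <- paste(witnesses$species,
                   pmin(witnesses$template_a, witnesses$template_b),
                   pmax(witnesses$template_a, witnesses$template_b),
                   witnesses$evidence_method, witnesses$source_db)
  expect_identical(sort(wit_key), sort(tpl_key))
})

test_that("first_neighbors returns the induced neighborhood edge set", {
  star <- data.frame(protein_a = "hub",
                     protein_b = sprintf("l%d", 1:5),
                     stringsAsFactors = FALSE)
  expect_equal(nrow(first_neighbors(star, "hub")), 5L)
  expect_equal(nrow(first_neighbors(star, "l1")), 1L)

  tri <- data.frame(protein_a = c("a", "b", "a"),
                    protein_b = c("b", "c", "c"), stringsAsFactors = FALSE)
  expect_equal(nrow(first_neighbors(tri, "a")), 3L)  # induced, not incident

  expect_error(first_neighbors(star, "nope"), "not present")
})

test_that("hub ranking sorts by degree with lexicographic ties and counts self-loops once", {
  path <- data.frame(protein_a = c("a", "b"), protein_b = c("b", "c"),
                     stringsAsFactors = FALSE)
  got <- rank_hubs(path)
  expect_equal(got$protein, c("b", "a", "c"))
  expect_equal(got$degree, c(2L, 1L, 1L))

  withloop <- data.frame(protein_a = c("x", "x"), protein_b = c("x", "y"),
                         stringsAsFactors = FALSE)
  got2 <- rank_hubs(withloop)
  expect_equal(got2$degree[got2$protein == "x"], 2L)

  # planted hub in a preferential-attachment network ranks first
  set.seed(5)
  g <- igraph::sample_pa(200, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(protein_a = sprintf("p%03d", el[, 1]),
                      protein_b = sprintf("p%03d", el[, 2]),
                      stringsAsFactors = FALSE)
  census <- table(c(edges$protein_a, edges$protein_b))
  expect_equal(rank_hubs(edges, 1)$protein,
               names(census)[which.max(census)])
  expect_equal(rank_hubs(edges, 1)$degree, max(census))
})
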