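# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph, where the package uses it).

pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# nested-loop interolog transfer: the set of canonical target pair keys
oracle_transfer_keys <- function(templates, orthomap) {
  keys <- character()
  for (i in seq_len(nrow(templates))) {
    ta <- orthomap$target_id[orthomap$template_id == templates$protein_a[i]]
    tb <- orthomap$target_id[orthomap$template_id == templates$protein_b[i]]
    for (a in ta) for (b in tb) {
      keys <- c(keys, pkey(a, b))
    }
  }
  sort(unique(keys))
}

# adjacency list over distinct endpoints, self-loops dropped
oracle_adj <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- stats::setNames(lapply(nodes, function(x) character()), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$protein_a[i]; b <- edges$protein_b[i]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# all-pairs BFS shortest-path matrix (hops; Inf when unreachable)
oracle_dist_matrix <- function(edges) {
  adj <- oracle_adj(edges)
  nodes <- names(adj)
  n <- length(nodes)
  dmat <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (!is.finite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    dmat[s, ] <- dist
  }
  dmat
}

# mean shortest path over connected unordered pairs of distinct nodes
oracle_avg_path_length <- function(edges) {
  d <- oracle_dist_matrix(edges)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

# mean local clustering coefficient (C_i = 0 for degree < 2)
oracle_clustering <- function(edges) {
  adj <- oracle_adj(edges)
  cs <- vapply(names(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    cnt <- 0L
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) cnt <- cnt + 1L
    }
    2 * cnt / (k * (k - 1))
  }, numeric(1))
  mean(cs)
}

# DFS cycle detection on an undirected connected (or not) simple graph
oracle_has_cycle <- function(edges) {
  # parallel rows or self-loops are cycles outright
  if (any(edges$protein_a == edges$protein_b)) return(TRUE)
  if (anyDuplicated(pkey(edges$protein_a, edges$protein_b))) return(TRUE)
  adj <- oracle_adj(edges)
  color <- stats::setNames(rep(0L, length(adj)), names(adj))
  for (root in names(adj)) {
    if (color[root]) next
    stack <- list(c(root, NA))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      v <- top[1L]; parent <- top[2L]
      if (color[v]) return(TRUE)  # reached twice along distinct paths
      color[v] <- 1L
      for (w in adj[[v]]) {
        if (is.na(parent) || w != parent) {
          if (color[w]) return(TRUE)
          stack[[length(stack) + 1L]] <- c(w, v)
        }
      }
    }
  }
  FALSE
}

# Hazen percentile rank then tier split, computed pointwise
oracle_tiers <- function(cv, hi = 80, lo = 50) {
  n <- length(cv)
  vapply(cv, function(v) {
    r <- 100 * (sum(cv < v) + sum(cv == v) / 2) / n
    if (r > hi) "H1" else if (r >= lo) "H2" else "H3"
  }, character(1))
}

# random simple graph as an edge data frame (node names v01..)
random_edge_df <- function(n_nodes, n_edges) {
  all_pairs <- t(utils::combn(n_nodes, 2))
  pick <- all_pairs[sample.int(nrow(all_pairs), n_edges), , drop = FALSE]
  data.frame(protein_a = sprintf("v%02d", pick[, 1]),
             protein_b = sprintf("v%02d", pick[, 2]),
             stringsAsFactors = FALSE)
}

# one alignment hit row in the package's internal shape
make_hit <- function(query = "Q1", subject = "S1", identity = 80,
                     qstart = 1L, qend = 200L, evalue = 1e-30,
                     qlen = 200L) {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = identity, align_start_q = as.integer(qstart),
             align_end_q = as.integer(qend), evalue = evalue,
             query_length = as.integer(qlen), stringsAsFactors = FALSE)
}

# small template-interaction row
make_template <- function(species = "ath", a = "A", b = "B",
                          evidence = "computational", source = "dbA") {
  data.frame(species = species, protein_a = pmin(a, b),
             protein_b = pmax(a, b), evidence_method = evidence,
             source_db = source, stringsAsFactors = FALSE)
}

# tiny world configuration for fast recovery tests (overridable defaults)
small_world_config <- function(...) {
  args <- utils::modifyList(
    list(species = c("ath", "osa", "stu"), edges_per_species = c(45, 18, 8),
         n_groups = 40, n_presence = 1, n_matrix = 0, n_timeseries = 1),
    list(...))
  do.call(world_config, args)
}
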