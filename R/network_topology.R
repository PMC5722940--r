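# Global topology statistics: degree distribution and power-law exponent,
# average shortest-path length, clustering coefficient, and matched
# Erdos-Renyi G(n, m) references for the small-world comparison.

edges_to_graph <- function(network, drop_loops = TRUE) {
  g <- igraph::graph_from_data_frame(
    network[, c("protein_a", "protein_b"), drop = FALSE], directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = drop_loops)
}

# restore the caller's RNG stream after seeded simulation
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Degree distribution of a network
#'
#' Exact degree census over the edge table; a self-loop adds 1 to its node's
#' degree, parallel rows are counted as given.
#'
#' @param network Edge data frame with `protein_a`, `protein_b` columns.
#' @return Named integer vector mapping degree `k` (names) to node count.
#' @export
degree_distribution <- function(network) {
  self <- network$protein_a == network$protein_b
  ends <- c(network$protein_a[!self], network$protein_b[!self],
            network$protein_a[self])
  deg <- table(ends)
  hist <- table(as.integer(deg))
  stats::setNames(as.integer(hist), names(hist))
}

#' Fit a power-law exponent to a degree histogram
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over degrees `k >= 1`
#' with `P(k) > 0`; returns `-slope` as the exponent gamma of
#' `P(k) ~ k^-gamma`. Matches the log-log straight-line fitting practice of
#' network-analysis GUIs rather than maximum likelihood.
#'
#' @param histogram Named numeric vector (names = degree, values = counts),
#'   as returned by [degree_distribution()].
#' @return The fitted exponent gamma.
#' @export
fit_power_law <- function(histogram) {
  k <- as.numeric(names(histogram))
  cnt <- as.numeric(histogram)
  keep <- k >= 1 & cnt > 0
  k <- k[keep]
  p <- cnt[keep] / sum(cnt[keep])
  if (length(k) < 3L) {
    stop("power-law fit needs at least 3 distinct degrees with nonzero counts",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = log10(k), y = log10(p)))
  -unname(stats::coef(fit)[2L])
}

#' Average shortest-path length
#'
#' Mean shortest-path length (in hops) over all unordered pairs of distinct
#' nodes that are connected; unreachable pairs are excluded from both
#' numerator and denominator. Self-loops are ignored.
#'
#' @param network Edge data frame.
#' @return The average path length L.
#' @export
average_path_length <- function(network) {
  g <- edges_to_graph(network)
  if (igraph::vcount(g) < 2L) stop("need at least 2 nodes", call. = FALSE)
  L <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(L)) stop("no connected pair of distinct nodes", call. = FALSE)
  L
}

#' Mean local clustering coefficient
#'
#' Local `C_i = 2 * (edges among neighbors) / (k_i * (k_i - 1))` for nodes of
#' degree >= 2 and `C_i = 0` otherwise, averaged over all nodes. Self-loops
#' are excluded from neighbor sets.
#'
#' @param network Edge data frame.
#' @return Mean clustering coefficient in \[0, 1\].
#' @export
clustering_coefficient <- function(network) {
  g <- edges_to_graph(network)
  if (igraph::vcount(g) < 1L) stop("need at least 1 node", call. = FALSE)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Network diameter
#'
#' Maximum finite shortest-path length over connected node pairs.
#'
#' @param network Edge data frame.
#' @return Integer diameter.
#' @export
network_diameter <- function(network) {
  g <- edges_to_graph(network)
  igraph::diameter(g, directed = FALSE, unconnected = TRUE)
}

#' Matched uniform random reference network
#'
#' Seeded Erdos-Renyi G(n, m) graph: a uniform random simple graph with
#' exactly `n_nodes` nodes and `n_edges` edges, matching the observed
#' network's node count and average edge count.
#'
#' @param n_nodes,n_edges Node and edge counts; `n_edges` must not exceed
#'   `n (n - 1) / 2`.
#' @param seed Integer seed (the caller's RNG stream is left untouched).
#' @return Edge data frame with `protein_a`, `protein_b` columns (node ids
#'   `v1..vn`).
#' @export
random_reference <- function(n_nodes, n_edges, seed) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2) {
    stop("infeasible edge count: ", n_edges, " > n(n-1)/2", call. = FALSE)
  }
  g <- with_seed(seed, igraph::sample_gnm(n_nodes, n_edges, directed = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  p <- canonical_pair(paste0("v", el[, 1L]), paste0("v", el[, 2L]))
  df <- data.frame(protein_a = p$a, protein_b = p$b, stringsAsFactors = FALSE)
  df[order(df$protein_a, df$protein_b, method = "radix"), , drop = FALSE]
}

#' Full topology statistics of a network
#'
#' @param network Edge data frame.
#' @param fit_gamma Attempt the power-law fit (NA when fewer than 3 support
#'   points).
#' @return List with `n_nodes`, `n_edges`, `degree_histogram`, `gamma`,
#'   `avg_path_length`, `clustering_coefficient`, `diameter`.
#' @export
network_stats <- function(network, fit_gamma = TRUE) {
  hist <- degree_distribution(network)
  gamma <- if (fit_gamma) {
    tryCatch(fit_power_law(hist), error = function(e) NA_real_)
  } else NA_real_
  L <- tryCatch(average_path_length(network), error = function(e) NA_real_)
  list(n_nodes = sum(hist),
       n_edges = nrow(network),
       degree_histogram = hist,
       gamma = gamma,
       avg_path_length = L,
       clustering_coefficient = clustering_coefficient(network),
       diameter = network_diameter(network))
}

#' Small-world comparison against matched random references
#'
#' Computes (L, C) of the network and the mean (L, C) over `n_reference`
#' seeded G(n, m) references with the same node and edge counts, plus the two
#' small-world judgements: `L >= L_random` and `C / C_random >
#' ratio_threshold`.
#'
#' @param network Edge data frame.
#' @param seed Base integer seed; reference i uses `seed + i`.
#' @param n_reference Number of random references (default 10).
#' @param ratio_threshold Clustering-ratio threshold (default 2).
#' @return List with `L`, `C`, `L_random`, `C_random`, `L_ge_random`,
#'   `C_ratio`, `C_exceeds_random`.
#' @export
small_world_report <- function(network, seed, n_reference = 10,
                               ratio_threshold = 2) {
  L <- average_path_length(network)
  C <- clustering_coefficient(network)
  hist <- degree_distribution(network)
  n <- sum(hist)
  m <- nrow(unique(canonical_pair(network$protein_a, network$protein_b)))
  refs <- lapply(seq_len(n_reference), function(i) {
    r <- random_reference(n, m, seed + i)
    c(L = average_path_length(r), C = clustering_coefficient(r))
  })
  Lr <- mean(vapply(refs, `[[`, numeric(1), "L"))
  Cr <- mean(vapply(refs, `[[`, numeric(1), "C"))
  list(L = L, C = C, L_random = Lr, C_random = Cr,
       L_ge_random = L >= Lr,
       C_ratio = if (Cr > 0) C / Cr else Inf,
       C_exceeds_random = if (Cr > 0) C / Cr > ratio_threshold else C > 0)
}
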