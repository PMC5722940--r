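# Expression-based validation: which proteins are observed expressed, which
# edges connect two expressed proteins, and which interacting pairs are
# co-expressed over time-series profiles (Pearson r > 0.9, p < 0.1).

#' Highly expressed genes of a matrix dataset
#'
#' Each gene is summarized by its mean across samples; genes whose summary
#' lies strictly above the dataset's cutoff are returned, where the cutoff is
#' the inverse-ECDF (type-1) quantile of the summaries at `percentile`. With
#' all-equal summaries, or a single gene, nothing exceeds the cutoff.
#'
#' @param dataset An `expression_dataset` holding a matrix.
#' @param percentile Percentile rank cutoff (default 80).
#' @param summary Per-gene summary across samples: `"mean"` (default) or
#'   `"max"`.
#' @return Character vector of gene ids.
#' @export
high_expression_set <- function(dataset, percentile = 80, summary = "mean") {
  stopifnot(inherits(dataset, "expression_dataset"),
            dataset$kind %in% c("gene_matrix", "time_series"))
  m <- dataset$members
  if (nrow(m) == 0L) stop("empty expression matrix", call. = FALSE)
  s <- switch(match.arg(summary, c("mean", "max")),
              mean = rowMeans(m),
              max = apply(m, 1L, max))
  cutoff <- stats::quantile(s, probs = percentile / 100, type = 1,
                            names = FALSE)
  rownames(m)[s > cutoff]
}

#' Union of proteins with expression evidence
#'
#' Unions the members of every presence dataset with the highly expressed
#' genes of every matrix (gene matrix or time series) dataset.
#'
#' @param datasets List of `expression_dataset` objects.
#' @param percentile Percentile cutoff passed to [high_expression_set()].
#' @return Character vector of protein ids.
#' @export
expressed_protein_set <- function(datasets, percentile = 80) {
  ids <- lapply(datasets, function(ds) {
    stopifnot(inherits(ds, "expression_dataset"))
    if (ds$kind == "protein_presence") ds$members
    else high_expression_set(ds, percentile = percentile)
  })
  unique(unlist(c(list(character()), ids)))
}

#' Flag edges whose both endpoints are expressed
#'
#' @param network Edge data frame with `protein_a`, `protein_b` columns.
#' @param expressed_set Character vector of expressed protein ids.
#' @return `network` with an added logical `expression_supported` column; the
#'   supported fraction is attached as attribute `fraction_supported` (NaN for
#'   an empty network).
#' @export
flag_edge_expression <- function(network, expressed_set) {
  network$expression_supported <- network$protein_a %in% expressed_set &
    network$protein_b %in% expressed_set
  attr(network, "fraction_supported") <- mean(network$expression_supported)
  network
}

#' Pearson correlation with two-sided significance
#'
#' Sample Pearson correlation of two equal-length profiles; the p-value comes
#' from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom, two-sided. `r = +/-1` exactly gives `p = 0`.
#'
#' @param profile_x,profile_y Numeric vectors, `n >= 3`, nonzero variance.
#' @return List with `pcc`, `p_value`, `n_points`.
#' @export
pearson_with_p <- function(profile_x, profile_y) {
  n <- length(profile_x)
  if (length(profile_y) != n) stop("profiles differ in length", call. = FALSE)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::var(profile_x) == 0 || stats::var(profile_y) == 0) {
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(profile_x, profile_y)
  if (1 - r^2 <= 0) {
    p <- 0
    r <- sign(r)
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(pcc = r, p_value = p, n_points = n)
}

#' Detect co-expressed interacting pairs on time-series data
#'
#' For every edge and every time-series dataset in which both endpoint
#' profiles are available, the Pearson correlation and its p-value are
#' computed. An edge is co-expressed when any dataset satisfies both strict
#' thresholds (`pcc > pcc_min` and `p < p_max`). Zero-variance profiles make
#' the edge non-co-expressed in that dataset (recorded with NA statistics).
#'
#' @param network Edge data frame with `protein_a`, `protein_b` columns.
#' @param time_series_datasets List of `expression_dataset` objects of kind
#'   `time_series`.
#' @param pcc_min,p_max Strict thresholds (defaults 0.9 and 0.1).
#' @return Data frame of per-edge, per-dataset results: `protein_a`,
#'   `protein_b`, `dataset_id`, `pcc`, `p_value`, `n_points`, `coexpressed`.
#' @export
find_coexpressed_edges <- function(network, time_series_datasets,
                                   pcc_min = 0.9, p_max = 0.1) {
  res <- list()
  for (ds in time_series_datasets) {
    stopifnot(inherits(ds, "expression_dataset"),
              ds$kind == "time_series")
    m <- ds$members
    have <- network$protein_a %in% rownames(m) &
      network$protein_b %in% rownames(m)
    for (i in which(have)) {
      x <- m[network$protein_a[i], ]
      y <- m[network$protein_b[i], ]
      if (stats::var(x) == 0 || stats::var(y) == 0) {
        res[[length(res) + 1L]] <- data.frame(
          protein_a = network$protein_a[i], protein_b = network$protein_b[i],
          dataset_id = ds$dataset_id, pcc = NA_real_, p_value = NA_real_,
          n_points = ncol(m), coexpressed = FALSE, stringsAsFactors = FALSE)
        next
      }
      pp <- pearson_with_p(x, y)
      res[[length(res) + 1L]] <- data.frame(
        protein_a = network$protein_a[i], protein_b = network$protein_b[i],
        dataset_id = ds$dataset_id, pcc = pp$pcc, p_value = pp$p_value,
        n_points = pp$n_points,
        coexpressed = pp$pcc > pcc_min && pp$p_value < p_max,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      dataset_id = character(), pcc = numeric(),
                      p_value = numeric(), n_points = integer(),
                      coexpressed = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Flag co-expressed edges on a network
#'
#' @param network Edge data frame.
#' @param coexpression_results Result of [find_coexpressed_edges()].
#' @return `network` with an added logical `coexpressed` column (any-dataset
#'   rule).
#' @export
flag_coexpression <- function(network, coexpression_results) {
  hit <- coexpression_results[coexpression_results$coexpressed, , drop = FALSE]
  keys <- unique(pair_key(hit$protein_a, hit$protein_b))
  network$coexpressed <- pair_key(network$protein_a, network$protein_b) %in%
    keys
  network
}

#' Classify co-expressed components by topology
#'
#' Connected components of the co-expressed edge set are classified as
#' `heterodimeric` (exactly two proteins), `linear_multimeric` (three or more
#' proteins, acyclic — branched acyclic components are flagged with
#' `branched = TRUE` rather than forming a fourth class) or
#' `circular_multimeric` (contains a cycle).
#'
#' @param coexpressed_edges Edge data frame (`protein_a`, `protein_b`) among
#'   co-expressed pairs.
#' @return Data frame with one row per component: `shape`, `n_proteins`,
#'   `n_edges`, `branched`, and a `members` list-column of sorted protein ids.
#' @export
classify_coexpression_groups <- function(coexpressed_edges) {
  empty <- data.frame(shape = character(), n_proteins = integer(),
                      n_edges = integer(), branched = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(coexpressed_edges) == 0L) {
    empty$members <- list()
    return(empty)
  }
  p <- canonical_pair(coexpressed_edges$protein_a,
                      coexpressed_edges$protein_b)
  edges <- unique(data.frame(a = p$a, b = p$b, stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  rows <- lapply(seq_len(comp$no), function(k) {
    vs <- names(comp$membership)[comp$membership == k]
    sub <- igraph::induced_subgraph(g, vs)
    nv <- igraph::vcount(sub)
    ne <- igraph::ecount(sub)
    has_cycle <- ne >= nv  # connected component: tree iff ne == nv - 1
    shape <- if (has_cycle) "circular_multimeric"
             else if (nv == 2L) "heterodimeric"
             else "linear_multimeric"
    branched <- !has_cycle && nv >= 3L && max(igraph::degree(sub)) > 2
    if (branched) {
      warning("branched acyclic co-expression component reported as linear",
              call. = FALSE)
    }
    data.frame(shape = shape, n_proteins = nv, n_edges = ne,
               branched = branched, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(seq_len(comp$no), function(k) {
    sort(names(comp$membership)[comp$membership == k])
  })
  out
}
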