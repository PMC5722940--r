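# Interolog transfer: project template-species interactions onto the target
# species through the ortholog map, merging provenance across species.

#' Transfer template interactions through an ortholog map
#'
#' For every template interaction (A, B) in species s and every combination of
#' a in orthologs(A), b in orthologs(B), the target pair \{a, b\} is predicted
#' (full cross-product, not best-hit-only). Pairs witnessed repeatedly are
#' merged into one prediction whose provenance accumulates every distinct
#' (species, evidence_method, source_db, template pair) witness; the
#' supporting-species count N is the number of distinct species in the
#' provenance. Template interactions with an unmapped endpoint are skipped and
#' counted, not errors. Shared orthologs yield retained self-pairs.
#'
#' @param template_interactions Data frame from [read_template_ppi_tsv()].
#' @param ortholog_map Data frame from [filter_orthologs()].
#' @return A data frame of predictions with columns `protein_a`, `protein_b`
#'   (canonical order), `n_species` and a `provenance` list-column of witness
#'   data frames. Attributes: `n_skipped` (untransferable template
#'   interactions) and `species_counts` (named vector of inferred-interaction
#'   counts per template species).
#' @export
transfer_interactions <- function(template_interactions, ortholog_map) {
  tl <- ortholog_targets(ortholog_map)
  n <- nrow(template_interactions)
  wit <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ta <- tl[[template_interactions$protein_a[i]]]
    tb <- tl[[template_interactions$protein_b[i]]]
    if (is.null(ta) || is.null(tb)) {
      skipped <- skipped + 1L
      next
    }
    grid <- expand.grid(a = ta, b = tb, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    p <- canonical_pair(grid$a, grid$b)
    wit[[i]] <- data.frame(
      target_a = p$a, target_b = p$b,
      species = template_interactions$species[i],
      evidence_method = template_interactions$evidence_method[i],
      source_db = template_interactions$source_db[i],
      template_a = template_interactions$protein_a[i],
      template_b = template_interactions$protein_b[i],
      stringsAsFactors = FALSE)
  }
  wit <- do.call(rbind, wit)
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      n_species = integer(), stringsAsFactors = FALSE)
  if (is.null(wit) || nrow(wit) == 0L) {
    empty$provenance <- list()
    attr(empty, "n_skipped") <- skipped
    attr(empty, "species_counts") <- integer()
    return(empty)
  }
  # one witness per distinct (pair, species, evidence, source, template pair):
  # overlapping ortholog sets can emit the same witness twice
  wit <- unique(wit)
  key <- paste(wit$target_a, wit$target_b, sep = "\r")
  groups <- split(seq_len(nrow(wit)), key)
  ord <- order(names(groups), method = "radix")
  groups <- groups[ord]
  first <- vapply(groups, `[[`, integer(1), 1L)
  prov <- lapply(groups, function(idx) {
    p <- wit[idx, c("species", "evidence_method", "source_db",
                    "template_a", "template_b"), drop = FALSE]
    rownames(p) <- NULL
    p
  })
  out <- data.frame(protein_a = wit$target_a[first],
                    protein_b = wit$target_b[first],
                    n_species = vapply(prov, function(p)
                      length(unique(p$species)), integer(1)),
                    stringsAsFactors = FALSE)
  out$provenance <- unname(prov)
  rownames(out) <- NULL
  # per-species inferred-interaction counts (distinct target pairs witnessed
  # by each species), the analogue of a per-template summary table
  sp_pair <- unique(wit[, c("species", "target_a", "target_b")])
  counts <- table(sp_pair$species)
  attr(out, "n_skipped") <- skipped
  attr(out, "species_counts") <- stats::setNames(as.integer(counts),
                                                 names(counts))
  out
}

#' First-neighbor subnetwork of a protein
#'
#' Returns the induced edge set over the protein and its direct interaction
#' partners (so partner-partner edges are included).
#'
#' @param network Edge data frame with `protein_a`, `protein_b` columns.
#' @param protein_id Query protein; must be present in the network.
#' @return The subset of edge rows induced by the neighborhood.
#' @export
first_neighbors <- function(network, protein_id) {
  nodes <- c(network$protein_a, network$protein_b)
  if (!protein_id %in% nodes) {
    stop("protein '", protein_id, "' not present in the network",
         call. = FALSE)
  }
  nb <- unique(c(protein_id,
                 network$protein_b[network$protein_a == protein_id],
                 network$protein_a[network$protein_b == protein_id]))
  keep <- network$protein_a %in% nb & network$protein_b %in% nb
  out <- network[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hub proteins by degree
#'
#' Degree census over the edge set; a self-interaction adds 1 to its
#' protein's degree. Ties are broken lexicographically.
#'
#' @param network Edge data frame with `protein_a`, `protein_b` columns.
#' @param top_n Number of proteins to return (default: all).
#' @return A data frame with columns `protein`, `degree`, sorted by degree
#'   descending.
#' @export
rank_hubs <- function(network, top_n = Inf) {
  if (nrow(network) == 0L) stop("empty network", call. = FALSE)
  self <- network$protein_a == network$protein_b
  ends <- c(network$protein_a[!self], network$protein_b[!self],
            network$protein_a[self])
  tab <- table(ends)
  out <- data.frame(protein = names(tab), degree = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$protein, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
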