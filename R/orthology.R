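# Ortholog identification from BLASTp tabular hits.
#
# A template protein and a target protein are called orthologous when at least
# one alignment hit between them passes all three admission thresholds
# (identity >= 60 %, query coverage >= 80 %, e-value <= 1e-10 by default),
# boundary values inclusive. Orthology is one-way and many-to-many: no
# reciprocal-best-hit requirement, every hit row tested independently.

#' Query coverage of an alignment hit
#'
#' Coverage is defined over the query (template) protein: the aligned query
#' span as a percentage of the query length,
#' `100 * (align_end_q - align_start_q + 1) / query_length`.
#'
#' @param align_start_q,align_end_q 1-based inclusive query coordinates.
#' @param query_length Query length in residues.
#' @return Numeric coverage percentage(s).
#' @examples
#' compute_coverage(1, 200, 250)  # 80
#' @export
compute_coverage <- function(align_start_q, align_end_q, query_length) {
  100 * (align_end_q - align_start_q + 1) / query_length
}

#' Filter alignment hits into an ortholog map
#'
#' Admits a (template, target) protein pair when at least one hit satisfies
#' all three thresholds (inclusive: `>=`, `>=`, `<=`). Among multiple
#' admitting hits for the same pair, the hit with the smallest e-value is
#' recorded (ties broken by highest identity). Mappings are many-to-many.
#'
#' @param hits Alignment-hit data frame (see [read_blast_tab()]).
#' @param min_identity Minimum percent identity (default 60).
#' @param min_coverage Minimum query coverage percentage (default 80).
#' @param max_evalue Maximum e-value (default 1e-10).
#' @return A data frame with one row per admitted (template, target) pair:
#'   columns `template_id`, `target_id`, `percent_identity`, `coverage`,
#'   `evalue`.
#' @export
filter_orthologs <- function(hits, min_identity = 60, min_coverage = 80,
                             max_evalue = 1e-10) {
  cov <- compute_coverage(hits$align_start_q, hits$align_end_q,
                          hits$query_length)
  pass <- hits$percent_identity >= min_identity & cov >= min_coverage &
    hits$evalue <= max_evalue
  adm <- data.frame(template_id = hits$query_id[pass],
                    target_id = hits$subject_id[pass],
                    percent_identity = hits$percent_identity[pass],
                    coverage = cov[pass],
                    evalue = hits$evalue[pass],
                    stringsAsFactors = FALSE)
  if (nrow(adm) == 0L) return(adm)
  # best admitting hit per pair: smallest e-value, then highest identity
  ord <- order(adm$template_id, adm$target_id, adm$evalue,
               -adm$percent_identity, method = "radix")
  adm <- adm[ord, , drop = FALSE]
  key <- paste(adm$template_id, adm$target_id, sep = "\r")
  adm <- adm[!duplicated(key), , drop = FALSE]
  rownames(adm) <- NULL
  adm
}

# template protein id -> character vector of target ids
ortholog_targets <- function(ortholog_map) {
  split(ortholog_map$target_id, ortholog_map$template_id)
}
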