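# Domain-domain interaction (DDI) support for predicted interactions.
#
# For a protein pair with domain sets A and B, the enrichment D is the
# fraction of the |A| x |B| possible cross-domain pairs that are catalogued
# interacting domain pairs; the correction factor d halves the score when both
# proteins carry exactly one domain (where D is forced into {0, 1}); the
# DDI confidence component is CV_DDI = d * D.

ddi_rule_keys <- function(ddi_rules) {
  if (nrow(ddi_rules) == 0L) return(character())
  unique(pair_key(ddi_rules$domain_x, ddi_rules$domain_y))
}

#' Count catalogued interacting domain pairs between two proteins
#'
#' Counts the distinct unordered domain pairs (x in A, y in B) present in the
#' rule table. A rule matched in both orientations counts once; duplicate
#' accessions within a protein are collapsed first (sets, not multisets).
#'
#' @param domains_a,domains_b Character vectors of domain accessions (possibly
#'   empty).
#' @param ddi_rules Data frame of canonical rules (see [read_ddi_table()]).
#' @return Integer count of matched rules.
#' @export
count_ddi <- function(domains_a, domains_b, ddi_rules) {
  domains_a <- unique(domains_a)
  domains_b <- unique(domains_b)
  if (length(domains_a) == 0L || length(domains_b) == 0L) return(0L)
  grid <- expand.grid(x = domains_a, y = domains_b, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  keys <- unique(pair_key(grid$x, grid$y))
  sum(keys %in% ddi_rule_keys(ddi_rules))
}

#' Domain enrichment D
#'
#' `D = ddi_count / (n_dom_a * n_dom_b)`; defined as 0 when either protein has
#' no annotated domain.
#'
#' @param ddi_count Matched rule count(s).
#' @param n_dom_a,n_dom_b Distinct-domain counts of the two proteins.
#' @return Numeric enrichment ratio(s) in \[0, 1\].
#' @examples
#' compute_D(2, 3, 4)  # 2/12
#' @export
compute_D <- function(ddi_count, n_dom_a, n_dom_b) {
  # recycle all three arguments to a common length before the zero guard
  v <- data.frame(cnt = ddi_count, a = n_dom_a, b = n_dom_b)
  ifelse(v$a == 0 | v$b == 0, 0, v$cnt / (v$a * v$b))
}

#' Single-domain correction factor d
#'
#' 0.5 when both proteins carry exactly one domain, otherwise 1. The halving
#' compensates the bias of D for pairs where the ratio is forced into
#' \{0, 1\}.
#'
#' @param n_dom_a,n_dom_b Distinct-domain counts of the two proteins.
#' @return 0.5 or 1 (vectorized).
#' @export
compute_d <- function(n_dom_a, n_dom_b) {
  v <- data.frame(a = n_dom_a, b = n_dom_b)
  ifelse(v$a == 1 & v$b == 1, 0.5, 1)
}

#' Assess DDI support for one protein pair
#'
#' Composes [count_ddi()], [compute_D()] and [compute_d()]:
#' `cv_ddi = d * D`. Proteins absent from the annotation table have empty
#' domain sets.
#'
#' @param protein_a,protein_b Protein identifiers.
#' @param domain_annotations Data frame from [read_domain_table()], or a named
#'   list of domain character vectors.
#' @param ddi_rules Data frame from [read_ddi_table()].
#' @return A list with `ddi_count`, `n_dom_a`, `n_dom_b`, `D`, `d`, `cv_ddi`.
#' @export
assess_pair <- function(protein_a, protein_b, domain_annotations, ddi_rules) {
  dl <- as_domain_list(domain_annotations)
  da <- dl[[protein_a]] %||% character()
  db <- dl[[protein_b]] %||% character()
  cnt <- count_ddi(da, db, ddi_rules)
  na <- length(unique(da))
  nb <- length(unique(db))
  D <- compute_D(cnt, na, nb)
  d <- compute_d(na, nb)
  list(ddi_count = cnt, n_dom_a = na, n_dom_b = nb, D = D, d = d,
       cv_ddi = d * D)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

as_domain_list <- function(domain_annotations) {
  if (is.data.frame(domain_annotations)) {
    split(domain_annotations$domain_accession, domain_annotations$protein_id)
  } else {
    domain_annotations
  }
}

#' Add DDI assessment columns to a prediction table
#'
#' @param predictions Prediction data frame (see [transfer_interactions()]).
#' @param domain_annotations,ddi_rules As in [assess_pair()].
#' @return `predictions` with added columns `ddi_count`, `n_dom_a`, `n_dom_b`,
#'   `D`, `d`, `cv_ddi`.
#' @export
add_ddi_support <- function(predictions, domain_annotations, ddi_rules) {
  dl <- as_domain_list(domain_annotations)
  rule_keys <- ddi_rule_keys(ddi_rules)
  n <- nrow(predictions)
  cnt <- integer(n); na <- integer(n); nb <- integer(n)
  for (i in seq_len(n)) {
    da <- unique(dl[[predictions$protein_a[i]]] %||% character())
    db <- unique(dl[[predictions$protein_b[i]]] %||% character())
    na[i] <- length(da)
    nb[i] <- length(db)
    if (na[i] && nb[i]) {
      grid <- expand.grid(x = da, y = db, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      cnt[i] <- sum(unique(pair_key(grid$x, grid$y)) %in% rule_keys)
    }
  }
  predictions$ddi_count <- cnt
  predictions$n_dom_a <- na
  predictions$n_dom_b <- nb
  predictions$D <- compute_D(cnt, na, nb)
  predictions$d <- compute_d(na, nb)
  predictions$cv_ddi <- predictions$d * predictions$D
  predictions
}
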