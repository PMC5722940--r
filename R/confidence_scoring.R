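# Confidence scoring and tiering.
#
# CV_interolog = sum_i S_i M_i / N over the N supporting species, with the
# existence factor S_i = 1 always (orthologs are identified before an
# interaction enters the network) and the method-reliability weight M_i = 1
# for experimentally measured, 0.5 for computationally predicted source
# interactions. The final confidence value is CV = CV_interolog * CV_DDI.
# DDI-unsupported edges form the Basal (B) tier; DDI-supported edges are split
# into H1/H2/H3 at the 80th and 50th percentile rank of CV.

#' Interolog confidence component
#'
#' Mean of S_i * M_i over the supporting species (S_i = 1). When a species
#' supplies both experimental and computational witnesses for the same pair,
#' the experimental evidence dominates (M_i = 1).
#'
#' @param provenance Witness data frame with columns `species`,
#'   `evidence_method` (as stored by [transfer_interactions()]).
#' @return CV_interolog in \[0.5, 1\].
#' @export
compute_cv_interolog <- function(provenance) {
  if (is.null(provenance) || nrow(provenance) == 0L) {
    stop("empty provenance: CV_interolog requires at least one supporting species",
         call. = FALSE)
  }
  has_exp <- tapply(provenance$evidence_method == "experimental",
                    provenance$species, any)
  M <- ifelse(has_exp, 1, 0.5)
  mean(1 * M)  # S_i = 1
}

#' Final confidence value
#'
#' `CV = CV_interolog * CV_DDI` (both factors in \[0, 1\]).
#'
#' @param cv_interolog,cv_ddi The two confidence components.
#' @return The product (vectorized).
#' @export
compute_cv <- function(cv_interolog, cv_ddi) {
  stopifnot(all(cv_interolog >= 0 & cv_interolog <= 1),
            all(cv_ddi >= 0 & cv_ddi <= 1))
  cv_interolog * cv_ddi
}

#' Score a prediction table
#'
#' Adds `cv_interolog` (from the provenance list-column) and `cv`
#' (`cv_interolog * cv_ddi`) to a prediction table that already carries DDI
#' assessment columns (see [add_ddi_support()]).
#'
#' @param predictions Prediction data frame with `provenance` and `cv_ddi`.
#' @return `predictions` with added `cv_interolog` and `cv` columns.
#' @export
score_interactions <- function(predictions) {
  stopifnot("provenance" %in% names(predictions),
            "cv_ddi" %in% names(predictions))
  predictions$cv_interolog <- vapply(predictions$provenance,
                                     compute_cv_interolog, numeric(1))
  predictions$cv <- compute_cv(predictions$cv_interolog, predictions$cv_ddi)
  predictions
}

# Percentile rank of each value within x: Hazen definition
# 100 * (rank - 0.5) / n with average ranks for ties, equivalently
# 100 * (#strictly smaller + #equal / 2) / n. Ties always share a rank (and
# therefore a tier) and the ranks are invariant under duplicating the
# population.
percentile_rank <- function(x) {
  100 * (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Assign confidence tiers
#'
#' Edges without DDI support (`ddi_count == 0`) are Basal (`B`). The
#' remaining (high-confidence, `H`) edges receive the percentile rank of
#' their CV within the H population and are split into `H1` (rank > 80),
#' `H2` (50 <= rank <= 80) and `H3` (rank < 50). Equal CVs always share a
#' tier.
#'
#' @param predictions Scored prediction data frame (see
#'   [score_interactions()]).
#' @param hi,lo Percentile cut points (defaults 80 and 50).
#' @return `predictions` with added `percentile_rank` (NA for B edges) and
#'   `tier` columns.
#' @export
assign_tiers <- function(predictions, hi = 80, lo = 50) {
  stopifnot(all(c("ddi_count", "cv") %in% names(predictions)))
  n <- nrow(predictions)
  tier <- rep("B", n)
  pr <- rep(NA_real_, n)
  h <- which(predictions$ddi_count > 0)
  if (length(h)) {
    r <- percentile_rank(predictions$cv[h])
    pr[h] <- r
    tier[h] <- ifelse(r > hi, "H1", ifelse(r >= lo, "H2", "H3"))
  }
  predictions$percentile_rank <- pr
  predictions$tier <- tier
  predictions
}
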