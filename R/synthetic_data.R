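# Seeded synthetic test worlds with planted ground truth.
#
# A world mimics the study conditions of a multi-template interolog screen:
# several template species whose interaction counts are log-spread (one
# species dominating, as public plant PPI repositories do), a scale-free
# master interaction structure shared across species, many-to-many ortholog
# maps whose alignment statistics straddle the admission thresholds, domain
# annotations with planted DDI rules, and time-series expression with planted
# co-expressed pairs. Every quantity the pipeline should recover is recorded
# independently in the truth record.

#' Default synthetic-world configuration
#'
#' @param species Template species labels (default 7).
#' @param edges_per_species Interactions sampled per species from the master
#'   structure; log-spread so the first species dominates.
#' @param n_groups Number of ortholog groups in the master structure.
#' @param conservation Probability that a group has target-species orthologs.
#' @param multi_ortholog_prob Probability that a conserved group maps to two
#'   target proteins (exercising many-to-many transfer).
#' @param experimental_fraction Fraction of template interactions labelled
#'   experimental (the rest computational).
#' @param ddi_fraction Fraction of transferable pairs given a planted DDI
#'   rule.
#' @param max_domains Per-protein domain count drawn uniformly from
#'   `1:max_domains`.
#' @param domain_pool_size Size of the domain-accession pool.
#' @param n_timepoints Time points per time-series dataset (>= 3).
#' @param noise_sd Gaussian noise added to each co-expressed member's shared
#'   latent profile.
#' @param coexpressed_fraction Fraction of transferable pairs planted as
#'   co-expressed.
#' @param n_presence,presence_fraction Number of protein-presence datasets and
#'   the fraction of target proteins each contains.
#' @param n_matrix Number of (non-time-series) gene expression matrices.
#' @param n_timeseries Number of time-series datasets (planting happens in the
#'   first).
#' @return A validated configuration list.
#' @export
world_config <- function(species = c("ath", "osa", "stu", "zma", "gma",
                                     "ptr", "rco"),
                         edges_per_species = c(500, 150, 45, 25, 14, 9, 6),
                         n_groups = 300,
                         conservation = 0.6,
                         multi_ortholog_prob = 0.15,
                         experimental_fraction = 0.3,
                         ddi_fraction = 0.3,
                         max_domains = 4,
                         domain_pool_size = 60,
                         n_timepoints = 4,
                         noise_sd = 0.25,
                         coexpressed_fraction = 0.1,
                         n_presence = 2,
                         presence_fraction = 0.3,
                         n_matrix = 1,
                         n_timeseries = 2) {
  cfg <- list(species = species, edges_per_species = edges_per_species,
              n_groups = n_groups, conservation = conservation,
              multi_ortholog_prob = multi_ortholog_prob,
              experimental_fraction = experimental_fraction,
              ddi_fraction = ddi_fraction, max_domains = max_domains,
              domain_pool_size = domain_pool_size,
              n_timepoints = n_timepoints, noise_sd = noise_sd,
              coexpressed_fraction = coexpressed_fraction,
              n_presence = n_presence, presence_fraction = presence_fraction,
              n_matrix = n_matrix, n_timeseries = n_timeseries)
  fracs <- c(conservation, multi_ortholog_prob, experimental_fraction,
             ddi_fraction, coexpressed_fraction, presence_fraction)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(edges_per_species) != length(species)) {
    stop("edges_per_species must match species in length", call. = FALSE)
  }
  if (any(edges_per_species < 0) || n_groups < 4 || max_domains < 1 ||
      n_timepoints < 3 || noise_sd < 0) {
    stop("infeasible configuration (negative counts or too-small sizes)",
         call. = FALSE)
  }
  cfg
}

#' Generate a synthetic world with planted truth
#'
#' All randomness derives from `seed`; the caller's RNG stream is preserved.
#' Alignment statistics for conserved proteins are sampled inside the
#' admission region (identity in \[60, 100\], query coverage in \[80, 100\],
#' e-value <= 1e-10); every decoy hit fails at least one threshold.
#'
#' @param config Configuration list from [world_config()] (or a partial list
#'   of overrides).
#' @param seed Integer seed.
#' @return A list with elements `world` (inputs: `template_ppi`,
#'   `blast_hits`, `domains`, `ddi_rules`, `expression`) and `truth`
#'   (`transferable`, `ddi_supported`, `coexpressed`), plus `config` and
#'   `seed`.
#' @export
generate_world <- function(config = world_config(), seed) {
  if (!identical(sort(names(config)), sort(names(world_config())))) {
    config <- do.call(world_config, config)
  }
  with_seed(seed, generate_world_impl(config, seed))
}

generate_world_impl <- function(cfg, seed) {
  n_sp <- length(cfg$species)
  ## master scale-free structure over ortholog groups
  master_g <- igraph::sample_pa(cfg$n_groups, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(master_g, names = FALSE)
  master <- unique(data.frame(g = pmin(el[, 1], el[, 2]),
                              h = pmax(el[, 1], el[, 2])))
  master <- master[master$g != master$h, , drop = FALSE]
  n_master <- nrow(master)
  if (any(cfg$edges_per_species > n_master)) {
    stop("edges_per_species exceeds the master edge pool (", n_master, ")",
         call. = FALSE)
  }

  prot <- function(sp, g) sprintf("%s_P%04d", sp, g)

  ## per-species template interactions: sampled master edges with evidence
  sp_rows <- lapply(seq_len(n_sp), function(si) {
    idx <- sort(sample.int(n_master, cfg$edges_per_species[si]))
    data.frame(
      species = cfg$species[si],
      g = master$g[idx], h = master$h[idx],
      evidence_method = ifelse(
        stats::runif(length(idx)) < cfg$experimental_fraction,
        "experimental", "computational"),
      source_db = sample(c("dbA", "dbB", "dbC"), length(idx), replace = TRUE),
      stringsAsFactors = FALSE)
  })
  sp_edges <- do.call(rbind, sp_rows)
  template_ppi <- data.frame(
    species = sp_edges$species,
    protein_a = prot(sp_edges$species, sp_edges$g),
    protein_b = prot(sp_edges$species, sp_edges$h),
    evidence_method = sp_edges$evidence_method,
    source_db = sp_edges$source_db,
    stringsAsFactors = FALSE)
  template_ppi <- validate_template_ppi(template_ppi)

  ## ortholog-group conservation and target proteins
  conserved <- stats::runif(cfg$n_groups) < cfg$conservation
  two_targets <- stats::runif(cfg$n_groups) < cfg$multi_ortholog_prob
  targets_of <- lapply(seq_len(cfg$n_groups), function(g) {
    if (!conserved[g]) return(character())
    ids <- sprintf("T%04da", g)
    if (two_targets[g]) ids <- c(ids, sprintf("T%04db", g))
    ids
  })

  ## alignment hits: passing hits for conserved proteins present in template
  ## edges, decoy hits (failing >= 1 threshold) for the rest
  used <- unique(rbind(
    data.frame(species = sp_edges$species, g = sp_edges$g),
    data.frame(species = sp_edges$species, g = sp_edges$h)))
  hit_rows <- vector("list", nrow(used))
  for (i in seq_len(nrow(used))) {
    g <- used$g[i]
    qid <- prot(used$species[i], g)
    qlen <- sample(150:600, 1L)
    if (conserved[g]) {
      tg <- targets_of[[g]]
      qend <- ceiling(qlen * stats::runif(length(tg), 0.8, 1.0))
      hit_rows[[i]] <- data.frame(
        query_id = qid, subject_id = tg,
        percent_identity = stats::runif(length(tg), 60, 100),
        align_start_q = 1L, align_end_q = as.integer(qend),
        evalue = 10^stats::runif(length(tg), -50, -10),
        query_length = qlen, stringsAsFactors = FALSE)
    } else {
      # decoy: fail a random non-empty subset of the three thresholds
      fail <- sample(1:7, 1L)  # bits: 1 identity, 2 coverage, 4 evalue
      ident <- if (bitwAnd(fail, 1L)) stats::runif(1, 20, 59.9)
               else stats::runif(1, 60, 100)
      covq <- if (bitwAnd(fail, 2L)) stats::runif(1, 30, 79)
              else stats::runif(1, 80, 100)
      ev <- if (bitwAnd(fail, 4L)) 10^stats::runif(1, -9, -1)
            else 10^stats::runif(1, -50, -10)
      qend <- if (bitwAnd(fail, 2L)) max(1L, floor(qlen * covq / 100))
              else ceiling(qlen * covq / 100)
      hit_rows[[i]] <- data.frame(
        query_id = qid, subject_id = sprintf("DEC%04d", g),
        percent_identity = ident, align_start_q = 1L,
        align_end_q = as.integer(qend), evalue = ev, query_length = qlen,
        stringsAsFactors = FALSE)
    }
  }
  blast_hits <- do.call(rbind, hit_rows)
  rownames(blast_hits) <- NULL

  ## planted transferable truth: master edges witnessed by >= 1 species whose
  ## endpoints are both conserved, expanded over the target cross-product
  master$key <- paste(master$g, master$h)
  sp_edges$mkey <- paste(sp_edges$g, sp_edges$h)
  truth_rows <- list()
  for (j in seq_len(n_master)) {
    g <- master$g[j]; h <- master$h[j]
    if (!conserved[g] || !conserved[h]) next
    inst <- sp_edges[sp_edges$mkey == master$key[j], , drop = FALSE]
    if (nrow(inst) == 0L) next
    # per-species M: experimental dominates within a species
    has_exp <- tapply(inst$evidence_method == "experimental", inst$species,
                      any)
    cvi <- mean(ifelse(has_exp, 1, 0.5))
    grid <- expand.grid(a = targets_of[[g]], b = targets_of[[h]],
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    p <- canonical_pair(grid$a, grid$b)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      protein_a = p$a, protein_b = p$b,
      n_species = length(unique(inst$species)),
      cv_interolog = cvi, stringsAsFactors = FALSE)
  }
  transferable <- if (length(truth_rows)) {
    unique(do.call(rbind, truth_rows))
  } else {
    data.frame(protein_a = character(), protein_b = character(),
               n_species = integer(), cv_interolog = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(transferable) <- NULL

  ## domain annotations over target proteins
  target_proteins <- sort(unique(unlist(targets_of)))
  pool <- sprintf("PF%05d", seq_len(cfg$domain_pool_size))
  dom_of <- lapply(target_proteins, function(p) {
    sort(sample(pool, sample.int(cfg$max_domains, 1L)))
  })
  names(dom_of) <- target_proteins
  domains <- if (length(target_proteins)) {
    data.frame(protein_id = rep(target_proteins, lengths(dom_of)),
               domain_accession = unlist(dom_of), stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(), domain_accession = character(),
               stringsAsFactors = FALSE)
  }
  rownames(domains) <- NULL

  ## planted DDI rules on a fraction of transferable pairs
  n_plant <- round(cfg$ddi_fraction * nrow(transferable))
  rule_rows <- list()
  if (n_plant > 0) {
    pick <- sample.int(nrow(transferable), n_plant)
    for (i in pick) {
      da <- dom_of[[transferable$protein_a[i]]]
      db <- dom_of[[transferable$protein_b[i]]]
      k <- min(sample(1:2, 1L), length(da) * length(db))
      for (r in seq_len(k)) {
        rule_rows[[length(rule_rows) + 1L]] <-
          canonical_pair(sample(da, 1L), sample(db, 1L))
      }
    }
  }
  ddi_rules <- if (length(rule_rows)) {
    rr <- unique(do.call(rbind, rule_rows))
    data.frame(domain_x = rr$a, domain_y = rr$b, stringsAsFactors = FALSE)
  } else {
    data.frame(domain_x = character(), domain_y = character(),
               stringsAsFactors = FALSE)
  }
  rownames(ddi_rules) <- NULL

  ## independently recomputed expected DDI statistics per transferable pair
  ## (plain double loop over the domain cross-product, kept separate from the
  ## pipeline's vectorized implementation)
  rule_keys <- if (nrow(ddi_rules)) {
    unique(paste(pmin(ddi_rules$domain_x, ddi_rules$domain_y),
                 pmax(ddi_rules$domain_x, ddi_rules$domain_y)))
  } else character()
  nt <- nrow(transferable)
  cnt <- integer(nt); na <- integer(nt); nb <- integer(nt)
  for (i in seq_len(nt)) {
    da <- unique(dom_of[[transferable$protein_a[i]]])
    db <- unique(dom_of[[transferable$protein_b[i]]])
    na[i] <- length(da); nb[i] <- length(db)
    seen <- character()
    for (x in da) for (y in db) {
      kk <- paste(min(x, y), max(x, y))
      if (kk %in% rule_keys && !kk %in% seen) seen <- c(seen, kk)
    }
    cnt[i] <- length(seen)
  }
  transferable$ddi_count <- cnt
  transferable$n_dom_a <- na
  transferable$n_dom_b <- nb
  transferable$D <- ifelse(na == 0 | nb == 0, 0, cnt / (na * nb))
  transferable$d <- ifelse(na == 1 & nb == 1, 0.5, 1)
  transferable$cv_ddi <- transferable$d * transferable$D
  transferable$cv <- transferable$cv_interolog * transferable$cv_ddi
  ddi_supported <- transferable[transferable$ddi_count > 0,
                                c("protein_a", "protein_b"), drop = FALSE]
  rownames(ddi_supported) <- NULL

  ## expression datasets
  expression <- list()
  np <- length(target_proteins)
  for (k in seq_len(cfg$n_presence)) {
    members <- if (np) sample(target_proteins,
                              floor(cfg$presence_fraction * np))
               else character()
    expression[[length(expression) + 1L]] <-
      expression_dataset(sprintf("presence_%d", k), "protein_presence",
                         sort(members))
  }
  tp_labels <- sprintf("t%d", seq_len(cfg$n_timepoints))
  rw_profile <- function() pmax(10 + cumsum(stats::rnorm(cfg$n_timepoints)), 0)
  ## planted co-expressed pairs: endpoint-disjoint transferable pairs sharing
  ## a latent random-walk profile in the first time-series dataset
  n_coex <- round(cfg$coexpressed_fraction * nt)
  coex_idx <- integer()
  if (n_coex > 0 && cfg$n_timeseries > 0) {
    used_p <- character()
    for (i in sample.int(nt)) {
      a <- transferable$protein_a[i]; b <- transferable$protein_b[i]
      if (a == b || a %in% used_p || b %in% used_p) next
      coex_idx <- c(coex_idx, i)
      used_p <- c(used_p, a, b)
      if (length(coex_idx) >= n_coex) break
    }
  }
  coexpressed <- transferable[coex_idx, c("protein_a", "protein_b"),
                              drop = FALSE]
  rownames(coexpressed) <- NULL
  for (k in seq_len(cfg$n_timeseries)) {
    if (k == 1L && np) {
      ids <- target_proteins
      m <- t(vapply(ids, function(p) rw_profile(),
                    numeric(cfg$n_timepoints)))
      for (i in coex_idx) {
        latent <- 10 + cumsum(stats::rnorm(cfg$n_timepoints))
        m[transferable$protein_a[i], ] <-
          pmax(latent + stats::rnorm(cfg$n_timepoints, sd = cfg$noise_sd), 0)
        m[transferable$protein_b[i], ] <-
          pmax(latent + stats::rnorm(cfg$n_timepoints, sd = cfg$noise_sd), 0)
      }
      colnames(m) <- tp_labels
    } else {
      ids <- if (np) sort(sample(target_proteins, ceiling(np / 2)))
             else character()
      m <- t(vapply(ids, function(p) rw_profile(),
                    numeric(cfg$n_timepoints)))
      if (length(ids) == 0L)
        m <- matrix(numeric(), 0, cfg$n_timepoints)
      colnames(m) <- tp_labels
      rownames(m) <- ids
    }
    expression[[length(expression) + 1L]] <-
      expression_dataset(sprintf("timeseries_%d", k), "time_series", m)
  }
  for (k in seq_len(cfg$n_matrix)) {
    ids <- if (np) sort(sample(target_proteins, ceiling(np / 2)))
           else character()
    m <- matrix(stats::rexp(length(ids) * 5, rate = 0.2), ncol = 5,
                dimnames = list(ids, sprintf("s%d", 1:5)))
    expression[[length(expression) + 1L]] <-
      expression_dataset(sprintf("matrix_%d", k), "gene_matrix", m)
  }

  list(world = list(template_ppi = template_ppi, blast_hits = blast_hits,
                    domains = domains, ddi_rules = ddi_rules,
                    expression = expression),
       truth = list(transferable = transferable,
                    ddi_supported = ddi_supported,
                    coexpressed = coexpressed),
       config = cfg, seed = seed)
}

#' Write a synthetic world to canonical input files
#'
#' Emits the template PPI table, BLAST tabular file plus query-length table,
#' domain and DDI tables, all expression datasets, and the planted truth as
#' JSON.
#'
#' @param world_bundle Result of [generate_world()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of written paths.
#' @export
write_world <- function(world_bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- world_bundle$world
  paths <- list(
    template_ppi = file.path(out_dir, "template_ppi.tsv"),
    blast = file.path(out_dir, "blast_hits.tsv"),
    qlen = file.path(out_dir, "query_lengths.tsv"),
    domains = file.path(out_dir, "domains.tsv"),
    ddi_rules = file.path(out_dir, "ddi_rules.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_template_ppi_tsv(w$template_ppi, paths$template_ppi)
  write_blast_tab(w$blast_hits, paths$blast, paths$qlen)
  write_domain_table(w$domains, paths$domains)
  write_ddi_table(w$ddi_rules, paths$ddi_rules)
  paths$presence <- character()
  paths$timeseries <- character()
  paths$matrix <- character()
  for (ds in w$expression) {
    p <- file.path(out_dir, paste0(ds$dataset_id, ".tsv"))
    if (ds$kind == "protein_presence") {
      write_presence_list(ds, p)
      paths$presence <- c(paths$presence, p)
    } else if (ds$kind == "time_series") {
      write_expression_matrix(ds, p)
      paths$timeseries <- c(paths$timeseries, p)
    } else {
      write_expression_matrix(ds, p)
      paths$matrix <- c(paths$matrix, p)
    }
  }
  jsonlite::write_json(world_bundle$truth, paths$truth, dataframe = "columns",
                       digits = NA)
  invisible(paths)
}

#' Compare pipeline output against a world's planted truth
#'
#' Reports recall and precision of the transferred interaction set against
#' the planted transferable pairs, the maximum absolute disagreement of every
#' score component with the truth record's independently recomputed
#' expectation, and the co-expression detection confusion matrix.
#'
#' @param world_bundle Result of [generate_world()].
#' @param predictions Fully processed prediction table (scored, tiered,
#'   expression-flagged).
#' @return A list with `transfer` (recall, precision), `scores` (per-component
#'   max absolute difference, n_compared) and `coexpression` (tp, fp, fn, tn).
#' @export
end_to_end_check <- function(world_bundle, predictions) {
  truth <- world_bundle$truth
  tkey <- pair_key(truth$transferable$protein_a, truth$transferable$protein_b)
  pkey <- pair_key(predictions$protein_a, predictions$protein_b)
  recall <- if (length(tkey)) mean(tkey %in% pkey) else 1
  precision <- if (length(pkey)) mean(pkey %in% tkey) else 1
  idx <- match(tkey, pkey)
  ok <- !is.na(idx)
  comp <- c("n_species", "cv_interolog", "ddi_count", "D", "d", "cv_ddi",
            "cv")
  diffs <- vapply(comp, function(cn) {
    if (!cn %in% names(predictions) || !any(ok)) return(NA_real_)
    max(abs(predictions[[cn]][idx[ok]] - truth$transferable[[cn]][ok]))
  }, numeric(1))
  coex <- list(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
  if ("coexpressed" %in% names(predictions)) {
    ckey <- pair_key(truth$coexpressed$protein_a, truth$coexpressed$protein_b)
    pred_pos <- pkey[predictions$coexpressed]
    coex$tp <- sum(ckey %in% pred_pos)
    coex$fn <- sum(!ckey %in% pred_pos)
    coex$fp <- sum(!pred_pos %in% ckey)
    coex$tn <- length(pkey) - coex$tp - coex$fn - coex$fp
  }
  list(transfer = list(recall = recall, precision = precision),
       scores = list(max_abs_diff = diffs, n_compared = sum(ok)),
       coexpression = coex)
}
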