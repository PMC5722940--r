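# One-shot orchestration of the full procedure: ortholog filtering ->
# interolog transfer -> DDI assessment -> confidence scoring and tiering ->
# expression/co-expression validation -> topology, with a machine-readable
# run report. Every threshold is a config key whose default is the published
# parameterization (identity 60 / coverage 80 / e-value 1e-10, PCC > 0.9 with
# p < 0.1, 80th-percentile expression filter, tier cut points 80/50).

pipeline_defaults <- function() {
  list(min_identity = 60, min_coverage = 80, max_evalue = 1e-10,
       pcc_min = 0.9, p_max = 0.1, expression_percentile = 80,
       tier_hi = 80, tier_lo = 50,
       seed = 1, n_reference = 10, ratio_threshold = 2,
       formats = "edge_tsv", out_dir = NULL,
       template_ppi = character(), blast = NULL, qlen = NULL,
       domains = NULL, ddi_rules = NULL,
       presence = character(), matrices = character(),
       timeseries = character())
}

#' Parse a flat key=value pipeline configuration file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' multi-file keys (`template_ppi`, `presence`, `matrices`, `timeseries`,
#' `formats`) take `;`-separated lists; numeric values are converted.
#'
#' @param path Path to the configuration file.
#' @return A named configuration list (unset keys fall back to defaults at
#'   run time).
#' @export
parse_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  cfg <- list()
  multi <- c("template_ppi", "presence", "matrices", "timeseries", "formats")
  numeric_keys <- c("min_identity", "min_coverage", "max_evalue", "pcc_min",
                    "p_max", "expression_percentile", "tier_hi", "tier_lo",
                    "seed", "n_reference", "ratio_threshold")
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", ln))[[1L]]
    if (length(kv) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- kv[2L]; val <- kv[3L]
    if (key %in% multi) val <- strsplit(val, ";", fixed = TRUE)[[1L]]
    if (key %in% numeric_keys) val <- as.numeric(val)
    cfg[[key]] <- val
  }
  cfg
}

#' Run the full prediction-and-validation pipeline
#'
#' Executes all stages in order from flat-file inputs, persists the exported
#' network (when `out_dir` is set) and returns a run report mirroring the
#' summary structure of an interolog screen: per-stage record counts,
#' per-species inferred-interaction counts, the expression-supported
#' fraction, co-expressed edge count, tier counts and global topology
#' statistics.
#'
#' @param config Path to a key=value config file (see
#'   [parse_pipeline_config()]) or an equivalent named list. Required keys:
#'   `template_ppi`, `blast`, `qlen`, `domains`, `ddi_rules`; optional:
#'   `presence`, `matrices`, `timeseries`, `out_dir`, `formats`, and any
#'   threshold override.
#' @return A list with elements `report` (the run report; also written as
#'   JSON when `out_dir` is set) and `predictions` (the fully annotated edge
#'   table).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- parse_pipeline_config(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  required <- c("template_ppi", "blast", "qlen", "domains", "ddi_rules")
  for (key in required) {
    if (is.null(cfg[[key]]) || length(cfg[[key]]) == 0L) {
      stop("config key '", key, "' is required", call. = FALSE)
    }
  }
  all_inputs <- c(cfg$template_ppi, cfg$blast, cfg$qlen, cfg$domains,
                  cfg$ddi_rules, cfg$presence, cfg$matrices, cfg$timeseries)
  missing <- all_inputs[!file.exists(all_inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  templates <- do.call(rbind, lapply(cfg$template_ppi, read_template_ppi_tsv))
  hits <- read_blast_tab(cfg$blast, cfg$qlen)
  domains <- read_domain_table(cfg$domains)
  ddi_rules <- read_ddi_table(cfg$ddi_rules)
  presence <- lapply(cfg$presence, read_presence_list)
  matrices <- lapply(cfg$matrices, read_expression_matrix,
                     kind = "gene_matrix")
  timeseries <- lapply(cfg$timeseries, read_expression_matrix,
                       kind = "time_series")

  orthomap <- filter_orthologs(hits, cfg$min_identity, cfg$min_coverage,
                               cfg$max_evalue)
  preds <- transfer_interactions(templates, orthomap)
  preds <- add_ddi_support(preds, domains, ddi_rules)
  preds <- score_interactions(preds)
  preds <- assign_tiers(preds, hi = cfg$tier_hi, lo = cfg$tier_lo)

  expressed <- expressed_protein_set(c(presence, matrices, timeseries),
                                     percentile = cfg$expression_percentile)
  preds <- flag_edge_expression(preds, expressed)
  coex <- find_coexpressed_edges(preds, timeseries, pcc_min = cfg$pcc_min,
                                 p_max = cfg$p_max)
  preds <- flag_coexpression(preds, coex)

  stats <- if (nrow(preds)) network_stats(preds) else NULL
  small_world <- if (nrow(preds) && !is.na(stats$avg_path_length)) {
    small_world_report(preds, seed = cfg$seed,
                       n_reference = cfg$n_reference,
                       ratio_threshold = cfg$ratio_threshold)
  } else NULL

  tier_counts <- as.list(table(factor(preds$tier,
                                      levels = c("B", "H1", "H2", "H3"))))
  cfg_file <- tempfile()
  saveRDS(cfg, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)

  report <- list(
    tool = "interologr",
    version = as.character(utils::packageVersion("interologr")),
    seed = cfg$seed,
    config_hash = cfg_hash,
    counts = list(
      template_interactions = nrow(templates),
      alignment_hits = nrow(hits),
      ortholog_pairs = nrow(orthomap),
      predicted_interactions = nrow(preds),
      predicted_proteins = length(unique(c(preds$protein_a,
                                           preds$protein_b))),
      skipped_template_interactions = attr(preds, "n_skipped") %||% 0L),
    species_inferred_counts = as.list(attr(preds, "species_counts")),
    fraction_expression_supported = attr(preds, "fraction_supported"),
    n_coexpressed_edges = sum(preds$coexpressed),
    tier_counts = tier_counts,
    topology = if (is.null(stats)) NULL else
      stats[c("n_nodes", "n_edges", "gamma", "avg_path_length",
              "clustering_coefficient", "diameter")],
    small_world = small_world)

  if (!is.null(cfg$out_dir)) {
    write_network(preds, out_dir = cfg$out_dir, formats = cfg$formats)
    jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(report = report, predictions = preds)
}
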