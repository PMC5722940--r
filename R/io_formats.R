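# Readers and writers for every flat-file table the pipeline touches.
# All canonical tables are UTF-8 TSV with a mandatory header row; lines
# starting with '#' are ignored. Unordered protein pairs are always stored in
# canonical (lexicographic) order.

#' Canonicalize an unordered identifier pair
#'
#' Protein-protein interactions are undirected; every pair in the package is
#' stored with the lexicographically smaller identifier first so that equal
#' pairs compare equal and output row order is deterministic.
#'
#' @param a,b Character vectors of identifiers (recycled to common length).
#' @return A two-column data frame with columns `a` and `b`, `a <= b` row-wise.
#' @examples
#' canonical_pair(c("P2", "P1"), c("P1", "P2"))
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  data.frame(a = pmin(a, b), b = pmax(a, b), stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p$a, p$b, sep = "\r")
}

# Strict TSV reader used by all canonical-table readers: verifies the header,
# enforces a constant field count, and reports the 1-based file line of the
# first malformed row.
read_tsv_strict <- function(path, expected_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(keep) == 0L) stop("no header row in ", path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!is.null(expected_cols) && !identical(header, expected_cols)) {
    stop("expected header '", paste(expected_cols, collapse = "\t"),
         "' in ", path, " but found '", paste(header, collapse = "\t"), "'",
         call. = FALSE)
  }
  ncol <- length(header)
  rows <- fields[-1L]
  lens <- lengths(rows)
  bad <- which(lens != ncol)
  if (length(bad)) {
    stop("malformed row at line ", keep[-1L][bad[1L]], " of ", path,
         ": expected ", ncol, " fields, found ", lens[bad[1L]], call. = FALSE)
  }
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(), nrow = 0, ncol = ncol),
                        stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  names(df) <- header
  df
}

as_numeric_strict <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("non-numeric ", what, " '", x[bad[1L]], "' in ", path, call. = FALSE)
  }
  out
}

EVIDENCE_LEVELS <- c("experimental", "computational")

#' Read a template-species PPI table
#'
#' Reads the canonical 5-column interaction table
#' (`species`, `protein_a`, `protein_b`, `evidence_method`, `source_db`).
#' Pairs are canonicalized to lexicographic order and exact duplicate records
#' (same species, pair, evidence method and source) are collapsed.
#'
#' @param path Path to a TSV file with the required header.
#' @return A data frame of template interactions, one row per distinct record.
#' @export
read_template_ppi_tsv <- function(path) {
  df <- read_tsv_strict(path, c("species", "protein_a", "protein_b",
                                "evidence_method", "source_db"))
  validate_template_ppi(df, path)
}

validate_template_ppi <- function(df, origin = "input") {
  if (nrow(df)) {
    if (any(!nzchar(df$protein_a)) || any(!nzchar(df$protein_b))) {
      stop("empty protein identifier in ", origin, call. = FALSE)
    }
    bad <- setdiff(unique(df$evidence_method), EVIDENCE_LEVELS)
    if (length(bad)) {
      stop("unknown evidence_method '", bad[1L], "' in ", origin,
           " (expected experimental or computational)", call. = FALSE)
    }
    p <- canonical_pair(df$protein_a, df$protein_b)
    df$protein_a <- p$a
    df$protein_b <- p$b
    df <- unique(df)
  }
  rownames(df) <- NULL
  df
}

#' Read a minimal PSI-MITAB 2.5 subset
#'
#' Consumes columns 1 and 2 (interactor identifiers; the accession part of the
#' first `db:accession` token is used) and column 7 (interaction detection
#' method). Detection-method terms (`MI:NNNN`) are mapped to
#' `experimental`/`computational` through `method_map`; unmapped terms fall
#' back to `default_method`. MITAB rows carry no species token in the consumed
#' columns, so the species label is supplied by the caller.
#'
#' @param path Path to a tab-separated MITAB file (`#` lines ignored).
#' @param method_map Named character vector mapping `MI:NNNN` term ids to
#'   `"experimental"` or `"computational"`.
#' @param species Species label attached to every interaction.
#' @param default_method Evidence class used for unmapped detection methods.
#' @param source_db Source label attached to every interaction.
#' @return A data frame in the same shape as [read_template_ppi_tsv()].
#' @export
read_mitab_subset <- function(path, method_map, species,
                              default_method = "computational",
                              source_db = "mitab") {
  stopifnot(default_method %in% EVIDENCE_LEVELS)
  if (length(method_map) && !all(method_map %in% EVIDENCE_LEVELS)) {
    stop("method_map values must be experimental or computational",
         call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(lens < 7L)
  if (length(bad)) {
    stop("line ", keep[bad[1L]], " of ", path, ": fewer than 7 columns (",
         lens[bad[1L]], ")", call. = FALSE)
  }
  first_accession <- function(x) {
    tok <- vapply(strsplit(x, "|", fixed = TRUE), `[[`, character(1), 1L)
    sub("^[^:]*:", "", tok)
  }
  if (length(fields) == 0L) {
    return(validate_template_ppi(data.frame(
      species = character(), protein_a = character(), protein_b = character(),
      evidence_method = character(), source_db = character(),
      stringsAsFactors = FALSE)))
  }
  id_a <- first_accession(vapply(fields, `[[`, character(1), 1L))
  id_b <- first_accession(vapply(fields, `[[`, character(1), 2L))
  det <- vapply(fields, `[[`, character(1), 7L)
  mi <- regmatches(det, regexpr("MI:[0-9]+", det))
  mi_full <- rep(NA_character_, length(det))
  mi_full[regexpr("MI:[0-9]+", det) > 0] <- mi
  ev <- ifelse(!is.na(mi_full) & mi_full %in% names(method_map),
               unname(method_map[mi_full]), default_method)
  validate_template_ppi(data.frame(
    species = species, protein_a = id_a, protein_b = id_b,
    evidence_method = ev, source_db = source_db, stringsAsFactors = FALSE),
    origin = path)
}

#' Read BLAST tabular output (outfmt 6) with query lengths
#'
#' Parses the standard 12-column BLAST tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), headerless, `#` comment lines ignored. Query lengths are
#' resolved from a 2-column TSV (`protein_id`, `length`) or, if the file
#' carries a 13th column, from that `qlen` column directly.
#'
#' @param path Path to the BLAST tabular file.
#' @param qlen_path Optional path to the query-length table; required unless
#'   every row carries 13 columns.
#' @return A data frame of alignment hits with columns `query_id`,
#'   `subject_id`, `percent_identity`, `align_start_q`, `align_end_q`,
#'   `evalue`, `query_length`.
#' @export
read_blast_tab <- function(path, qlen_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(!startsWith(lines, "#") & nzchar(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lens <- lengths(fields)
  bad <- which(!(lens %in% c(12L, 13L)))
  if (length(bad)) {
    stop("malformed row at line ", keep[bad[1L]], " of ", path,
         ": expected 12 or 13 fields, found ", lens[bad[1L]], call. = FALSE)
  }
  if (length(fields) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), align_start_q = integer(),
                      align_end_q = integer(), evalue = numeric(),
                      query_length = integer(), stringsAsFactors = FALSE))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    query_id = col(1L),
    subject_id = col(2L),
    percent_identity = as_numeric_strict(col(3L), "percent identity", path),
    align_start_q = as.integer(as_numeric_strict(col(7L), "qstart", path)),
    align_end_q = as.integer(as_numeric_strict(col(8L), "qend", path)),
    evalue = as_numeric_strict(col(11L), "e-value", path),
    stringsAsFactors = FALSE
  )
  has13 <- lens == 13L
  qlen <- rep(NA_real_, nrow(hits))
  qlen[has13] <- as_numeric_strict(
    vapply(fields[has13], `[[`, character(1), 13L), "qlen", path)
  if (!is.null(qlen_path)) {
    tab <- read_tsv_strict(qlen_path, c("protein_id", "length"))
    lut <- as_numeric_strict(tab$length, "length", qlen_path)
    names(lut) <- tab$protein_id
    need <- is.na(qlen)
    qlen[need] <- unname(lut[hits$query_id[need]])
  }
  if (anyNA(qlen)) {
    missing_q <- hits$query_id[which(is.na(qlen))[1L]]
    stop("no query length resolvable for query '", missing_q, "'",
         call. = FALSE)
  }
  hits$query_length <- as.integer(qlen)
  validate_alignment_hits(hits)
  hits
}

validate_alignment_hits <- function(hits) {
  with(hits, {
    if (any(percent_identity < 0 | percent_identity > 100))
      stop("percent identity outside [0, 100]", call. = FALSE)
    if (any(evalue < 0)) stop("negative e-value", call. = FALSE)
    if (any(align_start_q < 1 | align_start_q > align_end_q |
            align_end_q > query_length))
      stop("alignment coordinates violate 1 <= qstart <= qend <= qlen",
           call. = FALSE)
  })
  invisible(hits)
}

#' Read a protein-to-domain annotation table
#'
#' Two-column long table (`protein_id`, `domain_accession`). Duplicate
#' (protein, domain) rows are collapsed: domain annotations are sets.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `protein_id`, `domain_accession`.
#' @export
read_domain_table <- function(path) {
  df <- read_tsv_strict(path, c("protein_id", "domain_accession"))
  df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Read a domain-domain interaction rule table
#'
#' Two-column table of unordered interacting domain pairs (self-pairs
#' permitted), canonicalized and de-duplicated.
#'
#' @param path Path to the TSV file.
#' @return A data frame with columns `domain_x`, `domain_y` (`domain_x <=
#'   domain_y`).
#' @export
read_ddi_table <- function(path) {
  df <- read_tsv_strict(path, c("domain_x", "domain_y"))
  if (nrow(df)) {
    p <- canonical_pair(df$domain_x, df$domain_y)
    df$domain_x <- p$a
    df$domain_y <- p$b
    df <- unique(df)
  }
  rownames(df) <- NULL
  df
}

#' Construct an expression dataset
#'
#' @param dataset_id Dataset label.
#' @param kind One of `"protein_presence"`, `"gene_matrix"`, `"time_series"`.
#' @param members For `protein_presence`, a character vector of protein ids;
#'   otherwise a numeric matrix with protein ids as row names and ordered
#'   sample labels as column names.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, kind, members) {
  kind <- match.arg(kind, c("protein_presence", "gene_matrix", "time_series"))
  if (kind == "protein_presence") {
    members <- unique(as.character(members))
  } else {
    if (!is.matrix(members) || !is.numeric(members))
      stop("matrix datasets need a numeric matrix", call. = FALSE)
    if (nrow(members) > 0 &&
        (is.null(rownames(members)) || anyDuplicated(rownames(members))))
      stop("matrix rows must carry unique protein ids", call. = FALSE)
    if (anyNA(members))
      stop("missing expression cells are not accepted (no imputation rule)",
           call. = FALSE)
    if (any(members < 0))
      stop("expression values must be non-negative", call. = FALSE)
    if (kind == "time_series" && ncol(members) < 3L)
      stop("time_series datasets need at least 3 ordered samples",
           call. = FALSE)
  }
  structure(list(dataset_id = dataset_id, kind = kind, members = members),
            class = "expression_dataset")
}

#' Read a one-column protein presence list
#'
#' @param path Path to a 1-column TSV (header `protein_id`).
#' @param dataset_id Dataset label.
#' @return An `expression_dataset` of kind `protein_presence`.
#' @export
read_presence_list <- function(path, dataset_id = basename(path)) {
  df <- read_tsv_strict(path, "protein_id")
  expression_dataset(dataset_id, "protein_presence", df$protein_id)
}

#' Read an expression matrix
#'
#' First column is the protein/gene id; remaining header fields are ordered
#' sample labels. Cells must be numeric and non-negative; missing cells are
#' rejected at load time.
#'
#' @param path Path to the TSV file.
#' @param kind `"gene_matrix"` or `"time_series"`.
#' @param dataset_id Dataset label.
#' @return An `expression_dataset`.
#' @export
read_expression_matrix <- function(path, kind = "gene_matrix",
                                   dataset_id = basename(path)) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("expression matrix needs id + sample columns",
                          call. = FALSE)
  ids <- df[[1L]]
  vals <- vapply(df[-1L], as_numeric_strict, numeric(nrow(df)),
                 what = "expression value", path = path)
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, names(df)[-1L]))
  if (nrow(df) == 0L) vals <- matrix(numeric(), nrow = 0L,
                                     ncol = ncol(df) - 1L,
                                     dimnames = list(NULL, names(df)[-1L]))
  rownames(vals) <- ids
  expression_dataset(dataset_id, kind, vals)
}

# ---- writers -----------------------------------------------------------------

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_template_ppi_tsv
#' @param interactions Data frame of template interactions.
#' @export
write_template_ppi_tsv <- function(interactions, path) {
  cols <- c("species", "protein_a", "protein_b", "evidence_method",
            "source_db")
  write_tsv_plain(interactions[, cols, drop = FALSE], path)
}

#' @rdname read_domain_table
#' @param domains Data frame with columns `protein_id`, `domain_accession`.
#' @export
write_domain_table <- function(domains, path) {
  write_tsv_plain(domains[, c("protein_id", "domain_accession")], path)
}

#' @rdname read_ddi_table
#' @param rules Data frame with columns `domain_x`, `domain_y`.
#' @export
write_ddi_table <- function(rules, path) {
  write_tsv_plain(rules[, c("domain_x", "domain_y")], path)
}

#' Write BLAST tabular output and its query-length table
#'
#' Emits a 12-column outfmt-6 file (filling the unparsed columns with zeros)
#' plus the companion 2-column query-length TSV.
#'
#' @param hits Alignment-hit data frame as returned by [read_blast_tab()].
#' @param path Output path for the tabular file.
#' @param qlen_path Output path for the query-length table.
#' @export
write_blast_tab <- function(hits, path, qlen_path) {
  rows <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$percent_identity,
    length = hits$align_end_q - hits$align_start_q + 1L,
    mismatch = 0L, gapopen = 0L,
    qstart = hits$align_start_q, qend = hits$align_end_q,
    sstart = 1L, send = hits$align_end_q - hits$align_start_q + 1L,
    evalue = format(hits$evalue, scientific = TRUE, trim = TRUE),
    bitscore = 0, stringsAsFactors = FALSE)
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ql <- unique(data.frame(protein_id = hits$query_id,
                          length = hits$query_length,
                          stringsAsFactors = FALSE))
  write_tsv_plain(ql, qlen_path)
  invisible(path)
}

#' @rdname read_presence_list
#' @param dataset An `expression_dataset` of kind `protein_presence`.
#' @export
write_presence_list <- function(dataset, path) {
  write_tsv_plain(data.frame(protein_id = dataset$members,
                             stringsAsFactors = FALSE), path)
}

#' @rdname read_expression_matrix
#' @param dataset An `expression_dataset` holding a matrix.
#' @export
write_expression_matrix <- function(dataset, path) {
  m <- dataset$members
  df <- data.frame(protein_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

NETWORK_EDGE_COLS <- c("protein_a", "protein_b", "CV", "CV_interolog",
                       "CV_DDI", "N", "ddi_count", "D", "d", "tier",
                       "expression_supported", "coexpressed",
                       "supporting_species")

# Flatten a prediction table (possibly holding a provenance list-column and
# lower-case score columns) into the fixed export column set.
flatten_network_edges <- function(predictions) {
  n <- nrow(predictions)
  pick <- function(dest, alts, default) {
    for (a in c(dest, alts)) {
      if (a %in% names(predictions)) return(predictions[[a]])
    }
    rep(default, n)
  }
  supporting <- if ("provenance" %in% names(predictions)) {
    vapply(predictions$provenance, function(p) {
      paste(sort(unique(p$species)), collapse = ";")
    }, character(1))
  } else {
    pick("supporting_species", character(), NA_character_)
  }
  out <- data.frame(
    protein_a = predictions$protein_a,
    protein_b = predictions$protein_b,
    CV = pick("CV", "cv", NA_real_),
    CV_interolog = pick("CV_interolog", "cv_interolog", NA_real_),
    CV_DDI = pick("CV_DDI", "cv_ddi", NA_real_),
    N = pick("N", "n_species", NA_integer_),
    ddi_count = pick("ddi_count", character(), NA_integer_),
    D = pick("D", character(), NA_real_),
    d = pick("d", character(), NA_real_),
    tier = pick("tier", character(), NA_character_),
    expression_supported = pick("expression_supported", character(), NA),
    coexpressed = pick("coexpressed", character(), NA),
    supporting_species = supporting,
    stringsAsFactors = FALSE)
  out[order(out$protein_a, out$protein_b, method = "radix"), , drop = FALSE]
}

#' Export a predicted network
#'
#' Writes the scored network in one or more formats: `edge_tsv` (the canonical
#' flat edge table), `node_tsv` (node attributes), `sif` (Cytoscape simple
#' interaction format, relation token `pp`) and `graphml` (typed edge/node
#' attributes via igraph). Rows are emitted in canonical pair order.
#'
#' @param predictions Prediction data frame (any scoring stage).
#' @param node_attributes Optional data frame with a `protein_id` column.
#' @param out_dir Output directory (created if absent).
#' @param formats Subset of `c("edge_tsv", "node_tsv", "sif", "graphml")`.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_network <- function(predictions, node_attributes = NULL, out_dir,
                          formats = "edge_tsv") {
  known <- c("edge_tsv", "node_tsv", "sif", "graphml")
  bad <- setdiff(formats, known)
  if (length(bad)) stop("unknown format token: ", bad[1L], call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- flatten_network_edges(predictions)
  written <- character()
  if ("edge_tsv" %in% formats) {
    p <- file.path(out_dir, "network_edges.tsv")
    write_tsv_plain(flat, p)
    written["edge_tsv"] <- p
  }
  if ("node_tsv" %in% formats) {
    p <- file.path(out_dir, "network_nodes.tsv")
    nodes <- sort(unique(c(flat$protein_a, flat$protein_b)))
    nd <- data.frame(protein_id = nodes, stringsAsFactors = FALSE)
    if (!is.null(node_attributes)) {
      nd <- merge(nd, node_attributes, by = "protein_id", all.x = TRUE,
                  sort = TRUE)
    }
    write_tsv_plain(nd, p)
    written["node_tsv"] <- p
  }
  if ("sif" %in% formats) {
    p <- file.path(out_dir, "network.sif")
    writeLines(paste(flat$protein_a, "pp", flat$protein_b, sep = "\t"), p)
    written["sif"] <- p
  }
  if ("graphml" %in% formats) {
    p <- file.path(out_dir, "network.graphml")
    g <- igraph::graph_from_data_frame(flat, directed = FALSE)
    igraph::write_graph(g, p, format = "graphml")
    written["graphml"] <- p
  }
  invisible(written)
}

#' Read back a canonical edge_tsv network export
#'
#' @param path Path written by [write_network()] with format `edge_tsv`.
#' @return A typed data frame with the fixed export columns.
#' @export
read_network_edge_tsv <- function(path) {
  df <- read_tsv_strict(path, NETWORK_EDGE_COLS)
  num <- c("CV", "CV_interolog", "CV_DDI", "D", "d")
  int <- c("N", "ddi_count")
  lgl <- c("expression_supported", "coexpressed")
  for (cn in num) df[[cn]] <- suppressWarnings(as.numeric(df[[cn]]))
  for (cn in int) df[[cn]] <- suppressWarnings(as.integer(df[[cn]]))
  for (cn in lgl) df[[cn]] <- as.logical(df[[cn]])
  df$tier[df$tier == "NA"] <- NA_character_
  df
}
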