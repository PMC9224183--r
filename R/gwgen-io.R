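# Data model and I/O for candidate GWGENs and expression matrices.
#
# A GWGEN (genome-wide genetic and epigenetic network) is the union of four
# interaction layers over typed nodes:
#   ppi       protein-protein interaction (undirected, stored canonically)
#   tf_gene   transcription-factor -> regulated-node activation/repression
#   lnc_gene  lncRNA -> regulated-node regulation
#   mir_gene  miRNA -| regulated-node repression (non-negative repression
#             ability, entering the model with a negative sign)
# "gene" in the kind names reads as "regulated node": the same regulation
# models apply when the target is a lncRNA or miRNA node.

#' Construct a node table
#'
#' @param id character vector of unique node identifiers.
#' @param kind node kind, one of `"protein"`, `"receptor"`, `"TF"`,
#'   `"gene"`, `"miRNA"`, `"lncRNA"`. Receptors are protein-kind nodes with a
#'   distinguishing label only; they get no special treatment in the math.
#' @param gene optional character vector linking protein/TF nodes to the gene
#'   they are translated from (`NA` where not applicable).
#' @return a `data.frame` with columns `id`, `kind`, `gene`.
#' @export
node_table <- function(id, kind, gene = NA_character_) {
  id <- as.character(id)
  kind <- as.character(kind)
  if (anyDuplicated(id)) stop_input("node ids must be unique")
  bad <- setdiff(unique(kind), NODE_KINDS)
  if (length(bad)) stop_input("unknown node kind(s): %s", toString(bad))
  data.frame(id = id, kind = kind,
             gene = rep_len(as.character(gene), length(id)),
             stringsAsFactors = FALSE)
}

# Canonical edge form: character columns, ppi stored with source <= target,
# duplicates removed.  Row order is deterministic (kind, source, target).
canonicalize_edges <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0L) {
    return(data.frame(source = character(), target = character(),
                      edge_kind = character(), stringsAsFactors = FALSE))
  }
  need <- c("source", "target", "edge_kind")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stop_input("edge table missing column(s): %s", toString(miss))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      edge_kind = as.character(edges$edge_kind),
                      stringsAsFactors = FALSE)
  bad <- setdiff(unique(edges$edge_kind), EDGE_KINDS)
  if (length(bad)) stop_input("unknown edge_kind(s): %s", toString(bad))
  swap <- edges$edge_kind == "ppi" & edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  edges <- unique(edges)
  edges[order(edges$edge_kind, edges$source, edges$target), , drop = FALSE] ->
    edges
  rownames(edges) <- NULL
  edges
}

#' Read / write a typed edge table
#'
#' Edge tables are TSV files with columns `source`, `target`, `edge_kind`.
#' Reading applies set semantics (duplicate rows collapse to one edge) and
#' canonicalizes undirected `ppi` edges to `source <= target`; writing a read
#' result and reading it back is the identity.
#'
#' @param path file path.
#' @return `read_edge_table`: a canonical edge `data.frame`.
#' @export
read_edge_table <- function(path) {
  edges <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", quote = "",
                             comment.char = "")
  canonicalize_edges(edges)
}

#' @rdname read_edge_table
#' @param edges an edge `data.frame` (columns source, target, edge_kind).
#' @export
write_edge_table <- function(edges, path) {
  edges <- canonicalize_edges(edges)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# validate edge endpoint kinds against a node table
check_edge_kinds <- function(edges, nodes) {
  kind <- stats::setNames(nodes$kind, nodes$id)
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing)) {
    stop_input("edge endpoint(s) absent from node table: %s",
               toString(utils::head(missing, 5L)))
  }
  sk <- kind[edges$source]; tk <- kind[edges$target]
  ok <- rep(TRUE, nrow(edges))
  is_ppi <- edges$edge_kind == "ppi"
  ok[is_ppi] <- protein_layer(sk[is_ppi]) & protein_layer(tk[is_ppi])
  is_tf <- edges$edge_kind == "tf_gene"
  ok[is_tf] <- protein_layer(sk[is_tf]) & rna_layer(tk[is_tf])
  is_lnc <- edges$edge_kind == "lnc_gene"
  ok[is_lnc] <- sk[is_lnc] == "lncRNA" & rna_layer(tk[is_lnc])
  is_mir <- edges$edge_kind == "mir_gene"
  ok[is_mir] <- sk[is_mir] == "miRNA" & rna_layer(tk[is_mir])
  if (any(!ok)) {
    i <- which(!ok)[1L]
    stop_input("edge %s -> %s has kind '%s' but endpoint kinds (%s, %s)",
               edges$source[i], edges$target[i], edges$edge_kind[i],
               sk[i], tk[i])
  }
  if (any(is_ppi & edges$source == edges$target)) {
    stop_input("self-loop ppi edges are not allowed")
  }
  invisible(TRUE)
}

#' Construct a candidate GWGEN
#'
#' A candidate GWGEN is a Boolean typed-edge network: an interaction is either
#' present or absent, never weighted. Candidate networks are the database-
#' derived superset that system identification subsequently prunes.
#'
#' @param nodes a node table (see [node_table()]).
#' @param edges an edge `data.frame` with columns `source`, `target`,
#'   `edge_kind`.
#' @return an object of class `candidate_gwgen`: a list with elements
#'   `nodes` and `edges` (canonical form).
#' @export
candidate_gwgen <- function(nodes, edges) {
  edges <- canonicalize_edges(edges)
  check_edge_kinds(edges, nodes)
  structure(list(nodes = nodes, edges = edges), class = "candidate_gwgen")
}

#' @export
print.candidate_gwgen <- function(x, ...) {
  cat("Candidate GWGEN:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat("  node kinds:",
      paste(sprintf("%s=%d", names(table(x$nodes$kind)),
                    as.integer(table(x$nodes$kind))), collapse = ", "), "\n")
  cat("  edge kinds:",
      paste(sprintf("%s=%d", names(table(x$edges$edge_kind)),
                    as.integer(table(x$edges$edge_kind))), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-node candidate in-degrees
#'
#' For each node the number of candidate PPI partners (Y), candidate TFs (J),
#' candidate lncRNA regulators (W) and candidate miRNA repressors (H); these
#' are the maximal model orders searched during identification.
#'
#' @param gwgen a `candidate_gwgen`.
#' @return a `data.frame` with columns `id`, `Y`, `J`, `W`, `H`.
#' @export
candidate_degrees <- function(gwgen) {
  ids <- gwgen$nodes$id
  e <- gwgen$edges
  cnt <- function(x) {
    t <- table(factor(x, levels = ids))
    as.integer(t)
  }
  is_ppi <- e$edge_kind == "ppi"
  data.frame(
    id = ids,
    Y = cnt(c(e$source[is_ppi], e$target[is_ppi])),
    J = cnt(e$target[e$edge_kind == "tf_gene"]),
    W = cnt(e$target[e$edge_kind == "lnc_gene"]),
    H = cnt(e$target[e$edge_kind == "mir_gene"]),
    stringsAsFactors = FALSE)
}

# regulators of `id` by layer, given canonical edges
node_regulators <- function(edges, id) {
  is_ppi <- edges$edge_kind == "ppi"
  partners <- sort(unique(c(edges$target[is_ppi & edges$source == id],
                            edges$source[is_ppi & edges$target == id])))
  list(
    ppi = partners,
    tf  = sort(edges$source[edges$edge_kind == "tf_gene" & edges$target == id]),
    lnc = sort(edges$source[edges$edge_kind == "lnc_gene" & edges$target == id]),
    mir = sort(edges$source[edges$edge_kind == "mir_gene" & edges$target == id]))
}

#' Merge heterogeneous edge sources into one candidate GWGEN
#'
#' Takes the deduplicated union of several edge tables (as mined from
#' different interaction databases) and validates endpoint kinds. Merging is
#' idempotent and order-independent.
#'
#' @param sources a list of edge `data.frame`s.
#' @param nodes a node table covering every endpoint.
#' @return a `candidate_gwgen`.
#' @export
merge_sources <- function(sources, nodes) {
  stopifnot(is.list(sources))
  all_edges <- do.call(rbind, lapply(sources, canonicalize_edges))
  candidate_gwgen(nodes, all_edges)
}

#' Read / write an expression matrix
#'
#' Expression matrices are CSV, samples in rows (first column `sample`),
#' nodes in columns (header = node ids).
#'
#' @param path file path.
#' @return `read_expression`: numeric matrix, samples x nodes, with
#'   `rownames` = sample ids and `colnames` = node ids.
#' @export
read_expression <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression
#' @param expr numeric samples x nodes matrix with dimnames.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample = rownames(expr) %||% seq_len(nrow(expr)),
                   expr, check.names = FALSE)
  # 17 significant digits so values round-trip exactly through the file
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align a candidate network with an expression dataset
#'
#' Nodes without a measured expression column are dropped from the network
#' together with their incident edges (identification needs complete
#' regressors; no imputation). The expression matrix is restricted and
#' column-ordered to the surviving nodes.
#'
#' @param candidate a `candidate_gwgen`.
#' @param expr samples x nodes numeric matrix (colnames = node ids).
#' @return a list with elements `network` (pruned `candidate_gwgen`), `expr`
#'   (restricted matrix), and `dropped` (ids removed).
#' @export
align_network <- function(candidate, expr) {
  if (is.null(colnames(expr))) stop_input("expression matrix needs colnames")
  if (nrow(expr) < 2L) stop_input("need at least 2 samples")
  if (anyNA(expr)) stop_input("expression matrix contains missing values")
  keep <- candidate$nodes$id %in% colnames(expr)
  dropped <- candidate$nodes$id[!keep]
  nodes <- candidate$nodes[keep, , drop = FALSE]
  e <- candidate$edges
  e <- e[e$source %in% nodes$id & e$target %in% nodes$id, , drop = FALSE]
  net <- candidate_gwgen(nodes, e)
  list(network = net,
       expr = expr[, nodes$id, drop = FALSE],
       dropped = dropped)
}

#' Parse a GEO series-matrix file
#'
#' Reads a plain-text series-matrix file (the format GEO serves for
#' expression series), returning the expression matrix transposed to samples
#' x probes plus a per-sample subtype label scraped from the sample
#' characteristics lines (`ABC` / `GCB` / `NA`). Operates on a local file
#' only; no downloading.
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @return list with `expr` (samples x probes matrix) and `subtype`
#'   (character vector along samples).
#' @export
load_geo_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop_input("malformed series matrix: missing or empty data table")
  }
  tab <- utils::read.table(text = lines[(beg + 1L):(end - 1L)], header = TRUE,
                           sep = "\t", quote = "\"", check.names = FALSE,
                           comment.char = "")
  probes <- as.character(tab[[1]])
  m <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(m) <- probes
  storage.mode(m) <- "double"
  char_lines <- grep("^!Sample_characteristics", lines, value = TRUE)
  subtype <- rep(NA_character_, nrow(m))
  for (ln in char_lines) {
    fields <- strsplit(sub("^[^\t]*\t", "", ln), "\t")[[1]]
    fields <- gsub("\"", "", fields)
    hit <- grepl("ABC|GCB", fields)
    if (any(hit)) {
      lab <- ifelse(grepl("ABC", fields), "ABC",
                    ifelse(grepl("GCB", fields), "GCB", NA_character_))
      subtype[seq_along(lab)] <- ifelse(is.na(subtype[seq_along(lab)]),
                                        lab, subtype[seq_along(lab)])
    }
  }
  list(expr = m, subtype = subtype[seq_len(nrow(m))])
}
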