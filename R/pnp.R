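# Principal network projection (PNP): assemble the combined ability matrix
# Z of the identified network, decompose it, keep the minimal set of leading
# singular directions carrying at least 85% of the squared-singular-value
# energy, rank every node by the 2-norm of its row's projection onto those
# directions, and extract the induced core subnetwork on the top-ranked
# nodes.

#' Assemble the combined network matrix Z
#'
#' One row per regulated node (proteins, genes, lncRNAs, miRNAs), one column
#' per regulator identity (a protein acting as a PPI partner and as a TF
#' shares a single column). Each row holds the node's fitted abilities in its
#' regulators' columns; everything pruned by AIC is exactly zero, and miRNA
#' repression entries are stored as `-C_qh <= 0`. Basal levels are not
#' regulator abilities and are excluded.
#'
#' @param real a `gwgen_fit`.
#' @return an object of class `combined_matrix`: the numeric matrix with
#'   rownames (regulated node ids) and colnames (regulator ids).
#' @export
assemble_combined_matrix <- function(real) {
  stopifnot(inherits(real, "gwgen_fit"))
  if (nrow(real$edges) == 0L) stop_input("network has no surviving edges")
  rows <- real$nodes$id
  cols <- sort(unique(real$edges$source))
  Z <- matrix(0, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  e <- real$edges
  Z[cbind(match(e$target, rows), match(e$source, cols))] <- e$ability
  structure(Z, class = c("combined_matrix", class(Z)))
}

#' Singular value decomposition with normalized energies
#'
#' Full SVD of Z; the energy of the r-th singular direction is
#' `E_r = k_r^2 / sum(k^2)`, so the energies sum to one.
#'
#' @param Z a `combined_matrix` (or plain numeric matrix).
#' @return an object of class `pnp_svd`: list with `u`, `d` (singular values,
#'   non-increasing), `v` (right singular vectors as columns), `energies`.
#' @export
decompose_network <- function(Z) {
  Z <- unclass(Z)
  if (all(Z == 0)) stop_input("combined matrix is identically zero")
  s <- svd(Z)
  energies <- s$d^2 / sum(s$d^2)
  structure(list(u = s$u, d = s$d, v = s$v, energies = energies),
            class = "pnp_svd")
}

#' Minimal rank reaching an energy threshold
#'
#' The smallest R such that the leading R normalized energies sum to at
#' least `threshold` (default 0.85: the retained directions describe 85% of
#' the network structure).
#'
#' @param energies normalized energy vector (non-increasing, sums to 1).
#' @param threshold energy fraction in (0, 1].
#' @return integer R.
#' @export
select_rank <- function(energies, threshold = 0.85) {
  if (threshold <= 0 || threshold > 1) {
    stop_input("threshold must be in (0, 1]")
  }
  cum <- cumsum(energies)
  R <- which(cum >= threshold - 1e-12)[1L]
  if (is.na(R)) R <- length(energies)
  as.integer(R)
}

#' Project nodes onto the principal network structure
#'
#' For each row `d_t` of Z, the projections `F(t, a) = d_t . r_a` onto the
#' leading R right singular vectors, and the 2-norm projection value
#' `P(t) = sqrt(sum_a F(t, a)^2)`. P is invariant to sign flips of singular
#' vector pairs, nonnegative, and bounded by the row's Euclidean norm.
#'
#' @param Z the `combined_matrix`.
#' @param svd_res a `pnp_svd` from [decompose_network()].
#' @param rank number of leading directions R (default: [select_rank()] at
#'   0.85).
#' @return an object of class `pnp_projection`: list with `F` (nodes x R
#'   projection matrix), `value` (named vector P(t)), `rank`, and `ranking`
#'   (node ids, decreasing P, ties by id).
#' @export
project_nodes <- function(Z, svd_res, rank = select_rank(svd_res$energies)) {
  Zm <- unclass(Z)
  R <- as.integer(rank)
  stopifnot(R >= 1, R <= ncol(svd_res$v))
  Fmat <- Zm %*% svd_res$v[, seq_len(R), drop = FALSE]
  P <- sqrt(rowSums(Fmat^2))
  names(P) <- rownames(Zm)
  ord <- order(-P, names(P))
  structure(list(F = Fmat, value = P, rank = R,
                 ranking = names(P)[ord]),
            class = "pnp_projection")
}

#' Extract the core GWGEN
#'
#' Keeps the `top_k` nodes by projection value (all nodes if fewer), ties
#' broken by node id ascending, and returns the induced subnetwork of the
#' identified network on those nodes.
#'
#' @param real a `gwgen_fit`.
#' @param proj a `pnp_projection` over the same network.
#' @param top_k number of core nodes (the study default is 3000).
#' @return an object of class `core_gwgen`: list with `nodes` (node table of
#'   the selected nodes), `edges` (induced edges), `projection` (P values of
#'   selected nodes, in ranking order).
#' @export
extract_core <- function(real, proj, top_k = 3000) {
  if (top_k < 1) stop_input("top_k must be >= 1")
  sel <- utils::head(proj$ranking, top_k)
  nodes <- real$nodes[real$nodes$id %in% sel, , drop = FALSE]
  e <- real$edges
  edges <- e[e$source %in% sel & e$target %in% sel, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 projection = proj$value[sel]),
            class = "core_gwgen")
}

#' @export
print.core_gwgen <- function(x, ...) {
  cat("Core GWGEN:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "induced interactions\n")
  invisible(x)
}

#' Run the full projection stage
#'
#' Convenience wrapper: combined matrix, SVD, rank selection, projection and
#' core extraction in one call.
#'
#' @param real a `gwgen_fit`.
#' @param threshold energy fraction for [select_rank()].
#' @param top_k core size for [extract_core()].
#' @return list with `Z`, `svd`, `rank`, `projection`, `core`.
#' @export
pnp <- function(real, threshold = 0.85, top_k = 3000) {
  Z <- assemble_combined_matrix(real)
  s <- decompose_network(Z)
  R <- select_rank(s$energies, threshold)
  proj <- project_nodes(Z, s, R)
  list(Z = Z, svd = s, rank = R, projection = proj,
       core = extract_core(real, proj, top_k))
}

#' Compare two core networks
#'
#' Exact set operations over node ids and canonical edge keys: the common
#' part and each core's specific part.
#'
#' @param core_a,core_b `core_gwgen` objects over a shared id universe.
#' @return list with `common` (nodes, edges), `specific_a`, `specific_b`,
#'   and `counts`.
#' @export
compare_cores <- function(core_a, core_b) {
  edge_key <- function(core) {
    e <- canonicalize_edges(core$edges[, c("source", "target", "edge_kind")])
    paste(e$source, e$target, e$edge_kind, sep = "\r")
  }
  na <- core_a$nodes$id; nb <- core_b$nodes$id
  ea <- edge_key(core_a); eb <- edge_key(core_b)
  res <- list(
    common = list(nodes = intersect(na, nb), edges = intersect(ea, eb)),
    specific_a = list(nodes = setdiff(na, nb), edges = setdiff(ea, eb)),
    specific_b = list(nodes = setdiff(nb, na), edges = setdiff(eb, ea)))
  res$counts <- c(common_nodes = length(res$common$nodes),
                  common_edges = length(res$common$edges),
                  specific_a_nodes = length(res$specific_a$nodes),
                  specific_b_nodes = length(res$specific_b$nodes))
  res
}
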