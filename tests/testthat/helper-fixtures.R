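# Shared fixtures and small oracles for the test suite.

# canonical "source|target|kind" keys for edge-set comparisons
edge_keys <- function(edges) {
  cc <- gwgendrug:::canonicalize_edges(
    edges[, c("source", "target", "edge_kind")])
  paste(cc$source, cc$target, cc$edge_kind, sep = "|")
}

# directed per-row keys (regulator -> regulated), for comparing abilities
# between a planted edge frame and the per-equation rows of a fit. PPI
# edges must be matched directionally: the reverse equation of an exact
# two-node relation legitimately retains the edge with the reciprocal
# coefficient, so only the generation-direction row carries the planted
# ability.
directed_keys <- function(edges) {
  paste(edges$source, edges$target, edges$edge_kind, sep = "|")
}

# A small hand-constructed planted model that is identifiable by
# construction even at noise_sd = 0: the protein cascade is nonlinear in the
# product form, regulated RNA nodes never co-occur as regulators alongside
# their own complete regulator sets, and root lncRNA/miRNA inputs are
# independent.  Used for the exact noiseless-recovery checks, where randomly
# planted networks can be genuinely unidentifiable (a regulated lncRNA with
# no miRNA repressor is an exact affine function of its regulators).
toy_planted <- function(noise_sd = 0, root_sd = 0.5,
                        regressor_form = "product") {
  nodes <- node_table(
    id   = c("proA", "proB", "tfA", "tfB", "lncA", "mirA", "gene1", "gene2"),
    kind = c("protein", "protein", "TF", "TF", "lncRNA", "miRNA",
             "gene", "gene"))
  edges <- data.frame(
    source    = c("proA", "tfA",  "tfB",  "lncA",  "mirA",  "tfA",  "mirA"),
    target    = c("tfB",  "lncA", "gene1", "gene1", "gene1", "gene2", "gene2"),
    edge_kind = c("ppi",  "tf_gene", "tf_gene", "lnc_gene", "mir_gene",
                  "tf_gene", "mir_gene"),
    ability   = c(0.2, 0.8, 0.7, -0.5, -0.3, 0.9, -0.4),
    stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    edges = edges,
    basal = stats::setNames(c(1.0, 1.2, 0.9, 1.1, 0.8, 1.3, 1.0, 0.7),
                            nodes$id),
    noise_sd = stats::setNames(rep(noise_sd, nrow(nodes)), nodes$id),
    root_sd = root_sd,
    regressor_form = regressor_form,
    order = c("proA", "proB", "tfA", "tfB", "lncA", "mirA", "gene1",
              "gene2")),
    class = "planted_model")
}

candidate_from_planted <- function(planted) {
  candidate_gwgen(planted$nodes,
                  planted$edges[, c("source", "target", "edge_kind")])
}

# A bare node_regression with s_true signal columns and s_spur pure-noise
# columns, for order-search recovery simulations.
toy_regression <- function(seed, N = 200L, s_true = 3L, s_spur = 2L,
                           noise_sd = 0.1) {
  gwgendrug:::with_seed(seed, {
    p <- s_true + s_spur
    X <- matrix(stats::rnorm(N * p), N, p)
    beta <- rep_len(c(0.8, -0.6, 0.7), s_true)
    y <- as.numeric(X[, seq_len(s_true), drop = FALSE] %*% beta + 1 +
                      stats::rnorm(N, 0, noise_sd))
    design <- cbind(X, 1)
    colnames(design) <- c(paste0("tf:r", seq_len(p)), "(basal)")
    structure(list(node = "g", node_kind = "gene", response = y,
                   design = design,
                   columns = data.frame(
                     regulator = c(sprintf("r%02d", seq_len(p)),
                                   NA_character_),
                     kind = c(rep("tf", p), "intercept"),
                     constraint = "free", stringsAsFactors = FALSE)),
              class = "node_regression")
  })
}

# exhaustive all-subsets AIC oracle for a node_regression
exhaustive_best_aic <- function(reg) {
  p <- ncol(reg$design) - 1L
  best <- gwgendrug:::intercept_only_fit(reg)$aic
  if (p == 0L) return(best)
  for (k in seq_len(p)) {
    combs <- utils::combn(p, k)
    for (i in seq_len(ncol(combs))) {
      f <- tryCatch(gwgendrug:::fit_active(reg, combs[, i]),
                    error = function(e) NULL)
      if (!is.null(f) && f$aic < best) best <- f$aic
    }
  }
  best
}

geo_fixture_path <- function() {
  system.file("extdata", "mini_series_matrix.txt", package = "gwgendrug",
              mustWork = TRUE)
}
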