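#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  All stochastic operations in the package
# funnel through this so that (inputs, seed) fully determine outputs.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed so that independent generator calls
# inside one seeded run do not reuse the same stream.
child_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

NODE_KINDS <- c("protein", "receptor", "TF", "gene", "miRNA", "lncRNA")
EDGE_KINDS <- c("ppi", "tf_gene", "lnc_gene", "mir_gene")

# Node kinds whose expression can appear on the left-hand side of a model:
# the protein layer (protein/receptor/TF) uses the protein-interaction model,
# the RNA layer (gene/lncRNA/miRNA) the gene-regulation model.
protein_layer <- function(kind) kind %in% c("protein", "receptor", "TF")
rna_layer     <- function(kind) kind %in% c("gene", "lncRNA", "miRNA")
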