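# System identification: per-node regression construction, (constrained)
# least squares, AIC model-order detection by forward/backward search, and
# assembly of the pruned, data-supported ("real") GWGEN.
#
# Protein-layer model (interaction):    p_i[n] = sum_k alpha_ik p_i[n] p_k[n]
#                                                + phi_i + eta_i[n]
# RNA-layer model (regulation):         g_q[n] = sum_j A_qj z_j[n]
#                                                + sum_w B_qw x_w[n]
#                                                - sum_h C_qh g_q[n] d_h[n]
#                                                + phi_q + eta_q[n],  C_qh >= 0
# The same regulation model is reused for lncRNA and miRNA responses.

#' Build the per-node regression problem
#'
#' Constructs the response vector and design matrix for one node from the
#' candidate network and expression data. Protein-layer nodes get one
#' bilinear column `p_i * p_k` per candidate PPI partner (or `p_k` alone
#' under `ppi_regressor = "partner"`); RNA-layer nodes get one column per
#' candidate TF (`z_j`) and lncRNA (`x_w`), plus one sign-constrained column
#' `g_q * d_h` per candidate miRNA repressor, whose coefficient `-C_qh` must
#' be nonpositive. The intercept (basal level) is always the last column and
#' never counts toward the model order.
#'
#' Under `ppi_regressor = "partner"` the two bilinear column types are
#' replaced by their linear counterparts: `p_k` for PPI partners and `d_h`
#' (still sign-constrained) for miRNA repressors. The bilinear columns
#' contain the response variable itself, so under noise any such candidate
#' column is strongly correlated with the response whether or not the edge is
#' real; the linear form does not have this endogeneity and is the form under
#' which pruning of spurious candidates is statistically well-posed (see the
#' package vignette).
#'
#' @param node_id node to model.
#' @param network a `candidate_gwgen`.
#' @param expr samples x nodes expression matrix.
#' @param ppi_regressor `"product"` (default, the bilinear regressors as the
#'   models state) or `"partner"` (regulator expression alone).
#' @return an object of class `node_regression`: list with `response`,
#'   `design` (N x (order+1), intercept last) and `columns` metadata
#'   (`regulator`, `kind`, `constraint`).
#' @export
build_node_regression <- function(node_id, network, expr,
                                  ppi_regressor = c("product", "partner")) {
  ppi_regressor <- match.arg(ppi_regressor)
  if (!node_id %in% colnames(expr)) {
    stop_input("node '%s' has no expression column", node_id)
  }
  kind <- network$nodes$kind[match(node_id, network$nodes$id)]
  if (is.na(kind)) stop_input("node '%s' not in network", node_id)
  y <- expr[, node_id]
  N <- length(y)
  regs <- node_regulators(network$edges, node_id)
  cols <- list(); meta <- NULL
  addcol <- function(v, regulator, kind, constraint) {
    cols[[length(cols) + 1L]] <<- v
    meta <<- rbind(meta, data.frame(regulator = regulator, kind = kind,
                                    constraint = constraint,
                                    stringsAsFactors = FALSE))
  }
  if (protein_layer(kind)) {
    for (k in regs$ppi) {
      v <- if (ppi_regressor == "product") y * expr[, k] else expr[, k]
      addcol(v, k, "ppi_product", "free")
    }
  } else {
    for (j in regs$tf)  addcol(expr[, j], j, "tf", "free")
    for (w in regs$lnc) addcol(expr[, w], w, "lnc", "free")
    for (h in regs$mir) {
      v <- if (ppi_regressor == "product") y * expr[, h] else expr[, h]
      addcol(v, h, "mir_product", "nonpositive")
    }
  }
  addcol(rep(1, N), NA_character_, "intercept", "free")
  design <- do.call(cbind, cols)
  colnames(design) <- ifelse(meta$kind == "intercept", "(basal)",
                             paste0(meta$kind, ":", meta$regulator))
  if (N < ncol(design) + 1L) {
    stop_input("node '%s': %d samples cannot identify %d coefficients",
               node_id, N, ncol(design))
  }
  structure(list(node = node_id, node_kind = kind, response = y,
                 design = design, columns = meta),
            class = "node_regression")
}

#' Akaike information criterion for a node model
#'
#' `log(rss_mean) + 2 * (order + 1) / N`, where `rss_mean` is the mean
#' squared residual over the N samples and `order` counts retained regulators
#' (the always-present basal term contributes the `+ 1`). The residual is
#' floored at 1e-12 before the log so that noiseless (zero-residual) fits
#' stay finite.
#'
#' @param rss_mean mean squared residual.
#' @param order number of regulators in the model (intercept excluded).
#' @param N sample count.
#' @return the AIC value.
#' @export
aic_score <- function(rss_mean, order, N) {
  stopifnot(N >= 1, rss_mean >= 0)
  log(max(rss_mean, 1e-12)) + 2 * (order + 1) / N
}

# least squares on selected columns (intercept always included).
# `active`: indices into the regressor columns (excluding intercept).
ls_solve <- function(design, y, active) {
  X <- design[, c(active, ncol(design)), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop_input("singular design: collinear column(s) %s", toString(dep))
  }
  coef <- qr.coef(qrX, y)
  res <- y - X %*% coef
  list(coef = as.numeric(coef), rss_mean = mean(res^2))
}

# Active-set solver for min 0.5 ||X b - y||^2 s.t. b_j <= 0 for j in `neg`
# (column indices of X). Sign-flips the constrained columns and runs
# Lawson-Hanson NNLS with the unconstrained variables permanently passive.
ls_solve_signed <- function(X, y, neg, tol = 1e-9, max_iter = 300L) {
  p <- ncol(X)
  Xf <- X
  if (length(neg)) Xf[, neg] <- -Xf[, neg]
  free <- setdiff(seq_len(p), neg)
  passive <- rep(FALSE, p); passive[free] <- TRUE
  b <- numeric(p)
  solve_passive <- function(pas) {
    z <- numeric(p)
    if (any(pas)) {
      fit <- qr(Xf[, pas, drop = FALSE])
      if (fit$rank < sum(pas)) {
        stop_input("singular design: collinear column(s) %s",
                   toString(colnames(X)[which(pas)[fit$pivot[
                     seq.int(fit$rank + 1L, sum(pas))]]]))
      }
      z[pas] <- qr.coef(fit, y)
    }
    z
  }
  b <- solve_passive(passive)
  # pull any infeasible start (none expected: constrained vars start at 0)
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(crossprod(Xf, y - Xf %*% b))
    cand <- which(!passive)
    if (!length(cand) || max(w[cand]) <= tol) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    z <- solve_passive(passive)
    inner <- 0L
    while (TRUE) {
      viol <- which(passive & z < -tol)
      viol <- intersect(viol, neg)
      if (!length(viol)) break
      alpha <- min(b[viol] / (b[viol] - z[viol]))
      b <- b + alpha * (z - b)
      drop_j <- intersect(which(passive & abs(b) <= tol * 10), neg)
      # numerical guard: always drop at least the most negative violator
      if (!length(drop_j)) drop_j <- viol[which.min(z[viol])]
      passive[drop_j] <- FALSE
      b[drop_j] <- 0
      z <- solve_passive(passive)
      inner <- inner + 1L
      if (inner > max_iter) stop_input("constrained solver failed to converge")
    }
    b <- z
  }
  b[!passive] <- 0
  # KKT check: at an active bound the flipped-space gradient must be <= 0
  w <- as.numeric(crossprod(Xf, y - Xf %*% b))
  kkt <- max(c(0, w[!passive], abs(w[passive])))
  if (kkt > 1e-6 * max(1, sqrt(sum(y^2)))) {
    stop_input("constrained solver KKT residual %g above tolerance", kkt)
  }
  out <- b
  if (length(neg)) out[neg] <- -out[neg]
  out
}

node_fit <- function(reg, active, coef, rss_mean, constrained) {
  N <- length(reg$response)
  est <- data.frame(reg$columns[active, , drop = FALSE],
                    estimate = coef[seq_along(active)],
                    stringsAsFactors = FALSE)
  structure(list(node = reg$node, node_kind = reg$node_kind,
                 estimates = est,
                 basal = coef[length(coef)],
                 rss_mean = rss_mean,
                 order = length(active),
                 aic = aic_score(rss_mean, length(active), N),
                 n = N,
                 constrained = constrained,
                 active = active),
            class = "node_fit")
}

#' Unconstrained least-squares fit of a node regression
#'
#' Minimizes `0.5 * ||design %*% phi - response||^2` over all columns
#' (coefficients and basal level); the mean squared residual over the N
#' samples is reported as `rss_mean`.
#'
#' @param reg a `node_regression`.
#' @param active optional integer vector of regressor columns to use
#'   (default: all); the intercept is always included.
#' @return a `node_fit` with `estimates`, `basal`, `rss_mean`, `order`, `aic`.
#' @export
fit_unconstrained <- function(reg, active = NULL) {
  p <- ncol(reg$design) - 1L
  active <- sort(active %||% seq_len(p))
  sol <- ls_solve(reg$design, reg$response, active)
  node_fit(reg, active, sol$coef, sol$rss_mean, constrained = FALSE)
}

#' Sign-constrained least-squares fit of a node regression
#'
#' Same objective as [fit_unconstrained()], subject to every miRNA-product
#' coefficient being nonpositive (repression abilities `C_qh >= 0`). With no
#' constrained columns in the active set the result equals the unconstrained
#' fit. Solved by an active-set method; KKT residuals are verified.
#'
#' @inheritParams fit_unconstrained
#' @return a `node_fit`; all `mir_product` estimates are `<= 0`.
#' @export
fit_constrained <- function(reg, active = NULL) {
  p <- ncol(reg$design) - 1L
  active <- sort(active %||% seq_len(p))
  constrained_local <- which(reg$columns$constraint[active] == "nonpositive")
  if (!length(constrained_local)) return(fit_unconstrained(reg, active))
  X <- reg$design[, c(active, ncol(reg$design)), drop = FALSE]
  coef <- ls_solve_signed(X, reg$response, neg = constrained_local)
  res <- reg$response - X %*% coef
  node_fit(reg, active, coef, mean(res^2), constrained = TRUE)
}

# fit dispatch: constrained solver engaged only when the active set contains
# a sign-constrained column
fit_active <- function(reg, active) {
  if (any(reg$columns$constraint[active] == "nonpositive")) {
    fit_constrained(reg, active)
  } else {
    fit_unconstrained(reg, active)
  }
}

intercept_only_fit <- function(reg) {
  mu <- mean(reg$response)
  node_fit(reg, integer(0), mu, mean((reg$response - mu)^2),
           constrained = FALSE)
}

#' AIC model-order detection by greedy forward/backward search
#'
#' Starting from the basal-only model, repeatedly adds the candidate
#' regulator whose inclusion lowers AIC the most; when no addition lowers
#' AIC, repeatedly removes the retained regulator whose exclusion lowers AIC
#' the most. Ties break toward the smallest regulator id. The constrained
#' solver is engaged whenever a miRNA-product column is active. Returns the
#' best-AIC fit visited.
#'
#' @param reg a `node_regression`.
#' @return a `node_fit` for the selected model order.
#' @export
order_search <- function(reg) {
  p <- ncol(reg$design) - 1L
  best <- intercept_only_fit(reg)
  if (p == 0L) return(best)
  try_fit <- function(active) {
    tryCatch(fit_active(reg, active), error = function(e) NULL)
  }
  tie_key <- function(j) reg$columns$regulator[j]
  current <- best
  repeat {  # forward
    remaining <- setdiff(seq_len(p), current$active)
    if (!length(remaining)) break
    fits <- lapply(remaining, function(j) try_fit(c(current$active, j)))
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, 0)
    if (!any(is.finite(aics)) || min(aics) >= current$aic) break
    winners <- remaining[aics <= min(aics) + 0]
    j <- winners[order(tie_key(winners))][1L]
    current <- fits[[match(j, remaining)]]
  }
  repeat {  # backward
    if (current$order == 0L) break
    fits <- lapply(current$active,
                   function(j) try_fit(setdiff(current$active, j)))
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, 0)
    if (!any(is.finite(aics)) || min(aics) >= current$aic) break
    drops <- current$active[aics <= min(aics) + 0]
    j <- drops[order(tie_key(drops))][1L]
    current <- fits[[match(j, current$active)]]
  }
  if (current$aic <= best$aic) current else best
}

#' Identify the real GWGEN from a candidate network and expression data
#'
#' Runs [order_search()] independently on every node of the (aligned)
#' candidate network, prunes every candidate interaction that falls outside a
#' node's selected model order, and assembles the surviving network with its
#' estimated abilities. A PPI edge survives if either endpoint retains the
#' partner; regulations survive if the regulated node retains the regulator.
#' Per-node fit failures are logged and leave that node unmodeled (its own
#' regulations are dropped) rather than aborting the run.
#'
#' @param candidate a `candidate_gwgen`.
#' @param expr samples x nodes expression matrix (extra columns ignored;
#'   unmeasured nodes dropped via [align_network()]).
#' @param ppi_regressor see [build_node_regression()].
#' @return an object of class `gwgen_fit`: list with `nodes`, `edges`
#'   (directed regulator -> regulated rows with `ability`), `fits` (per-node
#'   `node_fit`), `failed` (node ids), `counts`, and the call.
#' @export
gwgen_fit <- function(candidate, expr, ppi_regressor = c("product", "partner")) {
  ppi_regressor <- match.arg(ppi_regressor)
  al <- align_network(candidate, expr)
  net <- al$network; expr <- al$expr
  fits <- list(); failed <- character(0)
  src <- character(0); tgt <- character(0); knd <- character(0); abl <- numeric(0)
  for (id in net$nodes$id) {
    f <- tryCatch({
      reg <- build_node_regression(id, net, expr, ppi_regressor)
      order_search(reg)
    }, error = function(e) e)
    if (inherits(f, "error")) {
      failed <- c(failed, id)
      next
    }
    fits[[id]] <- f
    if (f$order > 0L) {
      est <- f$estimates
      kind_map <- c(ppi_product = "ppi", tf = "tf_gene", lnc = "lnc_gene",
                    mir_product = "mir_gene")
      src <- c(src, est$regulator)
      tgt <- c(tgt, rep(id, nrow(est)))
      knd <- c(knd, unname(kind_map[est$kind]))
      abl <- c(abl, est$estimate)
    }
  }
  edges <- data.frame(source = src, target = tgt, edge_kind = knd,
                      ability = abl, stringsAsFactors = FALSE)
  structure(list(nodes = net$nodes, edges = edges, fits = fits,
                 failed = failed, dropped = al$dropped,
                 ppi_regressor = ppi_regressor,
                 counts = real_counts(net$nodes, edges),
                 n_samples = nrow(expr)),
            class = "gwgen_fit")
}

real_counts <- function(nodes, edges) {
  kind <- stats::setNames(nodes$kind, nodes$id)
  c(I = sum(protein_layer(kind)), Q = sum(kind == "gene"),
    V = sum(kind == "lncRNA"), M = sum(kind == "miRNA"),
    J = length(unique(edges$source[edges$edge_kind == "tf_gene"])),
    W = length(unique(edges$source[edges$edge_kind == "lnc_gene"])),
    H = length(unique(edges$source[edges$edge_kind == "mir_gene"])),
    edges = nrow(edges))
}

#' Build a real-GWGEN object directly from a planted model
#'
#' Bypasses identification: the surviving edges are the planted edges and the
#' recorded abilities are the planted abilities. Useful for exercising the
#' projection and core-extraction stages at sizes where running thousands of
#' per-node regressions adds nothing.
#'
#' @param planted a `planted_model`.
#' @return a `gwgen_fit` (with empty `fits`).
#' @export
real_gwgen_from_planted <- function(planted) {
  stopifnot(inherits(planted, "planted_model"))
  structure(list(nodes = planted$nodes, edges = planted$edges,
                 fits = list(), failed = character(0), dropped = character(0),
                 ppi_regressor = "product",
                 counts = real_counts(planted$nodes, planted$edges),
                 n_samples = NA_integer_),
            class = "gwgen_fit")
}

#' @export
print.gwgen_fit <- function(x, ...) {
  cat("Identified GWGEN:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "surviving interactions\n")
  if (length(x$failed)) cat("  unmodeled nodes:", length(x$failed), "\n")
  invisible(x)
}

#' @export
summary.gwgen_fit <- function(object, ...) {
  fits <- object$fits
  out <- list(
    nodes = nrow(object$nodes),
    edges = nrow(object$edges),
    edge_kinds = table(object$edges$edge_kind),
    counts = object$counts,
    failed = object$failed,
    mean_order = if (length(fits)) {
      mean(vapply(fits, function(f) f$order, 0))
    } else NA_real_,
    mean_aic = if (length(fits)) {
      mean(vapply(fits, function(f) f$aic, 0))
    } else NA_real_)
  class(out) <- "summary.gwgen_fit"
  out
}

#' @export
print.summary.gwgen_fit <- function(x, ...) {
  cat("Identified GWGEN\n")
  cat("  nodes:", x$nodes, "  surviving interactions:", x$edges, "\n")
  if (length(x$edge_kinds)) {
    cat("  by kind:",
        paste(sprintf("%s=%d", names(x$edge_kinds),
                      as.integer(x$edge_kinds)), collapse = ", "), "\n")
  }
  cat(sprintf("  mean selected order: %.2f   mean AIC: %.3f\n",
              x$mean_order, x$mean_aic))
  if (length(x$failed)) cat("  unmodeled nodes:", toString(x$failed), "\n")
  invisible(x)
}

#' @export
coef.gwgen_fit <- function(object, ...) {
  object$edges
}
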