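# Synthetic-data module: plants ground-truth networks, generates expression
# data consistent with the node models, drug-target feature sets, and drug
# annotation tables, so every downstream stage is testable without any
# database mining.
#
# The node models are static regressions, not a generative process, so the
# generator inverts them: networks are generated as DAGs (regulators are
# sampled from nodes earlier in a fixed evaluation order) and each node's
# response is the closed-form solution of its rearranged model equation.
# Samples whose protein denominator 1 - sum(alpha * p_k) or RNA denominator
# 1 + sum(C * d_h) comes within `denom_floor` of zero are redrawn.

#' Define a synthetic scenario
#'
#' Bundles the node counts, sample size, edge densities and noise level that
#' the generators consume. Identical scenario + seed gives byte-identical
#' outputs.
#'
#' @param n_protein,n_tf,n_gene,n_lnc,n_mir node counts per kind (TFs are
#'   protein-layer nodes that additionally act as transcriptional regulators).
#' @param n_samples number of expression samples N.
#' @param density per-candidate-slot probability of a planted (true) edge;
#'   the regulator pool per node and layer is capped at `max_regulators` so
#'   model orders stay identifiable.
#' @param fp_rate probability that a non-planted valid edge slot enters the
#'   candidate network as a false positive (in `[0, 1)`).
#' @param noise_sd standard deviation of the additive model noise per node
#'   and sample.
#' @param root_sd standard deviation of the exogenous per-sample variation
#'   of root nodes (nodes with no planted regulators). Roots are the
#'   network's inputs; their variation propagates downstream and is what
#'   makes the regulated nodes' equations identifiable even at
#'   `noise_sd = 0`.
#' @param max_regulators cap on planted regulators per node per layer.
#' @param regressor_form `"product"` generates from the models as stated
#'   (protein and miRNA-repression terms bilinear in the regulated node's own
#'   expression, solved in closed form); `"partner"` generates from the
#'   explicit linear variant in which the PPI term is `alpha * p_k` and the
#'   repression term `-C * d_h`. The same toggle exists on the
#'   identification side; see [build_node_regression()].
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_protein = 12, n_tf = 6, n_gene = 15,
                               n_lnc = 5, n_mir = 5, n_samples = 200,
                               density = 0.25, fp_rate = 0.3,
                               noise_sd = 0.1, root_sd = 0.5,
                               max_regulators = 3,
                               regressor_form = c("product", "partner"),
                               seed = 1) {
  regressor_form <- match.arg(regressor_form)
  counts <- c(n_protein = n_protein, n_tf = n_tf, n_gene = n_gene,
              n_lnc = n_lnc, n_mir = n_mir, n_samples = n_samples)
  if (any(counts < 0)) stop_input("counts must be nonnegative")
  if (fp_rate < 0 || fp_rate >= 1) stop_input("fp_rate must be in [0, 1)")
  if (density < 0 || density > 1) stop_input("density must be in [0, 1]")
  if (noise_sd < 0) stop_input("noise_sd must be nonnegative")
  if (root_sd < 0) stop_input("root_sd must be nonnegative")
  structure(list(n_protein = n_protein, n_tf = n_tf, n_gene = n_gene,
                 n_lnc = n_lnc, n_mir = n_mir, n_samples = n_samples,
                 density = density, fp_rate = fp_rate, noise_sd = noise_sd,
                 root_sd = root_sd, max_regulators = max_regulators,
                 regressor_form = regressor_form,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Sample `m` distinct non-planted slots out of a large slot universe by
# rejection; `draw()` returns a data.frame(source, target) of random slots,
# `key()` maps rows to a collision key.
sample_fp_slots <- function(n_slots, fp_rate, draw, planted_keys) {
  if (n_slots <= 0L || fp_rate <= 0) {
    return(NULL)
  }
  m <- stats::rbinom(1L, n_slots, fp_rate)
  if (m == 0L) return(NULL)
  got <- character(0)
  out <- NULL
  guard <- 0L
  while (length(got) < m && guard < 200L) {
    need <- m - length(got)
    cand <- draw(max(need * 2L, 10L))
    keys <- paste(cand$source, cand$target, sep = "\r")
    ok <- !(keys %in% planted_keys) & !(keys %in% got) & !duplicated(keys)
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
    got <- c(got, paste(cand$source, cand$target, sep = "\r"))
    out <- rbind(out, cand)
    guard <- guard + 1L
  }
  out
}

#' Generate a candidate GWGEN with a planted true model
#'
#' Plants a ground-truth network (edges with known interaction/regulation
#' abilities and per-node basal levels), then overlays false-positive edges
#' at rate `fp_rate` over the non-planted valid slots. The candidate edge set
#' always contains the planted edge set.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with elements `candidate` (a `candidate_gwgen`) and
#'   `planted` (a `planted_model`: directed model edges with abilities,
#'   basal levels, noise level and the node evaluation order).
#' @export
generate_candidate_gwgen <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  with_seed(scenario$seed, {
    ids_pro <- sprintf("pro%03d", seq_len(scenario$n_protein))
    ids_tf  <- sprintf("tf%03d",  seq_len(scenario$n_tf))
    ids_gen <- sprintf("gene%04d", seq_len(scenario$n_gene))
    ids_lnc <- sprintf("lnc%03d", seq_len(scenario$n_lnc))
    ids_mir <- sprintf("mir%03d", seq_len(scenario$n_mir))
    nodes <- node_table(
      id = c(ids_pro, ids_tf, ids_gen, ids_lnc, ids_mir),
      kind = c(rep("protein", scenario$n_protein),
               rep("TF", scenario$n_tf),
               rep("gene", scenario$n_gene),
               rep("lncRNA", scenario$n_lnc),
               rep("miRNA", scenario$n_mir)))

    # evaluation order: protein layer first (shuffled), then lncRNA/miRNA
    # (shuffled between themselves), genes last
    prot_order <- sample(c(ids_pro, ids_tf))
    rna_order  <- c(sample(c(ids_lnc, ids_mir)), sample(ids_gen))

    pick <- function(pool, density, cap) {
      if (!length(pool) || density <= 0) return(character(0))
      pool <- if (length(pool) > 20L) sample(pool, 20L) else pool
      chosen <- pool[stats::runif(length(pool)) < density]
      if (length(chosen) > cap) chosen <- sample(chosen, cap)
      sort(chosen)
    }
    cap <- scenario$max_regulators

    src <- character(0); tgt <- character(0); knd <- character(0)
    abl <- numeric(0)
    add <- function(regs, node, kind, ability) {
      if (!length(regs)) return(invisible(NULL))
      src <<- c(src, regs); tgt <<- c(tgt, rep(node, length(regs)))
      knd <<- c(knd, rep(kind, length(regs))); abl <<- c(abl, ability)
      invisible(NULL)
    }

    # protein layer: PPI partners among earlier protein-layer nodes; small
    # interaction abilities keep the implicit-model denominator well away
    # from zero
    for (i in seq_along(prot_order)) {
      node <- prot_order[i]
      regs <- pick(prot_order[seq_len(i - 1L)], scenario$density, cap)
      k <- length(regs)
      if (k) {
        mag <- stats::runif(k, 0.10, 0.25) / k
        add(regs, node, "ppi", mag * sample(c(-1, 1), k, replace = TRUE))
      }
    }
    # RNA layer: TF activators, earlier lncRNA regulators, earlier miRNA
    # repressors (repression ability >= 0)
    lncmir_seen <- character(0)
    for (node in rna_order) {
      tf_regs <- pick(ids_tf, scenario$density, cap)
      if (length(tf_regs)) {
        add(tf_regs, node, "tf_gene",
            stats::runif(length(tf_regs), 0.4, 1.0) *
              sample(c(-1, 1), length(tf_regs), replace = TRUE, prob = c(.3, .7)))
      }
      lnc_regs <- pick(intersect(lncmir_seen, ids_lnc), scenario$density, cap)
      if (length(lnc_regs)) {
        add(lnc_regs, node, "lnc_gene",
            stats::runif(length(lnc_regs), 0.4, 1.0) *
              sample(c(-1, 1), length(lnc_regs), replace = TRUE))
      }
      mir_regs <- pick(intersect(lncmir_seen, ids_mir), scenario$density, cap)
      if (length(mir_regs)) {
        # ability column carries the signed model coefficient -C_qh <= 0;
        # the repression ability C_qh is its negation
        add(mir_regs, node, "mir_gene",
            -stats::runif(length(mir_regs), 0.2, 0.6))
      }
      if (node %in% c(ids_lnc, ids_mir)) lncmir_seen <- c(lncmir_seen, node)
    }
    planted_edges <- data.frame(source = src, target = tgt, edge_kind = knd,
                                ability = abl, stringsAsFactors = FALSE)

    planted <- structure(list(
      nodes = nodes,
      edges = planted_edges,
      basal = stats::setNames(stats::runif(nrow(nodes), 0.5, 1.5), nodes$id),
      noise_sd = stats::setNames(rep(scenario$noise_sd, nrow(nodes)),
                                 nodes$id),
      root_sd = scenario$root_sd,
      regressor_form = scenario$regressor_form %||% "product",
      order = c(prot_order, rna_order)), class = "planted_model")

    candidate_edges <- planted_edges[, c("source", "target", "edge_kind")]
    # false positives per edge type over the non-planted valid slots
    fp <- scenario$fp_rate
    if (fp > 0) {
      prot_ids <- c(ids_pro, ids_tf)
      rna_ids <- c(ids_gen, ids_lnc, ids_mir)
      key <- function(s, t) paste(s, t, sep = "\r")
      can_key <- function(s, t, kind) {
        sw <- kind == "ppi" & s > t
        tmp <- s[sw]; s[sw] <- t[sw]; t[sw] <- tmp
        key(s, t)
      }
      pk <- can_key(planted_edges$source, planted_edges$target,
                    planted_edges$edge_kind)
      np <- length(prot_ids)
      fp_for <- function(n_slots, kind, draw) {
        slots <- sample_fp_slots(n_slots, fp, draw, pk)
        if (is.null(slots) || !nrow(slots)) return(NULL)
        data.frame(source = slots$source, target = slots$target,
                   edge_kind = kind, stringsAsFactors = FALSE)
      }
      n_ppi_slots <- np * (np - 1L) / 2L -
        sum(planted_edges$edge_kind == "ppi")
      fp_ppi <- fp_for(n_ppi_slots, "ppi", function(m) {
        i <- sample.int(np, m, replace = TRUE)
        j <- sample.int(np, m, replace = TRUE)
        keep <- i != j
        i <- i[keep]; j <- j[keep]
        s <- pmin(prot_ids[i], prot_ids[j])
        t <- pmax(prot_ids[i], prot_ids[j])
        data.frame(source = s, target = t, stringsAsFactors = FALSE)
      })
      pair_draw <- function(srcs, tgts) function(m) {
        s <- srcs[sample.int(length(srcs), m, replace = TRUE)]
        t <- tgts[sample.int(length(tgts), m, replace = TRUE)]
        keep <- s != t
        data.frame(source = s[keep], target = t[keep],
                   stringsAsFactors = FALSE)
      }
      n_tf_slots <- length(ids_tf) * length(rna_ids) -
        sum(planted_edges$edge_kind == "tf_gene")
      fp_tf <- if (length(ids_tf)) {
        fp_for(n_tf_slots, "tf_gene", pair_draw(ids_tf, rna_ids))
      }
      n_lnc_slots <- length(ids_lnc) * (length(rna_ids) - 1L) -
        sum(planted_edges$edge_kind == "lnc_gene")
      fp_lnc <- if (length(ids_lnc)) {
        fp_for(max(n_lnc_slots, 0L), "lnc_gene", pair_draw(ids_lnc, rna_ids))
      }
      n_mir_slots <- length(ids_mir) * (length(rna_ids) - 1L) -
        sum(planted_edges$edge_kind == "mir_gene")
      fp_mir <- if (length(ids_mir)) {
        fp_for(max(n_mir_slots, 0L), "mir_gene", pair_draw(ids_mir, rna_ids))
      }
      candidate_edges <- rbind(candidate_edges, fp_ppi, fp_tf, fp_lnc, fp_mir)
    }
    list(candidate = candidate_gwgen(nodes, candidate_edges),
         planted = planted)
  })
}

# planted model edges targeting `node`, split by kind
planted_regulators <- function(planted, node) {
  e <- planted$edges
  mine <- e[e$target == node, , drop = FALSE]
  split(mine, factor(mine$edge_kind, levels = EDGE_KINDS))
}

#' Simulate expression data from a planted model
#'
#' Evaluates nodes in the planted topological order, per sample. Under the
#' default `"product"` form each node's rearranged model equation is solved
#' in closed form: for a protein-layer node
#' `p = (phi + eta) / (1 - sum(alpha * p_k))`, for an RNA-layer node
#' `g = (sum(A z) + sum(B x) + phi + eta) / (1 + sum(C d))` with the same
#' structure for lncRNA and miRNA responses. Under the `"partner"` form the
#' equations are explicit (`p = sum(alpha * p_k) + phi + eta`,
#' `g = sum(A z) + sum(B x) - sum(C d) + phi + eta`) and no denominators
#' arise. Noise `eta` is drawn i.i.d.
#' Normal(0, noise_sd^2) per node and sample. Root nodes (no planted
#' regulators) are the network's exogenous inputs: they additionally vary by
#' Normal(0, root_sd^2) per sample, which propagates downstream; at
#' `noise_sd = 0` every regulated node then satisfies its model equation
#' exactly while the data still carry sample-to-sample variation. Samples
#' whose denominator falls within `denom_floor` of zero are redrawn (up to
#' `max_resample` times).
#'
#' @param planted a `planted_model` from [generate_candidate_gwgen()].
#' @param n_samples number of samples N.
#' @param seed integer seed.
#' @param denom_floor minimum tolerated `|denominator|` (default 0.1).
#' @param max_resample redraw budget per sample.
#' @return numeric matrix, samples x nodes (colnames = node ids).
#' @export
simulate_expression <- function(planted, n_samples, seed,
                                denom_floor = 0.1, max_resample = 100L) {
  stopifnot(inherits(planted, "planted_model"), n_samples >= 1)
  ids <- planted$nodes$id
  kind <- stats::setNames(planted$nodes$kind, ids)
  regs <- lapply(stats::setNames(planted$order, planted$order),
                 function(nd) planted_regulators(planted, nd))
  n_regs <- vapply(regs, function(r) sum(vapply(r, nrow, 0L)), 0L)
  root_sd <- planted$root_sd %||% 0
  bilinear <- (planted$regressor_form %||% "product") == "product"
  with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_samples, ncol = length(ids),
                  dimnames = list(sprintf("s%04d", seq_len(n_samples)), ids))
    for (n in seq_len(n_samples)) {
      ok <- FALSE
      for (try in seq_len(max_resample)) {
        eta <- stats::rnorm(length(ids), 0, planted$noise_sd[ids])
        names(eta) <- ids
        root <- stats::rnorm(length(ids), 0, root_sd)
        names(root) <- ids
        val <- stats::setNames(rep(NA_real_, length(ids)), ids)
        good <- TRUE
        for (nd in planted$order) {
          r <- regs[[nd]]
          if (n_regs[[nd]] == 0L) {
            val[nd] <- planted$basal[[nd]] + root[[nd]] + eta[[nd]]
            next
          }
          if (protein_layer(kind[[nd]])) {
            s <- if (nrow(r$ppi)) sum(r$ppi$ability * val[r$ppi$source]) else 0
            if (bilinear) {
              den <- 1 - s
              if (abs(den) < denom_floor) { good <- FALSE; break }
              val[nd] <- (planted$basal[[nd]] + eta[[nd]]) / den
            } else {
              val[nd] <- planted$basal[[nd]] + eta[[nd]] + s
            }
          } else {
            num <- planted$basal[[nd]] + eta[[nd]]
            if (nrow(r$tf_gene)) {
              num <- num + sum(r$tf_gene$ability * val[r$tf_gene$source])
            }
            if (nrow(r$lnc_gene)) {
              num <- num + sum(r$lnc_gene$ability * val[r$lnc_gene$source])
            }
            mir <- if (nrow(r$mir_gene)) {
              sum(r$mir_gene$ability * val[r$mir_gene$source])
            } else 0
            if (bilinear) {
              den <- 1 - mir
              if (abs(den) < denom_floor) { good <- FALSE; break }
              val[nd] <- num / den
            } else {
              val[nd] <- num + mir
            }
          }
        }
        if (good) { out[n, ] <- val[ids]; ok <- TRUE; break }
      }
      if (!ok) {
        stop_input("sample %d: model denominator below %g after %d redraws",
                   n, denom_floor, max_resample)
      }
    }
    out
  })
}

#' Generate a labeled drug-target pair dataset
#'
#' Emits `n_pos` interacting (label 1) and `n_pos` non-interacting (label 0)
#' drug-target pairs. Each drug carries a 363-long descriptor block and each
#' target a 996-long block (standard-normal base vectors); the pair feature
#' vector is their concatenation (length 1359) shifted by +/- separation/2
#' along one random unit direction according to the label, so the
#' class-conditional distributions are Normal with means `class_separation`
#' apart and identity covariance (Bayes error `pnorm(-class_separation/2)`).
#'
#' @param n_pos number of positive pairs (same number of negatives drawn).
#' @param class_separation nonnegative distance between class means.
#' @param seed integer seed.
#' @param n_drugs,n_targets sizes of the drug/target universes.
#' @return an object of class `dti_pairs`: list with `pairs`
#'   (data.frame drug_id, target_id, label) and `features`
#'   (numeric matrix, rows aligned with `pairs`).
#' @export
generate_dti_dataset <- function(n_pos, class_separation, seed,
                                 n_drugs = max(20L, ceiling(n_pos / 4)),
                                 n_targets = max(20L, ceiling(n_pos / 4))) {
  if (n_pos < 1) stop_input("n_pos must be >= 1")
  if (class_separation < 0) stop_input("class_separation must be nonnegative")
  if (as.double(n_drugs) * n_targets < 2 * n_pos) {
    stop_input("pair universe too small for %d positives + negatives", n_pos)
  }
  with_seed(seed, {
    drug_ids <- sprintf("D%04d", seq_len(n_drugs))
    target_ids <- sprintf("T%04d", seq_len(n_targets))
    drug_feat <- matrix(stats::rnorm(n_drugs * DRUG_BLOCK), nrow = n_drugs,
                        dimnames = list(drug_ids, NULL))
    target_feat <- matrix(stats::rnorm(n_targets * TARGET_BLOCK),
                          nrow = n_targets, dimnames = list(target_ids, NULL))
    u <- stats::rnorm(DRUG_BLOCK + TARGET_BLOCK)
    u <- u / sqrt(sum(u^2))

    draw_pairs <- function(m, exclude) {
      got <- character(0); di <- integer(0); ti <- integer(0)
      while (length(got) < m) {
        need <- m - length(got)
        i <- sample.int(n_drugs, need * 2L, replace = TRUE)
        j <- sample.int(n_targets, need * 2L, replace = TRUE)
        k <- paste(i, j)
        keep <- !(k %in% exclude) & !(k %in% got) & !duplicated(k)
        i <- i[keep]; j <- j[keep]; k <- k[keep]
        if (length(k) > need) { i <- i[seq_len(need)]; j <- j[seq_len(need)]
                                k <- k[seq_len(need)] }
        di <- c(di, i); ti <- c(ti, j); got <- c(got, k)
      }
      list(drug = di, target = ti, key = got)
    }
    pos <- draw_pairs(n_pos, character(0))
    neg <- draw_pairs(n_pos, pos$key)
    di <- c(pos$drug, neg$drug); ti <- c(pos$target, neg$target)
    label <- rep(c(1L, 0L), each = n_pos)
    feat <- cbind(drug_feat[di, , drop = FALSE],
                  target_feat[ti, , drop = FALSE])
    shift <- ifelse(label == 1L, class_separation / 2, -class_separation / 2)
    feat <- feat + outer(shift, u)
    dimnames(feat) <- list(NULL, NULL)
    structure(list(
      pairs = data.frame(drug_id = drug_ids[di], target_id = target_ids[ti],
                         label = label, stringsAsFactors = FALSE),
      features = feat), class = "dti_pairs")
  })
}

#' Specify the biomarker panel a drug combination must cover
#'
#' @param id biomarker (drug target) identifiers.
#' @param action desired therapeutic action per biomarker: `"inhibit"`
#'   (abnormally up-regulated in disease, to be pushed down) or `"activate"`.
#' @return data.frame of class `biomarker_spec`.
#' @export
biomarker_spec <- function(id, action) {
  id <- as.character(id); action <- as.character(action)
  if (anyDuplicated(id)) stop_input("biomarker ids must be unique")
  if (!all(action %in% c("inhibit", "activate"))) {
    stop_input("action must be 'inhibit' or 'activate'")
  }
  structure(data.frame(id = id, action = action, stringsAsFactors = FALSE),
            class = c("biomarker_spec", "data.frame"))
}

#' Generate synthetic drug annotation tables
#'
#' For each drug: a ground-truth target subset of the biomarker panel, a
#' predicted interaction probability per biomarker (high on true targets, low
#' elsewhere), a signed regulation signature per biomarker (+1 up-regulates,
#' -1 down-regulates, 0 no effect), and an LD50 (mg/kg). A fraction
#' `reversal_fraction` of drugs reverse the abnormal direction of every one
#' of their targets (signature -1 on inhibit targets, +1 on activate
#' targets); the rest get at least one non-reversing target signature.
#'
#' @param n_drugs number of drugs.
#' @param biomarkers a [biomarker_spec()].
#' @param seed integer seed.
#' @param reversal_fraction probability a drug is a full reverser.
#' @return list with `drugs` (a `drug_records` data-bundle: `prob` and
#'   `signature` matrices drugs x biomarkers, `ld50` vector), `targets`
#'   (ground-truth target list per drug) and `reverses` (logical truth).
#' @export
generate_drug_annotations <- function(n_drugs, biomarkers, seed,
                                      reversal_fraction = 0.5) {
  stopifnot(inherits(biomarkers, "biomarker_spec"), nrow(biomarkers) >= 1)
  with_seed(seed, {
    ids <- sprintf("drug%03d", seq_len(n_drugs))
    nb <- nrow(biomarkers)
    desired <- ifelse(biomarkers$action == "inhibit", -1L, 1L)
    prob <- matrix(stats::runif(n_drugs * nb, 0.0, 0.4), nrow = n_drugs,
                   dimnames = list(ids, biomarkers$id))
    sig <- matrix(0L, nrow = n_drugs, ncol = nb,
                  dimnames = list(ids, biomarkers$id))
    targets <- vector("list", n_drugs); names(targets) <- ids
    reverses <- stats::runif(n_drugs) < reversal_fraction
    for (d in seq_len(n_drugs)) {
      k <- sample.int(min(3L, nb), 1L)
      tg <- sort(sample.int(nb, k))
      targets[[d]] <- biomarkers$id[tg]
      prob[d, tg] <- stats::runif(k, 0.6, 0.99)
      sig[d, tg] <- desired[tg]
      if (!reverses[d]) {
        # sample.int on the index set: sample(tg, 1) would draw from
        # 1:tg when the drug has a single target
        flip <- tg[sample.int(length(tg), 1L)]
        sig[d, flip] <- -desired[flip]
      }
    }
    ld50 <- stats::setNames(stats::rlnorm(n_drugs, log(500), 1), ids)
    drugs <- structure(list(id = ids, prob = prob, signature = sig,
                            ld50 = ld50), class = "drug_records")
    list(drugs = drugs, targets = targets, reverses = reverses)
  })
}

#' Write the synthetic bundle to disk
#'
#' Writes the node table and edge table (TSV), the expression matrix (CSV)
#' and the planted model (JSON) for a scenario, mirroring the file formats
#' the identification stage reads.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of file paths written.
#' @export
write_synthetic_bundle <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_candidate_gwgen(scenario)
  expr <- simulate_expression(gen$planted, scenario$n_samples,
                              seed = child_seed(scenario$seed, 1L))
  paths <- list(
    nodes = file.path(dir, "nodes.tsv"),
    edges = file.path(dir, "candidate_edges.tsv"),
    expression = file.path(dir, "expression.csv"),
    planted = file.path(dir, "planted_model.json"))
  utils::write.table(gen$candidate$nodes[, c("id", "kind")], paths$nodes,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_table(gen$candidate$edges, paths$edges)
  write_expression(expr, paths$expression)
  jsonlite::write_json(
    list(edges = gen$planted$edges,
         basal = as.list(gen$planted$basal),
         noise_sd = as.list(gen$planted$noise_sd),
         order = gen$planted$order,
         regressor_form = gen$planted$regressor_form,
         seed = scenario$seed),
    paths$planted, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
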