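# End-to-end orchestration: one subtype run (candidate network -> system
# identification -> principal network projection -> DTI -> drug design) and
# the two-subtype comparison. Every artifact is written once, in plain-text
# formats, and (config, seed) fully determines every byte.

#' Assemble a run configuration
#'
#' @param scenario a [synthetic_scenario()] describing the inputs, or `NULL`
#'   when reading from files.
#' @param out_dir directory for artifacts (created if needed).
#' @param edges_path,nodes_path,expression_path input files used when
#'   `scenario` is `NULL`: candidate edge TSV, node TSV, expression CSV.
#' @param threshold energy fraction for rank selection.
#' @param top_k core size.
#' @param seed run seed (defaults to the scenario seed).
#' @param drug_stage,dti_stage enable the drug-design / DTI stages.
#' @param n_drugs,reversal_fraction,ld50_min drug-annotation generation and
#'   toxicity filter settings.
#' @param dti_n_pos,dti_separation synthetic DTI dataset size / class
#'   separation.
#' @param dti_config a [dti_config()] for the DTI stage.
#' @param n_biomarkers size of the biomarker panel picked from the core.
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, out_dir,
                       edges_path = NULL, nodes_path = NULL,
                       expression_path = NULL,
                       threshold = 0.85, top_k = 3000,
                       seed = if (!is.null(scenario)) scenario$seed else 1L,
                       drug_stage = TRUE, dti_stage = TRUE,
                       n_drugs = 40L, reversal_fraction = 0.6,
                       ld50_min = 500,
                       dti_n_pos = 60L, dti_separation = 6,
                       dti_config = NULL, n_biomarkers = 5L) {
  if (is.null(scenario) &&
      (is.null(edges_path) || is.null(nodes_path) ||
       is.null(expression_path))) {
    stop_input("either a scenario or all three input paths are required")
  }
  structure(list(scenario = scenario, out_dir = out_dir,
                 edges_path = edges_path, nodes_path = nodes_path,
                 expression_path = expression_path,
                 threshold = threshold, top_k = top_k,
                 seed = as.integer(seed),
                 drug_stage = drug_stage, dti_stage = dti_stage,
                 n_drugs = as.integer(n_drugs),
                 reversal_fraction = reversal_fraction,
                 ld50_min = ld50_min,
                 dti_n_pos = as.integer(dti_n_pos),
                 dti_separation = dti_separation,
                 dti_config = dti_config, n_biomarkers = as.integer(n_biomarkers)),
            class = "run_config")
}

config_snapshot <- function(config) {
  snap <- config
  snap$scenario <- if (!is.null(config$scenario)) {
    unclass(config$scenario)
  }
  snap$dti_config <- if (!is.null(config$dti_config)) {
    unclass(config$dti_config)
  }
  c(unclass(snap),
    list(package_version = as.character(utils::packageVersion("gwgendrug"))))
}

#' Run the pipeline for one subtype / condition
#'
#' Executes the stages in order: input loading or synthesis, per-node system
#' identification, principal network projection and core extraction, DTI
#' model training (when enabled), drug filtering and combination assembly.
#' All artifacts are written under `config$out_dir` together with a resolved
#' configuration snapshot; a stage failure aborts with the stage name while
#' earlier artifacts remain on disk.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `real`, `pnp`, `core`, `dti`, `drugs`,
#'   `combination`, `biomarkers`, `paths`.
#' @export
run_subtype <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(config$out_dir, "config.json"))
  jsonlite::write_json(config_snapshot(config), paths$config,
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$scenario)) {
      gen <- generate_candidate_gwgen(config$scenario)
      expr <- simulate_expression(gen$planted, config$scenario$n_samples,
                                  seed = child_seed(config$seed, 1L))
      paths$nodes <- file.path(config$out_dir, "nodes.tsv")
      paths$edges <- file.path(config$out_dir, "candidate_edges.tsv")
      paths$expression <- file.path(config$out_dir, "expression.csv")
      utils::write.table(gen$candidate$nodes[, c("id", "kind")],
                         paths$nodes, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      write_edge_table(gen$candidate$edges, paths$edges)
      write_expression(expr, paths$expression)
      list(candidate = gen$candidate, expr = expr, planted = gen$planted)
    } else {
      nodes_df <- utils::read.table(config$nodes_path, header = TRUE,
                                    sep = "\t", colClasses = "character")
      list(candidate = candidate_gwgen(
             node_table(nodes_df$id, nodes_df$kind),
             read_edge_table(config$edges_path)),
           expr = read_expression(config$expression_path),
           planted = NULL)
    }
  })

  form <- if (!is.null(config$scenario)) {
    config$scenario$regressor_form %||% "product"
  } else "product"
  real <- stage("sysid", gwgen_fit(inputs$candidate, inputs$expr,
                                   ppi_regressor = form))
  paths$real_edges <- file.path(config$out_dir, "real_edges.tsv")
  re <- real$edges
  re$ability <- format(re$ability, digits = 17, trim = TRUE)
  utils::write.table(re, paths$real_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$fit_report <- file.path(config$out_dir, "fit_report.json")
  jsonlite::write_json(
    list(counts = as.list(real$counts),
         failed = real$failed,
         orders = lapply(real$fits, function(f) f$order),
         aic = lapply(real$fits, function(f) f$aic)),
    paths$fit_report, auto_unbox = TRUE, digits = NA)

  proj <- stage("pnp", pnp(real, config$threshold, config$top_k))
  paths$ranking <- file.path(config$out_dir, "ranking.json")
  jsonlite::write_json(
    list(rank = proj$rank,
         energy = sum(proj$svd$energies[seq_len(proj$rank)]),
         projection = as.list(proj$projection$value[proj$projection$ranking])),
    paths$ranking, auto_unbox = TRUE, digits = NA)
  paths$core_nodes <- file.path(config$out_dir, "core_nodes.tsv")
  paths$core_edges <- file.path(config$out_dir, "core_edges.tsv")
  utils::write.table(proj$core$nodes[, c("id", "kind")], paths$core_nodes,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ce <- proj$core$edges
  ce$ability <- format(ce$ability, digits = 17, trim = TRUE)
  utils::write.table(ce, paths$core_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  dti <- NULL
  if (config$dti_stage) {
    dti <- stage("dti", {
      ds <- generate_dti_dataset(config$dti_n_pos, config$dti_separation,
                                 seed = child_seed(config$seed, 2L))
      cfg <- config$dti_config %||%
        dti_config(max_epochs = 30L, seed = child_seed(config$seed, 3L))
      dti_train(ds, cfg)
    })
    paths$dti_metrics <- file.path(config$out_dir, "dti_metrics.json")
    jsonlite::write_json(as.list(dti$metrics), paths$dti_metrics,
                         auto_unbox = TRUE, digits = NA)
  }

  drugs <- combination <- biomarkers <- NULL
  if (config$drug_stage) {
    res <- stage("drug_design", {
      # biomarker panel: top-ranked protein-layer core nodes; the first is
      # designated for activation, the rest for inhibition
      kind <- stats::setNames(real$nodes$kind, real$nodes$id)
      prot <- proj$projection$ranking[
        protein_layer(kind[proj$projection$ranking])]
      ids <- utils::head(prot, config$n_biomarkers)
      if (!length(ids)) stop_input("no protein-layer nodes in the core")
      biomarkers <- biomarker_spec(
        ids, c("activate", rep("inhibit", length(ids) - 1L)))
      ann <- generate_drug_annotations(config$n_drugs, biomarkers,
                                       seed = child_seed(config$seed, 4L),
                                       reversal_fraction =
                                         config$reversal_fraction)
      passing <- toxicity_filter(
        regulation_filter(ann$drugs, biomarkers), config$ld50_min)
      list(biomarkers = biomarkers, annotations = ann, passing = passing,
           combination = assemble_combination(passing, biomarkers))
    })
    drugs <- res$passing
    combination <- res$combination
    biomarkers <- res$biomarkers
    paths$combination <- file.path(config$out_dir, "combination.json")
    jsonlite::write_json(
      list(biomarkers = res$biomarkers,
           selected = combination$selected,
           covering = combination$covering,
           uncovered = combination$uncovered,
           complete = combination$complete),
      paths$combination, auto_unbox = TRUE, digits = NA)
  }

  invisible(list(real = real, pnp = proj, core = proj$core, dti = dti,
                 drugs = drugs, combination = combination,
                 biomarkers = biomarkers, planted = inputs$planted,
                 paths = paths))
}

#' Run and compare two conditions
#'
#' Runs [run_subtype()] for both configurations and reports the common and
#' specific parts of the two core networks plus both drug proposals.
#'
#' @param config_a,config_b [run_config()] objects (distinct `out_dir`s).
#' @return list with `run_a`, `run_b`, `comparison`.
#' @export
run_comparison <- function(config_a, config_b) {
  a <- run_subtype(config_a)
  b <- run_subtype(config_b)
  cmp <- compare_cores(a$core, b$core)
  path <- file.path(config_a$out_dir, "core_comparison.json")
  jsonlite::write_json(
    list(counts = as.list(cmp$counts),
         common_nodes = cmp$common$nodes,
         specific_a = cmp$specific_a$nodes,
         specific_b = cmp$specific_b$nodes),
    path, auto_unbox = TRUE, digits = NA)
  list(run_a = a, run_b = b, comparison = cmp, comparison_path = path)
}
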