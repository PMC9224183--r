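# Multi-molecule drug design: filter DTI candidates by expression-reversal
# ability (connectivity-map-style signed signatures) and by acute toxicity
# (LD50), then assemble a drug combination covering the biomarker panel by
# greedy set cover.

#' Drug records
#'
#' Bundles, for a cohort of drugs over a biomarker panel: predicted
#' interaction probabilities, signed regulation signatures (+1 the drug
#' up-regulates the biomarker, -1 down-regulates, 0 no recorded effect) and
#' LD50 values (mg/kg; higher = less acutely toxic).
#'
#' @param id drug identifiers.
#' @param prob drugs x biomarkers probability matrix.
#' @param signature drugs x biomarkers matrix over \{-1, 0, 1\}.
#' @param ld50 positive numeric vector.
#' @return object of class `drug_records`.
#' @export
drug_records <- function(id, prob, signature, ld50) {
  id <- as.character(id)
  stopifnot(nrow(prob) == length(id), nrow(signature) == length(id),
            length(ld50) == length(id))
  if (any(prob < 0 | prob > 1)) stop_input("probabilities must be in [0, 1]")
  if (!all(signature %in% c(-1, 0, 1))) {
    stop_input("signatures must be -1, 0 or +1")
  }
  if (any(ld50 <= 0)) stop_input("LD50 values must be positive")
  rownames(prob) <- id; rownames(signature) <- id; names(ld50) <- id
  structure(list(id = id, prob = prob, signature = signature, ld50 = ld50),
            class = "drug_records")
}

subset_drugs <- function(drugs, keep) {
  structure(list(id = drugs$id[keep],
                 prob = drugs$prob[keep, , drop = FALSE],
                 signature = drugs$signature[keep, , drop = FALSE],
                 ld50 = drugs$ld50[keep]),
            class = "drug_records")
}

# biomarkers a drug is predicted to target (probability strictly above the
# threshold)
drug_targets <- function(drugs, threshold = 0.5) {
  lapply(stats::setNames(seq_along(drugs$id), drugs$id), function(d) {
    colnames(drugs$prob)[drugs$prob[d, ] > threshold]
  })
}

#' Filter drugs by regulation-reversal ability
#'
#' A drug passes if, for every biomarker it is predicted to target
#' (probability above `threshold`), its signature opposes the biomarker's
#' abnormal direction: signature -1 on biomarkers to be inhibited, +1 on
#' biomarkers to be activated. Biomarkers the drug does not target are
#' ignored. A targeted biomarker with no recorded signature (0) excludes the
#' drug with a warning.
#'
#' @param drugs a [drug_records()].
#' @param biomarkers a [biomarker_spec()].
#' @param threshold target-call probability cutoff.
#' @return the passing subset, a `drug_records`.
#' @export
regulation_filter <- function(drugs, biomarkers, threshold = 0.5) {
  desired <- stats::setNames(ifelse(biomarkers$action == "inhibit", -1, 1),
                             biomarkers$id)
  missing <- setdiff(biomarkers$id, colnames(drugs$signature))
  if (length(missing)) {
    stop_input("signature columns missing for biomarker(s): %s",
               toString(missing))
  }
  targets <- drug_targets(drugs, threshold)
  keep <- vapply(seq_along(drugs$id), function(d) {
    tg <- intersect(targets[[d]], biomarkers$id)
    if (!length(tg)) return(TRUE)
    sig <- drugs$signature[d, tg]
    if (any(sig == 0)) {
      warning(sprintf("drug %s: no signature for targeted biomarker(s) %s",
                      drugs$id[d], toString(tg[sig == 0])), call. = FALSE)
      return(FALSE)
    }
    all(sig == desired[tg])
  }, logical(1))
  subset_drugs(drugs, keep)
}

#' Filter drugs by acute toxicity
#'
#' Keeps drugs with LD50 at or above `ld50_min` (mg/kg); a higher median
#' lethal dose means lower acute toxicity. The default cutoff of 500 mg/kg
#' is a configuration choice, not a pharmacological constant.
#'
#' @param drugs a [drug_records()].
#' @param ld50_min positive cutoff.
#' @return the passing subset, a `drug_records`.
#' @export
toxicity_filter <- function(drugs, ld50_min = 500) {
  if (ld50_min <= 0) stop_input("ld50_min must be positive")
  subset_drugs(drugs, drugs$ld50 >= ld50_min)
}

#' Assemble a multi-molecule drug by greedy set cover
#'
#' Repeatedly selects the drug covering the most still-uncovered biomarkers
#' (ties: higher mean probability over its targets, then lexicographic drug
#' id), until the panel is covered or no drug adds coverage. Incomplete
#' coverage is reported, not an error. A drug covering zero uncovered
#' biomarkers is never selected.
#'
#' @param drugs a [drug_records()] (normally already passed both filters).
#' @param biomarkers a [biomarker_spec()].
#' @param threshold target-call probability cutoff.
#' @return object of class `drug_combination`: `selected` (drug ids, in
#'   selection order), `covering` (biomarker -> covering drugs), `uncovered`,
#'   `complete` flag, and the target matrix of the selected drugs.
#' @export
assemble_combination <- function(drugs, biomarkers, threshold = 0.5) {
  targets <- drug_targets(drugs, threshold)
  targets <- lapply(targets, intersect, biomarkers$id)
  uncovered <- biomarkers$id
  selected <- character(0)
  avail <- drugs$id
  while (length(uncovered) && length(avail)) {
    gain <- vapply(avail, function(d) length(intersect(targets[[d]],
                                                       uncovered)), 0L)
    if (max(gain) == 0L) break
    cand <- avail[gain == max(gain)]
    if (length(cand) > 1L) {
      mp <- vapply(cand, function(d) {
        tg <- targets[[d]]
        if (length(tg)) mean(drugs$prob[d, tg]) else 0
      }, 0)
      cand <- cand[mp == max(mp)]
      cand <- sort(cand)
    }
    pick <- cand[1L]
    selected <- c(selected, pick)
    uncovered <- setdiff(uncovered, targets[[pick]])
    avail <- setdiff(avail, pick)
  }
  covering <- lapply(stats::setNames(biomarkers$id, biomarkers$id),
                     function(b) {
                       selected[vapply(selected,
                                       function(d) b %in% targets[[d]],
                                       logical(1))]
                     })
  structure(list(selected = selected, covering = covering,
                 uncovered = uncovered,
                 complete = length(uncovered) == 0L,
                 targets = targets[selected]),
            class = "drug_combination")
}

#' @export
print.drug_combination <- function(x, ...) {
  cat("Multi-molecule drug:", if (length(x$selected)) {
    paste(x$selected, collapse = " + ")
  } else "(none)", "\n")
  for (b in names(x$covering)) {
    cat(sprintf("  %-10s %s\n", b, if (length(x$covering[[b]])) {
      paste(x$covering[[b]], collapse = ", ")
    } else "UNCOVERED"))
  }
  cat(if (x$complete) "  coverage complete\n" else "  coverage incomplete\n")
  invisible(x)
}

#' Published biomarker panels and drug-target matrices for the two DLBCL
#' subtypes
#'
#' Curated fixtures: the five-biomarker panels identified for the activated
#' B-cell (ABC) and germinal-center B-cell (GCB) subtypes of diffuse large
#' B-cell lymphoma, with the therapeutic direction each biomarker calls for,
#' and the reported drug-target matrices of the proposed three-drug
#' combinations.
#'
#' @param subtype `"ABC"` or `"GCB"`.
#' @return `dlbcl_biomarkers`: a [biomarker_spec()].
#' @export
dlbcl_biomarkers <- function(subtype = c("ABC", "GCB")) {
  subtype <- match.arg(subtype)
  if (subtype == "ABC") {
    biomarker_spec(
      id = c("FOXL1", "NFKB1", "AKT1", "MYC", "STAT3"),
      action = c("activate", "inhibit", "inhibit", "inhibit", "inhibit"))
  } else {
    biomarker_spec(
      id = c("FOXL1", "NFKB1", "AKT1", "MYC", "EZH2"),
      action = c("activate", "inhibit", "inhibit", "inhibit", "inhibit"))
  }
}

#' @rdname dlbcl_biomarkers
#' @return `dlbcl_drug_target_matrix`: a logical drugs x biomarkers matrix
#'   (`TRUE` where the drug targets the biomarker).
#' @export
dlbcl_drug_target_matrix <- function(subtype = c("ABC", "GCB")) {
  subtype <- match.arg(subtype)
  if (subtype == "ABC") {
    m <- rbind(
      famotidine    = c(FOXL1 = FALSE, NFKB1 = TRUE,  AKT1 = TRUE,
                        MYC = FALSE, STAT3 = TRUE),
      chlorzoxazone = c(FOXL1 = TRUE,  NFKB1 = TRUE,  AKT1 = FALSE,
                        MYC = FALSE, STAT3 = TRUE),
      etoposide     = c(FOXL1 = FALSE, NFKB1 = TRUE,  AKT1 = FALSE,
                        MYC = TRUE,  STAT3 = TRUE))
  } else {
    m <- rbind(
      famotidine    = c(FOXL1 = FALSE, NFKB1 = TRUE,  AKT1 = TRUE,
                        MYC = FALSE, EZH2 = TRUE),
      chlorzoxazone = c(FOXL1 = TRUE,  NFKB1 = TRUE,  AKT1 = FALSE,
                        MYC = FALSE, EZH2 = TRUE),
      methotrexate  = c(FOXL1 = FALSE, NFKB1 = FALSE, AKT1 = TRUE,
                        MYC = TRUE,  EZH2 = TRUE))
  }
  m
}

#' Drug records for a published drug-target matrix
#'
#' Wraps a logical drug-target matrix as [drug_records()] with probability
#' 0.9 on targets / 0.1 elsewhere, fully reversing signatures, and a common
#' LD50, so the published combinations flow through the same filter and
#' cover machinery as synthetic cohorts.
#'
#' @param subtype `"ABC"` or `"GCB"`.
#' @return a `drug_records`.
#' @export
dlbcl_drug_records <- function(subtype = c("ABC", "GCB")) {
  subtype <- match.arg(subtype)
  m <- dlbcl_drug_target_matrix(subtype)
  bm <- dlbcl_biomarkers(subtype)
  desired <- ifelse(bm$action == "inhibit", -1, 1)
  sig <- t(apply(m, 1, function(row) ifelse(row, desired, 0)))
  colnames(sig) <- bm$id
  prob <- ifelse(m, 0.9, 0.1)
  drug_records(rownames(m), prob, sig,
               ld50 = stats::setNames(rep(1000, nrow(m)), rownames(m)))
}
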