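# gwgendrug

Systems drug discovery for diffuse large B-cell lymphoma (DLBCL) subtypes:
identification of genome-wide genetic and epigenetic networks (GWGENs)
from expression data, core-network extraction by principal network
projection, drug–target interaction (DTI) prediction with a feed-forward
neural network, and multi-molecule drug-combination design — all in base
R, with a synthetic-data module that makes the whole pipeline testable at
desk scale.

## The scientific problem

DLBCL subtypes (germinal-center B-cell, GCB, vs. activated B-cell, ABC)
differ in how proteins, transcription factors, lncRNAs and miRNAs are
wired together. Starting from a *candidate* GWGEN — a typed interaction
table pooled from databases (edge kinds `ppi`, `tf_gene`, `lnc_gene`,
`mir_gene`) — the workflow decides which interactions the expression data
actually support, finds the core of the resulting network, designates
biomarkers, and assembles a drug combination that reverses their abnormal
regulation without excessive toxicity.

## Core model

Each protein node *i* follows a bilinear interaction model

> pᵢ = Σₖ αᵢₖ · pᵢ pₖ + φᵢ + ηᵢ

and each RNA node *q* (gene / lncRNA / miRNA) follows

> g_q = Σⱼ A_qⱼ zⱼ + Σᵥ B_qᵥ xᵥ − Σₕ C_qₕ · g_q dₕ + φ_q + η_q,  C_qₕ ≥ 0

with TF inputs *z*, lncRNA inputs *x*, and miRNA repression *d* entering
as a self-product under a sign constraint. Identification is per-node
constrained least squares with greedy AIC model-order detection; the
surviving edges and their estimated abilities form the *real* GWGEN. Its
combined ability matrix *Z* is decomposed by SVD, the rank *R* is chosen
so the top singular energies reach 85%, and nodes are ranked by the
projection norm ‖Z₍ₜ₎ V₁:R‖ to extract the core network. A
618-input multilayer perceptron (512/256/128/64 hidden units, dropout,
binary cross-entropy, early stopping) scores drug–target pairs, and a
greedy set cover over regulation- and toxicity-filtered drugs produces
the final combination.

Because the bilinear terms contain the response variable, the product
regressors are endogenous under noise; the package exposes
`regressor_form = c("product", "partner")` in both the generator and the
identification stage, and quantitative recovery claims are made under the
linear partner form. See the vignette
(`vignettes/systems-drug-discovery.Rmd`) for the full analysis, the AIC
selection ceiling, and other limitations.

## Worked example

```r
library(gwgendrug)

# a scenario with 50% planted false-positive candidate edges
sc   <- synthetic_scenario(fp_rate = 0.5, n_samples = 300,
                           regressor_form = "partner", seed = 1)
gen  <- generate_candidate_gwgen(sc)
expr <- simulate_expression(gen$planted, 300, seed = 2)

# system identification: which candidate edges survive the data?
fit <- gwgen_fit(gen$candidate, expr, ppi_regressor = "partner")
summary(fit)
#> Identified GWGEN
#>   nodes: 43   surviving interactions: 156 
#>   by kind: lnc_gene=30, mir_gene=25, ppi=57, tf_gene=44 
#>   mean selected order: 3.63   mean AIC: -4.121

# principal network projection and core extraction
proj <- pnp(fit, threshold = 0.85, top_k = 20)
proj$rank
#> [1] 10
head(proj$projection$ranking, 6)
#> [1] "pro004"   "pro007"   "tf001"    "tf005"    "pro002"   "gene0009"

# drug-combination design on the bundled ABC-subtype worked example
comb <- assemble_combination(dlbcl_drug_records("ABC"),
                             dlbcl_biomarkers("ABC"))
comb
#> Multi-molecule drug: chlorzoxazone + etoposide + famotidine 
#>   FOXL1      chlorzoxazone
#>   NFKB1      chlorzoxazone, etoposide, famotidine
#>   AKT1       famotidine
#>   MYC        etoposide
#>   STAT3      chlorzoxazone, etoposide, famotidine
#>   coverage complete
```

`run_subtype(run_config(...))` chains all stages (inputs →
identification → projection → DTI → drug design) and writes every
artifact — edge tables, rankings, DTI metrics, the selected
combination — as plain text under an output directory; same-seed runs are
byte-identical.

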