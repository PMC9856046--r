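# One-call synthetic end-to-end analysis: generate labelled data for every
# stage, run the full method stack, and return the collected outputs.

#' Run the full synthetic pipeline from one seed
#'
#' Generates CRP-like proteins, a codon alignment with planted positively
#' selected sites, a target/decoy PSM table, an expression matrix and an
#' annotation table from one seed, then runs classification, the
#' M0/M7/M8 fits with the M7-vs-M8 likelihood ratio test and BEB site
#' identification, PSM FDR tiers, median-of-ratios normalization with
#' specificity categorization, and Fisher enrichment with the reporting
#' filter.
#'
#' @param seed Integer seed controlling every stage.
#' @param n_taxa,n_codons Size of the simulated codon alignment.
#' @param n_per_class Positives per CRP class for the grammar stage.
#' @param site_spec Generating site-class specification (default: M8 with
#'   20% of sites at omega = 4).
#' @param config Site-model fitting configuration.
#' @return Named list with the stage outputs: `classification` (+ report),
#'   `fits`, `lrt`, `beb`, `flagged_sites`, `psm`, `expression`,
#'   `enrichment`, and the generating truths.
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_taxa = 6L, n_codons = 60L,
                                   n_per_class = 5L,
                                   site_spec = list(type = "M8", p = 0.5,
                                                    q = 1.5, p0 = 0.8,
                                                    omega_s = 4),
                                   config = site_model_config(
                                     freqs = "equal", n_starts = 1,
                                     seed = seed)) {
  defs <- crp_class_defs()
  prots <- gen_crp_proteins(defs, n_per_class = n_per_class, seed = seed)
  class_tab <- do.call(rbind, lapply(seq_len(nrow(prots)), function(i) {
    r <- classify_protein(prots$sequence[i], defs, id = prots$id[i])
    summarize_classification(list(r))
  }))
  report <- generate_report(class_tab, defs)

  set.seed(seed)
  tree <- ape::rtree(n_taxa)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.3)
  sim <- sim_codon_alignment(tree, n_codons, site_spec, kappa = 2,
                             seed = seed + 1L)
  f0 <- fit_model("M0", sim$aln, tree, config)
  f7 <- fit_model("M7", sim$aln, tree, config, m0_fit = f0)
  f8 <- fit_model("M8", sim$aln, tree, config, m0_fit = f0)
  test <- lrt(f7, f8)
  beb <- beb_posteriors(f8, sim$aln, tree)
  flagged <- flag_sites(beb, sim$aln)

  psm <- psm_fdr(gen_psm_table(seed = seed + 2L))

  expr <- gen_expression_matrix(seed = seed + 3L)
  norm <- median_of_ratios(expr$counts, pseudo_reference = TRUE)
  categories <- classify_specificity(norm$normalized, expr$roles)

  ann <- gen_annotation_table(seed = seed + 4L)
  enr <- fisher_enrich(ann$sample, ann$annotation, background = ann$items)
  enr_hits <- report_filter(enr)

  list(proteins = prots, classification = class_tab, report = report,
       sim = sim, fits = list(M0 = f0, M7 = f7, M8 = f8), lrt = test,
       beb = beb, flagged_sites = flagged,
       psm = psm,
       expression = list(truth = expr$truth, size_factors = norm$size_factors,
                         categories = categories),
       enrichment = list(planted = ann$planted_terms, results = enr,
                         hits = enr_hits))
}
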