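# Seeded synthetic-data generators: ground-truth-labelled inputs with the
# statistical structure each analysis stage assumes. Every generator calls
# set.seed(seed) on entry, so a fixed seed reproduces its output exactly.

HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W")
NONCYS_AA <- setdiff(AA_ALPHABET20, "C")

#' Generate labelled CRP-like protein sequences from class grammars
#'
#' Positives are built directly from a class's cysteine-spacing pattern:
#' spacer lengths are drawn uniformly within the pattern ranges and spacer
#' residues uniformly from the 19 non-cysteine letters, with an optional
#' hydrophobic N-terminal prefix emulating a signal peptide remnant.
#' Negatives are produced by knocking out one conserved cysteine (replaced
#' by serine) in a copy of each positive.
#'
#' @param defs Class definitions ([crp_class_defs()]).
#' @param n_per_class Positives per class.
#' @param seed Integer seed.
#' @param species Species row to draw patterns from (default: cycle through
#'   the rows of each class).
#' @param prefix_range Min/max prefix length (0 disables).
#' @param knockouts Also emit one single-cysteine knockout per positive.
#' @return data.frame with `id`, `class_id`, `species`, `type`
#'   (`"positive"`/`"knockout"`), `sequence`.
#' @export
gen_crp_proteins <- function(defs = crp_class_defs(), n_per_class = 10L,
                             seed = 1L, species = NULL,
                             prefix_range = c(5L, 15L), knockouts = TRUE) {
  set.seed(seed)
  stopifnot(n_per_class >= 0L)
  rows <- list()
  for (def in defs) {
    pats <- if (is.null(species)) def$patterns else def$patterns[species]
    if (any(vapply(pats, is.null, logical(1)))) {
      stop("species not found in class ", def$class_id, call. = FALSE)
    }
    for (i in seq_len(n_per_class)) {
      pat <- pats[[((i - 1L) %% length(pats)) + 1L]]
      sp <- pat$spacers
      gaps <- apply(sp, 1, function(r)
        if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L))
      core <- "C"
      for (g in gaps) {
        core <- paste0(core,
                       paste(sample(NONCYS_AA, g, replace = TRUE),
                             collapse = ""), "C")
      }
      prefix <- if (prefix_range[2] > 0) {
        plen <- if (prefix_range[1] == prefix_range[2]) prefix_range[1]
          else sample(prefix_range[1]:prefix_range[2], 1L)
        paste(sample(HYDROPHOBIC_AA, plen, replace = TRUE), collapse = "")
      } else ""
      seqpos <- paste0(prefix, core)
      id <- sprintf("%s_%s_%03d", gsub("[^A-Za-z0-9]", "", def$class_id),
                    gsub("[^A-Za-z0-9]", "", pat$species_tag), i)
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, class_id = def$class_id,
                   species = pat$species_tag, type = "positive",
                   sequence = seqpos, stringsAsFactors = FALSE)
      if (knockouts) {
        cpos <- which(strsplit(seqpos, "")[[1]] == "C")
        hit <- sample(cpos, 1L)
        ko <- seqpos
        substr(ko, hit, hit) <- "S"
        rows[[length(rows) + 1L]] <-
          data.frame(id = paste0(id, "_ko"), class_id = def$class_id,
                     species = pat$species_tag, type = "knockout",
                     sequence = ko, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), class_id = character(0),
                      species = character(0), type = character(0),
                      sequence = character(0)))
  }
  do.call(rbind, rows)
}

#' Simulate a codon alignment under a site-class model
#'
#' Per site, an omega value is drawn from the site-class specification; the
#' root codon is drawn from the equilibrium frequencies and evolved along
#' the tree with the transition matrices of that site's rate matrix. All
#' class matrices share the joint rate scaling implied by the
#' specification, so branch lengths are expected substitutions per codon.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_sites Number of codons.
#' @param site_spec One of `list(type = "M0", omega =)`,
#'   `list(type = "discrete", omegas =, weights =)`,
#'   `list(type = "M7", p =, q =)` (omega drawn from the continuous beta) or
#'   `list(type = "M8", p =, q =, p0 =, omega_s =)`.
#' @param kappa Transition/transversion ratio.
#' @param freqs Codon frequencies (61 values) or `"equal"`.
#' @param seed Integer seed.
#' @return List with `aln` (a [codon_alignment()]), `truth` (data.frame
#'   `site`, `omega`, `positive`), `tree`, and the generating parameters.
#' @export
sim_codon_alignment <- function(tree, n_sites, site_spec, kappa = 2,
                                freqs = "equal", seed = 1L) {
  set.seed(seed)
  stopifnot(inherits(tree, "phylo"), n_sites >= 1L)
  if (identical(freqs, "equal")) freqs <- rep(1 / 61, 61)
  stopifnot(length(freqs) == 61L, abs(sum(freqs) - 1) < 1e-8)

  draw <- switch(site_spec$type,
    M0 = list(omega = rep(site_spec$omega, n_sites),
              positive = rep(site_spec$omega > 1, n_sites),
              ref = data.frame(omega = site_spec$omega, weight = 1)),
    discrete = {
      k <- sample.int(length(site_spec$omegas), n_sites, replace = TRUE,
                      prob = site_spec$weights)
      list(omega = site_spec$omegas[k],
           positive = site_spec$omegas[k] > 1,
           ref = data.frame(omega = site_spec$omegas,
                            weight = site_spec$weights))
    },
    M7 = {
      w <- stats::rbeta(n_sites, site_spec$p, site_spec$q)
      w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
      d <- discretize_beta(site_spec$p, site_spec$q, 200L)
      list(omega = w, positive = rep(FALSE, n_sites),
           ref = data.frame(omega = d$omega, weight = d$weight))
    },
    M8 = {
      pos <- stats::runif(n_sites) > site_spec$p0
      w <- stats::rbeta(n_sites, site_spec$p, site_spec$q)
      w <- pmin(pmax(w, 1e-6), 1 - 1e-6)
      w[pos] <- site_spec$omega_s
      d <- discretize_beta(site_spec$p, site_spec$q, 200L)
      list(omega = w, positive = pos,
           ref = data.frame(omega = c(d$omega, site_spec$omega_s),
                            weight = c(site_spec$p0 * d$weight,
                                       1 - site_spec$p0)))
    },
    stop("unknown site_spec type: ", site_spec$type, call. = FALSE)
  )

  # joint rate scaling from the specification's omega distribution
  rates <- vapply(draw$ref$omega, function(w)
    mean_rate(gy94_generator(kappa, w, freqs, scale = FALSE), freqs),
    numeric(1))
  scale <- sum(draw$ref$weight * rates)

  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge
  elen <- tree_po$edge.length
  ntip <- length(tree_po$tip.label)
  nnode_tot <- ntip + tree_po$Nnode
  states <- matrix(NA_integer_, nnode_tot, n_sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L, n_sites, replace = TRUE, prob = freqs)

  sq <- sqrt(freqs)
  for (w in unique(draw$omega)) {
    sites <- which(draw$omega == w)
    Q <- gy94_generator(kappa, w, freqs, scale = FALSE) / scale
    S <- sweep(sweep(Q, 1, sq, `*`), 2, sq, `/`)
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    V <- sweep(e$vectors, 1, sq, `/`)
    W <- t(sweep(e$vectors, 1, sq, `*`))
    for (ei in rev(seq_len(nrow(edge)))) {  # preorder: root towards tips
      P <- V %*% (exp(e$values * elen[ei]) * W)
      P[P < 0] <- 0
      P <- P / rowSums(P)
      for (h in sites) {
        states[edge[ei, 2], h] <-
          sample.int(61L, 1L, prob = P[states[edge[ei, 1], h], ])
      }
    }
  }
  ct <- codon_table()
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(row)
    paste(ct$codons[row], collapse = ""))
  names(seqs) <- tree_po$tip.label
  list(aln = codon_alignment(seqs),
       truth = data.frame(site = seq_len(n_sites), omega = draw$omega,
                          positive = draw$positive),
       tree = tree, kappa = kappa, freqs = freqs, site_spec = site_spec,
       scale = scale)
}

#' Generate a target/decoy PSM score table
#'
#' Target scores are a two-component Gaussian mixture (correct matches at a
#' higher mean, incorrect matches from the null); decoy scores are drawn
#' from the null component.
#'
#' @param n_target,n_decoy Row counts.
#' @param prop_true Proportion of targets that are correct matches.
#' @param mu_true,mu_null,sd Mixture component means and common sd.
#' @param seed Integer seed.
#' @return data.frame with `spectrum_id`, `peptide`, `protein_id`, `score`,
#'   `is_decoy` and the truth column `is_true`.
#' @export
gen_psm_table <- function(n_target = 400L, n_decoy = 400L, prop_true = 0.6,
                          mu_true = 4, mu_null = 0, sd = 1, seed = 1L) {
  set.seed(seed)
  stopifnot(n_target >= 0L, n_decoy >= 0L, prop_true >= 0, prop_true <= 1)
  is_true <- stats::runif(n_target) < prop_true
  t_scores <- ifelse(is_true, stats::rnorm(n_target, mu_true, sd),
                     stats::rnorm(n_target, mu_null, sd))
  d_scores <- stats::rnorm(n_decoy, mu_null, sd)
  n <- n_target + n_decoy
  pep <- vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET20, 8L, replace = TRUE), collapse = ""),
    character(1))
  data.frame(
    spectrum_id = sprintf("spec%05d", seq_len(n)),
    peptide = pep,
    protein_id = sprintf("prot%04d", sample.int(max(1L, n %/% 4L), n,
                                                replace = TRUE)),
    score = c(t_scores, d_scores),
    is_decoy = rep(c(FALSE, TRUE), c(n_target, n_decoy)),
    is_true = c(is_true, rep(FALSE, n_decoy)),
    stringsAsFactors = FALSE)
}

#' Generate an overdispersed count matrix with planted specific genes
#'
#' Counts are negative binomial around gene- and tissue-specific means.
#' Planted mature-anther-specific genes are expressed in the target tissues
#' with a configurable leakage fraction into reference tissues; planted
#' young-anther genes peak in the auxiliary tissues; background genes are
#' broadly expressed; silent genes have mean zero everywhere.
#'
#' @param n_broad,n_specific,n_young,n_silent Gene counts per truth class.
#' @param roles Tissue-role vector from [tissue_roles()].
#' @param mu_broad,mu_specific Mean expression levels.
#' @param leakage Reference-tissue mean as a fraction of the specific mean.
#' @param dispersion Negative binomial size parameter.
#' @param depth_factors Optional per-sample relative depths (recycled);
#'   default exaggerates depth differences so normalization matters.
#' @param seed Integer seed.
#' @return List with `counts`, `roles`, `truth` (data.frame `gene`,
#'   `category`).
#' @export
gen_expression_matrix <- function(n_broad = 100L, n_specific = 20L,
                                  n_young = 10L, n_silent = 10L,
                                  roles = tissue_roles(
                                    target = c("anther_open", "anther_mature"),
                                    auxiliary = c("anther_young", "flower_young"),
                                    reference = c("leaf", "root_apex",
                                                  "stigma", "carpel")),
                                  mu_broad = 200, mu_specific = 2000,
                                  leakage = 0, dispersion = 5,
                                  depth_factors = NULL, seed = 1L) {
  set.seed(seed)
  tissues <- names(roles)
  nt <- length(tissues)
  if (is.null(depth_factors)) {
    depth_factors <- rep(c(1, 2, 0.5, 1.5), length.out = nt)
  }
  depth_factors <- rep(depth_factors, length.out = nt)
  ngene <- n_broad + n_specific + n_young + n_silent
  mu <- matrix(0, ngene, nt, dimnames = list(NULL, tissues))
  cat_truth <- character(ngene)
  g <- 0L
  for (i in seq_len(n_broad)) {
    g <- g + 1L
    mu[g, ] <- stats::rlnorm(1, log(mu_broad), 0.6)
    cat_truth[g] <- "broadly-expressed"
  }
  for (i in seq_len(n_specific)) {
    g <- g + 1L
    lev <- stats::rlnorm(1, log(mu_specific), 0.4)
    mu[g, roles == "target"] <- lev
    mu[g, roles == "auxiliary"] <- lev * 0.2
    mu[g, roles == "reference"] <- lev * leakage
    cat_truth[g] <- "mature-anther-specific"
  }
  for (i in seq_len(n_young)) {
    g <- g + 1L
    lev <- stats::rlnorm(1, log(mu_specific), 0.4)
    mu[g, roles == "auxiliary"] <- lev
    mu[g, roles == "reference"] <- lev * leakage
    cat_truth[g] <- "young-anther/bud-enriched"
  }
  for (i in seq_len(n_silent)) {
    g <- g + 1L
    cat_truth[g] <- "not-expressed"
  }
  mu <- sweep(mu, 2, depth_factors, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                   nrow = ngene, dimnames = list(
                     sprintf("gene%04d", seq_len(ngene)), tissues))
  list(counts = counts, roles = roles,
       truth = data.frame(gene = rownames(counts), category = cat_truth,
                          stringsAsFactors = FALSE))
}

#' Generate an annotation table with planted enriched terms
#'
#' Background items receive each term independently with a base
#' probability; the sample is drawn with selection weights boosted for
#' items carrying planted terms, producing genuine over-representation.
#'
#' @param n_items Background size.
#' @param n_terms Term count (terms `T001`...).
#' @param n_planted Number of planted enriched terms (the first ones).
#' @param sample_size Sample size.
#' @param base_prob Per-item membership probability of each term.
#' @param enrich_weight Additional selection weight per planted-term
#'   membership (0 = null table).
#' @param seed Integer seed.
#' @return List with `annotation` (data.frame `item`, `term`), `items` (the
#'   full background, including unannotated items), `sample` (item ids),
#'   `planted_terms`.
#' @export
gen_annotation_table <- function(n_items = 2000L, n_terms = 40L,
                                 n_planted = 4L, sample_size = 100L,
                                 base_prob = 0.05, enrich_weight = 15,
                                 seed = 1L) {
  set.seed(seed)
  stopifnot(n_planted <= n_terms, sample_size <= n_items)
  items <- sprintf("item%05d", seq_len(n_items))
  terms <- sprintf("T%03d", seq_len(n_terms))
  member <- matrix(stats::runif(n_items * n_terms) < base_prob,
                   n_items, n_terms)
  idx <- which(member, arr.ind = TRUE)
  annotation <- data.frame(item = items[idx[, 1]], term = terms[idx[, 2]],
                           stringsAsFactors = FALSE)
  planted <- terms[seq_len(n_planted)]
  w <- 1 + enrich_weight *
    rowSums(member[, seq_len(n_planted), drop = FALSE])
  sample_ids <- sample(items, sample_size, prob = w)
  list(annotation = annotation, items = items, sample = sample_ids,
       planted_terms = planted)
}
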