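# Bayes empirical Bayes site posteriors for the M8 positive-selection class.
# Parameter uncertainty in (p, q, p0, omega_s) is integrated over a fixed
# grid with a uniform prior; site likelihoods are precomputed on a fine
# omega grid (branch lengths, kappa and the rate scaling held at their
# maximum-likelihood values), so each grid point only recombines class
# weights.

#' Configuration of the BEB grid
#'
#' @param n_grid Grid points per parameter dimension (default 10).
#' @param pq_max Upper end of the uniform prior ranges for the beta shapes p
#'   and q (priors are uniform on (0, pq_max); default 4).
#' @param omega_s_max Upper end of the uniform prior for the positive-class
#'   omega (prior uniform on (1, omega_s_max); default 11).
#' @param n_fine Fine omega grid size on (0, 1) used to tabulate site
#'   likelihoods (default 101).
#' @export
beb_config <- function(n_grid = 10L, pq_max = 4, omega_s_max = 11,
                       n_fine = 101L) {
  stopifnot(n_grid >= 2L, pq_max > 0, omega_s_max > 1, n_fine >= 10L)
  list(n_grid = as.integer(n_grid), pq_max = pq_max,
       omega_s_max = omega_s_max, n_fine = as.integer(n_fine))
}

grid_mid <- function(lo, hi, n) lo + (seq_len(n) - 0.5) * (hi - lo) / n

#' Bayes empirical Bayes posteriors for positively selected sites
#'
#' For a converged M8 fit, integrates the per-site posterior probability of
#' the omega_s (> 1) class over a uniform prior grid on (p, q, p0, omega_s),
#' weighting grid points by the data likelihood. Also returns the per-site
#' posterior mean omega. Tiers are assigned at posterior probability 0.95
#' and 0.99.
#'
#' @param fit An M8 `site_model_fit` (not flagged).
#' @param aln,tree The alignment and tree the model was fitted to (the
#'   tree's branch lengths are ignored in favour of the fitted ones).
#' @param config See [beb_config()].
#' @return Object of class `site_posterior`: data.frame with `site`
#'   (1-based codon index), `pr_positive`, `pr_beta` (= 1 - pr_positive),
#'   `post_mean_omega` and `tier` (`">=0.99"`, `">=0.95"`, `"<0.95"`);
#'   attribute `method = "BEB"`.
#' @export
beb_posteriors <- function(fit, aln, tree, config = beb_config()) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (fit$model_id != "M8") {
    stop("BEB site identification requires an M8 fit", call. = FALSE)
  }
  if (fit$convergence$flagged) {
    stop("refusing to compute BEB posteriors from a flagged (unconverged or ",
         "unidentifiable) fit", call. = FALSE)
  }
  tp <- prep_tree(fit$tree, aln$taxa)
  tipL <- tip_partials(aln, tp$tip_label)
  freqs <- fit$params$freqs
  kappa <- fit$params$kappa
  scale <- fit$params$scale
  ns <- aln$nsites
  G <- config$n_grid

  # site log-likelihoods on a fixed omega grid (MLE rate scaling)
  w01 <- grid_mid(0, 1, config$n_fine)
  ws_grid <- grid_mid(1, config$omega_s_max, G)
  omega_all <- c(w01, ws_grid)
  Qs <- lapply(omega_all, function(w) {
    gy94_generator(kappa, w, freqs, scale = FALSE) / scale
  })
  logf <- class_site_loglik_cpp(tp$edge, tp$edge_len, tp$ntip, tp$nnode,
                                tipL, Qs, freqs)
  mh <- apply(logf, 2, max)
  expf <- exp(sweep(logf, 2, mh))

  pq_grid <- grid_mid(0, config$pq_max, G)
  p0_grid <- grid_mid(0, 1, G)
  K <- length(fit$params$weights) - 1L  # beta categories of the fitted model

  # pass 1: marginal log-likelihood of every grid point
  npq <- G * G
  logliks <- matrix(NA_real_, npq, G * G)  # rows: (p,q); cols: (p0, ws)
  sbeta_list <- vector("list", npq)
  sbw_list <- vector("list", npq)
  r <- 0L
  for (pi_ in seq_len(G)) {
    for (qi in seq_len(G)) {
      r <- r + 1L
      d <- discretize_beta(pq_grid[pi_], pq_grid[qi], K)
      idx <- pmin(pmax(round(d$omega * config$n_fine + 0.5), 1L),
                  config$n_fine)
      eb <- expf[idx, , drop = FALSE]
      sbeta_list[[r]] <- colMeans(eb)
      sbw_list[[r]] <- colMeans(eb * w01[idx])
      cc <- 0L
      for (p0i in seq_len(G)) {
        for (wsi in seq_len(G)) {
          cc <- cc + 1L
          fh <- p0_grid[p0i] * sbeta_list[[r]] +
            (1 - p0_grid[p0i]) * expf[config$n_fine + wsi, ]
          logliks[r, cc] <- sum(log(fh))
        }
      }
    }
  }
  lmax <- max(logliks)
  post_g <- exp(logliks - lmax)
  post_g <- post_g / sum(post_g)

  # pass 2: accumulate site posteriors with normalized grid weights
  pr_pos <- numeric(ns)
  mean_w <- numeric(ns)
  r <- 0L
  for (pi_ in seq_len(G)) {
    for (qi in seq_len(G)) {
      r <- r + 1L
      sbeta <- sbeta_list[[r]]
      sbw <- sbw_list[[r]]
      cc <- 0L
      for (p0i in seq_len(G)) {
        for (wsi in seq_len(G)) {
          cc <- cc + 1L
          wg <- post_g[r, cc]
          if (wg < 1e-14) next
          p0 <- p0_grid[p0i]
          e_s <- expf[config$n_fine + wsi, ]
          fh <- p0 * sbeta + (1 - p0) * e_s
          pr_pos <- pr_pos + wg * (1 - p0) * e_s / fh
          mean_w <- mean_w + wg * (p0 * sbw + (1 - p0) * ws_grid[wsi] * e_s) / fh
        }
      }
    }
  }
  tier <- ifelse(pr_pos >= 0.99, ">=0.99",
                 ifelse(pr_pos >= 0.95, ">=0.95", "<0.95"))
  out <- data.frame(site = seq_len(ns), pr_positive = pr_pos,
                    pr_beta = 1 - pr_pos, post_mean_omega = mean_w,
                    tier = tier, stringsAsFactors = FALSE)
  structure(out, method = "BEB", class = c("site_posterior", "data.frame"))
}

#' Naive empirical Bayes site posteriors
#'
#' Per-site class posteriors at the maximum-likelihood parameter estimates
#' (no integration over parameter uncertainty). Available for any site-class
#' fit; the positive-class posterior is reported for models with a class at
#' omega > 1 (M2a, M8).
#'
#' @param fit A `site_model_fit`.
#' @param aln,tree Alignment and tree.
#' @return `site_posterior` data.frame as in [beb_posteriors()] with
#'   attribute `method = "NEB"` and attribute `class_posterior` holding the
#'   full (K x nsites) class posterior matrix.
#' @export
neb_posteriors <- function(fit, aln, tree) {
  stopifnot(inherits(fit, "site_model_fit"))
  if (fit$convergence$flagged) {
    stop("refusing to compute posteriors from a flagged fit", call. = FALSE)
  }
  tp <- prep_tree(fit$tree, aln$taxa)
  tipL <- tip_partials(aln, tp$tip_label)
  ll <- mixture_site_loglik(tp, tipL, tp$edge_len, fit$params$kappa,
                            fit$params$omegas, fit$params$weights,
                            fit$params$freqs)
  cls <- attr(ll, "by_class")
  w <- fit$params$weights
  post <- exp(sweep(cls, 2, apply(cls, 2, max))) * w
  post <- sweep(post, 2, colSums(post), `/`)
  omegas <- fit$params$omegas
  pos_class <- which(omegas > 1)
  pr_pos <- if (length(pos_class)) colSums(post[pos_class, , drop = FALSE])
    else rep(0, ncol(post))
  mean_w <- colSums(post * omegas)
  tier <- ifelse(pr_pos >= 0.99, ">=0.99",
                 ifelse(pr_pos >= 0.95, ">=0.95", "<0.95"))
  out <- data.frame(site = seq_len(ncol(post)), pr_positive = pr_pos,
                    pr_beta = 1 - pr_pos, post_mean_omega = mean_w,
                    tier = tier, stringsAsFactors = FALSE)
  attr(out, "class_posterior") <- post
  structure(out, method = "NEB", class = c("site_posterior", "data.frame"))
}

#' Tiered report of candidate positively selected sites
#'
#' Partitions sites by the posterior probability of the positive-selection
#' class and keys the report to a reference taxon's residues, in the
#' conventional "23E" style (1-based site plus the reference amino acid).
#' Cysteine columns of the reference are marked so the behaviour of
#' conserved cysteines can be inspected.
#'
#' @param posteriors A `site_posterior`.
#' @param aln The codon alignment.
#' @param ref_taxon Reference taxon name (default: first taxon).
#' @param thresholds Two descending posterior thresholds (default 0.99,
#'   0.95).
#' @return data.frame with `site`, `ref_aa`, `label`, `pr_positive`,
#'   `post_mean_omega`, `tier` and `is_cysteine`, ordered by site; only
#'   sites at or above the lower threshold are returned.
#' @export
flag_sites <- function(posteriors, aln, ref_taxon = NULL,
                       thresholds = c(0.99, 0.95)) {
  stopifnot(inherits(posteriors, "site_posterior"),
            length(thresholds) == 2L, thresholds[1] >= thresholds[2])
  ref_taxon <- ref_taxon %||% aln$taxa[1]
  if (!ref_taxon %in% aln$taxa) {
    stop(sprintf("reference taxon %s absent from alignment", sQuote(ref_taxon)),
         call. = FALSE)
  }
  ct <- codon_table()
  cod <- aln$codons[ref_taxon, ]
  aa <- ifelse(is.na(match(cod, ct$codons)), "X",
               ct$aa[match(cod, ct$codons)])
  keep <- posteriors$pr_positive >= thresholds[2]
  out <- posteriors[keep, , drop = FALSE]
  out$ref_aa <- aa[out$site]
  out$label <- paste0(out$site, out$ref_aa)
  out$tier <- ifelse(out$pr_positive >= thresholds[1],
                     sprintf(">=%.2g", thresholds[1]),
                     sprintf(">=%.2g", thresholds[2]))
  out$is_cysteine <- out$ref_aa == "C"
  rownames(out) <- NULL
  out[, c("site", "ref_aa", "label", "pr_positive", "post_mean_omega",
          "tier", "is_cysteine")]
}
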