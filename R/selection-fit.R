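# Site-class codon model fitting: M0 (one ratio), M1a/M2a (nearly neutral /
# positive selection), M7/M8 (beta / beta + omega_s >= 1), with likelihoods
# evaluated by pruning over the tree and mixtures averaged over site classes.

prep_tree <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree must have branch lengths", call. = FALSE)
  }
  if (!setequal(tree$tip.label, taxa)) {
    stop("tree tips and alignment taxa must match one-to-one", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths", call. = FALSE)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  list(edge = tree$edge, edge_len = tree$edge.length,
       ntip = length(tree$tip.label), nnode = tree$Nnode,
       tip_label = tree$tip.label, tree = tree)
}

# leaf partial-likelihood cube in tree tip order; missing cells = all ones
tip_partials <- function(aln, tip_label) {
  n <- 61L
  ns <- aln$nsites
  arr <- array(0, dim = c(n, ns, length(tip_label)))
  for (t in seq_along(tip_label)) {
    row <- aln$idx[tip_label[t], ]
    m <- matrix(0, n, ns)
    obs <- which(!is.na(row))
    m[cbind(row[obs], obs)] <- 1
    if (length(obs) < ns) m[, setdiff(seq_len(ns), obs)] <- 1
    arr[, , t] <- m
  }
  arr
}

# per-site log-likelihood of a class mixture; attr "by_class" holds the
# (K x nsites) per-class matrix
mixture_site_loglik <- function(tp, tipL, edge_len, kappa, omegas, weights,
                                freqs) {
  cm <- build_class_matrices(kappa, omegas, weights, freqs)
  cls <- class_site_loglik_cpp(tp$edge, edge_len, tp$ntip, tp$nnode, tipL,
                               cm$Q, freqs)
  if (length(weights) == 1L) {
    ll <- cls[1, ]
  } else {
    m <- apply(cls, 2, max)
    ll <- m + log(colSums(weights * exp(sweep(cls, 2, m))))
  }
  attr(ll, "by_class") <- cls
  attr(ll, "scale") <- cm$scale
  ll
}

#' Per-site log-likelihoods under a site-class codon model
#'
#' Evaluates the phylogenetic likelihood of a codon alignment by pruning,
#' marginalizing gaps and ambiguous codons as missing data, and averaging
#' site likelihoods over site classes with the class weights.
#'
#' @param tree `phylo` tree with branch lengths (expected substitutions per
#'   codon); tips must match the alignment taxa.
#' @param aln A [codon_alignment()].
#' @param params List with `kappa`, `freqs` (61 values), `omegas` and
#'   `weights` (equal-length class vectors; scalar omega with weight 1 for a
#'   one-ratio model).
#' @return Numeric vector of per-site log-likelihoods (sum = total lnL);
#'   attribute `"by_class"` carries the per-class site log-likelihoods.
#' @export
site_loglik <- function(tree, aln, params) {
  stopifnot(inherits(aln, "codon_alignment"))
  tp <- prep_tree(tree, aln$taxa)
  tipL <- tip_partials(aln, tp$tip_label)
  mixture_site_loglik(tp, tipL, tp$edge_len, params$kappa, params$omegas,
                      params$weights, params$freqs)
}

# ---- model parameterizations -------------------------------------------

model_par_info <- function(model_id, config) {
  eps <- 1e-6
  wmax <- config$omega_max
  switch(model_id,
    M0 = list(names = "omega", lower = 1e-6, upper = wmax, start = 0.4,
              classes = function(par, K)
                list(omegas = par[["omega"]], weights = 1)),
    M1a = list(names = c("p0", "omega0"), lower = c(eps, eps),
               upper = c(1 - eps, 1), start = c(0.7, 0.2),
               classes = function(par, K)
                 list(omegas = c(par[["omega0"]], 1),
                      weights = c(par[["p0"]], 1 - par[["p0"]]))),
    M2a = list(names = c("p0", "f1", "omega0", "omega_s"),
               lower = c(eps, eps, eps, 1), upper = c(1 - eps, 1 - eps, 1, wmax),
               start = c(0.7, 0.8, 0.2, 2),
               # a start with the positive-class weight near zero reduces to
               # the M1a surface, guarding the nesting inequality
               extra_starts = list(c(0.7, 1 - eps, 0.2, 1.5)),
               classes = function(par, K) {
                 p0 <- par[["p0"]]
                 p1 <- (1 - p0) * par[["f1"]]
                 list(omegas = c(par[["omega0"]], 1, par[["omega_s"]]),
                      weights = c(p0, p1, 1 - p0 - p1))
               }),
    M7 = list(names = c("p", "q"), lower = c(0.005, 0.005),
              upper = c(99, 99), start = c(0.5, 1.5),
              classes = function(par, K) {
                d <- discretize_beta(par[["p"]], par[["q"]], K)
                list(omegas = d$omega, weights = d$weight)
              }),
    M8 = list(names = c("p", "q", "p0", "omega_s"),
              lower = c(0.005, 0.005, eps, 1),
              upper = c(99, 99, 1, wmax), start = c(0.5, 1.5, 0.9, 2),
              # a start at p0 ~ 1 tracks the M7 surface first, so the fitted
              # M8 can never stay below the nested M7 optimum
              extra_starts = list(c(0.5, 1.5, 1 - eps, 1.5)),
              classes = function(par, K) {
                d <- discretize_beta(par[["p"]], par[["q"]], K)
                p0 <- par[["p0"]]
                list(omegas = c(d$omega, par[["omega_s"]]),
                     weights = c(p0 * d$weight, 1 - p0))
              }),
    stop("unknown model id: ", model_id, call. = FALSE)
  )
}

#' Configuration for site-model fitting
#'
#' @param freqs Codon frequency setting: `"F3x4"` (default), `"equal"` or
#'   `"F61"`.
#' @param n_beta Number of equal-probability beta categories for M7/M8
#'   (default 10).
#' @param n_starts Total optimizer starts (1 default start plus random
#'   restarts; default 3).
#' @param seed Seed for the random restarts.
#' @param kappa Fix kappa at this value instead of estimating it (NULL =
#'   estimate; default).
#' @param omega_max Upper bound for omega during optimization.
#' @param lnl_tol Convergence tolerance on the log-likelihood.
#' @param branch_lengths `"M0"` (optimize under M0, then hold fixed for the
#'   site-class models; default) or `"fixed"` (use the input tree's lengths
#'   everywhere).
#' @return List of settings for [fit_model()].
#' @export
site_model_config <- function(freqs = "F3x4", n_beta = 10L, n_starts = 3L,
                              seed = 1L, kappa = NULL, omega_max = 50,
                              lnl_tol = 1e-6, branch_lengths = c("M0", "fixed")) {
  if (!freqs %in% c("F3x4", "equal", "F61")) {
    stop("freqs must be one of F3x4, equal, F61", call. = FALSE)
  }
  if (n_starts < 1L || n_beta < 1L) {
    stop("n_starts and n_beta must be >= 1", call. = FALSE)
  }
  list(freqs = freqs, n_beta = as.integer(n_beta),
       n_starts = as.integer(n_starts), seed = seed, kappa = kappa,
       omega_max = omega_max, lnl_tol = lnl_tol,
       branch_lengths = match.arg(branch_lengths))
}

run_starts <- function(obj, start, lower, upper, config,
                       extra_starts = list()) {
  best <- NULL
  starts <- c(list(start), extra_starts)
  if (config$n_starts > 1L) {
    # draw restart points from a private RNG stream, leaving the caller's
    # RNG state untouched
    rng_state <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(config$seed)
    extra <- lapply(seq_len(config$n_starts - 1L), function(i) {
      stats::runif(length(start), lower, pmin(upper, lower + 5))
    })
    if (!is.null(rng_state)) assign(".Random.seed", rng_state, globalenv())
    starts <- c(starts, extra)
  }
  msgs <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, obj, lower = lower, upper = upper,
                    control = list(iter.max = 1000, eval.max = 4000,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) {
      msgs <- c(msgs, "optimizer error at one start")
      next
    }
    msgs <- c(msgs, fit$message %||% "")
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  best$messages <- msgs
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a site-class codon model by maximum likelihood
#'
#' Fits one of M0, M1a, M2a, M7 or M8 to a codon alignment and tree. Under
#' M0 the branch lengths (and kappa, unless fixed) are estimated jointly
#' with omega; for the site-class models the branch lengths are first
#' optimized under M0 and then held fixed (configurable), while kappa and
#' the site-class parameters are estimated.
#'
#' @param model_id One of `"M0"`, `"M1a"`, `"M2a"`, `"M7"`, `"M8"`.
#' @param aln A [codon_alignment()].
#' @param tree `phylo` with starting branch lengths.
#' @param config See [site_model_config()].
#' @param m0_fit Optional previously computed M0 fit to take branch lengths
#'   (and the kappa start) from; computed internally when needed.
#' @return Object of class `site_model_fit`: `model_id`, `lnL`, `params`
#'   (kappa, model parameters, class `omegas`/`weights`, frequency vector,
#'   joint rate `scale`), `tree` (with the branch lengths used), `n_categories`,
#'   `n_free` (free parameter count) and `convergence` (code, messages,
#'   `flagged` plus reasons, e.g. no variable sites).
#' @export
fit_model <- function(model_id = c("M0", "M1a", "M2a", "M7", "M8"), aln, tree,
                      config = site_model_config(), m0_fit = NULL) {
  model_id <- match.arg(model_id)
  stopifnot(inherits(aln, "codon_alignment"))
  tp <- prep_tree(tree, aln$taxa)
  tipL <- tip_partials(aln, tp$tip_label)
  freqs <- codon_freqs(aln, config$freqs)
  info <- model_par_info(model_id, config)
  K <- config$n_beta

  flagged <- FALSE
  reasons <- character(0)
  variable <- any(apply(aln$idx, 2, function(col) {
    length(unique(col[!is.na(col)])) > 1L
  }))
  if (!variable) {
    flagged <- TRUE
    reasons <- c(reasons, "no variable sites: omega unidentifiable")
  }

  kappa_free <- is.null(config$kappa)
  optimize_bl <- model_id == "M0" && config$branch_lengths == "M0"
  if (model_id != "M0" && config$branch_lengths == "M0") {
    if (is.null(m0_fit)) {
      m0_fit <- fit_model("M0", aln, tree, config)
    }
    stopifnot(inherits(m0_fit, "site_model_fit"), m0_fit$model_id == "M0")
    tp <- prep_tree(m0_fit$tree, aln$taxa)
    tipL <- tip_partials(aln, tp$tip_label)
  }
  edge_len0 <- tp$edge_len
  if (optimize_bl && any(edge_len0 <= 0)) {
    edge_len0[edge_len0 <= 0] <- 0.05
  }

  kappa_start <- if (!kappa_free) config$kappa
    else if (!is.null(m0_fit)) m0_fit$params$kappa else 2
  nm <- info$names
  start <- stats::setNames(info$start, nm)
  lower <- stats::setNames(info$lower, nm)
  upper <- stats::setNames(info$upper, nm)
  if (kappa_free) {
    start <- c(start, kappa = kappa_start)
    lower <- c(lower, kappa = 0.05)
    upper <- c(upper, kappa = 99)
  }
  if (optimize_bl) {
    nb <- length(edge_len0)
    start <- c(start, stats::setNames(edge_len0, paste0("bl", seq_len(nb))))
    lower <- c(lower, rep(1e-8, nb))
    upper <- c(upper, rep(50, nb))
  }

  obj <- function(par) {
    par <- stats::setNames(par, names(start))
    cl <- info$classes(par, K)
    kap <- if (kappa_free) par[["kappa"]] else config$kappa
    el <- if (optimize_bl) unname(par[grep("^bl", names(par))]) else tp$edge_len
    ll <- mixture_site_loglik(tp, tipL, el, kap, cl$omegas, cl$weights, freqs)
    v <- -sum(ll)
    if (!is.finite(v)) 1e10 else v
  }

  extra <- lapply(info$extra_starts %||% list(), function(s) {
    full <- start
    full[nm] <- s
    full
  })
  best <- run_starts(obj, start, lower, upper, config, extra)
  par <- stats::setNames(best$par, names(start))
  cl <- info$classes(par, K)
  kap <- if (kappa_free) par[["kappa"]] else config$kappa
  el <- if (optimize_bl) unname(par[grep("^bl", names(par))]) else tp$edge_len
  ll <- mixture_site_loglik(tp, tipL, el, kap, cl$omegas, cl$weights, freqs)
  out_tree <- tp$tree
  out_tree$edge.length <- el
  if (best$convergence != 0 &&
      !grepl("relative convergence|X-convergence|both X|singular convergence",
             best$message %||% "")) {
    flagged <- TRUE
    reasons <- c(reasons, sprintf("optimizer did not report convergence (%s)",
                                  best$message %||% "no message"))
  }
  structure(list(
    model_id = model_id,
    lnL = sum(ll),
    site_loglik = as.numeric(ll),
    params = list(kappa = unname(kap),
                  model = par[nm],
                  omegas = cl$omegas, weights = cl$weights,
                  freqs = freqs, freq_method = config$freqs,
                  scale = attr(ll, "scale")),
    tree = out_tree,
    n_categories = length(cl$omegas),
    n_free = length(nm) + as.integer(kappa_free) +
      if (optimize_bl) length(el) else 0L,
    convergence = list(code = best$convergence, flagged = flagged,
                       reasons = reasons, n_starts = config$n_starts)),
    class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("<site_model_fit> %s  lnL = %.4f  kappa = %.3f\n",
              x$model_id, x$lnL, x$params$kappa))
  mp <- x$params$model
  if (length(mp)) {
    cat("  ", paste(sprintf("%s = %.4f", names(mp), mp), collapse = ", "), "\n")
  }
  if (x$convergence$flagged) {
    cat("  flagged:", paste(x$convergence$reasons, collapse = "; "), "\n")
  }
  invisible(x)
}

LRT_PAIRS <- list(c("M1a", "M2a"), c("M7", "M8"), c("M0", "M1a"))

#' Likelihood ratio test between nested site models
#'
#' Computes `2 * (lnL_alt - lnL_null)` (clamped at zero), the chi-square
#' degrees of freedom as the difference in free parameter counts, and the
#' upper-tail p-value. Significance stars follow the convention
#' `*` p < 0.05, `**` p < 0.001, `***` p < 0.0001.
#'
#' @param null_fit,alt_fit `site_model_fit` objects for a nested pair
#'   (M1a vs M2a, M7 vs M8, or M0 vs M1a).
#' @return Object of class `lrt_result`: `stat`, `df`, `p_value`, `stars`,
#'   model ids.
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "site_model_fit"),
            inherits(alt_fit, "site_model_fit"))
  pair <- c(null_fit$model_id, alt_fit$model_id)
  ok <- any(vapply(LRT_PAIRS, identical, logical(1), pair))
  if (!ok) {
    stop(sprintf("%s is not nested in %s (supported: %s)", pair[1], pair[2],
                 paste(vapply(LRT_PAIRS, paste, character(1), collapse = " vs "),
                       collapse = ", ")), call. = FALSE)
  }
  df <- alt_fit$n_free - null_fit$n_free
  stopifnot(df >= 1)
  stat <- max(0, 2 * (alt_fit$lnL - null_fit$lnL))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(null = pair[1], alt = pair[2], stat = stat, df = df,
                 p_value = p, stars = lrt_stars(p)),
            class = "lrt_result")
}

lrt_stars <- function(p) {
  if (p < 1e-4) "***" else if (p < 1e-3) "**" else if (p < 0.05) "*" else ""
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt> %s vs %s: 2dlnL = %.3f, df = %d, p = %.4g %s\n",
              x$null, x$alt, x$stat, x$df, x$p_value, x$stars))
  invisible(x)
}

#' Summarize model fits and tests as a table
#'
#' @param fits List of `site_model_fit`s.
#' @param lrts Optional list of `lrt_result`s appended as attribute-style
#'   columns on the matching alternative model row.
#' @return data.frame with model, lnL, kappa, parameter string, and (when
#'   supplied) LRT statistic/df/p/stars.
#' @export
fit_table <- function(fits, lrts = NULL) {
  rows <- lapply(fits, function(f) {
    data.frame(model = f$model_id, lnL = f$lnL, kappa = f$params$kappa,
               params = paste(sprintf("%s=%.4g", names(f$params$model),
                                      f$params$model), collapse = ","),
               stat = NA_real_, df = NA_integer_, p_value = NA_real_,
               stars = "", stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (l in lrts %||% list()) {
    i <- which(tab$model == l$alt)
    if (length(i)) {
      tab$stat[i] <- l$stat
      tab$df[i] <- l$df
      tab$p_value[i] <- l$p_value
      tab$stars[i] <- l$stars
    }
  }
  tab
}
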