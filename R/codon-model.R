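# Goldman-Yang style codon substitution machinery over the 61 sense codons
# of the standard genetic code. Rates exist only between codons differing at
# a single nucleotide position and are proportional to the target codon
# frequency, multiplied by kappa for transitions and by omega for
# nonsynonymous changes.

codon_env <- new.env(parent = emptyenv())

#' Sense-codon table for the standard genetic code
#'
#' @return List with `codons` (61 sense codons), `aa` (their one-letter
#'   amino acids), `stops`, and precomputed single-nucleotide-difference
#'   masks used by [gy94_generator()].
#' @export
codon_table <- function() {
  if (!is.null(codon_env$table)) return(codon_env$table)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)
  nucmat <- do.call(rbind, strsplit(codons, ""))
  single <- matrix(FALSE, n, n)
  ts <- matrix(FALSE, n, n)
  nonsyn <- matrix(FALSE, n, n)
  is_transition <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diffpos <- which(nucmat[i, ] != nucmat[j, ])
      if (length(diffpos) == 1L) {
        single[i, j] <- TRUE
        ts[i, j] <- is_transition(nucmat[i, diffpos], nucmat[j, diffpos])
        nonsyn[i, j] <- aa[i] != aa[j]
      }
    }
  }
  codon_env$table <- list(codons = codons, aa = aa,
                          stops = names(gc)[gc == "*"],
                          nucmat = nucmat, single = single, ts = ts,
                          nonsyn = nonsyn)
  codon_env$table
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61 x 61 codon rate matrix with off-diagonal rate
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]` for single-nucleotide
#' changes and zero otherwise; rows sum to zero. With `scale = TRUE` the
#' matrix is rescaled so the expected rate at equilibrium is one substitution
#' per codon per unit branch length.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs Equilibrium frequencies over the 61 sense codons (sum 1).
#' @param scale Rescale to mean rate 1 (default TRUE). Site-class mixtures
#'   are scaled jointly by [build_class_matrices()] instead.
#' @return 61 x 61 rate matrix with codon dimnames.
#' @export
gy94_generator <- function(kappa, omega, freqs = rep(1 / 61, 61),
                           scale = TRUE) {
  ct <- codon_table()
  n <- length(ct$codons)
  stopifnot(kappa > 0, omega >= 0, length(freqs) == n)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    stop("freqs must be nonnegative and sum to 1", call. = FALSE)
  }
  Q <- matrix(0, n, n, dimnames = list(ct$codons, ct$codons))
  Q[ct$single] <- rep(freqs, each = n)[ct$single]
  Q[ct$single & ct$ts] <- Q[ct$single & ct$ts] * kappa
  Q[ct$single & ct$nonsyn] <- Q[ct$single & ct$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    r <- -sum(freqs * diag(Q))
    if (r <= 0) stop("degenerate rate matrix (zero total rate)", call. = FALSE)
    Q <- Q / r
  }
  Q
}

# Mean substitution rate at equilibrium of an unscaled generator.
mean_rate <- function(Q, freqs) -sum(freqs * diag(Q))

#' Jointly scaled site-class rate matrices
#'
#' Builds one GY94 generator per site class (shared kappa and frequencies,
#' class-specific omega) and rescales all of them by the mixture-averaged
#' rate, so branch lengths are expected substitutions per codon averaged
#' over site classes.
#'
#' @param kappa,freqs As in [gy94_generator()].
#' @param omegas,weights Class omega values and mixing proportions
#'   (weights sum to 1).
#' @return List with `Q` (list of matrices) and `scale` (the joint factor
#'   the unscaled matrices were divided by).
#' @export
build_class_matrices <- function(kappa, omegas, weights, freqs) {
  stopifnot(length(omegas) == length(weights),
            abs(sum(weights) - 1) < 1e-8)
  Qs <- lapply(omegas, function(w) gy94_generator(kappa, w, freqs,
                                                  scale = FALSE))
  rates <- vapply(Qs, mean_rate, numeric(1), freqs = freqs)
  f <- sum(weights * rates)
  if (f <= 0) stop("degenerate mixture (zero average rate)", call. = FALSE)
  list(Q = lapply(Qs, function(q) q / f), scale = f)
}

#' Codon transition probability matrix
#'
#' Matrix exponential of a reversible codon generator via symmetric eigen
#' decomposition.
#'
#' @param Q Rate matrix (rows sum to zero, reversible w.r.t. `freqs`).
#' @param freqs Equilibrium frequencies.
#' @param t Branch length.
#' @return Transition probability matrix P(t) with rows summing to 1.
#' @export
codon_pmat <- function(Q, freqs, t) {
  sq <- sqrt(freqs)
  S <- sweep(sweep(Q, 1, sq, `*`), 2, sq, `/`)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  P <- sweep(e$vectors, 1, sq, `/`) %*%
    (exp(e$values * t) * t(sweep(e$vectors, 1, sq, `*`)))
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Discretize a beta distribution into equal-probability categories
#'
#' Cuts Beta(p, q) into `K` equal-probability intervals and represents each
#' by its conditional mean, the convention used for beta-distributed omega
#' site classes.
#'
#' @param p,q Beta shape parameters (> 0).
#' @param K Number of categories (default 10).
#' @return data.frame with columns `omega` (category means in (0,1)) and
#'   `weight` (all `1/K`).
#' @export
discretize_beta <- function(p, q, K = 10L) {
  stopifnot(p > 0, q > 0, K >= 1L)
  # qbeta warns about reduced accuracy at extreme shapes; the equal-weight
  # category means only need the boundaries approximately
  b <- suppressWarnings(stats::qbeta(seq(0, 1, length.out = K + 1L), p, q))
  # conditional mean on each slice via the incomplete-beta identity
  mass <- stats::pbeta(b[-1], p + 1, q) - stats::pbeta(b[-(K + 1L)], p + 1, q)
  omega <- (p / (p + q)) * mass * K
  omega <- pmin(pmax(omega, 1e-9), 1 - 1e-9)
  data.frame(omega = omega, weight = rep(1 / K, K))
}

#' Build a codon alignment object
#'
#' @param seqs Named character vector of equal-length nucleotide strings
#'   (length divisible by 3), or a [Biostrings::DNAStringSet-class].
#' @param stop_codons `"reject"` (default) errors on any in-frame stop
#'   codon; `"mask"` treats the affected codon cell as missing data.
#' @return Object of class `codon_alignment`: list with `taxa`, `nsites`
#'   (codon count), `idx` (taxa x sites matrix of 1-based sense-codon
#'   indices, NA for gaps/ambiguity/masked stops) and `codons` (taxa x sites
#'   character matrix).
#' @export
codon_alignment <- function(seqs, stop_codons = c("reject", "mask")) {
  stop_codons <- match.arg(stop_codons)
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  seqs <- toupper(gsub("U", "T", seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must have equal length", call. = FALSE)
  }
  if (lens[1] %% 3L != 0L) {
    stop("alignment length must be divisible by 3", call. = FALSE)
  }
  nsites <- unname(lens[1]) %/% 3L
  ct <- codon_table()
  cod <- t(vapply(seqs, function(s) {
    substring(s, seq(1, lens[1], by = 3), seq(3, lens[1], by = 3))
  }, character(nsites)))
  if (nsites == 1L) cod <- matrix(cod, ncol = 1L,
                                  dimnames = list(names(seqs), NULL))
  idx <- matrix(match(cod, ct$codons), nrow = length(seqs),
                dimnames = list(names(seqs), NULL))
  is_stop <- matrix(cod %in% ct$stops, nrow = length(seqs))
  if (any(is_stop)) {
    if (stop_codons == "reject") {
      bad <- which(is_stop, arr.ind = TRUE)[1, ]
      stop(sprintf("in-frame stop codon at codon %d of taxon %s %s",
                   bad[2], sQuote(names(seqs)[bad[1]]),
                   "(use stop_codons = 'mask' to treat as missing)"),
           call. = FALSE)
    }
    idx[is_stop] <- NA_integer_
  }
  structure(list(taxa = names(seqs), nsites = nsites, idx = idx,
                 codons = cod), class = "codon_alignment")
}

#' Read a codon alignment from FASTA or sequential PHYLIP
#'
#' @param file Path. Format is taken from the extension (`.fa`, `.fasta`,
#'   `.fna` = FASTA; anything else is read as PHYLIP) unless given.
#' @param format `"fasta"` or `"phylip"`.
#' @param ... Passed to [codon_alignment()].
#' @export
read_codon_alignment <- function(file, format = NULL, ...) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fa|fasta|fna)$", file, ignore.case = TRUE))
      "fasta" else "phylip"
  }
  if (format == "fasta") {
    codon_alignment(Biostrings::readDNAStringSet(file), ...)
  } else {
    m <- ape::read.dna(file, format = "sequential", as.character = TRUE)
    seqs <- apply(toupper(m), 1, paste, collapse = "")
    codon_alignment(seqs, ...)
  }
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codons (%d missing cells)\n",
              length(x$taxa), x$nsites, sum(is.na(x$idx))))
  invisible(x)
}

#' Empirical codon frequencies
#'
#' @param aln A `codon_alignment`.
#' @param method `"F3x4"` (product of per-codon-position nucleotide
#'   frequencies, renormalized over sense codons; the usual default),
#'   `"equal"` (1/61 each) or `"F61"` (observed codon frequencies with a
#'   pseudocount).
#' @return Numeric vector of 61 frequencies summing to 1.
#' @export
codon_freqs <- function(aln, method = c("F3x4", "equal", "F61")) {
  method <- match.arg(method)
  ct <- codon_table()
  n <- length(ct$codons)
  if (method == "equal") return(rep(1 / n, n))
  cod <- aln$codons[!is.na(aln$idx)]
  if (method == "F61") {
    cnt <- table(factor(cod, levels = ct$codons)) + 0.5
    return(as.numeric(cnt / sum(cnt)))
  }
  nucs <- do.call(rbind, strsplit(cod, ""))
  posfreq <- apply(nucs, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T"))) + 0.5
    tab / sum(tab)
  })
  f <- posfreq[ct$nucmat[, 1], 1] * posfreq[ct$nucmat[, 2], 2] *
    posfreq[ct$nucmat[, 3], 3]
  unname(f / sum(f))
}
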