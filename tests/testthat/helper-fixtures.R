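# shared fixtures: small trees and alignments built in code

suppressPackageStartupMessages(library(ape))

# deterministic random tree with moderate branch lengths
fixture_tree <- function(ntip, seed = 1, bl = c(0.05, 0.3)) {
  set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- stats::runif(nrow(tr$edge), bl[1], bl[2])
  tr
}

# unrooted 4-taxon tree (two internal nodes) for enumeration oracles
fixture_quartet <- function(bl = c(0.1, 0.2, 0.15, 0.25, 0.12)) {
  tr <- ape::read.tree(text = sprintf(
    "(a:%f,b:%f,(c:%f,d:%f):%f);", bl[1], bl[2], bl[3], bl[4], bl[5]))
  tr
}

# brute-force site likelihoods for the quartet: explicit summation over the
# two internal node states (independent of the pruning kernel)
quartet_bruteforce_loglik <- function(tree, aln, kappa, omega, freqs) {
  Q <- gy94_generator(kappa, omega, freqs)
  tip_lab <- tree$tip.label
  # node ids: tips 1..4, root 5, inner 6 (ape read.tree convention)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    codon_pmat(Q, freqs, tree$edge.length[e]))
  idx <- aln$idx[tip_lab, , drop = FALSE]
  ns <- aln$nsites
  ll <- numeric(ns)
  edges <- tree$edge
  P_of <- function(chi) P[[which(edges[, 2] == chi)]]
  inner <- 6L  # the non-root internal node
  for (h in seq_len(ns)) {
    # joint probability over every (root state i, inner state j) pair
    va <- freqs * P_of(1)[, idx[1, h]] * P_of(2)[, idx[2, h]]
    vb <- P_of(3)[, idx[3, h]] * P_of(4)[, idx[4, h]]
    grid <- outer(va, vb) * P_of(inner)
    ll[h] <- log(sum(grid))
  }
  ll
}
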