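# Post-processing of peptide-spectrum match (PSM) and protein tables:
# target-decoy FDR with confidence tiers, replicate merging with relative
# abundance, molecular-weight profiles and set-overlap reports.

#' Target-decoy FDR estimation and confidence tiers for PSMs
#'
#' At a score threshold s the FDR estimate is
#' `#(decoys with score >= s) / #(targets with score >= s)` (decoys tied
#' with the threshold count against it, which is conservative). The q-value
#' of a PSM is the minimum FDR over all thresholds that would accept it,
#' which makes q-values non-increasing in score. Tiers: `high` q <= 1%,
#' `medium` 1% < q <= 5%, `excluded` q > 5% (the 1% boundary is counted as
#' high confidence).
#'
#' @param records data.frame with numeric `score` (higher is better) and
#'   logical `is_decoy`.
#' @param pseudocount Add-one correction to the decoy count (off by
#'   default).
#' @return The input with columns `fdr` (the q-value) and `tier` appended.
#' @export
psm_fdr <- function(records, pseudocount = FALSE) {
  stopifnot(is.data.frame(records),
            all(c("score", "is_decoy") %in% names(records)))
  if (anyNA(records$score)) stop("NA scores", call. = FALSE)
  n_target <- sum(!records$is_decoy)
  if (n_target == 0L) stop("no target PSMs", call. = FALSE)

  thr <- sort(unique(records$score), decreasing = TRUE)
  n_dec_ge <- vapply(thr, function(s) sum(records$is_decoy &
                                            records$score >= s), numeric(1))
  n_tgt_ge <- vapply(thr, function(s) sum(!records$is_decoy &
                                            records$score >= s), numeric(1))
  num <- n_dec_ge + if (pseudocount) 1 else 0
  fdr_thr <- ifelse(n_tgt_ge == 0, 1, pmin(1, num / pmax(n_tgt_ge, 1)))
  # q(s) = min FDR over thresholds <= s: cumulative minimum scanning from
  # the lowest threshold upward
  q_thr <- rev(cummin(rev(fdr_thr)))
  q <- q_thr[match(records$score, thr)]
  records$fdr <- q
  records$tier <- ifelse(q <= 0.01, "high",
                         ifelse(q <= 0.05, "medium", "excluded"))
  records
}

#' Merge replicate protein identification lists
#'
#' Union semantics: a protein identified in any replicate is retained, with
#' the number of supporting replicates and, when peptide areas are present,
#' a relative abundance as the percentage of the total peptide area across
#' replicates. Duplicate protein ids within a replicate are collapsed with
#' summed area (a message is emitted).
#'
#' @param replicates Named list of data.frames, each with `protein_id` and
#'   optionally `area` and `molecular_weight`.
#' @return data.frame with `protein_id`, `n_replicates`, `replicate_ids`,
#'   `area` (summed), `rel_abundance` (%, summing to 100), and
#'   `molecular_weight` when supplied.
#' @export
merge_replicates <- function(replicates) {
  stopifnot(is.list(replicates), length(replicates) >= 1L)
  if (is.null(names(replicates)) || any(!nzchar(names(replicates)))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }
  reps <- lapply(names(replicates), function(nm) {
    df <- replicates[[nm]]
    stopifnot("protein_id" %in% names(df))
    if (!"area" %in% names(df)) df$area <- 1
    if (anyDuplicated(df$protein_id)) {
      message(sprintf("replicate %s: duplicate protein ids collapsed with summed area", nm))
      agg <- stats::aggregate(area ~ protein_id, df, sum)
      if ("molecular_weight" %in% names(df)) {
        agg$molecular_weight <-
          df$molecular_weight[match(agg$protein_id, df$protein_id)]
      }
      df <- agg
    }
    df$replicate <- nm
    df
  })
  all <- do.call(rbind, lapply(reps, function(d)
    d[, intersect(c("protein_id", "area", "molecular_weight", "replicate"),
                  names(d)), drop = FALSE]))
  ids <- sort(unique(all$protein_id))
  out <- data.frame(protein_id = ids,
                    n_replicates = as.integer(table(all$protein_id)[ids]),
                    replicate_ids = vapply(ids, function(i)
                      paste(sort(all$replicate[all$protein_id == i]),
                            collapse = ";"), character(1)),
                    area = vapply(ids, function(i)
                      sum(all$area[all$protein_id == i]), numeric(1)),
                    stringsAsFactors = FALSE)
  total <- sum(out$area)
  out$rel_abundance <- if (total > 0) 100 * out$area / total else 0
  if ("molecular_weight" %in% names(all)) {
    out$molecular_weight <- all$molecular_weight[match(out$protein_id,
                                                       all$protein_id)]
  }
  rownames(out) <- NULL
  out
}

#' Molecular-weight profile of protein hits
#'
#' Fraction of proteins per molecular-weight bin. The default edges
#' reproduce the conventional below-20 / 20-40 / 40-60 / 60-plus kDa
#' summary.
#'
#' @param weights_kda Positive molecular weights in kDa.
#' @param edges Increasing internal bin edges (kDa).
#' @return data.frame with `bin` labels, `n` and `fraction` (sums to 1).
#' @export
size_profile <- function(weights_kda, edges = c(20, 40, 60)) {
  stopifnot(length(weights_kda) >= 1L, all(weights_kda > 0),
            all(diff(edges) > 0))
  brk <- c(0, edges, Inf)
  labs <- c(sprintf("<%g", edges[1]),
            if (length(edges) > 1)
              sprintf("%g-%g", edges[-length(edges)], edges[-1]),
            sprintf(">=%g", edges[length(edges)]))
  cut_idx <- cut(weights_kda, breaks = brk, right = FALSE, labels = FALSE)
  n <- tabulate(cut_idx, nbins = length(labs))
  data.frame(bin = labs, n = n, fraction = n / length(weights_kda),
             stringsAsFactors = FALSE)
}

#' Pairwise and k-way overlap report for named sets
#'
#' @param sets Named list of vectors (duplicates are ignored).
#' @return List with `sizes`, `pairwise` (matrix of pairwise intersection
#'   counts, diagonal = set sizes) and `regions` (data.frame of every
#'   non-empty combination of membership with exclusive element counts, as
#'   in a Venn diagram, plus `n_intersection`, the full intersection count
#'   of the named subset).
#' @export
overlap_report <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  k <- length(sets)
  nm <- names(sets)
  pw <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, nm))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- nm
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  regions <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    inn <- unlist(combos[i, ])
    excl <- sum(apply(member, 1, function(r) all(r == inn)))
    inter <- sum(apply(member[, inn, drop = FALSE], 1, all))
    data.frame(subset = paste(nm[inn], collapse = "&"),
               n_exclusive = excl, n_intersection = inter,
               stringsAsFactors = FALSE)
  }))
  list(sizes = vapply(sets, length, integer(1)), pairwise = pw,
       regions = regions)
}

# average residue masses (Da) for molecular weight from sequence
AA_AVG_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                 C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                 H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                 M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                 T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
                 X = 110.0)

#' Molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water; the ambiguity letter X is
#' given the average residue mass.
#'
#' @param sequence Residue string.
#' @return Weight in kDa.
#' @export
protein_mw <- function(sequence) {
  check_protein_seq(sequence)
  aa <- strsplit(sequence, "")[[1]]
  (sum(AA_AVG_MASS[aa]) + 18.0153) / 1000
}
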