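# Term-enrichment statistics: one-sided Fisher (hypergeometric tail) test
# per term, fold enrichment over expectation, Benjamini-Hochberg FDR, and
# the fold > 3 & p < 0.05 reporting filter.

#' Fisher over-representation test per annotation term
#'
#' For every term with at least one background annotation, tests whether
#' the term is over-represented in the sample relative to the background
#' using the one-sided hypergeometric tail, and reports the fold enrichment
#' `(k/n) / (K/N)` over the expected count `n*K/N`.
#'
#' @param sample Character vector of sample item ids. Items absent from the
#'   background are dropped with a warning.
#' @param annotation data.frame with columns `item` and `term` (one row per
#'   item-term association). The background is the set of distinct items.
#' @param background Optional explicit background item vector (defaults to
#'   the annotated items); unannotated background items count toward N.
#' @return data.frame (class `enrichment_result`) with `term`, `k`, `n`,
#'   `K`, `N`, `expected`, `fold`, `p_value`, `q_value`, ordered by
#'   `p_value`.
#' @export
fisher_enrich <- function(sample, annotation, background = NULL) {
  stopifnot(is.data.frame(annotation),
            all(c("item", "term") %in% names(annotation)))
  sample <- unique(as.character(sample))
  if (length(sample) == 0L) stop("empty sample", call. = FALSE)
  background <- unique(as.character(background %||% annotation$item))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  missing_items <- setdiff(sample, background)
  if (length(missing_items) > 0L) {
    warning(sprintf("%d sample item(s) absent from the background were dropped",
                    length(missing_items)))
    sample <- intersect(sample, background)
    if (length(sample) == 0L) stop("no sample items in background", call. = FALSE)
  }
  annotation <- annotation[annotation$item %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(sample)
  terms <- sort(unique(annotation$term))
  rows <- lapply(terms, function(tm) {
    items <- unique(annotation$item[annotation$term == tm])
    K <- length(items)
    k <- length(intersect(items, sample))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expected <- n * K / N
    fold <- (k / n) / (K / N)
    data.frame(term = tm, k = k, n = n, K = K, N = N, expected = expected,
               fold = fold, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$term), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values (q-values) controlling the false discovery
#' rate.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values (same order as `p`).
#' @export
bh_fdr <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Reporting filter for enrichment results
#'
#' Retains terms with fold enrichment strictly greater than `fold_min` and
#' p-value strictly below `p_max` (defaults 3 and 0.05), sorted by
#' p-value.
#'
#' @param results An `enrichment_result` (or compatible data.frame with
#'   `fold` and `p_value`).
#' @param fold_min,p_max Filter thresholds.
#' @param use_q Filter on `q_value` instead of `p_value`.
#' @return Filtered, sorted data.frame.
#' @export
report_filter <- function(results, fold_min = 3, p_max = 0.05,
                          use_q = FALSE) {
  stopifnot(all(c("fold", "p_value") %in% names(results)))
  pcol <- if (use_q) results$q_value else results$p_value
  out <- results[results$fold > fold_min & pcol < p_max, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an item-term annotation table
#'
#' @param file Two-column TSV (`item <TAB> term`), no header by default.
#' @param header Logical.
#' @return data.frame with columns `item`, `term`.
#' @export
read_annotation <- function(file, header = FALSE) {
  tab <- utils::read.delim(file, header = header, stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("item", "term")
  tab[, c("item", "term")]
}
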