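# Median-of-ratios normalization of gene x tissue count matrices and
# categorization of tissue specificity (mature-anther-specific, young
# anther/bud-enriched, broadly expressed, not expressed).

#' Median-of-ratios size factors and normalization
#'
#' Per-sample size factor = median, over genes with nonzero counts in every
#' sample (the reference gene set), of the ratio of the gene's count to its
#' geometric mean across samples. Normalized counts are raw counts divided
#' by the sample's factor.
#'
#' @param counts Nonnegative gene x sample numeric matrix.
#' @param pseudo_reference With the strict method an error is raised when no
#'   gene is nonzero everywhere; with `pseudo_reference = TRUE` the
#'   geometric mean is taken over nonzero entries only and each sample's
#'   median ratio runs over its positively counted genes.
#' @return List with `size_factors` (per sample) and `normalized` (matrix).
#' @export
median_of_ratios <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (!pseudo_reference) {
    ref <- rowSums(counts == 0) == 0
    if (!any(ref)) {
      stop("no gene has nonzero counts in all samples; consider ",
           "pseudo_reference = TRUE", call. = FALSE)
    }
    geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
    sf <- apply(counts[ref, , drop = FALSE], 2, function(col)
      stats::median(col / geo))
  } else {
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    ok <- is.finite(geo) & geo > 0
    sf <- apply(counts, 2, function(col) {
      use <- ok & col > 0
      if (!any(use)) stop("a sample shares no positive gene with the ",
                          "pseudo-reference", call. = FALSE)
      stats::median(col[use] / geo[use])
    })
  }
  if (any(sf <= 0)) stop("nonpositive size factor", call. = FALSE)
  list(size_factors = sf, normalized = sweep(counts, 2, sf, `/`))
}

#' Tissue-role assignment for expression columns
#'
#' @param target Column names of the target tissues (mature/opened
#'   anthers).
#' @param auxiliary Young-flower anthers and young flower buds.
#' @param reference Tissues expected to be silent for specific genes
#'   (leaf, root apex, stigmatic tissue, carpels).
#' @return Named character vector of roles keyed by column name.
#' @export
tissue_roles <- function(target, auxiliary = character(0), reference) {
  roles <- c(stats::setNames(rep("target", length(target)), target),
             stats::setNames(rep("auxiliary", length(auxiliary)), auxiliary),
             stats::setNames(rep("reference", length(reference)), reference))
  if (anyDuplicated(names(roles))) {
    stop("a tissue may have only one role", call. = FALSE)
  }
  roles
}

#' Specificity thresholds
#'
#' @param expressed_floor Minimum normalized count for a gene to count as
#'   expressed in a tissue (default 10).
#' @param ref_fraction "Very little" expression in a reference tissue means
#'   at most this fraction of the peak signal (default 0.05).
#' @param ref_abs ...or at most this many normalized counts, whichever is
#'   larger (default 5).
#' @export
specificity_config <- function(expressed_floor = 10, ref_fraction = 0.05,
                               ref_abs = 5) {
  stopifnot(expressed_floor > 0, ref_fraction >= 0, ref_abs >= 0)
  list(expressed_floor = expressed_floor, ref_fraction = ref_fraction,
       ref_abs = ref_abs)
}

#' Categorize tissue specificity of normalized expression
#'
#' Assigns each gene exactly one label:
#' * `mature-anther-specific`: peak target signal at or above the expressed
#'   floor and every reference tissue below
#'   `max(ref_fraction * peak_target, ref_abs)`;
#' * `young-anther/bud-enriched`: otherwise, peak auxiliary signal at or
#'   above the floor with every reference tissue below the same cap
#'   relative to the overall anther/bud peak;
#' * `not-expressed`: no tissue reaches the floor;
#' * `broadly-expressed`: anything else.
#'
#' @param normalized Gene x sample matrix of normalized counts.
#' @param roles Named role vector from [tissue_roles()] covering every
#'   column.
#' @param config See [specificity_config()].
#' @return data.frame (one row per gene): `gene`, `category`, `peak_target`,
#'   `peak_auxiliary`, `max_reference`.
#' @export
classify_specificity <- function(normalized, roles,
                                 config = specificity_config()) {
  normalized <- as.matrix(normalized)
  if (is.null(rownames(normalized))) {
    rownames(normalized) <- paste0("gene", seq_len(nrow(normalized)))
  }
  if (!all(colnames(normalized) %in% names(roles))) {
    stop("missing role assignment for: ",
         paste(setdiff(colnames(normalized), names(roles)), collapse = ", "),
         call. = FALSE)
  }
  roles <- roles[colnames(normalized)]
  tcols <- roles == "target"
  acols <- roles == "auxiliary"
  rcols <- roles == "reference"
  if (!any(tcols) || !any(rcols)) {
    stop("need at least one target and one reference tissue", call. = FALSE)
  }
  peak_t <- apply(normalized[, tcols, drop = FALSE], 1, max)
  peak_a <- if (any(acols)) apply(normalized[, acols, drop = FALSE], 1, max)
    else rep(0, nrow(normalized))
  max_r <- apply(normalized[, rcols, drop = FALSE], 1, max)
  peak_all <- pmax(peak_t, peak_a,
                   apply(normalized, 1, max))
  cap_t <- pmax(config$ref_fraction * peak_t, config$ref_abs)
  cap_ta <- pmax(config$ref_fraction * pmax(peak_t, peak_a), config$ref_abs)

  category <- ifelse(peak_all < config$expressed_floor, "not-expressed",
              ifelse(peak_t >= config$expressed_floor & max_r <= cap_t,
                     "mature-anther-specific",
              ifelse(peak_a >= config$expressed_floor & max_r <= cap_ta,
                     "young-anther/bud-enriched", "broadly-expressed")))
  data.frame(gene = rownames(normalized), category = category,
             peak_target = peak_t, peak_auxiliary = peak_a,
             max_reference = max_r, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a count matrix with a tissue-role header
#'
#' Expects a TSV whose first line is a comment of the form
#' `#roles<TAB>target<TAB>reference...` aligned with the data columns,
#' followed by a regular header and gene rows.
#'
#' @param file Path.
#' @return List with `counts` matrix and `roles` vector.
#' @export
read_expression_matrix <- function(file) {
  first <- readLines(file, n = 1L)
  if (!startsWith(first, "#roles")) {
    stop("first line must be a '#roles' comment", call. = FALSE)
  }
  roles_raw <- strsplit(first, "\t")[[1]][-1]
  tab <- utils::read.delim(file, comment.char = "#", row.names = 1,
                           check.names = FALSE)
  if (length(roles_raw) != ncol(tab)) {
    stop("role header does not match column count", call. = FALSE)
  }
  list(counts = as.matrix(tab),
       roles = stats::setNames(roles_raw, colnames(tab)))
}
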