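#' @useDynLib pollencrp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Amino-acid alphabet accepted in protein sequences: the 20 standard residues
# plus the ambiguity letter X.
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_VALID <- c(AA_ALPHABET20, "X")

#' Parse a cysteine-spacing pattern notation string
#'
#' Parses the compact notation used to describe conserved cysteine skeletons
#' of small cysteine-rich proteins (CRPs): `C` marks a conserved cysteine,
#' `X` any non-cysteine residue, a literal run of k `X`s a spacer of exactly
#' k residues, `X(a)` a spacer of exactly a residues, and `X(a-b)` a spacer
#' of a to b residues. Adjacent `CC` denotes a zero-length spacer.
#'
#' One typographic variant is normalized before parsing: `C(a-b)C` is read as
#' `CX(a-b)C` (a bracket can only quantify a spacer, never a cysteine). When
#' this normalization fires it is recorded in the `normalized` field.
#'
#' @param text Notation string, e.g. `"CXXXXCX(7-8)CXCCX(6-8)CX(6)CXXXC"`.
#' @param class_id Family label carried on the result.
#' @param species_tag Source row label (or `"envelope"` for merged patterns).
#' @return An object of class `crp_pattern` with fields `class_id`,
#'   `species_tag`, `n_cys`, `spacers` (an (n_cys-1) x 2 integer matrix of
#'   min/max residue counts), `source_text`, and `normalized`.
#' @examples
#' p <- parse_pattern("CXXXXCX(7-8)CXCCX(6-8)CX(6)CXXXC", "PCP-B", "A.thaliana")
#' p$n_cys        # 8
#' p$spacers[2, ] # 7 8
#' @export
parse_pattern <- function(text, class_id = NA_character_,
                          species_tag = NA_character_) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  src <- text
  normalized <- grepl("C\\(", text)
  text <- gsub("C(", "CX(", text, fixed = TRUE)

  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  cys <- 0L
  spacers <- list()
  # pending spacer between the previous C and the next C; NULL means the next
  # C is adjacent to the previous one
  pending <- NULL
  seen_first_c <- FALSE
  i <- 1L
  fail <- function(msg, at) {
    stop(sprintf("pattern parse error at offset %d of %s: %s", at, sQuote(src),
                 msg), call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "C") {
      if (seen_first_c) {
        spacers[[length(spacers) + 1L]] <-
          if (is.null(pending)) c(0L, 0L) else pending
      }
      seen_first_c <- TRUE
      pending <- NULL
      i <- i + 1L
    } else if (ch == "X") {
      if (!seen_first_c) fail("spacer before first cysteine", i)
      if (!is.null(pending)) fail("two spacer tokens between one cysteine pair", i)
      run <- 0L
      while (i <= n && chars[i] == "X") {
        run <- run + 1L
        i <- i + 1L
      }
      if (i <= n && chars[i] == "(") {
        if (run > 1L) fail("bracket after a multi-X run is ambiguous", i)
        close <- i
        while (close <= n && chars[close] != ")") close <- close + 1L
        if (close > n) fail("unbalanced bracket", i)
        body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
        m <- regmatches(body, regexec("^([0-9]+)(-([0-9]+))?$", body))[[1]]
        if (length(m) == 0L) fail(sprintf("non-numeric range %s", sQuote(body)), i)
        lo <- as.integer(m[2])
        hi <- if (nzchar(m[4])) as.integer(m[4]) else lo
        if (lo > hi) fail(sprintf("min > max in range %s", sQuote(body)), i)
        pending <- c(lo, hi)
        i <- close + 1L
      } else {
        pending <- c(run, run)
      }
    } else {
      fail(sprintf("unexpected character %s", sQuote(ch)), i)
    }
  }
  if (!seen_first_c) fail("no cysteine in pattern", 1L)
  if (!is.null(pending)) fail("pattern ends in a spacer (must end with C)", n)
  cys <- length(spacers) + 1L
  if (cys < 2L) fail("pattern must contain at least two cysteines", n)
  sp <- do.call(rbind, spacers)
  colnames(sp) <- c("min", "max")
  structure(list(class_id = class_id, species_tag = species_tag,
                 n_cys = cys, spacers = sp, source_text = src,
                 normalized = normalized),
            class = "crp_pattern")
}

#' Render a parsed cysteine pattern back to notation
#'
#' Produces a canonical notation string: exact spacers of up to five residues
#' are written as literal `X` runs, longer exact spacers as `X(a)`, and
#' ranges as `X(a-b)`. Re-parsing the rendered string recovers an identical
#' spacer structure.
#'
#' @param pattern A `crp_pattern`.
#' @return Notation string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "crp_pattern"))
  sp <- pattern$spacers
  out <- "C"
  for (k in seq_len(nrow(sp))) {
    lo <- sp[k, 1]
    hi <- sp[k, 2]
    tok <- if (lo == hi) {
      if (lo == 0L) "" else if (lo <= 5L) strrep("X", lo) else sprintf("X(%d)", lo)
    } else {
      sprintf("X(%d-%d)", lo, hi)
    }
    out <- paste0(out, tok, "C")
  }
  out
}

#' @export
print.crp_pattern <- function(x, ...) {
  cat(sprintf("<crp_pattern> %s [%s]: %d cysteines\n  %s\n",
              x$class_id, x$species_tag, x$n_cys, render_pattern(x)))
  invisible(x)
}

#' Cysteine skeleton of a protein sequence
#'
#' Positions of every cysteine in order, with the count of intervening
#' non-cysteine residues to the next cysteine.
#'
#' @param sequence Residue string (20-letter alphabet plus X).
#' @return data.frame with columns `pos` (0-based cysteine position) and
#'   `gap` (residues to the next cysteine; NA for the last).
#' @examples
#' cys_skeleton("ACAAACA") # pos 1,5; gap 3,NA
#' @export
cys_skeleton <- function(sequence) {
  check_protein_seq(sequence)
  pos <- as.integer(gregexpr("C", sequence, fixed = TRUE)[[1]])
  if (length(pos) == 1L && pos[1] == -1L) {
    return(data.frame(pos = integer(0), gap = integer(0)))
  }
  pos0 <- pos - 1L
  gap <- c(diff(pos0) - 1L, NA_integer_)
  data.frame(pos = pos0, gap = gap)
}

check_protein_seq <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence", call. = FALSE)
  bad <- setdiff(strsplit(sequence, "")[[1]], AA_VALID)
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue letter(s): %s",
                 paste(sQuote(unique(bad)), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Match a cysteine-spacing pattern against a sequence
#'
#' A match anchors on `n_cys` consecutive cysteines of the sequence skeleton
#' whose successive inter-cysteine gaps each lie within the pattern's spacer
#' ranges. Spacers are cysteine-free by construction (gaps are counted
#' between consecutive skeleton cysteines), matching the convention that `X`
#' excludes cysteine. Cysteines outside the matched span do not invalidate a
#' match.
#'
#' @param pattern A `crp_pattern`.
#' @param sequence Residue string.
#' @return data.frame with one row per match: `start`, `end` (0-based,
#'   half-open, spanning first to last matched cysteine) and `gaps` (list
#'   column with the observed spacer vector).
#' @export
match_pattern <- function(pattern, sequence) {
  stopifnot(inherits(pattern, "crp_pattern"))
  skel <- cys_skeleton(sequence)
  nc <- pattern$n_cys
  res <- data.frame(start = integer(0), end = integer(0))
  res$gaps <- list()
  if (nrow(skel) < nc) return(res)
  gaps <- skel$gap
  sp <- pattern$spacers
  hits <- list()
  for (a in seq_len(nrow(skel) - nc + 1L)) {
    g <- gaps[a:(a + nc - 2L)]
    if (all(g >= sp[, 1] & g <= sp[, 2])) {
      hits[[length(hits) + 1L]] <-
        list(start = skel$pos[a], end = skel$pos[a + nc - 1L] + 1L, gaps = g)
    }
  }
  if (length(hits) == 0L) return(res)
  out <- data.frame(start = vapply(hits, `[[`, integer(1), "start"),
                    end = vapply(hits, `[[`, integer(1), "end"))
  out$gaps <- lapply(hits, `[[`, "gaps")
  out
}

#' Merge per-species patterns into a class envelope
#'
#' The envelope takes, per spacer position, the minimum of the minima and the
#' maximum of the maxima, so it accepts every sequence any input pattern
#' accepts.
#'
#' @param patterns List of `crp_pattern`s with equal `n_cys`.
#' @return A `crp_pattern` tagged `species_tag = "envelope"`.
#' @export
build_envelope <- function(patterns) {
  stopifnot(is.list(patterns), length(patterns) >= 1L,
            all(vapply(patterns, inherits, logical(1), "crp_pattern")))
  ncys <- vapply(patterns, `[[`, integer(1), "n_cys")
  if (length(unique(ncys)) != 1L) {
    stop("cannot merge patterns with unequal cysteine counts: ",
         paste(ncys, collapse = ", "), call. = FALSE)
  }
  sp <- patterns[[1]]$spacers
  for (p in patterns[-1]) {
    sp[, 1] <- pmin(sp[, 1], p$spacers[, 1])
    sp[, 2] <- pmax(sp[, 2], p$spacers[, 2])
  }
  env <- patterns[[1]]
  env$species_tag <- "envelope"
  env$spacers <- sp
  env$source_text <- NA_character_
  env$source_text <- render_pattern(env)
  env
}

#' Load CRP class definitions
#'
#' Reads a plain-text class configuration (tab-separated columns `class_id`,
#' `species`, `n_crps`, `size_min`, `size_max`, `subgroups`, `pattern`, with
#' the cysteine patterns in notation form) and builds, per class, the parsed
#' per-species patterns plus a merged envelope. The default file ships the
#' five pollen-coat CRP families of Arabidopsis thaliana, Arabidopsis lyrata
#' and Brassica oleracea.
#'
#' @param file Path to the TSV config; default the shipped definition.
#' @return Named list of `crp_classdef` objects, each with `class_id`,
#'   `patterns` (per species), `envelope`, `size_range`, `subgroup_ids`.
#' @export
crp_class_defs <- function(file = system.file("extdata", "crp_classes.tsv",
                                              package = "pollencrp")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  needed <- c("class_id", "species", "size_min", "size_max", "subgroups",
              "pattern")
  if (!all(needed %in% names(tab))) {
    stop("class config must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  defs <- lapply(split(tab, tab$class_id), function(rows) {
    pats <- lapply(seq_len(nrow(rows)), function(i) {
      parse_pattern(rows$pattern[i], rows$class_id[i], rows$species[i])
    })
    names(pats) <- rows$species
    structure(list(class_id = rows$class_id[1],
                   patterns = pats,
                   envelope = build_envelope(pats),
                   size_range = c(min(rows$size_min), max(rows$size_max)),
                   subgroup_ids = unique(unlist(strsplit(rows$subgroups, ","))),
                   n_crps_reported = if ("n_crps" %in% names(rows))
                     sum(rows$n_crps) else NA_integer_),
              class = "crp_classdef")
  })
  defs[unique(tab$class_id)]
}

#' Classification configuration
#'
#' @param max_length Size filter: sequences longer than this many residues
#'   are not matched (the shipped families span 52-265 residues).
#' @param use_envelope Match the merged class envelope (default) rather than
#'   requiring a specific species row.
#' @return List of settings.
#' @export
crp_classify_config <- function(max_length = 300L, use_envelope = TRUE) {
  max_length <- as.integer(max_length)
  if (is.na(max_length) || max_length < 1L) {
    stop("max_length must be a positive integer", call. = FALSE)
  }
  list(max_length = max_length, use_envelope = isTRUE(use_envelope))
}

# Deterministic primary-class tie rule: more matched cysteines first, then
# the more specific pattern (smaller total spacer-range width), then a fixed
# class order.
CLASS_TIE_ORDER <- c("PCP-B", "SCRL", "GASA", "nsLTP", "PCP-A/DEFL/LCR")

#' Classify one protein sequence into CRP families
#'
#' Applies the size filter, matches every class pattern (envelope by
#' default), and selects a primary class by a deterministic tie rule: more
#' matched cysteines win; then the smaller total spacer-range width (the more
#' specific pattern); then the fixed order PCP-B, SCRL, GASA, nsLTP,
#' PCP-A/DEFL/LCR, followed by any other class ids alphabetically.
#'
#' @param sequence Residue string.
#' @param defs List of `crp_classdef` (default the shipped families).
#' @param config See [crp_classify_config()].
#' @param id Optional accession carried through to the result.
#' @return Object of class `crp_classification`: list with `protein_id`,
#'   `matches` (data.frame class_id/start/end/gaps), `primary_class`
#'   (`"unclassified"` when nothing matches) and `reasons`.
#' @export
classify_protein <- function(sequence, defs = crp_class_defs(),
                             config = crp_classify_config(),
                             id = NA_character_) {
  stopifnot(length(defs) >= 1L)
  check_protein_seq(sequence)
  len <- nchar(sequence)
  reasons <- character(0)
  matches <- data.frame(class_id = character(0), start = integer(0),
                        end = integer(0))
  matches$gaps <- list()
  primary <- "unclassified"
  if (len > config$max_length) {
    reasons <- sprintf("size-filter: length %d > %d", len, config$max_length)
  } else if (!grepl("C", sequence, fixed = TRUE)) {
    reasons <- "no-cysteine"
  } else {
    rows <- list()
    for (def in defs) {
      pats <- if (config$use_envelope) list(def$envelope) else def$patterns
      for (p in pats) {
        m <- match_pattern(p, sequence)
        if (nrow(m) > 0L) {
          m$class_id <- def$class_id
          rows[[length(rows) + 1L]] <- m
        }
      }
    }
    if (length(rows) > 0L) {
      matches <- do.call(rbind, rows)
      matches <- matches[, c("class_id", "start", "end", "gaps")]
      matches <- matches[!duplicated(matches[c("class_id", "start", "end")]), ]
      cand <- unique(matches$class_id)
      key <- lapply(cand, function(cl) {
        def <- defs[[which(vapply(defs, `[[`, character(1), "class_id") == cl)]]
        p <- if (config$use_envelope) def$envelope else def$patterns[[1]]
        rank <- match(cl, CLASS_TIE_ORDER)
        if (is.na(rank)) rank <- length(CLASS_TIE_ORDER) + 1L
        c(-p$n_cys, sum(p$spacers[, 2] - p$spacers[, 1]), rank)
      })
      ord <- do.call(order, as.data.frame(do.call(rbind, key)))
      cand_sorted <- cand[ord]
      # alphabetical fallback among classes beyond the fixed order
      primary <- cand_sorted[1]
    } else {
      reasons <- "no-pattern-match"
    }
  }
  structure(list(protein_id = id, matches = matches, primary_class = primary,
                 reasons = reasons, length = len),
            class = "crp_classification")
}

#' Classify a FASTA file (or AAStringSet) of proteins
#'
#' @param fasta Path to a protein FASTA file, or a
#'   [Biostrings::AAStringSet-class].
#' @param defs,config As in [classify_protein()].
#' @return data.frame with one row per protein: `protein_id`, `length`,
#'   `primary_class`, `n_matches`, `match_classes`, `span_start`, `span_end`
#'   (1-based inclusive coordinates of the primary match; NA when
#'   unclassified), `skeleton` (dash-joined observed spacers) and `reason`.
#' @export
classify_fasta <- function(fasta, defs = crp_class_defs(),
                           config = crp_classify_config()) {
  seqs <- if (inherits(fasta, "AAStringSet")) fasta else {
    Biostrings::readAAStringSet(fasta)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  res <- lapply(seq_along(seqs), function(i) {
    classify_protein(as.character(seqs[[i]]), defs, config, id = ids[i])
  })
  summarize_classification(res)
}

summarize_classification <- function(results) {
  rows <- lapply(results, function(r) {
    prim <- r$matches[r$matches$class_id == r$primary_class, , drop = FALSE]
    if (r$primary_class != "unclassified" && nrow(prim) > 0L) {
      data.frame(protein_id = r$protein_id, length = r$length,
                 primary_class = r$primary_class,
                 n_matches = nrow(r$matches),
                 match_classes = paste(unique(r$matches$class_id),
                                       collapse = ";"),
                 span_start = prim$start[1] + 1L, span_end = prim$end[1],
                 skeleton = paste(prim$gaps[[1]], collapse = "-"),
                 reason = "", stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = r$protein_id, length = r$length,
                 primary_class = "unclassified", n_matches = 0L,
                 match_classes = "", span_start = NA_integer_,
                 span_end = NA_integer_, skeleton = "",
                 reason = paste(r$reasons, collapse = "; "),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Per-class summary report of a classification table
#'
#' @param classified data.frame from [classify_fasta()] (or
#'   `summarize_classification`).
#' @param defs Class definitions; classes with zero assignments are reported
#'   as zero rows.
#' @return data.frame with `class_id`, `n_proteins`, `size_min`, `size_max`.
#'   Counts sum to the number of classified proteins.
#' @export
generate_report <- function(classified, defs = crp_class_defs()) {
  class_ids <- vapply(defs, `[[`, character(1), "class_id")
  rows <- lapply(class_ids, function(cl) {
    sub <- classified[classified$primary_class == cl, , drop = FALSE]
    data.frame(class_id = cl, n_proteins = nrow(sub),
               size_min = if (nrow(sub)) min(sub$length) else NA_integer_,
               size_max = if (nrow(sub)) max(sub$length) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  uncl <- classified[classified$primary_class == "unclassified", , drop = FALSE]
  rbind(out, data.frame(class_id = "unclassified", n_proteins = nrow(uncl),
                        size_min = if (nrow(uncl)) min(uncl$length) else NA_integer_,
                        size_max = if (nrow(uncl)) max(uncl$length) else NA_integer_))
}
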