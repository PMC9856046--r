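test_that("pattern notation parses to the expected spacer structure", {
  p <- parse_pattern("CXXXXCX(7-8)CXCCX(6-8)CX(6)CXXXC", "PCP-B", "A.thaliana")
  expect_equal(p$n_cys, 8L)
  expect_equal(unname(p$spacers[, 1]), c(4, 7, 1, 0, 6, 6, 3))
  expect_equal(unname(p$spacers[, 2]), c(4, 8, 1, 0, 8, 6, 3))

  gasa <- parse_pattern("CXXXCXXXCX(8)CXXXCXXCCXXCX(1-2)CX(11)CXCX(12)C",
                        "GASA", "A.thaliana")
  expect_equal(gasa$n_cys, 12L)

  cc <- parse_pattern("CC")
  expect_equal(cc$n_cys, 2L)
  expect_equal(unname(cc$spacers[1, ]), c(0, 0))
})

test_that("typo normalization reads C(a-b)C as CX(a-b)C and is recorded", {
  p <- parse_pattern("CX(7-16)CX(4-8)CXXXCX(9-16)CX(4-13)CXC(1-8)C",
                     "PCP-A/DEFL/LCR", "A.lyrata")
  expect_equal(p$n_cys, 8L)
  expect_true(p$normalized)
  expect_equal(unname(p$spacers[7, ]), c(1, 8))
  expect_false(parse_pattern("CXC")$normalized)
})

test_that("malformed notation fails with an informative offset", {
  expect_error(parse_pattern("CX(4-2)C"), "min > max")
  expect_error(parse_pattern("CX(4C"), "unbalanced")
  expect_error(parse_pattern("CX(a)C"), "non-numeric")
  expect_error(parse_pattern("CXZC"), "unexpected character")
  expect_error(parse_pattern("CXX"), "must end with C")
  expect_error(parse_pattern("XXC"), "before first cysteine")
})

test_that("parse-render round trip is the identity on all shipped patterns", {
  defs <- crp_class_defs()
  pats <- unlist(lapply(defs, `[[`, "patterns"), recursive = FALSE)
  expect_length(pats, 15L)
  for (p in pats) {
    p2 <- parse_pattern(render_pattern(p), p$class_id, p$species_tag)
    expect_equal(p2$n_cys, p$n_cys)
    expect_equal(unname(p2$spacers), unname(p$spacers))
  }
  # conserved cysteine counts implied by the printed patterns
  ncys <- vapply(defs, function(d) d$envelope$n_cys, integer(1))
  expect_equal(unname(ncys[c("PCP-A/DEFL/LCR", "PCP-B", "SCRL", "nsLTP",
                             "GASA")]), c(8L, 8L, 8L, 8L, 12L))
})

test_that("cysteine skeleton enumerates positions and gaps", {
  sk <- cys_skeleton("ACAAACA")
  expect_equal(sk$pos, c(1L, 5L))
  expect_equal(sk$gap, c(3L, NA))
  expect_equal(nrow(cys_skeleton("AAAA")), 0L)
  expect_equal(cys_skeleton("CCC")$gap, c(0L, 0L, NA))
  expect_error(cys_skeleton("AB1"), "invalid residue")
})

test_that("pattern matching anchors on consecutive skeleton cysteines", {
  cc <- parse_pattern("CC")
  m <- match_pattern(cc, "ACCA")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 3L))

  # a gap outside the spacer range kills the match
  p <- parse_pattern("CXXC")  # spacer (3,3)
  expect_equal(nrow(match_pattern(p, "ACAAAAAC")), 0L)

  p24 <- parse_pattern("CX(2-4)C")
  expect_equal(nrow(match_pattern(p24, "CAAAAAC")), 0L)  # gap 5
  expect_equal(nrow(match_pattern(p24, "CAAAC")), 1L)    # gap 3
})

test_that("single-cysteine substitution destroys a constructed match", {
  defs <- crp_class_defs()
  pat <- defs[["PCP-B"]]$patterns[["A.thaliana"]]
  set.seed(42)
  sim <- gen_crp_proteins(defs["PCP-B"], n_per_class = 5, seed = 42,
                          species = "A.thaliana")
  pos <- sim[sim$type == "positive", ]
  ko <- sim[sim$type == "knockout", ]
  for (s in pos$sequence) expect_gte(nrow(match_pattern(pat, s)), 1L)
  for (s in ko$sequence) expect_equal(nrow(match_pattern(pat, s)), 0L)
})

test_that("envelope merging takes the interval hull and stays sound", {
  a <- parse_pattern("CXXXXC")          # (4,4)
  b <- parse_pattern("CX(3-5)C")        # (3,5)
  env <- build_envelope(list(a, b))
  expect_equal(unname(env$spacers[1, ]), c(3, 5))
  expect_equal(unname(build_envelope(list(a, a))$spacers[1, ]), c(4, 4))
  expect_error(build_envelope(list(a, parse_pattern("CCC"))),
               "unequal cysteine counts")

  # envelope accepts whatever any per-species pattern accepts
  defs <- crp_class_defs()
  for (cl in names(defs)) {
    env <- defs[[cl]]$envelope
    sim <- gen_crp_proteins(defs[cl], n_per_class = 6, seed = 7,
                            knockouts = FALSE)
    for (i in seq_len(nrow(sim))) {
      sp_pat <- defs[[cl]]$patterns[[sim$species[i]]]
      expect_gte(nrow(match_pattern(sp_pat, sim$sequence[i])), 1L)
      expect_gte(nrow(match_pattern(env, sim$sequence[i])), 1L)
    }
  }
})

test_that("classification applies size filter, tie rule and reasons", {
  defs <- crp_class_defs()
  # cysteine-free
  r <- classify_protein("AAAAGGGL", defs)
  expect_equal(r$primary_class, "unclassified")
  expect_match(r$reasons, "no-cysteine")
  # over the size filter
  long <- paste(rep("A", 301), collapse = "")
  r <- classify_protein(long, defs)
  expect_match(r$reasons, "size-filter")
  expect_error(crp_classify_config(max_length = 0), "positive integer")
  # generated PCP-B protein gets PCP-B primary
  sim <- gen_crp_proteins(defs["PCP-B"], n_per_class = 3, seed = 3,
                          knockouts = FALSE)
  for (s in sim$sequence) {
    expect_equal(classify_protein(s, defs)$primary_class, "PCP-B")
  }
})

test_that("report counts equal planted labels and empty input yields zeros", {
  defs <- crp_class_defs()
  sim <- gen_crp_proteins(defs, n_per_class = 4, seed = 11, knockouts = FALSE)
  seqs <- Biostrings::AAStringSet(setNames(sim$sequence, sim$id))
  tab <- classify_fasta(seqs, defs)
  rep <- generate_report(tab, defs)
  for (cl in names(defs)) {
    expect_equal(rep$n_proteins[rep$class_id == cl], sum(sim$class_id == cl))
  }
  empty <- generate_report(tab[0, , drop = FALSE], defs)
  expect_true(all(empty$n_proteins == 0L))
})

test_that("fasta round trip through a temporary file works", {
  defs <- crp_class_defs()
  sim <- gen_crp_proteins(defs["SCRL"], n_per_class = 2, seed = 9,
                          knockouts = FALSE)
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", sim$id, "\n", sim$sequence), fa)
  tab <- classify_fasta(fa, defs)
  expect_equal(tab$primary_class, rep("SCRL", 2))
  expect_true(all(tab$span_start >= 1 & tab$span_end <= tab$length))
})
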