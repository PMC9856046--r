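test_that("median-of-ratios size factors satisfy the defining formula", {
  # identical columns: all factors 1
  m <- matrix(rep(c(5, 10, 20), 3), ncol = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  mor <- median_of_ratios(m)
  expect_equal(unname(mor$size_factors), rep(1, 3))

  # doubling one column doubles its factor relative to the others (the
  # geometric-mean reference absorbs a global 2^(1/3))
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  sf2 <- unname(median_of_ratios(m2)$size_factors)
  expect_equal(sf2[2] / sf2[1], 2)
  expect_equal(sf2[3], sf2[1])
  norm2 <- median_of_ratios(m2)$normalized
  expect_equal(unname(norm2[, 2] / norm2[, 1]), rep(1, 3))

  # random matrix against the direct formula
  set.seed(51)
  r <- matrix(rnbinom(300, mu = 100, size = 3) + 1L, ncol = 5)
  got <- median_of_ratios(r)
  geo <- exp(rowMeans(log(r)))
  sf <- apply(r, 2, function(col) median(col / geo))
  expect_lt(max(abs(got$size_factors - sf)), 1e-10)
  expect_lt(max(abs(got$normalized - sweep(r, 2, sf, `/`))), 1e-10)
})

test_that("median-of-ratios agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  # odd gene count: the median needs no interpolation, so the linear-space
  # median of ratios coincides with DESeq2's log-space median exactly
  set.seed(52)
  m <- matrix(rnbinom(606, mu = 80, size = 4) + 1L, ncol = 6)
  ours <- median_of_ratios(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("strict mode requires an all-nonzero reference gene", {
  m <- matrix(c(0, 5, 3, 0, 2, 8), ncol = 3)
  expect_error(median_of_ratios(m), "pseudo_reference")
  out <- median_of_ratios(m, pseudo_reference = TRUE)
  expect_true(all(out$size_factors > 0))
  expect_error(median_of_ratios(-m), "negative")
})

test_that("specificity categories follow the documented rules", {
  roles <- tissue_roles(target = c("anther_open", "anther_mature"),
                        auxiliary = "anther_young",
                        reference = c("leaf", "root", "stigma"))
  mat <- rbind(
    specific = c(100, 150, 10, 0, 0, 0),
    leaky_ok = c(200, 180, 20, 5, 9, 0),    # refs under max(5% * 200, 5) = 10
    leaky_bad = c(200, 180, 20, 30, 0, 0),  # ref 30 > 10
    young = c(1, 2, 80, 0, 3, 1),
    broad = c(50, 60, 55, 45, 50, 40),
    silent = c(0, 0, 0, 0, 0, 0),
    low = c(4, 3, 2, 1, 0, 0))
  colnames(mat) <- names(roles)
  got <- classify_specificity(mat, roles)
  expect_equal(got$category, c("mature-anther-specific",
                               "mature-anther-specific",
                               "broadly-expressed",
                               "young-anther/bud-enriched",
                               "broadly-expressed",
                               "not-expressed",
                               "not-expressed"))
  expect_error(classify_specificity(mat, roles[-1]), "missing role")
})

test_that("categorization is invariant to global rescaling", {
  gen <- gen_expression_matrix(seed = 53)
  norm <- median_of_ratios(gen$counts, pseudo_reference = TRUE)$normalized
  c1 <- classify_specificity(norm, gen$roles)
  c2 <- classify_specificity(norm * 1, gen$roles,
                             specificity_config(expressed_floor = 10,
                                                ref_fraction = 0.05, ref_abs = 5))
  c3 <- classify_specificity(norm * 3, gen$roles,
                             specificity_config(expressed_floor = 30,
                                                ref_fraction = 0.05, ref_abs = 15))
  expect_equal(c1$category, c2$category)
  expect_equal(c1$category, c3$category)
})

test_that("planted specific genes are recovered after normalization", {
  gen <- gen_expression_matrix(n_broad = 120, n_specific = 25, n_young = 12,
                               n_silent = 8, leakage = 0, seed = 54)
  norm <- median_of_ratios(gen$counts, pseudo_reference = TRUE)$normalized
  got <- classify_specificity(norm, gen$roles)
  truth <- gen$truth$category
  spec_idx <- truth == "mature-anther-specific"
  # zero leakage: planted specific genes classified exactly
  expect_equal(mean(got$category[spec_idx] == "mature-anther-specific"), 1)
  expect_equal(mean(got$category[truth == "not-expressed"] == "not-expressed"), 1)
  # nothing else claims anther specificity
  expect_equal(sum(got$category == "mature-anther-specific"), sum(spec_idx))
})

test_that("count matrices round trip through the role-header TSV format", {
  gen <- gen_expression_matrix(n_broad = 10, n_specific = 2, n_young = 1,
                               n_silent = 1, seed = 55)
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("#roles", unname(gen$roles)), collapse = "\t"),
               paste(c("gene", colnames(gen$counts)), collapse = "\t"),
               vapply(seq_len(nrow(gen$counts)), function(i)
                 paste(c(rownames(gen$counts)[i], gen$counts[i, ]),
                       collapse = "\t"), character(1))), f)
  rt <- read_expression_matrix(f)
  expect_equal(unname(rt$counts), unname(gen$counts))
  expect_equal(unname(rt$roles), unname(gen$roles))
})
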