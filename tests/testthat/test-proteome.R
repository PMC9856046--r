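test_that("target-decoy FDR matches the worked example and boundary cases", {
  rec <- data.frame(score = c(10, 8, 6, 4, 9, 3),
                    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  out <- psm_fdr(rec)
  # FDR at threshold 8 is 1 decoy / 2 targets = 0.5; the q-value rides the
  # better cutoff at 4 (1/4)
  expect_equal(out$fdr[out$score == 8], 0.25)
  expect_equal(out$fdr[out$score == 10], 0)
  expect_equal(out$fdr[out$score == 3], 0.5)

  # no decoys: everything high confidence
  nd <- psm_fdr(data.frame(score = rnorm(10), is_decoy = FALSE))
  expect_true(all(nd$fdr == 0) && all(nd$tier == "high"))

  # all decoys outrank all targets: everything excluded
  ad <- psm_fdr(data.frame(score = c(1, 2, 10, 11),
                           is_decoy = c(FALSE, FALSE, TRUE, TRUE)))
  expect_true(all(ad$tier[!ad$is_decoy] == "excluded"))
  expect_error(psm_fdr(data.frame(score = 1, is_decoy = TRUE)), "no target")
})

test_that("q-values match an exhaustive sweep oracle and are monotone", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    rec <- data.frame(score = round(rnorm(n), 2),
                      is_decoy = runif(n) < 0.4)
    if (!any(!rec$is_decoy)) rec$is_decoy[1] <- FALSE
    out <- psm_fdr(rec)
    expect_lt(max(abs(out$fdr - sweep_q_oracle(rec$score, rec$is_decoy))),
              1e-10)
    o <- order(out$score)
    expect_true(all(diff(out$fdr[o]) <= 1e-12))
  }
})

test_that("tier boundaries sit exactly at 1% and 5%", {
  rec <- data.frame(score = c(3, 2, 1), is_decoy = FALSE)
  out <- psm_fdr(rec)
  out$fdr <- c(0.01, 0.05, 0.0500001)
  tier <- ifelse(out$fdr <= 0.01, "high",
                 ifelse(out$fdr <= 0.05, "medium", "excluded"))
  expect_equal(tier, c("high", "medium", "excluded"))
  # pseudocount variant shifts estimates up
  rec2 <- data.frame(score = c(5, 4), is_decoy = c(FALSE, TRUE))
  expect_gte(psm_fdr(rec2, pseudocount = TRUE)$fdr[1],
             psm_fdr(rec2)$fdr[1])
})

test_that("replicate merging uses union semantics with replicate counts", {
  reps <- list(r1 = data.frame(protein_id = c("A", "B"), area = c(1, 2)),
               r2 = data.frame(protein_id = c("B", "C"), area = c(3, 4)),
               r3 = data.frame(protein_id = c("C", "D"), area = c(5, 6)))
  m <- merge_replicates(reps)
  expect_equal(nrow(m), 4L)
  expect_equal(m$n_replicates[m$protein_id %in% c("B", "C")], c(2L, 2L))
  expect_equal(sum(m$rel_abundance), 100, tolerance = 1e-6)
  expect_equal(m$rel_abundance[m$protein_id == "B"], 100 * 5 / 21)

  # single replicate is the identity on ids
  single <- merge_replicates(reps["r1"])
  expect_equal(single$protein_id, c("A", "B"))

  # merge is order-invariant
  m2 <- merge_replicates(reps[c(3, 1, 2)])
  expect_equal(m$protein_id, m2$protein_id)
  expect_equal(m$area, m2$area)

  # in-replicate duplicates collapse with summed area
  expect_message(
    dup <- merge_replicates(list(r = data.frame(protein_id = c("A", "A"),
                                                area = c(1, 2)))),
    "collapsed")
  expect_equal(dup$area, 3)
})

test_that("size profile fractions the weights into the standard bins", {
  p <- size_profile(c(10, 15, 25), edges = 20)
  expect_equal(p$fraction, c(2 / 3, 1 / 3))
  p4 <- size_profile(c(5, 19.9, 20, 45, 61, 300))
  expect_equal(p4$bin, c("<20", "20-40", "40-60", ">=60"))
  expect_equal(sum(p4$fraction), 1)
  expect_equal(p4$n, c(2L, 1L, 1L, 2L))
  expect_equal(size_profile(c(30, 31), edges = 20)$fraction, c(0, 1))
  expect_error(size_profile(numeric(0)))
  # random panel against a counting oracle
  set.seed(32)
  w <- rlnorm(500, 3, 1)
  p <- size_profile(w)
  expect_equal(p$n[1], sum(w < 20))
  expect_equal(p$n[4], sum(w >= 60))
})

test_that("overlap report counts pairwise and k-way regions correctly", {
  disj <- overlap_report(list(a = 1:3, b = 4:6))
  expect_equal(disj$pairwise["a", "b"], 0L)
  same <- overlap_report(list(a = 1:5, b = 1:5))
  expect_equal(same$pairwise["a", "b"], 5L)
  expect_equal(same$regions$n_exclusive[same$regions$subset == "a&b"], 5)

  set.seed(33)
  sets <- list(x = sample(1:30, 15), y = sample(1:30, 12), z = sample(1:30, 9))
  rep <- overlap_report(sets)
  expect_equal(rep$pairwise["x", "y"], length(intersect(sets$x, sets$y)))
  full <- rep$regions$n_intersection[rep$regions$subset == "x&y&z"]
  expect_equal(full, length(Reduce(intersect, sets)))
  # exclusive regions partition the universe
  expect_equal(sum(rep$regions$n_exclusive), length(unique(unlist(sets))))
})

test_that("molecular weight from sequence lands in the expected range", {
  w <- protein_mw("ACDEFGHIKLMNPQRSTVWY")
  expect_gt(w, 2); expect_lt(w, 3)   # a 20-mer weighs roughly 2.4 kDa
  expect_gt(protein_mw(strrep("K", 200)), 20)
})
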