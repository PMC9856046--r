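test_that("M8 with the positive-class weight at zero reproduces the M7 likelihood", {
  tr <- fixture_tree(5, seed = 12)
  sim <- sim_codon_alignment(tr, 60, list(type = "M7", p = 0.4, q = 1.1),
                             seed = 13)
  f <- rep(1 / 61, 61)
  d <- discretize_beta(0.4, 1.1, 10)
  ll_m7 <- sum(site_loglik(tr, sim$aln, list(kappa = 2, freqs = f,
                                             omegas = d$omega,
                                             weights = d$weight)))
  ll_m8_null <- sum(site_loglik(tr, sim$aln, list(
    kappa = 2, freqs = f,
    omegas = c(d$omega, 5), weights = c(1 * d$weight, 0))))
  expect_equal(ll_m8_null, ll_m7, tolerance = 1e-6)
})

test_that("M0 recovers the generating omega and kappa on one replicate", {
  tr <- fixture_tree(8, seed = 14, bl = c(0.1, 0.4))
  sim <- sim_codon_alignment(tr, 300, list(type = "M0", omega = 0.3),
                             kappa = 2, seed = 15)
  fit <- fit_model("M0", sim$aln, tr,
                   site_model_config(freqs = "equal", n_starts = 1))
  expect_false(fit$convergence$flagged)
  expect_lt(abs(fit$params$model[["omega"]] - 0.3), 0.1)
  expect_lt(abs(fit$params$kappa - 2), 0.6)
})

test_that("an alignment of identical sequences is flagged unidentifiable", {
  tr <- fixture_tree(4, seed = 16)
  seqs <- setNames(rep(paste(rep("ATG", 20), collapse = ""), 4), tr$tip.label)
  aln <- codon_alignment(seqs)
  fit <- suppressWarnings(
    fit_model("M0", aln, tr, site_model_config(freqs = "equal", n_starts = 1)))
  expect_true(fit$convergence$flagged)
  expect_match(paste(fit$convergence$reasons, collapse = " "),
               "unidentifiable")
})

test_that("the LRT clamps at zero, uses df = 2 for the beta pairs, and stars follow the legend", {
  mk <- function(model, lnl, nfree) {
    structure(list(model_id = model, lnL = lnl, n_free = nfree,
                   convergence = list(flagged = FALSE)),
              class = "site_model_fit")
  }
  r <- lrt(mk("M7", -100, 3), mk("M8", -100, 5))
  expect_equal(r$stat, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2L)
  # alternative numerically below the null clamps to zero
  r <- lrt(mk("M7", -100, 3), mk("M8", -100.000001, 5))
  expect_equal(r$stat, 0)
  # star tiers at 0.05 / 0.001 / 0.0001
  expect_equal(lrt(mk("M1a", -50, 4), mk("M2a", -46, 6))$stars, "*")
  stat_to_fits <- function(s) list(mk("M7", -100, 3), mk("M8", -100 + s / 2, 5))
  expect_equal(do.call(lrt, stat_to_fits(16))$stars, "**")
  expect_equal(do.call(lrt, stat_to_fits(30))$stars, "***")
  expect_error(lrt(mk("M0", -10, 2), mk("M8", -9, 5)), "not nested")
})

test_that("fit_table collates fits and attaches matching LRT rows", {
  tr <- fixture_tree(5, seed = 17)
  sim <- sim_codon_alignment(tr, 50, list(type = "M0", omega = 0.4), seed = 18)
  cfg <- site_model_config(freqs = "equal", n_starts = 1)
  f0 <- fit_model("M0", sim$aln, tr, cfg)
  f7 <- fit_model("M7", sim$aln, tr, cfg, m0_fit = f0)
  f8 <- fit_model("M8", sim$aln, tr, cfg, m0_fit = f0)
  expect_gte(f8$lnL, f7$lnL - 1e-4)
  tab <- fit_table(list(f0, f7, f8), list(lrt(f7, f8)))
  expect_equal(tab$model, c("M0", "M7", "M8"))
  expect_false(is.na(tab$p_value[tab$model == "M8"]))
  expect_true(is.na(tab$p_value[tab$model == "M7"]))
})

test_that("the nearly-neutral pair fits and orders correctly", {
  tr <- fixture_tree(5, seed = 26)
  sim <- sim_codon_alignment(tr, 60, list(type = "discrete",
                                          omegas = c(0.1, 1),
                                          weights = c(0.6, 0.4)), seed = 27)
  cfg <- site_model_config(freqs = "equal", n_starts = 1)
  f0 <- fit_model("M0", sim$aln, tr, cfg)
  f1 <- fit_model("M1a", sim$aln, tr, cfg, m0_fit = f0)
  f2 <- fit_model("M2a", sim$aln, tr, cfg, m0_fit = f0)
  expect_equal(f1$n_categories, 2L)
  expect_equal(f2$n_categories, 3L)
  expect_gte(f2$lnL, f1$lnL - 1e-4)
  r <- lrt(f1, f2)
  expect_equal(r$df, 2L)
  expect_gte(r$p_value, 0)
  # neutral data: no positive-selection signal
  expect_gt(r$p_value, 0.001)
})
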