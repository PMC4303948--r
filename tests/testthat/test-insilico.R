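# perturbation experiments on a fitted (here: true-parameter) toy circuit

test_that("regulatory weights behave as the normalized RSS change", {
  gt <- get_toy(1)
  # a zero-strength site (TF concentration always 0 cannot happen here, so
  # use an appended site with negligible llr): w_r must be ~0
  m2 <- gt$model
  extra <- m2$regions$g1$sites[1, ]
  extra$start <- 1400; extra$end <- extra$start + (extra$end - extra$start)
  extra$llr <- extra$llr - 60  # strength suppressed by exp(-60)
  m2$regions$g1$sites <- rbind(m2$regions$g1$sites, extra)
  w0 <- regulatory_weight(m2, gt$params_true, gt$dataset, gt$grid,
                          gt$external_inputs, gene = "g1",
                          site = nrow(m2$regions$g1$sites))
  expect_equal(w0, 0, tolerance = 1e-6)
  expect_error(
    regulatory_weight(gt$model, gt$params_true, gt$dataset, gt$grid,
                      gt$external_inputs, gene = "g1", site = 999),
    "not found")
  # arithmetic contract: RSS_mut = 2 RSS_ref gives w_r = -1
  expect_equal((10 - 20) / 10, -1)
})

test_that("the site weight report identifies the dominant activator", {
  gt <- get_toy(1)
  rep_ <- site_weight_report(gt$model, gt$params_true, gt$dataset, gt$grid,
                             gt$external_inputs)
  expect_s3_class(rep_, "site_weight_report")
  expect_equal(nrow(rep_), sum(vapply(gt$model$regions,
                                      function(r) nrow(r$sites),
                                      integer(1))))
  expect_true(all(rep_$w_r <= 1))
  # with true parameters the reference fit is near the noise floor, so
  # removing any real site can only worsen it: weights skew negative
  expect_gt(mean(rep_$w_r < 0.001), 0.5)
  # consensus actA activator sites on g1 carry the largest impact among
  # g1-region activator sites
  g1a <- rep_[rep_$gene == "g1" & rep_$tf == "actA", ]
  expect_gt(max(abs(g1a$w_r)), 0)
})

test_that("the removal curve starts at 1 and degrades the model", {
  gt <- get_toy(1)
  rep_ <- site_weight_report(gt$model, gt$params_true, gt$dataset, gt$grid,
                             gt$external_inputs)
  curve <- ranked_removal_curve(gt$model, gt$params_true, gt$dataset,
                                gt$grid, gt$external_inputs, report = rep_)
  expect_equal(nrow(curve), nrow(rep_) + 1L)
  expect_equal(curve$relative_rss[1], 1)
  # removing every site (including all activators) must leave the model
  # worse than the reference
  expect_gt(curve$relative_rss[nrow(curve)], 1)
})

test_that("mutant simulation knocks out synthesis and reproduces wild type otherwise", {
  gt <- get_toy(1)
  wt <- simulate_circuit(gt$model, gt$params_true, gt$external_inputs,
                         gt$grid)
  # no knockout, same inputs: bit-identical to wild type
  same <- simulate_mutant(gt$model, gt$params_true, gene = NULL,
                          external_inputs = gt$external_inputs,
                          grid = gt$grid)
  expect_identical(same$v, wt$v)
  # g1 null: its own products identically zero...
  mut <- simulate_mutant(gt$model, gt$params_true, gene = "g1",
                         external_inputs = gt$external_inputs,
                         grid = gt$grid)
  expect_true(all(mut$u[mut$gene == "g1"] == 0))
  expect_true(all(mut$v[mut$gene == "g1"] == 0))
  # ...and the known repressive edge g1 -| g2 means g2 rises anteriorly
  fin <- max(wt$time)
  g2_wt <- wt$v[wt$gene == "g2" & wt$time == fin]
  g2_mut <- mut$v[mut$gene == "g2" & mut$time == fin]
  expect_gt(mean(g2_mut[1:10] - g2_wt[1:10]), 0)
  expect_error(simulate_mutant(gt$model, gt$params_true, gene = "nope",
                               grid = gt$grid), "unknown gene")
})

test_that("reporter constructs are driven by CRE-restricted site sets", {
  gt <- get_toy(1)
  model <- gt$model
  n <- nchar(model$regions$g1$sequence)
  model$regions$g1$cres <- list(whole = c(0, n),
                                empty = c(n - 2, n),
                                anterior_cluster = c(0, 600))
  # inputs for all TFs: external activator plus simulated gap proteins,
  # sampled densely so linear interpolation tracks the feedback closely
  dense_t <- seq(0, gt$grid$t_end, by = 0.5)
  wt_dense <- simulate_circuit(model, gt$params_true, gt$external_inputs,
                               gt$grid, out_times = dense_t)
  wt <- simulate_circuit(model, gt$params_true, gt$external_inputs, gt$grid)
  gap_profiles <- data.frame(gene = wt_dense$gene, time = wt_dense$time,
                             nucleus = wt_dense$nucleus, conc = wt_dense$v)
  # cycle-13 rows must be at cycle-14 resolution for input profiles
  c13 <- gap_profiles[gap_profiles$time < gt$grid$t_mitosis, ]
  c13a <- c13; c13a$nucleus <- 2 * c13$nucleus - 1
  c13b <- c13; c13b$nucleus <- 2 * c13$nucleus
  inputs <- rbind(as.data.frame(gt$external_inputs)[
    c("gene", "time", "nucleus", "conc")],
    gap_profiles[gap_profiles$time >= gt$grid$t_mitosis, ], c13a, c13b)

  # CRE covering the whole region: the reporter reproduces the endogenous
  # solution driven by the same (frozen) inputs
  rep_whole <- simulate_reporter(model, gt$params_true, "g1", "whole",
                                 inputs, gt$grid)
  endo <- wt[wt$gene == "g1", ]
  expect_equal(rep_whole$v, endo$v, tolerance = 0.02)
  # empty CRE: basal-only solution, far below the driven one
  rep_empty <- simulate_reporter(model, gt$params_true, "g1", "empty",
                                 inputs, gt$grid)
  fin <- max(wt$time)
  expect_lt(max(rep_empty$v[rep_empty$time == fin]),
            max(endo$v[endo$time == fin]) / 2)
  # the anterior activator cluster drives an anterior-peaked reporter
  rep_ant <- simulate_reporter(model, gt$params_true, "g1",
                               "anterior_cluster", inputs, gt$grid)
  v_fin <- rep_ant$v[rep_ant$time == fin]
  expect_lte(which.max(v_fin), 3)
  expect_error(simulate_reporter(model, gt$params_true, "g1", "nope",
                                 inputs, gt$grid), "unknown CRE")
})

test_that("topology classification counts signs across networks", {
  genes <- c("g1", "g2"); tfs <- c("a", "b")
  mk <- function(tvals) circuit_params(genes, tfs,
                                       T = matrix(tvals, 2, 2, byrow = TRUE),
                                       q_btm = 0.1, K = 0.01, omega = 1,
                                       d_r = 100, tau = 1, lambda_u = 0.1,
                                       lambda_v = 0.1)
  # single network, all positive
  tp <- classify_topology(list(mk(c(1, 2, 3, 4))))
  expect_true(all(tp$n_positive == 1 & tp$n_negative == 0))
  expect_true(all(tp$consensus == "activation"))
  # counts sum to the number of networks when no zeros; zeros in neither
  fits <- list(mk(c(1, -2, 0, 4)), mk(c(2, -1, -1, 4)), mk(c(-1, -3, 2, 4)))
  tp2 <- classify_topology(fits)
  expect_true(all(tp2$n_positive + tp2$n_negative <= 3))
  r_ab <- tp2[tp2$gene == "g1" & tp2$tf == "b", ]
  expect_equal(r_ab$n_negative, 3)
  expect_equal(r_ab$consensus, "repression")
  r_za <- tp2[tp2$gene == "g2" & tp2$tf == "a", ]
  expect_equal(r_za$n_positive + r_za$n_negative, 2L)  # one zero entry
})

test_that("weight-score correlation handles exact and null cases", {
  w <- data.frame(w_r = 1:10, llr = 1:10)
  out <- weight_vs_llr_correlation(w)
  expect_equal(out$spearman$rho, 1)
  expect_equal(out$pearson$r, 1)
  anti <- data.frame(w_r = 1:10, llr = 10:1)
  expect_equal(weight_vs_llr_correlation(anti)$spearman$rho, -1)
  # independent weights and scores: |rho| small for n = 500
  set.seed(23)
  null <- data.frame(w_r = rnorm(500), llr = rnorm(500))
  expect_lt(abs(weight_vs_llr_correlation(null)$spearman$rho), 0.15)
  expect_error(weight_vs_llr_correlation(w[1:2, ]), "at least 3")
  expect_error(weight_vs_llr_correlation(
    data.frame(w_r = rep(1, 5), llr = 1:5)), "degenerate")
})
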