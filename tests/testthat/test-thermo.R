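# thermodynamic occupancy layer

simple_params <- function(t_row, d_r = 100, d_coop = 50, q_btm = 0.1,
                          K = NULL, omega = NULL) {
  tfs <- names(t_row)
  if (is.null(K)) K <- stats::setNames(rep(0.01, length(tfs)), tfs)
  if (is.null(omega)) omega <- stats::setNames(rep(1, length(tfs)), tfs)
  thermo_params("g", t_row, K, omega, repression_range = d_r,
                coop_range = d_coop, q_btm = q_btm)
}

one_site <- function(tf, start = 10, llr = 5) {
  data.frame(tf = tf, start = start, end = start + 10, strand = "+",
             word = "N", llr = llr, stringsAsFactors = FALSE)
}

test_that("site strength follows q = K * v * exp(llr - llr_max)", {
  p <- simple_params(c(hb = 5), K = c(hb = 0.005731))
  s <- list(tf = "hb", llr = 8)
  # strongest site at concentration 100: q = K * v
  expect_equal(site_strength(s, p, 100, llr_max = 8), 0.5731)
  # zero concentration
  expect_equal(site_strength(s, p, 0, llr_max = 8), 0)
  # a site ln 2 below the strongest has half the strength
  s2 <- list(tf = "hb", llr = 8 - log(2))
  expect_equal(site_strength(s2, p, 100, llr_max = 8), 0.5731 / 2)
  expect_error(site_strength(s, p, -1, llr_max = 8), "negative")
})

test_that("configuration weights multiply strengths, cooperativity and beta", {
  p <- simple_params(c(A = 3, R = -7), q_btm = 0.1,
                     omega = c(A = 5, R = 1))
  sites <- rbind(one_site("A", 0), one_site("A", 20), one_site("R", 300))
  conc <- c(A = 100, R = 50)
  lm_ <- c(A = 5, R = 5)
  q <- c(1, 1, 0.5)  # K*v at llr_max
  # empty configuration: W = 1, Q = q_btm
  w0 <- config_weight(list(bound = integer(0), effective = integer(0)),
                      sites, p, conc, lm_)
  expect_equal(w0$W, 1)
  expect_equal(w0$Q, 0.1)
  # one bound activator: W = q, Q = q_btm * alpha
  w1 <- config_weight(list(bound = 1L, effective = integer(0)), sites, p,
                      conc, lm_)
  expect_equal(w1$W, q[1])
  expect_equal(w1$Q, 0.1 * 3)
  # two same-TF sites 10 bp apart with omega = 5, d_coop = 50
  w2 <- config_weight(list(bound = c(1L, 2L), effective = integer(0)),
                      sites, p, conc, lm_)
  expect_equal(w2$W, q[1] * q[2] * 5)
  expect_equal(w2$Q, 0.1 * 9)
  # effective repressor multiplies beta into W, contributes nothing to Q
  w3 <- config_weight(list(bound = 3L, effective = 3L), sites, p, conc, lm_)
  expect_equal(w3$W, q[3] * 7)
  expect_equal(w3$Q, 0.1)
  # invalid configurations are rejected
  expect_error(config_weight(list(bound = c(1L, 2L), effective = 1L),
                             sites, p, conc, lm_), "repressor")
  overlapping <- rbind(one_site("A", 0), one_site("A", 5))
  expect_error(config_weight(list(bound = c(1L, 2L), effective = integer(0)),
                             overlapping, p, conc, lm_), "overlap")
})

test_that("brute-force activation matches hand enumeration", {
  p <- simple_params(c(A = 3), q_btm = 0.1)
  # zero sites: E = q_btm / (1 + q_btm)
  e0 <- activation_brute_force(one_site("A")[0, ], p, c(A = 0), c(A = 5))
  expect_equal(e0, 0.1 / 1.1)
  # one activator: 2 configurations
  q <- 0.01 * 100
  e1 <- activation_brute_force(one_site("A"), p, c(A = 100), c(A = 5))
  expect_equal(e1, (0.1 + q * 0.1 * 3) / (0.1 + q * 0.1 * 3 + 1 + q))
  # enumerating too many sites is refused
  many <- do.call(rbind, lapply(0:16, function(i) one_site("A", i * 20)))
  expect_error(activation_brute_force(many, p, c(A = 1), c(A = 5)),
               "refused")
})

test_that("a strong repressor in range lowers activation", {
  p_off <- simple_params(c(A = 10, R = -1e-9), d_r = 100)
  p_on <- simple_params(c(A = 10, R = -1e4), d_r = 100)
  sites <- rbind(one_site("A", 0, llr = 5), one_site("R", 40, llr = 5))
  conc <- c(A = 100, R = 100)
  lm_ <- c(A = 5, R = 5)
  e_off <- activation_brute_force(sites, p_off, conc, lm_)
  e_on <- activation_brute_force(sites, p_on, conc, lm_)
  expect_lt(e_on, e_off)
})

test_that("DP equals brute force and the independent-binding product form", {
  for (i in 1:40) {
    inst <- random_thermo_instance(seed = 1000 + i, max_sites = 9L)
    e_bf <- activation_brute_force(inst$sites, inst$params, inst$conc,
                                   inst$llr_max)
    e_dp <- activation_dp(inst$sites, inst$params, inst$conc, inst$llr_max)
    expect_equal(e_dp, e_bf, tolerance = 1e-12)
    expect_gte(e_dp, 0)
    expect_lte(e_dp, 1)
  }
  # with omega = 1, d_R = 0 and non-overlapping sites the closed-form
  # product oracle applies
  set.seed(99)
  for (i in 1:20) {
    tfs <- c("A", "R")
    p <- simple_params(c(A = runif(1, 0, 50), R = -runif(1, 0, 50)),
                       d_r = 0, q_btm = runif(1, 0.01, 0.5))
    n <- sample(1:8, 1)
    start <- (0:(n - 1)) * 30
    sites <- data.frame(tf = sample(tfs, n, TRUE), start = start,
                        end = start + 10, strand = "+", word = "N",
                        llr = runif(n, 0, 5))
    conc <- c(A = runif(1, 0, 100), R = runif(1, 0, 100))
    lm_ <- c(A = 5, R = 5)
    e_prod <- activation_product_form(sites, p, conc, lm_)
    e_dp <- activation_dp(sites, p, conc, lm_)
    expect_equal(e_dp, e_prod, tolerance = 1e-12)
  }
})

test_that("zero-strength sites are neutral and E is monotone in T", {
  inst <- random_thermo_instance(seed = 77, max_sites = 8L)
  e_ref <- activation_dp(inst$sites, inst$params, inst$conc, inst$llr_max)
  # appending a zero-concentration TF site leaves E unchanged
  extra <- inst$sites[1, ]
  extra$start <- 450; extra$end <- 460
  conc0 <- inst$conc; conc0[extra$tf] <- 0
  sites2 <- rbind(inst$sites, extra)
  e_ref0 <- activation_dp(inst$sites, inst$params, conc0, inst$llr_max)
  e_with <- activation_dp(sites2, inst$params, conc0, inst$llr_max)
  expect_equal(e_with, e_ref0, tolerance = 1e-12)
  # raising an activator strength raises E; deepening a repressor lowers it
  p_up <- inst$params; p_up$t_row["A1"] <- p_up$t_row["A1"] * 2 + 1
  expect_gte(activation_dp(inst$sites, p_up, inst$conc, inst$llr_max),
             e_ref - 1e-9)
  p_dn <- inst$params; p_dn$t_row["R1"] <- p_dn$t_row["R1"] * 2 - 1
  expect_lte(activation_dp(inst$sites, p_dn, inst$conc, inst$llr_max),
             e_ref + 1e-9)
})

test_that("the DP scales to hundreds of sites", {
  set.seed(5)
  n <- 200L
  start <- sort(sample(0:5000, n))
  tfs <- c("A1", "A2", "R1")
  sites <- data.frame(tf = sample(tfs, n, TRUE), start = start,
                      end = start + 8, strand = "+", word = "N",
                      llr = runif(n, 0, 6))
  p <- thermo_params("g", c(A1 = 20, A2 = 10, R1 = -30),
                     stats::setNames(rep(0.01, 3), tfs),
                     stats::setNames(c(2, 1, 1), tfs),
                     repression_range = 100, coop_range = 50, q_btm = 0.05)
  tm <- system.time(
    e <- activation_dp(sites, p, c(A1 = 50, A2 = 50, R1 = 50),
                       stats::setNames(rep(6, 3), tfs)))
  expect_lt(tm[["elapsed"]], 1)
  expect_gte(e, 0)
  expect_lte(e, 1)
})
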