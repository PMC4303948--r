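# shared fixtures: all built in code, deterministic under fixed seeds

## a peaked 3-position PWM with consensus ACG
test_pwm <- function(tf = "toy", threshold = NULL) {
  p <- pwm(matrix(c(8, 0, 0, 0,
                    0, 8, 0, 0,
                    0, 0, 8, 0), ncol = 4, byrow = TRUE), tf)
  if (!is.null(threshold)) p$threshold <- threshold
  p
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random thermodynamic instance: mixed activators/repressors, overlaps
## allowed, cooperativity on/off; small enough for the brute-force oracle
random_thermo_instance <- function(seed, max_sites = 12L) {
  set.seed(seed)
  tfs <- c("A1", "A2", "R1")
  # activator weights alpha > 1 (an alpha below 1 would repress the basal
  # machinery directly, which is outside the model's activator semantics)
  t_row <- c(A1 = runif(1, 1, 80), A2 = runif(1, 1, 80),
             R1 = -runif(1, 0, 200))
  if (runif(1) < 0.3) t_row["A2"] <- 0  # occasional "no interaction"
  params <- thermo_params(
    "g", t_row = t_row,
    affinity = stats::setNames(runif(3, 1e-4, 0.05), tfs),
    cooperativity = stats::setNames(c(1, 1, 1) + (runif(1) < 0.5) * runif(3, 0, 4),
                                    tfs),
    repression_range = runif(1, 0, 150),
    coop_range = sample(c(0, 50, 100), 1L),
    q_btm = runif(1, 0.01, 0.5))
  n <- sample.int(max_sites, 1L)
  start <- sort(sample(0:400, n))
  w <- sample(5:12, n, replace = TRUE)
  sites <- data.frame(tf = sample(tfs, n, replace = TRUE), start = start,
                      end = start + w, strand = "+", word = "N",
                      llr = runif(n, 0, 8), stringsAsFactors = FALSE)
  conc <- stats::setNames(runif(3, 0, 200), tfs)
  llr_max <- stats::setNames(rep(8, 3), tfs)
  list(sites = sites, params = params, conc = conc, llr_max = llr_max)
}

## single-gene, zero-site model: constant activation E = q_btm/(1+q_btm)
constant_e_model <- function(R_u = 10, R_v = 0.1, D_u = 0, D_v = 0,
                             lambda_u = 0.2, lambda_v = 0.1, tau = 0,
                             q_btm = 0.25) {
  region <- regulatory_region("g", "ACGT")
  model <- gap_model("g", "g", regions = list(g = region),
                     llr_max = c(g = 1), R_u = c(g = R_u), R_v = c(g = R_v),
                     D_u = c(g = D_u), D_v = c(g = D_v))
  params <- circuit_params("g", "g", T = matrix(0, 1, 1), q_btm = q_btm,
                           K = 0.01, omega = 1, d_r = 100, tau = tau,
                           lambda_u = lambda_u, lambda_v = lambda_v)
  list(model = model, params = params)
}

## cached toy ground truth so the expensive acceptance fixtures are built
## once per test run
toy_cache <- new.env(parent = emptyenv())
get_toy <- function(seed = 1L) {
  key <- paste0("gt", seed)
  if (is.null(toy_cache[[key]])) toy_cache[[key]] <- synth_ground_truth(seed)
  toy_cache[[key]]
}
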