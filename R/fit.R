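#' Differential evolution minimizer
#'
#' DE with binomial crossover: each generation every population member is
#' challenged by a trial vector `base + F * (a - b)` (with `a`, `b` distinct
#' population members) crossed over coordinate-wise with probability `CR`
#' and clipped to bounds. The base vector is a random member
#' (classic rand/1/bin) with probability `1 - best_frac`, and the current
#' best member otherwise; `F` may be given as a range, in which case it is
#' re-drawn each generation (dither). The hybrid base choice plus dither
#' converges far faster on the rugged circuit objective than plain
#' rand/1/bin at desk-scale budgets, while retaining its exploration.
#' Deterministic for a given seed; non-finite objective values are treated
#' as `+Inf`.
#'
#' @param fn objective function of a numeric vector.
#' @param lower,upper finite bounds per coordinate.
#' @param seed RNG seed (required, for provenance).
#' @param budget maximum number of objective evaluations.
#' @param np population size; default `10 * dimension` (populations of
#'   1-2x dimension are markedly faster on the circuit fits at small
#'   budgets).
#' @param F differential weight: a scalar, or a length-2 range for
#'   per-generation dither.
#' @param CR crossover probability.
#' @param best_frac probability that a trial uses the current best member
#'   as its base vector (0 recovers rand/1/bin).
#' @param trace print progress every `trace` generations (0 = silent).
#' @return list with `par`, `value`, `n_evaluations`, `converged` (TRUE
#'   when a finite objective value was found).
#' @export
de_optimize <- function(fn, lower, upper, seed, budget = 2000L,
                        np = NULL, F = c(0.5, 1.0), CR = 0.9,
                        best_frac = 0.3, trace = 0L) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  if (is.null(np)) np <- 10L * d
  np <- max(4L, as.integer(np))
  set.seed(seed)
  evalfn <- function(x) {
    v <- suppressWarnings(fn(x))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
  }
  pop <- matrix(stats::runif(np * d, lower, upper), nrow = np, byrow = TRUE)
  vals <- apply(pop, 1L, evalfn)
  nev <- np
  gen <- 0L
  while (nev + np <= budget) {
    gen <- gen + 1L
    Fg <- if (length(F) == 2L) stats::runif(1, F[1L], F[2L]) else F
    bi <- which.min(vals)
    for (i in seq_len(np)) {
      idx <- sample(setdiff(seq_len(np), i), 3L)
      base <- if (stats::runif(1) < best_frac) pop[bi, ] else pop[idx[1L], ]
      trial <- base + Fg * (pop[idx[2L], ] - pop[idx[3L], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1L)] <- TRUE
      trial[!cross] <- pop[i, !cross]
      trial <- pmin(pmax(trial, lower), upper)
      tv <- evalfn(trial)
      nev <- nev + 1L
      if (tv <= vals[i]) {
        pop[i, ] <- trial
        vals[i] <- tv
      }
    }
    if (trace > 0L && gen %% trace == 0L) {
      message(sprintf("DE gen %d: best %.6g (%d evals)", gen, min(vals), nev))
    }
  }
  best <- which.min(vals)
  list(par = stats::setNames(pop[best, ], names(lower)), value = vals[best],
       n_evaluations = nev, converged = is.finite(vals[best]))
}

## objective closure over the packed parameter vector (reference path,
## assembling a full tidy trajectory per evaluation)
circuit_objective <- function(model, data, grid, external_inputs, template,
                              weights = c(1, 5e4, 1e-3), v_init = NULL,
                              penalty_norm = "squared_sum") {
  force(model); force(data); force(grid); force(external_inputs)
  function(x) {
    params <- unpack_params(x, template)
    traj <- tryCatch(
      simulate_circuit(model, params, external_inputs, grid, v_init = v_init),
      error = function(e) NULL)
    if (is.null(traj)) return(Inf)
    sc <- tryCatch(
      score_fit(traj, data, params, weights = weights,
                penalty_norm = penalty_norm),
      error = function(e) NULL)
    if (is.null(sc)) return(Inf)
    sc$error
  }
}

## fast objective: identical value to circuit_objective (checked in the
## tests) but with every static structure - site tables, external-input
## array, observation index map, wPGP pattern groups - precomputed once,
## so each evaluation is one C++ call plus vector arithmetic
fast_circuit_objective <- function(model, data, grid, external_inputs,
                                   template, weights = c(1, 5e4, 1e-3),
                                   v_init = NULL,
                                   penalty_norm = "squared_sum") {
  genes <- model$genes; tfs <- model$tfs
  ng <- length(genes)
  n13 <- grid$n_nuclei_c13; n14 <- grid$n_nuclei_c14
  ct <- class_times(grid)
  out_times <- ct$time
  ext_tfs <- tfs[is.na(model$tf_source)]
  ext <- build_ext_array(external_inputs, ext_tfs, n14)
  tf_ext <- rep(-1L, length(tfs))
  tf_ext[is.na(model$tf_source)] <- seq_along(ext_tfs) - 1L
  site_tab <- lapply(genes, function(g) {
    s <- model$regions[[g]]$sites
    s <- s[order(s$start, s$end), , drop = FALSE]
    list(tf = match(s$tf, tfs) - 1L, tf_name = s$tf,
         start = as.numeric(s$start), end = as.numeric(s$end),
         mid = site_midpoints(s),
         efac = exp(s$llr - as.numeric(model$llr_max[s$tf])))
  })
  zero_init <- matrix(0, ng, n13)
  if (is.null(v_init)) v_init <- zero_init
  u_init <- zero_init

  ## observation index map into the (gene, out_time, nucleus) output array
  gi <- match(data$gene, genes)
  oi <- match(data$time_class, ct$time_class)
  if (anyNA(gi) || anyNA(oi)) stop("observation outside the model grid")
  col <- ifelse(ct$cycle[oi] == 13L, 2L * data$nucleus - 1L, data$nucleus)
  idx <- cbind(gi, oi, col)
  r <- data$conc
  rmax <- r_max(data)
  groups <- split(seq_along(r), paste(data$gene, data$time_class))
  D_u <- model$D_u; D_v <- model$D_v
  R_u <- as.numeric(model$R_u); R_v <- as.numeric(model$R_v)

  function(x) {
    params <- unpack_params(x, template)
    qbase <- lapply(site_tab, function(st) {
      as.numeric(params$K[st$tf_name]) * st$efac
    })
    res <- tryCatch(
      cpp_simulate(lapply(site_tab, `[[`, "tf"),
                   lapply(site_tab, `[[`, "start"),
                   lapply(site_tab, `[[`, "end"),
                   lapply(site_tab, `[[`, "mid"), qbase,
                   params$T[genes, tfs, drop = FALSE],
                   as.numeric(params$omega[tfs]),
                   as.numeric(params$d_r[genes]), params$d_coop,
                   as.numeric(params$q_btm[genes]), R_u, R_v, D_u, D_v,
                   as.numeric(params$lambda_u[genes]),
                   as.numeric(params$lambda_v[genes]),
                   as.numeric(params$tau[genes]),
                   as.integer(model$tf_source) - 1L, tf_ext, ext$arr,
                   as.integer(ext$dim), ext$times, grid$t_mitosis,
                   grid$t_end, grid$dt, n13, u_init, v_init, out_times),
      error = function(e) NULL)
    if (is.null(res)) return(Inf)
    p <- res$v[idx]
    RSS <- sum((p - r)^2)
    W <- mean(vapply(groups, function(i) {
      wpgp_pattern(p[i], r[i], rmax, penalty_norm)
    }, numeric(1L)))
    weights[1L] * RSS + weights[2L] * W + weights[3L] * sum(params$T^2)
  }
}

#' Fit a gap gene circuit by differential evolution
#'
#' Minimizes the combined objective (RSS + weighted pattern generating
#' potential + regulatory-magnitude penalty) over the packed free-parameter
#' vector.
#'
#' @param model a [gap_model()].
#' @param data an [expression_dataset()] of target-gene protein
#'   observations.
#' @param grid a [simulation_grid()].
#' @param external_inputs external TF profiles (see [simulate_circuit()]).
#' @param template a [circuit_params()] giving names and `d_coop`; defaults
#'   to a neutral template over the model's genes/TFs.
#' @param bounds list with `lower`/`upper` as from [default_bounds()].
#' @param seed RNG seed (required).
#' @param budget maximum objective evaluations.
#' @param np DE population size (default `10 * dimension`).
#' @param weights combined-error weights.
#' @param v_init initial protein state (see [simulate_circuit()]).
#' @param trace DE progress trace interval.
#' @param log_affinity search the strictly positive multiplicative blocks
#'   (affinities `K` and basal weights `q_btm`) on a log10 scale (default
#'   TRUE). Affinities span orders of magnitude and trade off
#'   multiplicatively against the regulatory strengths; sampling them
#'   uniformly on a linear scale wastes most of the population on one
#'   decade. The reported parameters are always on the natural scale.
#' @param ... further DE settings passed to [de_optimize()] (`F`, `CR`,
#'   `best_frac`).
#' @return a `fit_result`: list with `params` ([circuit_params()]),
#'   `error`, `rss`, `rms`, `wpgp`, `penalty`, `seed`, `n_evaluations`,
#'   `converged`.
#' @export
fit_circuit <- function(model, data, grid, external_inputs = NULL,
                        template = NULL, bounds = NULL, seed,
                        budget = 20000L, np = NULL,
                        weights = c(1, 5e4, 1e-3), v_init = NULL,
                        trace = 0L, log_affinity = TRUE, ...) {
  if (is.null(template)) {
    template <- circuit_params(model$genes, model$tfs,
                               T = matrix(0, length(model$genes),
                                          length(model$tfs)),
                               q_btm = 0.1, K = 0.01, omega = 1, d_r = 100,
                               tau = 1, lambda_u = 0.1, lambda_v = 0.1)
  }
  if (is.null(bounds)) bounds <- default_bounds(model$genes, model$tfs)
  obj <- fast_circuit_objective(model, data, grid, external_inputs, template,
                                weights = weights, v_init = v_init)
  lower <- bounds$lower; upper <- bounds$upper
  nm <- names(lower)
  logblk <- startsWith(nm, "K[") | startsWith(nm, "q_btm[")
  if (log_affinity && any(logblk)) {
    lower[logblk] <- log10(lower[logblk])
    upper[logblk] <- log10(upper[logblk])
    obj_nat <- obj
    obj <- function(x) {
      x[logblk] <- 10^x[logblk]
      obj_nat(x)
    }
  }
  de <- de_optimize(obj, lower, upper, seed = seed,
                    budget = budget, np = np, trace = trace, ...)
  if (log_affinity && any(logblk)) de$par[logblk] <- 10^de$par[logblk]
  params <- unpack_params(de$par, template)
  traj <- simulate_circuit(model, params, external_inputs, grid,
                           v_init = v_init)
  sc <- score_fit(traj, data, params, weights = weights)
  structure(list(params = params, error = sc$error, rss = sc$rss,
                 rms = sc$rms, wpgp = sc$wpgp, penalty = sc$penalty,
                 seed = seed, n_evaluations = de$n_evaluations,
                 converged = de$converged),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Circuit fit (seed %s): error %.4g, rss %.4g, rms %.4g, wPGP %.4g, %d evaluations\n",
    format(x$seed), x$error, x$rss, x$rms, x$wpgp, x$n_evaluations))
  invisible(x)
}

#' k-fold cross-validation of the fitting procedure
#'
#' Partitions the observations at random into `k` near-equal subsets, fits
#' the circuit on each training complement and evaluates the root mean
#' square prediction error on the held-out subset, so that every subset is
#' left out exactly once.
#'
#' @inheritParams fit_circuit
#' @param k number of folds.
#' @param seed RNG seed for both the partition and the fits.
#' @param ... passed on to [fit_circuit()] (`budget`, `np`, ...).
#' @return list with one element per fold: `fold`, `fit` (training
#'   `fit_result`), `test_rms`, `test_indices`.
#' @export
crossvalidate <- function(model, data, grid, external_inputs = NULL, k = 4L,
                          seed, ...) {
  D <- n_observations(data)
  if (k > D) stop("k exceeds the number of observations")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), D))
  lapply(seq_len(k), function(i) {
    train <- expression_dataset(data[fold != i, , drop = FALSE],
                                r_max = r_max(data))
    test <- expression_dataset(data[fold == i, , drop = FALSE],
                               r_max = r_max(data))
    fit <- fit_circuit(model, train, grid, external_inputs,
                       seed = seed + i, ...)
    traj <- simulate_circuit(model, fit$params, external_inputs, grid)
    list(fold = i, fit = fit,
         test_rms = rms(rss(traj, test), n_observations(test)),
         test_indices = which(fold == i))
  })
}

#' Shuffled-target negative control dataset
#'
#' Swaps the target expression patterns between pairs of genes (by default
#' hb with kni and Kr with gt) while leaving every other column untouched,
#' producing a "nonsense" pairing of regulatory regions and expression
#' patterns. Applying the swap twice restores the original dataset.
#'
#' @param data an [expression_dataset()].
#' @param pairs list of length-2 character vectors of gene names to swap.
#' @return the shuffled [expression_dataset()].
#' @export
make_negative_control <- function(data,
                                  pairs = list(c("hb", "kni"),
                                               c("Kr", "gt"))) {
  g <- data$gene
  for (p in pairs) {
    if (!all(p %in% g)) stop("missing gene(s): ", paste(p, collapse = ", "))
    i1 <- g == p[1L]; i2 <- g == p[2L]
    data$gene[i1] <- p[2L]
    data$gene[i2] <- p[1L]
  }
  data
}

#' Flag parameter sets with effectively switched-off TFs
#'
#' Fits to shuffled data tend to null out regulators by driving their
#' affinity constants to tiny values; parameter sets where at least
#' `n_tfs` affinities fall below `k_min` are flagged as degenerate and
#' excluded from downstream analysis.
#'
#' @param params a [circuit_params()] (or a `fit_result`).
#' @param k_min affinity threshold.
#' @param n_tfs minimum number of sub-threshold TFs to flag.
#' @return logical.
#' @export
is_degenerate_fit <- function(params, k_min = 1e-4, n_tfs = 2L) {
  if (inherits(params, "fit_result")) params <- params$params
  sum(params$K < k_min) >= n_tfs
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  x <- list(error = fit$error, rss = fit$rss, rms = fit$rms,
            wpgp = fit$wpgp, penalty = fit$penalty, seed = fit$seed,
            n_evaluations = fit$n_evaluations, converged = fit$converged,
            parameters = as.list(pack_params(fit$params)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
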