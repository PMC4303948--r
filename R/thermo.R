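#' Thermodynamic parameters for one target gene
#'
#' Bundles everything the occupancy layer needs for a single target gene:
#' the signed regulatory row of the interconnectivity matrix (positive
#' entries are activator statistical weights alpha, negative magnitudes are
#' repressor strengths beta acting by short-range repression), per-TF
#' affinity constants of the strongest site, homotypic cooperativity
#' constants, the short-range repression radius, the cooperativity distance
#' and the basal transcriptional machinery weight.
#'
#' @param target_gene gene identifier.
#' @param t_row named numeric: regulatory strength of each TF on this gene
#'   (`T^ab`); 0 means no interaction.
#' @param affinity named numeric, strictly positive: binding affinity
#'   `K(S_max)` of each TF's strongest site.
#' @param cooperativity named numeric, non-negative: homotypic cooperativity
#'   `omega` per TF.
#' @param repression_range short-range repression radius `d_R` in bp
#'   (distance from an effective repressor's midpoint within which no other
#'   TF can bind).
#' @param coop_range maximum edge-to-edge distance (bp) at which two
#'   consecutively bound same-TF sites receive the cooperativity bonus.
#' @param q_btm basal transcriptional machinery weight (> 0); with no sites
#'   bound the activation probability is `q_btm / (1 + q_btm)`.
#' @return an object of class `thermo_params`.
#' @export
thermo_params <- function(target_gene, t_row, affinity, cooperativity,
                          repression_range = 100, coop_range = 50,
                          q_btm = 0.05) {
  tfs <- names(t_row)
  if (is.null(tfs)) stop("t_row must be a named vector (one entry per TF)")
  if (!setequal(tfs, names(affinity)) || !setequal(tfs, names(cooperativity))) {
    stop("t_row, affinity and cooperativity must name the same TFs")
  }
  if (any(affinity <= 0)) stop("affinity constants must be strictly positive")
  if (any(cooperativity < 0)) stop("cooperativity must be non-negative")
  if (q_btm <= 0) stop("q_btm must be strictly positive")
  structure(list(target_gene = as.character(target_gene),
                 t_row = t_row[tfs],
                 affinity = affinity[tfs],
                 cooperativity = cooperativity[tfs],
                 repression_range = repression_range,
                 coop_range = coop_range, q_btm = q_btm),
            class = "thermo_params")
}

#' Strength of a binding site at a given TF concentration
#'
#' `q(S) = K(S_max) * v_TF * exp(LLR(S) - LLR(S_max))`: the strongest site
#' of a TF has strength `K * v`, weaker sites are discounted by the
#' exponential of their log-odds deficit.
#'
#' @param site one site: a list or one-row data.frame with `tf` and `llr`.
#' @param params a [thermo_params()] object.
#' @param v_tf TF concentration (>= 0).
#' @param llr_max maximum achievable log-odds score of the TF's PWM.
#' @return numeric site strength (>= 0).
#' @export
site_strength <- function(site, params, v_tf, llr_max) {
  if (v_tf < 0) stop("negative TF concentration")
  K <- params$affinity[[site$tf]]
  K * v_tf * exp(site$llr - llr_max)
}

## site strengths for a whole site table; concentrations and llr_max are
## named per TF
site_strengths <- function(sites, params, concentrations, llr_max) {
  if (nrow(sites) == 0L) return(numeric(0))
  v <- concentrations[sites$tf]
  if (any(v < 0)) stop("negative TF concentration")
  as.numeric(params$affinity[sites$tf]) * as.numeric(v) *
    exp(sites$llr - as.numeric(llr_max[sites$tf]))
}

site_midpoints <- function(sites) (sites$start + sites$end) / 2

#' Statistical weight of one binding configuration
#'
#' Direct evaluation of the configuration weight `W` and its interaction
#' weight with the basal machinery `Q`. `W` is the product of bound-site
#' strengths, cooperativity bonuses for consecutively bound same-TF sites
#' within the cooperativity distance, and `beta = |T|` for every effective
#' repressor. `Q` is `q_btm` times `alpha = T` for every bound activator;
#' repressors (effective or neutral) contribute nothing to `Q`.
#'
#' @param config list with `bound` (site indices) and `effective` (subset of
#'   bound repressor indices).
#' @param sites site data.frame (`tf`, `start`, `end`, `llr`).
#' @param params a [thermo_params()] object.
#' @param concentrations named TF concentrations.
#' @param llr_max named per-TF maximum achievable log-odds scores.
#' @return list with elements `W` and `Q`.
#' @export
config_weight <- function(config, sites, params, concentrations, llr_max) {
  bound <- sort(config$bound)
  eff <- config$effective
  if (!all(eff %in% bound)) stop("effective sites must be bound")
  q <- site_strengths(sites, params, concentrations, llr_max)
  alpha <- as.numeric(params$t_row[sites$tf])
  if (any(alpha[eff] >= 0)) stop("effective sites must be repressor sites")
  mid <- site_midpoints(sites)
  k <- length(bound)
  if (k > 1L) {
    b <- sites[bound, , drop = FALSE]
    if (any(b$start[-1L] < b$end[-k])) stop("bound sites overlap")
  }
  for (e in eff) {
    others <- setdiff(bound, e)
    if (any(abs(mid[others] - mid[e]) <= params$repression_range)) {
      stop("a bound site lies inside an effective repressor's range")
    }
  }
  W <- prod(q[bound])
  if (k > 1L) {
    b <- sites[bound, , drop = FALSE]
    same <- b$tf[-1L] == b$tf[-k]
    gap <- b$start[-1L] - b$end[-k]
    close <- same & gap <= params$coop_range
    if (any(close)) {
      W <- W * prod(as.numeric(params$cooperativity[b$tf[-1L][close]]))
    }
  }
  if (length(eff)) W <- W * prod(-alpha[eff])
  act <- bound[alpha[bound] > 0]
  Q <- params$q_btm * if (length(act)) prod(alpha[act]) else 1
  list(W = W, Q = Q)
}

#' Activation probability by exhaustive configuration enumeration
#'
#' Enumerates every valid binding configuration (all non-overlapping site
#' subsets, with every assignment of effective/neutral status to bound
#' repressors that respects the short-range exclusion zones), evaluates each
#' with [config_weight()], and returns
#' `E = sum(W*Q) / (sum(W*Q) + sum(W))`. Exponential cost; serves as the
#' independent oracle for [activation_dp()].
#'
#' @inheritParams config_weight
#' @param max_sites refuse instances with more sites than this.
#' @return activation probability in `[0, 1]`.
#' @export
activation_brute_force <- function(sites, params, concentrations, llr_max,
                                   max_sites = 15L) {
  n <- nrow(sites)
  if (n > max_sites) {
    stop("brute-force enumeration refused for ", n, " sites (cap ",
         max_sites, ")")
  }
  ord <- order(sites$start, sites$end)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  alpha <- as.numeric(params$t_row[sites$tf])
  num <- params$q_btm  # empty configuration: W = 1, Q = q_btm
  den <- 1
  if (n > 0L) {
    for (mask in seq_len(2^n) - 1L) {
      if (mask == 0L) next
      bound <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) != 0L)
      k <- length(bound)
      if (k > 1L &&
          any(sites$start[bound][-1L] < sites$end[bound][-k])) next
      reps <- bound[alpha[bound] < 0]
      r <- length(reps)
      for (emask in seq_len(2^r) - 1L) {
        eff <- if (r) reps[bitwAnd(emask, bitwShiftL(1L, seq_len(r) - 1L)) != 0L]
               else integer(0)
        wq <- tryCatch(
          config_weight(list(bound = bound, effective = eff), sites, params,
                        concentrations, llr_max),
          error = function(e) NULL)
        if (is.null(wq)) next  # violates an exclusion zone
        num <- num + wq$W * wq$Q
        den <- den + wq$W
      }
    }
  }
  num / (num + den)
}

#' Activation probability by dynamic programming
#'
#' Polynomial-cost evaluation of the same configuration sums as
#' [activation_brute_force()], implemented in compiled code with a recursion
#' over the last bound site. Accepts a vector of concentrations (one value
#' per TF) or a TF x condition matrix to evaluate many nuclei at once.
#'
#' @inheritParams config_weight
#' @param concentrations named TF concentration vector, or a matrix with one
#'   row per TF (rownames = TF names) and one column per condition.
#' @return activation probability, one value per condition.
#' @export
activation_dp <- function(sites, params, concentrations, llr_max) {
  tfs <- names(params$t_row)
  if (is.matrix(concentrations)) {
    conc <- concentrations[tfs, , drop = FALSE]
  } else {
    conc <- matrix(concentrations[tfs], ncol = 1L, dimnames = list(tfs, NULL))
  }
  if (any(conc < 0)) stop("negative TF concentration")
  n <- nrow(sites)
  if (n == 0L) {
    return(rep(params$q_btm / (1 + params$q_btm), ncol(conc)))
  }
  ord <- order(sites$start, sites$end)
  sites <- sites[ord, , drop = FALSE]
  tf_idx <- match(sites$tf, tfs)
  if (anyNA(tf_idx)) stop("site TF not present in parameters")
  qbase <- as.numeric(params$affinity[sites$tf]) *
    exp(sites$llr - as.numeric(llr_max[sites$tf]))
  qmat <- qbase * conc[tf_idx, , drop = FALSE]
  cpp_activation(qmat, tf_idx - 1L, as.numeric(sites$start),
                 as.numeric(sites$end), site_midpoints(sites),
                 as.numeric(params$t_row[sites$tf]),
                 as.numeric(params$cooperativity[tfs]),
                 params$repression_range, params$coop_range, params$q_btm)
}

#' Independent-binding closed form for the activation probability
#'
#' With cooperativity switched off (`omega = 1`), repression range zero and
#' mutually non-overlapping sites, every site binds independently and the
#' partition function factorizes:
#' activator sites contribute `(1 + q)` to the denominator sum and
#' `(1 + q*alpha)` to the numerator sum, repressor sites contribute
#' `(1 + q + q*beta)` to both. Used as a second, product-form oracle.
#'
#' @inheritParams config_weight
#' @return activation probability.
#' @export
activation_product_form <- function(sites, params, concentrations, llr_max) {
  q <- site_strengths(sites, params, concentrations, llr_max)
  alpha <- as.numeric(params$t_row[sites$tf])
  fn <- ifelse(alpha > 0, 1 + q * alpha, 1 + q + q * pmax(-alpha, 0))
  fz <- ifelse(alpha > 0, 1 + q, 1 + q + q * pmax(-alpha, 0))
  num <- params$q_btm * prod(fn)
  num / (num + prod(fz))
}
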