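#' Free parameters of a gap gene circuit
#'
#' The optimized parameter set of the two-layer model: the genetic
#' interconnectivity matrix `T` (one signed regulatory strength per target
#' gene x TF pair), per-gene basal machinery weights, per-TF affinity and
#' cooperativity constants, per-gene short-range repression radii,
#' protein-synthesis delays and mRNA/protein decay rates. For the standard
#' 4-gene / 8-regulator configuration this is
#' 32 + 4 + 8 + 8 + 4 + 4 + 8 = 68 free values. Diffusion coefficients and
#' synthesis rates are fixed (see [gap_model()]) and never enter the
#' vector; the cooperativity distance `d_coop` is a structural constant.
#'
#' @param genes target gene names.
#' @param tfs regulator names.
#' @param T genes x tfs matrix of regulatory strengths (positive =
#'   activator weight alpha, negative magnitude = repressor strength beta).
#' @param q_btm per-gene basal machinery weight (> 0).
#' @param K per-TF affinity constant of the strongest site (> 0).
#' @param omega per-TF homotypic cooperativity constant (>= 0).
#' @param d_r per-gene short-range repression radius (bp).
#' @param tau per-gene protein synthesis delay (minutes, >= 0).
#' @param lambda_u,lambda_v per-gene mRNA/protein decay rates (per minute).
#' @param d_coop cooperativity distance in bp (fixed, not optimized).
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(genes, tfs, T, q_btm, K, omega, d_r, tau,
                           lambda_u, lambda_v, d_coop = 50) {
  ng <- length(genes); ntf <- length(tfs)
  T <- matrix(as.numeric(T), ng, ntf, dimnames = list(genes, tfs))
  named <- function(x, nm) {
    x <- rep_len(as.numeric(x), length(nm)); names(x) <- nm; x
  }
  q_btm <- named(q_btm, genes); K <- named(K, tfs); omega <- named(omega, tfs)
  if (any(q_btm <= 0) || any(K <= 0)) {
    stop("q_btm and K must be strictly positive")
  }
  if (any(omega < 0)) stop("cooperativity must be non-negative")
  structure(list(genes = genes, tfs = tfs, T = T, q_btm = q_btm, K = K,
                 omega = omega, d_r = named(d_r, genes),
                 tau = named(tau, genes), lambda_u = named(lambda_u, genes),
                 lambda_v = named(lambda_v, genes), d_coop = d_coop),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("Circuit parameters: %d genes x %d TFs, %d free parameters\n",
              length(x$genes), length(x$tfs), length(pack_params(x))))
  print(round(x$T, 2))
  invisible(x)
}

#' Per-gene thermodynamic view of a circuit parameter set
#'
#' @param params a [circuit_params()].
#' @param gene target gene.
#' @return a [thermo_params()] for that gene.
#' @export
gene_thermo_params <- function(params, gene) {
  thermo_params(gene, t_row = params$T[gene, ], affinity = params$K,
                cooperativity = params$omega,
                repression_range = params$d_r[[gene]],
                coop_range = params$d_coop, q_btm = params$q_btm[[gene]])
}

#' Pack circuit parameters into the free-parameter vector
#'
#' Block order: T (by gene, then TF), q_btm, K, omega, d_r, tau, lambda_u,
#' lambda_v. `unpack_params(pack_params(p), p)` is the identity.
#'
#' @param params a [circuit_params()].
#' @return named numeric vector.
#' @export
pack_params <- function(params) {
  g <- params$genes; f <- params$tfs
  tv <- as.numeric(t(params$T))
  names(tv) <- paste0("T[", rep(g, each = length(f)), ",", rep(f, length(g)), "]")
  c(tv,
    stats::setNames(params$q_btm, paste0("q_btm[", g, "]")),
    stats::setNames(params$K, paste0("K[", f, "]")),
    stats::setNames(params$omega, paste0("omega[", f, "]")),
    stats::setNames(params$d_r, paste0("d_r[", g, "]")),
    stats::setNames(params$tau, paste0("tau[", g, "]")),
    stats::setNames(params$lambda_u, paste0("lambda_u[", g, "]")),
    stats::setNames(params$lambda_v, paste0("lambda_v[", g, "]")))
}

#' Rebuild circuit parameters from a packed vector
#'
#' @param x numeric vector as produced by [pack_params()].
#' @param template a [circuit_params()] supplying gene/TF names and the
#'   fixed `d_coop`.
#' @return a [circuit_params()].
#' @export
unpack_params <- function(x, template) {
  g <- template$genes; f <- template$tfs
  ng <- length(g); ntf <- length(f)
  need <- ng * ntf + 2L * ng + 2L * ntf + 3L * ng
  if (length(x) != need) {
    stop("parameter vector length ", length(x), " != expected ", need)
  }
  pos <- 0L
  take <- function(n) {
    out <- x[(pos + 1L):(pos + n)]; pos <<- pos + n; out
  }
  T <- matrix(take(ng * ntf), ng, ntf, byrow = TRUE,
              dimnames = list(g, f))
  circuit_params(g, f, T, q_btm = take(ng), K = take(ntf),
                 omega = take(ntf), d_r = take(ng), tau = take(ng),
                 lambda_u = take(ng), lambda_v = take(ng),
                 d_coop = template$d_coop)
}

#' Default optimization bounds per parameter block
#'
#' Regulatory strengths span [-1e4, 1e4] (magnitudes guided by fitted gap
#' circuits), affinities [1e-5, 0.1], cooperativity [1, 5], repression
#' range [50, 250] bp, delay [0, 10] min, decay rates from half-lives of
#' 1-100 min, and basal weights [1e-3, 1].
#'
#' @param genes,tfs gene and TF names.
#' @return list with `lower` and `upper` named vectors aligned with
#'   [pack_params()].
#' @export
default_bounds <- function(genes, tfs) {
  ng <- length(genes); ntf <- length(tfs)
  lower <- c(rep(-1e4, ng * ntf), rep(1e-3, ng), rep(1e-5, ntf),
             rep(1, ntf), rep(50, ng), rep(0, ng),
             rep(log(2) / 100, 2L * ng))
  upper <- c(rep(1e4, ng * ntf), rep(1, ng), rep(0.1, ntf),
             rep(5, ntf), rep(250, ng), rep(10, ng),
             rep(log(2) / 1, 2L * ng))
  template <- circuit_params(genes, tfs, T = matrix(1, ng, ntf), q_btm = 0.1,
                             K = 0.01, omega = 1, d_r = 100, tau = 1,
                             lambda_u = 0.1, lambda_v = 0.1)
  nm <- names(pack_params(template))
  list(lower = stats::setNames(lower, nm), upper = stats::setNames(upper, nm))
}
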