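#' Sensitivity (residual Jacobian) matrix by central finite differences
#'
#' Differentiates the residual vector of a model with respect to each free
#' parameter. For the asymptotic theory to apply to fluorescence-like data,
#' the residuals should be formed on the variance-stabilized (square-root)
#' scale; [make_residual_fn()] does this for circuit fits.
#'
#' @param resid_fn function mapping a parameter vector to the residual
#'   vector (length N).
#' @param theta parameter vector at which to differentiate (length m).
#' @param rel_step relative step size; the absolute step for coordinate i
#'   is `rel_step * max(|theta_i|, 1)`.
#' @return N x m sensitivity matrix with parameter names as column names.
#' @export
residual_jacobian <- function(resid_fn, theta, rel_step = 1e-4) {
  m <- length(theta)
  r0 <- resid_fn(theta)
  if (any(!is.finite(r0))) stop("non-finite residuals at theta")
  J <- matrix(NA_real_, length(r0), m,
              dimnames = list(NULL, names(theta)))
  for (i in seq_len(m)) {
    h <- rel_step * max(abs(theta[i]), 1)
    tp <- theta; tp[i] <- theta[i] + h
    tm <- theta; tm[i] <- theta[i] - h
    rp <- resid_fn(tp); rm_ <- resid_fn(tm)
    if (any(!is.finite(rp)) || any(!is.finite(rm_))) {
      stop("non-finite model output when perturbing parameter ",
           if (is.null(names(theta))) i else names(theta)[i])
    }
    J[, i] <- (rp - rm_) / (2 * h)
  }
  J
}

#' Residual function of a circuit fit on the variance-stabilized scale
#'
#' Returns a closure mapping a packed parameter vector to
#' `sqrt(model) - sqrt(data)` over all observations, for use with
#' [residual_jacobian()].
#'
#' @inheritParams fit_circuit
#' @return function of a packed parameter vector.
#' @export
make_residual_fn <- function(model, data, grid, external_inputs = NULL,
                             template, v_init = NULL) {
  obs <- as.numeric(sqrt_transform(data$conc))
  function(x) {
    params <- unpack_params(x, template)
    traj <- simulate_circuit(model, params, external_inputs, grid,
                             v_init = v_init)
    p <- model_at_observations(traj, data)
    sqrt(pmax(p, 0)) - obs
  }
}

#' Asymptotic confidence intervals from the sensitivity matrix
#'
#' Axis projections of the joint confidence ellipsoid
#' `(theta - theta_hat)' J'J (theta - theta_hat) <= m/(N-m) * S(theta_hat) *
#' F(alpha; m, N-m)`: the half-width of parameter i is
#' `sqrt(m/(N-m) * S * qF * [(J'J)^-1]_ii)`. Parameters whose interval is
#' bounded away from zero are flagged identifiable (the sign of the
#' estimate is trustworthy). A singular `J'J` yields infinite intervals
#' for the parameters involved.
#'
#' @param J N x m sensitivity matrix.
#' @param theta_hat parameter estimates (length m).
#' @param S_hat residual sum of squares at the estimate (on the same scale
#'   as the residuals used for `J`).
#' @param alpha significance level (default 0.05 for 95% intervals).
#' @return data.frame of class `confidence_report`: `parameter`,
#'   `estimate`, `lower`, `upper`, `identifiable`, plus attributes `alpha`
#'   and `ellipsoid_rhs` (the right-hand side of the ellipsoid inequality).
#' @export
confidence_intervals <- function(J, theta_hat, S_hat, alpha = 0.05) {
  N <- nrow(J); m <- ncol(J)
  if (N <= m) stop("need more observations than parameters (N > m)")
  rhs <- m / (N - m) * S_hat * stats::qf(1 - alpha, m, N - m)
  ## parameters with no effect on the residuals (zero sensitivity column)
  ## are non-identifiable outright; the inversion runs on the rest
  nonzero <- colSums(J^2) > 0
  inv_diag <- rep(Inf, m)
  if (any(nonzero)) {
    ## diag((J'J)^-1) via the SVD of J: numerically stable even for the
    ## severely ill-conditioned sensitivities typical of thermodynamic
    ## models. Directions with exactly (machine-) zero singular value are
    ## null: parameters loading on them get infinite intervals; tiny but
    ## genuine singular values simply produce very large, finite ones.
    s <- svd(J[, nonzero, drop = FALSE])
    tol <- max(s$d) * 1e-14
    null_dir <- s$d < tol
    V2 <- s$v^2
    sub <- as.numeric(V2[, !null_dir, drop = FALSE] %*%
                        (1 / s$d[!null_dir]^2))
    if (any(null_dir)) {
      sub[rowSums(V2[, null_dir, drop = FALSE]) > 1e-8] <- Inf
    }
    inv_diag[nonzero] <- sub
  }
  half <- sqrt(rhs * inv_diag)
  nm <- if (is.null(colnames(J))) paste0("p", seq_len(m)) else colnames(J)
  out <- data.frame(parameter = nm, estimate = as.numeric(theta_hat),
                    lower = theta_hat - half, upper = theta_hat + half,
                    identifiable = (theta_hat - half > 0) |
                      (theta_hat + half < 0),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "ellipsoid_rhs") <- rhs
  class(out) <- c("confidence_report", "data.frame")
  out
}

normalize_columns <- function(J) {
  nrm <- sqrt(colSums(J^2))
  if (any(nrm == 0)) stop("zero-norm sensitivity column: ",
                          paste(colnames(J)[nrm == 0], collapse = ", "))
  sweep(J, 2L, nrm, "/")
}

#' Collinearity index of a parameter subset
#'
#' `gamma = 1 / sqrt(min eigenvalue)` of the subset's submatrix of the
#' column-normalized `J'J`. Orthogonal columns give gamma = 1; near-linear
#' dependence gives large gamma (identical columns: infinity). Large
#' values mean the subset is jointly poorly identifiable.
#'
#' @param J N x m sensitivity matrix (columns are normalized internally,
#'   so gamma is invariant to column scaling).
#' @param subset column indices or names (length >= 2).
#' @return collinearity index.
#' @export
collinearity_index <- function(J, subset) {
  if (length(subset) < 2L) stop("subset must contain at least 2 parameters")
  Jn <- normalize_columns(J[, subset, drop = FALSE])
  lam <- min(eigen(crossprod(Jn), symmetric = TRUE,
                   only.values = TRUE)$values)
  if (lam <= 0) Inf else 1 / sqrt(lam)
}

#' Scan parameter subsets for collinearity
#'
#' Computes the collinearity index for every subset of sizes 2..`k_max`
#' and reports those exceeding the threshold, sorted by decreasing index.
#'
#' @param J N x m sensitivity matrix with named columns.
#' @param k_max largest subset size (exhaustive enumeration).
#' @param threshold report subsets with gamma above this value (default 4).
#' @return data.frame of class `collinearity_report`: `subset`
#'   (comma-separated parameter names), `k`, `gamma`.
#' @export
scan_collinear_subsets <- function(J, k_max = 3L, threshold = 4) {
  m <- ncol(J)
  nm <- if (is.null(colnames(J))) paste0("p", seq_len(m)) else colnames(J)
  Jn <- normalize_columns(J)
  G <- crossprod(Jn)
  rows <- list()
  for (k in 2:min(k_max, m)) {
    combs <- utils::combn(m, k)
    for (ci in seq_len(ncol(combs))) {
      s <- combs[, ci]
      lam <- min(eigen(G[s, s], symmetric = TRUE, only.values = TRUE)$values)
      gamma <- if (lam <= 0) Inf else 1 / sqrt(lam)
      if (gamma > threshold) {
        rows[[length(rows) + 1L]] <-
          data.frame(subset = paste(nm[s], collapse = ","), k = k,
                     gamma = gamma, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subset = character(0), k = integer(0), gamma = numeric(0))
  out <- out[order(-out$gamma), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("collinearity_report", "data.frame")
  out
}
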