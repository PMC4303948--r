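#' Expression dataset container
#'
#' Tidy observations of protein concentration per (gene, time class,
#' nucleus), FlyEx-like. `r_max` (the maximum observed level) and `D` (the
#' number of observations) are attached as attributes.
#'
#' @param observations data.frame with columns `gene`, `time_class`,
#'   `time`, `nucleus`, `conc`.
#' @param r_max maximum observable/observed expression level; defaults to
#'   the maximum observed concentration.
#' @return data.frame of class `expression_dataset`.
#' @export
expression_dataset <- function(observations, r_max = NULL) {
  need <- c("gene", "time_class", "time", "nucleus", "conc")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(observations$conc)) || any(observations$conc < 0)) {
    stop("concentrations must be finite and non-negative")
  }
  if (is.null(r_max)) r_max <- max(observations$conc)
  out <- as.data.frame(observations)
  rownames(out) <- NULL
  attr(out, "r_max") <- r_max
  class(out) <- c("expression_dataset", "data.frame")
  out
}

#' Number of observations in a dataset
#' @param data an [expression_dataset()] or plain data.frame.
#' @return integer count.
#' @export
n_observations <- function(data) nrow(data)

#' Maximum observed expression level
#' @param data an [expression_dataset()].
#' @return numeric `r_max` (attribute if present, else max of `conc`).
#' @export
r_max <- function(data) {
  rm <- attr(data, "r_max")
  if (is.null(rm)) max(data$conc) else rm
}

## model protein values aligned with the observations; errors if any
## observation has no model value
model_at_observations <- function(model_traj, data) {
  key <- function(d) paste(d$gene, d$time_class, d$nucleus, sep = "\r")
  idx <- match(key(data), key(model_traj))
  if (anyNA(idx)) {
    miss <- data[is.na(idx), c("gene", "time_class", "nucleus")]
    stop("no model value for ", nrow(miss), " observation(s), e.g. ",
         paste(unlist(miss[1L, ]), collapse = "/"))
  }
  model_traj$v[idx]
}

#' Residual sum of squares between model and data
#'
#' Sum of squared differences between the simulated protein concentration
#' and the observed concentration over exactly the observed
#' (gene, time class, nucleus) triples.
#'
#' @param model a `gap_trajectory` (or data.frame with `gene`,
#'   `time_class`, `nucleus`, `v`).
#' @param data an [expression_dataset()].
#' @return RSS (>= 0).
#' @export
rss <- function(model, data) {
  p <- model_at_observations(model, data)
  sum((p - data$conc)^2)
}

#' Root mean square from an RSS
#'
#' `rms = sqrt(RSS / D)` where `D` is the number of observations.
#'
#' @param RSS residual sum of squares.
#' @param D number of observations (> 0).
#' @return numeric rms.
#' @export
rms <- function(RSS, D) {
  if (D <= 0) stop("D must be positive")
  sqrt(RSS / D)
}

## one spatial pattern's wPGP components
wpgp_pattern <- function(p, r, rmax, penalty_norm) {
  reward <- sum(r * pmin(r, p)) / sum(r * r)
  den <- switch(penalty_norm,
                squared_sum = sum(rmax - r)^2,
                sum_times_rmax = sum(rmax - r) * rmax,
                stop("unknown penalty normalization: ", penalty_norm))
  pen <- sum((rmax - r) * abs(p - r)) / den
  0.5 + 0.5 * (pen - reward)
}

#' Weighted Pattern Generating Potential
#'
#' Direction-aware goodness of fit: `wPGP = 0.5 + 0.5*(penalty - reward)`
#' with `reward = sum(r*min(r,p)) / sum(r*r)` and
#' `penalty = sum((r_max - r)*|p - r|) / [sum(r_max - r)]^2`. A perfect fit
#' scores 0; lower is better. The score is computed per (gene, time class)
#' spatial pattern and averaged over patterns; patterns with an all-zero
#' reference are an error.
#'
#' @param model a `gap_trajectory` (or vector of predictions when `data` is
#'   a vector of observations).
#' @param data an [expression_dataset()] (or numeric vector).
#' @param rmax maximum observed expression; default from `data`.
#' @param penalty_norm denominator convention for the penalty term:
#'   `"squared_sum"` (the printed form, default) or `"sum_times_rmax"`
#'   (`sum(r_max - r) * r_max`).
#' @return wPGP score.
#' @export
wpgp <- function(model, data, rmax = NULL, penalty_norm = c("squared_sum",
                                                            "sum_times_rmax")) {
  penalty_norm <- match.arg(penalty_norm)
  if (is.numeric(model) && is.numeric(data)) {
    if (all(data == 0)) stop("all-zero reference pattern: reward undefined")
    if (is.null(rmax)) rmax <- max(data)
    return(wpgp_pattern(model, data, rmax, penalty_norm))
  }
  if (is.null(rmax)) rmax <- r_max(data)
  p <- model_at_observations(model, data)
  groups <- split(seq_len(nrow(data)), paste(data$gene, data$time_class))
  vals <- vapply(groups, function(i) {
    r <- data$conc[i]
    if (all(r == 0)) stop("all-zero reference pattern: reward undefined")
    wpgp_pattern(p[i], r, rmax, penalty_norm)
  }, numeric(1L))
  mean(vals)
}

#' Penalty on regulatory parameter magnitudes
#'
#' Sum of squares of all interconnectivity matrix entries; limits the
#' growth of the regulatory strengths, whose allowed ranges are very wide.
#'
#' @param T regulatory matrix (or a [circuit_params()]).
#' @return sum of squared entries.
#' @export
t_penalty <- function(T) {
  if (inherits(T, "circuit_params")) T <- T$T
  sum(T^2)
}

#' Combined optimization objective
#'
#' `Error = RSS + 5e4 * wPGP + 1e-3 * Penalty` (weights configurable).
#'
#' @param RSS residual sum of squares.
#' @param wPGP weighted pattern generating potential.
#' @param Penalty regulatory-magnitude penalty.
#' @param weights length-3 numeric: weights of the three components.
#' @return combined error.
#' @export
combined_error <- function(RSS, wPGP, Penalty,
                           weights = c(1, 5e4, 1e-3)) {
  stopifnot(all(is.finite(c(RSS, wPGP, Penalty))))
  weights[1L] * RSS + weights[2L] * wPGP + weights[3L] * Penalty
}

#' Variance-stabilizing square-root transform
#'
#' For data whose error grows roughly linearly with the mean (as for
#' Poisson-like fluorescence counts), `y = sqrt(x)` makes the error
#' approximately independent of the mean. The result is tagged so that an
#' accidental second application is caught.
#'
#' @param values non-negative numeric vector (or a data.frame with a `conc`
#'   column, transformed in place).
#' @return transformed values carrying attribute `sqrt_transformed = TRUE`.
#' @export
sqrt_transform <- function(values) {
  if (is.data.frame(values)) {
    values$conc <- sqrt_transform(values$conc)
    return(values)
  }
  if (isTRUE(attr(values, "sqrt_transformed"))) {
    stop("values are already sqrt-transformed")
  }
  if (any(values < 0)) stop("negative input to sqrt_transform")
  structure(sqrt(values), sqrt_transformed = TRUE)
}

#' Score a trajectory against a dataset
#'
#' Convenience wrapper returning all objective components.
#'
#' @param model a `gap_trajectory`.
#' @param data an [expression_dataset()].
#' @param params optional [circuit_params()] for the penalty term (0 if
#'   absent).
#' @param weights combined-error weights, see [combined_error()].
#' @inheritParams wpgp
#' @return list with `rss`, `rms`, `wpgp`, `penalty`, `error`.
#' @export
score_fit <- function(model, data, params = NULL,
                      weights = c(1, 5e4, 1e-3),
                      penalty_norm = "squared_sum") {
  RSS <- rss(model, data)
  W <- wpgp(model, data, penalty_norm = penalty_norm)
  P <- if (is.null(params)) 0 else t_penalty(params)
  list(rss = RSS, rms = rms(RSS, n_observations(data)), wpgp = W,
       penalty = P, error = combined_error(RSS, W, P, weights))
}
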