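#' Decay rate from a half-life
#'
#' `lambda = ln(2) / t_1/2`.
#'
#' @param halflife half-life in minutes (> 0).
#' @return decay rate per minute.
#' @export
decay_from_halflife <- function(halflife) {
  if (any(halflife <= 0)) stop("half-life must be positive")
  log(2) / halflife
}

#' Simulation grid for cleavage cycles 13 and 14A
#'
#' Time is measured in minutes from the start of cycle 13. Nuclei double at
#' the cycle 13 to 14A transition; cycle 14A is divided into temporal
#' classes (T1, T2, ...) of `class_duration` minutes each. Output times are
#' the cycle-13 midpoint and each class midpoint.
#'
#' @param n_nuclei_c13 nuclei along the A-P axis in cycle 13.
#' @param c13_duration length of cycle 13 in minutes.
#' @param class_duration length of one cycle-14A temporal class (minutes).
#' @param n_classes_c14 number of temporal classes in cycle 14A.
#' @param dt integration step in minutes.
#' @return an object of class `simulation_grid`.
#' @export
simulation_grid <- function(n_nuclei_c13 = 29L, c13_duration = 16,
                            class_duration = 6.5, n_classes_c14 = 8L,
                            dt = class_duration / 100) {
  if (dt <= 0) stop("negative or zero dt")
  n_classes_c14 <- as.integer(n_classes_c14)
  g <- structure(list(n_nuclei_c13 = as.integer(n_nuclei_c13),
                      n_nuclei_c14 = 2L * as.integer(n_nuclei_c13),
                      c13_duration = c13_duration,
                      class_duration = class_duration,
                      n_classes_c14 = n_classes_c14,
                      t_mitosis = c13_duration,
                      t_end = c13_duration + n_classes_c14 * class_duration,
                      dt = dt),
                 class = "simulation_grid")
  g
}

#' Temporal classes of a simulation grid
#'
#' @param grid a [simulation_grid()].
#' @return data.frame with `time_class` ("C13", "T1", ...), `time` (class
#'   midpoint in minutes) and `cycle` (13 or 14).
#' @export
class_times <- function(grid) {
  k <- seq_len(grid$n_classes_c14)
  data.frame(
    time_class = c("C13", paste0("T", k)),
    time = c(grid$c13_duration / 2,
             grid$t_mitosis + (k - 0.5) * grid$class_duration),
    cycle = c(13L, rep(14L, grid$n_classes_c14)),
    stringsAsFactors = FALSE)
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf(
    "Grid: %d -> %d nuclei, c13 %g min, %d classes of %g min, dt %g min\n",
    x$n_nuclei_c13, x$n_nuclei_c14, x$c13_duration, x$n_classes_c14,
    x$class_duration, x$dt))
  invisible(x)
}

#' Interpolate tabulated expression profiles at an arbitrary time
#'
#' Profiles are given per (gene, time, nucleus); interpolation is
#' piecewise-linear in time for each nucleus, with constant extrapolation
#' beyond the first and last tabulated times.
#'
#' @param dataset data.frame with columns `gene`, `time`, `nucleus`, `conc`.
#' @param t time (minutes).
#' @return named list, one concentration vector (indexed by nucleus) per
#'   gene.
#' @export
interpolate_inputs <- function(dataset, t) {
  if (nrow(dataset) == 0L) stop("empty dataset")
  out <- lapply(split(dataset, dataset$gene), function(d) {
    nuc <- sort(unique(d$nucleus))
    vapply(nuc, function(j) {
      dj <- d[d$nucleus == j, , drop = FALSE]
      dj <- dj[order(dj$time), , drop = FALSE]
      if (nrow(dj) == 1L) return(dj$conc)
      approx(dj$time, dj$conc, xout = t, rule = 2L)$y
    }, numeric(1L))
  })
  out
}

#' Gap gene circuit model definition
#'
#' Holds the structural (non-optimized) part of a circuit: the target
#' genes, the regulating TFs, where each TF's concentration field comes
#' from (a simulated target gene feeding back, or an external tabulated
#' profile), the annotated regulatory regions with their binding sites, the
#' maximum achievable PWM score per TF, and the fixed kinetic constants
#' (synthesis rates and per-cycle diffusion coefficients are fixed during
#' optimization).
#'
#' @param genes character vector of target gene names.
#' @param tfs character vector of TF names (superset roles: gap genes that
#'   feed back and external inputs).
#' @param regions named list of [regulatory_region()] objects, one per
#'   target gene, with `sites` filled in.
#' @param llr_max named numeric: maximum achievable log-odds score per TF.
#' @param R_u,R_v named numeric per gene: maximum mRNA/protein synthesis
#'   rates.
#' @param D_u,D_v genes x 2 matrices of diffusion coefficients (columns:
#'   cycle 13, cycle 14A); a vector is recycled to both cycles.
#' @return an object of class `gap_model`.
#' @export
gap_model <- function(genes, tfs, regions, llr_max, R_u, R_v, D_u, D_v) {
  stopifnot(all(genes %in% names(regions)), all(tfs %in% c(names(llr_max))))
  as_d <- function(D) {
    if (is.matrix(D)) D[genes, , drop = FALSE]
    else matrix(D[genes], nrow = length(genes), ncol = 2L,
                dimnames = list(genes, c("c13", "c14")))
  }
  structure(list(genes = genes, tfs = tfs,
                 tf_source = ifelse(tfs %in% genes, match(tfs, genes),
                                    NA_integer_),
                 regions = regions[genes], llr_max = llr_max[tfs],
                 R_u = R_u[genes], R_v = R_v[genes],
                 D_u = as_d(D_u), D_v = as_d(D_v)),
            class = "gap_model")
}

#' @export
print.gap_model <- function(x, ...) {
  ns <- vapply(x$regions, function(r) nrow(r$sites), integer(1L))
  cat(sprintf("Gap circuit model: genes [%s], TFs [%s], sites per region: %s\n",
              paste(x$genes, collapse = ", "), paste(x$tfs, collapse = ", "),
              paste(ns, collapse = ", ")))
  invisible(x)
}

## Build the flattened external-input array consumed by the C++ integrator:
## dims (n_ext_tf, n_knots, n_nuclei_c14), plus the knot times.
build_ext_array <- function(external_inputs, ext_tfs, n14) {
  if (length(ext_tfs) == 0L) {
    return(list(arr = numeric(0), dim = c(0L, 0L, n14), times = numeric(0)))
  }
  d <- external_inputs[external_inputs$gene %in% ext_tfs, , drop = FALSE]
  if (nrow(d) == 0L) stop("no external input profiles for TFs: ",
                          paste(ext_tfs, collapse = ", "))
  times <- sort(unique(d$time))
  arr <- array(NA_real_, dim = c(length(ext_tfs), length(times), n14))
  ti <- match(d$time, times)
  ei <- match(d$gene, ext_tfs)
  if (anyNA(ei) || any(d$nucleus < 1L) || any(d$nucleus > n14)) {
    stop("external inputs must cover nuclei 1..", n14)
  }
  arr[cbind(ei, ti, d$nucleus)] <- d$conc
  if (anyNA(arr)) {
    ## TFs tabulated on different time grids: fill each (TF, nucleus)
    ## series by interpolation over its own knots
    for (e in seq_along(ext_tfs)) {
      for (j in seq_len(n14)) {
        y <- arr[e, , j]
        ok <- !is.na(y)
        if (!any(ok)) {
          stop("no external input profile for TF ", ext_tfs[e],
               " at nucleus ", j)
        }
        if (!all(ok)) {
          arr[e, , j] <- approx(times[ok], y[ok], xout = times,
                                rule = 2L)$y
        }
      }
    }
  }
  list(arr = as.numeric(arr), dim = dim(arr), times = times)
}

#' Simulate the two-layer gap gene circuit
#'
#' Integrates the delay reaction-diffusion equations
#' `du/dt = R_u * E + D_u * (neighbour differences) - lambda_u * u` and
#' `dv/dt = R_v * u(t - tau) + D_v * (neighbour differences) - lambda_v * v`
#' with a fixed-step scheme: the decay term is integrated exactly over
#' each step (exponential time differencing), production, diffusion and
#' the delayed synthesis are held constant over the step (forward Euler;
#' the scheme reduces to plain forward Euler when the decay rate is
#' zero, and is exact for constant drive). The activation probability `E`
#' is recomputed at every step from the current protein fields of
#' feedback TFs and the interpolated external profiles. Nuclei double at
#' the cycle 13/14A boundary (daughters inherit parental concentrations);
#' boundaries are no-flux; the delayed mRNA uses the stored history with
#' `u(t < 0) = u(0)`.
#'
#' @param model a [gap_model()].
#' @param params a [circuit_params()] parameter set.
#' @param external_inputs data.frame (`gene`, `time`, `nucleus`, `conc`)
#'   with profiles for every external TF at cycle-14 nucleus resolution
#'   (during cycle 13 a nucleus sees the mean of its two daughters).
#' @param grid a [simulation_grid()].
#' @param v_init optional genes x n_nuclei_c13 matrix of initial protein
#'   concentrations (default 0).
#' @param u_init optional initial mRNA matrix (default 0).
#' @param out_times times at which to report the state; default the class
#'   midpoints of `grid`.
#' @return a `gap_trajectory`: tidy data.frame (`gene`, `time_class`,
#'   `time`, `nucleus`, `u`, `v`) with the grid attached as an attribute.
#'   Cycle-13 rows carry `n_nuclei_c13` nuclei, cycle-14A rows
#'   `n_nuclei_c14`.
#' @export
simulate_circuit <- function(model, params, external_inputs = NULL, grid,
                             v_init = NULL, u_init = NULL, out_times = NULL) {
  stopifnot(inherits(model, "gap_model"), inherits(params, "circuit_params"),
            inherits(grid, "simulation_grid"))
  genes <- model$genes
  tfs <- model$tfs
  ng <- length(genes)
  n13 <- grid$n_nuclei_c13
  n14 <- grid$n_nuclei_c14
  ct <- class_times(grid)
  if (is.null(out_times)) out_times <- ct$time

  ext_tfs <- tfs[is.na(model$tf_source)]
  ext <- build_ext_array(external_inputs, ext_tfs, n14)
  tf_ext <- rep(-1L, length(tfs))
  tf_ext[is.na(model$tf_source)] <- match(ext_tfs, ext_tfs)[
    match(tfs[is.na(model$tf_source)], ext_tfs)] - 1L

  site_tab <- lapply(genes, function(g) {
    s <- model$regions[[g]]$sites
    s <- s[order(s$start, s$end), , drop = FALSE]
    list(tf = match(s$tf, tfs) - 1L,
         start = as.numeric(s$start), end = as.numeric(s$end),
         mid = site_midpoints(s),
         qbase = as.numeric(params$K[s$tf]) *
           exp(s$llr - as.numeric(model$llr_max[s$tf])))
  })
  if (any(vapply(site_tab, function(x) anyNA(x$tf), logical(1L)))) {
    stop("site TF not among the model's TFs")
  }

  zero_init <- matrix(0, ng, n13)
  if (is.null(v_init)) v_init <- zero_init
  if (is.null(u_init)) u_init <- zero_init

  res <- cpp_simulate(
    lapply(site_tab, `[[`, "tf"), lapply(site_tab, `[[`, "start"),
    lapply(site_tab, `[[`, "end"), lapply(site_tab, `[[`, "mid"),
    lapply(site_tab, `[[`, "qbase"),
    params$T[genes, tfs, drop = FALSE], as.numeric(params$omega[tfs]),
    as.numeric(params$d_r[genes]), params$d_coop,
    as.numeric(params$q_btm[genes]),
    as.numeric(model$R_u), as.numeric(model$R_v), model$D_u, model$D_v,
    as.numeric(params$lambda_u[genes]), as.numeric(params$lambda_v[genes]),
    as.numeric(params$tau[genes]), as.integer(model$tf_source) - 1L,
    tf_ext, ext$arr, as.integer(ext$dim), ext$times,
    grid$t_mitosis, grid$t_end, grid$dt, n13, u_init, v_init, out_times)

  traj_from_arrays(res$u, res$v, genes, out_times, grid)
}

traj_from_arrays <- function(u, v, genes, out_times, grid) {
  ct <- class_times(grid)
  labels <- ct$time_class[match(round(out_times, 9), round(ct$time, 9))]
  labels[is.na(labels)] <- sprintf("t%.6g", out_times[is.na(labels)])
  rows <- lapply(seq_along(out_times), function(o) {
    c13 <- out_times[o] < grid$t_mitosis
    if (c13) {
      nuc <- seq_len(grid$n_nuclei_c13)
      cols <- 2L * nuc - 1L  # daughters are duplicates of the parent
    } else {
      nuc <- seq_len(grid$n_nuclei_c14)
      cols <- nuc
    }
    do.call(rbind, lapply(seq_along(genes), function(g) {
      data.frame(gene = genes[g], time_class = labels[o],
                 time = out_times[o], nucleus = nuc,
                 u = u[g, o, cols], v = v[g, o, cols],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  class(out) <- c("gap_trajectory", "data.frame")
  out
}

#' Initial protein state from a dataset's earliest time point
#'
#' @param dataset observations (`gene`, `time`, `nucleus`, `conc`).
#' @param genes gene order for the rows of the returned matrix.
#' @param grid a [simulation_grid()]; cycle-14-resolution observations are
#'   averaged over daughter pairs to the cycle-13 grid.
#' @return genes x n_nuclei_c13 matrix.
#' @export
initial_state_from_data <- function(dataset, genes, grid) {
  t0 <- min(dataset$time)
  d0 <- dataset[dataset$time == t0, , drop = FALSE]
  n13 <- grid$n_nuclei_c13
  out <- matrix(0, length(genes), n13, dimnames = list(genes, NULL))
  for (g in intersect(genes, unique(d0$gene))) {
    dg <- d0[d0$gene == g, , drop = FALSE]
    vals <- rep(0, max(dg$nucleus))
    vals[dg$nucleus] <- dg$conc
    if (max(dg$nucleus) > n13) {
      out[g, ] <- (vals[2 * seq_len(n13) - 1L] + vals[2 * seq_len(n13)]) / 2
    } else {
      out[g, seq_len(min(n13, length(vals)))] <-
        vals[seq_len(min(n13, length(vals)))]
    }
  }
  out
}

#' Write a trajectory as tidy TSV
#'
#' @param traj a `gap_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tidy trajectory/profile TSV
#'
#' @param path TSV with columns `gene`, `time_class`, `time`, `nucleus` and
#'   value columns.
#' @return data.frame.
#' @export
read_profiles <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
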