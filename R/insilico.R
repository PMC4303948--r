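## model with one site (or several) removed from one gene's region;
## parameters are left untouched
drop_sites <- function(model, gene, site_indices) {
  s <- model$regions[[gene]]$sites
  model$regions[[gene]]$sites <- s[-site_indices, , drop = FALSE]
  model
}

#' Regulatory weight of a single binding site
#'
#' `w_r = (RSS_ref - RSS_mut) / RSS_ref` where `RSS_ref` is the residual
#' sum of squares of the full-site-set solution against the data and
#' `RSS_mut` the same quantity with the one site excluded, parameters held
#' fixed. Positive weights mean the site's removal worsens the fit.
#'
#' @param model a [gap_model()].
#' @param params fitted [circuit_params()].
#' @param data an [expression_dataset()].
#' @param grid a [simulation_grid()].
#' @param external_inputs external TF profiles.
#' @param gene gene whose region carries the site.
#' @param site row index into that region's site table.
#' @param rss_ref precomputed reference RSS (recomputed when NULL).
#' @param v_init initial protein state.
#' @return numeric regulatory weight (<= 1).
#' @export
regulatory_weight <- function(model, params, data, grid,
                              external_inputs = NULL, gene, site,
                              rss_ref = NULL, v_init = NULL) {
  ns <- nrow(model$regions[[gene]]$sites)
  if (site < 1L || site > ns) stop("site ", site, " not found in ", gene)
  if (is.null(rss_ref)) {
    ref <- simulate_circuit(model, params, external_inputs, grid,
                            v_init = v_init)
    rss_ref <- rss(ref, data)
  }
  mut <- simulate_circuit(drop_sites(model, gene, site), params,
                          external_inputs, grid, v_init = v_init)
  (rss_ref - rss(mut, data)) / rss_ref
}

#' Regulatory weights of every annotated site
#'
#' Computes [regulatory_weight()] for each site of each region, with the
#' reference solution computed once.
#'
#' @inheritParams regulatory_weight
#' @return data.frame of class `site_weight_report`: `gene`, `site`
#'   (row index), `tf`, `start`, `end`, `strand`, `llr`, `w_r`,
#'   `inside_cre`.
#' @export
site_weight_report <- function(model, params, data, grid,
                               external_inputs = NULL, v_init = NULL) {
  ref <- simulate_circuit(model, params, external_inputs, grid,
                          v_init = v_init)
  rss_ref <- rss(ref, data)
  rows <- lapply(model$genes, function(g) {
    s <- model$regions[[g]]$sites
    if (nrow(s) == 0L) return(NULL)
    cres <- model$regions[[g]]$cres
    in_cre <- rep(FALSE, nrow(s))
    for (cre in cres) {
      in_cre <- in_cre | (s$start < cre[2L] & s$end > cre[1L])
    }
    w <- vapply(seq_len(nrow(s)), function(i) {
      regulatory_weight(model, params, data, grid, external_inputs, g, i,
                        rss_ref = rss_ref, v_init = v_init)
    }, numeric(1L))
    data.frame(gene = g, site = seq_len(nrow(s)), tf = s$tf,
               start = s$start, end = s$end, strand = s$strand, llr = s$llr,
               w_r = w, inside_cre = in_cre, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rss_ref") <- rss_ref
  class(out) <- c("site_weight_report", "data.frame")
  out
}

#' Model degradation under ranked site removal
#'
#' Removes sites cumulatively in order of increasing `|w_r|` and reports
#' the relative RSS (`RSS(subset) / RSS_ref`) after each removal.
#'
#' @inheritParams site_weight_report
#' @param report a [site_weight_report()]; computed if NULL.
#' @return data.frame with `n_removed` (0..site count) and `relative_rss`.
#' @export
ranked_removal_curve <- function(model, params, data, grid,
                                 external_inputs = NULL, report = NULL,
                                 v_init = NULL) {
  if (is.null(report)) {
    report <- site_weight_report(model, params, data, grid, external_inputs,
                                 v_init = v_init)
  }
  rss_ref <- attr(report, "rss_ref")
  ord <- report[order(abs(report$w_r)), , drop = FALSE]
  rel <- numeric(nrow(ord) + 1L)
  rel[1L] <- 1
  cur <- model
  for (i in seq_len(nrow(ord))) {
    g <- ord$gene[i]
    s <- cur$regions[[g]]$sites
    ## locate the site by coordinates within the current (shrinking) table
    j <- which(s$start == ord$start[i] & s$end == ord$end[i] &
                 s$tf == ord$tf[i] & s$strand == ord$strand[i])[1L]
    cur <- drop_sites(cur, g, j)
    traj <- simulate_circuit(cur, params, external_inputs, grid,
                             v_init = v_init)
    rel[i + 1L] <- rss(traj, data) / rss_ref
  }
  data.frame(n_removed = 0:nrow(ord), relative_rss = rel)
}

#' Simulate a null mutant
#'
#' Sets the maximum mRNA and protein synthesis rates of the named gene to
#' zero and (optionally) substitutes TF concentration profiles measured in
#' mutant embryos, leaving everything else identical. With `gene = NULL`
#' and unchanged inputs this reproduces the wild-type simulation exactly.
#'
#' @inheritParams simulate_circuit
#' @param gene gene to knock out (NULL for none).
#' @param mutant_inputs external TF profiles from the mutant background;
#'   default: the wild-type `external_inputs`.
#' @param external_inputs wild-type external profiles.
#' @return a `gap_trajectory`.
#' @export
simulate_mutant <- function(model, params, gene = NULL,
                            mutant_inputs = NULL, external_inputs = NULL,
                            grid, v_init = NULL) {
  if (!is.null(gene)) {
    if (!gene %in% model$genes) stop("unknown gene: ", gene)
    model$R_u[gene] <- 0
    model$R_v[gene] <- 0
  }
  inputs <- if (is.null(mutant_inputs)) external_inputs else mutant_inputs
  simulate_circuit(model, params, inputs, grid, v_init = v_init)
}

#' Simulate a reporter construct driven by one CRE
#'
#' The reporter gene is driven only by the binding sites of the parent
#' gene's region that overlap the named cis-regulatory element; it inherits
#' the parent gene's thermodynamic and kinetic parameters but does not feed
#' back into any TF field, so every TF concentration (including the gap
#' proteins) must be supplied as a tabulated profile.
#'
#' @inheritParams simulate_circuit
#' @param gene parent gene whose region and parameters drive the reporter.
#' @param cre_name name of a CRE annotated on the parent region.
#' @param inputs profiles for all of the model's TFs (`gene`, `time`,
#'   `nucleus`, `conc`).
#' @return a `gap_trajectory` for the single reporter gene
#'   `<gene>_<cre_name>`.
#' @export
simulate_reporter <- function(model, params, gene, cre_name, inputs, grid,
                              v_init = NULL) {
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  region <- model$regions[[gene]]
  rep_name <- paste0(gene, "_", cre_name)
  region$sites <- restrict_sites_to_cre(region, cre_name)
  region$gene <- rep_name
  rmodel <- gap_model(genes = rep_name, tfs = model$tfs,
                      regions = stats::setNames(list(region), rep_name),
                      llr_max = model$llr_max,
                      R_u = stats::setNames(model$R_u[[gene]], rep_name),
                      R_v = stats::setNames(model$R_v[[gene]], rep_name),
                      D_u = matrix(model$D_u[gene, ], 1L, 2L,
                                   dimnames = list(rep_name, NULL)),
                      D_v = matrix(model$D_v[gene, ], 1L, 2L,
                                   dimnames = list(rep_name, NULL)))
  rparams <- circuit_params(rep_name, model$tfs,
                            T = matrix(params$T[gene, ], 1L,
                                       length(model$tfs)),
                            q_btm = params$q_btm[[gene]], K = params$K,
                            omega = params$omega,
                            d_r = params$d_r[[gene]],
                            tau = params$tau[[gene]],
                            lambda_u = params$lambda_u[[gene]],
                            lambda_v = params$lambda_v[[gene]],
                            d_coop = params$d_coop)
  simulate_circuit(rmodel, rparams, inputs, grid, v_init = v_init)
}

#' Classify network topology over a collection of fitted circuits
#'
#' Counts, for every (target gene, TF) pair, in how many fitted networks
#' the regulatory strength is positive (activation) and negative
#' (repression); zeros count in neither category. The consensus is the
#' majority category.
#'
#' @param fits list of [circuit_params()] or `fit_result` objects.
#' @return data.frame of class `topology_summary`: `gene`, `tf`,
#'   `n_positive`, `n_negative`, `consensus`.
#' @export
classify_topology <- function(fits) {
  if (length(fits) == 0L) stop("need at least one fitted network")
  plist <- lapply(fits, function(f) {
    if (inherits(f, "fit_result")) f$params else f
  })
  genes <- plist[[1L]]$genes; tfs <- plist[[1L]]$tfs
  rows <- expand.grid(gene = genes, tf = tfs, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  vals <- sapply(plist, function(p) p$T[cbind(rows$gene, rows$tf)])
  vals <- matrix(vals, nrow = nrow(rows))
  rows$n_positive <- rowSums(vals > 0)
  rows$n_negative <- rowSums(vals < 0)
  rows$consensus <- ifelse(rows$n_positive > rows$n_negative, "activation",
                           ifelse(rows$n_negative > rows$n_positive,
                                  "repression", "ambiguous"))
  class(rows) <- c("topology_summary", "data.frame")
  rows
}

#' Correlation between regulatory weight and PWM score
#'
#' Rank (Spearman) and linear (Pearson) correlation between the per-site
#' regulatory weights and their log-odds PWM scores.
#'
#' @param report a [site_weight_report()] (needs `w_r` and `llr`; >= 3
#'   sites).
#' @return list with `spearman` (`rho`, `p`) and `pearson` (`r`, `p`).
#' @export
weight_vs_llr_correlation <- function(report) {
  if (nrow(report) < 3L) stop("need at least 3 sites")
  if (stats::sd(report$w_r) == 0 || stats::sd(report$llr) == 0) {
    stop("degenerate (constant) weights or scores")
  }
  sp <- suppressWarnings(
    stats::cor.test(report$w_r, report$llr, method = "spearman"))
  pe <- stats::cor.test(report$w_r, report$llr, method = "pearson")
  list(spearman = list(rho = unname(sp$estimate), p = sp$p.value),
       pearson = list(r = unname(pe$estimate), p = pe$p.value))
}
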