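#' Synthetic PWM with controllable peakiness
#'
#' Draws a random consensus word and builds a count matrix in which the
#' consensus base holds a fraction `0.25 + 0.75 * information_content` of
#' the counts at each position (the remainder spread evenly), so
#' `information_content = 1` gives a near-deterministic motif and 0 a flat
#' one.
#'
#' @param seed RNG seed (same seed, same matrix).
#' @param length motif length (>= 4).
#' @param information_content peakiness in `[0, 1]`.
#' @param tf_name TF identifier.
#' @param n_sequences simulated count depth per position.
#' @param threshold log-odds threshold attached to the PWM (default: 4.5
#'   below the maximum achievable score, so one-substitution variants of
#'   the consensus are typically still recovered).
#' @return a [pwm()] with the generating counts in attribute `counts`.
#' @export
synth_pwm <- function(seed, length, information_content = 0.9,
                      tf_name = "TF", n_sequences = 100L,
                      threshold = NULL) {
  if (length < 4L) stop("motif length must be >= 4")
  set.seed(seed)
  p_cons <- 0.25 + 0.75 * information_content
  cons <- sample.int(4L, length, replace = TRUE)
  counts <- matrix(n_sequences * (1 - p_cons) / 3, length, 4L)
  counts[cbind(seq_len(length), cons)] <- n_sequences * p_cons
  counts <- round(counts, 6)
  out <- pwm(counts, tf_name)
  if (is.null(threshold)) threshold <- out$max_score - 4.5
  out$threshold <- threshold
  attr(out, "counts") <- counts
  out
}

#' Synthetic regulatory region with planted binding sites
#'
#' Generates a random background sequence at a configured GC content and
#' inserts motif words (the consensus, optionally with random
#' substitutions) at stated positions. The truth set of planted intervals
#' is returned alongside, so a scanner round trip can be checked exactly.
#'
#' @param seed RNG seed.
#' @param length region length in bp.
#' @param planted data.frame with columns `tf` and `position` (0-based
#'   start) and optionally `n_mismatch` (substitutions applied to the
#'   consensus word, default 0).
#' @param pwms named list of [pwm()] objects covering the planted TFs.
#' @param gene gene identifier for the region.
#' @param gc background GC content.
#' @param tss_offset position of the transcription start site.
#' @return a [regulatory_region()] (fully accessible) with the truth set in
#'   attribute `truth` (`tf`, `start`, `end`, `word`).
#' @export
synth_region <- function(seed, length, planted, pwms, gene = "gene",
                         gc = 0.5, tss_offset = 0L) {
  set.seed(seed)
  bases <- sample(DNA_BASES, length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  if (nrow(planted) > 0L) {
    if (is.null(planted$n_mismatch)) planted$n_mismatch <- 0L
    w <- vapply(planted$tf, function(tf) pwms[[tf]]$length, integer(1L))
    ord <- order(planted$position)
    p <- planted[ord, , drop = FALSE]; w <- w[ord]
    if (any(p$position < 0L) || any(p$position + w > length)) {
      stop("planted site outside the region")
    }
    if (nrow(p) > 1L && any(p$position[-1L] < (p$position + w)[-nrow(p)])) {
      stop("planted sites overlap")
    }
    words <- character(nrow(p))
    for (i in seq_len(nrow(p))) {
      word <- strsplit(pwms[[p$tf[i]]]$consensus, "")[[1L]]
      if (p$n_mismatch[i] > 0L) {
        at <- sample.int(length(word), p$n_mismatch[i])
        for (j in at) word[j] <- sample(setdiff(DNA_BASES, word[j]), 1L)
      }
      bases[(p$position[i] + 1L):(p$position[i] + w[i])] <- word
      words[i] <- paste(word, collapse = "")
    }
    truth <- data.frame(tf = p$tf, start = p$position,
                        end = p$position + w, word = words,
                        stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(tf = character(0), start = integer(0),
                        end = integer(0), word = character(0))
  }
  region <- regulatory_region(gene, paste(bases, collapse = ""),
                              tss_offset = tss_offset,
                              accessibility = data.frame(start = 0L,
                                                         end = length))
  attr(region, "truth") <- truth
  region
}

## analytic gradient shapes over the AP axis coordinate x in [0, 1]
gradient_shape <- function(shape, x, amplitude, location, scale) {
  switch(shape,
         exponential = amplitude * exp(-x / scale),
         sigmoid = amplitude / (1 + exp(-(x - location) / scale)),
         gaussian = amplitude * exp(-(x - location)^2 / (2 * scale^2)),
         stop("unknown gradient shape: ", shape))
}

#' Synthetic FlyEx-like expression profiles
#'
#' Generates smooth per-TF profiles over nuclei and time classes
#' (anterior exponential gradients, posterior sigmoids, bell-shaped
#' domains) with multiplicative Gaussian noise whose standard deviation is
#' proportional to the mean (constant coefficient of variation, emulating
#' fluorescence data whose error grows with concentration), clipped to
#' `[0, r_max]`.
#'
#' @param shapes named list; each element describes one TF as
#'   `list(shape = "exponential"|"sigmoid"|"gaussian", amplitude=,
#'   location=, scale=)` (location/scale on the 0-1 AP axis).
#' @param grid a [simulation_grid()]; profiles are produced at every class
#'   time and at cycle-14 nucleus resolution.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = exact analytic shapes).
#' @param r_max clipping ceiling (maximum fluorescence level).
#' @param seed RNG seed.
#' @return an [expression_dataset()] with one gene per TF.
#' @export
synth_gradients <- function(shapes, grid, noise_cv = 0, r_max = 255,
                            seed = 1L) {
  set.seed(seed)
  ct <- class_times(grid)
  n <- grid$n_nuclei_c14
  x <- (seq_len(n) - 0.5) / n
  rows <- lapply(names(shapes), function(tf) {
    s <- shapes[[tf]]
    base <- gradient_shape(s$shape, x, s$amplitude,
                           if (is.null(s$location)) 0.5 else s$location,
                           s$scale)
    do.call(rbind, lapply(seq_len(nrow(ct)), function(k) {
      conc <- base
      if (noise_cv > 0) {
        conc <- conc * (1 + noise_cv * stats::rnorm(n))
      }
      data.frame(gene = tf, time_class = ct$time_class[k], time = ct$time[k],
                 nucleus = seq_len(n), conc = pmin(pmax(conc, 0), r_max),
                 stringsAsFactors = FALSE)
    }))
  })
  expression_dataset(do.call(rbind, rows), r_max = r_max)
}

#' Noisy observations from a simulated trajectory
#'
#' Samples the protein concentrations of the named genes at every output
#' time and applies multiplicative Gaussian noise (constant CV), clipped to
#' `[0, r_max]`.
#'
#' @param traj a `gap_trajectory`.
#' @param genes genes to observe (default all).
#' @param noise_cv coefficient of variation.
#' @param r_max clipping ceiling.
#' @param seed RNG seed.
#' @return an [expression_dataset()].
#' @export
dataset_from_trajectory <- function(traj, genes = NULL, noise_cv = 0,
                                    r_max = 255, seed = 1L) {
  set.seed(seed)
  d <- as.data.frame(traj)
  if (!is.null(genes)) d <- d[d$gene %in% genes, , drop = FALSE]
  conc <- d$v
  if (noise_cv > 0) conc <- conc * (1 + noise_cv * stats::rnorm(length(conc)))
  out <- data.frame(gene = d$gene, time_class = d$time_class, time = d$time,
                    nucleus = d$nucleus,
                    conc = pmin(pmax(conc, 0), r_max),
                    stringsAsFactors = FALSE)
  expression_dataset(out, r_max = r_max)
}

#' Ground-truth two-gene circuit fixture
#'
#' Builds a complete miniature realization of the two-layer model for
#' parameter-recovery benchmarks: three TFs (one external
#' anterior-exponential activator `actA` plus the two target genes `g1`
#' and `g2` feeding back), synthetic PWMs, regulatory regions with planted
#' sites (activating `actA` and autoregulatory sites on both genes,
#' mutual-repression sites between them), known parameters, the noiseless
#' forward simulation, and a noisy protein dataset in the format the
#' fitter consumes. `g1` wins the anterior (stronger activation), mutual
#' repression then carves an abutting `g2` domain.
#'
#' @param seed RNG seed controlling every random choice.
#' @param noise_cv observation noise CV (default 5%).
#' @param n_nuclei_c13 cycle-13 nuclei (doubling to the observed grid).
#' @param n_classes_c14 cycle-14A time classes.
#' @param r_max fluorescence ceiling.
#' @return list with `model` ([gap_model()]), `params_true`
#'   ([circuit_params()]), `grid`, `pwms`, `external_inputs`,
#'   `trajectory` (noiseless), `dataset` (noisy observations of g1, g2).
#' @export
synth_ground_truth <- function(seed = 1L, noise_cv = 0.05,
                               n_nuclei_c13 = 10L, n_classes_c14 = 5L,
                               r_max = 255) {
  grid <- simulation_grid(n_nuclei_c13 = n_nuclei_c13,
                          n_classes_c14 = n_classes_c14)
  tfs <- c("actA", "g1", "g2")
  genes <- c("g1", "g2")
  pwms <- list(actA = synth_pwm(seed + 11L, 10L, 0.9, "actA"),
               g1 = synth_pwm(seed + 12L, 10L, 0.9, "g1"),
               g2 = synth_pwm(seed + 13L, 10L, 0.9, "g2"))
  llr_max <- vapply(pwms, `[[`, numeric(1L), "max_score")

  plant <- function(tfseq, positions, mism) {
    data.frame(tf = tfseq, position = positions, n_mismatch = mism,
               stringsAsFactors = FALSE)
  }
  ## <= 12 sites per region: repressor sites interleaved within the 100 bp
  ## quenching radius of the activator/autoregulatory sites they silence;
  ## a mix of consensus and 1-substitution (weakened) words
  region_g1 <- synth_region(seed + 21L, 1500L,
                            plant(c("actA", "g2", "actA", "g2", "g1",
                                    "actA", "g2", "g1"),
                                  c(100L, 160L, 220L, 300L, 380L, 700L,
                                    760L, 830L),
                                  c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 1L)),
                            pwms, gene = "g1")
  ## no actA sites in g2's region: the anterior gradient can only act on
  ## g2 through g1, which makes the two regions functionally asymmetric
  ## (the genes cannot simply exchange roles, so shuffled-pattern negative
  ## controls are structurally unfittable)
  region_g2 <- synth_region(seed + 22L, 1500L,
                            plant(c("g1", "g2", "g1", "g2", "g1", "g2"),
                                  c(150L, 210L, 270L, 330L, 390L, 450L),
                                  c(0L, 0L, 0L, 0L, 1L, 0L)),
                            pwms, gene = "g2")
  regions <- list(g1 = predict_sites(region_g1, pwms),
                  g2 = predict_sites(region_g2, pwms))

  ## g1: anterior domain driven by actA, quenched posteriorly by g2;
  ## g2: basal+autoactivation counter-domain, quenched anteriorly by
  ## actA and g1
  params <- circuit_params(
    genes, tfs,
    T = matrix(c(600, 10, -200,  # g1 row: actA, g1, g2
                 0, -800, 80),   # g2 row: actA has no sites here (T = 0)
               2L, 3L, byrow = TRUE, dimnames = list(genes, tfs)),
    q_btm = c(0.02, 0.08), K = c(actA = 0.008, g1 = 0.004, g2 = 0.006),
    omega = c(actA = 1, g1 = 2, g2 = 2), d_r = c(100, 100),
    tau = c(3, 3), lambda_u = decay_from_halflife(c(5, 5)),
    lambda_v = decay_from_halflife(c(6, 6)), d_coop = 50)

  model <- gap_model(genes, tfs, regions, llr_max,
                     R_u = c(g1 = 40, g2 = 40), R_v = c(g1 = 0.11, g2 = 0.11),
                     D_u = c(g1 = 0.1, g2 = 0.1),
                     D_v = c(g1 = 0.2, g2 = 0.2))

  shapes <- list(actA = list(shape = "exponential", amplitude = 220,
                             scale = 0.22))
  external_inputs <- synth_gradients(shapes, grid, noise_cv = 0,
                                     r_max = r_max, seed = seed)
  traj <- simulate_circuit(model, params, external_inputs, grid)
  dataset <- dataset_from_trajectory(traj, genes = genes,
                                     noise_cv = noise_cv, r_max = r_max,
                                     seed = seed + 99L)
  list(model = model, params_true = params, grid = grid, pwms = pwms,
       external_inputs = external_inputs, trajectory = traj,
       dataset = dataset)
}

#' Write a complete fixture directory in standard formats
#'
#' Serializes a ground-truth fixture as FASTA (region sequences), PWM
#' matrix files, BED (accessibility intervals and site truth), TSV
#' (external profiles and noisy dataset) and JSON (true parameter vector),
#' so that every input can be round-tripped through the package's readers.
#'
#' @param gt a [synth_ground_truth()] fixture.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- vapply(gt$model$regions, `[[`, character(1L), "sequence")
  write_fasta(seqs, file.path(dir, "regions.fasta"))
  for (tf in names(gt$pwms)) {
    write_pwm(gt$pwms[[tf]], file.path(dir, paste0("pwm_", tf, ".txt")))
  }
  for (g in names(gt$model$regions)) {
    r <- gt$model$regions[[g]]
    write_sites_bed(r$sites, file.path(dir, paste0("sites_", g, ".bed")),
                    chrom = g)
    acc <- r$accessibility
    writeLines(sprintf("%s\t%d\t%d", g, acc$start, acc$end),
               file.path(dir, paste0("accessibility_", g, ".bed")))
  }
  utils::write.table(as.data.frame(gt$external_inputs),
                     file.path(dir, "external_inputs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(gt$dataset),
                     file.path(dir, "dataset.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(pack_params(gt$params_true)),
                       file.path(dir, "params_true.json"),
                       auto_unbox = TRUE, digits = NA)
  m <- gt$model; g <- gt$grid
  jsonlite::write_json(
    list(genes = m$genes, tfs = m$tfs, llr_max = as.list(m$llr_max),
         R_u = as.list(m$R_u), R_v = as.list(m$R_v),
         D_u = lapply(seq_along(m$genes), function(i) m$D_u[i, ]),
         D_v = lapply(seq_along(m$genes), function(i) m$D_v[i, ]),
         d_coop = gt$params_true$d_coop,
         grid = list(n_nuclei_c13 = g$n_nuclei_c13,
                     c13_duration = g$c13_duration,
                     class_duration = g$class_duration,
                     n_classes_c14 = g$n_classes_c14, dt = g$dt),
         r_max = r_max(gt$dataset)),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into model objects
#'
#' Reconstructs the [gap_model()], [simulation_grid()], true parameters,
#' external inputs and dataset from the standard-format files written by
#' [write_fixture()].
#'
#' @param dir fixture directory.
#' @return list with `model`, `grid`, `params_true` (NULL when absent),
#'   `external_inputs`, `dataset`.
#' @export
read_fixture <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  seqs <- read_fasta(file.path(dir, "regions.fasta"))
  regions <- lapply(cfg$genes, function(g) {
    bed <- read_bed(file.path(dir, paste0("sites_", g, ".bed")))
    acc <- read_bed(file.path(dir, paste0("accessibility_", g, ".bed")))
    sites <- data.frame(tf = bed$name, start = bed$start, end = bed$end,
                        strand = bed$strand, word = "N", llr = bed$score,
                        stringsAsFactors = FALSE)
    regulatory_region(g, seqs[[g]],
                      accessibility = acc[, c("start", "end")],
                      sites = sites)
  })
  names(regions) <- cfg$genes
  dmat <- function(x) matrix(unlist(x), length(cfg$genes), 2L, byrow = TRUE,
                             dimnames = list(cfg$genes, NULL))
  model <- gap_model(cfg$genes, cfg$tfs, regions,
                     llr_max = unlist(cfg$llr_max),
                     R_u = unlist(cfg$R_u), R_v = unlist(cfg$R_v),
                     D_u = dmat(cfg$D_u), D_v = dmat(cfg$D_v))
  grid <- simulation_grid(n_nuclei_c13 = cfg$grid$n_nuclei_c13,
                          c13_duration = cfg$grid$c13_duration,
                          class_duration = cfg$grid$class_duration,
                          n_classes_c14 = cfg$grid$n_classes_c14,
                          dt = cfg$grid$dt)
  pfile <- file.path(dir, "params_true.json")
  params <- NULL
  if (file.exists(pfile)) {
    template <- circuit_params(cfg$genes, cfg$tfs,
                               T = matrix(0, length(cfg$genes),
                                          length(cfg$tfs)),
                               q_btm = 0.1, K = 0.01, omega = 1, d_r = 100,
                               tau = 1, lambda_u = 0.1, lambda_v = 0.1,
                               d_coop = cfg$d_coop)
    params <- unpack_params(
      unlist(jsonlite::read_json(pfile, simplifyVector = TRUE)), template)
  }
  ext <- read_profiles(file.path(dir, "external_inputs.tsv"))
  ds <- expression_dataset(read_profiles(file.path(dir, "dataset.tsv")),
                           r_max = cfg$r_max)
  list(model = model, grid = grid, params_true = params,
       external_inputs = ext, dataset = ds)
}
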