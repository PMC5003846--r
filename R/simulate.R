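#' Build a simulation sample design (conditions x cell lines x replicates)
#'
#' @param cell_lines Cell-line labels. Default: three melanoma lines.
#' @param conditions Condition labels; the first matching `untreated` is the
#'   reference, all others are "treated" (treatment effects apply).
#' @param replicates Replicates per cell line x condition.
#' @param untreated Label of the untreated condition.
#' @return data.frame with columns `sample_id`, `cell_line`, `condition`,
#'   `treated` (logical).
#' @export
sim_design <- function(cell_lines = c("Me275", "Me290", "T1185B"),
                       conditions = c("untreated", "CTL_coculture",
                                      "cytokines"),
                       replicates = 1, untreated = "untreated") {
  if (replicates < 1) stop("invalid design: need >= 1 replicate")
  if (!untreated %in% conditions)
    stop("invalid design: untreated label '", untreated,
         "' not among conditions")
  d <- expand.grid(replicate = seq_len(replicates),
                   condition = conditions, cell_line = cell_lines,
                   stringsAsFactors = FALSE)
  d$treated <- d$condition != untreated
  d$sample_id <- paste(d$cell_line, d$condition, d$replicate, sep = "_")
  d[, c("sample_id", "cell_line", "condition", "treated")]
}

#' Assemble a simulation ground truth
#'
#' Encodes everything the generator needs and everything the pipeline should
#' recover: per-sample lane scale factors and background rates, per-gene base
#' means and stability classes, per-cell-line true treatment effects,
#' negative-binomial dispersion, per-sample contamination fractions and the
#' contaminating cell type's marker signature.
#'
#' @param design A [sim_design()] data.frame.
#' @param mu Named vector of per-gene base means (linear counts), > 0.
#' @param stability_class Named character vector, `"stable"` or `"variable"`
#'   per gene; stable genes must have zero treatment effect.
#' @param delta Matrix of true log2 treatment effects, genes x cell lines
#'   (0 for unaffected genes).
#' @param probe_class Named probe class per gene (`"endogenous"` /
#'   `"housekeeping"`); negatives are added by the generator.
#' @param lane_factor Per-sample multiplicative lane factor (> 0); default 1.
#' @param background Per-sample Poisson background rate for negative-control
#'   probes; default 8 counts.
#' @param dispersion Negative-binomial dispersion \eqn{\phi} (variance
#'   \eqn{\mu + \phi \mu^2}); 0 gives Poisson counts. Default 0.1.
#' @param contamination Per-sample contamination fraction \eqn{\pi_j} in
#'   `[0, 1)`; default 0.
#' @param marker_signature Named vector of contaminant mean counts (0 for
#'   genes the contaminating cell type does not express).
#' @param n_negatives Number of negative-control probes. Default 8.
#' @param sigma_stable Log2 noise SD of stable genes on the expression
#'   platform. Default 0.05.
#' @param sigma_variable_meanlog,sigma_variable_sdlog Parameters of the
#'   log-normal from which variable genes' log2 noise SDs are drawn
#'   (median `exp(meanlog)` = 0.6 by default).
#' @param missing_rate Fraction of entries masked as missing on the
#'   expression platform. Default 0.
#' @param seed RNG seed; same seed gives bit-identical simulated data.
#' @return Object of class `simulation_truth`.
#' @seealso [preset_panel_truth()], [preset_expression_truth()]
#' @export
simulation_truth <- function(design, mu, stability_class, delta,
                             probe_class = NULL, lane_factor = NULL,
                             background = 8, dispersion = 0.1,
                             contamination = 0, marker_signature = NULL,
                             n_negatives = 8, sigma_stable = 0.05,
                             sigma_variable_meanlog = log(0.6),
                             sigma_variable_sdlog = 0.15,
                             missing_rate = 0, seed = 1) {
  genes <- names(mu)
  if (is.null(genes)) stop("mu must be a named vector")
  if (any(mu <= 0)) stop("all base means must be positive")
  stability_class <- stability_class[genes]
  if (anyNA(stability_class) ||
      !all(stability_class %in% c("stable", "variable")))
    stop("stability_class must be 'stable' or 'variable' for every gene")
  delta <- as.matrix(delta)[genes, , drop = FALSE]
  if (any(delta[stability_class == "stable", ] != 0))
    stop("stable genes must have zero treatment effect in all cell lines")
  if (!all(unique(design$cell_line) %in% colnames(delta)))
    stop("delta must have a column per cell line in the design")

  n <- nrow(design)
  lane_factor <- rep_len(lane_factor %||% 1, n)
  if (any(lane_factor <= 0)) stop("lane factors must be positive")
  background <- rep_len(background, n)
  if (any(background < 0)) stop("background rates must be non-negative")
  contamination <- rep_len(contamination, n)
  if (any(contamination < 0 | contamination >= 1))
    stop("contamination fractions must be in [0, 1)")
  names(lane_factor) <- names(background) <- names(contamination) <-
    design$sample_id
  marker_signature <- marker_signature %||%
    stats::setNames(rep(0, length(genes)), genes)
  sig <- stats::setNames(rep(0, length(genes)), genes)
  sig[names(marker_signature)[names(marker_signature) %in% genes]] <-
    marker_signature[names(marker_signature) %in% genes]
  probe_class <- probe_class %||%
    stats::setNames(rep("endogenous", length(genes)), genes)

  structure(
    list(design = design, mu = mu, stability_class = stability_class,
         delta = delta, probe_class = probe_class[genes],
         lane_factor = lane_factor, background = background,
         dispersion = dispersion, contamination = contamination,
         marker_signature = sig, n_negatives = n_negatives,
         sigma_stable = sigma_stable,
         sigma_variable_meanlog = sigma_variable_meanlog,
         sigma_variable_sdlog = sigma_variable_sdlog,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

#' Study-like targeted-panel simulation truth
#'
#' Default preset mirroring the study conditions: 3 cell lines x
#' \{untreated, CTL co-culture, cytokines\}, 185 endogenous target genes, 8
#' housekeeping candidates of which 3 are planted at background level
#' (mirroring candidates that turn out too lowly expressed to normalize on),
#' 5 T-cell marker genes expressed only by the contaminant, lognormal lane
#' factors, Poisson negative-control background, NB dispersion 0.1.
#'
#' @param design A [sim_design()]; default [sim_design()] itself.
#' @param n_targets Number of endogenous target genes. Default 185.
#' @param n_de Number of treatment-responsive target genes. Default 40.
#' @param de_delta Either a single log2 effect applied in all cell lines, or
#'   `NULL` (default) for varied effects: per-gene base magnitude uniform in
#'   [1, 3.5], sign 80% up, jittered per cell line (SD 0.2).
#' @param contaminate Sample ids to contaminate at fraction `pi`.
#' @param pi Contamination fraction for `contaminate` samples. Default 0.05.
#' @param lane_sdlog sdlog of the lognormal lane factors. Default 0.25.
#' @param dispersion NB dispersion. Default 0.1.
#' @param background_rate Negative-control Poisson rate. Default 8.
#' @param seed RNG seed (drives both truth draws and data generation).
#' @return A [simulation_truth()].
#' @export
preset_panel_truth <- function(design = sim_design(), n_targets = 185,
                               n_de = 40, de_delta = NULL,
                               contaminate = character(0), pi = 0.05,
                               lane_sdlog = 0.25, dispersion = 0.1,
                               background_rate = 8, seed = 17) {
  set.seed(seed)
  targets <- sprintf("TGT%03d", seq_len(n_targets))
  hk_usable <- c("ALG12", "GUSB", "RPLP0", "KRBA2", "ADAT2")
  hk_low <- c("DIRC1", "SLC26A3", "PHKG1")
  markers <- CTL_MARKERS
  genes <- c(targets, hk_usable, hk_low, markers)

  mu <- c(stats::setNames(stats::rlnorm(n_targets, log(150), 1.2), targets),
          stats::setNames(c(3000, 1500, 500, 150, 60), hk_usable),
          stats::setNames(rep(0.5, length(hk_low)), hk_low),
          stats::setNames(rep(0.3, length(markers)), markers))

  lines <- unique(design$cell_line)
  delta <- matrix(0, length(genes), length(lines),
                  dimnames = list(genes, lines))
  de_genes <- sample(targets, n_de)
  if (is.null(de_delta)) {
    base <- stats::runif(n_de, 1, 3.5) *
      ifelse(stats::runif(n_de) < 0.8, 1, -1)
    for (cl in lines)
      delta[de_genes, cl] <- base + stats::rnorm(n_de, 0, 0.2)
  } else {
    delta[de_genes, ] <- de_delta
  }

  stability <- stats::setNames(
    ifelse(genes %in% c(hk_usable, hk_low) |
             !(genes %in% de_genes), "stable", "variable"), genes)
  stability[de_genes] <- "variable"
  probe_class <- stats::setNames(
    ifelse(genes %in% c(hk_usable, hk_low), "housekeeping", "endogenous"),
    genes)

  contam <- stats::setNames(rep(0, nrow(design)), design$sample_id)
  contam[intersect(contaminate, names(contam))] <- pi
  sig <- stats::setNames(rep(2000, length(markers)), markers)

  simulation_truth(
    design, mu = mu, stability_class = stability, delta = delta,
    probe_class = probe_class,
    lane_factor = stats::rlnorm(nrow(design), 0, lane_sdlog),
    background = background_rate, dispersion = dispersion,
    contamination = contam, marker_signature = sig, seed = seed)
}

#' Genome-wide expression-matrix simulation truth
#'
#' Preset emulating a processed log2 microarray: `n_stable` genuinely stable
#' genes (log2 noise SD `sigma_stable` = 0.05, no treatment effect) among
#' `n_variable` variable genes whose noise SDs are drawn from a log-normal
#' with median 0.6; a fraction `de_frac` of the variable genes additionally
#' responds to treatment with per-cell-line log2 effects.
#'
#' @param design A [sim_design()]; default 3 cell lines x 2 conditions x 2
#'   replicates (12 samples).
#' @param n_stable,n_variable Gene counts. Defaults 100 / 900.
#' @param de_frac Fraction of variable genes that respond to treatment.
#' @param missing_rate Fraction of entries masked as missing. Default 0.
#' @param seed RNG seed.
#' @return A [simulation_truth()].
#' @export
preset_expression_truth <- function(design = sim_design(
                                      conditions = c("untreated",
                                                     "CTL_coculture"),
                                      replicates = 2),
                                    n_stable = 100, n_variable = 900,
                                    de_frac = 0.3, missing_rate = 0,
                                    seed = 17) {
  set.seed(seed)
  genes <- c(sprintf("STB%03d", seq_len(n_stable)),
             sprintf("VAR%03d", seq_len(n_variable)))
  mu <- stats::setNames(2 ^ stats::runif(length(genes), 4, 14), genes)
  stability <- stats::setNames(
    rep(c("stable", "variable"), c(n_stable, n_variable)), genes)
  lines <- unique(design$cell_line)
  delta <- matrix(0, length(genes), length(lines),
                  dimnames = list(genes, lines))
  var_genes <- genes[stability == "variable"]
  de_genes <- sample(var_genes, round(de_frac * length(var_genes)))
  base <- stats::runif(length(de_genes), 0.5, 3) *
    ifelse(stats::runif(length(de_genes)) < 0.7, 1, -1)
  for (cl in lines)
    delta[de_genes, cl] <- base * (1 + stats::rnorm(length(de_genes), 0, 0.15))
  simulation_truth(design, mu = mu, stability_class = stability,
                   delta = delta, missing_rate = missing_rate, seed = seed)
}

#' Simulate a targeted-panel run from a ground truth
#'
#' Endogenous and housekeeping counts are negative-binomial with mean
#' \deqn{f_j (\mu_g 2^{\delta_{gc} t_j} (1 - \pi_j) + \pi_j s_g)}
#' where \eqn{f_j} is the lane factor, \eqn{t_j} indicates a treated sample,
#' \eqn{\pi_j} the contamination fraction and \eqn{s_g} the contaminant
#' marker signature; dispersion \eqn{\phi} (variance \eqn{\mu + \phi\mu^2};
#' Poisson when \eqn{\phi = 0}). Negative-control probes are Poisson with
#' rate \eqn{\lambda_j}. Fully reproducible from the truth's seed.
#'
#' @param truth A [simulation_truth()].
#' @param design Sample design; defaults to the design stored in `truth`.
#' @return List with `run` (a [panel_run()]) and `truth`.
#' @export
simulate_panel <- function(truth, design = truth$design) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!all(c("sample_id", "cell_line", "condition", "treated") %in%
           names(design)))
    stop("invalid design: need sample_id, cell_line, condition, treated")
  set.seed(truth$seed)
  genes <- names(truth$mu)
  n <- nrow(design)
  counts <- matrix(0, length(genes), n,
                   dimnames = list(genes, design$sample_id))
  for (j in seq_len(n)) {
    d <- truth$delta[, design$cell_line[j]] * design$treated[j]
    m <- truth$lane_factor[j] *
      (truth$mu * 2 ^ d * (1 - truth$contamination[j]) +
         truth$contamination[j] * truth$marker_signature)
    counts[, j] <- if (truth$dispersion > 0)
      stats::rnbinom(length(m), mu = m, size = 1 / truth$dispersion)
    else stats::rpois(length(m), m)
  }
  negs <- matrix(stats::rpois(truth$n_negatives * n,
                              rep(truth$background, each = truth$n_negatives)),
                 truth$n_negatives, n,
                 dimnames = list(sprintf("NEG_%02d",
                                         seq_len(truth$n_negatives)),
                                 design$sample_id))
  all_counts <- rbind(counts, negs)
  cls <- c(truth$probe_class,
           stats::setNames(rep("negative", truth$n_negatives),
                           rownames(negs)))
  run <- panel_run(all_counts, cls, design$condition, design$cell_line)
  list(run = run, truth = truth)
}

#' Simulate a processed log2 expression matrix from a ground truth
#'
#' Values are \eqn{\log_2\mu_g + \delta_{gc} t_j + \varepsilon} with
#' \eqn{\varepsilon \sim N(0, \sigma_g)}; \eqn{\sigma_g} is `sigma_stable`
#' for stable genes and drawn from the truth's log-normal for variable
#' genes. Missing entries are injected completely at random at the truth's
#' `missing_rate`. Fully reproducible from the seed.
#'
#' @param truth A [simulation_truth()].
#' @param design Sample design; defaults to the design stored in `truth`.
#' @return List with `expr` (an [expression_matrix()]), `truth`, and `sigma`
#'   (the per-gene noise SDs drawn).
#' @export
simulate_expression_matrix <- function(truth, design = truth$design) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(truth$seed)
  genes <- names(truth$mu)
  n <- nrow(design)
  sigma <- ifelse(truth$stability_class == "stable", truth$sigma_stable,
                  stats::rlnorm(length(genes), truth$sigma_variable_meanlog,
                                truth$sigma_variable_sdlog))
  names(sigma) <- genes
  vals <- matrix(NA_real_, length(genes), n,
                 dimnames = list(genes, design$sample_id))
  for (j in seq_len(n)) {
    d <- truth$delta[, design$cell_line[j]] * design$treated[j]
    vals[, j] <- log2(truth$mu) + d + stats::rnorm(length(genes), 0, sigma)
  }
  if (truth$missing_rate > 0) {
    mask <- stats::runif(length(vals)) < truth$missing_rate
    vals[mask] <- NA_real_
  }
  expr <- expression_matrix(vals, design$condition, design$cell_line)
  list(expr = expr, truth = truth, sigma = sigma)
}

#' Simulate fold-changes measured on two platforms with known compression
#'
#' Generates a common vector of true log2 fold-changes and two platform
#' readouts: platform b reads the truth with small noise, platform a reads
#' `compression x truth` plus noise — the structure behind one platform
#' systematically underestimating fold-changes relative to another.
#'
#' @param n_genes Number of genes. Default 150.
#' @param compression True compression factor c of platform a. Default 0.6.
#' @param sd_true SD of the true log2 fold-changes. Default 1.5.
#' @param noise_a,noise_b Measurement noise SDs. Defaults 0.2 / 0.05.
#' @param seed RNG seed.
#' @return List with `fc_a`, `fc_b` ([fold_change_table()]s, single cell
#'   line) and `true_logfc`.
#' @export
simulate_platform_pair <- function(n_genes = 150, compression = 0.6,
                                   sd_true = 1.5, noise_a = 0.2,
                                   noise_b = 0.05, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  truth <- stats::rnorm(n_genes, 0, sd_true)
  a <- compression * truth + stats::rnorm(n_genes, 0, noise_a)
  b <- truth + stats::rnorm(n_genes, 0, noise_b)
  fc_a <- fold_change_table(matrix(a, ncol = 1,
                                   dimnames = list(genes, "sim")))
  fc_b <- fold_change_table(matrix(b, ncol = 1,
                                   dimnames = list(genes, "sim")))
  list(fc_a = fc_a, fc_b = fc_b,
       true_logfc = stats::setNames(truth, genes))
}

#' Write / read a simulation truth to and from YAML
#'
#' Lossless on-disk round trip of the ground-truth record, so simulated data
#' sets can be archived next to their generating parameters.
#'
#' @param truth A [simulation_truth()].
#' @param path YAML file path.
#' @return `write_truth`: `truth` invisibly; `read_truth`: the
#'   reconstructed [simulation_truth()].
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  obj <- list(
    design = lapply(truth$design, as.vector),
    genes = names(truth$mu),
    mu = unname(truth$mu),
    stability_class = unname(truth$stability_class),
    probe_class = unname(truth$probe_class),
    delta = list(cell_lines = colnames(truth$delta),
                 values = as.vector(truth$delta)),
    lane_factor = unname(truth$lane_factor),
    background = unname(truth$background),
    dispersion = truth$dispersion,
    contamination = unname(truth$contamination),
    marker_signature = list(genes = names(truth$marker_signature),
                            values = unname(truth$marker_signature)),
    n_negatives = truth$n_negatives,
    sigma_stable = truth$sigma_stable,
    sigma_variable_meanlog = truth$sigma_variable_meanlog,
    sigma_variable_sdlog = truth$sigma_variable_sdlog,
    missing_rate = truth$missing_rate,
    seed = truth$seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(truth)
}

#' @rdname write_truth
#' @param path YAML file path.
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  design <- as.data.frame(obj$design, stringsAsFactors = FALSE)
  genes <- obj$genes
  delta <- matrix(obj$delta$values, nrow = length(genes),
                  dimnames = list(genes, obj$delta$cell_lines))
  simulation_truth(
    design,
    mu = stats::setNames(obj$mu, genes),
    stability_class = stats::setNames(obj$stability_class, genes),
    delta = delta,
    probe_class = stats::setNames(obj$probe_class, genes),
    lane_factor = obj$lane_factor,
    background = obj$background,
    dispersion = obj$dispersion,
    contamination = obj$contamination,
    marker_signature = stats::setNames(obj$marker_signature$values,
                                       obj$marker_signature$genes),
    n_negatives = obj$n_negatives,
    sigma_stable = obj$sigma_stable,
    sigma_variable_meanlog = obj$sigma_variable_meanlog,
    sigma_variable_sdlog = obj$sigma_variable_sdlog,
    missing_rate = obj$missing_rate,
    seed = obj$seed)
}
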