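# Synthetic expression data with the statistical structure the analysis
# assumes: deterministic Hill-ODE trajectories, signal-proportional Gaussian
# noise, the experimental sampling design, and per-experiment max-scaling.

#' Reference kinetic parameters for synthetic studies
#'
#' A fixed, documented parameter set used as ground truth when generating
#' synthetic data from a chosen structure. Rates are chosen so that mRNA
#' trajectories rise sigmoidally through the 0-72 h developmental window on
#' the order of the normalized expression scale (0.1-5), with scaled protein
#' levels reaching the tens-to-hundreds range: mRNA half-life a few hours
#' (`k_m` = 0.2/h), slow protein turnover (`k_p` = 0.05/h), weak basal
#' transcription, and half-max constants inside the protein dynamic range.
#'
#' @param model the `grn_model` the parameters are assembled for (half-max
#'   constants are laid out to match its terms).
#' @return A [grn_params()] in the symmetry-reduced parameterization.
#' @export
reference_params <- function(model) {
  genes <- names(model$terms)
  alpha_all <- c(`eud-1` = 0.01, `nhr-40` = 0.02, `sult-1` = 0.01)
  kt_all <- c(`eud-1` = 1.0, `nhr-40` = 1.2, `sult-1` = 0.8)
  m0_all <- c(`eud-1` = 0.1, `nhr-40` = 0.2, `sult-1` = 0.1)
  p0_all <- c(`eud-1` = 1e-3, `nhr-40` = 1, `sult-1` = 1e-3)
  K <- lapply(model$terms[genes], function(term) {
    c(10, 5)[seq_along(term$regulators)]
  })
  grn_params(
    model,
    alpha = alpha_all[genes], kt_max = kt_all[genes],
    k_m = 0.2, k_p = 0.05,
    K = setNames(K, genes),
    m0 = m0_all[genes], p0 = p0_all[genes]
  )
}

#' Random positive parameter draws
#'
#' Log-uniform draws over moderate, integrable ranges, used for
#' property-style checks such as the scaling-symmetry invariance test.
#'
#' @param model a `grn_model`.
#' @param seed integer seed.
#' @param unreduced draw an explicit translation rate `k_t` (unreduced
#'   system)?
#' @return A [grn_params()].
#' @export
random_params <- function(model, seed, unreduced = FALSE) {
  set.seed(seed)
  genes <- names(model$terms)
  logu <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))
  K <- lapply(model$terms[genes], function(term) {
    logu(max(1, length(term$regulators)), 0.1, 100)
  })
  grn_params(
    model,
    alpha = setNames(logu(length(genes), 1e-3, 0.1), genes),
    kt_max = setNames(logu(length(genes), 0.05, 2), genes),
    k_m = logu(1, 0.05, 0.5), k_p = logu(1, 0.02, 0.2),
    K = setNames(K, genes),
    m0 = setNames(logu(length(genes), 0.01, 1), genes),
    p0 = setNames(logu(length(genes), 0.1, 10), genes),
    k_t = if (unreduced) logu(1, 0.2, 5)
  )
}

#' Sampling design of the three expression experiments
#'
#' Six time points (0, 12, 24, 48, 60, 72 h post-synchronization) in every
#' experiment; four biological replicates for wild type, two for each
#' knock-out. Knock-out experiments observe only the two remaining modelled
#' genes.
#'
#' @param experiment one of `"WT"`, `"eud1_KO"`, `"sult1_KO"`.
#' @return A list with `times` (hours), `replicates`, `genes` and `knockout`.
#' @export
#' @examples
#' experimental_design("WT")
experimental_design <- function(experiment = c("WT", "eud1_KO", "sult1_KO")) {
  experiment <- match.arg(experiment)
  times <- c(0, 12, 24, 48, 60, 72)
  switch(experiment,
    WT = list(times = times, replicates = 4L, genes = grn_genes(),
              knockout = NULL),
    eud1_KO = list(times = times, replicates = 2L,
                   genes = c("nhr-40", "sult-1"), knockout = "eud-1"),
    sult1_KO = list(times = times, replicates = 2L,
                    genes = c("eud-1", "nhr-40"), knockout = "sult-1")
  )
}

#' Generate a synthetic expression dataset
#'
#' Simulates the model's mRNA trajectories and draws independent replicate
#' observations under the multiplicative error model `y = x (1 + cv * Z)`,
#' `Z ~ N(0, 1)` — Gaussian noise with standard deviation proportional to the
#' signal. Draws below a small positive floor are truncated to the floor so
#' that the data stay strictly positive.
#'
#' @param model a `grn_model`.
#' @param params a [grn_params()] (ground truth).
#' @param times observation times in hours.
#' @param replicates replicate observations per (gene, time).
#' @param cv proportionality constant of the noise standard deviation
#'   (coefficient of variation).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param experiment label recorded in the `experiment` column.
#' @param floor truncation floor for non-positive draws.
#' @return A tibble with columns `experiment`, `gene`, `time_h`, `replicate`,
#'   `value`.
#' @export
#' @examples
#' m <- named_models()$model_11574
#' d <- generate_dataset(m, reference_params(m),
#'                       times = c(0, 12, 24, 48, 60, 72),
#'                       replicates = 4, cv = 0.2, seed = 1)
generate_dataset <- function(model, params, times, replicates, cv, seed,
                             experiment = "synthetic", floor = 1e-6) {
  if (replicates < 1) abort("`replicates` must be at least 1.")
  if (cv < 0) abort("`cv` must be non-negative.")
  traj <- simulate_model(model, params, times)
  set.seed(seed)
  out <- tidyr::crossing(
    dplyr::select(traj, "gene", "time_h", x = "value"),
    replicate = seq_len(replicates)
  )
  out$value <- out$x * (1 + cv * rnorm(nrow(out)))
  out$value <- pmax(out$value, floor)
  tibble::tibble(
    experiment = experiment,
    gene = out$gene,
    time_h = out$time_h,
    replicate = as.integer(out$replicate),
    value = out$value
  )
}

#' Scale expression data by its maximum
#'
#' Divides values by the maximum observed value, either across the whole
#' experiment (the default, matching how each experiment's data are
#' normalized to `[0, 1]` jointly across genes, time points and replicates)
#' or separately per gene.
#'
#' @param dataset a tibble with at least `gene` and `value` columns.
#' @param scope `"experiment_global"` or `"per_gene"`.
#' @return The dataset with scaled `value`; the scaling maximum and scope are
#'   attached as attributes `scale_max` and `scale_scope`. Idempotent.
#' @export
max_scale <- function(dataset, scope = c("experiment_global", "per_gene")) {
  scope <- match.arg(scope)
  if (all(dataset$value <= 0)) {
    abort("max_scale requires at least one positive value.")
  }
  if (scope == "experiment_global") {
    mx <- max(dataset$value)
    dataset$value <- dataset$value / mx
  } else {
    dataset <- dataset |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(value = .data$value / max(.data$value)) |>
      dplyr::ungroup()
    mx <- "per-gene maxima"
  }
  attr(dataset, "scale_max") <- mx
  attr(dataset, "scale_scope") <- scope
  dataset
}

#' Build a sampling-rate by noise-level sweep grid
#'
#' The Cartesian product of temporal sampling densities and noise levels used
#' by the misspecification sweep. Each sampling count maps to equally spaced
#' times over `[0, 72]` h; the cell whose sampling count is 6 and whose noise
#' level equals `experimental_cv` is flagged as the approximate experimental
#' regime (and uses the uneven experimental design times instead of an even
#' grid).
#'
#' @param sampling_counts integer vector of numbers of time points (each at
#'   least 2); 73 corresponds to hourly sampling.
#' @param cvs numeric vector of noise levels (coefficients of variation).
#' @param experimental_cv the noise level taken to approximate the
#'   experimental regime.
#' @return A tibble with columns `sampling_count`, `cv`, `times`
#'   (list-column) and `experimental_regime`.
#' @export
#' @examples
#' sweep_grid(c(6, 73), c(0.02, 0.2))
sweep_grid <- function(sampling_counts = c(4, 6, 9, 13, 25, 73),
                       cvs = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5),
                       experimental_cv = 0.2) {
  if (any(sampling_counts < 2)) abort("sampling counts must be at least 2.")
  if (any(cvs < 0)) abort("noise levels must be non-negative.")
  grid <- tidyr::crossing(sampling_count = as.integer(sampling_counts),
                          cv = as.numeric(cvs))
  grid$experimental_regime <- grid$sampling_count == 6L &
    grid$cv == experimental_cv
  grid$times <- purrr::map2(grid$sampling_count, grid$experimental_regime,
    function(n, expcell) {
      if (expcell) experimental_design("WT")$times
      else seq(0, 72, length.out = n)
    })
  grid[, c("sampling_count", "cv", "times", "experimental_regime")]
}
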