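# Misspecification sweeps over sampling x noise regimes, cost-curve ranking,
# acceptability thresholds and prediction-uncertainty bands.

#' Misspecification sweep over sampling and noise regimes
#'
#' For every cell of a sampling-rate by noise-level grid, generates one
#' seeded synthetic dataset from the true structure and refits every
#' candidate structure (the true one and the misspecified alternatives),
#' recording each candidate's best negative log-likelihood. In dense,
#' low-noise regimes the true structure should attain the lowest value; in
#' sparse, noisy regimes structures become practically indistinguishable.
#'
#' @param true_model the generating `grn_model`.
#' @param true_params ground-truth [grn_params()].
#' @param candidates named list of `grn_model`s to refit (should include the
#'   true structure).
#' @param grid a [sweep_grid()] tibble.
#' @param n_starts multistart budget per fit.
#' @param seed master seed; each cell's dataset seed is derived from it.
#' @param replicates replicate observations per (gene, time) in each cell.
#' @param options passed to [fit_model()].
#' @return A tibble with one row per (cell, candidate): `sampling_count`,
#'   `cv`, `experimental_regime`, `candidate`, `nll`, `sigma_hat`, `failed`.
#' @export
misspecification_sweep <- function(true_model, true_params, candidates,
                                   grid = sweep_grid(), n_starts = 50,
                                   seed = 1, replicates = 1,
                                   options = list()) {
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    abort("`candidates` must be a named list of models.")
  }
  cells <- purrr::map(seq_len(nrow(grid)), function(i) {
    cell_seed <- derive_seed(seed, i)
    data <- generate_dataset(
      true_model, true_params, times = grid$times[[i]],
      replicates = replicates, cv = grid$cv[i], seed = cell_seed
    )
    purrr::imap(candidates, function(cand, nm) {
      fit <- try(fit_model(cand, data, n_starts = n_starts,
                           seed = derive_seed(cell_seed, match(nm, names(candidates))),
                           options = options),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        return(tibble::tibble(
          sampling_count = grid$sampling_count[i], cv = grid$cv[i],
          experimental_regime = grid$experimental_regime[i], candidate = nm,
          nll = grn_penalty(), sigma_hat = NA_real_, failed = TRUE
        ))
      }
      tibble::tibble(
        sampling_count = grid$sampling_count[i], cv = grid$cv[i],
        experimental_regime = grid$experimental_regime[i], candidate = nm,
        nll = fit$nll, sigma_hat = fit$sigma_hat, failed = fit$failed
      )
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(cells)
}

#' Sort fitted structures into a cost curve
#'
#' Stable sort of a family fit table by negative log-likelihood (ties broken
#' by model index), exposing the rank-versus-cost curve whose plateau and
#' jumps delimit the acceptable structures.
#'
#' @param fit_table a [fit_family()] result (columns `model_index`, `nll`).
#' @return A tibble of class `grn_cost_curve`: the input sorted, with a
#'   `rank` column (1 = best).
#' @export
cost_curve <- function(fit_table) {
  if (nrow(fit_table) == 0) abort("the fit table is empty.")
  curve <- dplyr::arrange(fit_table, .data$nll, .data$model_index)
  curve$rank <- seq_len(nrow(curve))
  class(curve) <- c("grn_cost_curve", class(curve))
  curve
}

#' Label structures as acceptable or unacceptable fits
#'
#' Either the `k` lowest-cost structures are acceptable (`rank_k`, as used
#' for the wild-type family where the curve plateaus after about 1000
#' models), or the curve is split at its largest consecutive cost jump
#' (`largest_gap`, matching the discrete jump seen in the knock-out curves).
#'
#' @param curve a [cost_curve()].
#' @param mode `"rank_k"` or `"largest_gap"`.
#' @param k number of acceptable structures for `rank_k`.
#' @return The curve with a logical `acceptable` column.
#' @export
select_acceptance_threshold <- function(curve, mode = c("rank_k", "largest_gap"),
                                        k = 1000) {
  mode <- match.arg(mode)
  n <- nrow(curve)
  if (mode == "rank_k") {
    if (k > n) abort("`k` cannot exceed the number of fitted structures.")
    curve$acceptable <- curve$rank <= k
  } else {
    diffs <- diff(curve$nll)
    if (all(diffs == 0)) abort("constant cost curve: no gap to split at.")
    cut <- which.max(diffs)
    curve$acceptable <- curve$rank <= cut
  }
  curve
}

#' One-standard-deviation prediction band
#'
#' Under the multiplicative error model the predictive standard deviation at
#' a prediction `x` is `sigma_hat * x`, so the band is
#' `x (1 - sigma_hat)` to `x (1 + sigma_hat)` (lower edge floored at 0 for
#' display).
#'
#' @param fit a non-failed `grn_fit`.
#' @return The fit's predictions tibble with `lower` and `upper` columns.
#' @export
uncertainty_band <- function(fit) {
  stopifnot(inherits(fit, "grn_fit"))
  if (fit$failed) abort("cannot compute a band for a failed fit.")
  band <- fit$predictions
  band$lower <- pmax(0, band$value * (1 - fit$sigma_hat))
  band$upper <- band$value * (1 + fit$sigma_hat)
  band
}

#' Candidate structures for the misspecification studies
#'
#' The reference set of structures refit against data generated from the
#' `"model_11574"` structure: the true structure itself; a shared-feature
#' candidate keeping NHR-40 activation of *eud-1* and *nhr-40* and EUD-1
#' activation of *sult-1* but dropping the SULT-1 input and the
#' cooperativity; and two candidates sharing no regulated-by, sign or
#' cooperativity feature with the truth, one simple (three single
#' repressions) and one complex (a squared repression and two two-factor
#' repression products).
#'
#' @return A named list of `grn_model`s: `true`, `shared`,
#'   `disjoint_simple`, `disjoint_complex`.
#' @export
study_candidates <- function() {
  fam <- build_family()
  truth <- named_models()$model_11574
  structures <- list(
    shared = list(
      `eud-1` = grn_term("N", "activation"),
      `nhr-40` = grn_term("N", "activation"),
      `sult-1` = grn_term("E", "activation")
    ),
    disjoint_simple = list(
      `eud-1` = grn_term("E", "repression"),
      `nhr-40` = grn_term("S", "repression"),
      `sult-1` = grn_term("S", "repression")
    ),
    disjoint_complex = list(
      `eud-1` = grn_term("E", "repression", exponent = 2L),
      `nhr-40` = grn_term(c("E", "S"), c("repression", "repression")),
      `sult-1` = grn_term(c("N", "S"), c("repression", "repression"))
    )
  )
  cands <- lapply(structures, function(terms) {
    mdl <- new_grn_model(terms, NULL, grn_regulators())
    mdl$model_index <- index_of_model(fam, mdl)
    mdl
  })
  c(list(true = truth), cands)
}
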