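# Kinetic parameters, production-term evaluation, ODE integration and the
# scaling symmetry of the unreduced system.

#' Kinetic parameter set for a regulatory network model
#'
#' Holds every rate constant, half-max constant and initial condition the ODE
#' system of a given structure needs. In the symmetry-reduced
#' parameterization (`k_t = NULL`, the default) protein states and half-max
#' constants are measured in translation-rate-scaled units; supplying an
#' explicit translation rate `k_t` gives the unreduced system used for
#' symmetry-invariance checks.
#'
#' @param model the `grn_model` the parameters belong to.
#' @param alpha named numeric, basal transcription rate per gene
#'   (expression/h).
#' @param kt_max named numeric, maximal regulated transcription rate per gene
#'   (expression/h).
#' @param k_m shared mRNA degradation rate (1/h).
#' @param k_p shared protein degradation rate (1/h).
#' @param K named list, per gene a numeric vector of half-max constants, one
#'   per Hill factor of that gene's production term (a squared single factor
#'   uses one constant).
#' @param m0 named numeric, mRNA initial conditions.
#' @param p0 named numeric, protein initial conditions (scaled units when
#'   `k_t` is `NULL`).
#' @param k_t translation rate (1/h) for the unreduced system, or `NULL` for
#'   the reduced system.
#' @return An object of class `grn_params`.
#' @export
grn_params <- function(model, alpha, kt_max, k_m, k_p, K, m0, p0,
                       k_t = NULL) {
  stopifnot(inherits(model, "grn_model"))
  genes <- names(model$terms)
  for (nm in list(alpha = alpha, kt_max = kt_max, m0 = m0, p0 = p0)) {
    if (!all(genes %in% names(nm))) {
      abort("alpha, kt_max, m0 and p0 must be named by the model's genes.")
    }
  }
  if (!all(genes %in% names(K))) abort("`K` must be a list named by gene.")
  for (g in genes) {
    need <- length(model$terms[[g]]$regulators)
    if (length(K[[g]]) < need) {
      abort(sprintf("gene %s needs %d half-max constant(s).", g, need))
    }
  }
  pos <- c(k_m, k_p, unlist(K[genes]), k_t)
  nonneg <- c(unlist(alpha[genes]), unlist(kt_max[genes]),
              unlist(m0[genes]), unlist(p0[genes]))
  if (any(!is.finite(c(pos, nonneg))) || any(pos <= 0) || any(nonneg < 0)) {
    abort(paste("degradation rates, half-max constants and k_t must be",
                "positive; rates and initial conditions non-negative."))
  }
  structure(
    list(alpha = alpha[genes], kt_max = kt_max[genes], k_m = k_m, k_p = k_p,
         K = K[genes], m0 = m0[genes], p0 = p0[genes], k_t = k_t),
    class = "grn_params"
  )
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params>", if (is.null(x$k_t)) " (symmetry-reduced)" else
    sprintf(" (unreduced, k_t = %g)", x$k_t), "\n", sep = "")
  cat("  alpha:", paste(signif(unlist(x$alpha), 3), collapse = " "), "\n")
  cat("  kt_max:", paste(signif(unlist(x$kt_max), 3), collapse = " "), "\n")
  cat("  k_m:", signif(x$k_m, 3), " k_p:", signif(x$k_p, 3), "\n")
  invisible(x)
}

#' Evaluate one production term
#'
#' Computes the product of Hill factors of a term at given protein levels:
#' activation factors `x/(K + x)`, repression factors `K/(K + x)`, squared
#' single factors squared. The empty (knock-out-collapsed) term evaluates
#' to 0.
#'
#' @param term a [grn_term()].
#' @param protein_levels named numeric of non-negative protein levels, names
#'   from [grn_regulators()].
#' @param halfmax numeric vector of positive half-max constants, one per
#'   factor.
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' production_value(grn_term("N", "activation"), c(N = 5), 5)   # 0.5
#' production_value(grn_term("N", "repression"), c(N = 0), 2)   # 1
production_value <- function(term, protein_levels, halfmax) {
  stopifnot(inherits(term, "grn_term"))
  nfac <- length(term$regulators)
  if (nfac == 0) return(0)
  if (length(halfmax) < nfac) {
    abort("a half-max constant is required for every Hill factor.")
  }
  if (!all(term$regulators %in% names(protein_levels))) {
    abort("protein level missing for a regulator of this term.")
  }
  if (any(halfmax[seq_len(nfac)] <= 0)) abort("half-max constants must be positive.")
  value <- 1
  for (j in seq_len(nfac)) {
    x <- protein_levels[[term$regulators[j]]]
    K <- halfmax[[j]]
    h <- if (term$signs[j] == "activation") x / (K + x) else K / (K + x)
    if (term$exponent == 2L) h <- h * h
    value <- value * h
  }
  value
}

#' Right-hand side of the network ODE system (reference implementation)
#'
#' Pure-R evaluation of the time derivatives: for each modelled gene `g`,
#' `dM_g/dt = alpha_g + kt_g * F_g(proteins) - k_m * M_g` and
#' `dP_g/dt = k_t * M_g - k_p * P_g` (with `k_t = 1` in the reduced system).
#' Integration itself uses a compiled equivalent; this function is the
#' independent reference against which the compiled code is tested, and is
#' convenient for inspecting derivatives at a point.
#'
#' @param model a `grn_model`.
#' @param m named numeric, current mRNA levels by gene.
#' @param p named numeric, current protein levels by gene.
#' @param params a [grn_params()].
#' @return A list with components `dm` and `dp`, named by gene.
#' @export
grn_rhs <- function(model, m, p, params) {
  genes <- names(model$terms)
  prot <- setNames(as.numeric(p[genes]), gene_to_regulator(genes))
  k_t <- params$k_t %||% 1
  dm <- dp <- setNames(numeric(length(genes)), genes)
  for (g in genes) {
    term <- model$terms[[g]]
    if (!all(term$regulators %in% names(prot))) {
      abort(sprintf("term of gene %s references a protein not in the model.", g))
    }
    F <- production_value(term, prot, params$K[[g]])
    dm[g] <- params$alpha[[g]] + params$kt_max[[g]] * F - params$k_m * m[[g]]
    dp[g] <- k_t * m[[g]] - params$k_p * p[[g]]
  }
  list(dm = dm, dp = dp)
}

# Packing for the compiled derivative function -------------------------------

GRN_NPARMS <- 64L
REG_ID <- c(E = 1, N = 2, S = 3)
SIGN_ID <- c(activation = 0, repression = 1)

pack_parms <- function(model, params) {
  genes <- names(model$terms)
  ng <- length(genes)
  p <- numeric(GRN_NPARMS)
  p[1] <- ng
  p[2] <- params$k_t %||% 1
  p[3] <- params$k_m
  p[4] <- params$k_p
  for (g in seq_len(ng)) {
    term <- model$terms[[genes[g]]]
    if (!all(term$regulators %in% model$regulators)) {
      abort(sprintf("term of gene %s references a protein not in the model.",
                    genes[g]))
    }
    b <- 4 + (g - 1) * 12
    Kg <- params$K[[genes[g]]]
    nfac <- length(term$regulators)
    p[b + 1] <- REG_ID[[gene_to_regulator(genes[g])]]
    p[b + 2] <- params$alpha[[genes[g]]]
    p[b + 3] <- params$kt_max[[genes[g]]]
    p[b + 4] <- nfac
    if (nfac >= 1) {
      p[b + 5] <- REG_ID[[term$regulators[1]]]
      p[b + 6] <- SIGN_ID[[term$signs[1]]]
      p[b + 7] <- term$exponent
      p[b + 8] <- Kg[1]
    }
    if (nfac == 2) {
      p[b + 9] <- REG_ID[[term$regulators[2]]]
      p[b + 10] <- SIGN_ID[[term$signs[2]]]
      p[b + 11] <- Kg[2]
    }
  }
  p
}

pack_state <- function(model, params) {
  genes <- names(model$terms)
  c(as.numeric(params$m0[genes]), as.numeric(params$p0[genes]))
}

# Fast internal path: integrate and return the times x genes mRNA matrix, or
# NULL on integration failure. `parms` is a packed vector, `y0` a packed
# state. Times must start at 0.
sim_mrna_matrix <- function(parms, y0, times, rtol = 1e-8, atol = 1e-10) {
  ng <- as.integer(parms[1])
  out <- try(suppressWarnings(
    deSolve::lsoda(y0, times, func = "grn_derivs", parms = parms,
                   dllname = "grnsets", initfunc = "grn_init",
                   rtol = rtol, atol = atol)
  ), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  istate <- attr(out, "istate")
  rstate <- attr(out, "rstate")
  t_end <- times[length(times)]
  if (is.null(istate) || istate[1] != 2 || nrow(out) < length(times) ||
      (!is.null(rstate) && t_end > 0 && rstate[3] < t_end * (1 - 1e-8))) {
    return(NULL)
  }
  m <- out[, 2:(1 + ng), drop = FALSE]
  if (any(!is.finite(m)) || any(out[, -1] < -1e-9)) return(NULL)
  m
}

#' Simulate a regulatory network model
#'
#' Integrates the ODE system from `t = 0` with the initial conditions in
#' `params` using an adaptive stiff-capable solver (lsoda) with a compiled
#' right-hand side, and returns the trajectories at the requested times. Only
#' mRNA states are observable; protein trajectories (hidden states) are
#' returned on request.
#'
#' @param model a `grn_model`.
#' @param params a [grn_params()].
#' @param times non-negative, strictly increasing observation times (hours).
#' @param include_proteins also return the hidden protein states?
#' @param rtol,atol relative/absolute integration tolerances.
#' @return A tibble with columns `time_h`, `gene`, `species` (`"mRNA"` and
#'   optionally `"protein"`) and `value`. Integration failure raises a
#'   condition of class `grn_integration_failure` rather than returning
#'   clipped values.
#' @export
#' @examples
#' m <- named_models()$model_11574
#' p <- reference_params(m)
#' simulate_model(m, p, times = c(0, 12, 24, 48, 60, 72))
simulate_model <- function(model, params, times, include_proteins = FALSE,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "grn_model"), inherits(params, "grn_params"))
  times <- as.numeric(times)
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be non-negative and strictly increasing.")
  }
  solve_times <- if (length(times) == 0 || times[1] > 0) c(0, times) else times
  genes <- names(model$terms)
  ng <- length(genes)
  parms <- pack_parms(model, params)
  y0 <- pack_state(model, params)
  out <- try(suppressWarnings(
    deSolve::lsoda(y0, solve_times, func = "grn_derivs", parms = parms,
                   dllname = "grnsets", initfunc = "grn_init",
                   rtol = rtol, atol = atol)
  ), silent = TRUE)
  t_end <- solve_times[length(solve_times)]
  failed <- inherits(out, "try-error") ||
    attr(out, "istate")[1] != 2 || nrow(out) < length(solve_times) ||
    (t_end > 0 && attr(out, "rstate")[3] < t_end * (1 - 1e-8)) ||
    any(!is.finite(out[, -1])) || any(out[, -1] < -1e-9)
  if (failed) {
    abort("ODE integration failed (stiff failure or non-finite/negative state).",
          class = "grn_integration_failure")
  }
  keep <- solve_times %in% times
  mrna <- tibble::tibble(
    time_h = rep(solve_times[keep], times = ng),
    gene = rep(genes, each = sum(keep)),
    species = "mRNA",
    value = as.vector(out[keep, 2:(1 + ng), drop = FALSE])
  )
  if (!include_proteins) return(mrna[, c("time_h", "gene", "species", "value")])
  prot <- tibble::tibble(
    time_h = rep(solve_times[keep], times = ng),
    gene = rep(genes, each = sum(keep)),
    species = "protein",
    value = as.vector(out[keep, (2 + ng):(1 + 2 * ng), drop = FALSE])
  )
  dplyr::arrange(dplyr::bind_rows(mrna, prot), .data$gene, .data$species,
                 .data$time_h)
}

#' Apply the scaling symmetry of the unreduced system
#'
#' The unreduced model (explicit translation rate `k_t`) is invariant in its
#' mRNA observables under scaling all protein states and initial conditions,
#' all half-max constants and the translation rate by any `xi > 0`. This
#' transform is the basis of the numerical invariance test that motivates
#' fitting the reduced parameterization (`xi = 1/k_t`).
#'
#' @param params a [grn_params()] with non-`NULL` `k_t`.
#' @param xi positive scale factor.
#' @return The transformed `grn_params`.
#' @export
apply_scaling_symmetry <- function(params, xi) {
  stopifnot(inherits(params, "grn_params"))
  if (!is.numeric(xi) || length(xi) != 1 || xi <= 0) {
    abort("`xi` must be a single positive number.")
  }
  if (is.null(params$k_t)) {
    abort("the scaling symmetry is defined on the unreduced system (k_t set).")
  }
  params$p0 <- unlist(params$p0) * xi
  params$K <- lapply(params$K, function(v) v * xi)
  params$k_t <- params$k_t * xi
  params
}
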