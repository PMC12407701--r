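# Parameter bounds, free/fixed layout, Latin-hypercube multistart and the
# bounded quasi-Newton fit of one structure or a whole family.

#' Default optimization bounds
#'
#' Unscaled kinetic parameters (basal and maximal transcription rates,
#' degradation rates, mRNA initial conditions) are bounded in
#' `[1e-5, 1e4 + 1]` with Latin-hypercube starts log-uniform over
#' `[1e-4, 1e4]`; translation-rate-scaled parameters (half-max constants and
#' the scaled NHR-40 protein initial condition) in `[1e-9, 1e8 + 1]` with
#' starts over `[1e-8, 1e8]`.
#'
#' @return A list with elements `unscaled` and `scaled`, each containing
#'   `lower`, `upper`, `lhs_lo`, `lhs_hi`.
#' @export
default_bounds <- function() {
  list(
    unscaled = list(lower = 1e-5, upper = 1e4 + 1, lhs_lo = 1e-4, lhs_hi = 1e4),
    scaled = list(lower = 1e-9, upper = 1e8 + 1, lhs_lo = 1e-8, lhs_hi = 1e8)
  )
}

#' Free/fixed parameter layout for fitting one structure
#'
#' Assembles the free parameter vector of a model: per gene the basal rate,
#' maximal regulated rate and mRNA initial condition; the shared degradation
#' rates; one half-max constant per Hill factor. The EUD-1 and SULT-1 protein
#' initial conditions are fixed to a low preset value (their expression is
#' low in all experiments); the scaled NHR-40 initial condition is free
#' exactly when N appears in at least one production term of the model
#' (when it does not, it is unidentifiable and fixed to the preset).
#'
#' @param model a `grn_model`.
#' @param bounds from [default_bounds()].
#' @param preset_p0 the fixed low protein initial condition (scaled units).
#' @return A tibble with one row per parameter: `name`, `gene`, `role`
#'   (`"unscaled"`/`"scaled"`), `free`, `fixed_value`, `lower`, `upper`,
#'   `lhs_lo`, `lhs_hi`.
#' @export
parameter_spec <- function(model, bounds = default_bounds(),
                           preset_p0 = 1e-3) {
  genes <- names(model$terms)
  rows <- list()
  add <- function(name, gene, role, free, fixed_value = NA_real_) {
    b <- bounds[[role]]
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = name, gene = gene, role = role, free = free,
      fixed_value = fixed_value, lower = b$lower, upper = b$upper,
      lhs_lo = b$lhs_lo, lhs_hi = b$lhs_hi
    )
  }
  for (g in genes) add(paste0("alpha_", g), g, "unscaled", TRUE)
  for (g in genes) add(paste0("ktmax_", g), g, "unscaled", TRUE)
  add("k_m", NA_character_, "unscaled", TRUE)
  add("k_p", NA_character_, "unscaled", TRUE)
  for (g in genes) add(paste0("m0_", g), g, "unscaled", TRUE)
  for (g in genes) {
    nfac <- length(model$terms[[g]]$regulators)
    for (j in seq_len(nfac)) {
      add(paste0("K_", g, "_", j), g, "scaled", TRUE)
    }
  }
  n_referenced <- any(vapply(model$terms, function(t) "N" %in% t$regulators,
                             logical(1)))
  for (g in genes) {
    free <- g == "nhr-40" && n_referenced
    add(paste0("p0_", g), g, "scaled", free,
        fixed_value = if (!free) preset_p0)
  }
  dplyr::bind_rows(rows)
}

#' Latin-hypercube multistart points
#'
#' A stratified unit-hypercube sample (one point per stratum and dimension)
#' mapped log-uniformly onto each free parameter's start range, so every
#' start lies strictly inside the optimizer bounds.
#'
#' @param n_starts number of start points.
#' @param spec a [parameter_spec()] (only free rows are sampled).
#' @param seed integer seed.
#' @return A numeric matrix, `n_starts` rows by one column per free
#'   parameter, on the natural parameter scale.
#' @export
lhs_starts <- function(n_starts, spec, seed) {
  free <- spec[spec$free, ]
  d <- nrow(free)
  if (n_starts < 1) abort("`n_starts` must be at least 1.")
  set.seed(seed)
  u <- lhs::randomLHS(n_starts, d)
  lo <- log10(free$lhs_lo)
  hi <- log10(free$lhs_hi)
  starts <- 10^sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(starts) <- free$name
  starts
}

# Fast objective construction ------------------------------------------------

# Precomputes the packed parameter template, index maps from the free vector
# into the packed parms / initial state, and the observation lookup, then
# returns the sigma-profiled negative log-likelihood as a function of the
# log10 free-parameter vector.
make_objective <- function(model, data, spec, options = list()) {
  genes <- names(model$terms)
  if (!setequal(unique(data$gene), genes)) {
    abort("dataset genes must match the model's observed genes.")
  }
  rtol <- options$rtol %||% 1e-6
  atol <- options$atol %||% 1e-8
  sigma_floor <- options$sigma_floor %||% 1e-6
  times <- sort(unique(data$time_h))
  solve_times <- if (times[1] > 0) c(0, times) else times
  row_of_time <- match(data$time_h, solve_times)
  col_of_gene <- match(data$gene, genes)
  obs_idx <- cbind(row_of_time, col_of_gene)
  y <- data$value
  ng <- length(genes)

  # template packing with placeholder positives, then overwrite
  placeholder <- grn_params(
    model,
    alpha = setNames(rep(1, ng), genes), kt_max = setNames(rep(1, ng), genes),
    k_m = 1, k_p = 1,
    K = setNames(lapply(genes, function(g) {
      rep(1, max(1, length(model$terms[[g]]$regulators)))
    }), genes),
    m0 = setNames(rep(1, ng), genes), p0 = setNames(rep(1, ng), genes)
  )
  parms0 <- pack_parms(model, placeholder)
  y0 <- pack_state(model, placeholder)

  # map each spec row to its slot
  slot_of <- function(name, gene) {
    g <- match(gene, genes)
    b <- 4L + (g - 1L) * 12L
    if (startsWith(name, "alpha_")) c(1L, b + 2L)
    else if (startsWith(name, "ktmax_")) c(1L, b + 3L)
    else if (name == "k_m") c(1L, 3L)
    else if (name == "k_p") c(1L, 4L)
    else if (startsWith(name, "m0_")) c(2L, g)
    else if (startsWith(name, "K_")) {
      j <- as.integer(sub(".*_", "", name))
      c(1L, b + if (j == 1L) 8L else 11L)
    } else if (startsWith(name, "p0_")) c(2L, ng + g)
    else abort(paste("unknown parameter", name))
  }
  slots <- t(vapply(seq_len(nrow(spec)), function(i) {
    slot_of(spec$name[i], spec$gene[i])
  }, integer(2)))
  fixed <- which(!spec$free)
  for (i in fixed) {
    if (slots[i, 1] == 1L) parms0[slots[i, 2]] <- spec$fixed_value[i]
    else y0[slots[i, 2]] <- spec$fixed_value[i]
  }
  free_slots <- slots[spec$free, , drop = FALSE]
  in_parms <- free_slots[, 1] == 1L
  parms_pos <- free_slots[in_parms, 2]
  y0_pos <- free_slots[!in_parms, 2]

  function(log_theta) {
    theta <- 10^log_theta
    parms <- parms0
    st <- y0
    parms[parms_pos] <- theta[in_parms]
    st[y0_pos] <- theta[!in_parms]
    m <- sim_mrna_matrix(parms, st, solve_times, rtol = rtol, atol = atol)
    if (is.null(m)) return(grn_penalty())
    x <- m[obs_idx]
    profiled_nll(x, y, sigma_floor)
  }
}

# Deterministic data-informed warm starts. A small grid of nominal starting
# points built from summary statistics of the data: degradation rates from a
# plausible range of turnover timescales, transcription rates sized so that
# steady-state mRNA matches the observed mean, mRNA initial conditions at
# the observed t = 0 means, and half-max constants at (a multiple of) the
# implied scale of the regulating protein. These complement the log-uniform
# LHS starts, which rarely land at mutually consistent scales in a
# 9-17-decade search box.
warm_start_matrix <- function(model, data, spec) {
  free <- spec[spec$free, ]
  genes <- names(model$terms)
  gm <- tapply(data$value, data$gene, mean)
  d0 <- data[data$time_h == min(data$time_h), ]
  g0 <- tapply(d0$value, d0$gene, mean)
  kp <- 0.1
  variants <- expand.grid(km = c(0.05, 0.1, 0.2, 0.4),
                          kmult = c(0.3, 1, 3))
  starts <- matrix(NA_real_, nrow(variants), nrow(free),
                   dimnames = list(NULL, free$name))
  for (v in seq_len(nrow(variants))) {
    km <- variants$km[v]
    kmult <- variants$kmult[v]
    s <- setNames(numeric(nrow(free)), free$name)
    for (g in genes) {
      if (paste0("alpha_", g) %in% free$name) {
        s[paste0("alpha_", g)] <- 0.1 * gm[[g]] * km
      }
      if (paste0("ktmax_", g) %in% free$name) {
        s[paste0("ktmax_", g)] <- 2 * gm[[g]] * km
      }
      if (paste0("m0_", g) %in% free$name) {
        s[paste0("m0_", g)] <- max(g0[[g]], 1e-4)
      }
    }
    s["k_m"] <- km
    s["k_p"] <- kp
    pscale <- gm / kp
    for (nm in free$name[startsWith(free$name, "K_")]) {
      parts <- strsplit(nm, "_")[[1]]
      gene <- parts[2]
      j <- as.integer(parts[3])
      reg <- model$terms[[gene]]$regulators[j]
      reg_gene <- regulator_to_gene(reg)
      s[nm] <- kmult * pscale[[reg_gene]]
    }
    if ("p0_nhr-40" %in% free$name) {
      s["p0_nhr-40"] <- 0.1 * pscale[["nhr-40"]]
    }
    starts[v, ] <- pmin(pmax(s, free$lhs_lo), free$lhs_hi)
  }
  starts
}

derive_seed <- function(master, unit) {
  as.integer((as.numeric(master) * 48271 + as.numeric(unit) * 10007 + 1) %%
               2147483629)
}

#' Fit one model structure by multistart maximum likelihood
#'
#' Minimizes the sigma-profiled multiplicative-error negative log-likelihood
#' over the model's free parameters with bounded quasi-Newton (L-BFGS-B)
#' local searches started from Latin-hypercube points. Optimization runs in
#' log10 parameter space (the bounds span 9-17 decades and starts are
#' log-uniform, so log coordinates are the natural metric). The best few
#' exploratory finishes are polished with a longer iteration budget.
#'
#' @param model a `grn_model`.
#' @param data tibble with columns `gene`, `time_h`, `replicate`, `value`;
#'   its genes must equal the model's genes (knocked-out gene excluded).
#' @param n_starts number of Latin-hypercube starts.
#' @param seed integer seed for the start sample.
#' @param bounds from [default_bounds()].
#' @param options list of optional settings: `maxit` (exploration iteration
#'   cap, default 200), `n_polish` and `maxit_polish` (top finishes refined,
#'   default 5 and 400), `n_hops`/`hop_sd`/`maxit_hop`/`hop_patience`
#'   (monotone basin-hopping refinement of the incumbent; defaults 20, 1,
#'   60, 10; `n_hops = 0` disables), `warm_starts` (append a deterministic
#'   grid of data-informed nominal starts to the LHS sample; default TRUE),
#'   `pgtol` (default 1e-8), `sigma_floor`
#'   (1e-6), `preset_p0` (1e-3), `rtol`/`atol` (integration tolerances
#'   during fitting, 1e-6/1e-8).
#' @return An object of class `grn_fit` with elements `model`, `theta`
#'   (tibble of all parameters at the optimum), `sigma_hat`, `nll`,
#'   `predictions` (fitted trajectory at the observation times),
#'   `starts` (per-start finishing values), `n_failed_starts`, `failed`,
#'   `seed`.
#' @export
fit_model <- function(model, data, n_starts = 100, seed = 1,
                      bounds = default_bounds(), options = list()) {
  stopifnot(inherits(model, "grn_model"))
  spec <- parameter_spec(model, bounds, options$preset_p0 %||% 1e-3)
  obj <- make_objective(model, data, spec, options)
  starts <- lhs_starts(n_starts, spec, seed)
  if (isTRUE(options$warm_starts %||% TRUE)) {
    starts <- rbind(starts, warm_start_matrix(model, data, spec))
  }
  n_total <- nrow(starts)
  free <- spec[spec$free, ]
  lower <- log10(free$lower)
  upper <- log10(free$upper)
  maxit <- options$maxit %||% 200
  pgtol <- options$pgtol %||% 1e-8
  # forward-difference gradient in log10 space (d+1 evaluations instead of
  # the 2d of internal central differences; step matches optim's ndeps)
  grad <- function(v) {
    f0 <- obj(v)
    h <- 1e-3
    vapply(seq_along(v), function(j) {
      vj <- v
      vj[j] <- vj[j] + h
      (obj(vj) - f0) / h
    }, numeric(1))
  }
  run_optim <- function(par0, iter) {
    res <- try(optim(par0, obj, gr = grad, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = iter, pgtol = pgtol)),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      list(par = par0, value = grn_penalty(), convergence = 99L)
    } else res
  }
  # DLSODA prints step-limit diagnostics straight from Fortran during
  # infeasible excursions; silence stdout for the optimization phase only
  sink(nullfile(), type = "output")
  on.exit(sink(), add = TRUE)
  results <- lapply(seq_len(n_total), function(i) {
    run_optim(log10(starts[i, ]), maxit)
  })
  values <- vapply(results, function(r) r$value, numeric(1))
  n_polish <- min(options$n_polish %||% 5, n_total)
  polish_idx <- order(values)[seq_len(n_polish)]
  for (i in polish_idx) {
    if (values[i] >= grn_penalty()) next
    pol <- run_optim(results[[i]]$par, options$maxit_polish %||% 400)
    if (pol$value < values[i]) {
      results[[i]] <- pol
      values[i] <- pol$value
    }
  }
  best_i <- which.min(values)
  best <- results[[best_i]]
  # monotone basin-hopping refinement: restart short local searches from
  # log-normal perturbations of the incumbent, keeping only improvements;
  # stops early after `hop_patience` consecutive non-improvements
  n_hops <- options$n_hops %||% 20
  if (n_hops > 0 && best$value < grn_penalty()) {
    hop_sd <- options$hop_sd %||% 1
    maxit_hop <- options$maxit_hop %||% 60
    patience <- options$hop_patience %||% 10
    set.seed(derive_seed(seed, 777))
    stale <- 0
    for (hop in seq_len(n_hops)) {
      if (stale >= patience) break
      par0 <- pmin(pmax(best$par + rnorm(length(best$par), 0, hop_sd),
                        lower), upper)
      cand <- run_optim(par0, maxit_hop)
      if (cand$value < best$value) {
        best <- cand
        stale <- 0
      } else {
        stale <- stale + 1
      }
    }
  }
  failed <- best$value >= grn_penalty()
  theta_free <- 10^best$par
  theta <- tibble::tibble(
    name = spec$name, gene = spec$gene, role = spec$role, free = spec$free,
    value = ifelse(spec$free, NA_real_, spec$fixed_value)
  )
  theta$value[spec$free] <- theta_free
  predictions <- NULL
  sigma_hat <- NA_real_
  if (!failed) {
    params <- params_from_spec(model, spec, theta$value)
    times <- sort(unique(data$time_h))
    traj <- simulate_model(model, params, times,
                           rtol = options$rtol %||% 1e-6,
                           atol = options$atol %||% 1e-8)
    x <- traj$value[match(paste(data$gene, data$time_h),
                          paste(traj$gene, traj$time_h))]
    sigma_hat <- profile_sigma(x, data$value,
                               options$sigma_floor %||% 1e-6)
    predictions <- dplyr::distinct(
      tibble::tibble(gene = data$gene, time_h = data$time_h, value = x)
    )
  }
  structure(
    list(
      model = model, spec = spec, theta = theta, sigma_hat = sigma_hat,
      nll = best$value, predictions = predictions,
      starts = tibble::tibble(
        start = seq_len(n_total), nll = values,
        convergence = vapply(results, function(r) as.integer(r$convergence),
                             integer(1))
      ),
      n_failed_starts = sum(values >= grn_penalty()),
      failed = failed, seed = seed, data = data
    ),
    class = "grn_fit"
  )
}

# Rebuild a grn_params from a spec and the full value vector.
params_from_spec <- function(model, spec, values) {
  genes <- names(model$terms)
  val <- setNames(values, spec$name)
  K <- lapply(genes, function(g) {
    nfac <- length(model$terms[[g]]$regulators)
    if (nfac == 0) return(1) # placeholder; unused by an empty term
    unname(val[paste0("K_", g, "_", seq_len(nfac))])
  })
  grn_params(
    model,
    alpha = setNames(unname(val[paste0("alpha_", genes)]), genes),
    kt_max = setNames(unname(val[paste0("ktmax_", genes)]), genes),
    k_m = unname(val["k_m"]), k_p = unname(val["k_p"]),
    K = setNames(K, genes),
    m0 = setNames(unname(val[paste0("m0_", genes)]), genes),
    p0 = setNames(unname(val[paste0("p0_", genes)]), genes)
  )
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("<grn_fit>", if (x$failed) " FAILED" else "", "\n", sep = "")
  print(x$model)
  cat("  nll = ", format(x$nll, digits = 8), ", sigma_hat = ",
      format(x$sigma_hat, digits = 4), ", ", x$n_failed_starts,
      " failed start(s) of ", nrow(x$starts), "\n", sep = "")
  invisible(x)
}

#' Fit every structure of a family (or a subset)
#'
#' Runs [fit_model()] for each requested family member with a per-model seed
#' derived deterministically from the master seed and the model index, so the
#' whole table is reproducible and resumable. Per-model results can be
#' checkpointed as JSON records and are then skipped on re-runs.
#'
#' @param family a `grn_family`.
#' @param data the experiment's dataset (genes matching the family's genes).
#' @param n_starts starts per model.
#' @param seed master seed.
#' @param indices 0-based model indices to fit (default: the whole family).
#' @param checkpoint_dir optional directory for per-model JSON checkpoints.
#' @param options passed to [fit_model()].
#' @return A tibble sorted by increasing `nll` with columns `model_index`,
#'   `signature`, `nll`, `sigma_hat`, `converged`, `n_failed_starts`,
#'   `failed` and a `theta` list-column of parameter tables.
#' @export
fit_family <- function(family, data, n_starts = 100, seed = 1,
                       indices = NULL, checkpoint_dir = NULL,
                       options = list()) {
  stopifnot(inherits(family, "grn_family"))
  indices <- indices %||% (seq_len(family$size) - 1)
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  rows <- purrr::map(indices, function(idx) {
    ckpt <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("model_%06d.json", idx))
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      rec <- jsonlite::fromJSON(ckpt)
      return(tibble::tibble(
        model_index = idx, signature = rec$signature, nll = rec$nll,
        sigma_hat = rec$sigma_hat, converged = rec$converged,
        n_failed_starts = rec$n_failed_starts, failed = rec$failed,
        theta = list(tibble::as_tibble(rec$theta))
      ))
    }
    model <- model_from_index(family, idx)
    fit <- fit_model(model, data, n_starts = n_starts,
                     seed = derive_seed(seed, idx), options = options)
    sig <- paste(vapply(model$terms, term_signature, character(1)),
                 collapse = " | ")
    row <- tibble::tibble(
      model_index = idx, signature = sig, nll = fit$nll,
      sigma_hat = fit$sigma_hat,
      converged = !fit$failed && any(fit$starts$convergence == 0),
      n_failed_starts = fit$n_failed_starts, failed = fit$failed,
      theta = list(fit$theta)
    )
    if (!is.null(ckpt)) {
      rec <- as.list(row[, c("signature", "nll", "sigma_hat", "converged",
                             "n_failed_starts", "failed")])
      rec$theta <- fit$theta
      jsonlite::write_json(rec, ckpt, auto_unbox = TRUE, digits = NA)
    }
    row
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$nll, .data$model_index)
}
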