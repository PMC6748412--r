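# Bounded global maximum likelihood by differential evolution, the
# variant-specific optimization bounds, and AIC model comparison.

structural_names <- function(variant) {
  switch(variant,
         ISDDE = c("K", "B", "P", "D", "a", "r", "tau", "sigma", "eps"),
         SDDE = c("K", "B", "P", "D", "tau", "sigma", "eps"),
         SDE = c("K", "B", "sigma", "eps"))
}

nuisance_names <- function(variant) {
  if (variant == "SDE") c("x0", "xdot0", "mu") else c("x0", "xdot0", "xddot0", "mu")
}

#' Differential-evolution settings
#'
#' Defaults follow the recommended strategy for this likelihood surface:
#' DE/rand/1/bin with per-vector dither (each trial vector draws its own
#' scale factor uniformly from `[f, 1]`), a high crossover probability to
#' cope with strong parameter dependence, and a long iteration cap with a
#' no-improvement stopping window.
#'
#' @param iterations iteration cap.
#' @param population population size (`>= 4`).
#' @param cr crossover probability in `[0, 1]`.
#' @param f lower end of the dithered scale factor, in `(0, 2]`.
#' @param c success-weighting constant; `0` disables self-adaptation (plain
#'   rand/1/bin), the only supported value.
#' @param step_tol number of consecutive iterations with relative
#'   improvement below `rel_tol` after which the search stops.
#' @param rel_tol relative objective tolerance for the stopping window.
#' @param seed optional integer seed.
#' @return a list of class `de_settings`.
#' @export
de_settings <- function(iterations = 15000, population = 30, cr = 0.95,
                        f = 0.15, c = 0, step_tol = 500, rel_tol = 1e-10,
                        seed = NULL) {
  stopifnot(population >= 4, cr >= 0, cr <= 1, f > 0, f <= 2, c == 0,
            iterations >= 1, step_tol >= 1, rel_tol >= 0)
  structure(list(iterations = as.integer(iterations),
                 population = as.integer(population), cr = cr, f = f, c = c,
                 step_tol = as.integer(step_tol), rel_tol = rel_tol,
                 seed = seed),
            class = "de_settings")
}

#' Minimize a bounded objective by DE/rand/1/bin with dither
#'
#' @param fn objective returning a finite scalar or `Inf`/`NA` (treated as
#'   `Inf`). With `vectorized = TRUE`, `fn` receives a matrix with one
#'   candidate per row and must return one value per row.
#' @param lower,upper bound vectors of equal length.
#' @param settings a [de_settings()] object.
#' @param vectorized whether `fn` is population-vectorized.
#' @param init_pop optional initial population (one candidate per row,
#'   clipped into the bounds); rows beyond `settings$population` are
#'   dropped, missing rows are drawn uniformly.
#' @return list with `par`, `value`, `iterations`, `converged`, the
#'   best-value `trace`, and the final `population` with its `fitness`.
#' @export
de_optimize <- function(fn, lower, upper, settings = de_settings(),
                        vectorized = FALSE, init_pop = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  if (!is.null(settings$seed)) set.seed(settings$seed)
  d <- length(lower)
  np <- settings$population
  span <- upper - lower

  evalp <- function(X) {
    if (vectorized) {
      v <- fn(X)
    } else {
      v <- numeric(nrow(X))
      for (i in seq_len(nrow(X))) v[i] <- fn(X[i, ])
    }
    v[!is.finite(v)] <- Inf
    v
  }

  pop <- matrix(runif(np * d), np, d) %*% diag(span, d, d) +
    matrix(lower, np, d, byrow = TRUE)
  if (!is.null(init_pop)) {
    init_pop <- as.matrix(init_pop)
    stopifnot(ncol(init_pop) == d)
    k <- min(nrow(init_pop), np)
    pop[seq_len(k), ] <- init_pop[seq_len(k), , drop = FALSE]
    pop <- pmin(pmax(pop, matrix(lower, np, d, byrow = TRUE)),
                matrix(upper, np, d, byrow = TRUE))
  }
  fit <- evalp(pop)
  best_i <- which.min(fit)
  best_v <- fit[best_i]
  trace <- numeric(0)
  stall <- 0L
  iters <- 0L
  converged <- FALSE

  lo <- matrix(lower, np, d, byrow = TRUE)
  hi <- matrix(upper, np, d, byrow = TRUE)
  idx <- seq_len(np)
  for (g in seq_len(settings$iterations)) {
    iters <- g
    prev_best <- best_v
    Fi <- runif(np, settings$f, 1)          # per-vector dither
    # three distinct partners per target vector, none equal to the target
    r1 <- sample.int(np, np, replace = TRUE)
    r2 <- sample.int(np, np, replace = TRUE)
    r3 <- sample.int(np, np, replace = TRUE)
    for (rep_ in 1:8) {
      bad <- r1 == idx | r2 == idx | r3 == idx | r1 == r2 | r1 == r3 |
        r2 == r3
      if (!any(bad)) break
      nb <- sum(bad)
      r1[bad] <- sample.int(np, nb, replace = TRUE)
      r2[bad] <- sample.int(np, nb, replace = TRUE)
      r3[bad] <- sample.int(np, nb, replace = TRUE)
    }
    mut <- pop[r1, , drop = FALSE] +
      Fi * (pop[r2, , drop = FALSE] - pop[r3, , drop = FALSE])
    mask <- matrix(runif(np * d) < settings$cr, np, d)
    mask[cbind(idx, sample.int(d, np, replace = TRUE))] <- TRUE
    trial <- pop
    trial[mask] <- mut[mask]
    trial <- pmin(pmax(trial, lo), hi)
    fv <- evalp(trial)
    take <- fv <= fit
    pop[take, ] <- trial[take, , drop = FALSE]
    fit[take] <- fv[take]
    best_i <- which.min(fit)
    best_v <- fit[best_i]
    trace <- c(trace, best_v)

    rel_imp <- (prev_best - best_v) / max(1, abs(best_v))
    stall <- if (is.finite(rel_imp) && rel_imp < settings$rel_tol)
      stall + 1L else 0L
    if (stall >= settings$step_tol) {
      converged <- TRUE
      break
    }
  }
  if (!is.finite(best_v)) {
    stop("differential evolution failed: objective never finite within bounds")
  }
  list(par = pop[best_i, ], value = best_v, iterations = iters,
       converged = converged, trace = trace,
       population = pop, fitness = fit)
}

#' Optimization bounds per variant and context
#'
#' Returns the `[lower, upper]` box for every estimated coordinate. The
#' `"simulation"` context is the box used for the recovery studies (one set
#' for all parameters, e.g. `tau` in `[0.15, 0.25]`); the `"empirical"`
#' context is the variant-specific box for fitting measured sway, with
#' theoretically motivated restrictions for the delayed variants (non-negative
#' friction, a small insensitivity radius) and looser, sign-free ranges for
#' the SDE.
#'
#' @param variant `"ISDDE"`, `"SDDE"` or `"SDE"`.
#' @param context `"simulation"` or `"empirical"`.
#' @return data.frame with columns `parameter`, `lower`, `upper` covering
#'   the structural parameters and one generic nuisance block (`x0`,
#'   `xdot0`, `xddot0`, `mu`) applied to every trial.
#' @export
default_bounds <- function(variant = "ISDDE",
                           context = c("simulation", "empirical")) {
  variant <- match.arg(toupper(variant), VARIANTS)
  context <- match.arg(context)
  tab <- if (context == "simulation") {
    c(K = "0,1", B = "-1000,1000", P = "0,2", D = "-1000,1000", a = "0,1",
      r = "0,2", tau = "0.15,0.25", sigma = "0,5", eps = "0,1",
      x0 = "-10,10", xdot0 = "-50,50", xddot0 = "-100,100", mu = "-20,20")
  } else {
    switch(variant,
      ISDDE = c(K = "0,1", B = "0,2000", P = "0,2", D = "-2000,2000",
                a = "0,1", r = "0,0.1", tau = "0,1", sigma = "0,5",
                eps = "0,0.03", x0 = "-5,5", xdot0 = "-150,150",
                xddot0 = "-500,500", mu = "-1,1"),
      SDDE = c(K = "0,1", B = "0,2000", P = "-2,2", D = "-2000,2000",
               tau = "0,1", sigma = "0,5", eps = "0,0.03", x0 = "-5,5",
               xdot0 = "-150,150", xddot0 = "-500,500", mu = "-1,1"),
      SDE = c(K = "-10,10", B = "-2000,2000", sigma = "0,100", eps = "0,10",
              x0 = "-5,5", xdot0 = "-150,150", mu = "-1,1"))
  }
  keep <- c(structural_names(variant), nuisance_names(variant))
  tab <- tab[keep]
  lims <- do.call(rbind, lapply(strsplit(unname(tab), ","), as.numeric))
  data.frame(parameter = keep, lower = lims[, 1], upper = lims[, 2],
             stringsAsFactors = FALSE)
}

# assemble the full optimization vector layout for a variant and trial count
fit_layout <- function(variant, n_trials, bounds) {
  sn <- structural_names(variant)
  nn <- nuisance_names(variant)
  rownames(bounds) <- bounds$parameter
  names_all <- c(sn, unlist(lapply(seq_len(n_trials), function(j) {
    paste0(nn, "_", j)
  })))
  base <- c(sn, rep(nn, n_trials))
  list(names = names_all,
       lower = bounds[base, "lower"],
       upper = bounds[base, "upper"],
       sn = sn, nn = nn, n_trials = n_trials)
}

theta_to_model <- function(theta, layout, variant) {
  sv <- setNames(theta[seq_along(layout$sn)], layout$sn)
  full <- c(K = 0, B = 0, P = 0, D = 0, a = 0, r = 0, tau = 0, sigma = 0,
            eps = 0)
  full[names(sv)] <- sv
  params <- do.call(ipc_params, as.list(full))
  nuisances <- vector("list", layout$n_trials)
  off <- length(layout$sn)
  nl <- length(layout$nn)
  for (j in seq_len(layout$n_trials)) {
    nv <- setNames(theta[off + (j - 1) * nl + seq_len(nl)], layout$nn)
    nuisances[[j]] <- do.call(ipc_nuisance, as.list(nv))
  }
  list(params = params, nuisances = nuisances)
}

#' Fit an IPC variant by differential-evolution maximum likelihood
#'
#' Minimizes the joint -2 log-likelihood of one or more trials over the
#' concatenated vector of shared structural parameters and per-trial
#' nuisance parameters, within the given bounds.
#'
#' @param trials an [ipc_trajectory()] or a list of them (shared sampling
#'   rate).
#' @param variant `"ISDDE"`, `"SDDE"` or `"SDE"`.
#' @param bounds a data.frame as returned by [default_bounds()] (or `NULL`
#'   for the default box of `context`).
#' @param settings a [de_settings()] object.
#' @param constants [ipc_constants()].
#' @param context bound context when `bounds` is `NULL`.
#' @param compat_lag use the paper-compatibility lag-interpolation sign.
#' @param n_starts number of independent differential-evolution starts; the
#'   likelihood surface is multimodal (local optimizers reliably fail on it,
#'   and single DE runs can be captured by a near-passive local optimum), so
#'   the fit keeps the best of `n_starts` seeded runs. Start seeds are fanned
#'   out from `settings$seed` via [seed_stream()].
#' @param start_iterations when `n_starts > 1`, an optional reduced
#'   iteration cap for the screening starts; the best screening population
#'   is then refined under the full `settings` budget. `NULL` runs every
#'   start at the full budget.
#' @param profile_tau the delay axis has comb-like local optima (a delay
#'   error can be partially compensated by the other gains), so searches can
#'   converge with the delay pinned at a bound. With `profile_tau = TRUE`
#'   the refined solution is re-optimized within each quarter of the delay
#'   bounds (population re-seeded there) and the best likelihood kept.
#'   Ignored by the delay-free variant.
#' @return an object of class `ipc_fit`: estimates, per-trial nuisance,
#'   `minus2LL`, `AIC`, `n_parameters`, optimizer diagnostics, and flags for
#'   boundary-pinned estimates.
#' @export
ipc_fit <- function(trials, variant = "ISDDE", bounds = NULL,
                    settings = de_settings(), constants = ipc_constants(),
                    context = "simulation", compat_lag = FALSE,
                    n_starts = 1, start_iterations = NULL,
                    profile_tau = FALSE) {
  if (inherits(trials, "ipc_trajectory")) trials <- list(trials)
  stopifnot(length(trials) >= 1,
            all(vapply(trials, inherits, logical(1), "ipc_trajectory")))
  variant <- match.arg(toupper(variant), VARIANTS)
  if (is.null(bounds)) bounds <- default_bounds(variant, context)
  layout <- fit_layout(variant, length(trials), bounds)

  ys <- lapply(trials, function(tr) tr$values)
  dt <- trials[[1]]$dt
  vc <- variant_code(variant)
  m <- constants$mass; h <- constants$com_height
  g <- constants$gravity; I <- constants$inertia
  ns <- length(layout$sn)
  nl <- length(layout$nn)
  has_xdd <- "xddot0" %in% layout$nn
  sidx <- setNames(seq_len(ns), layout$sn)
  gets <- function(theta, nm) if (nm %in% layout$sn) theta[[sidx[[nm]]]] else 0

  objective <- function(theta) {
    tot <- 0
    K <- gets(theta, "K"); B <- gets(theta, "B"); P <- gets(theta, "P")
    D <- gets(theta, "D"); a <- gets(theta, "a"); r <- gets(theta, "r")
    tau <- gets(theta, "tau"); sigma <- gets(theta, "sigma")
    eps <- gets(theta, "eps")
    for (j in seq_along(ys)) {
      off <- ns + (j - 1) * nl
      x0 <- theta[[off + 1]]
      xd0 <- theta[[off + 2]]
      xdd0 <- if (has_xdd) theta[[off + 3]] else 0
      mu <- theta[[off + nl]]
      v <- cpp_m2ll(ys[[j]], dt, K, B, P, D, a, r, tau, sigma, eps,
                    x0, xd0, xdd0, mu, m, h, g, I, vc, compat_lag, 0)
      if (!is.finite(v)) return(Inf)
      tot <- tot + v
    }
    tot
  }

  stopifnot(n_starts >= 1)
  start_seeds <- if (is.null(settings$seed)) rep(list(NULL), n_starts) else
    as.list(seed_stream(settings$seed, n_starts + 1))
  opt <- NULL
  n_used <- 0L
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    st <- settings
    st$seed <- start_seeds[[i]]
    if (!is.null(start_iterations) && n_starts > 1) {
      st$iterations <- as.integer(start_iterations)
      st$step_tol <- min(st$step_tol, as.integer(ceiling(start_iterations / 4)))
    }
    o <- de_optimize(objective, layout$lower, layout$upper, st)
    n_used <- n_used + o$iterations
    runs[[i]] <- o
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  if (!is.null(start_iterations) && n_starts > 1) {
    # refine the best screening populations under the full budget; distinct
    # shallow basins can rank above the deep one at the screening stage, so
    # more than one candidate population is carried forward
    vals <- vapply(runs, function(o) o$value, numeric(1))
    refine <- order(vals)[seq_len(min(3L, n_starts))]
    for (k in seq_along(refine)) {
      st <- settings
      st$seed <- start_seeds[[n_starts + 1]] + k - 1L
      o <- de_optimize(objective, layout$lower, layout$upper, st,
                       init_pop = runs[[refine[k]]]$population)
      n_used <- n_used + o$iterations
      if (o$value <= opt$value) opt <- o
    }
  }
  if (profile_tau && variant != "SDE") {
    ti <- match("tau", layout$sn)
    tlo <- layout$lower[ti]
    thi <- layout$upper[ti]
    if (thi > tlo) {
      edges <- seq(tlo, thi, length.out = 5)
      for (k in 1:4) {
        st <- settings
        st$seed <- start_seeds[[n_starts + 1]] + 10L + k
        st$iterations <- min(st$iterations, 1500L)
        st$step_tol <- min(st$step_tol, 200L)
        lo2 <- layout$lower; hi2 <- layout$upper
        lo2[ti] <- edges[k]; hi2[ti] <- edges[k + 1]
        set.seed(st$seed)
        ip <- opt$population
        ip[, ti] <- runif(nrow(ip), edges[k], edges[k + 1])
        o <- de_optimize(objective, lo2, hi2, st, init_pop = ip)
        n_used <- n_used + o$iterations
        if (o$value < opt$value) opt <- o
      }
      # final polish over the full box from the winning population
      st <- settings
      st$seed <- start_seeds[[n_starts + 1]] + 20L
      st$iterations <- min(st$iterations, 1000L)
      st$step_tol <- min(st$step_tol, 200L)
      o <- de_optimize(objective, layout$lower, layout$upper, st,
                       init_pop = opt$population)
      n_used <- n_used + o$iterations
      if (o$value < opt$value) opt <- o
    }
  }
  opt$iterations <- n_used
  mdl <- theta_to_model(opt$par, layout, variant)
  k <- length(opt$par)
  rng <- layout$upper - layout$lower
  at_bound <- (opt$par - layout$lower < 1e-8 * rng) |
    (layout$upper - opt$par < 1e-8 * rng)
  structure(list(
    variant = variant,
    estimates = mdl$params,
    nuisances = mdl$nuisances,
    par = setNames(opt$par, layout$names),
    minus2LL = opt$value,
    n_parameters = k,
    AIC = aic(opt$value, k),
    iterations_used = opt$iterations,
    converged = opt$converged,
    at_bound = setNames(at_bound, layout$names),
    bounds = bounds,
    settings = settings,
    seed = settings$seed,
    n_trials = length(trials),
    n_obs = sum(lengths(ys))),
    class = "ipc_fit")
}

#' @export
print.ipc_fit <- function(x, ...) {
  cat(sprintf("IPC %s fit: %d trials, %d observations\n",
              x$variant, x$n_trials, x$n_obs))
  cat(sprintf("  -2lnL = %.4f, k = %d, AIC = %.4f (%s after %d iterations)\n",
              x$minus2LL, x$n_parameters, x$AIC,
              if (x$converged) "converged" else "iteration cap",
              x$iterations_used))
  est <- unlist(x$estimates)[structural_names(x$variant)]
  print(round(est, 5))
  if (any(x$at_bound)) {
    cat("  boundary-pinned:", paste(names(which(x$at_bound)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Akaike information criterion
#' @param minus2LL -2 log-likelihood at the optimum.
#' @param k number of estimated parameters.
#' @return `minus2LL + 2 * k`.
#' @export
aic <- function(minus2LL, k) {
  stopifnot(k >= 0)
  minus2LL + 2 * k
}

#' Select a model variant by AIC
#'
#' @param fits list of `ipc_fit` objects on the same data.
#' @return the variant name with the lowest AIC; ties go to the fit with
#'   fewer parameters.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "ipc_fit")))
  aics <- vapply(fits, function(f) f$AIC, numeric(1))
  ks <- vapply(fits, function(f) f$n_parameters, numeric(1))
  fits[[order(aics, ks)[1]]]$variant
}
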