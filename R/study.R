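# Recovery studies: the noiseless specification check (one deterministic
# trajectory per preset, fitted to machine precision) and the noisy
# parameter-recovery experiment (simulated individuals with several trials
# each, fitted jointly, summarized across replicates).

#' Deterministic seed fan-out
#'
#' Derives a stream of child seeds from one master seed, so that a study is
#' bit-reproducible while its individuals, trials and optimizer runs use
#' independent seeds. The scheme: seed R's RNG with the master seed and draw
#' `n` integers uniformly from `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
seed_stream <- function(master, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(master)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Noiseless specification check for one preset
#'
#' Simulates a preset deterministically (no process noise, perfect
#' measurement) from `x0 = 1, xdot0 = 0`, downsamples, and fits the full
#' ISDDE by differential evolution under the simulation bounds. With a
#' correctly specified estimator the recovered parameters should match the
#' generating values almost exactly; remaining bias reflects the linear lag
#' interpolation and the backward extrapolation, and is known to load on the
#' velocity coefficients `B` and `D`.
#'
#' @param preset preset name (see [ipc_presets()]) or an [ipc_params()].
#' @param hz observation rate after downsampling.
#' @param duration series length, s.
#' @param de_iterations DE iteration cap.
#' @param constants [ipc_constants()].
#' @param seed optimizer seed.
#' @param fine_dt integration step for the generator.
#' @param n_starts independent DE starts (best kept); see [ipc_fit()].
#' @param de_step_tol early-stopping window per start.
#' @param start_iterations screening-stage iteration cap (see [ipc_fit()]).
#' @return the `ipc_fit` object (estimates in `$estimates`).
#' @export
run_noiseless_check <- function(preset = "Asai et al.", hz = 100,
                                duration = 20, de_iterations = 3000,
                                constants = ipc_constants(), seed = 1,
                                fine_dt = 1e-5, n_starts = 32,
                                de_step_tol = 300,
                                start_iterations = 700) {
  params <- if (is.character(preset)) ipc_preset(preset) else preset
  traj <- ipc_simulate(params, constants, duration = duration,
                       fine_dt = fine_dt, x0 = 1, xdot0 = 0,
                       noiseless = TRUE, record_hz = hz)
  settings <- de_settings(iterations = de_iterations, step_tol = de_step_tol,
                          seed = seed)
  ipc_fit(traj, "ISDDE", settings = settings, constants = constants,
          context = "simulation", n_starts = n_starts,
          start_iterations = start_iterations, profile_tau = TRUE)
}

#' Noisy parameter-recovery study for one preset
#'
#' Simulates `n_individuals` independent individuals, each with
#' `trials_per_individual` trials sharing the preset's structural
#' parameters, adds measurement noise, fits the ISDDE jointly per
#' individual, and summarizes the estimates across replicates. Defaults are
#' desk scale (10 individuals, 30 s trials, 2000 DE iterations); pass
#' `duration = 60, n_individuals = 100` and more iterations for a
#' full-scale run.
#'
#' @param preset preset name or [ipc_params()].
#' @param n_individuals number of simulated individuals.
#' @param trials_per_individual trials per individual.
#' @param duration trial length, s.
#' @param hz observation rate.
#' @param de_iterations DE iteration cap per fit.
#' @param de_step_tol early-stopping window per fit.
#' @param constants [ipc_constants()].
#' @param seed master seed; all trial and optimizer seeds are fanned out
#'   from it via [seed_stream()].
#' @param fine_dt integration step for the generator.
#' @param n_starts independent DE starts per individual fit.
#' @return an object of class `ipc_recovery`: per-replicate estimates, the
#'   summary table, failure records and the scale settings.
#' @export
run_noisy_recovery <- function(preset = "Asai et al.", n_individuals = 10,
                               trials_per_individual = 3, duration = 30,
                               hz = 100, de_iterations = 2000,
                               de_step_tol = 500,
                               constants = ipc_constants(), seed = 1,
                               fine_dt = 1e-5, n_starts = 1) {
  params <- if (is.character(preset)) ipc_preset(preset) else preset
  preset_name <- if (is.character(preset)) preset else
    attr(preset, "preset") %||% "custom"
  n_seeds <- n_individuals * (trials_per_individual + 1)
  seeds <- matrix(seed_stream(seed, n_seeds), nrow = n_individuals)

  sn <- structural_names("ISDDE")
  est <- matrix(NA_real_, n_individuals, length(sn),
                dimnames = list(NULL, sn))
  m2ll <- rep(NA_real_, n_individuals)
  failures <- character(0)

  for (ind in seq_len(n_individuals)) {
    fit <- tryCatch({
      trials <- lapply(seq_len(trials_per_individual), function(j) {
        tr <- ipc_simulate(params, constants, duration = duration,
                           fine_dt = fine_dt, x0 = 0, xdot0 = 0,
                           seed = seeds[ind, j], record_hz = hz)
        observe(tr, eps = params$eps, mu = 0)
      })
      settings <- de_settings(iterations = de_iterations,
                              step_tol = de_step_tol,
                              seed = seeds[ind, trials_per_individual + 1])
      ipc_fit(trials, "ISDDE", settings = settings, constants = constants,
              context = "simulation", n_starts = n_starts)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("individual %d: %s", ind,
                                      conditionMessage(fit)))
    } else {
      est[ind, ] <- unlist(fit$estimates)[sn]
      m2ll[ind] <- fit$minus2LL
    }
  }

  estimates <- as.data.frame(est)
  structure(list(
    preset = preset_name,
    true_params = unclass(params),
    estimates = estimates,
    minus2LL = m2ll,
    summary = summarize_estimates(estimates),
    failures = failures,
    seeds = seeds,
    scale = list(n_individuals = n_individuals,
                 trials_per_individual = trials_per_individual,
                 duration = duration, hz = hz,
                 de_iterations = de_iterations, fine_dt = fine_dt,
                 master_seed = seed)),
    class = "ipc_recovery")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize replicate estimates
#'
#' Per-parameter mean, standard deviation, median, and the trimmed standard
#' deviation computed after removing the `trim_count` largest values (a
#' guard against the occasional boundary-pinned replicate).
#'
#' @param estimates data.frame or matrix, one row per replicate.
#' @param trim_count number of largest values to drop for the trimmed SD.
#' @return data.frame with one row per parameter.
#' @export
summarize_estimates <- function(estimates, trim_count = 0) {
  estimates <- as.data.frame(estimates)
  stopifnot(trim_count < nrow(estimates))
  out <- lapply(estimates, function(x) {
    x <- x[!is.na(x)]
    xt <- if (trim_count > 0 && length(x) > trim_count) {
      sort(x)[seq_len(length(x) - trim_count)]
    } else x
    c(mean = mean(x), sd = sd(x), median = median(x),
      trimmed_sd = sd(xt), n = length(x))
  })
  cbind(parameter = names(out),
        as.data.frame(do.call(rbind, out), row.names = FALSE))
}

#' @export
print.ipc_recovery <- function(x, ...) {
  cat(sprintf("IPC recovery study: preset '%s', %d individuals x %d trials of %g s at %g Hz\n",
              x$preset, x$scale$n_individuals, x$scale$trials_per_individual,
              x$scale$duration, x$scale$hz))
  if (length(x$failures)) {
    cat(sprintf("  %d failed replicates\n", length(x$failures)))
  }
  s <- x$summary
  s$true <- unlist(x$true_params)[s$parameter]
  print(s, digits = 4)
  invisible(x)
}
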