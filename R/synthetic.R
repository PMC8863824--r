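#' Generative response profile of one chemical
#'
#' Defines the phenotype of a simulated attractant: how long the
#' exclusive-CCW excitation lasts as a function of concentration
#' (`tau = tau0 + beta * log10(x)`, scaled per cell by a lognormal factor
#' with unit median and CV `cell_cv`), and the shape of the multi-phase
#' recovery back toward baseline.
#'
#' @param name Chemical label.
#' @param tau0 Excitation duration at the 1 mM reference, seconds.
#' @param beta Dose slope of the excitation duration, seconds per decade of
#'   concentration.
#' @param recovery_total Total recovery duration, seconds.
#' @param recovery_fracs Three positive fractions summing to 1: shares of
#'   `recovery_total` assigned to the L3/L4/L5 phases.
#' @param recovery_shape Three fractions in `[0, 1]`: CW-bias level at the
#'   end of each recovery phase, relative to the span from 0 to the final
#'   level (the third is normally 1).
#' @param overshoot Final minus baseline CW bias (0 for exact adaptation).
#' @param conc_range Valid concentration range `c(lo, hi)` in mM.
#' @param cell_cv Coefficient of variation of the per-cell excitation
#'   duration (cell-to-cell variability; default 0.3).
#' @param baseline_mean,baseline_kappa Mean and concentration parameter of
#'   the Beta distribution of per-cell baseline CW bias.
#' @return An object of class `chemical_profile`.
#' @export
chemical_profile <- function(name, tau0, beta, recovery_total,
                             recovery_fracs = c(1, 1, 1) / 3,
                             recovery_shape = c(0.4, 0.8, 1),
                             overshoot = 0,
                             conc_range = c(0.01, 10),
                             cell_cv = 0.3,
                             baseline_mean = 0.3, baseline_kappa = 25) {
  stopifnot(tau0 >= 0, recovery_total >= 0, cell_cv >= 0,
            length(recovery_fracs) == 3, all(recovery_fracs > 0),
            abs(sum(recovery_fracs) - 1) < 1e-9,
            length(recovery_shape) == 3,
            all(recovery_shape >= 0 & recovery_shape <= 1),
            length(conc_range) == 2, all(conc_range > 0),
            conc_range[1] < conc_range[2],
            baseline_mean > 0, baseline_mean < 1, baseline_kappa > 0)
  structure(list(name = name, tau0 = tau0, beta = beta,
                 recovery_total = recovery_total,
                 recovery_fracs = recovery_fracs,
                 recovery_shape = recovery_shape,
                 overshoot = overshoot, conc_range = conc_range,
                 cell_cv = cell_cv, baseline_mean = baseline_mean,
                 baseline_kappa = baseline_kappa),
            class = "chemical_profile")
}

#' @export
print.chemical_profile <- function(x, ...) {
  cat(sprintf("<chemical_profile> %s: tau0=%g s, beta=%g s/decade, range %g-%g mM\n",
              x$name, x$tau0, x$beta, x$conc_range[1], x$conc_range[2]))
  invisible(x)
}

#' Simulation settings for the tethered-cell assay
#'
#' @param frame_interval Seconds per video frame (default 0.01, 100 fps).
#' @param bin_width CW-bias bin width, seconds.
#' @param duration Recording duration, seconds (at most 600).
#' @param stimulus_time Time of the attractant exchange, seconds.
#' @param n_cells Cells per ensemble (default 100).
#' @param dwell_mean Mean CW/CCW run length in the two-state switching
#'   process, seconds.
#' @param none_prob Probability a frame falls below the motion threshold
#'   and is labelled NONE.
#' @param seed Root integer seed; per-cell streams are derived by a counter
#'   so changing `n_cells` never reshuffles earlier cells.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(frame_interval = 0.01, bin_width = 1, duration = 600,
                       stimulus_time = 100, n_cells = 100, dwell_mean = 1,
                       none_prob = 0.1, seed = 1) {
  stopifnot(frame_interval > 0, bin_width > 0, duration > 0, duration <= 600,
            stimulus_time >= 0, stimulus_time <= duration, n_cells >= 1,
            dwell_mean > 0, none_prob >= 0, none_prob < 1)
  structure(list(frame_interval = frame_interval, bin_width = bin_width,
                 duration = duration, stimulus_time = stimulus_time,
                 n_cells = as.integer(n_cells), dwell_mean = dwell_mean,
                 none_prob = none_prob, seed = as.integer(seed)),
            class = "sim_config")
}

# counter-based seed stream: deterministic in (root, trace, cell), all
# arithmetic < 2^53 so exact in doubles
derive_seed <- function(root, trace_id, cell_index) {
  m <- 2147483563
  s <- (root %% m) * 48271 + trace_id * 16807 + cell_index * 69621
  as.integer(s %% m + 1)
}


#' Simulate one tethered cell
#'
#' Per-frame direction labels for a single cell: a two-state CW/CCW Markov
#' chain with stationary CW fraction equal to the cell's baseline bias
#' (drawn from the profile's Beta distribution), an exclusive-CCW window of
#' duration `max(0, (tau0 + beta * log10(x)) * eps)` at the stimulus (with
#' `eps` lognormal, unit median, CV `cell_cv`), a piecewise-linear recovery
#' of the target bias toward baseline plus overshoot, and i.i.d. NONE
#' thinning. Deterministic given `cell_seed`.
#'
#' @param profile A [chemical_profile()].
#' @param x Concentration in mM (> 0).
#' @param cfg A [sim_config()].
#' @param cell_seed Integer seed for this cell's stream.
#' @param cell_id Identifier stored in the output.
#' @return A tibble with columns `cell_id`, `frame`, `label`.
#' @export
simulate_cell <- function(profile, x, cfg = sim_config(), cell_seed = cfg$seed,
                          cell_id = "cell_1") {
  stopifnot(inherits(profile, "chemical_profile"), inherits(cfg, "sim_config"))
  if (x <= 0) abort("concentration `x` must be > 0")
  with_preserved_seed(cell_seed, {
    a <- profile$baseline_mean * profile$baseline_kappa
    b <- (1 - profile$baseline_mean) * profile$baseline_kappa
    p_c <- rbeta(1, a, b)
    eps <- if (profile$cell_cv > 0) {
      rlnorm(1, 0, sqrt(log(1 + profile$cell_cv^2)))
    } else 1
    tau_c <- max(0, (profile$tau0 + profile$beta * log10(x)) * eps)
    n <- round(cfg$duration / cfg$frame_interval)
    p_fin <- min(1, max(0, p_c + profile$overshoot))
    lab <- simulate_cell_cpp(
      n, cfg$frame_interval, p_c, tau_c, cfg$stimulus_time,
      rec_dur = cumsum(profile$recovery_total * profile$recovery_fracs),
      rec_lvl = profile$recovery_shape * p_fin,
      dwell_mean = cfg$dwell_mean, none_prob = cfg$none_prob)
    # factor labels: avoids allocating millions of strings when ensembles
    # are pooled
    tibble::tibble(cell_id = cell_id, frame = seq_len(n),
                   label = factor(lab + 1L, levels = 1:3,
                                  labels = c("CW", "CCW", "NONE")))
  })
}

#' Simulate an ensemble CW-bias trace
#'
#' Runs [simulate_cell()] for `cfg$n_cells` independent cells (seeds derived
#' from `cfg$seed` by counter) and pools them through [ensemble_cw_bias()].
#'
#' @inheritParams simulate_cell
#' @param trace_id Integer distinguishing traces drawn from the same root
#'   seed (used in the seed derivation).
#' @return A [cw_trace()].
#' @export
simulate_ensemble <- function(profile, x, cfg = sim_config(), trace_id = 1L) {
  cells <- purrr::map(seq_len(cfg$n_cells), function(ci) {
    simulate_cell(profile, x, cfg,
                  cell_seed = derive_seed(cfg$seed, trace_id, ci),
                  cell_id = sprintf("cell_%d", ci))
  })
  ensemble_cw_bias(dplyr::bind_rows(cells),
                   frame_interval = cfg$frame_interval,
                   bin_width = cfg$bin_width,
                   stimulus_time = cfg$stimulus_time)
}

#' Simulate a labelled training set of characteristic vectors
#'
#' For each (profile, concentration, replicate) cell: simulates an ensemble
#' trace, fits the six-line template and converts it to a labelled
#' characteristic vector. Fully deterministic given the profiles and
#' `cfg$seed`.
#'
#' @param profiles A list of [chemical_profile()]s (named or carrying
#'   `name` fields).
#' @param concentrations Either a numeric vector used for every profile, or
#'   a named list mapping profile names to concentration vectors (mM). All
#'   concentrations must lie inside each profile's `conc_range`.
#' @param reps Replicate traces per (profile, concentration).
#' @param cfg A [sim_config()].
#' @param ... Passed to [fit_template()].
#' @return A tibble of characteristic vectors with `label`,
#'   `concentration_mM` and `vector_id` columns.
#' @export
simulate_training_set <- function(profiles, concentrations, reps = 4,
                                  cfg = sim_config(), ...) {
  trace_counter <- 0L
  out <- purrr::map(profiles, function(pr) {
    conc <- if (is.list(concentrations)) concentrations[[pr$name]] else concentrations
    if (is.null(conc)) abort(sprintf("no concentrations given for %s", pr$name))
    if (any(conc < pr$conc_range[1] - 1e-12 | conc > pr$conc_range[2] + 1e-12)) {
      abort(sprintf("concentrations outside %s's range [%g, %g] mM",
                    pr$name, pr$conc_range[1], pr$conc_range[2]))
    }
    purrr::map(conc, function(xx) {
      purrr::map(seq_len(reps), function(r) {
        trace_counter <<- trace_counter + 1L
        trace <- simulate_ensemble(pr, xx, cfg, trace_id = trace_counter)
        fit <- fit_template(trace, ...)
        v <- template_to_vector(fit, label = pr$name, concentration_mM = xx)
        v$vector_id <- sprintf("%s_x%g_r%d", pr$name, xx, r)
        v
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  tibble::as_tibble(out)
}

#' Shipped chemical profiles
#'
#' Six standard attractant presets whose valid concentration ranges match
#' the assay's training ranges (l-Asp 0.001-3 mM, l-Glu 0.01-50 mM, d-Asp
#' 0.01-50 mM, l-Asn 0.05-30 mM, l-Cys 0.01-3 mM, l-Ser 0.001-0.05 mM) with
#' distinct excitation/recovery parameters, plus two "beverage" presets
#' whose traces are nearly identical at matched concentrations (same
#' recovery geometry, excitation durations differing < 10%) but whose dose
#' slopes differ - distinguishable only through the concentration
#' dependence of the indices.
#'
#' @param include_beverages Append the two beverage presets (default TRUE).
#' @return A named list of [chemical_profile()]s.
#' @export
default_profiles <- function(include_beverages = TRUE) {
  p <- list(
    chemical_profile("L-Asp", tau0 = 180, beta = 45, recovery_total = 140,
                     recovery_fracs = c(0.3, 0.4, 0.3),
                     recovery_shape = c(0.35, 0.75, 1),
                     overshoot = 0, conc_range = c(0.001, 3)),
    chemical_profile("L-Glu", tau0 = 120, beta = 55, recovery_total = 180,
                     recovery_fracs = c(0.5, 0.3, 0.2),
                     recovery_shape = c(0.5, 0.85, 1),
                     overshoot = 0.03, conc_range = c(0.01, 50)),
    chemical_profile("D-Asp", tau0 = 90, beta = 35, recovery_total = 120,
                     recovery_fracs = c(0.25, 0.5, 0.25),
                     recovery_shape = c(0.25, 0.6, 1),
                     overshoot = -0.03, conc_range = c(0.01, 50)),
    chemical_profile("L-Asn", tau0 = 150, beta = 70, recovery_total = 100,
                     recovery_fracs = c(0.4, 0.2, 0.4),
                     recovery_shape = c(0.3, 0.5, 1),
                     overshoot = 0, conc_range = c(0.05, 30)),
    chemical_profile("L-Cys", tau0 = 210, beta = 60, recovery_total = 200,
                     recovery_fracs = c(0.33, 0.33, 0.34),
                     recovery_shape = c(0.6, 0.8, 1),
                     overshoot = 0.05, conc_range = c(0.01, 3)),
    chemical_profile("L-Ser", tau0 = 260, beta = 50, recovery_total = 160,
                     recovery_fracs = c(0.2, 0.3, 0.5),
                     recovery_shape = c(0.4, 0.9, 1),
                     overshoot = 0, conc_range = c(0.001, 0.05)))
  if (include_beverages) {
    p <- c(p, list(
      chemical_profile("Cola-A", tau0 = 215, beta = 40, recovery_total = 150,
                       recovery_fracs = c(0.35, 0.35, 0.3),
                       recovery_shape = c(0.45, 0.8, 1),
                       overshoot = 0, conc_range = c(0.1, 10)),
      chemical_profile("Cola-B", tau0 = 205, beta = 70, recovery_total = 150,
                       recovery_fracs = c(0.35, 0.35, 0.3),
                       recovery_shape = c(0.45, 0.8, 1),
                       overshoot = 0, conc_range = c(0.1, 10))))
  }
  names(p) <- purrr::map_chr(p, "name")
  p
}
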