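#' Specify a simulated cohort group
#'
#' Describes one biological group (e.g. wild-type or an enhancer knockout)
#' for the Timer cohort simulator. Transcription is modelled as a
#' homogeneous Poisson burst process per cell: burst onsets arrive at
#' `burst_frequency_per_week`, each burst transcribes at `burst_rate`
#' molecules/h for `burst_duration_h` hours (truncated at the next onset so
#' intervals never overlap). Cell age at acquisition is drawn uniformly over
#' `obs_window_h`, so a cohort simultaneously contains cells with new,
#' persistent and arrested transcription states. Between-sample biological
#' variability multiplies the burst frequency by a log-normal factor with
#' coefficient of variation `sample_cv`.
#'
#' The default frequency of one burst per week reflects the periodic, brief
#' antigen-driven signals thought to re-trigger Foxp3 transcription in
#' regulatory T cells; a knockout with reduced transcriptional bursting is
#' emulated by lowering `burst_frequency_per_week`.
#'
#' @param group_label Group name.
#' @param n_samples Biological replicates per cohort.
#' @param cells_per_sample Cells acquired per sample.
#' @param burst_frequency_per_week Mean burst onsets per week per cell.
#' @param burst_duration_h Burst duration (hours).
#' @param burst_rate Transcription rate during a burst (molecules/h).
#' @param sample_cv Between-sample CV of burst frequency.
#' @param obs_window_h Length-2 vector: cell age window (hours) at acquisition.
#' @return A `timer_group_spec` object.
#' @export
timer_group_spec <- function(group_label,
                             n_samples = 10,
                             cells_per_sample = 2000,
                             burst_frequency_per_week = 1,
                             burst_duration_h = 12,
                             burst_rate = 1000,
                             sample_cv = 0.15,
                             obs_window_h = c(24, 672)) {
  stopifnot(n_samples >= 1, cells_per_sample >= 1,
            burst_frequency_per_week >= 0, burst_duration_h >= 0,
            burst_rate >= 0, sample_cv >= 0,
            length(obs_window_h) == 2, obs_window_h[1] >= 0,
            obs_window_h[2] >= obs_window_h[1])
  structure(as.list(environment()), class = "timer_group_spec")
}

#' Specify the fluorescence measurement model
#'
#' Raw fluorescence per channel is
#' `gain * molecules * lognormal_noise + autofluorescence`, where the
#' log-normal multiplicative noise has mean 1 and coefficient of variation
#' `lognormal_cv`, and autofluorescence is Gamma-distributed with the given
#' per-channel mean and CV `autofluor_cv` (the default CV of 1 gives an
#' exponential tail, reproducing the wedge-shaped floor of real Timer
#' Blue-Red clouds). Setting both CVs to 0 makes the measurement
#' deterministic. All outputs are strictly positive.
#'
#' @param autofluor_mean_blue,autofluor_mean_red Mean autofluorescence (a.u.).
#' @param lognormal_cv CV of multiplicative signal noise.
#' @param autofluor_cv CV of the autofluorescence distribution.
#' @param gain_blue,gain_red Fluorescence units per molecule.
#' @return A `measurement_model` object.
#' @export
measurement_model <- function(autofluor_mean_blue = 150,
                              autofluor_mean_red = 150,
                              lognormal_cv = 0.3,
                              autofluor_cv = 1,
                              gain_blue = 1,
                              gain_red = 1) {
  stopifnot(autofluor_mean_blue > 0, autofluor_mean_red > 0,
            lognormal_cv >= 0, autofluor_cv >= 0,
            gain_blue > 0, gain_red > 0)
  structure(as.list(environment()), class = "measurement_model")
}

#' Simulate the transcription history of one cell
#'
#' Draws burst onsets from a homogeneous Poisson process over the cell's
#' lifetime and truncates each burst at the following onset, yielding
#' non-overlapping piecewise-constant transcription intervals.
#'
#' @param spec A [timer_group_spec()].
#' @param observation_time_h Cell age (hours) at acquisition.
#' @return Tibble with columns `start_h`, `end_h`, `rate` (possibly 0 rows).
#' @export
simulate_cell_history <- function(spec, observation_time_h) {
  freq_h <- spec$burst_frequency_per_week / 168
  n <- rpois(1, freq_h * observation_time_h)
  if (n == 0 || spec$burst_duration_h == 0 || spec$burst_rate == 0) {
    return(tibble::tibble(start_h = numeric(0), end_h = numeric(0),
                          rate = numeric(0)))
  }
  onset <- sort(runif(n, 0, observation_time_h))
  next_onset <- c(onset[-1], Inf)
  end <- pmin(onset + spec$burst_duration_h, next_onset, observation_time_h)
  tibble::tibble(start_h = onset, end_h = end,
                 rate = rep(spec$burst_rate, n))
}

# Draw all burst intervals for `n` cells with ages obs_h under one spec.
# Returns a flat data.frame (cell, start_h, end_h, rate).
draw_bursts <- function(n, obs_h, spec, freq_mult = 1) {
  freq_h <- spec$burst_frequency_per_week * freq_mult / 168
  counts <- rpois(n, freq_h * obs_h)
  total <- sum(counts)
  if (total == 0) {
    return(data.frame(cell = integer(0), start_h = numeric(0),
                      end_h = numeric(0), rate = numeric(0)))
  }
  cell <- rep.int(seq_len(n), counts)
  onset <- runif(total, 0, rep.int(obs_h, counts))
  o <- order(cell, onset)
  cell <- cell[o]; onset <- onset[o]
  next_onset <- c(onset[-1], Inf)
  next_onset[cumsum(counts)[counts > 0]] <- Inf   # last burst of each cell
  end <- pmin(onset + spec$burst_duration_h, next_onset, obs_h[cell])
  data.frame(cell = cell, start_h = onset, end_h = end,
             rate = spec$burst_rate)
}

#' Apply the measurement model to molecule counts
#'
#' @param cells Data frame with columns `blue_molecules`, `red_molecules`.
#' @param model A [measurement_model()].
#' @return The input as a tibble with `blue_raw`, `red_raw` columns added.
#' @export
measure_cells <- function(cells, model = measurement_model()) {
  assert_columns(cells, c("blue_molecules", "red_molecules"), "cell table")
  stopifnot(all(cells$blue_molecules >= 0), all(cells$red_molecules >= 0))
  n <- nrow(cells)
  noise <- function(cv, n) {
    if (cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + cv^2))
    exp(rnorm(n, mean = -s^2 / 2, sd = s))   # mean exactly 1
  }
  af <- function(mean, cv, n) {
    if (cv == 0) return(rep(mean, n))
    rgamma(n, shape = 1 / cv^2, scale = mean * cv^2)
  }
  out <- tibble::as_tibble(cells)
  out$blue_raw <- model$gain_blue * cells$blue_molecules * noise(model$lognormal_cv, n) +
    af(model$autofluor_mean_blue, model$autofluor_cv, n)
  out$red_raw <- model$gain_red * cells$red_molecules * noise(model$lognormal_cv, n) +
    af(model$autofluor_mean_red, model$autofluor_cv, n)
  out
}

simulate_one_cohort <- function(groups, params, model, cohort_name) {
  purrr::map_dfr(groups, function(spec) {
    purrr::map_dfr(seq_len(spec$n_samples), function(si) {
      n <- spec$cells_per_sample
      obs_h <- runif(n, spec$obs_window_h[1], spec$obs_window_h[2])
      fmult <- if (spec$sample_cv > 0) {
        s <- sqrt(log(1 + spec$sample_cv^2))
        exp(rnorm(1, -s^2 / 2, s))
      } else 1
      bursts <- draw_bursts(n, obs_h, spec, fmult)
      mol <- solve_bursts_vec(bursts, obs_h, n, params)
      cells <- tibble::tibble(
        cell_id = sprintf("%s_%s_s%02d_c%05d", cohort_name, spec$group_label, si, seq_len(n)),
        blue_molecules = mol$blue,
        red_molecules = mol$red,
        age_h = obs_h
      )
      out <- measure_cells(cells, model)
      out$sample_id <- sprintf("%s_%s_%02d", cohort_name, spec$group_label, si)
      out$group <- spec$group_label
      out$cohort <- cohort_name
      out
    })
  })
}

#' Simulate labelled train/test Timer cohorts
#'
#' Generates two disjoint cohorts (train and test) of per-cell raw Timer
#' Blue/Red fluorescence from the burst-transcription + maturation model.
#' All randomness flows through `seed`; the same seed reproduces the cohort
#' bit-for-bit.
#'
#' @param groups List of [timer_group_spec()] objects (>= 2 for
#'   classification fixtures; a single group is allowed when
#'   `require_groups = 1`).
#' @param params [kinetic_params()].
#' @param model [measurement_model()].
#' @param seed Integer seed.
#' @param cohorts Character vector of cohort names to generate.
#' @param require_groups Minimum number of groups (default 2).
#' @return Tibble of cells with columns `cohort`, `sample_id`, `group`,
#'   `cell_id`, `blue_raw`, `red_raw`, plus ground-truth `blue_molecules`,
#'   `red_molecules`, `age_h`. A manifest of all generating parameters is
#'   attached as attribute `"manifest"`.
#' @export
#' @examples
#' coh <- simulate_timer_cohort(
#'   groups = list(timer_group_spec("WT", n_samples = 2, cells_per_sample = 50),
#'                 timer_group_spec("KO", n_samples = 2, cells_per_sample = 50,
#'                                  burst_frequency_per_week = 0.5)),
#'   seed = 1)
#' dplyr::count(coh, cohort, group)
simulate_timer_cohort <- function(groups,
                                  params = kinetic_params(),
                                  model = measurement_model(),
                                  seed = 1,
                                  cohorts = c("train", "test"),
                                  require_groups = 2) {
  if (inherits(groups, "timer_group_spec")) groups <- list(groups)
  labels <- vapply(groups, `[[`, "", "group_label")
  if (length(unique(labels)) < require_groups) {
    abort(sprintf("classifier fixtures need >= %d distinct groups; got %d",
                  require_groups, length(unique(labels))))
  }
  out <- purrr::imap_dfr(setNames(cohorts, cohorts), function(nm, i) {
    withr::with_seed(child_seed(seed, match(nm, cohorts)),
                     simulate_one_cohort(groups, params, model, nm))
  })
  manifest <- list(
    seed = seed, cohorts = cohorts,
    kinetics = unclass(params), measurement = unclass(model),
    groups = lapply(groups, unclass)
  )
  attr(out, "manifest") <- manifest
  out
}

#' Simulate a shape-only group difference
#'
#' Builds two groups whose Timer Angle and Timer Intensity marginal
#' distributions are identical but whose 2D joint distributions differ: in
#' group A intensity rises with angle, in group B it falls (the intensity
#' rank profile is mirrored). Quadrant and polygon gates, %Timer+ and mean
#' Timer Angle are therefore distribution-identical between the groups,
#' while the density image differs. Used to benchmark image-based
#' classifiers against marginal gating.
#'
#' Cells are emitted directly on the normalized Blue/Red scale (as if
#' preprocessed): `blue_norm = intensity * cos(angle)`,
#' `red_norm = intensity * sin(angle)`.
#'
#' @param n_samples Samples per group per cohort.
#' @param cells_per_sample Cells per sample.
#' @param seed Integer seed.
#' @param coupling Strength in `[0, 1]` of the angle-intensity dependence.
#' @param cohorts Cohort names to generate.
#' @return Tibble with `cohort`, `sample_id`, `group` ("A"/"B"), `cell_id`,
#'   `blue_norm`, `red_norm`, `timer_positive`, `angle_deg`, `intensity`.
#' @export
simulate_shape_cohort <- function(n_samples = 10, cells_per_sample = 2000,
                                  seed = 1, coupling = 0.8,
                                  cohorts = c("train", "test")) {
  stopifnot(coupling >= 0, coupling <= 1)
  gen_sample <- function(group, nm, si) {
    n <- cells_per_sample
    angle <- runif(n, 5, 85)
    # intensity conditional on angle: same Beta-ish marginal in both groups,
    # but the location moves up with angle in A and down in B.
    u <- runif(n)
    a_scaled <- (angle - 5) / 80
    loc <- if (group == "A") a_scaled else 1 - a_scaled
    intensity <- 0.15 + 0.75 * ((1 - coupling) * u + coupling * pmin(1, pmax(0, loc + 0.18 * (u - 0.5))))
    tibble::tibble(
      cohort = nm,
      sample_id = sprintf("%s_%s_%02d", nm, group, si),
      group = group,
      cell_id = sprintf("%s_%s_s%02d_c%05d", nm, group, si, seq_len(n)),
      angle_deg = angle,
      intensity = intensity,
      blue_norm = intensity * cospi(angle / 180),
      red_norm = intensity * sinpi(angle / 180),
      timer_positive = TRUE
    )
  }
  purrr::imap_dfr(setNames(cohorts, cohorts), function(nm, i) {
    withr::with_seed(child_seed(seed, 100 + match(nm, cohorts)), {
      purrr::map_dfr(c("A", "B"), function(g) {
        purrr::map_dfr(seq_len(n_samples), function(si) gen_sample(g, nm, si))
      })
    })
  })
}

#' Write a simulated cohort to per-sample CSV event tables
#'
#' @param cohort Tibble from [simulate_timer_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths. A `manifest.yaml` (or `.json`
#'   fallback) records the generating parameters.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- cohort |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(df, key) {
      p <- file.path(dir, paste0(key$sample_id, ".csv"))
      utils::write.csv(df[, intersect(c("cell_id", "blue_raw", "red_raw"), names(df))],
                       p, row.names = FALSE)
      p
    })
  manifest <- attr(cohort, "manifest")
  if (!is.null(manifest)) {
    if (requireNamespace("yaml", quietly = TRUE)) {
      yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
    } else if (requireNamespace("jsonlite", quietly = TRUE)) {
      writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
                 file.path(dir, "manifest.json"))
    } else {
      warn("neither yaml nor jsonlite available; manifest not written")
    }
  }
  invisible(unlist(paths))
}
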