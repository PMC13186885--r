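## Replicated synthetic-data experiments: wire the generators and fitters
## into the named studies and emit tidy long-format result tables, plus the
## bias/variance and posterior-metric grids behind the heatmap figures.

study_seed <- function(seed, i) (abs(seed) + 104729 * i) %% 2147483647

tidy_fit_row <- function(fit, study_id, scenario, replicate, data_kind) {
  dplyr::mutate(tidy(fit),
    study_id = study_id, scenario = scenario, replicate = replicate,
    data = data_kind, r2 = fit$r2, adj_r2 = fit$adj_r2,
    converged = fit$converged, .before = 1
  ) |>
    dplyr::rename(parameter = "term", ci_lower = "conf.low",
                  ci_upper = "conf.high")
}

#' Run a named replicated study
#'
#' Repeats a full generate-and-fit cycle and collects the estimates,
#' confidence intervals and fit statistics in a tidy long table (one row
#' per replicate, scenario, fitted-data kind and parameter). Studies:
#'
#' * `"linear"`: the three linear designs, true-data and observed-data
#'   ordinary least squares each replicate.
#' * `"oscillator"`: the four cosine designs; amplitude `a` fitted with the
#'   frequency `b` fixed at its true value.
#' * `"parasite"`: the three parasite fit variants per replicate — no
#'   timing error with all four parameters free; timing error with all
#'   free; timing error with only `(V0, g)` free and the background fixed
#'   at truth.
#' * `"tumour"`: the three error scenarios; pooled `(r, K)` fit with
#'   `y0` fixed to the mean day-0 response, and a pooled all-parameter fit.
#' * `"tumour_individual"`: per-tumour fits of `(y0, r, K)` under each
#'   scenario, reported as relative errors against each tumour's own truth.
#'
#' Replicates are seeded independently from the root `seed`, so the table
#' is reproducible and any prefix of replicates is stable.
#'
#' @param study_id One of the study names above.
#' @param replicates Number of synthetic datasets (>= 1).
#' @param seed Root seed.
#' @param ... Passed to the study's generator (e.g. `var_u`, `params`).
#' @return A tibble (`StudyTable`): `study_id`, `scenario`, `replicate`,
#'   `data`, `parameter`, `estimate`, `std.error`, `ci_lower`, `ci_upper`,
#'   `r2`, `adj_r2`, `converged` (plus `subject_id`/`rel_error` for
#'   `"tumour_individual"`).
#' @examples
#' run_study("linear", replicates = 2, seed = 1)
#' @export
run_study <- function(study_id = c("linear", "oscillator", "parasite",
                                   "tumour", "tumour_individual"),
                      replicates = 1000, seed = 1, ...) {
  study_id <- match.arg(study_id)
  stopifnot(replicates >= 1)
  fn <- switch(study_id,
    linear = study_linear_once, oscillator = study_oscillator_once,
    parasite = study_parasite_once, tumour = study_tumour_once,
    tumour_individual = study_tumour_individual_once
  )
  purrr::map_dfr(seq_len(replicates), function(i) {
    set.seed(study_seed(seed, i))
    tryCatch(fn(i, ...),
             error = function(e) {
               warn(paste0("replicate ", i, " failed: ", conditionMessage(e)))
               tibble::tibble()
             })
  })
}

study_linear_once <- function(i, params = linear_params(0, 1),
                              var_u = 0.25, var_eps = 0.25, n = 50) {
  purrr::map_dfr(
    c("noncontrolled_classical", "noncontrolled_berkson", "controlled_berkson"),
    function(des) {
      d <- generate_linear_dataset(des, n = n, params = params,
                                   var_u = var_u, var_eps = var_eps)
      dplyr::bind_rows(
        tidy_fit_row(fit_least_squares(d, time = "true"),
                     "linear", des, i, "true"),
        tidy_fit_row(fit_least_squares(d, time = "protocol"),
                     "linear", des, i, "observed")
      )
    }
  )
}

study_oscillator_once <- function(i, params = cosine_params(3, 4),
                                  var_u = 0.05, var_eps = 0.05, n = 50) {
  b_true <- params$b
  purrr::map_dfr(
    c("noncontrolled_classical", "noncontrolled_berkson",
      "controlled_case1", "controlled_case2"),
    function(des) {
      d <- generate_oscillation_dataset(des, params = params, var_u = var_u,
                                        var_eps = var_eps, n = n)
      fit_a <- function(time) {
        fit_least_squares(d, time = time, free = "a", fixed = c(b = b_true),
                          init = c(a = 1))
      }
      dplyr::bind_rows(
        tidy_fit_row(fit_a("true"), "oscillator", des, i, "true"),
        tidy_fit_row(fit_a("protocol"), "oscillator", des, i, "observed")
      )
    }
  )
}

study_parasite_once <- function(i,
                                params = parasite_params(0.002, 0.531,
                                                         0.02, 0.323),
                                sigma_U = 0.25, sigma_eps = 0) {
  clean <- generate_parasite_dataset(params, sigma_U = 0, sigma_eps = 0)
  noisy <- generate_parasite_dataset(params, sigma_U = sigma_U,
                                     sigma_eps = sigma_eps)
  dplyr::bind_rows(
    tidy_fit_row(fit_least_squares(clean), "parasite", "no_time_error", i,
                 "observed"),
    tidy_fit_row(fit_least_squares(noisy), "parasite", "all_params", i,
                 "observed"),
    tidy_fit_row(
      fit_least_squares(noisy, free = c("V0", "g"),
                        fixed = c(B0 = params$B0, k = params$k)),
      "parasite", "V0_g_only", i, "observed"
    )
  )
}

fit_tumour_pooled <- function(d, y0_fixed = TRUE) {
  if (y0_fixed) {
    y0 <- mean(d$response[d$protocol_time == 0])
    fit_least_squares(d, free = c("r", "K"), fixed = c(y0 = y0),
                      init = c(r = 0.1, K = max(d$response) * 1.5))
  } else {
    fit_least_squares(d, free = c("y0", "r", "K"),
                      init = c(y0 = max(min(d$response), 1), r = 0.1,
                               K = max(d$response) * 1.5))
  }
}

study_tumour_once <- function(i, n_tumours = 6, mean_duration = 1 / 6,
                              sd_duration = 0.1, K = 4000) {
  purrr::map_dfr(c("perfect", "ordered", "random_order"), function(sc) {
    d <- generate_tumour_dataset(sc, n_tumours = n_tumours,
                                 mean_duration = mean_duration,
                                 sd_duration = sd_duration, K = K)
    dplyr::bind_rows(
      tidy_fit_row(fit_tumour_pooled(d, TRUE), "tumour", sc, i, "y0_fixed"),
      tidy_fit_row(fit_tumour_pooled(d, FALSE), "tumour", sc, i, "y0_free")
    )
  })
}

study_tumour_individual_once <- function(i, n_tumours = 6,
                                         mean_duration = 1 / 6,
                                         sd_duration = 0.1, K = 4000) {
  purrr::map_dfr(c("perfect", "ordered", "random_order"), function(sc) {
    d <- generate_tumour_dataset(sc, n_tumours = n_tumours,
                                 mean_duration = mean_duration,
                                 sd_duration = sd_duration, K = K)
    truth <- timecourse_meta(d)$meta$true_params
    ests <- fit_subjects(d, free = c("y0", "r", "K"))
    truth_long <- tidyr::pivot_longer(truth, c("y0", "r", "K"),
                                      names_to = "term", values_to = "truth")
    dplyr::left_join(ests, truth_long, by = c("subject_id", "term")) |>
      dplyr::transmute(
        study_id = "tumour_individual", scenario = sc, replicate = i,
        data = "observed", subject_id = .data$subject_id,
        parameter = .data$term, estimate = .data$estimate,
        truth = .data$truth,
        rel_error = (.data$estimate - .data$truth) / .data$truth,
        converged = .data$converged
      )
  })
}

## Grids --------------------------------------------------------------------

#' Bias/variance and posterior-metric grids
#'
#' `"parasite_grid"`: for each `(sigma_U, sigma_eps)` cell, generates
#' `reps` parasite datasets, fits `(V0, g)` with the background fixed at
#' truth (starting from truth), and records the mean bias and variance of
#' each estimate. `"glut4_grid"`: for each `(Delta, sigma_Y)` cell, runs
#' the SMC posterior on `reps` datasets and averages the MAP absolute
#' error, credibility-interval width and truth-to-interval distance per
#' parameter; cells with `sigma_Y = 0` (degenerate likelihood) or with no
#' successful fit are marked missing.
#'
#' @param study_id `"parasite_grid"` or `"glut4_grid"`.
#' @param sigma_U,sigma_eps Parasite grid axes (defaults: 20 points on
#'   `[0, 0.5]` each).
#' @param Delta,sigma_Y GLUT4 grid axes (defaults: 10 points on `[0, 1]`
#'   minutes and `[0, 0.3]`).
#' @param reps Replicates per cell.
#' @param seed Root seed.
#' @param params True model parameters.
#' @param n_rep,n_particles,n_moves GLUT4 grid: replicates per protocol
#'   time, SMC particles and MH sweeps.
#' @return A tidy tibble keyed by the grid axes and `parameter`, with
#'   `bias`/`variance` (parasite) or `map_abs_error`/`ci_width`/
#'   `ci_distance` (GLUT4), ready for heatmap rendering.
#' @export
bias_variance_grid <- function(study_id = c("parasite_grid", "glut4_grid"),
                               sigma_U = seq(0, 0.5, length.out = 20),
                               sigma_eps = seq(0, 0.5, length.out = 20),
                               Delta = seq(0, 1, length.out = 10),
                               sigma_Y = seq(0, 0.3, length.out = 10),
                               reps = 1000, seed = 1,
                               params = NULL, n_rep = 50,
                               n_particles = 400, n_moves = 3) {
  study_id <- match.arg(study_id)
  if (study_id == "parasite_grid") {
    parasite_grid(sigma_U, sigma_eps, reps, seed,
                  params %||% parasite_params(0.002, 0.531, 0.02, 0.323))
  } else {
    glut4_grid(Delta, sigma_Y, reps, seed,
               params %||% glut4_params(0.1, 0.1, 1),
               n_rep, n_particles, n_moves)
  }
}

parasite_grid <- function(sigma_U, sigma_eps, reps, seed, params) {
  truth <- c(V0 = params$V0, g = params$g)
  cells <- tidyr::expand_grid(sigma_U = sigma_U, sigma_eps = sigma_eps)
  purrr::pmap_dfr(cells, function(sigma_U, sigma_eps) {
    cell_id <- which(cells$sigma_U == sigma_U & cells$sigma_eps == sigma_eps)[1]
    ests <- purrr::map(seq_len(reps), function(r) {
      set.seed(study_seed(seed, (cell_id - 1) * reps + r))
      d <- generate_parasite_dataset(params, sigma_U = sigma_U,
                                     sigma_eps = sigma_eps)
      f <- tryCatch(
        fit_least_squares(d, free = c("V0", "g"),
                          fixed = c(B0 = params$B0, k = params$k),
                          init = truth),
        error = function(e) NULL
      )
      if (is.null(f) || !f$converged) NULL else f$theta_hat
    })
    ests <- do.call(rbind, purrr::compact(ests))
    if (is.null(ests) || nrow(ests) == 0) {
      return(tibble::tibble(sigma_U = sigma_U, sigma_eps = sigma_eps,
                            parameter = names(truth), bias = NA_real_,
                            variance = NA_real_, n_ok = 0L))
    }
    tibble::tibble(
      sigma_U = sigma_U, sigma_eps = sigma_eps,
      parameter = colnames(ests),
      bias = colMeans(ests) - truth[colnames(ests)],
      variance = apply(ests, 2, var),
      n_ok = nrow(ests)
    )
  })
}

glut4_grid <- function(Delta, sigma_Y, reps, seed, params,
                       n_rep, n_particles, n_moves) {
  truth <- c(P0 = params$P0, k = params$k, M = params$M)
  cells <- tidyr::expand_grid(Delta = Delta, sigma_Y = sigma_Y)
  purrr::pmap_dfr(cells, function(Delta, sigma_Y) {
    cell_id <- which(cells$Delta == Delta & cells$sigma_Y == sigma_Y)[1]
    if (sigma_Y <= 0) {
      return(tibble::tibble(Delta = Delta, sigma_Y = sigma_Y,
                            parameter = names(truth),
                            map_abs_error = NA_real_, ci_width = NA_real_,
                            ci_distance = NA_real_, n_ok = 0L))
    }
    mets <- purrr::map(seq_len(reps), function(r) {
      set.seed(study_seed(seed, (cell_id - 1) * reps + r))
      d <- generate_glut4_dataset(params, Delta = Delta, sigma_Y = sigma_Y,
                                  n_rep = n_rep)
      ps <- tryCatch(
        glut4_posterior(d, sigma_Y = sigma_Y, n_particles = n_particles,
                        n_moves = n_moves),
        error = function(e) NULL
      )
      if (is.null(ps)) NULL else posterior_metrics(ps, truth)
    })
    mets <- dplyr::bind_rows(purrr::compact(mets))
    if (nrow(mets) == 0) {
      return(tibble::tibble(Delta = Delta, sigma_Y = sigma_Y,
                            parameter = names(truth),
                            map_abs_error = NA_real_, ci_width = NA_real_,
                            ci_distance = NA_real_, n_ok = 0L))
    }
    dplyr::summarise(
      dplyr::group_by(mets, .data$parameter),
      map_abs_error = mean(.data$map_abs_error),
      ci_width = mean(.data$ci_width),
      ci_distance = mean(.data$ci_distance),
      n_ok = dplyr::n(), .groups = "drop"
    ) |>
      dplyr::mutate(Delta = Delta, sigma_Y = sigma_Y, .before = 1)
  })
}

#' Density summaries of a study table
#'
#' Gaussian-kernel densities ([kde()]) of the estimates (or of the
#' confidence-interval widths) of one parameter, per scenario and
#' fitted-data kind — the summaries behind the density figures.
#'
#' @param study_table Output of [run_study()].
#' @param parameter Parameter to summarise.
#' @param what `"estimate"` or `"ci_width"`.
#' @return A tibble with `scenario`, `data`, `x`, `density`.
#' @export
estimate_density <- function(study_table, parameter,
                             what = c("estimate", "ci_width")) {
  what <- match.arg(what)
  tab <- dplyr::filter(study_table, .data$parameter == !!parameter)
  if (what == "ci_width") {
    tab <- dplyr::mutate(tab, value = .data$ci_upper - .data$ci_lower)
  } else {
    tab <- dplyr::mutate(tab, value = .data$estimate)
  }
  dplyr::group_by(tab, .data$scenario, .data$data) |>
    dplyr::group_modify(~ kde(.x$value)) |>
    dplyr::ungroup()
}
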