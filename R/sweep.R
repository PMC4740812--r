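# Parameter sweeps: affinity response curves and the competition x
# residence phase diagram comparing the two promoter archetypes.

#' Sweep monomeric-TBP affinity
#'
#' Simulates the promoter chain over a grid of affinity values (all other
#' parameters fixed) with replicate seeds, recording the population CV at
#' each point. Under Mot1p-dominant competition the CV rises with the
#' probability of assembling monomeric TBP.
#'
#' @param params Base [promoter_params()]; each grid point overrides its
#'   `affinity`.
#' @param affinities Numeric grid of affinity values.
#' @param n_replicates Independent simulations per grid point.
#' @param n_cells,n_steps Simulation size per run.
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @return A tibble of class `affinity_sweep` with columns `affinity`,
#'   `replicate`, `cv`.
#' @export
sweep_affinity <- function(params, affinities = seq(0.05, 0.75, length.out = 8),
                           n_replicates = 3, n_cells = 500, n_steps = 150,
                           seed = 1L) {
  params <- as_promoter_params(params)
  if (!length(affinities)) abort("`affinities` must be non-empty.")
  grid <- tidyr::expand_grid(affinity = affinities,
                             replicate = seq_len(n_replicates))
  grid$cv <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    p <- update_params(params, affinity = grid$affinity[i])
    sim <- simulate_population(p, n_cells = n_cells, n_steps = n_steps,
                               seed = derive_seed(seed, i))
    suppressWarnings(population_noise(sim))
  })
  structure(grid, class = c("affinity_sweep", class(grid)),
            seed = as.integer(seed), n_cells = n_cells, n_steps = n_steps)
}

#' @method autoplot affinity_sweep
#' @export
autoplot.affinity_sweep <- function(object, ...) {
  smry <- object |>
    dplyr::group_by(.data$affinity) |>
    dplyr::summarise(mean_cv = mean(.data$cv), sd_cv = stats::sd(.data$cv),
                     .groups = "drop")
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$affinity, y = .data$mean_cv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_cv - .data$sd_cv,
                                      ymax = .data$mean_cv + .data$sd_cv),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "monomeric TBP affinity (f -> T probability)",
                  y = "population CV")
}

#' Competition x residence phase diagram
#'
#' Simulates both promoter archetypes over a grid of Mot1p/SAGA competition
#' values and SAGA residence times, replicate-averaging the population CV
#' of each, and records their difference. The diagram exposes both noise
#' regimes: Mot1p-dominant cells where the TATA-box archetype is noisier,
#' and SAGA-dominant/long-residence cells where it is quieter than the
#' TATA-like archetype.
#'
#' @param base_tata,base_talike Archetype parameter sets; each grid cell
#'   overrides their `competition` and `r_S`.
#' @param competition_grid,residence_grid Non-empty numeric grids.
#' @param n_replicates Simulations per archetype per cell (default 3).
#' @param n_cells,n_steps Simulation size per run.
#' @param seed Master seed.
#' @return A tibble of class `phase_diagram` with columns `competition`,
#'   `residence`, `cv_tata`, `cv_talike`, `cv_diff`, `n_replicates`.
#' @export
sweep_phase_diagram <- function(base_tata = params_tata_box(),
                                base_talike = params_tata_like(),
                                competition_grid = seq(0.05, 0.95, length.out = 10),
                                residence_grid = seq(5, 80, length.out = 10),
                                n_replicates = 3, n_cells = 500,
                                n_steps = 150, seed = 1L) {
  if (!length(competition_grid) || !length(residence_grid)) {
    abort("competition and residence grids must be non-empty.")
  }
  check_scalar(n_replicates, "n_replicates", 1, Inf)
  base_tata <- as_promoter_params(base_tata)
  base_talike <- as_promoter_params(base_talike)
  grid <- tidyr::expand_grid(competition = competition_grid,
                             residence = residence_grid)
  res <- purrr::map(seq_len(nrow(grid)), function(k) {
    cc <- grid$competition[k]; rr <- grid$residence[k]
    pt <- tryCatch(
      update_params(base_tata, competition = cc, r_S = rr),
      error = function(e) abort(sprintf(
        "invalid grid cell (competition = %g, residence = %g): %s",
        cc, rr, conditionMessage(e)))
    )
    pl <- tryCatch(
      update_params(base_talike, competition = cc, r_S = rr),
      error = function(e) abort(sprintf(
        "invalid grid cell (competition = %g, residence = %g): %s",
        cc, rr, conditionMessage(e)))
    )
    cvs <- vapply(seq_len(n_replicates), function(j) {
      s_t <- simulate_population(pt, n_cells = n_cells, n_steps = n_steps,
                                 seed = derive_seed(seed, 2L * (k * n_replicates + j)))
      s_l <- simulate_population(pl, n_cells = n_cells, n_steps = n_steps,
                                 seed = derive_seed(seed, 2L * (k * n_replicates + j) + 1L))
      c(suppressWarnings(population_noise(s_t)),
        suppressWarnings(population_noise(s_l)))
    }, numeric(2))
    tibble(competition = cc, residence = rr,
           cv_tata = mean(cvs[1, ]), cv_talike = mean(cvs[2, ]))
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::mutate(cv_diff = .data$cv_tata - .data$cv_talike,
                  n_replicates = n_replicates)
  structure(out, class = c("phase_diagram", class(out)),
            seed = as.integer(seed), n_cells = n_cells, n_steps = n_steps)
}

#' @method autoplot phase_diagram
#' @export
autoplot.phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$competition,
                                       y = .data$residence,
                                       fill = .data$cv_diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue4", mid = "white",
                                  high = "firebrick3", midpoint = 0) +
    ggplot2::labs(x = "competition (P(Mot1p engages) vs SAGA)",
                  y = "SAGA residence time (steps)",
                  fill = "CV(TATA-box) -\nCV(TATA-like)")
}
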