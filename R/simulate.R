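# Population simulation of the promoter-state chain and the per-simulation
# summaries (CV, waiting times, turnover).

# Deterministic per-cell seed stream: changing n_cells never reshuffles
# the streams of earlier cells.
cell_seed <- function(master, cell) {
  as.integer((as.numeric(master) + 104729 * as.numeric(cell)) %% 2147483647)
}

derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 7919 * as.numeric(index)) %% 2147483647)
}

#' Simulate a cell population at one promoter
#'
#' Runs `n_cells` independent realisations of the promoter-state chain for
#' `n_steps` steps each, starting from the free promoter `f` (after an
#' optional burn-in). Expression accrues `b_S` units per step spent in the
#' SAGA state and `b_D` per step in the TFIID state (or per *entry* into
#' those states with `accrual = "per_entry"`); no degradation is modelled.
#' Each cell consumes its own deterministic random stream derived from
#' `seed`, so results are bit-reproducible and enlarging the population
#' leaves earlier cells unchanged.
#'
#' @param params A [promoter_params()] object supplying burst sizes and,
#'   unless `P` is given, the transition matrix.
#' @param n_cells,n_steps Population size and trajectory length
#'   (defaults 500 cells x 150 steps).
#' @param seed Integer master seed.
#' @param P Optional row-stochastic transition matrix overriding
#'   `build_transition_matrix(params)`.
#' @param accrual `"per_step"` (default) or `"per_entry"` burst accounting.
#' @param burn_in Steps to run and discard before recording (default 0, a
#'   cold start from `f`).
#' @return A `promoter_sim` object: per-cell `expression` tibble, the
#'   integer state `histories` matrix (cells x steps), initial states, the
#'   matrix and parameters used, and the seed.
#' @seealso [population_noise()], [waiting_time_stats()], [turnover_rate()]
#' @export
#' @examples
#' sim <- simulate_population(params_tata_box(), n_cells = 50, seed = 1)
#' glance(sim)
simulate_population <- function(params, n_cells = 500, n_steps = 150,
                                seed = 1L, P = NULL,
                                accrual = c("per_step", "per_entry"),
                                burn_in = 0) {
  p <- as_promoter_params(params)
  if (is.null(P)) P <- build_transition_matrix(p)
  check_stochastic(P)
  accrual <- match.arg(accrual)
  check_scalar(n_cells, "n_cells", 1, Inf)
  check_scalar(n_steps, "n_steps", 1, Inf)
  check_scalar(burn_in, "burn_in", 0, Inf)
  n_cells <- as.integer(n_cells); n_steps <- as.integer(n_steps)
  burn_in <- as.integer(burn_in)

  total <- burn_in + n_steps
  U <- matrix(0, total, n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(cell_seed(seed, i))
    U[, i] <- stats::runif(total)
  }

  k <- nrow(P)
  cum <- t(apply(P, 1, cumsum))
  cum[, k] <- 1
  state <- rep(1L, n_cells)
  init <- state
  H <- matrix(0L, n_cells, n_steps)
  for (t in seq_len(total)) {
    state <- 1L + as.integer(rowSums(cum[state, , drop = FALSE] < U[t, ]))
    if (t == burn_in) init <- state
    if (t > burn_in) H[, t - burn_in] <- state
  }

  n_S <- as.integer(rowSums(H == 4L))
  n_D <- as.integer(rowSums(H == 5L))
  if (accrual == "per_step") {
    expression <- p$b_S * n_S + p$b_D * n_D
  } else {
    prev <- cbind(init, H[, -n_steps, drop = FALSE])
    expression <- p$b_S * rowSums(H == 4L & prev != 4L) +
      p$b_D * rowSums(H == 5L & prev != 5L)
  }

  structure(
    list(
      expression = tibble(cell = seq_len(n_cells), expression = expression,
                          n_S = n_S, n_D = n_D),
      histories = H,
      init_states = init,
      params = p,
      matrix = P,
      n_cells = n_cells,
      n_steps = n_steps,
      seed = as.integer(seed),
      accrual = accrual,
      burn_in = burn_in
    ),
    class = "promoter_sim"
  )
}

#' @export
print.promoter_sim <- function(x, ...) {
  cat(sprintf("<promoter_sim: %s | %d cells x %d steps | seed %d>\n",
              x$params$label, x$n_cells, x$n_steps, x$seed))
  cv <- suppressWarnings(population_noise(x))
  cat(sprintf("  mean expression %.3g, CV %s\n",
              mean(x$expression$expression),
              ifelse(is.na(cv), "undefined (zero mean)", sprintf("%.3g", cv))))
  invisible(x)
}

#' State history of a simulated population
#'
#' @param sim A `promoter_sim` object.
#' @param format `"integer"` codes (1..5) or `"label"` characters.
#' @return A cells x steps matrix.
#' @export
state_history <- function(sim, format = c("integer", "label")) {
  stopifnot(inherits(sim, "promoter_sim"))
  format <- match.arg(format)
  if (format == "integer") return(sim$histories)
  matrix(microstates()[sim$histories], nrow(sim$histories),
         ncol(sim$histories))
}

#' @rdname simulate_population
#' @param x A `promoter_sim` object.
#' @param ... Unused.
#' @method tidy promoter_sim
#' @export
tidy.promoter_sim <- function(x, ...) x$expression

#' @rdname simulate_population
#' @method glance promoter_sim
#' @export
glance.promoter_sim <- function(x, ...) {
  e <- x$expression$expression
  tibble(
    label = x$params$label,
    n_cells = x$n_cells,
    n_steps = x$n_steps,
    mean_expression = mean(e),
    sd_expression = stats::sd(e),
    cv = suppressWarnings(population_noise(x)),
    turnover = turnover_rate(x),
    frac_on = mean(x$histories %in% ON_STATES)
  )
}

#' Population expression noise (CV)
#'
#' Coefficient of variation of per-cell expression totals: sample standard
#' deviation (n - 1 denominator) divided by the mean. A zero-mean
#' population has no defined CV and returns `NA` with a warning rather
#' than dividing by zero.
#'
#' @param x A `promoter_sim` object or a numeric vector of per-cell
#'   expression totals (length >= 2).
#' @return A single number, or `NA` if the mean is zero.
#' @export
#' @examples
#' population_noise(c(2, 4))
population_noise <- function(x) {
  e <- if (inherits(x, "promoter_sim")) x$expression$expression else x
  if (!is.numeric(e)) abort("`x` must be numeric or a `promoter_sim`.")
  if (length(e) < 2L) abort("CV requires at least 2 cells.")
  m <- mean(e)
  if (m == 0) {
    warn("mean expression is zero; CV is undefined.")
    return(NA_real_)
  }
  stats::sd(e) / m
}

coerce_history_matrix <- function(x) {
  if (inherits(x, "promoter_sim")) return(x$histories)
  if (is.character(x)) x <- matrix(match(x, microstates()),
                                   nrow = if (is.matrix(x)) nrow(x) else 1)
  if (is.numeric(x) && !is.matrix(x)) x <- matrix(as.integer(x), nrow = 1)
  if (!is.matrix(x) || anyNA(x)) {
    abort("histories must be a `promoter_sim`, an integer matrix of state codes, or state labels.")
  }
  storage.mode(x) <- "integer"
  x
}

#' Waiting times between transcriptional On states
#'
#' For each cell, measures the lengths of maximal runs of Off states
#' (`f`, `T`, `M`) separating visits to the On states (`S`, `D`). Runs
#' censored by the start or end of the recording (no flanking On visit)
#' are excluded by default.
#'
#' @param x A `promoter_sim`, an integer state-code matrix (cells x steps)
#'   or a character vector/matrix of state labels.
#' @param include_censored Keep leading/trailing Off runs (default FALSE).
#' @return A list of class `waiting_times`: `runs` (tibble with `cell`,
#'   `length`), pooled `mean` and `median`, `n_runs`, and `no_on` — TRUE
#'   (with a warning) when no cell ever reaches an On state.
#' @export
#' @examples
#' waiting_time_stats(c("f", "f", "D", "f", "f", "f", "S"))
waiting_time_stats <- function(x, include_censored = FALSE) {
  H <- coerce_history_matrix(x)
  runs <- vector("list", nrow(H))
  for (i in seq_len(nrow(H))) {
    r <- rle(H[i, ] %in% ON_STATES)
    off <- which(!r$values)
    if (!include_censored) {
      off <- off[off > 1L & off < length(r$values)]
    }
    if (length(off)) runs[[i]] <- tibble(cell = i, length = r$lengths[off])
  }
  runs <- dplyr::bind_rows(runs)
  no_on <- !any(H %in% ON_STATES)
  if (nrow(runs) == 0L) {
    if (no_on) warn("no cell ever reached an On state; waiting times are empty.")
    runs <- tibble(cell = integer(), length = integer())
  }
  structure(
    list(runs = runs,
         mean = if (nrow(runs)) mean(runs$length) else NA_real_,
         median = if (nrow(runs)) stats::median(runs$length) else NA_real_,
         n_runs = nrow(runs),
         no_on = no_on),
    class = "waiting_times"
  )
}

#' @export
print.waiting_times <- function(x, ...) {
  cat(sprintf("<waiting_times: %d complete Off runs | mean %.3g, median %.3g>\n",
              x$n_runs, x$mean, x$median))
  invisible(x)
}

#' @method tidy waiting_times
#' @export
tidy.waiting_times <- function(x, ...) x$runs

#' TBP turnover rate
#'
#' Turnover is the rate at which a new TBP molecule binds the promoter
#' after the previous one was displaced: the count of transitions from the
#' free promoter into a TBP-containing state (`f -> T` or `f -> D`)
#' divided by the simulated time, averaged over cells.
#'
#' @param x A `promoter_sim` object.
#' @return Mean per-step binding rate; per-cell rates in attribute
#'   `"per_cell"`.
#' @export
turnover_rate <- function(x) {
  stopifnot(inherits(x, "promoter_sim"))
  H <- x$histories
  n_steps <- ncol(H)
  prev <- cbind(x$init_states, H[, -n_steps, drop = FALSE])
  events <- prev == 1L & (H == 2L | H == 5L)
  per_cell <- rowSums(events) / n_steps
  structure(mean(per_cell), per_cell = per_cell)
}

#' @rdname simulate_population
#' @param object A `promoter_sim` object.
#' @method autoplot promoter_sim
#' @export
autoplot.promoter_sim <- function(object, ...) {
  ggplot2::ggplot(object$expression, ggplot2::aes(x = .data$expression)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey35", colour = "white") +
    ggplot2::labs(
      x = "expression per cell (a.u.)", y = "cells",
      title = sprintf("%s promoter: %d cells x %d steps",
                      object$params$label, object$n_cells, object$n_steps),
      subtitle = sprintf("CV = %.3g",
                         suppressWarnings(population_noise(object)))
    )
}

#' Microstate history heat map
#'
#' Draws the per-cell microstate trajectories of a simulated population as
#' a cells x time tile plot, mirroring the usual presentation of promoter
#' state histories.
#'
#' @param sim A `promoter_sim` object.
#' @param cells Which cells to draw (default: up to 50).
#' @return A ggplot object.
#' @export
plot_state_history <- function(sim, cells = NULL) {
  stopifnot(inherits(sim, "promoter_sim"))
  if (is.null(cells)) cells <- seq_len(min(50L, sim$n_cells))
  H <- sim$histories[cells, , drop = FALSE]
  df <- tibble(
    cell = rep(cells, times = ncol(H)),
    step = rep(seq_len(ncol(H)), each = length(cells)),
    state = factor(microstates()[as.vector(H)], levels = microstates())
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$cell,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      f = "grey85", T = "goldenrod2", M = "mediumpurple3",
      S = "firebrick3", D = "deeppink3")) +
    ggplot2::labs(x = "time step", y = "cell", fill = "microstate")
}
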