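# Flow-cytometry processing: ADC-bound filtering with scatter-tail
# trimming, small-cell gating on total scatter, linear-model size
# correction of GFP, and replicate-averaged CV. The pipeline order is
# fixed (filter -> gate -> correct -> CV); every stage only removes rows
# or adds derived columns.

ADC_LIMIT <- 2^18 - 1  # 18-bit digitiser ceiling (262,143)

check_events <- function(events, need = c("fsc_a", "ssc_a", "gfp")) {
  if (!is.data.frame(events)) abort("`events` must be a data frame.")
  miss <- setdiff(need, names(events))
  if (length(miss)) {
    abort(sprintf("`events` is missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  events <- tibble::as_tibble(events)
  if (!"sample_id" %in% names(events)) events$sample_id <- "sample"
  if (!"replicate_id" %in% names(events)) events$replicate_id <- 1L
  events
}

#' Filter cytometry events
#'
#' Keeps events with both scatter channels strictly inside the 18-bit ADC
#' range `(0, 2^18 - 1)`, then discards the top and bottom `trim`
#' fraction (default 5%) of events ranked by total scatter
#' (`fsc_a * ssc_a`; `score = "per_channel"` trims each channel's tails
#' instead). The tail size is `floor(trim * n)` events per side.
#'
#' @param events Event tibble with columns `fsc_a`, `ssc_a`, `gfp`
#'   (optional `sample_id`, `replicate_id`).
#' @param adc_limit Upper (exclusive) ADC bound, default `2^18 - 1`.
#' @param trim Tail fraction per side (default 0.05).
#' @param score Scatter score for trimming: product of the channels
#'   (default) or per-channel tails.
#' @return The surviving events, order preserved.
#' @export
filter_events <- function(events, adc_limit = ADC_LIMIT, trim = 0.05,
                          score = c("product", "per_channel")) {
  events <- check_events(events)
  score <- match.arg(score)
  if (!nrow(events)) abort("`events` must be non-empty.")
  keep <- events$fsc_a > 0 & events$fsc_a < adc_limit &
    events$ssc_a > 0 & events$ssc_a < adc_limit
  ev <- events[keep, , drop = FALSE]
  if (!nrow(ev)) abort("no events remain after the ADC range filter.")
  trim_tails <- function(v, d) {
    n <- length(v)
    k <- floor(d * n)
    if (k == 0L) return(rep(TRUE, n))
    r <- rank(v, ties.method = "first")
    r > k & r <= n - k
  }
  if (score == "product") {
    ok <- trim_tails(ev$fsc_a * ev$ssc_a, trim)
  } else {
    ok <- trim_tails(ev$fsc_a, trim) & trim_tails(ev$ssc_a, trim)
  }
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) abort("no events remain after scatter-tail trimming.")
  ev
}

#' Gate the small-cell subpopulation
#'
#' Keeps events whose total scatter (`fsc_a * ssc_a`, a cell-size proxy)
#' lies strictly below the `cutoff` quantile of that product — by default
#' the median, selecting the smaller, unbudded half of the population.
#' With a degenerate (constant) scatter product no event is strictly
#' below the cutoff; the gate then falls back to `<=` with a warning.
#'
#' @param events Filtered event tibble.
#' @param cutoff Quantile of the scatter product (default 0.5);
#'   `cutoff >= 1` keeps all events.
#' @return The gated events.
#' @export
gate_small_cells <- function(events, cutoff = 0.5) {
  events <- check_events(events)
  check_scalar(cutoff, "cutoff", 0, 1)
  if (cutoff >= 1) return(events)
  prod_sc <- events$fsc_a * events$ssc_a
  q <- stats::quantile(prod_sc, cutoff, type = 7, names = FALSE)
  keep <- prod_sc < q
  if (!any(keep)) {
    warn("no event lies strictly below the scatter cutoff; gating with `<=` instead.")
    keep <- prod_sc <= q
  }
  events[keep, , drop = FALSE]
}

apply_correction <- function(raw, fitted, method) {
  switch(method,
         squared = raw^2 / fitted,
         ratio = raw / fitted,
         abort(sprintf("unknown correction method `%s`.", method)))
}

#' Size-correct GFP fluorescence
#'
#' Fits the ordinary least-squares model `gfp ~ fsc_a + ssc_a` (with
#' intercept) and derives size-corrected GFP per event. The default
#' `"squared"` rule divides the squared raw fluorescence by the fitted
#' value; the conventional `"ratio"` rule divides the raw fluorescence by
#' the fitted value and is the variant that recovers the expression CV
#' when fluorescence is a size x expression product (see the methods
#' vignette). Events with non-positive fitted values are flagged
#' (`correction_ok = FALSE`) and excluded from downstream CV.
#'
#' @param events Event tibble (>= 3 events for an identifiable fit).
#' @param method `"squared"` (default) or `"ratio"`.
#' @return `events` with `gfp_corrected` and `correction_ok` columns;
#'   the fit summary is stored in attribute `"size_fit"`.
#' @export
size_correct <- function(events, method = c("squared", "ratio")) {
  events <- check_events(events)
  method <- match.arg(method)
  if (nrow(events) < 3L) {
    abort("size correction needs at least 3 events to fit the linear model.")
  }
  fit <- stats::lm(gfp ~ fsc_a + ssc_a, data = events)
  if (anyNA(stats::coef(fit))) {
    abort("rank-deficient design: fsc_a and ssc_a are collinear.")
  }
  fv <- unname(stats::fitted(fit))
  events$gfp_corrected <- apply_correction(events$gfp, fv, method)
  events$correction_ok <- fv > 0
  if (any(!events$correction_ok)) {
    warn(sprintf("%d event(s) have non-positive fitted values; flagged and excluded from CV.",
                 sum(!events$correction_ok)))
  }
  fit_summary <- suppressWarnings(summary(fit))  # a perfect fit warns
  attr(events, "size_fit") <- list(
    coefficients = stats::coef(fit),
    sigma = fit_summary$sigma,
    r_squared = fit_summary$r.squared,
    mean_residual = mean(stats::residuals(fit)),
    method = method
  )
  events
}

#' Expression noise from corrected events
#'
#' Per-replicate CV (sample s.d. over mean of corrected GFP), then the
#' across-replicate mean CV and its standard error (s.d. / sqrt(k)) per
#' sample. A single replicate yields its own CV with an undefined
#' standard error (`NA`, with a warning).
#'
#' @param events Events that have passed [size_correct()] (each
#'   sample/replicate needs >= 2 usable events).
#' @return A list of class `cyto_noise`: `replicates` (per-replicate n
#'   and CV) and `samples` (per-sample `cv_mean`, `cv_se`,
#'   `n_replicates`).
#' @export
noise_from_events <- function(events) {
  events <- check_events(events)
  if (!"gfp_corrected" %in% names(events)) {
    abort("run `size_correct()` before computing noise from events.")
  }
  if (!"correction_ok" %in% names(events)) events$correction_ok <- TRUE
  usable <- events[events$correction_ok, , drop = FALSE]
  reps <- usable |>
    dplyr::group_by(.data$sample_id, .data$replicate_id) |>
    dplyr::summarise(n_events = dplyr::n(),
                     cv = stats::sd(.data$gfp_corrected) /
                       mean(.data$gfp_corrected),
                     .groups = "drop")
  if (any(reps$n_events < 2L)) {
    abort("every replicate needs at least 2 usable events for a CV.")
  }
  samples <- reps |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      cv_mean = mean(.data$cv),
      cv_se = if (dplyr::n() > 1L) {
        stats::sd(.data$cv) / sqrt(dplyr::n())
      } else NA_real_,
      .groups = "drop"
    )
  if (any(samples$n_replicates == 1L)) {
    warn("sample(s) with a single replicate: standard error is undefined.")
  }
  structure(list(replicates = reps, samples = samples),
            class = "cyto_noise")
}

#' @export
print.cyto_noise <- function(x, ...) {
  cat("<cyto_noise>\n")
  print(x$samples)
  invisible(x)
}

#' @method tidy cyto_noise
#' @export
tidy.cyto_noise <- function(x, ...) x$replicates

#' @method glance cyto_noise
#' @export
glance.cyto_noise <- function(x, ...) x$samples

#' Full cytometry processing chain
#'
#' Runs the order-fixed pipeline filter -> gate -> size-correct -> CV and
#' records the event count surviving each stage.
#'
#' @inheritParams filter_events
#' @inheritParams gate_small_cells
#' @inheritParams size_correct
#' @return A list of class `cyto_result`: `noise` (a `cyto_noise`),
#'   `events` (the final annotated events) and `stage_counts` (tibble of
#'   per-stage event counts).
#' @export
cytometry_pipeline <- function(events, trim = 0.05, cutoff = 0.5,
                               method = c("squared", "ratio"),
                               adc_limit = ADC_LIMIT) {
  events <- check_events(events)
  method <- match.arg(method)
  n0 <- nrow(events)
  ev <- filter_events(events, adc_limit = adc_limit, trim = trim)
  n1 <- nrow(ev)
  ev <- gate_small_cells(ev, cutoff = cutoff)
  n2 <- nrow(ev)
  ev <- size_correct(ev, method = method)
  noise <- noise_from_events(ev)
  structure(
    list(noise = noise, events = ev,
         stage_counts = tibble(
           stage = c("input", "filtered", "gated", "usable"),
           n_events = c(n0, n1, n2, sum(ev$correction_ok)))),
    class = "cyto_result"
  )
}

#' @export
print.cyto_result <- function(x, ...) {
  cat("<cyto_result>\n$stage_counts\n")
  print(x$stage_counts)
  print(x$noise)
  invisible(x)
}

#' Read a cytometry event table from CSV
#'
#' Expects columns `fsc_a`, `ssc_a`, `gfp` and optionally `sample_id`,
#' `replicate_id` (aliases `fsc`/`ssc`/`sample`/`replicate` are
#' normalised).
#'
#' @param path CSV file path.
#' @return An event tibble.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("event file not found: %s", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  nm <- tolower(names(x))
  nm[nm %in% c("fsc", "fsc-a")] <- "fsc_a"
  nm[nm %in% c("ssc", "ssc-a")] <- "ssc_a"
  nm[nm == "sample"] <- "sample_id"
  nm[nm == "replicate"] <- "replicate_id"
  names(x) <- nm
  check_events(x)
}
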