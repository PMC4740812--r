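# Protein-binding microarray (PBM) aggregation: per-8-mer median signal
# across replicate probes, and class-level comparisons of the TBS types.

#' Aggregate PBM probe intensities per motif
#'
#' The intrinsic binding signal of a motif is the median intensity over
#' the replicate probes carrying it (midpoint of the central pair for even
#' replicate counts). Motifs observed on a single probe are flagged.
#'
#' @param probes Tibble with columns `probe_id`, `motif`, `intensity`.
#' @return A tibble with `motif`, `median_intensity`, `n_probes`,
#'   `single_probe`.
#' @export
#' @examples
#' probes <- tibble::tibble(probe_id = 1:3, motif = "TATATAAA",
#'                          intensity = c(10, 12, 14))
#' aggregate_probe_signal(probes)
aggregate_probe_signal <- function(probes) {
  if (!is.data.frame(probes) ||
      !all(c("motif", "intensity") %in% names(probes))) {
    abort("`probes` must have `motif` and `intensity` columns.")
  }
  if (!nrow(probes)) abort("`probes` must be non-empty.")
  if (any(!is.finite(probes$intensity))) {
    abort("probe intensities must be finite.")
  }
  probes |>
    dplyr::group_by(.data$motif) |>
    dplyr::summarise(
      median_intensity = stats::median(.data$intensity),
      n_probes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_probe = .data$n_probes == 1L)
}

#' Class-level PBM signal summary
#'
#' Classifies motifs into TATA-box / TATA-like / other (and the T5/A5
#' subsets of exact matches), summarises the intensity distribution of
#' each group, and runs Wilcoxon rank-sum tests for all pairwise class
#' comparisons plus T5 vs A5, Benjamini-Hochberg adjusted. The input may
#' be per-motif medians (one row per motif, the aggregation convention) or
#' per-probe rows (several rows per motif, the convention of probe-level
#' box plots); group sizes follow the rows supplied. Comparisons where
#' either group has fewer than two values are skipped and flagged.
#'
#' @param data Tibble with columns `motif` and `intensity` (accepts
#'   `median_intensity` from [aggregate_probe_signal()]).
#' @param pattern IUPAC consensus for classification.
#' @return A list of class `pbm_summary`: `summary` (per-group n and
#'   median) and `comparisons` (`group_a`, `group_b`, `n_a`, `n_b`,
#'   `statistic`, `p_value`, `p_adj`, `skipped`).
#' @export
class_signal_summary <- function(data, pattern = "TATAWAWR") {
  if (!is.data.frame(data) || !"motif" %in% names(data)) {
    abort("`data` must have a `motif` column.")
  }
  val_col <- if ("intensity" %in% names(data)) {
    "intensity"
  } else if ("median_intensity" %in% names(data)) {
    "median_intensity"
  } else {
    abort("`data` must have an `intensity` (or `median_intensity`) column.")
  }
  cls <- classify_tbs(unique(toupper(data$motif)), pattern = pattern)
  d <- tibble(motif = toupper(data$motif), intensity = data[[val_col]]) |>
    dplyr::left_join(cls, by = c(motif = "sequence"))

  groups <- list(
    "TATA-box" = d$intensity[d$tbs_class == "TATA-box"],
    "TATA-like" = d$intensity[d$tbs_class == "TATA-like"],
    "other" = d$intensity[d$tbs_class == "other"],
    "T5" = d$intensity[d$subset == "T5"],
    "A5" = d$intensity[d$subset == "A5"]
  )
  smry <- tibble(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    median_intensity = vapply(
      groups, function(v) if (length(v)) stats::median(v) else NA_real_,
      numeric(1))
  )
  pairs <- list(c("TATA-box", "TATA-like"), c("TATA-box", "other"),
                c("TATA-like", "other"), c("T5", "A5"))
  cmp <- purrr::map(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (length(a) < 2L || length(b) < 2L) {
      return(tibble(group_a = pr[1], group_b = pr[2],
                    n_a = length(a), n_b = length(b),
                    statistic = NA_real_, p_value = NA_real_,
                    skipped = TRUE))
    }
    rs <- rank_sum_test(a, b)
    tibble(group_a = pr[1], group_b = pr[2],
           n_a = length(a), n_b = length(b),
           statistic = rs$statistic, p_value = rs$p_value, skipped = FALSE)
  }) |> dplyr::bind_rows()
  cmp$p_adj <- NA_real_
  if (any(!cmp$skipped)) {
    cmp$p_adj[!cmp$skipped] <- bh_adjust(cmp$p_value[!cmp$skipped])
  }
  structure(list(summary = smry, comparisons = cmp), class = "pbm_summary")
}

#' @export
print.pbm_summary <- function(x, ...) {
  cat("<pbm_summary>\n$summary\n")
  print(x$summary)
  cat("$comparisons\n")
  print(x$comparisons)
  invisible(x)
}

#' @method tidy pbm_summary
#' @export
tidy.pbm_summary <- function(x, ...) x$comparisons

#' @method glance pbm_summary
#' @export
glance.pbm_summary <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "group",
                     values_from = c("n", "median_intensity"))
}
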