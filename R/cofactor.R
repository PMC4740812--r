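# Co-activator regulation classes from ChIP occupancy tables: a gene is
# "regulated" by TFIID (Taf1p) or SAGA (Spt20p) when its promoter
# occupancy lies strictly above the across-gene median for that factor.

#' Classify genes by co-activator regulation
#'
#' Median-split classification: for each factor, the median occupancy is
#' taken over all genes with a measured value; genes strictly above it are
#' regulated (`+`) by that factor, genes at or below are not (`-`). The
#' two splits combine into four classes `+/+`, `+/-`, `-/+`, `-/-`
#' (TFIID / SAGA). Genes missing either factor are excluded.
#'
#' @param table Occupancy tibble: one row per gene, a `gene_id` column and
#'   one numeric column per factor (missing values as `NA`).
#' @param tfiid_factor,saga_factor Column names of the TFIID and SAGA
#'   proxy subunits (defaults `"Taf1p"`, `"Spt20p"`).
#' @return A tibble with `gene_id`, `tfiid_occ`, `saga_occ`,
#'   `tfiid_regulated`, `saga_regulated` and `class` (factor with the four
#'   labels). Attribute `"medians"` records the split points.
#' @export
#' @examples
#' tbl <- tibble::tibble(gene_id = paste0("g", 1:4),
#'                       Taf1p = c(1, 2, 3, 4), Spt20p = c(4, 3, 2, 1))
#' classify_coactivator(tbl)
classify_coactivator <- function(table, tfiid_factor = "Taf1p",
                                 saga_factor = "Spt20p") {
  if (!is.data.frame(table) || !"gene_id" %in% names(table)) {
    abort("`table` must be a data frame with a `gene_id` column.")
  }
  for (col in c(tfiid_factor, saga_factor)) {
    if (!col %in% names(table)) {
      abort(sprintf("occupancy column `%s` is missing from `table`.", col))
    }
  }
  tf <- table[[tfiid_factor]]
  sg <- table[[saga_factor]]
  med_tf <- stats::median(tf, na.rm = TRUE)
  med_sg <- stats::median(sg, na.rm = TRUE)
  keep <- !is.na(tf) & !is.na(sg)
  out <- tibble(
    gene_id = table$gene_id[keep],
    tfiid_occ = tf[keep],
    saga_occ = sg[keep],
    tfiid_regulated = tf[keep] > med_tf,
    saga_regulated = sg[keep] > med_sg
  )
  out$class <- factor(
    paste0(ifelse(out$tfiid_regulated, "+", "-"), "/",
           ifelse(out$saga_regulated, "+", "-")),
    levels = c("+/+", "+/-", "-/+", "-/-")
  )
  attr(out, "medians") <- c(tfiid = med_tf, saga = med_sg)
  out
}

#' Standardise occupancy columns
#'
#' Per-factor affine rescaling (subtract the mean, divide by the standard
#' deviation), a display convenience that leaves the median-split
#' classification unchanged. Zero-variance columns are centred only, with
#' a warning.
#'
#' @param table Occupancy tibble with a `gene_id` column.
#' @param factors Columns to transform (default: all numeric columns).
#' @return The table with transformed factor columns.
#' @export
rescale_center <- function(table, factors = NULL) {
  if (!is.data.frame(table)) abort("`table` must be a data frame.")
  if (is.null(factors)) {
    factors <- names(table)[vapply(table, is.numeric, logical(1))]
    factors <- setdiff(factors, "gene_id")
  }
  for (col in factors) {
    x <- table[[col]]
    if (!is.numeric(x)) abort(sprintf("column `%s` is not numeric.", col))
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warn(sprintf("column `%s` has zero variance; centred only.", col))
      table[[col]] <- x - m
    } else {
      table[[col]] <- (x - m) / s
    }
  }
  table
}

#' Bin genes by TBP turnover
#'
#' Median split of per-gene TBP turnover into `low` (at or below the
#' median) and `high` (above) bins, reporting the realised bin boundaries.
#'
#' @param values A tibble with `gene_id` and `turnover` columns, or a
#'   named numeric vector.
#' @return A tibble with `gene_id`, `turnover`, `bin` (factor low/high);
#'   attribute `"boundaries"` holds the low/high value ranges and the
#'   median.
#' @export
#' @examples
#' bin_turnover(c(a = 0.01, b = 0.02, c = 0.03, d = 0.05))
bin_turnover <- function(values) {
  if (is.numeric(values)) {
    values <- tibble(
      gene_id = if (is.null(names(values))) {
        paste0("gene_", seq_along(values))
      } else names(values),
      turnover = unname(values)
    )
  }
  if (!is.data.frame(values) || !all(c("gene_id", "turnover") %in% names(values))) {
    abort("`values` must have `gene_id` and `turnover` columns (or be a numeric vector).")
  }
  if (!nrow(values)) abort("`values` must be non-empty.")
  med <- stats::median(values$turnover)
  out <- dplyr::mutate(
    tibble::as_tibble(values),
    bin = factor(ifelse(.data$turnover > med, "high", "low"),
                 levels = c("low", "high"))
  )
  attr(out, "boundaries") <- list(
    median = med,
    low = range(out$turnover[out$bin == "low"]),
    high = if (any(out$bin == "high")) {
      range(out$turnover[out$bin == "high"])
    } else c(NA_real_, NA_real_)
  )
  out
}
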