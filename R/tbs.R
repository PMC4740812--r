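# TBS (TBP-binding site) sequence classification: mismatch counting
# against the yeast TATA-box consensus, the TATA-box / TATA-like / other
# thresholds, the T5/A5 position-5 subsets, and promoter scanning.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

check_pattern <- function(pattern) {
  pattern <- toupper(pattern)
  pat <- strsplit(pattern, "")[[1]]
  if (!length(pat) || !all(pat %in% names(IUPAC_SETS))) {
    abort("`pattern` must be a non-empty IUPAC nucleotide string.")
  }
  pat
}

check_seqs <- function(seqs, k) {
  if (!is.character(seqs) || !length(seqs)) {
    abort("sequences must be a non-empty character vector.")
  }
  seqs <- toupper(seqs)
  if (any(nchar(seqs) != k)) {
    abort(sprintf("all sequences must be %d bases long.", k))
  }
  if (any(!grepl("^[ACGT]+$", seqs))) {
    abort("sequences may only contain A, C, G, T.")
  }
  seqs
}

mismatches_impl <- function(seqs, pat) {
  mm <- integer(length(seqs))
  for (p in seq_along(pat)) {
    mm <- mm + !(substr(seqs, p, p) %in% IUPAC_SETS[[pat[p]]])
  }
  mm
}

#' Count mismatches against an IUPAC consensus
#'
#' Number of positions at which a sequence violates the IUPAC pattern
#' (default `TATAWAWR`, the 8-bp yeast TATA-box consensus; `W` = A/T,
#' `R` = A/G). Vectorised over sequences.
#'
#' @param seqs Character vector of DNA sequences, same length as `pattern`.
#' @param pattern IUPAC consensus (default `"TATAWAWR"`).
#' @return Integer vector of mismatch counts.
#' @export
#' @examples
#' count_mismatches(c("TATAAAAG", "TATACAAA", "GCGCGCGC"))
count_mismatches <- function(seqs, pattern = "TATAWAWR") {
  pat <- check_pattern(pattern)
  seqs <- check_seqs(seqs, length(pat))
  mismatches_impl(seqs, pat)
}

#' Classify TBS 8-mers
#'
#' Applies the mismatch thresholds that define the site classes: an exact
#' consensus match is a TATA-box, one or two mismatches a TATA-like site,
#' three or more "other". Exact matches are further split by the identity
#' of position 5 (1-based within the motif): thymine gives the T5 subset,
#' adenine the A5 subset.
#'
#' @inheritParams count_mismatches
#' @param subset_position Motif position used for the T5/A5 split
#'   (default 5).
#' @return A tibble with columns `sequence`, `mismatches`, `tbs_class`
#'   (factor: TATA-box / TATA-like / other) and `subset` (factor: T5 / A5 /
#'   none).
#' @export
#' @examples
#' classify_tbs(c("TATATAAA", "TATAAAAG", "TAAACAAA"))
classify_tbs <- function(seqs, pattern = "TATAWAWR", subset_position = 5) {
  pat <- check_pattern(pattern)
  seqs <- check_seqs(seqs, length(pat))
  mm <- mismatches_impl(seqs, pat)
  tbs_class <- dplyr::case_when(
    mm == 0 ~ "TATA-box",
    mm <= 2 ~ "TATA-like",
    TRUE ~ "other"
  )
  base5 <- substr(seqs, subset_position, subset_position)
  subset <- ifelse(mm == 0, ifelse(base5 == "T", "T5", "A5"), "none")
  tibble(
    sequence = seqs,
    mismatches = mm,
    tbs_class = factor(tbs_class, levels = c("TATA-box", "TATA-like", "other")),
    subset = factor(subset, levels = c("T5", "A5", "none"))
  )
}

# All fixed-length windows of a set of sequences, as one long tibble.
tbs_windows <- function(seqs, k) {
  n <- nchar(seqs)
  reps <- n - k + 1L
  tibble(
    gene = rep(seq_along(seqs), reps),
    offset = unlist(lapply(reps, seq_len)) - 1L,
    window = unname(substring(rep(seqs, reps),
                              unlist(lapply(reps, seq_len)),
                              unlist(lapply(reps, seq_len)) + k - 1L))
  )
}

#' Scan promoters for the best TBS window
#'
#' Slides the consensus over each promoter and reports the window with the
#' fewest mismatches (ties broken by the smallest offset). Forward strand
#' only by default; with `both_strands = TRUE` the reverse complement is
#' also scanned and the better strand reported (forward wins ties).
#'
#' @param sequences Named character vector of promoter sequences, or a
#'   `Biostrings::DNAStringSet` (e.g. from [read_promoters()]). Unnamed
#'   inputs are labelled `gene_1`, `gene_2`, ...
#' @inheritParams count_mismatches
#' @param both_strands Also scan the reverse complement (default FALSE).
#' @return A tibble with one row per promoter: `gene_id`, `offset`
#'   (0-based, on the reported strand), `strand`, `sequence` (the window),
#'   `mismatches`, `tbs_class`, `subset`.
#' @export
#' @examples
#' scan_promoter(c(geneA = "GGTATATAAAGG"))
scan_promoter <- function(sequences, pattern = "TATAWAWR",
                          both_strands = FALSE) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences) || !length(sequences)) {
    abort("`sequences` must be a non-empty character vector or DNAStringSet.")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("gene_", seq_along(sequences))
  }
  pat <- check_pattern(pattern)
  k <- length(pat)
  seqs <- toupper(sequences)
  if (any(nchar(seqs) < k)) {
    abort(sprintf("all promoter sequences must be at least %d bases long.", k))
  }
  if (any(!grepl("^[ACGT]+$", seqs))) {
    abort("sequences may only contain A, C, G, T.")
  }

  scan_strand <- function(s, strand) {
    w <- tbs_windows(s, k)
    w$mismatches <- mismatches_impl(w$window, pat)
    w$strand <- strand
    w
  }
  w <- scan_strand(seqs, "+")
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    w <- dplyr::bind_rows(w, scan_strand(rc, "-"))
  }
  # best window per gene: fewest mismatches, then forward strand, then
  # smallest offset
  o <- order(w$gene, w$mismatches, w$strand, w$offset)
  w <- w[o, ]
  best <- w[!duplicated(w$gene), ]
  cls <- classify_tbs(best$window, pattern = pattern)
  tibble(
    gene_id = unname(names(seqs)[best$gene]),
    offset = unname(best$offset),
    strand = unname(best$strand),
    sequence = unname(best$window),
    mismatches = cls$mismatches,
    tbs_class = cls$tbs_class,
    subset = cls$subset
  )
}

#' Read promoter sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_promoters <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path))
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write promoter sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
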