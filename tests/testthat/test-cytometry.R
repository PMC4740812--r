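make_events <- function(fsc, ssc = NULL, gfp = NULL, replicate = 1L) {
  n <- length(fsc)
  tibble::tibble(fsc_a = fsc,
                 ssc_a = if (is.null(ssc)) rep(1000, n) else ssc,
                 gfp = if (is.null(gfp)) rep(50, n) else gfp,
                 sample_id = "s", replicate_id = replicate)
}

test_that("ADC bounds are open and the 5% scatter tails are trimmed by rank", {
  adc <- 2^18 - 1
  ev <- make_events(c(0, 1, adc, adc - 1), ssc = c(10, 10, 10, 0.5))
  kept <- filter_events(ev, trim = 0)
  expect_equal(kept$fsc_a, c(1, adc - 1))

  # 20 in-range events with distinct scatter: one trimmed from each tail
  ev20 <- make_events(seq(1000, 20000, length.out = 20))
  kept20 <- filter_events(ev20)
  expect_equal(nrow(kept20), 18L)
  expect_false(min(ev20$fsc_a) %in% kept20$fsc_a)
  expect_false(max(ev20$fsc_a) %in% kept20$fsc_a)

  expect_error(filter_events(make_events(c(0, 0))), "no events remain")
})

test_that("the small-cell gate keeps events strictly below the scatter quantile", {
  ev <- make_events(c(1, 2, 3, 4), ssc = rep(1, 4))
  gated <- gate_small_cells(ev, cutoff = 0.5)
  expect_equal(gated$fsc_a, c(1, 2))

  expect_equal(nrow(gate_small_cells(ev, cutoff = 1)), 4L)

  const <- make_events(rep(2, 4), ssc = rep(3, 4))
  expect_warning(fallback <- gate_small_cells(const, cutoff = 0.5),
                 "strictly below")
  expect_equal(nrow(fallback), 4L)
})

test_that("size correction follows the printed squared rule and the ratio variant", {
  # the correction formulas themselves
  expect_equal(tbpnoise:::apply_correction(6, 4, "squared"), 9)
  expect_equal(tbpnoise:::apply_correction(6, 4, "ratio"), 1.5)

  # a perfectly linear GFP-scatter relationship: fitted == raw, so the
  # squared rule returns the raw values
  set.seed(91)
  ev <- make_events(runif(50, 1e3, 1e5), ssc = runif(50, 1e3, 1e5))
  ev$gfp <- 2 + 0.3 * ev$fsc_a + 0.1 * ev$ssc_a
  out <- size_correct(ev)
  expect_equal(out$gfp_corrected, ev$gfp, tolerance = 1e-8)
  expect_true(all(out$correction_ok))

  # collinear scatter channels: rank-deficient design
  coll <- make_events(runif(10, 1e3, 1e4))
  coll$ssc_a <- 2 * coll$fsc_a
  expect_error(size_correct(coll), "collinear")
  expect_error(size_correct(ev[1:2, ]), "at least 3")
})

test_that("ratio correction strips the size confound from synthetic events", {
  cfg <- small_config()
  ev <- gen_cytometry(cfg, seed = 101)
  ev <- gate_small_cells(filter_events(ev))
  out <- size_correct(ev, method = "ratio")
  expect_lt(abs(cor(out$gfp_corrected, out$fsc_a)),
            abs(cor(out$gfp, out$fsc_a)))
})

test_that("replicate CVs are averaged with a standard error", {
  # constant corrected signal: zero CV
  ev <- make_events(rep(10, 3))
  ev$gfp_corrected <- c(5, 5, 5); ev$correction_ok <- TRUE
  expect_equal(suppressWarnings(noise_from_events(ev))$samples$cv_mean, 0)

  # two replicates engineered to CVs 0.2 and 0.4
  mk <- function(cv, rep_id) {
    e <- make_events(rep(10, 2), replicate = rep_id)
    e$gfp_corrected <- c(1 - cv / sqrt(2), 1 + cv / sqrt(2))
    e$correction_ok <- TRUE
    e
  }
  res <- noise_from_events(dplyr::bind_rows(mk(0.2, 1L), mk(0.4, 2L)))
  expect_equal(res$replicates$cv, c(0.2, 0.4), tolerance = 1e-12)
  expect_equal(res$samples$cv_mean, 0.3, tolerance = 1e-12)
  expect_equal(res$samples$cv_se, sd(c(0.2, 0.4)) / sqrt(2),
               tolerance = 1e-12)

  # one replicate: its own CV, undefined standard error
  expect_warning(single <- noise_from_events(mk(0.2, 1L)), "single replicate")
  expect_equal(single$samples$cv_mean, 0.2, tolerance = 1e-12)
  expect_true(is.na(single$samples$cv_se))

  # the correction step is a hard prerequisite
  expect_error(noise_from_events(make_events(rep(10, 3))), "size_correct")
})

test_that("the pipeline recovers the generator CV and is deterministic", {
  cfg <- synth_config(cytometry = list(n_events = 5000))
  ev <- gen_cytometry(cfg, seed = 111)
  res <- cytometry_pipeline(ev, method = "ratio")
  expect_lt(abs(res$noise$samples$cv_mean - 0.3) / 0.3, 0.1)
  expect_equal(res$stage_counts$stage,
               c("input", "filtered", "gated", "usable"))
  expect_true(all(diff(res$stage_counts$n_events) <= 0))

  res2 <- cytometry_pipeline(gen_cytometry(cfg, seed = 111),
                             method = "ratio")
  expect_identical(res$noise$samples, res2$noise$samples)

  expect_s3_class(tidy(res$noise), "tbl_df")
  expect_identical(glance(res$noise), res$noise$samples)
})

test_that("event CSVs are read with normalised column names", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(`FSC-A` = c(1, 2), `SSC-A` = c(3, 4),
                                  GFP = c(5, 6), sample = "a",
                                  replicate = 1), tmp)
  ev <- read_events_csv(tmp)
  expect_true(all(c("fsc_a", "ssc_a", "gfp", "sample_id", "replicate_id")
                  %in% names(ev)))
  expect_error(read_events_csv(file.path(tempdir(), "nope_xyz.csv")),
               "nope_xyz")
})
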