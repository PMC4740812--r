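test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config(n_genes = 60)
  t1 <- gen_promoters(cfg, seed = 1)
  t2 <- gen_promoters(cfg, seed = 1)
  expect_identical(t1, t2)
  expect_false(identical(t1$sequence, gen_promoters(cfg, seed = 2)$sequence))
  expect_identical(gen_pbm(cfg, seed = 3), gen_pbm(cfg, seed = 3))
  expect_identical(gen_occupancy(cfg, t1, seed = 4),
                   gen_occupancy(cfg, t1, seed = 4))
  expect_identical(gen_cytometry(cfg, seed = 5), gen_cytometry(cfg, seed = 5))
})

test_that("empty configurations give empty outputs", {
  cfg0 <- synth_config(n_genes = 0)
  expect_equal(nrow(gen_promoters(cfg0)), 0L)
  expect_equal(nrow(gen_noise_table(cfg0, gen_promoters(cfg0))), 0L)
})

test_that("planted TBS classes and offsets are recovered exactly by scanning", {
  cfg <- small_config(n_genes = 300)
  truth <- gen_promoters(cfg, seed = 7)
  calls <- scan_promoter(stats::setNames(truth$sequence, truth$gene_id))
  expect_identical(as.character(calls$tbs_class),
                   as.character(truth$tbs_class))
  expect_identical(as.character(calls$subset), as.character(truth$subset))
  # the planted window is the unique best hit for motif-bearing classes
  planted <- truth$tbs_class != "other"
  expect_identical(calls$offset[planted], truth$offset[planted])
})

test_that("synthetic occupancies have class-ordered SAGA, flat TFIID and tracking Mot1p", {
  cfg <- synth_config(n_genes = 1200)
  truth <- gen_promoters(cfg, seed = 8)
  occ <- gen_occupancy(cfg, truth, seed = 9)
  d <- dplyr::inner_join(occ$occupancy,
                         dplyr::select(truth, gene_id, class), by = "gene_id")
  med <- d |>
    dplyr::group_by(class) |>
    dplyr::summarise(spt = median(Spt20p, na.rm = TRUE),
                     taf = median(Taf1p, na.rm = TRUE), .groups = "drop")
  spt <- setNames(med$spt, med$class)
  expect_gt(spt[["TATA-box-T5"]], spt[["TATA-box-A5"]])
  expect_gt(spt[["TATA-box-A5"]], spt[["TATA-like"]])
  # TFIID occupancy comparable across classes
  taf <- setNames(med$taf, med$class)
  expect_lt(max(abs(log2(taf / stats::median(d$Taf1p, na.rm = TRUE)))), 0.5)
  # Mot1p tracks the SAGA and TBP draws
  expect_gt(cor(log(d$Mot1p), log(d$Spt20p), use = "complete.obs"), 0.3)
  expect_gt(cor(log(d$Mot1p), log(d$TBP), use = "complete.obs"), 0.3)
})

test_that("the configured missing rate is respected", {
  cfg <- synth_config(n_genes = 800, occupancy = list(missing_rate = 0.1))
  truth <- gen_promoters(cfg, seed = 10)
  occ <- gen_occupancy(cfg, truth, seed = 11)$occupancy
  frac <- mean(is.na(occ$Taf1p))
  expect_gt(frac, 0.06)
  expect_lt(frac, 0.15)
})

test_that("single-replicate PBM probes are flagged downstream", {
  cfg <- small_config(pbm = list(replicates = 1))
  agg <- aggregate_probe_signal(gen_pbm(cfg, seed = 12))
  expect_true(all(agg$single_probe))
})

test_that("synthetic turnover stays in the measured range with the class ordering", {
  cfg <- synth_config(n_genes = 500)
  truth <- gen_promoters(cfg, seed = 13)
  tv <- gen_turnover(cfg, truth, seed = 14)
  expect_true(all(tv$turnover >= 0.008 & tv$turnover <= 0.051))
  mt <- tapply(tv$turnover, tv$tbs_class, mean)
  expect_gt(mt[["TATA-box"]], mt[["TATA-like"]])

  one <- gen_turnover(cfg, truth[1, ], seed = 15)
  expect_equal(nrow(one), 1L)
  expect_true(one$turnover >= 0.008 && one$turnover <= 0.051)
})

test_that("cytometry events respect the ADC bounds and the confound switch", {
  cfg <- small_config()
  ev <- gen_cytometry(cfg, seed = 16)
  expect_true(all(ev$fsc_a > 0 & ev$fsc_a <= 2^18 - 1))
  expect_true(all(ev$ssc_a > 0 & ev$ssc_a <= 2^18 - 1))
  expect_equal(length(unique(ev$replicate_id)), 2L)

  # no size confound: the raw CV already matches the target
  cfg0 <- synth_config(cytometry = list(n_events = 8000, confound = 0))
  ev0 <- gen_cytometry(cfg0, seed = 17)
  raw_cv <- sd(ev0$gfp) / mean(ev0$gfp)
  expect_lt(abs(raw_cv - 0.3) / 0.3, 0.1)
})

test_that("noise-table offsets order the recovered class DM as constructed", {
  cfg <- synth_config(n_genes = 1500)
  truth <- gen_promoters(cfg, seed = 18)
  nt <- gen_noise_table(cfg, truth, seed = 19)
  dm <- compute_dm(nt)
  cls_dm <- tapply(dm$dm, dm$class, median)
  expect_gt(cls_dm[["TATA-box-T5"]], cls_dm[["TATA-like"]])
  expect_gt(cls_dm[["TATA-like"]], cls_dm[["other"]])
})
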