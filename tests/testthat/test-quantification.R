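# Peak areas -> LH ratios -> absolute amounts -> complement profiles.

mk_records <- function(light, heavy, form = "canonical") {
  rbind(
    data.frame(label = "light", fragment = names(light), area = unname(light),
               form = form, stringsAsFactors = FALSE),
    data.frame(label = "heavy", fragment = names(heavy), area = unname(heavy),
               form = form, stringsAsFactors = FALSE))
}

test_that("LH ratio uses the intersection of observed fragments", {
  recs <- mk_records(c(y4 = 800, y5 = 200), c(y4 = 400, y5 = 100))
  expect_equal(lh_ratio(recs), 2)
  # a fragment seen only in light is ignored
  extra <- rbind(recs, data.frame(label = "light", fragment = "y6", area = 1e6,
                                  form = "canonical"))
  expect_equal(lh_ratio(extra), 2)
  expect_error(lh_ratio(mk_records(c(y4 = 1), c(y5 = 1))), "both light and heavy")
  expect_error(lh_ratio(mk_records(c(y4 = 1), c(y4 = 0))), "zero")
})

test_that("LH ratio is invariant to a common replicate scale factor", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      fr <- paste0("y", 3:7)
      light <- stats::setNames(runif(5, 10, 1000), fr)
      heavy <- stats::setNames(runif(5, 10, 1000), fr)
      base <- lh_ratio(mk_records(light, heavy))
      sc <- runif(1, 0.1, 50)
      expect_equal(lh_ratio(mk_records(light * sc, heavy * sc)), base,
                   tolerance = 1e-12)
    }
  })
})

test_that("oxidation correction sums areas per label before ratioing", {
  recs <- rbind(mk_records(c(y4 = 800), c(y4 = 400)),
                mk_records(c(y4 = 200), c(y4 = 100), form = "oxidized"))
  expect_equal(combine_oxidized(recs), 2)
  # no oxidized rows: identical to the plain ratio
  plain <- mk_records(c(y4 = 800, y5 = 200), c(y4 = 400, y5 = 100))
  expect_equal(combine_oxidized(plain), lh_ratio(plain))
  # oxidized only in light still enters the numerator
  lightox <- rbind(mk_records(c(y4 = 800), c(y4 = 500)),
                   data.frame(label = "light", fragment = "y4", area = 200,
                              form = "oxidized"))
  expect_equal(combine_oxidized(lightox), 2)
})

test_that("unit conversion handles fmol, ng and both normalizers", {
  expect_equal(to_absolute(1, "fmol", molar_mass = 21000), 0.021)
  expect_equal(to_absolute(5, "ng", normalizer = "ml_blood",
                           normalizer_value = 10), 0.5)
  expect_equal(to_absolute(0, "fmol", molar_mass = 21000), 0)
  expect_error(to_absolute(1, "ng", normalizer_value = 0), "positive")
  expect_error(to_absolute(1, "fmol"), "molar mass")
  # subtype molar masses come from the sequences, not a lookup table
  fam <- synthetic_h1_family()
  mm <- average_mass(fam$sequence[fam$id == "H1.0"])
  expect_gt(mm, 15000); expect_lt(mm, 30000)
})

test_that("complement percentages sum to 100 and respect LOQ exclusion", {
  q <- data.frame(subtype = c("A", "B"), amount = c(1, 1))
  prof <- complement_profile(q)
  expect_equal(unname(prof$percent), c(50, 50))
  q3 <- data.frame(subtype = c("A", "B", "C"), amount = c(2, 1, 1),
                   below_loq = c(FALSE, FALSE, TRUE))
  prof3 <- complement_profile(q3)
  expect_equal(sum(prof3$percent), 100)
  expect_equal(unname(prof3$percent), c(200 / 3, 100 / 3))
  expect_identical(prof3$excluded, "C")
  expect_equal(unname(complement_profile(
    data.frame(subtype = "A", amount = 3))$percent), 100)
  expect_error(complement_profile(
    data.frame(subtype = "A", amount = 1, below_loq = TRUE)), "below LOQ")
})

test_that("band percentages drop unbanded subtypes and renormalize", {
  prof <- list(percent = c(H1.0 = 10, H1.1 = 5, H1.2 = 25, H1.3 = 10,
                           H1.4 = 30, H1.5 = 20))
  bands <- expected_band_percentages(prof)
  expect_equal(bands, c(high = 60, intermediate = 30, low = 10))
  withx <- list(percent = c(H1.0 = 9.6, H1.2 = 28.8, H1.4 = 57.6, H1X = 4))
  bx <- expected_band_percentages(withx)
  expect_equal(sum(bx), 100)
  expect_equal(unname(bx["low"]), 10)    # 9.6 / 0.96
  nolow <- list(percent = c(H1.2 = 40, H1.4 = 60))
  expect_equal(unname(expected_band_percentages(nolow)["low"]), 0)
  expect_error(band_model(list(a = "H1.0", b = "H1.0")), "disjoint")
})

test_that("replicate CV is 100*sd/mean with sample sd", {
  expect_equal(replicate_cv(c(2, 2, 2)), 0)
  expect_equal(replicate_cv(c(1, 2, 3)), 50)
  expect_error(replicate_cv(3), "at least 2")
  expect_error(replicate_cv(c(-1, 1)), "mean is zero")
})

test_that("the full pipeline recovers ground truth exactly at zero noise", {
  cfg <- simulation_config(seed = 9, noise_cv = 0,
                           miscleavage_fraction = c(TAPAAPAAAPPAE = 0.25),
                           oxidation_fraction = 0.2)
  sim <- simulate_sample_report(cfg)
  ec <- simulate_external_curves(cfg, "miscleaved:TAPAAPAAAPPAE")
  q <- quantify_report(sim$report, cfg$assay, heavy_spike_ng = 1,
                       external_curves = ec)
  expect_equal(stats::setNames(q$amount, q$subtype),
               sim$truth$amounts_ng[q$subtype], tolerance = 1e-6)
  prof <- complement_profile(q)
  expect_equal(prof$percent, sim$truth$percent[names(prof$percent)],
               tolerance = 1e-6)
  expect_equal(sum(prof$percent), 100, tolerance = 1e-9)
})

test_that("missed-cleavage forms demand an external curve", {
  cfg <- simulation_config(seed = 9, noise_cv = 0,
                           miscleavage_fraction = c(TAPAAPAAAPPAE = 0.25))
  sim <- simulate_sample_report(cfg)
  expect_error(quantify_report(sim$report, cfg$assay, heavy_spike_ng = 1),
               "external curves")
})

test_that("replicate CV stays below 15% in most runs at 10% transition noise", {
  # three injection replicates, per-transition CV 10%; count how often the
  # recovered per-subtype CVs stay under the 15% reproducibility benchmark
  runs <- 40L
  ok <- 0L; total <- 0L
  for (s in seq_len(runs)) {
    cfg <- simulation_config(seed = 1000L + s, noise_cv = 0.10,
                             oxidation_fraction = 0)
    sim <- simulate_sample_report(cfg)
    q <- quantify_report(sim$report, cfg$assay, heavy_spike_ng = 1)
    cvs <- q$cv[!is.na(q$cv)]
    ok <- ok + sum(cvs < 15)
    total <- total + length(cvs)
  }
  expect_gte(ok / total, 0.90)
})
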