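test_that("simulate_karyotype applies events on top of a diploid baseline", {
  g <- tiny_genome()
  grid <- make_bins(g, 5e6)
  none <- simulate_karyotype(g, grid, seed = 1, events = list())
  expect_true(all(none$track$cn == 2))
  expect_equal(attr(none$track, "baseline_ploidy"), 2L)

  wgd <- simulate_karyotype(g, grid, seed = 1,
                            events = list(karyotype_event("WGD")))
  expect_true(all(wgd$track$cn == 4))
  expect_equal(attr(wgd$track, "baseline_ploidy"), 4L)

  gain <- simulate_karyotype(g, grid, seed = 1,
    events = list(karyotype_event("arm_gain", chrom = "1", arm = "q")))
  tr <- gain$track
  expect_true(all(tr$cn[tr$chrom == "1" & tr$arm == "q"] == 3))
  expect_true(all(tr$cn[!(tr$chrom == "1" & tr$arm == "q")] == 2))
})

test_that("chromothripsis rewrites one chromosome with the requested number
           of state changes", {
  g <- tiny_genome()
  grid <- make_bins(g, 2e6)
  ct <- simulate_karyotype(g, grid, seed = 5,
    events = list(karyotype_event("chromothripsis", chrom = "1",
                                  n_switches = 10, states = c(1, 3))))
  cn1 <- ct$track$cn[ct$track$chrom == "1"]
  expect_true(all(cn1 %in% c(1, 3)))
  expect_equal(sum(diff(cn1) != 0), 10)
  expect_true(all(ct$track$cn[ct$track$chrom == "2"] == 2))
  expect_error(karyotype_event("chromothripsis", chrom = "1",
                               n_switches = 1, states = c(1, 3)),
               "n_switches")
})

test_that("generators are reproducible for a fixed seed and conserve
           untargeted bins", {
  g <- tiny_genome()
  grid <- make_bins(g, 5e6)
  cfg <- sim_config()
  a <- simulate_karyotype(g, grid, cfg, seed = 11)
  b <- simulate_karyotype(g, grid, cfg, seed = 11)
  expect_identical(a$track$cn, b$track$cn)
  sa <- render_probe_signal(a$track, g, density = 5, noise_sd = 0.1,
                            seed = 3)
  sb <- render_probe_signal(b$track, g, density = 5, noise_sd = 0.1,
                            seed = 3)
  expect_identical(sa$logR, sb$logR)
})

test_that("render_probe_signal centers the median and maps CN to log2
           ratios", {
  g <- tiny_genome()
  grid <- make_bins(g, 5e6)
  flat <- simulate_karyotype(g, grid, seed = 1, events = list())$track
  s <- render_probe_signal(flat, g, density = 5, noise_sd = 0, seed = 2)
  expect_true(all(s$logR == 0))

  wgd <- simulate_karyotype(g, grid, seed = 1,
                            events = list(karyotype_event("WGD")))$track
  s4 <- render_probe_signal(wgd, g, density = 5, noise_sd = 0, seed = 2)
  expect_true(all(s4$logR == 0)) # pure WGD invisible after centering

  tri <- simulate_karyotype(g, grid, seed = 1,
    events = list(karyotype_event("whole_chrom_gain", chrom = "2")))$track
  s3 <- render_probe_signal(tri, g, density = 5, noise_sd = 0, seed = 2)
  expect_equal(unique(s3$logR[s3$chrom == "2"]), log2(3 / 2))
  expect_true(all(s3$logR[s3$chrom == "1"] == 0))
})

test_that("simulate_expression realizes the gene-dosage model", {
  g <- tiny_genome()
  grid <- make_bins(g, 5e6)
  tet2 <- simulate_karyotype(g, grid, seed = 1,
    events = list(karyotype_event("whole_chrom_gain", chrom = "2",
                                  copies = 2L)))$track # chr2 CN 4, chr1 CN 2
  gmap <- random_gene_map(g, genes_per_chrom = 500, seed = 9)
  # dosage_slope = 1, near-zero dispersion: CN4/CN2 mean ratio -> 2
  ex <- simulate_expression(tet2, gmap, dosage_slope = 1, dispersion = 0,
                            seed = 21)
  m1 <- mean(ex[gmap$chrom == "1", 1])
  m2 <- mean(ex[gmap$chrom == "2", 1])
  expect_equal(m2 / m1, 2, tolerance = 0.05)
  # dosage_slope = 0: expression independent of CN
  ex0 <- simulate_expression(tet2, gmap, dosage_slope = 0, dispersion = 0.05,
                             seed = 22)
  p <- t.test(ex0[gmap$chrom == "1", 1], ex0[gmap$chrom == "2", 1])$p.value
  expect_gt(p, 0.001)
  expect_error(simulate_expression(tet2, gmap[0, ]), "empty")
})

test_that("simulate_mutation_table realizes the requested class mix", {
  wt <- simulate_mutation_table(c(WT = 1), n_samples = 50, seed = 1)
  expect_true(all(wt$records$variant_class %in% "silent"))
  calls <- classify_tp53_table(wt$records, samples = names(wt$truth))
  expect_true(all(calls$call == "WT"))
  expect_error(simulate_mutation_table(c(WT = 0.5, missense = 0.4)),
               "sum to 1")
})

test_that("simulate_cohort_survival censors everything at extreme censor
           rates", {
  fga <- seq(0, 0.5, length.out = 20)
  rec <- simulate_cohort_survival(fga, hazard_ratio = 2,
                                  baseline_hazard = 1 / 1500,
                                  censor_rate = 1e6, seed = 4)
  expect_true(all(rec$event == 0))
  km <- km_curve(rec$time, rec$event)
  expect_true(all(km$surv == 1))
  expect_error(simulate_cohort_survival(numeric(0)), "empty")
})

test_that("growth curves invert exactly through doubling_time at zero
           noise", {
  gc <- simulate_growth_curve(24, duration = 48, n_timepoints = 3,
                              noise_cv = 0, n0 = 1000)
  expect_equal(gc$count[nrow(gc)] / gc$count[1], 4)
  expect_equal(doubling_time(gc)$Td, 24)
  # noisy recovery on average
  tds <- vapply(1:100, function(s)
    doubling_time(simulate_growth_curve(24, 120, 6, noise_cv = 0.05,
                                        seed = s))$Td, numeric(1))
  expect_equal(mean(tds), 24, tolerance = 0.02 * 24)
  expect_error(simulate_growth_curve(24, duration = -1), "duration")
})
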