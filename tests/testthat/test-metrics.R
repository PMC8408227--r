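test_that("relative profiles cancel ancestral alterations", {
  grid <- tiny_grid()
  a <- profile_on_grid(grid, rep(0.585, nrow(grid)))
  b <- profile_on_grid(grid, rep(0.585, nrow(grid)))
  rel <- relative_profile(a, b)
  expect_true(all(rel$logR == 0))
  zero <- profile_on_grid(grid, rep(0, nrow(grid)))
  expect_equal(relative_profile(a, zero)$logR, a$logR)
  other <- make_bins(tiny_genome(), 5e6)
  expect_error(relative_profile(a, profile_on_grid(other,
                                                   rep(0, nrow(other)))),
               "grid")
})

test_that("aneuploidy_score weights |logR| by Mb and is additive over
           splits", {
  grid <- tiny_grid() # 10 Mb bins
  z <- profile_on_grid(grid, rep(0, nrow(grid)))
  expect_equal(aneuploidy_score(z), 0)
  # one 50 Mb run at 0.5 -> 25.0 in per-Mb mode
  v <- rep(0, nrow(grid))
  v[1:5] <- 0.5
  p <- profile_on_grid(grid, v)
  expect_equal(aneuploidy_score(p, "per_Mb"), 25)
  expect_equal(aneuploidy_score(p, "per_bin"), 2.5)
  # splitting bins (finer grid, same signal) leaves the per-Mb score
  # unchanged
  fine <- make_bins(tiny_genome(), 5e6)
  vf <- rep(0, nrow(fine))
  vf[fine$chrom == "1" & fine$end <= 50e6] <- 0.5
  expect_equal(aneuploidy_score(profile_on_grid(fine, vf), "per_Mb"), 25)
  # translation bound: adding c to a non-negative profile adds exactly c*L
  L <- sum(grid$width) / 1e6
  p2 <- profile_on_grid(grid, abs(rnorm(nrow(grid), 0, 0.2)))
  shifted <- profile_on_grid(grid, p2$logR + 0.3)
  expect_equal(aneuploidy_score(shifted), aneuploidy_score(p2) + 0.3 * L)
})

test_that("fraction_genome_altered applies a strict threshold on segment
           length fractions", {
  seg <- segment_profile("A", c("1", "1"), c(0, 40e6), c(40e6, 100e6),
                         c(0.5, 0.0))
  expect_equal(fraction_genome_altered(seg), 0.40)
  flat <- segment_profile("B", "1", 0, 100e6, 0)
  expect_equal(fraction_genome_altered(flat), 0)
  at_thr <- segment_profile("C", c("1", "1"), c(0, 40e6), c(40e6, 100e6),
                            c(0.2, 0.5))
  expect_equal(fraction_genome_altered(at_thr), 0.6) # 0.2 is NOT altered
  # non-increasing in threshold
  set.seed(3)
  segr <- segment_profile("D", rep("1", 10), seq(0, 90e6, 10e6),
                          seq(10e6, 100e6, 10e6), rnorm(10, 0, 0.3))
  f <- vapply(c(0, 0.1, 0.2, 0.4), fraction_genome_altered, numeric(1),
              seg = segr)
  expect_true(all(diff(f) <= 0))
})

test_that("classify_by_quantile uses interpolated quartiles inclusive at
           the boundaries", {
  cls <- classify_by_quantile(1:8)
  expect_equal(as.character(cls),
               c("aneuploid_low", "aneuploid_low", "intermediate",
                 "intermediate", "intermediate", "intermediate",
                 "aneuploid_high", "aneuploid_high"))
  # invariant to monotone transforms
  expect_equal(as.character(classify_by_quantile(exp(1:8))),
               as.character(cls))
  expect_warning(all_eq <- classify_by_quantile(rep(2, 6)), "identical")
  expect_true(all(all_eq == "intermediate"))
  expect_error(classify_by_quantile(1:3), "4 samples")
  # group sizes bounded by ceiling(n/4)
  set.seed(5)
  for (n in c(8, 9, 17)) {
    v <- rnorm(n)
    cl <- classify_by_quantile(v)
    expect_lte(sum(cl == "aneuploid_low"), ceiling(n / 4))
    expect_lte(sum(cl == "aneuploid_high"), ceiling(n / 4))
  }
})

test_that("alteration_frequency counts threshold exceedances per bin", {
  grid <- tiny_grid()
  n <- nrow(grid)
  mk <- function(v) profile_on_grid(grid, v)
  v1 <- rep(0, n); v1[1] <- 0.5
  v2 <- rep(0, n); v2[1] <- 0.5; v2[2] <- -0.5
  grp <- list(mk(v1), mk(v2), mk(rep(0, n)), mk(rep(0, n)))
  ft <- alteration_frequency(grp)
  expect_equal(ft$gain_frac[1], 0.5)
  expect_equal(ft$loss_frac[2], 0.25)
  expect_true(all(ft$gain_frac[-1] == 0 | seq_len(n)[-1] == 2))
  expect_true(all(ft$gain_frac + ft$loss_frac <= 1))
  ft0 <- alteration_frequency(list(mk(rep(0, n))))
  expect_true(all(ft0$gain_frac == 0 & ft0$loss_frac == 0))
  expect_error(alteration_frequency(list()), "empty")
})

test_that("compare_arms returns null results for identical groups and the
           textbook BH adjustment", {
  grid <- tiny_grid()
  set.seed(2)
  grp <- lapply(1:3, function(i)
    profile_on_grid(grid, rnorm(nrow(grid), 0, 0.1)))
  res <- compare_arms(grp, grp)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$flagged))
  # BH on (0.01, 0.02, 0.03, 0.04) with m = 4 -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_true(all(res$p_adj >= res$p))
  expect_error(compare_arms(grp[1], grp), "2 samples")
})

test_that("compare_arms flags a genuinely shifted arm and controls the
           null", {
  grid <- tiny_grid()
  n <- nrow(grid)
  shift_idx <- which(grid$chrom == "1" & grid$arm == "q")
  hits <- 0
  false_frac <- numeric(40)
  for (s in 1:40) {
    set.seed(s)
    gA <- lapply(1:5, function(i) profile_on_grid(grid, rnorm(n, 0, 0.05)))
    gB <- lapply(1:5, function(i) {
      v <- rnorm(n, 0, 0.05)
      v[shift_idx] <- v[shift_idx] + 0.585
      profile_on_grid(grid, v)
    })
    res <- compare_arms(gA, gB)
    is_shifted <- res$chrom == "1" & res$arm == "q"
    if (res$flagged[is_shifted]) hits <- hits + 1
    false_frac[s] <- mean(res$flagged[!is_shifted])
  }
  expect_gte(hits, 38)              # the shifted arm is essentially always found
  expect_lte(mean(false_frac), 0.1) # unshifted arms flagged within FDR budget
})

test_that("chromosome_mean_copy converts weighted mean logR to copy
           number", {
  grid <- tiny_grid()
  expect_equal(chromosome_mean_copy(
    profile_on_grid(grid, rep(0, nrow(grid))), "1"), 2)
  expect_equal(chromosome_mean_copy(
    profile_on_grid(grid, rep(1, nrow(grid))), "1"), 4)
  half <- ifelse(grid$chrom == "1" & grid$start < 50e6, 1, 0)
  expect_equal(chromosome_mean_copy(profile_on_grid(grid, half), "1"),
               2 * 2^0.5)
  expect_error(chromosome_mean_copy(profile_on_grid(grid, half), "99"),
               "unknown")
})
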