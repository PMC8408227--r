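rec <- function(...) {
  cls <- c(..., character(0))
  data.frame(sample = rep("S1", length(cls)),
             gene = rep("TP53", length(cls)), variant_class = cls,
             stringsAsFactors = FALSE)
}

test_that("single-record calls follow the genotype definitions", {
  expect_equal(classify_tp53(rec("missense"))$call, "missense")
  expect_equal(classify_tp53(rec("nonsense"))$call, "truncating")
  expect_equal(classify_tp53(rec("frameshift"))$call, "truncating")
  expect_equal(classify_tp53(rec("splice_site"))$call, "truncating")
  expect_equal(classify_tp53(rec("stop_gain"))$call, "truncating")
  expect_equal(classify_tp53(rec("silent"))$call, "WT")
  expect_equal(classify_tp53(rec())$call, "WT")
  expect_equal(classify_tp53(rec("noncoding"))$call, "WT")
  expect_error(classify_tp53(rec("gibberish")), "unknown variant")
})

test_that("exclusion rules: multiple alterations and in-frame indels", {
  x <- classify_tp53(rec("missense", "frameshift"))
  expect_equal(x$call, "excluded")
  expect_equal(x$reason, "multiple alterations")
  y <- classify_tp53(rec("in_frame_indel"))
  expect_equal(y$call, "excluded")
  expect_equal(y$reason, "in-frame")
  # two truncating records are still multiple alterations
  expect_equal(classify_tp53(rec("nonsense", "nonsense"))$reason,
               "multiple alterations")
  # silent records are ignored before counting alterations
  expect_equal(classify_tp53(rec("missense", "silent"))$call, "missense")
  # not assayed dominates in tumor mode
  expect_equal(classify_tp53(rec(), assayed = FALSE)$call, "not_assayed")
  expect_equal(classify_tp53(rec(), mode = "cell_line",
                             assayed = FALSE)$call, "WT")
})

test_that("MAF dialect synonyms map to the canonical vocabulary", {
  maf <- data.frame(sample = "S1", gene = "TP53",
                    variant_class = c("Missense_Mutation",
                                      "Frame_Shift_Del", "Silent"))
  expect_equal(classify_tp53(maf)$call, "excluded")
  expect_equal(classify_tp53(maf[c(1, 3), ])$call, "missense")
  # records for other genes are ignored
  other <- data.frame(sample = "S1", gene = c("KRAS", "TP53"),
                      variant_class = c("missense", "silent"))
  expect_equal(classify_tp53(other)$call, "WT")
})

test_that("classification is deterministic and order-independent", {
  r <- rec("missense", "silent", "frameshift")
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    expect_equal(classify_tp53(r[perm, ])$call, "excluded")
  }
})

test_that("classifier recovers the generating mix and every excluded call
           carries a rule", {
  sim <- simulate_mutation_table(
    c(WT = 0.4, missense = 0.3, truncating = 0.2, multi = 0.06,
      inframe = 0.04), n_samples = 4000, seed = 77)
  calls <- classify_tp53_table(sim$records, samples = names(sim$truth))
  expected <- c(WT = "WT", missense = "missense",
                truncating = "truncating", multi = "excluded",
                inframe = "excluded")
  expect_equal(calls$call, unname(expected[sim$truth[calls$sample]]))
  expect_true(all(calls$reason[calls$call == "excluded"] %in%
                  c("multiple alterations", "in-frame")))
})

test_that("cohort filters drop the documented cases with a reported rule", {
  mk_cohort <- function(cohort, n_mis, n_tot) {
    data.frame(sample = sprintf("%s_%03d", cohort, seq_len(n_tot)),
               call = c(rep("missense", n_mis),
                        rep("WT", n_tot - n_mis)),
               cohort = cohort, stringsAsFactors = FALSE)
  }
  calls <- rbind(mk_cohort("A", 19, 300),   # count rule: 19 < 20
                 mk_cohort("B", 25, 300),   # frequency rule: 8.3% < 10%
                 mk_cohort("C", 40, 300))   # kept: 13.3%, 40 >= 20
  res <- apply_cohort_filters(calls)
  expect_equal(unique(res$kept$cohort), "C")
  expect_true(any(grepl("fewer than 20",
                        res$report$rule[grepl("^A", res$report$sample)])))
  expect_true(any(grepl("10% missense",
                        res$report$rule[grepl("^B", res$report$sample)])))
  # multi-tumor individuals: both records removed
  multi <- mk_cohort("D", 40, 300)
  multi$individual <- multi$sample
  multi$individual[2] <- multi$individual[1]
  res2 <- apply_cohort_filters(multi)
  expect_false(any(res2$kept$individual == multi$individual[1]))
  expect_equal(sum(res2$report$rule == "multiple tumors per individual"), 2)
  expect_error(apply_cohort_filters(data.frame(call = "WT")), "cohort")
})

test_that("genotype summaries conserve counts", {
  calls <- data.frame(call = c(rep("WT", 10), rep("missense", 5),
                               "excluded", "not_assayed"))
  tab <- summarize_genotypes(calls)
  expect_equal(unname(tab["WT"]), 10)
  expect_equal(unname(tab["missense"]), 5)
  expect_equal(sum(tab), nrow(calls))
  empty <- summarize_genotypes(data.frame(call = character(0)))
  expect_true(all(empty == 0))
})
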