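make_ct <- function(delta_cts, groups, nuclear = "18S", mt = "ND1",
                    base = 14) {
  # one replicate per target; delta_cts named by sample
  do.call(rbind, lapply(names(delta_cts), function(s) {
    data.frame(sample_id = s, target = c(mt, nuclear), replicate = 1L,
               ct = c(base + delta_cts[[s]], base), group = groups[[s]],
               stringsAsFactors = FALSE)
  }))
}

test_that("ddCt ratios follow the closed form 2^-ddCt", {
  groups <- c(n1 = "Natural", n2 = "Natural", i1 = "IVF", i2 = "IVF")
  # reference-group mean dCt = -5; i1 at ddCt +1, i2 at ddCt -2
  ct <- make_ct(c(n1 = -5.5, n2 = -4.5, i1 = -4, i2 = -7), groups)
  res <- ddct_ratio(ct, reference_group = "Natural")
  r <- setNames(res$ratios$ratio, res$ratios$sample_id)
  expect_equal(unname(r["i1"]), 0.5)
  expect_equal(unname(r["i2"]), 4.0)
  # a sample sitting exactly at the reference mean dCt has ratio 1
  ct2 <- make_ct(c(n1 = -5, n2 = -5, i1 = -5), groups[1:3])
  res2 <- ddct_ratio(ct2, reference_group = "Natural")
  expect_equal(res2$ratios$ratio, c(1, 1, 1))
  # the reference group's geometric mean ratio is 1 by construction
  ref_r <- r[c("n1", "n2")]
  expect_equal(exp(mean(log(ref_r))), 1)
})

test_that("ddCt is invariant to a constant machine offset on all Cts", {
  set.seed(61)
  groups <- setNames(rep(c("Natural", "IVF"), each = 4),
                     sprintf("s%d", 1:8))
  ct <- make_ct(setNames(rnorm(8, -5, 0.4), names(groups)), groups)
  shifted <- ct
  shifted$ct <- shifted$ct + 3.7
  r1 <- ddct_ratio(ct, reference_group = "Natural")$ratios
  r2 <- ddct_ratio(shifted, reference_group = "Natural")$ratios
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
})

test_that("ddCt replicates are averaged and errors are informative", {
  groups <- c(a = "Natural", b = "Natural", c = "IVF", d = "IVF")
  ct <- simulate_ct(c(Natural = 3, IVF = 3), effect_log2 = 1,
                    noise_sd = 0.3, seed = 62)
  res <- ddct_ratio(ct, reference_group = "Natural")
  truth <- oracle_ddct(ct, "18S", "Natural")
  got <- res$ratios[res$ratios$target == "ND1", ]
  expect_equal(got$ratio, unname(truth$ND1[got$sample_id]),
               tolerance = 1e-12)
  # missing nuclear Ct is a hard error naming the sample
  broken <- ct[!(ct$sample_id == "IVF_s01" & ct$target == "18S"), ]
  expect_error(ddct_ratio(broken), "IVF_s01")
  expect_error(ddct_ratio(ct, reference_group = "Mock"), "Mock")
})

test_that("two mitochondrial targets are normalized separately plus a mean", {
  groups <- c(n1 = "Natural", n2 = "Natural", i1 = "IVF")
  ct1 <- make_ct(c(n1 = -5, n2 = -5, i1 = -6), groups, mt = "ND1")
  ct2 <- make_ct(c(n1 = -3, n2 = -3, i1 = -3), groups, mt = "Cox3")
  res <- ddct_ratio(rbind(ct1, ct2), reference_group = "Natural")
  expect_setequal(unique(res$ratios$target), c("ND1", "Cox3", "mean_mt"))
  i1 <- res$ratios[res$ratios$sample_id == "i1", ]
  expect_equal(i1$ratio[i1$target == "ND1"], 2)
  expect_equal(i1$ratio[i1$target == "Cox3"], 1)
  expect_equal(i1$ratio[i1$target == "mean_mt"], 1.5)
})

test_that("per-CpG percent methylation follows the closed form", {
  mc <- data.frame(amplicon = "Esr1", cpg_index = 1:2,
                   methylated = c(3, 5), unmethylated = c(1, 15),
                   sample_id = "s1", group = "Natural")
  res <- methylation_summary(mc, min_coverage = 4)
  expect_equal(res$per_cpg$percent, c(75, 25))
  # amplicon percent is the coverage-weighted mean: (75*4 + 25*20) / 24
  expect_equal(res$per_amplicon$percent, (75 * 4 + 25 * 20) / 24)
})

test_that("low-coverage CpGs are flagged and excluded, never zeroed", {
  mc <- data.frame(amplicon = rep(c("LINE1", "IAP"), each = 2),
                   cpg_index = c(1, 2, 1, 2),
                   methylated = c(8, 1, 2, 1),
                   unmethylated = c(2, 1, 3, 0),
                   sample_id = "s1", group = "Natural")
  res <- methylation_summary(mc, min_coverage = 10)
  cpg <- res$per_cpg
  expect_equal(cpg$flagged, c(FALSE, TRUE, TRUE, TRUE))
  amp <- res$per_amplicon
  line1 <- amp[amp$amplicon == "LINE1", ]
  expect_equal(line1$percent, 80)  # only the covered CpG contributes
  iap <- amp[amp$amplicon == "IAP", ]
  expect_true(iap$missing)
  expect_true(is.na(iap$percent))
})

test_that("percent methylation is invariant to doubling all read counts", {
  set.seed(63)
  mc <- simulate_bisulfite(c(Esr1 = 8, LINE1 = 12),
                           list(Natural = c(Esr1 = 30, LINE1 = 70),
                                IVF = c(Esr1 = 55, LINE1 = 70)),
                           coverage_mean = 60, samples_per_group = 3,
                           seed = 64)
  doubled <- mc
  doubled$methylated <- 2 * doubled$methylated
  doubled$unmethylated <- 2 * doubled$unmethylated
  r1 <- methylation_summary(mc)
  r2 <- methylation_summary(doubled)
  expect_equal(r1$per_amplicon$percent, r2$per_amplicon$percent,
               tolerance = 1e-12)
  expect_equal(r1$group_means$mean_percent, r2$group_means$mean_percent,
               tolerance = 1e-12)
})

test_that("amplicon summaries stay within their CpG range and match brute force", {
  set.seed(65)
  mc <- simulate_bisulfite(c(A = 10), list(G1 = c(A = 40)),
                           coverage_mean = 50, samples_per_group = 4,
                           seed = 66)
  res <- methylation_summary(mc, min_coverage = 10)
  for (s in unique(mc$sample_id)) {
    d <- mc[mc$sample_id == s, ]
    cov <- d$methylated + d$unmethylated
    ok <- cov >= 10
    pct <- 100 * d$methylated / cov
    expected <- sum(pct[ok] * cov[ok]) / sum(cov[ok])
    got <- res$per_amplicon$percent[res$per_amplicon$sample_id == s]
    expect_equal(got, expected, tolerance = 1e-12)
    expect_gte(got, min(pct[ok]))
    expect_lte(got, max(pct[ok]))
  }
})
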