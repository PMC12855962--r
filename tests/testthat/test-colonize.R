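test_that("colonization bounds follow the diploid summed-VAF convention", {
  samples <- data.frame(sample = "s1", timepoint = 16, area_mm2 = 1,
                        stringsAsFactors = FALSE)
  calls <- make_call(class = "missense")
  calls$vaf <- 0.25
  est <- colonized_fraction(calls, samples, gene = "gene01")
  expect_equal(est$sigma_vaf, 0.25)
  expect_equal(est$point, 50)
  expect_equal(est$lower, 25)
  expect_equal(est$upper, 50)
  # the doubled estimate is capped at 100%
  calls$vaf <- 0.6
  est2 <- colonized_fraction(calls, samples, gene = "gene01")
  expect_equal(est2$upper, 100)
  expect_equal(est2$lower, 60)
  # zero summed VAF gives zero everywhere
  est3 <- colonized_fraction(calls[0, ], samples, gene = "gene01")
  expect_equal(c(est3$point, est3$lower, est3$upper), c(0, 0, 0))
  # synonymous input is rejected
  syn <- make_call(class = "synonymous")
  expect_error(colonized_fraction(syn, samples), "protein-altering")
})

test_that("area weighting and the bound ordering hold on random inputs", {
  set.seed(14)
  samples <- data.frame(sample = paste0("s", 1:6), timepoint = 16,
                        area_mm2 = runif(6, 1, 2), stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(1:40, function(i)
    make_call(sample = sample(samples$sample, 1), pos = i,
              class = "missense")))
  calls$vaf <- runif(40, 0, 0.2)
  est <- colonized_fraction(calls, samples, gene = "gene01")
  # independently computed area-weighted mean
  sv <- vapply(samples$sample, function(s)
    sum(calls$vaf[calls$sample == s]), numeric(1))
  expect_equal(est$sigma_vaf,
               sum(samples$area_mm2 * sv) / sum(samples$area_mm2))
  expect_true(est$lower <= est$point && est$point <= est$upper)
})

test_that("Trp53 stratification is a strict comparison against the epidermis", {
  te <- data.frame(tumor = c("t1", "t2", "t3", "t4"),
                   animal = c("m1", "m1", "m2", "m9"),
                   sigma_vaf = c(0.10, 0.50, 0.30, 0.2),
                   stringsAsFactors = FALSE)
  ee <- data.frame(animal = c("m1", "m2"), sigma_vaf = c(0.30, 0.30),
                   stringsAsFactors = FALSE)
  expect_warning(out <- trp53_stratify(te, ee), "without matched")
  expect_equal(out$label, c("low", "high", "high"))  # 0.3 vs 0.3 ties high
  # invariant to row order
  expect_warning(out2 <- trp53_stratify(te[c(3, 1, 4, 2), ], ee[2:1, ]))
  expect_equal(out2$label[order(out2$tumor)], out$label[order(out$tumor)])
})

test_that("gene-group comparison flags only real differences", {
  set.seed(15)
  tumors <- paste0("t", 1:20)
  groups <- setNames(rep(c("high", "low"), each = 10), tumors)
  gv <- expand.grid(tumor = tumors, gene = paste0("g", 1:6),
                    stringsAsFactors = FALSE)
  gv$sigma_vaf <- rnorm(nrow(gv), 0.2, 0.05)
  # one gene with a large true difference
  sel <- gv$gene == "g1" & gv$tumor %in% tumors[1:10]
  gv$sigma_vaf[sel] <- rnorm(sum(sel), 0.6, 0.01)
  out <- compare_gene_groups(gv, groups)
  expect_true(out$outlier[out$gene == "g1"])
  expect_lte(sum(out$outlier), 2)
  # identical groups give |Z| = 0 and p = 1
  gv2 <- gv
  gv2$sigma_vaf <- 0.3
  out2 <- compare_gene_groups(gv2, groups)
  expect_true(all(out2$z == 0))
  expect_true(all(out2$p == 1))
  # permuted labels produce few outliers on average
  fp <- replicate(40, {
    pg <- setNames(sample(groups), tumors)
    mean(compare_gene_groups(gv[gv$gene != "g1", ], pg)$outlier)
  })
  expect_lte(mean(fp), 0.05)
})

test_that("cohort tests delegate to the named routines", {
  expect_equal(cohort_test(c(1, 2, 3, 1, 2, 3),
                           rep(c("a", "b"), each = 3), "wilcoxon")$p, 1)
  x <- 1:20
  lr <- suppressWarnings(cohort_test(3 * x + 2, x, "linregress"))
  expect_equal(lr$effect, 1.0)
  # degenerate constant predictor
  expect_error(cohort_test(rnorm(5), rep(1, 5), "linregress"), "constant")
  # Kruskal-Wallis p-values are uniform under the null
  set.seed(16)
  ps <- replicate(1000, {
    cohort_test(rnorm(30), rep(1:3, each = 10), "kruskal")$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  # nested ANOVA detects a group effect over animal structure
  animal <- rep(paste0("m", 1:6), each = 5)
  grp <- rep(c("A", "B"), each = 15)
  y <- rnorm(30, ifelse(grp == "A", 0, 3), 0.5) + rnorm(6, 0, 0.2)[rep(1:6, each = 5)]
  an <- cohort_test(y, grp, "anova_nested", animal = animal)
  expect_lt(an$p, 0.01)
  expect_error(cohort_test(y, grp, "anova_nested"), "animal")
  # F test of variances runs on two groups
  fv <- cohort_test(c(rnorm(20, 0, 1), rnorm(20, 0, 1)),
                    rep(c("a", "b"), each = 20), "f_var")
  expect_true(is.finite(fv$statistic) && fv$p > 0)
})
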