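gs_sel <- generate_gene_models(6, 60, seed = 17)
en_sel <- enumerate_substitutions(gs_sel)

test_that("spectrum fitting reflects the synonymous channel counts", {
  # all synonymous calls in one channel: that channel dominates
  syn <- en_sel[en_sel$class == "synonymous", ]
  one <- syn[syn$channel == syn$channel[1], ][rep(1, 30), ]
  one$sample <- "s"; one$vaf <- 0.1
  sp <- fit_spectrum(one, gs_sel, enum = en_sel)
  expect_equal(names(which.max(sp$rates)), syn$channel[1])
  expect_gt(sp$rates[syn$channel[1]] / median(sp$rates), 10)
  # uniform counts over uniform opportunities give uniform rates
  opp <- table(factor(en_sel$channel[en_sel$class == "synonymous"],
                      levels = sbs96_channels()))
  covered <- names(opp)[opp > 0]
  unif <- do.call(rbind, lapply(covered, function(ch) {
    r <- syn[syn$channel == ch, ][1, ]
    r[rep(1, as.integer(opp[ch])), ]
  }))
  unif$sample <- "s"; unif$vaf <- 0.1
  sp2 <- fit_spectrum(unif, gs_sel, enum = en_sel)
  expect_equal(unname(sp2$rates[covered]), rep(1, length(covered)))
  expect_error(fit_spectrum(one[0, ], gs_sel, enum = en_sel), "synonymous")
})

test_that("expected counts equal exhaustive enumeration on small genes", {
  sp <- fit_spectrum(
    transform(en_sel[en_sel$class == "synonymous", ][1:40, ],
              sample = "s", vaf = 0.1),
    gs_sel, enum = en_sel)
  E <- expected_counts(gs_sel, sp, enum = en_sel)
  oracle <- oracle_expected_counts(gs_sel, sp)
  for (g in gs_sel$genes$gene) {
    expect_equal(E$E_syn[E$gene == g], unname(oracle[[g]]["synonymous"]),
                 tolerance = 1e-9)
    expect_equal(E$E_mis[E$gene == g], unname(oracle[[g]]["missense"]),
                 tolerance = 1e-9)
    expect_equal(E$E_non_splice[E$gene == g],
                 unname(oracle[[g]]["non_splice"]), tolerance = 1e-9)
  }
})

test_that("a hand-enumerated two-codon gene matches exactly", {
  # CDS ATG AAA TAA; the terminal stop is not part of the opportunity.
  # All 18 substitutions: 1 synonymous (AAA>AAG), 1 nonsense (AAA>TAA),
  # 16 missense.
  gs <- make_gene_set(c(toy = "ATGAAATAA"))
  E <- expected_counts(gs, uniform_spectrum(rate = 1))
  expect_equal(E$E_syn, 1)
  expect_equal(E$E_non_splice, 1)
  expect_equal(E$E_mis, 16)
  # scale invariance: doubling all rates doubles E but not the ratios
  E2 <- expected_counts(gs, uniform_spectrum(rate = 2))
  expect_equal(E2$E_mis / E2$E_syn, E$E_mis / E$E_syn)
  expect_equal(E2$E_syn, 2 * E$E_syn)
  # internal stop codon is rejected
  bad <- make_gene_set(c(bad = "ATGTAAAAATAA"))
  expect_error(expected_counts(bad, uniform_spectrum()), "internal stop")
})

test_that("dN/dS is 1 under the neutrality identity and labels follow the thresholds", {
  gs <- make_gene_set(c(toy = "ATGAAATAA"))
  # craft observed counts proportional to expectations: ratio must be 1
  counts <- data.frame(gene = "toy", n_syn = 4, n_mis = 64, n_non_splice = 4,
                       n_indel = 0, stringsAsFactors = FALSE)
  fit <- dnds(counts, gs, spectrum = uniform_spectrum(rate = 1))
  g <- fit$genes
  expect_equal(g$dnds[g$class == "missense"], 1.0)
  expect_equal(g$dnds[g$class == "non_splice"], 1.0)
  expect_equal(g$p[g$class == "non_splice"], 1.0)
  expect_equal(fit$labels$label, "neutral")
  # a large ratio with a non-significant q stays neutral
  counts2 <- data.frame(gene = "toy", n_syn = 4, n_mis = 64, n_non_splice = 8,
                        n_indel = 0, stringsAsFactors = FALSE)
  fit2 <- dnds(counts2, gs, spectrum = uniform_spectrum(rate = 1))
  g2 <- fit2$genes[fit2$genes$class == "non_splice", ]
  expect_equal(g2$dnds, 2.0)
  expect_gt(g2$q, 0.01)
  expect_equal(fit2$labels$label, "neutral")
  # genes without synonymous calls fall back to the global rate, flagged
  counts3 <- rbind(counts,
                   data.frame(gene = "toy2", n_syn = 0, n_mis = 10,
                              n_non_splice = 1, n_indel = 0))
  gs2 <- make_gene_set(c(toy = "ATGAAATAA", toy2 = "ATGAAATAA"))
  fit3 <- dnds(counts3, gs2, spectrum = uniform_spectrum(rate = 1))
  flagged <- fit3$genes[fit3$genes$gene == "toy2" &
                          !fit3$genes$no_opportunity, ]
  expect_true(all(flagged$syn_zero))
  expect_true(all(is.finite(flagged$dnds)))
  # the indel class with zero opportunity is flagged, not divided by
  expect_true(all(fit3$genes$no_opportunity[fit3$genes$class == "indel"]))
})

test_that("per-gene dN/dS is unbiased under neutral simulation", {
  gs <- generate_gene_models(200, 100, seed = 9)
  en <- enumerate_substitutions(gs)
  w <- clonesel:::uv_row_weights(en, 0.85, list())
  set.seed(12)
  mut <- en[sample.int(nrow(en), 20000, replace = TRUE, prob = w), ]
  mut$sample <- "pool"; mut$vaf <- 0.05
  fit <- dnds(mut, gs, enum = en)
  g <- fit$genes[fit$genes$class == "non_splice", ]
  expect_lt(abs(mean(g$dnds, na.rm = TRUE) - 1), 0.1)
  # type-I error at q < 0.01 stays at or below 1% of genes
  expect_lte(mean(g$q < 0.01, na.rm = TRUE), 0.01)
})

test_that("the VAF ratio statistic behaves as defined", {
  mk <- function(gene, class, vafs) {
    data.frame(gene = gene, class = class, vaf = vafs,
               stringsAsFactors = FALSE)
  }
  # identical multisets: ratio 1, p 1
  same <- rbind(mk("g", "missense", c(0.1, 0.2, 0.3)),
                mk("g", "synonymous", c(0.1, 0.2, 0.3)))
  r <- vaf_ratio(same)
  expect_equal(r$ratio, 1.0)
  expect_equal(r$p, 1.0)
  # simple arithmetic
  two <- rbind(mk("g", "missense", c(0.2, 0.2)),
               mk("g", "synonymous", c(0.1, 0.1)))
  expect_equal(vaf_ratio(two)$ratio, 2.0)
  # exact Wilcoxon on fully separated triples: 2 of 20 orderings
  sep <- rbind(mk("g", "missense", c(0.3, 0.25, 0.28)),
               mk("g", "synonymous", c(0.05, 0.06, 0.04)))
  r3 <- vaf_ratio(sep)
  expect_equal(r3$p, 0.1)
  expect_equal(r3$p, perm_wilcox_p(c(0.3, 0.25, 0.28), c(0.05, 0.06, 0.04)))
  # a missing class flags the ratio as undefined
  nosyn <- mk("g", "missense", c(0.2, 0.3))
  r4 <- vaf_ratio(nosyn)
  expect_false(r4$defined)
  expect_true(is.na(r4$ratio))
})

test_that("the exact Wilcoxon agrees with full permutation enumeration", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(3:8, 1); m <- sample(3:8, 1)
    x <- round(runif(n), 3); y <- round(runif(m), 3)
    if (any(duplicated(c(x, y)))) next
    calls <- rbind(data.frame(gene = "g", class = "missense", vaf = x),
                   data.frame(gene = "g", class = "synonymous", vaf = y))
    expect_equal(vaf_ratio(calls)$p, perm_wilcox_p(x, y), tolerance = 1e-12)
  }
})
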