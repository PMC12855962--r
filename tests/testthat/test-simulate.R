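gs_sim <- generate_gene_models(10, 120, seed = 11)
en_sim <- enumerate_substitutions(gs_sim)

test_that("zero mutation rates produce an empty truth set", {
  p <- sim_params(seed = 1, n_grids = 5, sbs_rate = 0, dbs_rate = 0,
                  indel_rate = 0)
  sim <- simulate_epidermis(p, genes = gs_sim, enum = en_sim)
  expect_equal(nrow(sim$truth$clones), 0)
  expect_equal(nrow(sim$counts), 0)
})

test_that("total mutation count follows the Poisson expectation", {
  p <- sim_params(seed = 21, n_grids = 40, sbs_rate = 30,
                  panel_footprint = 3e5, dbs_rate = 0, indel_rate = 0)
  sim <- simulate_epidermis(p, genes = gs_sim, enum = en_sim)
  n <- nrow(sim$truth$clones)
  expect_gt(n, 360 - 3 * sqrt(360))
  expect_lt(n, 360 + 3 * sqrt(360))
})

test_that("configured spectrum fractions are recovered", {
  p <- sim_params(seed = 31, n_grids = 60, sbs_rate = 60,
                  panel_footprint = 3e5, frac_CtoT = 0.85,
                  dbs_rate = 10, frac_CCtoTT_of_DBS = 0.35, indel_rate = 0)
  sim <- simulate_epidermis(p, genes = gs_sim, enum = en_sim)
  tc <- sim$truth$clones
  sbs <- tc[tc$class %in% c("synonymous", "missense", "nonsense",
                            "essential_splice"), ]
  is_ct <- (sbs$ref == "C" & sbs$alt == "T") | (sbs$ref == "G" & sbs$alt == "A")
  ci <- binom.test(sum(is_ct), nrow(sbs), 0.85)$conf.int
  # exact binomial CI at default level must cover the configured value
  expect_true(ci[1] <= 0.85 && 0.85 <= ci[2])
  dbs <- tc[tc$class == "DBS", ]
  cc <- sum(dbs$ref == "CC" & dbs$alt == "TT")
  ci2 <- binom.test(cc, nrow(dbs), 0.35)$conf.int
  expect_true(ci2[1] <= 0.35 && 0.35 <= ci2[2])
})

test_that("read counts conserve depth and truth records the VAF convention", {
  p <- sim_params(seed = 41, n_grids = 10, sbs_rate = 60,
                  panel_footprint = 3e5)
  sim <- simulate_epidermis(p, genes = gs_sim, enum = en_sim)
  expect_true(all(sim$counts$alt_fwd + sim$counts$alt_rev <= sim$counts$depth))
  expect_true(all(sim$counts$alt_fwd >= 0 & sim$counts$alt_rev >= 0))
  tc <- sim$truth$clones
  expect_equal(tc$vaf_true, pmin(tc$zygosity * tc$cell_fraction / 2, 1))
  expect_true(all(tc$cell_fraction >= 0 & tc$cell_fraction <= 1))
  # homozygous flag doubles the VAF
  p2 <- sim_params(seed = 41, n_grids = 10, sbs_rate = 60,
                   panel_footprint = 3e5, zygosity = 2)
  sim2 <- simulate_epidermis(p2, genes = gs_sim, enum = en_sim)
  expect_equal(sim2$truth$clones$vaf_true,
               pmin(sim2$truth$clones$cell_fraction, 1))
})

test_that("identical parameters and seed give identical outputs", {
  p <- sim_params(seed = 51, n_grids = 8, sbs_rate = 40, panel_footprint = 2e5)
  a <- simulate_epidermis(p, genes = gs_sim, enum = en_sim)
  b <- simulate_epidermis(p, genes = gs_sim, enum = en_sim)
  expect_identical(a, b)
  ta <- simulate_tumor(p, "monoclonal", genes = gs_sim, enum = en_sim)
  tb <- simulate_tumor(p, "monoclonal", genes = gs_sim, enum = en_sim)
  expect_identical(ta, tb)
})

test_that("parameter validation rejects invalid settings", {
  expect_error(sim_params(sbs_rate = -1), "non-negative")
  expect_error(sim_params(frac_CtoT = 1.4), "0, 1")
  expect_error(sim_params(depth_mean = NaN), "finite")
  expect_error(sim_params(zygosity = 3), "zygosity")
})

test_that("tumor architectures are constructed as declared", {
  p <- sim_params(seed = 61, n_tumor_slices = 3, n_founder_snvs = 6)
  mono <- simulate_tumor(p, "monoclonal", genes = gs_sim, enum = en_sim)
  tc <- mono$truth$clones
  founder <- unique(tc[tc$clone == "founder1",
                       c("chrom", "pos", "ref", "alt")])
  expect_equal(nrow(founder), 6)
  for (s in mono$samples$sample) {
    sl <- tc[tc$sample == s, ]
    expect_true(all(paste(founder$chrom, founder$pos) %in%
                      paste(sl$chrom, sl$pos)))
  }
  # founder CNA is chromosome-scale (> 10 Mb)
  expect_true(all(mono$truth$cna$end - mono$truth$cna$start > 10e6))
  expect_equal(mono$truth$clonality, "monoclonal")

  multi <- simulate_tumor(p, "multifocal", genes = gs_sim, enum = en_sim)
  f1 <- multi$truth$founder_snvs[[1]]
  f2 <- multi$truth$founder_snvs[[2]]
  expect_length(intersect(f1, f2), 0)
  expect_equal(multi$truth$clonality, "multifocal")

  p2 <- sim_params(seed = 61, n_tumor_slices = 1)
  expect_error(simulate_tumor(p2, "monoclonal", genes = gs_sim),
               "at least 2")
})

test_that("the normal panel is pure error with the configured moments", {
  p0 <- sim_params(seed = 71, seq_error_rate = 0)
  sites <- unique(en_sim[1:300, c("chrom", "pos", "ref")])
  pan0 <- simulate_background_panel(p0, 5, sites = sites)
  expect_true(all(pan0$alt_fwd + pan0$alt_rev == 0))

  p1 <- sim_params(seed = 72, depth_mean = 930, seq_error_rate = 1e-4,
                   error_rho = 1e-3)
  pan <- simulate_background_panel(p1, 30, sites = sites)
  tot_alt <- sum(pan$alt_fwd + pan$alt_rev)
  tot_depth <- sum(pan$depth)
  phat <- tot_alt / tot_depth
  # beta-binomial pooled-fraction standard error
  nbar <- mean(pan$depth)
  se <- sqrt(1e-4 * (1 - 1e-4) * (1 + (nbar - 1) * 1e-3) / tot_depth)
  expect_lt(abs(phat - 1e-4), 3 * se)
  expect_error(simulate_background_panel(p1, 1, sites = sites), "at least 2")
})

test_that("zero overdispersion reduces the error draw to a binomial", {
  set.seed(9)
  a <- clonesel:::rbetabinom(500, 930, 1e-3, 0)
  set.seed(9)
  b <- rbinom(500, 930, 1e-3)
  expect_identical(a, b)
})
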