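test_that("genotype simulation is deterministic and respects the design", {
  d <- gene_sampling_design("seabream", "vgll3")
  g1 <- simulate_genotypes(d, wild_freq = 0.35, seed = 11)
  g2 <- simulate_genotypes(d, wild_freq = 0.35, seed = 11)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 91)
  expect_equal(sum(g1$origin == "wild"), 54)
  expect_equal(sum(g1$origin == "farmed"), 37)
})

test_that("degenerate frequencies give monomorphic genotype tables", {
  d <- gene_sampling_design("seabream", "vgll3")
  g <- simulate_genotypes(d, wild_freq = 0, farmed_freq = 0, seed = 1)
  expect_true(all(g$allele1 == "A" & g$allele2 == "A"))
  expect_error(simulate_genotypes(d, wild_freq = 1.2),
               class = "domescan_config_error")
})

test_that("simulated allele frequencies follow binomial sampling", {
  d <- tibble::tibble(population = sprintf("p%02d", 1:10), origin = "wild",
                      period = "2004-2007", n = 50L)
  d$origin[1] <- "farmed"  # aggregate check uses all alleles below
  g <- simulate_genotypes(d, wild_freq = 0.5, farmed_freq = 0.5, seed = 5)
  phat <- mean(c(g$allele1, g$allele2) == "a")
  n_alleles <- 2 * sum(d$n)
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n_alleles))
})

test_that("poolseq generator is seed-deterministic and conserves reads", {
  cfg <- poolseq_config(n_snps = 300, seed = 42)
  s1 <- simulate_poolseq(cfg)
  s2 <- simulate_poolseq(poolseq_config(n_snps = 300, seed = 42))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$counts, s2$counts)

  # replicate depths sum to the pool depth at every position
  for (pid in s1$pools$pool_id) {
    reps <- s1$counts[grep(paste0("^", pid, "[.]"), names(s1$counts))]
    expect_length(reps, 2L)
    tot <- Reduce(`+`, lapply(reps, function(x) x$A + x$C + x$G + x$T))
    merged <- merge_replicates(reps)
    expect_identical(tot, merged$A + merged$C + merged$G + merged$T)
  }
})

test_that("truth table encodes the configured farmed-wild divergence", {
  cfg0 <- poolseq_config(n_snps = 2000, seed = 7, farmed_null = "identical")
  t0 <- simulate_poolseq(cfg0)$truth
  expect_equal(t0$farmed_freq, t0$wild_freq)

  cfgd <- poolseq_config(n_snps = 2000, seed = 7, farmed_null = "drift")
  td <- simulate_poolseq(cfgd)$truth
  # drift is unbiased: signed mean difference ~ 0
  expect_lt(abs(mean(td$farmed_freq - td$wild_freq)), 0.01)

  cfgs <- poolseq_config(n_snps = 2000, seed = 7, farmed_null = "identical",
                         selected_region = c(5e6, 1.5e7, 0.3))
  ts <- simulate_poolseq(cfgs)$truth
  inr <- ts$in_selected_region
  expect_gt(sum(inr), 0)
  expect_equal(mean(abs(ts$farmed_freq - ts$wild_freq)[inr]), 0.3,
               tolerance = 1e-6)
  expect_equal(mean(abs(ts$farmed_freq - ts$wild_freq)[!inr]), 0)
})

test_that("pool allele frequencies converge to truth at high depth", {
  # a very large pool removes chromosome-sampling noise, isolating the
  # read-sampling error that vanishes as depth grows
  cfg <- poolseq_config(n_snps = 400, seed = 9, mean_depth = 1e4,
                        depth_dispersion = 50, farmed_null = "identical",
                        pools = make_pools(1, 1, n_individuals = 5000,
                                           n_replicates = 1))
  sim <- simulate_poolseq(cfg)
  tab <- sim$counts[["wild01.rep1"]]
  alt_n <- vapply(seq_len(nrow(tab)), function(i)
    as.integer(tab[i, sim$truth$alt[i]]), integer(1))
  depth <- tab$A + tab$C + tab$G + tab$T
  phat <- alt_n / depth
  expect_lt(mean(abs(phat - sim$truth$wild_freq)), 0.02)
  expect_true(all(phat >= 0 & phat <= 1))
})

test_that("invalid selected regions are rejected", {
  expect_error(poolseq_config(selected_region = c(-5, 100, 0.3)),
               class = "domescan_config_error")
  expect_error(poolseq_config(chrom_length = 1000,
                              selected_region = c(1, 2000, 0.3)),
               class = "domescan_config_error")
  expect_error(poolseq_config(n_snps = 0), class = "domescan_config_error")
})
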