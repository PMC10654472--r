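test_that("pooled nucleotide diversity matches the corrected formula", {
  expect_equal(pool_pi(50, 50), 0.5 * 100 / 99)
  expect_equal(pool_pi(100, 0), 0)
  expect_true(is.na(pool_pi(1, 0)))
  # maximal at p = 0.5 for fixed depth
  pis <- pool_pi(0:100, 100:0)
  expect_equal(which.max(pis), 51L)
})

test_that("pairwise FST reproduces hand-computed values and bounds", {
  # identical pools: the finite-depth corrections C/(C-1) of pi_T (at 2C
  # reads) and pi_within (at C reads) do not cancel exactly, leaving a
  # small negative bias of order 1/(2C); exactly zero only as C -> Inf
  self <- pairwise_fst(30, 10, 30, 10)
  expect_lte(self, 0)
  expect_lt(abs(self), 0.02)
  expect_lt(abs(pairwise_fst(3000, 1000, 3000, 1000)), 2e-4)
  expect_equal(pairwise_fst(100, 0, 0, 100), 1)
  pi_t <- pool_pi(50, 50)
  pi_s <- pool_pi(40, 10)
  expect_equal(pairwise_fst(40, 10, 10, 40), (pi_t - pi_s) / pi_t)
  expect_equal(round(pairwise_fst(40, 10, 10, 40), 4), 0.3535)
  # symmetry and masking of monomorphic sites
  expect_equal(pairwise_fst(40, 10, 10, 40), pairwise_fst(10, 40, 40, 10))
  expect_true(is.na(pairwise_fst(50, 0, 30, 0)))
})

test_that("CMH test matches mantelhaen.test and the textbook formula", {
  # uninformative strata: odds ratio one everywhere
  flat <- cmh_test(rep(10, 3), rep(10, 3), rep(10, 3), rep(10, 3),
                   correct = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  set.seed(33)
  for (i in 1:40) {
    K <- sample(1:4, 1)
    tabs <- lapply(seq_len(K), function(k)
      matrix(sample(1:20, 4, replace = TRUE), 2))
    a <- vapply(tabs, function(t) t[1, 1], numeric(1))
    b <- vapply(tabs, function(t) t[1, 2], numeric(1))
    cc <- vapply(tabs, function(t) t[2, 1], numeric(1))
    d <- vapply(tabs, function(t) t[2, 2], numeric(1))
    for (corr in c(TRUE, FALSE)) {
      mine <- cmh_test(rbind(a), rbind(b), rbind(cc), rbind(d), correct = corr)
      orc <- oracle_cmh(tabs, correct = corr)
      expect_equal(mine$statistic, orc$statistic, tolerance = 1e-8)
      if (K >= 2) {  # mantelhaen.test requires at least two strata
        arr <- array(unlist(tabs), dim = c(2, 2, K))
        ref <- mantelhaen.test(arr, correct = corr)
        expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
        expect_equal(mine$p.value, ref$p.value, tolerance = 1e-8)
      }
    }
  }
})

test_that("CMH at one stratum is the (N-1)/N-scaled corrected chi-square", {
  t1 <- matrix(c(12, 5, 4, 14), 2, byrow = TRUE)
  mine <- cmh_test(12, 5, 4, 14, correct = TRUE)
  N <- sum(t1)
  ref <- suppressWarnings(chisq.test(t1, correct = TRUE))
  expect_equal(mine$statistic, unname(ref$statistic) * (N - 1) / N,
               tolerance = 1e-10)
  # zero variance in every stratum
  expect_warning(z <- cmh_test(5, 0, 3, 0), "zero variance")
  expect_equal(z$p.value, 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:200) {
    p <- runif(sample(1:25, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.1, 1.7)), class = "domescan_data_error")
})

test_that("rolling averages are centred, truncated and NA-aware", {
  expect_equal(rolling_average(rep(2.5, 10), 4), rep(2.5, 10))
  expect_equal(rolling_average(c(4, 8, 1), 1), c(4, 8, 1))
  expect_equal(rolling_average(c(0, 0, 9, 0, 0), 3)[3], 3)
  expect_warning(g <- rolling_average(1:4, 10), "global mean")
  expect_equal(g, rep(2.5, 4))

  skip_if_not_installed("zoo")
  set.seed(6)
  x <- rnorm(200)
  x[sample(200, 30)] <- NA
  for (w in c(3, 7, 51)) {
    ref <- zoo::rollapply(x, w, function(v) mean(v, na.rm = TRUE),
                          partial = TRUE, align = "center")
    expect_equal(rolling_average(x, w), ref, tolerance = 1e-12)
  }
})

test_that("scan statistics carry coherent columns on simulated data", {
  sim <- simulate_poolseq(poolseq_config(n_snps = 600, seed = 3))
  b <- suppressMessages(call_biallelic(merged_pools(sim)))
  st <- scan_statistics(b, pool_origins(sim))
  expect_equal(nrow(st), nrow(b$sites))
  expect_true(all(st$fisher_p >= 0 & st$fisher_p <= 1))
  expect_true(all(st$fisher_padj >= st$fisher_p - 1e-12))
  expect_true(all(st$cmh_padj >= st$cmh_p - 1e-12))
  expect_true(all(st$fst <= 1 + 1e-12, na.rm = TRUE))
  # clamped variant is non-negative
  stc <- scan_statistics(b, pool_origins(sim), clamp_fst = TRUE)
  expect_true(all(stc$fst >= 0, na.rm = TRUE))
})

test_that("peak detection recovers an injected region and handles edge cases", {
  cfg <- poolseq_config(n_snps = 4000, seed = 19,
                        selected_region = c(8e6, 1e7, 0.3))
  sim <- simulate_poolseq(cfg)
  b <- suppressMessages(call_biallelic(merged_pools(sim)))
  st <- scan_statistics(b, pool_origins(sim))
  tr <- rolling_track(st, window = 101)
  pk <- find_peaks(tr, st, window = 101)
  expect_true(pk$peak_pos >= 8e6 && pk$peak_pos <= 1e7)
  expect_true(pk$window_value <= max(st$fst, na.rm = TRUE) + 1e-12)
  expect_true(pk$significant)

  # single SNP: that SNP is the peak
  one <- st[1, ]
  tr1 <- rolling_track(one, window = 1)
  pk1 <- find_peaks(tr1, one, window = 1)
  expect_equal(pk1$peak_pos, one$pos)

  # all-masked track gives an empty report
  none <- one
  none$fst <- NA_real_
  pk0 <- find_peaks(rolling_track(none, window = 1), none, window = 1)
  expect_true(is.na(pk0$peak_pos))
})

test_that("flat nulls rarely produce BH-significant SNPs", {
  # Exact read-sampling null: both origins draw reads binomially at the
  # same frequency (no pool-chromosome sampling), where the Fisher null
  # distribution holds and BH controls the family-wise null.
  hits <- vapply(1:8, function(s) {
    set.seed(300 + s)
    n <- 800
    p <- rbeta(n, 0.8, 0.8)
    p <- pmin(pmax(p, 0.05), 0.95)
    df <- rnbinom(n, size = 5, mu = 240) + 25L
    dw <- rnbinom(n, size = 5, mu = 240) + 25L
    fa <- rbinom(n, df, p)
    wa <- rbinom(n, dw, p)
    pv <- domescan:::fisher_exact_vec(fa, df - fa, wa, dw - wa)
    sum(bh_adjust(pv) < 0.05)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.75)
})

test_that("the generator's pool-sampling null inflates naive read-count tests", {
  # with finite pools (2n chromosomes) the combined read counts are
  # overdispersed relative to the Fisher binomial null, so some
  # BH-significant calls appear even without farmed-wild divergence --
  # the reason the bottleneck/overdispersion-aware null matters
  cfg <- poolseq_config(n_snps = 800, seed = 301, farmed_null = "identical")
  sim <- simulate_poolseq(cfg)
  b <- suppressMessages(call_biallelic(merged_pools(sim)))
  st <- scan_statistics(b, pool_origins(sim))
  expect_gt(mean(st$fisher_p < 0.05, na.rm = TRUE), 0.05)
})

test_that("gene windows around published peaks return the published genes", {
  six6_chr <- tibble::tibble(
    chrom = "HG916829.1",
    start = c(12277343L, 12326653L, 12368259L),
    end = c(12318144L, 12365899L, 12370413L),
    strand = "+",
    gene_id = c("mboat2", "kidin220", "id2"),
    gene_name = c("mboat2", "kidin220", "id2"))
  hit <- genes_near(six6_chr, "HG916829.1", 12321585L, flank = 50000)
  expect_setequal(hit$gene_id, c("mboat2", "kidin220", "id2"))

  vgll3_chr <- tibble::tibble(
    chrom = "HG916832.1",
    start = c(16239969L, 16245284L, 16252778L, 16261017L, 16286421L,
              16293485L, 16298565L, 16304395L, 16313335L, 16325825L),
    end = c(16244529L, 16249612L, 16258234L, 16284118L, 16291829L,
            16297194L, 16302322L, 16307184L, 16324581L, 16335625L),
    strand = "+",
    gene_id = c("rpgr", "oct", "gpr161", "dcaf6", "mpc2", "rpl24", "cep97",
                "nxpe3", "me3", "ildr1"),
    gene_name = c("rpgr", "oct", "gpr161", "dcaf6", "mpc2", "rpl24", "cep97",
                  "nxpe3", "me3", "ildr1"))
  hit2 <- genes_near(vgll3_chr, "HG916832.1", 16286816L, flank = 50000)
  expect_equal(nrow(hit2), 10L)
  expect_equal(hit2$distance[hit2$gene_id == "rpgr"], 42287L)
  expect_equal(hit2$distance[hit2$gene_id == "mpc2"], 0L)

  # off-chromosome queries and empty annotations give empty results
  expect_equal(nrow(genes_near(six6_chr, "chrX", 12321585L)), 0L)
  expect_equal(nrow(genes_near(six6_chr[0, ], "HG916829.1", 1L)), 0L)
})

test_that("gene annotations round-trip through GFF3", {
  sim <- simulate_poolseq(poolseq_config(n_snps = 10, seed = 2, n_genes = 5))
  f <- tempfile(fileext = ".gff3")
  write_gene_annotation(sim$genes, f)
  back <- read_gene_annotation(f)
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
  expect_equal(back$gene_id, sim$genes$gene_id)
})
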