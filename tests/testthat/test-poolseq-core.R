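write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("readcount dialect parses constructed fixtures", {
  f <- write_tmp(c("chr1\t100\tA\t30\tA:28\tC:2",
                   "chr1\t101\tG\t12\tG:10\tT:1\tN:1"))
  s <- read_pileup(f, "readcount")
  expect_equal(s$A[1], 28L)
  expect_equal(s$C[1], 2L)
  expect_equal(s$G[2], 10L)
  expect_equal(s$N[2], 1L)
  expect_equal(s$pool, c(1L, 1L))

  # extra per-base fields after the count are ignored
  f2 <- write_tmp("chr1\t5\tC\t7\tC:5:60:0.1\tT:2:58:0.2")
  s2 <- read_pileup(f2, "readcount")
  expect_equal(s2$C, 5L)
  expect_equal(s2$T, 2L)
})

test_that("sync dialect parses the A:T:C:G:N:del column order", {
  f <- write_tmp("chr2\t42\tA\t10:0:5:0:0:0\t0:3:0:7:1:2")
  s <- read_pileup(f, "sync")
  p1 <- s[s$pool == 1, ]
  expect_equal(p1$A, 10L)
  expect_equal(p1$C, 5L)
  p2 <- s[s$pool == 2, ]
  expect_equal(p2$T, 3L)
  expect_equal(p2$G, 7L)
  expect_equal(p2$N, 1L)
  expect_equal(p2$del, 2L)
})

test_that("empty, malformed and unsorted pileups are handled", {
  expect_equal(nrow(read_pileup(write_tmp(character()), "sync")), 0L)
  expect_error(read_pileup(write_tmp("chr1\t1\tA"), "readcount"),
               class = "domescan_parse_error")
  err <- tryCatch(read_pileup(write_tmp(c("chr1\t10\tA\t5\tA:5",
                                          "chr1\tx\tA\t5\tA:5")),
                              "readcount"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "line 2")
  expect_error(read_pileup(write_tmp(c("chr1\t10\tA\t5\tA:5",
                                       "chr1\t9\tA\t5\tA:5")), "readcount"),
               class = "domescan_parse_error")
  expect_error(read_pileup(tempfile(), "sync"),
               class = "domescan_config_error")
})

test_that("pileup writing round-trips through both dialects", {
  sim <- simulate_poolseq(poolseq_config(n_snps = 50, seed = 13))
  tab <- sim$counts[[1]]
  for (dialect in c("readcount", "sync")) {
    f <- tempfile()
    write_pileup(tab, f, dialect)
    back <- read_pileup(f, dialect)
    expect_equal(back[, c("chrom", "pos", "A", "C", "G", "T")],
                 tab[, c("chrom", "pos", "A", "C", "G", "T")])
  }
})

test_that("replicate merging is additive, commutative, with empty identity", {
  a <- tibble::tibble(chrom = "c", pos = c(1L, 3L), ref = "A",
                      A = c(10L, 2L), C = 0L, G = 0L, T = c(0L, 1L))
  b <- tibble::tibble(chrom = "c", pos = c(1L, 2L), ref = "A",
                      A = c(5L, 7L), C = 1L, G = 0L, T = 0L)
  m <- merge_replicates(a, b)
  expect_equal(m$A[m$pos == 1], 15L)
  expect_equal(m$C[m$pos == 2], 1L)          # outer join keeps pos 2 and 3
  expect_equal(m$T[m$pos == 3], 1L)
  m2 <- merge_replicates(b, a)
  expect_equal(m, m2)

  empty <- a[0, ]
  expect_equal(merge_replicates(a, empty)[, names(a)], a[order(a$pos), ])
  # total reads conserved
  expect_equal(sum(m$A + m$C + m$G + m$T),
               sum(a$A + a$C + a$G + a$T) + sum(b$A + b$C + b$G + b$T))

  bad <- b
  bad$ref <- c("G", "A")
  expect_error(merge_replicates(a, bad), class = "domescan_data_error")
})

test_that("biallelic calling applies the depth and MAF filters", {
  mk <- function(A = 0L, C = 0L, G = 0L, T = 0L, pos = 1L) {
    tibble::tibble(chrom = "c", pos = pos, ref = "A",
                   A = A, C = C, G = G, T = T)
  }
  # pooled counts A=300, C=10, G=1 over 311 reads: G at 0.32% is dropped,
  # C at 3.2% is kept -> biallelic A/C
  pools <- list(p1 = mk(A = 150L, C = 5L, G = 1L), p2 = mk(A = 150L, C = 5L))
  b <- call_biallelic(pools, min_depth = 25, min_maf = 0.01)
  expect_equal(nrow(b$sites), 1L)
  expect_equal(b$sites$major, "A")
  expect_equal(b$sites$minor, "C")
  expect_equal(unname(b$major[1, ]), c(150L, 150L))
  expect_equal(unname(b$minor[1, ]), c(5L, 5L))

  # any pool below the depth threshold drops the site
  under <- list(p1 = mk(A = 20L, C = 4L), p2 = mk(A = 100L, C = 10L))
  expect_equal(nrow(call_biallelic(under, min_depth = 25)$sites), 0L)
  expect_equal(nrow(call_biallelic(under, min_depth = 24)$sites), 1L)

  # monomorphic sites are never emitted
  mono <- list(p1 = mk(A = 100L), p2 = mk(A = 90L))
  expect_equal(nrow(call_biallelic(mono)$sites), 0L)
})

test_that("biallelic calling is idempotent and bounds pooled frequencies", {
  sim <- simulate_poolseq(poolseq_config(n_snps = 400, seed = 23))
  pools <- merged_pools(sim)
  b1 <- suppressMessages(call_biallelic(pools))
  b2 <- suppressMessages(call_biallelic(bset_to_counts(b1)))
  expect_equal(b1$sites, b2$sites)
  expect_equal(b1$major, b2$major)
  expect_equal(b1$minor, b2$minor)

  minor_tot <- rowSums(b1$minor)
  depth_tot <- rowSums(b1$major + b1$minor)
  maf <- minor_tot / depth_tot
  expect_true(all(maf >= 0.01 & maf <= 0.5))
  # per-pool depth filter held
  expect_true(all(b1$major + b1$minor >= 25))
})

test_that("biallelic tables round-trip through TSV", {
  sim <- simulate_poolseq(poolseq_config(n_snps = 100, seed = 29))
  b <- suppressMessages(call_biallelic(merged_pools(sim)))
  f <- tempfile(fileext = ".tsv")
  write_biallelic(b, f)
  back <- read_biallelic(f)
  expect_equal(back$sites, b$sites)
  expect_equal(back$major, b$major)
  expect_equal(back$pool_ids, b$pool_ids)
})
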