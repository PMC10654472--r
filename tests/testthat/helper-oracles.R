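# Independent oracles used to cross-check package implementations. Each is
# deliberately written along a different code path than the function it
# validates.

# Step-up Benjamini-Hochberg written from the definition: sort ascending,
# multiply by m/rank, enforce monotonicity from the largest p downward.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(1, adj)[order(o)]
}

# Textbook Cochran-Mantel-Haenszel chi-square for one site, looping over
# strata with scalar arithmetic.
oracle_cmh <- function(tabs, correct = TRUE) {
  num <- 0
  den <- 0
  for (t in tabs) {
    a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
    n <- a + b + c + d
    num <- num + (a - (a + b) * (a + c) / n)
    den <- den + (a + b) * (c + d) * (a + c) * (b + d) / (n^2 * (n - 1))
  }
  yates <- if (correct && abs(num) >= 0.5) 0.5 else 0
  stat <- (abs(num) - yates)^2 / den
  list(statistic = stat, p.value = pchisq(stat, 1, lower.tail = FALSE))
}

# Exact conditional Hardy-Weinberg p-value via brute-force enumeration of
# heterozygote counts, with probabilities from binomial coefficients
# (choose()), not factorials.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  ways <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, numeric(1))
  pr <- ways / sum(ways)
  sum(pr[pr <= pr[match(n_Aa, hets)] * (1 + 1e-7)])
}

# Exact two-sided rank-sum p-value by recursive enumeration of all group
# assignments (no combn), using midranks; two-sided = 2 * min(tails).
oracle_wilcoxon <- function(g1, g2) {
  r <- rank(c(g1, g2))
  n1 <- length(g1)
  N <- length(r)
  sums <- c()
  recurse <- function(start, left, acc) {
    if (left == 0) {
      sums <<- c(sums, acc)
      return(invisible())
    }
    for (i in start:(N - left + 1)) recurse(i + 1, left - 1, acc + r[i])
  }
  recurse(1, n1, 0)
  w <- sum(r[seq_len(n1)])
  min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
}

# Reconstruct per-pool count tables from a biallelic_set, for idempotence
# checks: every site keeps only its two called alleles.
bset_to_counts <- function(bset) {
  out <- list()
  for (j in seq_along(bset$pool_ids)) {
    tab <- tibble::tibble(chrom = bset$sites$chrom, pos = bset$sites$pos,
                          ref = bset$sites$ref,
                          A = 0L, C = 0L, G = 0L, T = 0L)
    for (b in c("A", "C", "G", "T")) {
      tab[[b]] <- ifelse(bset$sites$major == b, bset$major[, j],
                         ifelse(bset$sites$minor == b, bset$minor[, j], 0L))
    }
    out[[bset$pool_ids[j]]] <- tab
  }
  out
}

# Merge the replicate libraries of a poolseq_sim into per-pool tables.
merged_pools <- function(sim) {
  pool_of <- sub("[.]rep[0-9]+$", "", names(sim$counts))
  lapply(split(names(sim$counts), pool_of),
         function(nm) merge_replicates(sim$counts[nm]))
}

pool_origins <- function(sim) setNames(sim$pools$origin, sim$pools$pool_id)
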