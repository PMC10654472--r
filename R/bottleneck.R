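# Wright-Fisher bottleneck null for farmed-vs-wild frequency tests.
#
# Farmed stocks of both species went through a documented contraction of
# effective population size (from ~1e6 in seabream and ~1e4 in seabass down
# to ~100 breeders, some 5-10 generations ago). Pure drift through that
# bottleneck can move allele frequencies far enough to fool a
# farmed-vs-wild test; the functions here quantify that false-positive rate.

#' Wright-Fisher drift through a bottleneck
#'
#' Propagates allele frequencies through `generations` rounds of binomial
#' resampling of `2 * nb` chromosomes (no mutation, selection or migration).
#' The pre-bottleneck size `n0` only bounds `nb`; per-generation drift at
#' `n0` of 1e4--1e6 is negligible and is not simulated.
#'
#' @param p0 Numeric vector of starting allele frequencies in \[0, 1\]. Each
#'   element follows an independent trajectory.
#' @param nb Bottleneck effective population size (diploid individuals).
#' @param generations Number of generations spent at size `nb`; 0 returns
#'   `p0` unchanged.
#' @param n0 Pre-bottleneck effective size; must satisfy `nb <= n0`.
#' @param seed Optional integer; when supplied the trajectory is computed
#'   under a local RNG seed and is fully reproducible.
#' @return Numeric vector of post-bottleneck frequencies, same length as
#'   `p0`. The boundaries 0 and 1 are absorbing.
#' @examples
#' wf_trajectory(c(0, 0.5, 1), nb = 50, generations = 10, seed = 1)
#' @export
wf_trajectory <- function(p0, nb = 100, generations = 8, n0 = 1e6, seed = NULL) {
  assert_prob(p0, "p0")
  assert_count(nb, "nb")
  assert_count(generations, "generations", min = 0L)
  if (nb > n0) stop_config("`nb` must not exceed `n0`")
  run <- function() {
    p <- p0
    for (g in seq_len(generations)) {
      p <- rbinom(length(p), 2L * nb, p) / (2L * nb)
    }
    p
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing all hypergeometric table
#' probabilities not exceeding that of the observed table (the same
#' definition as [stats::fisher.test()], against which it is tested). The
#' implementation is vectorised so genome scans can evaluate one table per
#' SNP without per-site overhead.
#'
#' @param x A 2x2 matrix of non-negative integer counts, or the count vector
#'   `c(a, b, c, d)` read row-wise.
#' @return The two-sided p-value. A table with a zero margin carries no
#'   information; it returns `p = 1` with a warning.
#' @examples
#' fisher_2x2(matrix(c(3, 0, 0, 3), nrow = 2, byrow = TRUE))  # 0.1
#' @export
fisher_2x2 <- function(x) {
  # matrix storage is column-major, so a 2x2 matrix arrives as a, c, b, d
  if (is.matrix(x)) x <- x[c(1L, 3L, 2L, 4L)]
  x <- as.integer(x)
  if (length(x) != 4L || anyNA(x) || any(x < 0)) {
    stop_data("expected four non-negative integer counts")
  }
  p <- fisher_exact_vec(x[1L], x[2L], x[3L], x[4L])
  if ((x[1L] + x[2L]) == 0L || (x[3L] + x[4L]) == 0L ||
      (x[1L] + x[3L]) == 0L || (x[2L] + x[4L]) == 0L) {
    warning("2x2 table has a zero margin; p = 1")
  }
  p
}

# Vectorised two-sided Fisher exact test over per-row tables [[a, b], [c, d]].
# Rows with a zero margin yield 1 silently (callers decide whether to warn).
fisher_exact_vec <- function(a, b, c, d) {
  n <- length(a)
  m <- a + c                              # first-column margin
  nn <- b + d
  k <- a + b                              # first-row margin
  p <- rep(1, n)
  relerr <- 1 + 1e-7
  for (i in seq_len(n)) {
    if (m[i] == 0L || nn[i] == 0L || k[i] == 0L || (m[i] + nn[i] - k[i]) == 0L) next
    lo <- max(0L, k[i] - nn[i])
    hi <- min(k[i], m[i])
    dens <- dhyper(lo:hi, m[i], nn[i], k[i])
    p[i] <- min(1, sum(dens[dens <= dens[a[i] - lo + 1L] * relerr]))
  }
  p
}

#' False-positive rate of farmed-vs-wild tests under a drift-only bottleneck
#'
#' For each wild allele frequency, repeatedly (i) drifts the frequency
#' through the bottleneck with [wf_trajectory()], (ii) draws a farmed sample
#' of `2 * farmed_n` alleles at the post-drift frequency and a wild sample of
#' `2 * wild_n` alleles at the original frequency, and (iii) applies the
#' Fisher exact test to the resulting 2x2 allele-count table. The
#' false-positive rate at level `alpha` is the fraction of replicates with
#' `p < alpha`: every rejection is false because only drift acted.
#'
#' @param wild_freq Named or unnamed numeric vector of observed wild allele
#'   frequencies (one per locus).
#' @param farmed_n,wild_n Diploid sample sizes of the farmed and wild
#'   collections being emulated (defaults match the seabream *vgll3*
#'   design: 37 farmed, 54 wild).
#' @param nb,generations,n0 Bottleneck demography; see [wf_trajectory()].
#' @param replicates Number of drift replicates per locus.
#' @param alpha Significance levels at which to report the FPR.
#' @param wild_sampling `"simulated"` (default) redraws the wild sample each
#'   replicate; `"expected"` fixes it at the rounded expected counts, i.e.
#'   compares simulated farmed samples against the observed wild table.
#' @param seed Integer seed; the whole run is reproducible.
#' @return An object of class `bottleneck_fpr`: a list with `fpr` (tibble of
#'   `locus`, `alpha`, `fpr`), `replicates` (tibble of per-replicate
#'   post-drift frequency and p-value) and the call parameters.
#' @examples
#' bottleneck_fpr(c(vgll3 = 0.3), replicates = 200, seed = 1)$fpr
#' @export
bottleneck_fpr <- function(wild_freq, farmed_n = 37, wild_n = 54,
                           nb = 100, generations = 8, n0 = 1e6,
                           replicates = 1000, alpha = c(0.05, 0.01),
                           wild_sampling = c("simulated", "expected"),
                           seed = 1L) {
  assert_prob(wild_freq, "wild_freq")
  assert_prob(alpha, "alpha")
  if (any(alpha <= 0 | alpha >= 1)) stop_config("`alpha` must lie in (0, 1)")
  assert_count(replicates, "replicates")
  assert_count(farmed_n, "farmed_n")
  assert_count(wild_n, "wild_n")
  wild_sampling <- match.arg(wild_sampling)
  loci <- names(wild_freq) %||% paste0("locus", seq_along(wild_freq))

  rep_tabs <- vector("list", length(wild_freq))
  with_seed(as.integer(seed), {
    for (j in seq_along(wild_freq)) {
      p0 <- wild_freq[[j]]
      p_drift <- wf_trajectory(rep(p0, replicates), nb = nb,
                               generations = generations, n0 = n0)
      fa <- rbinom(replicates, 2L * farmed_n, p_drift)   # farmed allele count
      wa <- if (wild_sampling == "simulated") {
        rbinom(replicates, 2L * wild_n, p0)
      } else {
        rep(round(2L * wild_n * p0), replicates)
      }
      pv <- fisher_exact_vec(fa, 2L * farmed_n - fa, wa, 2L * wild_n - wa)
      rep_tabs[[j]] <- tibble(locus = loci[j], replicate = seq_len(replicates),
                              p_drift = p_drift, p_value = pv)
    }
  })
  reps <- do.call(rbind, rep_tabs)
  fpr <- do.call(rbind, lapply(seq_along(wild_freq), function(j) {
    pv <- rep_tabs[[j]]$p_value
    tibble(locus = loci[j], alpha = alpha,
           fpr = vapply(alpha, function(a) mean(pv < a), numeric(1)))
  }))
  structure(
    list(fpr = fpr, replicates = reps,
         params = list(farmed_n = farmed_n, wild_n = wild_n, nb = nb,
                       generations = generations, n0 = n0,
                       n_replicates = replicates, alpha = alpha,
                       wild_sampling = wild_sampling, seed = seed)),
    class = "bottleneck_fpr"
  )
}

#' @export
print.bottleneck_fpr <- function(x, ...) {
  p <- x$params
  cat("Wright-Fisher bottleneck null (nb =", p$nb, ", G =", p$generations,
      ",", p$n_replicates, "replicates)\n")
  print(x$fpr)
  invisible(x)
}
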