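# Per-SNP farmed-vs-wild differentiation statistics and track utilities.
#
# FST follows the pooled nucleotide-diversity estimator: within-pool
# heterozygosity pi = (1 - p^2 - q^2) * C/(C-1) computed from read
# frequencies with the finite-depth correction C/(C-1), and
# FST = (pi_T - pi_S) / pi_T with pi_T from the summed counts of the
# compared pools and pi_S the mean within-pool value.

#' Pooled nucleotide diversity at one site
#'
#' @param major,minor Read counts of the two alleles (vectorised).
#' @return `(1 - p^2 - q^2) * C / (C - 1)` with `C = major + minor`; `NA`
#'   when `C < 2` (the correction is undefined).
#' @examples
#' pool_pi(50, 50)  # 0.50505...
#' @export
pool_pi <- function(major, minor) {
  C <- major + minor
  p <- major / C
  ifelse(is.na(C) | C < 2L, NA_real_, (1 - p^2 - (1 - p)^2) * C / (C - 1))
}

#' Pairwise FST between two pools from read counts
#'
#' @param a_major,a_minor,b_major,b_minor Allele read counts in pools A and
#'   B (vectorised over sites).
#' @return `(pi_T - mean(pi_A, pi_B)) / pi_T`; `NA` (masked) when the
#'   combined site is monomorphic (`pi_T = 0`) or either pool has depth < 2.
#'   Small negative values are legitimate finite-sample outcomes.
#' @examples
#' pairwise_fst(40, 10, 10, 40)  # 0.3535...
#' @export
pairwise_fst <- function(a_major, a_minor, b_major, b_minor) {
  pi_t <- pool_pi(a_major + b_major, a_minor + b_minor)
  pi_s <- (pool_pi(a_major, a_minor) + pool_pi(b_major, b_minor)) / 2
  ifelse(is.na(pi_t) | is.na(pi_s) | pi_t == 0, NA_real_, (pi_t - pi_s) / pi_t)
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 allele-count tables
#'
#' Chi-square statistic `(|sum(a_k - E a_k)| - c)^2 / sum(V_k)` with
#' `E a_k = R1_k C1_k / N_k` and
#' `V_k = R1_k R2_k C1_k C2_k / (N_k^2 (N_k - 1))`, referred to chi-square
#' with 1 df. The continuity constant `c` is 0.5 by default and, as in
#' [stats::mantelhaen.test()], is only applied when the summed deviation
#' reaches 0.5 (so the correction can never overshoot zero).
#'
#' @param a,b,c,d Matrices (sites x strata) or vectors (one site) of the
#'   2x2 cell counts per stratum `[[a, b], [c, d]]`. `NA` strata are
#'   skipped.
#' @param correct Apply the 0.5 continuity correction (default `TRUE`).
#' @return A list with vectors `statistic` and `p.value`. Sites whose
#'   strata all have zero variance return `p = 1` (with one warning).
#' @export
cmh_test <- function(a, b, c, d, correct = TRUE) {
  a <- rbind(a); b <- rbind(b); cc <- rbind(c); d <- rbind(d)
  n_k <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  ea <- r1 * c1 / n_k
  v <- r1 * r2 * c1 * c2 / (n_k^2 * (n_k - 1))
  v[!is.finite(v)] <- NA
  ea[!is.finite(ea)] <- NA
  dev <- rowSums(a - ea, na.rm = TRUE)
  vs <- rowSums(v, na.rm = TRUE)
  # continuity correction only where it cannot overshoot (|dev| >= 0.5),
  # matching the reference implementation in stats::mantelhaen.test
  cst <- if (correct) ifelse(abs(dev) >= 0.5, 0.5, 0) else 0
  stat <- (abs(dev) - cst)^2 / vs
  degenerate <- vs == 0 | !is.finite(vs)
  if (any(degenerate)) {
    warning(sum(degenerate), " site(s) with zero variance in all strata; p = 1")
    stat[degenerate] <- 0
  }
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  p[degenerate] <- 1
  list(statistic = as.numeric(stat), p.value = as.numeric(p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]), with
#' input validation; `NA` entries (masked sites) are passed through.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_data("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Centred rolling average over SNP index
#'
#' Moving mean over a window of `window` SNPs (by index, not bp), centred,
#' with edges truncated to the available SNPs and `NA` (masked) values
#' skipped.
#'
#' @param x Numeric vector ordered by position.
#' @param window Window size in SNPs.
#' @return Numeric vector of window means, same length as `x`. If
#'   `window > length(x)` the global mean is returned everywhere, with a
#'   warning.
#' @export
rolling_average <- function(x, window = 5000) {
  assert_count(window, "window")
  n <- length(x)
  if (n == 0L) return(numeric())
  if (window > n) {
    warning("window exceeds number of SNPs; returning the global mean")
    return(rep(mean(x, na.rm = TRUE), n))
  }
  ok <- !is.na(x)
  v <- ifelse(ok, x, 0)
  half <- (window - 1L) %/% 2L
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (window - 1L - half))
  cs <- c(0, cumsum(v))
  cn <- c(0, cumsum(ok))
  sums <- cs[hi + 1L] - cs[lo]
  cnts <- cn[hi + 1L] - cn[lo]
  ifelse(cnts > 0L, sums / cnts, NA_real_)
}

#' Per-SNP differentiation statistics between farmed and wild pools
#'
#' Computes, for every SNP of a [call_biallelic()] result: the combined-pool
#' FST (counts summed per origin; the headline statistic), the mean of all
#' farmed x wild pairwise FST values, the Fisher exact p-value on the
#' combined 2x2 allele-count table, the CMH test across pool-pair strata,
#' and Benjamini-Hochberg adjusted p-values (applied per chromosome across
#' all tested SNPs).
#'
#' @param bset A `biallelic_set`.
#' @param origins Pool origins: either a named character vector
#'   (`pool_id -> "farmed"/"wild"`) or a data frame with columns `pool_id`
#'   and `origin`.
#' @param pairing CMH strata: `"index"` (default) pairs the i-th farmed with
#'   the i-th wild pool after sorting pool ids, using
#'   `K = min(n_farmed, n_wild)` strata; `"manifest"` uses the explicit
#'   `pairs` table.
#' @param pairs For `pairing = "manifest"`: data frame with columns
#'   `farmed` and `wild` holding pool ids.
#' @param cmh_correct Continuity correction for the CMH test.
#' @param clamp_fst Clamp negative FST estimates to zero (for plotting);
#'   default `FALSE` reports them as computed.
#' @return A tibble with one row per SNP: `chrom`, `pos`, `major`, `minor`,
#'   `fst` (combined-pool), `fst_mean_pairwise`, `fisher_p`, `fisher_padj`,
#'   `cmh_stat`, `cmh_p`, `cmh_padj`.
#' @export
scan_statistics <- function(bset, origins, pairing = c("index", "manifest"),
                            pairs = NULL, cmh_correct = TRUE,
                            clamp_fst = FALSE) {
  pairing <- match.arg(pairing)
  if (!inherits(bset, "biallelic_set")) stop_config("not a biallelic_set")
  if (is.data.frame(origins)) {
    origins <- setNames(origins$origin, origins$pool_id)
  }
  miss <- setdiff(bset$pool_ids, names(origins))
  if (length(miss)) stop_config("origin missing for pool(s): ",
                                paste(miss, collapse = ", "))
  org <- origins[bset$pool_ids]
  if (!all(org %in% c("farmed", "wild"))) {
    stop_config("origins must be 'farmed' or 'wild'")
  }
  fi <- which(org == "farmed")
  wi <- which(org == "wild")
  if (!length(fi) || !length(wi)) stop_analysis("need both origins")

  M <- bset$major
  m <- bset$minor
  fM <- rowSums(M[, fi, drop = FALSE], na.rm = TRUE)
  fm <- rowSums(m[, fi, drop = FALSE], na.rm = TRUE)
  wM <- rowSums(M[, wi, drop = FALSE], na.rm = TRUE)
  wm <- rowSums(m[, wi, drop = FALSE], na.rm = TRUE)

  fst <- pairwise_fst(fM, fm, wM, wm)
  pairsum <- matrix(0, nrow(bset$sites), 0L)
  acc <- matrix(0, nrow(bset$sites), 2L)       # running sum and count
  for (i in fi) for (j in wi) {
    f <- pairwise_fst(M[, i], m[, i], M[, j], m[, j])
    ok <- !is.na(f)
    acc[ok, 1L] <- acc[ok, 1L] + f[ok]
    acc[ok, 2L] <- acc[ok, 2L] + 1
  }
  fst_mean <- ifelse(acc[, 2L] > 0, acc[, 1L] / acc[, 2L], NA_real_)
  if (clamp_fst) {
    fst <- pmax(0, fst)
    fst_mean <- pmax(0, fst_mean)
  }

  fisher_p <- fisher_exact_vec(fM, fm, wM, wm)

  if (pairing == "index") {
    fs <- sort(bset$pool_ids[fi])
    ws <- sort(bset$pool_ids[wi])
    K <- min(length(fs), length(ws))
    pairs <- tibble(farmed = fs[seq_len(K)], wild = ws[seq_len(K)])
  } else if (is.null(pairs) ||
             !all(c("farmed", "wild") %in% names(pairs))) {
    stop_config("`pairs` with columns farmed/wild required for manifest pairing")
  }
  pf <- match(pairs$farmed, bset$pool_ids)
  pw <- match(pairs$wild, bset$pool_ids)
  if (anyNA(pf) || anyNA(pw)) stop_config("unknown pool id in `pairs`")
  cmh <- cmh_test(M[, pf, drop = FALSE], m[, pf, drop = FALSE],
                  M[, pw, drop = FALSE], m[, pw, drop = FALSE],
                  correct = cmh_correct)

  out <- tibble(chrom = bset$sites$chrom, pos = bset$sites$pos,
                major = bset$sites$major, minor = bset$sites$minor,
                fst = fst, fst_mean_pairwise = fst_mean,
                fisher_p = fisher_p,
                cmh_stat = cmh$statistic, cmh_p = cmh$p.value)
  out$fisher_padj <- ave(out$fisher_p, out$chrom, FUN = bh_adjust)
  out$cmh_padj <- ave(out$cmh_p, out$chrom, FUN = bh_adjust)
  out[, c("chrom", "pos", "major", "minor", "fst", "fst_mean_pairwise",
          "fisher_p", "fisher_padj", "cmh_stat", "cmh_p", "cmh_padj")]
}

#' Rolling track of a per-SNP statistic
#'
#' @param stats A [scan_statistics()] tibble (or any tibble with `chrom`,
#'   `pos` and the chosen column), ordered by position.
#' @param stat Column to average (default `"fst"`).
#' @param window Window size in SNPs (default 5000).
#' @return A tibble `chrom`, `pos`, `index`, `value` with the centred
#'   rolling mean, one row per SNP.
#' @export
rolling_track <- function(stats, stat = "fst", window = 5000) {
  if (!stat %in% names(stats)) stop_config("no column `", stat, "`")
  tibble(chrom = stats$chrom, pos = stats$pos,
         index = seq_len(nrow(stats)),
         value = rolling_average(stats[[stat]], window = window))
}

#' Locate the differentiation peak of a rolling track
#'
#' Finds the global maximum of the rolling track; within that window,
#' reports the SNP with the maximal per-SNP statistic together with its
#' BH-adjusted significance (starred at 0.05 / 0.01 / 0.001), which is the
#' value displayed at scan peaks.
#'
#' @param track A [rolling_track()] tibble.
#' @param stats The matching [scan_statistics()] tibble (same SNPs, same
#'   order).
#' @param stat Per-SNP statistic maximised within the peak window.
#' @param padj Column holding the adjusted significance of that SNP.
#' @param window Window size used for the track.
#' @param alpha Significance level for calling the peak SNP significant.
#' @return A list of class `peak_report`: `window_pos` and `window_value`
#'   (rolling maximum), `peak_pos`, `peak_stat`, `peak_padj`,
#'   `significant`, `stars`, and `genes` (filled by [genes_near()],
#'   initially an empty tibble). All-masked tracks yield an empty report.
#' @export
find_peaks <- function(track, stats, stat = "fst", padj = "fisher_padj",
                       window = 5000, alpha = 0.05) {
  empty <- structure(list(window_pos = NA_integer_, window_value = NA_real_,
                          peak_pos = NA_integer_, peak_stat = NA_real_,
                          peak_padj = NA_real_, significant = NA,
                          stars = "", genes = tibble()),
                     class = "peak_report")
  if (nrow(track) == 0L || all(is.na(track$value))) return(empty)
  centre <- which.max(track$value)
  half <- (window - 1L) %/% 2L
  lo <- max(1L, centre - half)
  hi <- min(nrow(stats), centre + (window - 1L - half))
  vals <- stats[[stat]][lo:hi]
  if (all(is.na(vals))) return(empty)
  best <- (lo:hi)[which.max(vals)]
  pa <- stats[[padj]][best]
  structure(list(window_pos = track$pos[centre],
                 window_value = track$value[centre],
                 peak_pos = stats$pos[best],
                 peak_stat = stats[[stat]][best],
                 peak_padj = pa,
                 significant = !is.na(pa) && pa <= alpha,
                 stars = p_stars(pa),
                 genes = tibble()),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  if (is.na(x$peak_pos)) {
    cat("empty peak report (all sites masked)\n")
    return(invisible(x))
  }
  cat(sprintf("rolling maximum %.4g at %d; peak SNP %d (stat %.4g, padj %.3g%s)\n",
              x$window_value, x$window_pos, x$peak_pos, x$peak_stat,
              x$peak_padj, if (nzchar(x$stars)) paste0(" ", x$stars) else ""))
  if (nrow(x$genes)) print(x$genes)
  invisible(x)
}
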