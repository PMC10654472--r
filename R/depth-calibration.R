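# Read-depth calibration for pooled genotyping.
#
# A pool of P diploid individuals sequenced to read depth D represents each
# individual only if at least one of the D reads came from it. Resampling
# the identity of each read uniformly with replacement gives the
# distribution of distinct individuals represented at a site, whose lower
# confidence bound motivates the minimum-depth filter (depth 25 for pools
# of 25: at least 13 of the 25 individuals at the lower 95% limit, i.e. at
# least half of all possible genotypes). The closed-form mean is
# P * (1 - (1 - 1/P)^D).

#' Distribution of distinct individuals represented at a site
#'
#' Monte-Carlo resampling: each replicate draws `depth` reads uniformly with
#' replacement over `pool_size` individuals and counts how many distinct
#' individuals contributed at least one read.
#'
#' @param pool_size Number of diploid individuals in the pool (default 25).
#' @param depth Read depth per replicate (default 25).
#' @param replicates Number of resampling replicates (default 1e6).
#' @param ci_level Confidence level for the reported lower bound (default
#'   0.95).
#' @param side `"two"` (default) reports the `(1 - ci_level)/2` quantile as
#'   the lower bound (two-sided interval); `"one"` reports the
#'   `1 - ci_level` quantile.
#' @param seed Integer seed.
#' @return A list of class `depth_calibration`: `mean`, `lower` (the lower
#'   confidence bound), `expected_mean` (closed form), `quantiles`,
#'   `histogram` (tibble `k`, `count`, `prop`) and the parameters.
#' @examples
#' distinct_individuals(pool_size = 25, depth = 25, replicates = 1e4, seed = 1)
#' @export
distinct_individuals <- function(pool_size = 25, depth = 25,
                                 replicates = 1e6, ci_level = 0.95,
                                 side = c("two", "one"), seed = 1L) {
  pool_size <- assert_count(pool_size, "pool_size")
  depth <- assert_count(depth, "depth")
  replicates <- assert_count(replicates, "replicates")
  assert_prob(ci_level, "ci_level")
  side <- match.arg(side)

  counts <- integer(replicates)
  with_seed(as.integer(seed), {
    chunk <- max(1L, min(replicates, as.integer(2e7) %/% depth))
    done <- 0L
    while (done < replicates) {
      nrep <- min(chunk, replicates - done)
      draws <- sample.int(pool_size, nrep * depth, replace = TRUE)
      rep_id <- rep.int(seq_len(nrep), rep(depth, nrep))
      # distinct count = first occurrences of (replicate, individual) pairs
      dup <- duplicated(as.numeric(rep_id) * pool_size + draws)
      counts[done + seq_len(nrep)] <- tabulate(rep_id[!dup], nrep)
      done <- done + nrep
    }
  })
  kmax <- min(pool_size, depth)
  hist <- tabulate(counts, kmax)
  probs_lo <- if (side == "two") (1 - ci_level) / 2 else 1 - ci_level
  qs <- quantile(counts, c(probs_lo, 0.05, 0.25, 0.5, 0.75, 0.95), type = 1L)
  structure(
    list(mean = mean(counts),
         lower = unname(qs[1L]),
         expected_mean = pool_size * (1 - (1 - 1 / pool_size)^depth),
         quantiles = qs,
         histogram = tibble(k = seq_len(kmax), count = hist,
                            prop = hist / replicates),
         params = list(pool_size = pool_size, depth = depth,
                       replicates = replicates, ci_level = ci_level,
                       side = side, seed = seed)),
    class = "depth_calibration"
  )
}

#' @export
print.depth_calibration <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("depth calibration: pool of %d at depth %d (%d replicates)\n",
                     "  mean distinct individuals %.3f (closed form %.3f)\n",
                     "  lower %s%% bound: %d\n"),
              p$pool_size, p$depth, p$replicates, x$mean, x$expected_mean,
              format(100 * p$ci_level), x$lower))
  invisible(x)
}

#' Smallest read depth that represents a target fraction of the pool
#'
#' Increasing search over candidate depths: the chosen depth is the
#' smallest whose lower confidence bound on distinct individuals (from
#' [distinct_individuals()]) reaches `ceiling(target_fraction * pool_size)`.
#'
#' @param pool_size Individuals in the pool.
#' @param target_fraction Fraction of the pool that must be represented at
#'   the lower bound (default 0.5, i.e. half of all possible genotypes).
#' @param ci_level,side Confidence bound settings, as in
#'   [distinct_individuals()].
#' @param replicates Replicates per candidate depth (default 1e5).
#' @param max_depth Search cap; exceeded search is a configuration error.
#' @param seed Integer seed.
#' @return A list with `depth` (the chosen minimum), `target` (individuals
#'   required) and `evaluations` (tibble of `depth`, `lower`, `mean`).
#' @export
choose_min_depth <- function(pool_size, target_fraction = 0.5,
                             ci_level = 0.95, side = c("two", "one"),
                             replicates = 1e5, max_depth = 100 * pool_size,
                             seed = 1L) {
  pool_size <- assert_count(pool_size, "pool_size")
  side <- match.arg(side)
  if (target_fraction <= 0 || target_fraction > 1) {
    stop_config("`target_fraction` must be in (0, 1]")
  }
  target <- as.integer(ceiling(target_fraction * pool_size))
  if (target > pool_size) stop_config("target exceeds pool size")
  evals <- list()
  for (d in seq_len(max_depth)) {
    r <- distinct_individuals(pool_size, d, replicates = replicates,
                              ci_level = ci_level, side = side,
                              seed = seed + d)
    evals[[d]] <- tibble(depth = d, lower = r$lower, mean = r$mean)
    if (r$lower >= target) {
      return(list(depth = d, target = target,
                  evaluations = do.call(rbind, evals)))
    }
  }
  stop_config("no depth up to ", max_depth, " reaches the target")
}
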