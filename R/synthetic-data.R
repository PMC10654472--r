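# Synthetic-data generators. Both tracks of the analysis are developed and
# validated against simulated inputs with known ground truth: individual
# genotype tables for the gene-level track and per-position pooled base
# counts (plus a gene annotation and a truth table) for the Pool-Seq track.

#' Simulate an individual-level genotype table
#'
#' Draws Hardy-Weinberg genotypes for every individual of a sampling design.
#' Wild populations share the supplied wild allele frequency; farmed
#' populations either share a fixed frequency or (default) receive an
#' independently drifted frequency from a Wright-Fisher bottleneck pass, so
#' that farmed-vs-wild differences under the null carry realistic drift
#' noise.
#'
#' @param design A data frame with columns `population`, `origin`
#'   (`farmed`/`wild`), `period` and `n` (diploid individuals), e.g. from
#'   [gene_sampling_design()]. Rows with `n = 0` are dropped.
#' @param wild_freq Frequency of the variant allele (`alleles[2]`) in wild
#'   populations, in \[0, 1\].
#' @param farmed_freq Either a frequency in \[0, 1\] shared by all farmed
#'   populations, or `"drift"` (default) to derive each farmed population's
#'   frequency from `wild_freq` through [wf_trajectory()].
#' @param locus Locus identifier written to the table.
#' @param alleles Length-2 character vector; `alleles[1]` is the reference
#'   allele, `alleles[2]` the variant whose frequency is simulated. With
#'   `wild_freq = 0` every genotype is homozygous reference.
#' @param nb,generations Bottleneck demography used when
#'   `farmed_freq = "drift"`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A tibble with one row per individual x locus: `individual`,
#'   `population`, `origin`, `period`, `locus`, `allele1`, `allele2`.
#' @examples
#' g <- simulate_genotypes(gene_sampling_design("seabream", "vgll3"),
#'                         wild_freq = 0.35, seed = 7)
#' nrow(g)  # 91
#' @export
simulate_genotypes <- function(design, wild_freq, farmed_freq = "drift",
                               locus = "locus1", alleles = c("A", "a"),
                               nb = 100, generations = 8, seed = 1L) {
  need <- c("population", "origin", "period", "n")
  if (!all(need %in% names(design))) {
    stop_config("`design` needs columns ", paste(need, collapse = ", "))
  }
  if (!all(design$origin %in% c("farmed", "wild"))) {
    stop_config("`origin` must be 'farmed' or 'wild'")
  }
  assert_prob(wild_freq, "wild_freq")
  drift <- identical(farmed_freq, "drift")
  if (!drift) assert_prob(farmed_freq, "farmed_freq")
  if (length(alleles) != 2L || anyDuplicated(alleles)) {
    stop_config("`alleles` must be two distinct symbols")
  }
  design <- design[design$n > 0, , drop = FALSE]
  if (nrow(design) == 0L) stop_config("design has no individuals")

  with_seed(as.integer(seed), {
    pfreq <- ifelse(design$origin == "wild", wild_freq,
                    if (drift) NA_real_ else farmed_freq)
    if (drift) {
      farmed_rows <- which(design$origin == "farmed")
      pfreq[farmed_rows] <- wf_trajectory(rep(wild_freq, length(farmed_rows)),
                                          nb = nb, generations = generations)
    }
    rows <- lapply(seq_len(nrow(design)), function(i) {
      n <- design$n[i]
      a1 <- alleles[1L + rbinom(n, 1L, pfreq[i])]
      a2 <- alleles[1L + rbinom(n, 1L, pfreq[i])]
      tibble(
        individual = sprintf("%s_ind%02d", design$population[i], seq_len(n)),
        population = design$population[i],
        origin = design$origin[i],
        period = design$period[i],
        locus = locus,
        allele1 = a1,
        allele2 = a2
      )
    })
    do.call(rbind, rows)
  })
}

#' Configuration for the Pool-Seq simulator
#'
#' Bundles and validates the parameters of [simulate_poolseq()]. Defaults
#' describe one chromosome scanned at the scale used throughout the package:
#' 20,000 SNPs over 20 Mbp, pools of 25 diploids sequenced to a mean depth
#' of 60 reads with negative-binomial overdispersion.
#'
#' @param chrom Chromosome name written to all outputs.
#' @param chrom_length Chromosome length in bp.
#' @param n_snps Number of segregating sites to place (uniform positions
#'   without replacement, sorted).
#' @param pools A data frame with columns `pool_id`, `origin`
#'   (`farmed`/`wild`), `n_individuals`, `n_replicates`; defaults to
#'   [make_pools()] with 4 farmed and 4 wild pools of 25.
#' @param mean_depth,depth_dispersion Mean and dispersion (negative-binomial
#'   `size`) of the per-pool, per-site read depth.
#' @param wild_freq_prior Beta shape parameters `c(a, b)` for the wild
#'   allele-frequency spectrum.
#' @param selected_region `NULL`, or `c(start, end, delta)`: variant
#'   frequencies of farmed pools inside `[start, end]` (bp, 1-based
#'   inclusive) are shifted by `delta` away from the wild value (toward the
#'   more distant boundary), emulating a selected domestication region.
#' @param farmed_null `"drift"` (default) passes farmed frequencies outside
#'   the selected region through one Wright-Fisher bottleneck
#'   ([wf_trajectory()], shared by all farmed pools); `"identical"` copies
#'   the wild frequency exactly, for pure-null experiments.
#' @param nb,generations Bottleneck demography for `farmed_null = "drift"`.
#' @param n_genes,gene_length Number and length of uniformly placed gene
#'   models emitted in the annotation.
#' @param seed Integer seed.
#' @return A validated list of class `poolseq_config`.
#' @export
poolseq_config <- function(chrom = "chr1", chrom_length = 2e7, n_snps = 2e4,
                           pools = make_pools(), mean_depth = 60,
                           depth_dispersion = 5,
                           wild_freq_prior = c(0.8, 0.8),
                           selected_region = NULL,
                           farmed_null = c("drift", "identical"),
                           nb = 100, generations = 8,
                           n_genes = 25, gene_length = 2e4, seed = 1L) {
  assert_count(chrom_length, "chrom_length")
  assert_count(n_snps, "n_snps")
  if (n_snps > chrom_length) stop_config("more SNPs than positions")
  need <- c("pool_id", "origin", "n_individuals", "n_replicates")
  if (!all(need %in% names(pools))) {
    stop_config("`pools` needs columns ", paste(need, collapse = ", "))
  }
  if (!all(pools$origin %in% c("farmed", "wild"))) {
    stop_config("pool `origin` must be 'farmed' or 'wild'")
  }
  assert_count(pools$n_individuals, "n_individuals")
  assert_count(pools$n_replicates, "n_replicates")
  if (anyDuplicated(pools$pool_id)) stop_config("duplicate pool ids")
  if (mean_depth < 0 || depth_dispersion <= 0) {
    stop_config("depth parameters must be non-negative (dispersion > 0)")
  }
  if (length(wild_freq_prior) != 2L || any(wild_freq_prior <= 0)) {
    stop_config("`wild_freq_prior` must be two positive Beta shapes")
  }
  if (!is.null(selected_region)) {
    if (length(selected_region) != 3L) {
      stop_config("`selected_region` must be c(start, end, delta)")
    }
    if (selected_region[1] < 1 || selected_region[2] > chrom_length ||
        selected_region[1] > selected_region[2]) {
      stop_config("selected region outside [1, chrom_length]")
    }
    assert_prob(selected_region[3], "delta")
  }
  structure(
    list(chrom = chrom, chrom_length = as.integer(chrom_length),
         n_snps = as.integer(n_snps), pools = as_tibble(pools),
         mean_depth = mean_depth, depth_dispersion = depth_dispersion,
         wild_freq_prior = wild_freq_prior, selected_region = selected_region,
         farmed_null = match.arg(farmed_null), nb = nb,
         generations = generations, n_genes = as.integer(n_genes),
         gene_length = as.integer(gene_length), seed = as.integer(seed)),
    class = "poolseq_config"
  )
}

#' Build a balanced pool table
#'
#' @param n_farmed,n_wild Number of farmed and wild pools.
#' @param n_individuals Diploid individuals per pool.
#' @param n_replicates Technical replicate libraries per pool.
#' @return A tibble suitable for the `pools` field of [poolseq_config()].
#' @export
make_pools <- function(n_farmed = 4, n_wild = 4, n_individuals = 25,
                       n_replicates = 2) {
  tibble(
    pool_id = c(sprintf("farm%02d", seq_len(n_farmed)),
                sprintf("wild%02d", seq_len(n_wild))),
    origin = rep(c("farmed", "wild"), c(n_farmed, n_wild)),
    n_individuals = n_individuals,
    n_replicates = n_replicates
  )
}

#' Simulate a Pool-Seq experiment with known truth
#'
#' Per SNP: the wild variant frequency is drawn from the Beta prior; the
#' farmed frequency equals the wild one passed through the configured null
#' (drift or identity), except inside the selected region where it is
#' shifted by `delta` away from the wild value. Each pool then samples
#' `2 * n_individuals` chromosomes binomially, a read depth is drawn from
#' the negative-binomial depth model, and variant read counts are binomial
#' at the pool's chromosome frequency. Technical replicates partition the
#' pool's reads (uniform assignment, hypergeometric allele split), so
#' replicate depths always sum to the pool depth.
#'
#' @param config A [poolseq_config()] object.
#' @return An object of class `poolseq_sim`: a list with
#'   \describe{
#'     \item{truth}{tibble of `chrom`, `pos`, `ref`, `alt`, `wild_freq`,
#'       `farmed_freq`, `in_selected_region` (one row per SNP).}
#'     \item{counts}{named list, one tibble of per-position base counts
#'       (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`) per pool x replicate,
#'       named `<pool_id>.rep<k>`.}
#'     \item{genes}{tibble of simulated gene models (`chrom`, `start`,
#'       `end`, `strand`, `gene_id`, `gene_name`).}
#'     \item{pools, config}{the pool table and the generating config.}
#'   }
#' @examples
#' sim <- simulate_poolseq(poolseq_config(n_snps = 100, seed = 3))
#' names(sim$counts)[1:2]
#' @export
simulate_poolseq <- function(config) {
  if (!inherits(config, "poolseq_config")) {
    stop_config("`config` must come from poolseq_config()")
  }
  cf <- config
  bases <- c("A", "C", "G", "T")
  with_seed(cf$seed, {
    n <- cf$n_snps
    pos <- sort(sample.int(cf$chrom_length, n))
    ref_i <- sample.int(4L, n, replace = TRUE)
    alt_i <- 1L + (ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L

    pw <- rbeta(n, cf$wild_freq_prior[1], cf$wild_freq_prior[2])
    pf <- if (cf$farmed_null == "drift") {
      wf_trajectory(pw, nb = cf$nb, generations = cf$generations)
    } else {
      pw
    }
    in_region <- rep(FALSE, n)
    if (!is.null(cf$selected_region)) {
      sr <- cf$selected_region
      in_region <- pos >= sr[1] & pos <= sr[2]
      # shift toward the more distant boundary so |farmed - wild| = delta
      shifted <- ifelse(pw[in_region] <= 0.5,
                        pw[in_region] + sr[3], pw[in_region] - sr[3])
      pf[in_region] <- pmin(1, pmax(0, shifted))
    }
    truth <- tibble(chrom = cf$chrom, pos = pos,
                    ref = bases[ref_i], alt = bases[alt_i],
                    wild_freq = pw, farmed_freq = pf,
                    in_selected_region = in_region)

    counts <- list()
    for (i in seq_len(nrow(cf$pools))) {
      pool <- cf$pools[i, ]
      p <- if (pool$origin == "farmed") pf else pw
      chroms <- 2L * pool$n_individuals
      p_pool <- rbinom(n, chroms, p) / chroms          # pool chromosome freq
      depth <- rnbinom(n, size = cf$depth_dispersion, mu = cf$mean_depth)
      alt_reads <- rbinom(n, depth, p_pool)
      ref_reads <- depth - alt_reads
      # partition reads over replicates; allele split is hypergeometric
      d_left <- depth
      a_left <- alt_reads
      for (r in seq_len(pool$n_replicates)) {
        if (r < pool$n_replicates) {
          d_r <- rbinom(n, d_left, 1 / (pool$n_replicates - r + 1L))
        } else {
          d_r <- d_left
        }
        a_r <- rhyper(n, a_left, d_left - a_left, d_r)
        mat <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
        idx <- cbind(seq_len(n), ref_i)
        mat[idx] <- d_r - a_r
        idx_alt <- cbind(seq_len(n), alt_i)
        mat[idx_alt] <- mat[idx_alt] + a_r              # ref == alt impossible
        counts[[sprintf("%s.rep%d", pool$pool_id, r)]] <-
          tibble(chrom = cf$chrom, pos = pos, ref = bases[ref_i],
                 A = mat[, "A"], C = mat[, "C"], G = mat[, "G"], T = mat[, "T"])
        d_left <- d_left - d_r
        a_left <- a_left - a_r
      }
    }

    starts <- sort(sample.int(max(1L, cf$chrom_length - cf$gene_length),
                              cf$n_genes))
    genes <- tibble(chrom = cf$chrom, start = starts,
                    end = pmin(cf$chrom_length, starts + cf$gene_length - 1L),
                    strand = sample(c("+", "-"), cf$n_genes, replace = TRUE),
                    gene_id = sprintf("gene%03d", seq_len(cf$n_genes)),
                    gene_name = sprintf("g%03d", seq_len(cf$n_genes)))

    structure(list(truth = truth, counts = counts, genes = genes,
                   pools = cf$pools, config = cf),
              class = "poolseq_sim")
  })
}

#' @export
print.poolseq_sim <- function(x, ...) {
  cat("Pool-Seq simulation:", nrow(x$truth), "SNPs on", x$config$chrom,
      "|", nrow(x$pools), "pools,", length(x$counts), "libraries\n")
  invisible(x)
}

#' Write a simulated Pool-Seq experiment to disk
#'
#' Writes per-library pileup files (readcount and/or sync dialect, see
#' [read_pileup()]), the truth table and library manifest as TSV, and the
#' gene models as GFF3.
#'
#' @param sim A [simulate_poolseq()] result.
#' @param dir Output directory (created if missing).
#' @param dialect `"readcount"`, `"sync"` or `"both"`.
#' @return Invisibly, a tibble manifest of the written pileup files
#'   (`pool_id`, `replicate`, `origin`, `file`).
#' @export
write_poolseq_sim <- function(sim, dir, dialect = c("readcount", "sync", "both")) {
  dialect <- match.arg(dialect)
  if (!inherits(sim, "poolseq_sim")) stop_config("not a poolseq_sim")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- strsplit(names(sim$counts), ".rep", fixed = TRUE)
  manifest <- tibble(
    pool_id = vapply(lib, `[`, character(1), 1L),
    replicate = as.integer(vapply(lib, `[`, character(1), 2L)),
    file = NA_character_
  )
  manifest$origin <- sim$pools$origin[match(manifest$pool_id, sim$pools$pool_id)]
  for (i in seq_along(sim$counts)) {
    if (dialect %in% c("readcount", "both")) {
      f <- file.path(dir, paste0(names(sim$counts)[i], ".readcount.tsv"))
      write_pileup(sim$counts[[i]], f, dialect = "readcount")
      manifest$file[i] <- f
    }
    if (dialect %in% c("sync", "both")) {
      f <- file.path(dir, paste0(names(sim$counts)[i], ".sync"))
      write_pileup(sim$counts[[i]], f, dialect = "sync")
      if (is.na(manifest$file[i])) manifest$file[i] <- f
    }
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(manifest[, c("pool_id", "replicate", "origin", "file")],
              file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gene_annotation(sim$genes, file.path(dir, "genes.gff3"))
  invisible(manifest)
}
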