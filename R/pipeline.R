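# End-to-end runs: gene-level report and chromosome-level scan. Both write
# machine-readable outputs with a metadata block (package version, seed,
# config hash), so identical config + seed reproduce byte-identical
# reports.

#' Run the gene-level analysis end to end
#'
#' Computes per-population frequencies, the farmed-vs-wild Wilcoxon test,
#' Hardy-Weinberg checks per origin group, the binomial GLM with stepwise
#' AIC selection, and the bottleneck false-positive-rate null for every
#' locus of a genotype table, and writes one JSON report.
#'
#' @param genotypes A genotype table tibble or the path of a genotype TSV
#'   (see [read_genotypes()]).
#' @param out_dir Output directory; `report.json` is written there.
#' @param hwe `"exact"` or `"chisq"` ([hwe_test()]).
#' @param wilcoxon_on `"allele"` tests per-population variant-allele
#'   frequencies; `"genotype"` tests each genotype class's frequency.
#' @param bottleneck Named list of overrides for [bottleneck_fpr()]
#'   (`nb`, `generations`, `replicates`, `alpha`, ...); sample sizes
#'   default to the observed farmed/wild totals.
#' @param seed Integer seed for the bottleneck simulation.
#' @return The report, invisibly (a nested list mirroring the JSON).
#' @export
run_gene_level <- function(genotypes, out_dir = NULL,
                           hwe = c("exact", "chisq"),
                           wilcoxon_on = c("allele", "genotype"),
                           bottleneck = list(), seed = 1L) {
  hwe <- match.arg(hwe)
  wilcoxon_on <- match.arg(wilcoxon_on)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  freqs <- compute_frequencies(genotypes)
  loci <- unique(genotypes$locus)
  config <- list(hwe = hwe, wilcoxon_on = wilcoxon_on,
                 bottleneck = bottleneck, seed = as.integer(seed))

  per_locus <- lapply(loci, function(loc) {
    al <- freqs$alleles[freqs$alleles$locus == loc, ]
    gt <- freqs$genotypes[freqs$genotypes$locus == loc, ]
    agg <- aggregate_allele_counts(genotypes, loc)
    variant <- setdiff(unique(al$allele), agg$reference_allele)
    # per-population variant-allele frequency (0 where absent)
    pops <- unique(al[, c("population", "origin")])
    vfreq <- vapply(seq_len(nrow(pops)), function(i) {
      r <- al[al$population == pops$population[i] & al$allele %in% variant, ]
      sum(r$freq)
    }, numeric(1))
    wil <- if (wilcoxon_on == "allele") {
      list(allele = wilcoxon_origin_test(vfreq, pops$origin)$p.value)
    } else {
      gts <- sort(unique(gt$genotype))
      setNames(lapply(gts, function(gg) {
        f <- vapply(seq_len(nrow(pops)), function(i) {
          r <- gt[gt$population == pops$population[i] & gt$genotype == gg, ]
          if (nrow(r)) r$freq[1L] else 0
        }, numeric(1))
        wilcoxon_origin_test(f, pops$origin)$p.value
      }), gts)
    }
    hwe_by_origin <- lapply(c(farmed = "farmed", wild = "wild"), function(o) {
      sub <- genotypes[genotypes$locus == loc & genotypes$origin == o, ]
      het <- sum(sub$allele1 != sub$allele2)
      hom_ref <- sum(sub$allele1 == agg$reference_allele &
                     sub$allele2 == agg$reference_allele)
      hom_alt <- nrow(sub) - het - hom_ref
      if (nrow(sub) == 0L) return(NULL)
      t <- hwe_test(hom_ref, het, hom_alt, method = hwe)
      list(p_value = t$p.value, n = nrow(sub), method = t$method)
    })
    sel <- stepwise_aic(genotypes, loc)
    coefs <- summary(sel$selected$fit)$coefficients
    origin_p <- if ("originwild" %in% rownames(coefs)) {
      unname(coefs["originwild", "Pr(>|z|)"])
    } else NA_real_
    wild_freq <- {
      wrows <- al[al$origin == "wild" & al$allele %in% variant, ]
      sum(wrows$count) / sum(al$count[al$origin == "wild"])
    }
    bt_args <- c(list(wild_freq = setNames(wild_freq, loc),
                      farmed_n = sum(genotypes$origin == "farmed" &
                                     genotypes$locus == loc),
                      wild_n = sum(genotypes$origin == "wild" &
                                   genotypes$locus == loc),
                      seed = seed),
                 bottleneck)
    bt <- do.call(bottleneck_fpr, bt_args)
    list(
      locus = loc,
      reference_allele = agg$reference_allele,
      frequencies = list(alleles = al, populations = nrow(pops)),
      wilcoxon = wil,
      hwe = hwe_by_origin,
      model_selection = list(
        selected = sel$selected_model,
        aic = sel$selected$aic,
        origin_p = origin_p,
        trace = sel$trace
      ),
      bottleneck_fpr = bt$fpr[, c("alpha", "fpr")]
    )
  })
  report <- list(
    metadata = run_metadata(config),
    n_individuals = length(unique(genotypes$individual)),
    loci = setNames(per_locus, loci)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Run the chromosome-level Pool-Seq scan end to end
#'
#' Reads per-library pileups, merges technical replicates per pool, calls
#' biallelic SNPs under the depth and MAF filters, computes the per-SNP
#' differentiation statistics, the rolling track and the peak report with
#' neighbouring genes, and writes `snp_stats.tsv`, `rolling_track.tsv`,
#' `peaks.bed` (0-based half-open) and `report.json`. Stage counters
#' (input sites, surviving the depth filter, biallelic after the MAF
#' filter) are logged and recorded; they are non-increasing by
#' construction.
#'
#' @param manifest Library manifest: tibble or TSV path with columns
#'   `pool_id`, `replicate`, `origin`, `file`.
#' @param gff Optional GFF3 path (or gene tibble) for peak annotation.
#' @param out_dir Output directory.
#' @param dialect Pileup dialect of the manifest files.
#' @param min_depth,min_maf SNP-calling filters ([call_biallelic()]).
#' @param window Rolling window in SNPs.
#' @param flank Gene-annotation half-window in bp.
#' @param alpha Significance level for the peak report.
#' @param stat Per-SNP statistic for track and peak (default `"fst"`).
#' @param seed Recorded in the metadata (the scan itself is
#'   deterministic).
#' @return Invisibly, a list with `stats`, `track`, `peak`, `counters` and
#'   `report`.
#' @export
run_scan <- function(manifest, gff = NULL, out_dir = NULL,
                     dialect = c("readcount", "sync"),
                     min_depth = 25, min_maf = 0.01, window = 5000,
                     flank = 50000, alpha = 0.05, stat = "fst", seed = 1L) {
  dialect <- match.arg(dialect)
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop_config("file not found: ", manifest)
    manifest <- as_tibble(read.delim(manifest, colClasses = "character"))
    manifest$replicate <- as.integer(manifest$replicate)
  }
  need <- c("pool_id", "origin", "file")
  if (!all(need %in% names(manifest))) {
    stop_config("manifest needs columns ", paste(need, collapse = ", "))
  }
  missing <- manifest$file[!file.exists(manifest$file)]
  if (length(missing)) stop_config("pileup file(s) not found: ",
                                   paste(missing, collapse = ", "))
  config <- list(dialect = dialect, min_depth = min_depth, min_maf = min_maf,
                 window = window, flank = flank, alpha = alpha, stat = stat,
                 seed = as.integer(seed))

  pools <- split(manifest, manifest$pool_id)
  pool_counts <- lapply(pools, function(m) {
    merge_replicates(lapply(m$file, read_pileup, dialect = dialect))
  })
  origins <- vapply(pools, function(m) m$origin[1L], character(1))

  bset <- call_biallelic(pool_counts, min_depth = min_depth, min_maf = min_maf)
  counters <- list(input_sites = bset$n_input_sites,
                   depth_pass = bset$n_depth_pass,
                   biallelic = nrow(bset$sites))
  message("scan: ", counters$input_sites, " sites -> ",
          counters$depth_pass, " pass depth >= ", min_depth, " -> ",
          counters$biallelic, " biallelic SNPs")

  if (nrow(bset$sites) == 0L) {
    stats <- tibble()
    track <- tibble()
    peak <- find_peaks(tibble(pos = integer(), value = numeric()), tibble())
  } else {
    stats <- scan_statistics(bset, origins)
    track <- rolling_track(stats, stat = stat, window = window)
    peak <- find_peaks(track, stats, stat = stat, window = window,
                       alpha = alpha)
    if (!is.null(gff) && !is.na(peak$peak_pos)) {
      peak$genes <- genes_near(gff, stats$chrom[1L], peak$peak_pos,
                               flank = flank)
    }
  }
  report <- list(
    metadata = run_metadata(config),
    counters = counters,
    peak = list(window_pos = peak$window_pos,
                window_value = peak$window_value,
                peak_pos = peak$peak_pos, peak_stat = peak$peak_stat,
                peak_padj = peak$peak_padj, stars = peak$stars,
                genes = if (nrow(peak$genes)) peak$genes$gene_id else
                  character())
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (nrow(stats)) {
      write.table(stats, file.path(out_dir, "snp_stats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(track, file.path(out_dir, "rolling_track.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    bed <- if (!is.na(peak$peak_pos)) {
      sprintf("%s\t%d\t%d\tpeak\t%g", stats$chrom[1L], peak$peak_pos - 1L,
              peak$peak_pos, peak$peak_stat)
    } else character()
    writeLines(bed, file.path(out_dir, "peaks.bed"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(stats = stats, track = track, peak = peak,
                 counters = counters, report = report))
}

# Metadata block shared by both pipelines: version, seed, config hash.
run_metadata <- function(config) {
  list(package = "domescan",
       version = as.character(packageVersion("domescan")),
       seed = config$seed,
       config_hash = rlang::hash(config))
}

#' Read a pipeline configuration file
#'
#' YAML (if the yaml package is installed) with JSON fallback; the result
#' is a plain named list of arguments for [run_gene_level()] / [run_scan()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_config("yaml package required for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
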