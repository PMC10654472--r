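# Ingestion of pooled per-position base counts and biallelic SNP calling.
#
# Two plain-text pileup dialects are supported:
#   * "readcount": tab-separated `chrom pos ref depth base:count[:...]`
#     tokens, one library per file (the bam-readcount summary layout; any
#     per-base fields after the count are ignored);
#   * "sync": the PoPoolation2 synchronised format, `chrom pos ref` followed
#     by one `A:T:C:G:N:del` column per library.
# Coordinates are 1-based inclusive throughout.

SYNC_ORDER <- c("A", "T", "C", "G", "N", "del")

#' Read a pooled pileup file
#'
#' @param path Path to a pileup file.
#' @param dialect `"readcount"` or `"sync"` (see the format notes above).
#' @return A tibble of per-position base counts with columns `chrom`, `pos`,
#'   `ref`, `pool` (the sync column index; always 1 for readcount files),
#'   `A`, `C`, `G`, `T`, `N`, `del`. `N` and deletion counts are parsed but
#'   excluded from allele calling downstream. Positions must be sorted
#'   within each chromosome; malformed lines raise a parse error carrying
#'   the line number.
#' @examples
#' f <- tempfile()
#' writeLines("chr1\t100\tA\t30\tA:28\tC:2", f)
#' read_pileup(f, "readcount")
#' @export
read_pileup <- function(path, dialect = c("readcount", "sync")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_config("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  pool = integer(), A = integer(), C = integer(),
                  G = integer(), T = integer(), N = integer(),
                  del = integer()))
  }
  toks <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(toks)
  minf <- if (dialect == "readcount") 5L else 4L
  bad <- which(nf < minf)
  if (length(bad)) stop_parse("malformed line ", bad[1L], " in ", path)
  chrom <- vapply(toks, `[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(toks, `[`, character(1), 2L)))
  if (anyNA(pos) || any(pos < 1L)) {
    stop_parse("non-positive or non-integer position at line ",
               which(is.na(pos) | pos < 1L)[1L], " in ", path)
  }
  ref <- toupper(vapply(toks, `[`, character(1), 3L))
  unsorted <- which(chrom[-1L] == chrom[-length(chrom)] & diff(pos) < 0)
  if (length(unsorted)) {
    stop_parse("unsorted input at line ", unsorted[1L] + 1L, " in ", path)
  }

  if (dialect == "readcount") {
    n <- length(lines)
    out <- matrix(0L, n, 6L, dimnames = list(NULL, SYNC_ORDER))
    for (i in seq_len(n)) {
      for (tok in toks[[i]][-(1:4)]) {
        parts <- strsplit(tok, ":", fixed = TRUE)[[1L]]
        if (length(parts) < 2L) stop_parse("malformed base token at line ", i,
                                           " in ", path)
        base <- toupper(parts[1L])
        cnt <- suppressWarnings(as.integer(parts[2L]))
        if (is.na(cnt) || cnt < 0L) {
          stop_parse("malformed count at line ", i, " in ", path)
        }
        if (base %in% c("A", "C", "G", "T", "N")) {
          out[i, base] <- out[i, base] + cnt
        } else if (grepl("^[-+]", base)) {
          out[i, "del"] <- out[i, "del"] + cnt      # indel allele
        }                                           # else: ignored field
      }
    }
    tibble(chrom = chrom, pos = pos, ref = ref, pool = 1L,
           A = as.integer(out[, "A"]), C = as.integer(out[, "C"]),
           G = as.integer(out[, "G"]), T = as.integer(out[, "T"]),
           N = as.integer(out[, "N"]), del = as.integer(out[, "del"]))
  } else {
    npool <- nf[1L] - 3L
    if (any(nf != nf[1L])) {
      stop_parse("inconsistent column count at line ", which(nf != nf[1L])[1L],
                 " in ", path)
    }
    res <- vector("list", npool)
    for (j in seq_len(npool)) {
      cells <- vapply(toks, `[`, character(1), 3L + j)
      parts <- strsplit(cells, ":", fixed = TRUE)
      if (any(lengths(parts) != 6L)) {
        stop_parse("malformed sync column at line ",
                   which(lengths(parts) != 6L)[1L], " in ", path)
      }
      m <- matrix(suppressWarnings(as.integer(unlist(parts))),
                  ncol = 6L, byrow = TRUE, dimnames = list(NULL, SYNC_ORDER))
      if (anyNA(m) || any(m < 0L)) {
        stop_parse("malformed count in sync column ", j, " of ", path)
      }
      res[[j]] <- tibble(chrom = chrom, pos = pos, ref = ref, pool = j,
                         A = as.integer(m[, "A"]), C = as.integer(m[, "C"]),
                         G = as.integer(m[, "G"]), T = as.integer(m[, "T"]),
                         N = as.integer(m[, "N"]), del = as.integer(m[, "del"]))
    }
    do.call(rbind, res)
  }
}

#' Write per-position base counts to a pileup file
#'
#' @param sites A tibble with columns `chrom`, `pos`, `ref`, `A`, `C`, `G`,
#'   `T` (and optionally `N`, `del`, both defaulting to 0).
#' @param path Output path.
#' @param dialect `"readcount"` or `"sync"`; see [read_pileup()].
#' @return `path`, invisibly.
#' @export
write_pileup <- function(sites, path, dialect = c("readcount", "sync")) {
  dialect <- match.arg(dialect)
  nn <- if ("N" %in% names(sites)) sites$N else rep(0L, nrow(sites))
  dd <- if ("del" %in% names(sites)) sites$del else rep(0L, nrow(sites))
  if (dialect == "readcount") {
    depth <- sites$A + sites$C + sites$G + sites$T + nn + dd
    lines <- sprintf("%s\t%d\t%s\t%d\tA:%d\tC:%d\tG:%d\tT:%d\tN:%d",
                     sites$chrom, sites$pos, sites$ref, depth,
                     sites$A, sites$C, sites$G, sites$T, nn)
  } else {
    lines <- sprintf("%s\t%d\t%s\t%d:%d:%d:%d:%d:%d",
                     sites$chrom, sites$pos, sites$ref,
                     sites$A, sites$T, sites$C, sites$G, nn, dd)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Merge technical replicates of one pool
#'
#' Outer-joins replicate count tables on (chrom, pos) and sums the
#' per-base counts, mirroring the merge of replicate libraries before
#' genotyping. The operation is commutative and conserves total reads.
#'
#' @param ... Count tibbles as returned by [read_pileup()] (the `pool`
#'   column, if present, is ignored), or a single list of them.
#' @return One merged tibble sorted by `chrom`, `pos`.
#' @export
merge_replicates <- function(...) {
  reps <- list(...)
  if (length(reps) == 1L && is.list(reps[[1L]]) && !is.data.frame(reps[[1L]])) {
    reps <- reps[[1L]]
  }
  if (length(reps) == 0L) stop_config("no replicates supplied")
  all <- do.call(rbind, lapply(reps, function(x) {
    if (!"N" %in% names(x)) x$N <- 0L
    if (!"del" %in% names(x)) x$del <- 0L
    x[, c("chrom", "pos", "ref", "A", "C", "G", "T", "N", "del")]
  }))
  key <- paste(all$chrom, all$pos, sep = "\r")
  ref_by_key <- tapply(all$ref, key, function(r) length(unique(r)))
  if (any(ref_by_key > 1L)) {
    k <- names(ref_by_key)[ref_by_key > 1L][1L]
    stop_data("conflicting reference base at ", sub("\r", ":", k))
  }
  first <- !duplicated(key)
  sums <- rowsum(as.matrix(all[, c("A", "C", "G", "T", "N", "del")]),
                 group = key, reorder = FALSE)
  out <- tibble(chrom = all$chrom[first], pos = all$pos[first],
                ref = all$ref[first])
  out <- cbind(out, as_tibble(sums[match(key[first], rownames(sums)), ,
                                   drop = FALSE]))
  out <- as_tibble(out)
  out[order(out$chrom, out$pos), ]
}

#' Call biallelic SNPs across pools
#'
#' Applies the genotyping filters of the Pool-Seq track: a site is dropped
#' when any pool's read depth (A+C+G+T) is below `min_depth` (with
#' `depth_rule = "mask"`, only the under-covered pools are masked and the
#' site survives while at least one pool per origin can still be compared
#' downstream); base frequencies are computed from counts summed over all
#' retained pools (or per pool with `maf_scope = "per_pool"`, where a base
#' is retained if it reaches `min_maf` in at least one pool); bases below
#' the minor-allele-frequency cutoff are discarded as putative sequencing
#' errors; the site is emitted iff exactly two bases remain. The major
#' allele is the more frequent overall (ties broken alphabetically, with a
#' message). `N` and deletion counts never enter allele calling.
#'
#' @param pool_counts Named list of merged per-pool count tibbles (see
#'   [merge_replicates()]), all aligned on the same coordinate universe;
#'   positions missing from a pool count as depth 0 there.
#' @param min_depth Minimum per-pool read depth (default 25, the threshold
#'   supported by the resampling calibration in [distinct_individuals()]).
#' @param min_maf Minimum allele frequency (default 0.01).
#' @param maf_scope `"pooled"` (default) or `"per_pool"`.
#' @param depth_rule `"drop"` (default) or `"mask"`.
#' @return An object of class `biallelic_set`: list with `sites` (tibble
#'   `chrom`, `pos`, `ref`, `major`, `minor`), integer matrices `major` and
#'   `minor` of per-pool read counts (sites x pools, `NA` where masked),
#'   `pool_ids`, and `filters`.
#' @export
call_biallelic <- function(pool_counts, min_depth = 25, min_maf = 0.01,
                           maf_scope = c("pooled", "per_pool"),
                           depth_rule = c("drop", "mask")) {
  maf_scope <- match.arg(maf_scope)
  depth_rule <- match.arg(depth_rule)
  assert_count(min_depth, "min_depth")
  if (min_maf < 0 || min_maf >= 0.5) stop_config("`min_maf` must be in [0, 0.5)")
  if (is.null(names(pool_counts)) || !length(pool_counts)) {
    stop_config("`pool_counts` must be a named list of count tables")
  }
  npool <- length(pool_counts)
  keys <- lapply(pool_counts, function(x) paste(x$chrom, x$pos, sep = "\r"))
  ukey <- unique(unlist(keys))
  first_tab <- do.call(rbind, lapply(pool_counts, function(x) {
    tibble(chrom = x$chrom, pos = x$pos, ref = x$ref)
  }))
  meta <- first_tab[match(ukey, paste(first_tab$chrom, first_tab$pos, sep = "\r")), ]
  ord <- order(meta$chrom, meta$pos)
  meta <- meta[ord, ]
  ukey <- ukey[ord]
  ns <- length(ukey)

  bases <- c("A", "C", "G", "T")
  cnt <- array(0L, dim = c(ns, 4L, npool), dimnames = list(NULL, bases, NULL))
  for (j in seq_len(npool)) {
    idx <- match(keys[[j]], ukey)
    for (b in bases) cnt[idx, b, j] <- as.integer(pool_counts[[j]][[b]])
  }
  depth <- apply(cnt, c(1L, 3L), sum)
  under <- depth < min_depth
  if (depth_rule == "drop") {
    keep_site <- rowSums(under) == 0L
    mask <- matrix(FALSE, ns, npool)
  } else {
    mask <- under
    keep_site <- rowSums(!under) >= 2L
  }
  cnt_eff <- cnt
  for (j in seq_len(npool)) {
    if (any(mask[, j])) cnt_eff[mask[, j], , j] <- 0L
  }

  tot <- apply(cnt_eff, c(1L, 2L), sum)                  # sites x bases
  tot_depth <- rowSums(tot)
  freq <- tot / pmax(1L, tot_depth)
  retained <- if (maf_scope == "pooled") {
    freq >= min_maf & tot > 0L
  } else {
    per <- matrix(FALSE, ns, 4L, dimnames = list(NULL, bases))
    for (j in seq_len(npool)) {
      dj <- pmax(1L, depth[, j])
      fj <- cnt_eff[, , j] / dj
      per <- per | (fj >= min_maf & !mask[, j] & cnt_eff[, , j] > 0L)
    }
    per
  }
  biallelic <- rowSums(retained) == 2L
  keep <- keep_site & biallelic & tot_depth > 0L

  idx <- which(keep)
  n_out <- length(idx)
  major <- minor <- character(n_out)
  major_cnt <- minor_cnt <- matrix(NA_integer_, n_out, npool,
                                   dimnames = list(NULL, names(pool_counts)))
  n_ties <- 0L
  for (t in seq_along(idx)) {
    i <- idx[t]
    al <- bases[retained[i, ]]
    c1 <- tot[i, al[1L]]
    c2 <- tot[i, al[2L]]
    if (c1 == c2) n_ties <- n_ties + 1L                  # alphabetical major
    if (c2 > c1) al <- al[c(2L, 1L)]
    major[t] <- al[1L]
    minor[t] <- al[2L]
    major_cnt[t, ] <- ifelse(mask[i, ], NA_integer_, cnt[i, al[1L], ])
    minor_cnt[t, ] <- ifelse(mask[i, ], NA_integer_, cnt[i, al[2L], ])
  }
  if (n_ties > 0L) {
    message(n_ties, " site(s) with tied allele counts; major allele chosen ",
            "alphabetically")
  }
  structure(
    list(sites = tibble(chrom = meta$chrom[idx], pos = meta$pos[idx],
                        ref = meta$ref[idx], major = major, minor = minor),
         major = major_cnt, minor = minor_cnt,
         pool_ids = names(pool_counts),
         filters = list(min_depth = min_depth, min_maf = min_maf,
                        maf_scope = maf_scope, depth_rule = depth_rule),
         n_input_sites = ns,
         n_depth_pass = sum(keep_site)),
    class = "biallelic_set"
  )
}

#' @export
print.biallelic_set <- function(x, ...) {
  cat("biallelic_set:", nrow(x$sites), "SNPs x", length(x$pool_ids),
      "pools (min depth", x$filters$min_depth, ", MAF >=",
      x$filters$min_maf, ")\n")
  invisible(x)
}

#' Write / read a biallelic SNP table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `major`, `minor`, then one
#' `major:minor` count column per pool (`NA:NA` where masked).
#'
#' @param bset A `biallelic_set`.
#' @param path File path.
#' @return `write_biallelic()` returns `path` invisibly; `read_biallelic()`
#'   returns a `biallelic_set`.
#' @export
write_biallelic <- function(bset, path) {
  df <- bset$sites
  for (j in seq_along(bset$pool_ids)) {
    df[[bset$pool_ids[j]]] <- paste0(bset$major[, j], ":", bset$minor[, j])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biallelic
#' @export
read_biallelic <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  fixed <- c("chrom", "pos", "ref", "major", "minor")
  if (!all(fixed %in% names(df))) stop_parse("not a biallelic SNP table: ", path)
  pool_ids <- setdiff(names(df), fixed)
  n <- nrow(df)
  major <- minor <- matrix(NA_integer_, n, length(pool_ids),
                           dimnames = list(NULL, pool_ids))
  for (j in seq_along(pool_ids)) {
    parts <- strsplit(df[[pool_ids[j]]], ":", fixed = TRUE)
    major[, j] <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 1L)))
    minor[, j] <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2L)))
  }
  structure(
    list(sites = tibble(chrom = df$chrom, pos = as.integer(df$pos),
                        ref = df$ref, major = df$major, minor = df$minor),
         major = major, minor = minor, pool_ids = pool_ids,
         filters = NULL, n_input_sites = NA_integer_,
         n_depth_pass = NA_integer_),
    class = "biallelic_set"
  )
}
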