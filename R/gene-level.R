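# Gene-level track: per-population allele/genotype frequencies at
# candidate-gene SNPs, farmed-vs-wild Wilcoxon tests, Hardy-Weinberg
# checks, and binomial logistic models of origin and collection-period
# effects with stepwise AIC selection.

#' Per-population allele and genotype frequencies
#'
#' @param table A genotype table: one row per individual x locus with
#'   columns `individual`, `population`, `origin`, `period`, `locus`,
#'   `allele1`, `allele2` (see [simulate_genotypes()] or
#'   [read_genotypes()]).
#' @param alleles Optional declared allele set per locus (named list);
#'   genotypes using other symbols raise a data error. By default the
#'   observed alleles define the set.
#' @return A list of class `freq_table` with tibbles `alleles`
#'   (`population`, `origin`, `period`, `locus`, `allele`, `count`, `freq`,
#'   `n`) and `genotypes` (likewise with `genotype`, unordered `a/b`
#'   labels). Populations with no individuals at a locus are excluded with
#'   a warning.
#' @examples
#' g <- simulate_genotypes(gene_sampling_design("seabream", "vgll3"), 0.3,
#'                         seed = 1)
#' freqs <- compute_frequencies(g)
#' head(freqs$alleles)
#' @export
compute_frequencies <- function(table, alleles = NULL) {
  need <- c("individual", "population", "origin", "period", "locus",
            "allele1", "allele2")
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_data("empty genotype table")
  }
  if (!all(need %in% names(table))) {
    stop_data("genotype table needs columns ", paste(need, collapse = ", "))
  }
  if (!is.null(alleles)) {
    for (loc in names(alleles)) {
      obs <- unique(c(table$allele1[table$locus == loc],
                      table$allele2[table$locus == loc]))
      bad <- setdiff(obs, alleles[[loc]])
      if (length(bad)) {
        stop_data("unknown allele symbol(s) at ", loc, ": ",
                  paste(bad, collapse = ", "))
      }
    }
  }
  filtered <- is.na(table$allele1) | is.na(table$allele2) |
    table$allele1 == "" | table$allele2 == ""
  if (any(filtered)) {
    lost <- setdiff(unique(table$population[filtered]),
                    unique(table$population[!filtered]))
    if (length(lost)) {
      warning("population(s) empty after filtering, excluded: ",
              paste(lost, collapse = ", "))
    }
    table <- table[!filtered, , drop = FALSE]
    if (nrow(table) == 0L) stop_data("no genotypes left after filtering")
  }
  key <- interaction(table$population, table$locus, drop = TRUE)
  grp <- split(seq_len(nrow(table)), key)
  al_rows <- list()
  gt_rows <- list()
  for (g in grp) {
    sub <- table[g, ]
    n <- nrow(sub)
    a <- c(sub$allele1, sub$allele2)
    at <- table(a)
    gt <- table(paste(pmin(sub$allele1, sub$allele2),
                      pmax(sub$allele1, sub$allele2), sep = "/"))
    meta <- sub[1L, c("population", "origin", "period", "locus")]
    al_rows[[length(al_rows) + 1L]] <-
      tibble(meta, allele = names(at), count = as.integer(at),
             freq = as.integer(at) / (2 * n), n = n)
    gt_rows[[length(gt_rows) + 1L]] <-
      tibble(meta, genotype = names(gt), count = as.integer(gt),
             freq = as.integer(gt) / n, n = n)
  }
  structure(list(alleles = do.call(rbind, al_rows),
                 genotypes = do.call(rbind, gt_rows)),
            class = "freq_table")
}

#' Wilcoxon rank-sum test of farmed-vs-wild frequency differences
#'
#' Two-sided rank-sum test with populations as the sampling unit (each
#' population contributes one frequency). With a combined sample of at most
#' `exact_max` populations the permutation distribution of the midrank sum
#' is enumerated exactly (ties handled by midranks); larger samples use the
#' normal approximation with tie correction and continuity correction.
#'
#' @param x Per-population frequencies.
#' @param origin Origin label (`farmed`/`wild` or any two levels) per
#'   population.
#' @param exact_max Largest combined sample size for exact enumeration
#'   (default 12).
#' @return A list with `p.value`, `statistic` (rank sum of the first
#'   level's group) and `method`.
#' @examples
#' wilcoxon_origin_test(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9),
#'                      rep(c("farmed", "wild"), each = 3))$p.value  # 0.1
#' @export
wilcoxon_origin_test <- function(x, origin, exact_max = 12L) {
  if (length(x) != length(origin)) stop_config("lengths differ")
  keep <- !is.na(x) & !is.na(origin)
  x <- x[keep]
  origin <- as.character(origin)[keep]
  lev <- sort(unique(origin))
  if (length(lev) != 2L) stop_analysis("need exactly two non-empty groups")
  g1 <- x[origin == lev[1L]]
  g2 <- x[origin == lev[2L]]
  n1 <- length(g1)
  n2 <- length(g2)
  N <- n1 + n2
  r <- rank(c(g1, g2))
  w <- sum(r[seq_len(n1)])
  if (N <= exact_max) {
    sums <- combn(N, n1, FUN = function(i) sum(r[i]))
    p <- min(1, 2 * min(mean(sums <= w), mean(sums >= w)))
    method <- "exact midrank enumeration"
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation with tie correction"
  }
  list(p.value = p, statistic = w, method = method,
       groups = setNames(c(n1, n2), lev))
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Default is the exact conditional test: given the allele counts, the
#' probability of each possible heterozygote count is
#' `P(n_Aa) = C * n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa`, and the p-value sums
#' the probabilities not exceeding the observed one. Suited to the small
#' per-population samples of candidate-gene surveys; the 1-df chi-square
#' test is available by flag.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return A list with `p.value`, `statistic` (chi-square statistic, `NA`
#'   for the exact test) and `method`.
#' @examples
#' hwe_test(1, 2, 1)$p.value                      # 1: perfect HWE
#' hwe_test(25, 10, 25, method = "chisq")$statistic  # 26.67
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, method = c("exact", "chisq")) {
  method <- match.arg(method)
  cnt <- assert_count(c(n_AA, n_Aa, n_aa), "genotype counts", min = 0L)
  n <- sum(cnt)
  if (n == 0L) stop_analysis("all genotype counts are zero")
  nA <- 2L * cnt[1L] + cnt[2L]
  na <- 2L * cnt[3L] + cnt[2L]
  if (method == "chisq") {
    p_hat <- nA / (2 * n)
    expd <- n * c(p_hat^2, 2 * p_hat * (1 - p_hat), (1 - p_hat)^2)
    if (any(expd == 0)) {
      return(list(p.value = 1, statistic = 0, method = "chi-square (df = 1)"))
    }
    stat <- sum((cnt - expd)^2 / expd)
    return(list(p.value = pchisq(stat, df = 1L, lower.tail = FALSE),
                statistic = stat, method = "chi-square (df = 1)"))
  }
  het <- seq.int(nA %% 2L, min(nA, na), by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - het) / 2) - lfactorial(het) -
    lfactorial((na - het) / 2) + het * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- match(cnt[2L], het)
  p <- sum(pr[pr <= pr[obs] * (1 + 1e-7)])
  list(p.value = min(1, p), statistic = NA_real_, method = "exact conditional")
}

#' Binomial logistic model of origin and collection-period effects
#'
#' Aggregates allele counts per population (binomial totals, matching a
#' model of population-level proportions) and fits a logistic GLM of the
#' reference-allele proportion on the requested factors. The reference
#' level is the most frequent allele in the farmed populations (ties broken
#' toward the lexicographically first allele, with a message). The AIC is
#' recomputed as `-2 * log-likelihood + 2 * npar`.
#'
#' @param table A genotype table (see [compute_frequencies()]).
#' @param locus Locus to analyse (default: the single locus present).
#' @param terms Model terms: one of `"1"`, `"origin"`, `"time"`,
#'   `"origin+time"`, `"origin*time"`.
#' @return A list of class `glm_fit`: `fit` (the [stats::glm] object),
#'   `formula`, `coefficients`, `log_likelihood`, `npar`, `aic`,
#'   `reference_allele`, `separation` (`TRUE` when quasi-separation was
#'   detected; the fit is still returned) and `data` (the aggregated
#'   per-population counts).
#' @export
fit_origin_time_glm <- function(table, locus = NULL, terms = "origin*time") {
  agg <- aggregate_allele_counts(table, locus)
  rhs <- switch(terms,
    "1" = "1", "origin" = "origin", "time" = "time",
    "origin+time" = "origin + time", "origin*time" = "origin * time",
    stop_config("unknown terms: ", terms))
  if (terms %in% c("time", "origin+time", "origin*time") &&
      length(unique(agg$data$time)) < 2L ||
      terms %in% c("origin", "origin+time", "origin*time") &&
      length(unique(agg$data$origin)) < 2L) {
    stop_analysis("factor with a single level in the data for terms ", terms)
  }
  f <- as.formula(paste("cbind(ref_count, alt_count) ~", rhs))
  warned <- FALSE
  fit <- withCallingHandlers(
    glm(f, family = binomial("logit"), data = agg$data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  ll <- as.numeric(logLik(fit))
  npar <- attr(logLik(fit), "df")
  separation <- warned || any(abs(coef(fit)) > 15, na.rm = TRUE)
  structure(list(fit = fit, formula = f, coefficients = coef(fit),
                 log_likelihood = ll, npar = npar, aic = -2 * ll + 2 * npar,
                 reference_allele = agg$reference_allele,
                 separation = separation, data = agg$data),
            class = "glm_fit")
}

#' Aggregate a genotype table into per-population binomial allele counts
#'
#' Builds the modelling data of [fit_origin_time_glm()]: one row per
#' population with reference/alternative allele counts and `origin`/`time`
#' factors. The reference allele is the most frequent allele in the farmed
#' populations (ties broken lexicographically, with a message).
#'
#' @param table A genotype table.
#' @param locus Locus to aggregate (default: the single locus present).
#' @return A list with `data` (tibble of `population`, `origin`, `time`,
#'   `ref_count`, `alt_count`), `reference_allele` and `locus`.
#' @export
aggregate_allele_counts <- function(table, locus = NULL) {
  loci <- unique(table$locus)
  locus <- locus %||% if (length(loci) == 1L) loci else
    stop_config("several loci present; specify `locus`")
  sub <- table[table$locus == locus, ]
  if (nrow(sub) == 0L) stop_data("no rows for locus ", locus)
  if (length(unique(sub$origin)) < 2L) {
    stop_analysis("both origins must be present")
  }
  farmed <- sub[sub$origin == "farmed", ]
  at <- sort(table(c(farmed$allele1, farmed$allele2)), decreasing = TRUE)
  if (length(at) > 1L && at[1L] == at[2L]) {
    ref <- sort(names(at)[at == at[1L]])[1L]
    message("tied farmed allele counts; reference level set to '", ref, "'")
  } else {
    ref <- names(at)[1L]
  }
  pops <- split(sub, sub$population)
  data <- do.call(rbind, lapply(pops, function(p) {
    a <- c(p$allele1, p$allele2)
    tibble(population = p$population[1L], origin = p$origin[1L],
           time = p$period[1L],
           ref_count = sum(a == ref), alt_count = sum(a != ref))
  }))
  data <- data[order(data$population), ]
  data$origin <- factor(data$origin, levels = c("farmed", "wild"))
  data$time <- factor(data$time, levels = sort(unique(data$time)))
  list(data = as_tibble(data), reference_allele = ref, locus = locus)
}

#' Stepwise AIC selection over origin and time factors
#'
#' Both-direction stepwise search over the model lattice `{1, origin, time,
#' origin+time, origin*time}` (respecting marginality: the interaction is
#' only present together with both main effects), starting from the full
#' `origin*time` model. At each step the candidate with the lowest AIC is
#' adopted; AIC ties are broken toward fewer parameters. The search stops
#' when no neighbour improves the current model.
#'
#' @param table A genotype table.
#' @param locus Locus to analyse.
#' @param scope Character vector of admissible models (default: the full
#'   lattice). A singleton scope returns that model unchanged.
#' @return A list of class `model_selection`: `selected` (a `glm_fit`),
#'   `candidates` (all visited fits, named by model), `trace` (tibble of
#'   `step`, `model`, `aic`, `accepted`).
#' @export
stepwise_aic <- function(table, locus = NULL,
                         scope = c("1", "origin", "time", "origin+time",
                                   "origin*time")) {
  scope <- match.arg(scope, several.ok = TRUE)
  neighbours <- list(
    "origin*time" = c("origin+time"),
    "origin+time" = c("origin*time", "origin", "time"),
    "origin" = c("origin+time", "1"),
    "time" = c("origin+time", "1"),
    "1" = c("origin", "time")
  )
  start <- if ("origin*time" %in% scope) "origin*time" else scope[[1L]]
  fits <- list()
  fit_of <- function(m) {
    if (is.null(fits[[m]])) fits[[m]] <<- fit_origin_time_glm(table, locus, m)
    fits[[m]]
  }
  current <- start
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- c(current, intersect(neighbours[[current]], scope))
    aics <- vapply(cand, function(m) fit_of(m)$aic, numeric(1))
    npars <- vapply(cand, function(m) fit_of(m)$npar, numeric(1))
    best <- cand[order(aics, npars)][1L]
    trace[[step]] <- tibble(step = step, model = cand, aic = aics,
                            accepted = cand == best)
    if (best == current) break
    current <- best
  }
  structure(list(selected = fits[[current]], selected_model = current,
                 candidates = fits, trace = do.call(rbind, trace)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("stepwise AIC selection: selected ~", x$selected_model,
      sprintf("(AIC %.2f)\n", x$selected$aic))
  invisible(x)
}

#' Read / write a genotype table
#'
#' Tab-separated with header `individual, population, origin, period,
#' locus, allele1, allele2`.
#'
#' @param path File path.
#' @param table A genotype table tibble.
#' @return `read_genotypes()` returns a tibble; `write_genotypes()` returns
#'   `path` invisibly.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop_config("file not found: ", path)
  df <- read.delim(path, colClasses = "character")
  need <- c("individual", "population", "origin", "period", "locus",
            "allele1", "allele2")
  if (!all(need %in% names(df))) stop_parse("not a genotype table: ", path)
  as_tibble(df[, need])
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
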