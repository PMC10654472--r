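toy_table <- function(genos, population = "p1", origin = "wild",
                      period = "2004-2007", locus = "loc") {
  tibble::tibble(
    individual = sprintf("%s_i%d", population, seq_along(genos)),
    population = population, origin = origin, period = period, locus = locus,
    allele1 = substr(genos, 1, 1), allele2 = substr(genos, 2, 2)
  )
}

test_that("allele and genotype frequencies match hand counts", {
  f <- compute_frequencies(toy_table(c("AA", "AA", "Aa")))
  al <- f$alleles
  expect_equal(al$freq[al$allele == "A"], 5 / 6)
  expect_equal(al$freq[al$allele == "a"], 1 / 6)
  gt <- f$genotypes
  expect_equal(gt$freq[gt$genotype == "A/A"], 2 / 3)
  expect_equal(gt$freq[gt$genotype == "A/a"], 1 / 3)
  expect_equal(sum(al$freq), 1)
  expect_equal(sum(gt$freq), 1)

  fixed <- compute_frequencies(toy_table(c("aa", "aa")))
  expect_equal(fixed$alleles$freq[fixed$alleles$allele == "a"], 1)
})

test_that("frequencies sum to one per population and locus", {
  d <- gene_sampling_design("seabream", "six6")
  g <- simulate_genotypes(d, wild_freq = 0.4, seed = 3)
  f <- compute_frequencies(g)
  sums <- tapply(f$alleles$freq,
                 paste(f$alleles$population, f$alleles$locus), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("populations emptied by filtering are excluded with a warning", {
  tab <- rbind(toy_table(c("AA", "Aa")),
               toy_table(c("AA"), population = "p2"))
  tab$allele1[3] <- NA
  expect_warning(f <- compute_frequencies(tab), "p2")
  expect_false("p2" %in% f$alleles$population)
})

test_that("Wilcoxon origin test matches exact enumeration and is symmetric", {
  p <- wilcoxon_origin_test(c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9),
                            rep(c("farmed", "wild"), each = 3))
  expect_equal(p$p.value, 0.1)

  # identical multisets in both groups: no separation
  same <- wilcoxon_origin_test(c(0.2, 0.5, 0.2, 0.5), c("f", "f", "w", "w"))
  expect_equal(same$p.value, 1)

  set.seed(81)
  for (i in 1:20) {
    n1 <- sample(2:5, 1)
    n2 <- sample(2:5, 1)
    x <- round(runif(n1 + n2), 2)
    org <- rep(c("farmed", "wild"), c(n1, n2))
    p1 <- wilcoxon_origin_test(x, org)$p.value
    p2 <- wilcoxon_origin_test(x, ifelse(org == "farmed", "wild", "farmed"))$p.value
    expect_equal(p1, p2)
    expect_true(p1 >= 0 && p1 <= 1)
    # independent recursive enumeration oracle (combined n <= 10)
    expect_equal(p1, oracle_wilcoxon(x[seq_len(n1)], x[-seq_len(n1)]))
  }
})

test_that("exact Wilcoxon agrees with wilcox.test when there are no ties", {
  set.seed(4)
  for (i in 1:10) {
    g1 <- runif(4)
    g2 <- runif(5)
    mine <- wilcoxon_origin_test(c(g1, g2), rep(c("a", "b"), c(4, 5)))$p.value
    ref <- wilcox.test(g1, g2, exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
  }
  expect_error(wilcoxon_origin_test(1:3, rep("farmed", 3)),
               class = "domescan_analysis_error")
})

test_that("Hardy-Weinberg tests match the chi-square formula and exact enumeration", {
  cs <- hwe_test(25, 10, 25, method = "chisq")
  expect_equal(cs$statistic, 80 / 3, tolerance = 1e-12)  # 26.67

  expect_equal(hwe_test(1, 2, 1)$p.value, 1)

  set.seed(12)
  for (i in 1:25) {
    n <- sample(3:20, 1)
    aa <- sample(0:n, 1)
    ab <- sample(0:(n - aa), 1)
    bb <- n - aa - ab
    if (2 * aa + ab == 0 || 2 * bb + ab == 0) next
    expect_equal(hwe_test(aa, ab, bb)$p.value, oracle_hwe(aa, ab, bb),
                 tolerance = 1e-10)
  }
  expect_error(hwe_test(0, 0, 0), class = "domescan_analysis_error")
})

test_that("binomial GLM satisfies the AIC identity and detects null effects", {
  d <- gene_sampling_design("seabream", "vgll3")
  g <- simulate_genotypes(d, wild_freq = 0.4, farmed_freq = 0.4, seed = 21)
  fit <- fit_origin_time_glm(g, terms = "origin")
  expect_equal(fit$aic, -2 * fit$log_likelihood + 2 * fit$npar)
  expect_equal(fit$aic, AIC(fit$fit))

  se <- summary(fit$fit)$coefficients["originwild", "Std. Error"]
  expect_lt(abs(fit$coefficients[["originwild"]]), 3 * se)

  # identical responses: the extra origin parameter is pure penalty
  flat <- toy_table(rep("Aa", 5))
  flat2 <- toy_table(rep("Aa", 5), population = "p2", origin = "farmed")
  both <- rbind(flat, flat2)
  f0 <- fit_origin_time_glm(both, terms = "1")
  f1 <- fit_origin_time_glm(both, terms = "origin")
  expect_lt(abs(f1$coefficients[["originwild"]]), 1e-6)
  expect_lt(f0$aic, f1$aic)
})

test_that("reference level is the most frequent farmed allele", {
  d <- gene_sampling_design("seabream", "vgll3")
  g <- simulate_genotypes(d, wild_freq = 0.2, farmed_freq = 0.9, seed = 2)
  fit <- fit_origin_time_glm(g, terms = "origin")
  # farmed variant frequency 0.9: the variant allele "a" is the reference
  expect_equal(fit$reference_allele, "a")
})

test_that("stepwise AIC selects origin under a strong origin effect", {
  d <- gene_sampling_design("seabream", "vgll3")
  hits <- vapply(1:10, function(s) {
    g <- simulate_genotypes(d, wild_freq = 0.2, farmed_freq = 0.6, seed = s)
    sel <- stepwise_aic(g)
    grepl("origin", sel$selected_model)
  }, logical(1))
  expect_true(all(hits))
})

test_that("stepwise AIC agrees with an independent stepwise implementation", {
  skip_if_not_installed("MASS")
  d <- gene_sampling_design("seabream", "vgll3")
  norm_terms <- function(f) {
    t <- sort(attr(terms(f), "term.labels"))
    if (!length(t)) "1" else paste(t, collapse = "+")
  }
  for (s in 1:15) {
    g <- simulate_genotypes(d, wild_freq = 0.4, farmed_freq = 0.4, seed = s)
    sel <- stepwise_aic(g)
    agg <- aggregate_allele_counts(g)$data
    full <- glm(cbind(ref_count, alt_count) ~ origin * time,
                binomial, data = agg)
    ref <- MASS::stepAIC(full, direction = "both", trace = 0)
    expect_equal(norm_terms(formula(sel$selected$fit)),
                 norm_terms(formula(ref)))
    # selected model has the lowest AIC among all visited candidates
    aics <- vapply(sel$candidates, function(f) f$aic, numeric(1))
    expect_equal(sel$selected$aic, min(aics))
  }
})

test_that("null data most often selects the intercept-only model", {
  d <- gene_sampling_design("seabream", "vgll3")
  sel <- vapply(1:40, function(s) {
    g <- simulate_genotypes(d, wild_freq = 0.4, farmed_freq = 0.4,
                            seed = 100 + s)
    stepwise_aic(g)$selected_model
  }, character(1))
  tab <- sort(table(sel), decreasing = TRUE)
  expect_equal(names(tab)[1], "1")
})

test_that("a singleton scope is returned unchanged", {
  d <- gene_sampling_design("seabream", "vgll3")
  g <- simulate_genotypes(d, wild_freq = 0.3, seed = 5)
  sel <- stepwise_aic(g, scope = "1")
  expect_equal(sel$selected_model, "1")
  expect_equal(nrow(sel$trace), 1L)
})
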