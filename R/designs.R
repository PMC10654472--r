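# Published sampling layouts of the motivating candidate-gene survey of
# gilthead seabream (Sparus aurata) and European seabass (Dicentrarchus
# labrax). They serve as default designs for the synthetic generators and as
# bookkeeping inputs (sample totals, amplicon coordinates, pool layouts).

#' Sampling design of the gene-level genotyping survey
#'
#' Per-population sample sizes for the farmed and wild collections genotyped
#' by Sanger sequencing at the *vgll3* and *six6* candidate genes. Wild
#' populations were sampled from the Aegean and Ionian Seas, farmed ones from
#' Greek hatcheries, over two collection periods (2004--2007 and 2012--2016).
#'
#' @param species `"seabream"` or `"seabass"`.
#' @param gene `"vgll3"` or `"six6"`.
#' @return A tibble with columns `population`, `origin` (`farmed`/`wild`),
#'   `period` (`2004-2007`/`2012-2016`), `year` and `n` (individuals
#'   genotyped at that gene; populations with no data carry `n = 0`).
#' @examples
#' d <- gene_sampling_design("seabream", "vgll3")
#' sum(d$n)  # 91 genotyped individuals
#' @export
gene_sampling_design <- function(species = c("seabream", "seabass"),
                                 gene = c("vgll3", "six6")) {
  species <- match.arg(species)
  gene <- match.arg(gene)
  d <- if (species == "seabream") {
    tibble(
      population = c(paste0("seabream_w1.", 1:6), paste0("seabream_w2.", 1:5),
                     paste0("seabream_f1.", 1:4), paste0("seabream_f2.", 1:5)),
      origin = rep(c("wild", "farmed"), c(11L, 9L)),
      year = c(2004, 2004, 2005, 2005, 2005, 2006, 2013, 2013, 2013, 2014, 2016,
               2004, 2005, 2005, 2007, 2014, 2016, 2014, 2014, 2014),
      vgll3 = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 4, 5,
                4, 4, 3, 5, 5, 2, 4, 5, 5),
      six6 = c(4, 5, 3, 5, 5, 3, 5, 5, 5, 4, 1,
               4, 4, 2, 8, 5, 0, 3, 4, 4)
    )
  } else {
    tibble(
      population = c(paste0("seabass_w1.", 1:5), paste0("seabass_w2.", 1:6),
                     paste0("seabass_f1.", 1:2), paste0("seabass_f2.", 1:5)),
      origin = rep(c("wild", "farmed"), c(11L, 7L)),
      year = c(2004, 2004, 2004, 2005, 2005, 2013, 2013, 2013, 2014, 2016, 2016,
               2004, 2004, 2014, 2014, 2014, 2014, 2016),
      vgll3 = c(5, 5, 5, 5, 5, 4, 5, 4, 5, 3, 6,
                9, 9, 5, 4, 4, 3, 4),
      six6 = c(5, 5, 5, 4, 5, 4, 5, 4, 5, 2, 2,
               7, 11, 5, 5, 5, 4, 4)
    )
  }
  d$period <- ifelse(d$year <= 2007, "2004-2007", "2012-2016")
  d$n <- as.integer(d[[gene]])
  d[, c("population", "origin", "period", "year", "n")]
}

#' Amplicon panel used for candidate-gene Sanger genotyping
#'
#' Genomic coordinates (on the GCA_900880675.2 seabream and GCA_000689215.1
#' seabass assemblies), annealing temperatures and reported amplicon sizes of
#' the 16 PCR amplicons tiling the transcribed regions of *vgll3* and *six6*.
#' Reported sizes follow the `end - start` convention of the primer-design
#' coordinates.
#'
#' @return A tibble with columns `species`, `gene`, `start`, `end`,
#'   `annealing_c` and `size_bp` (the reported amplicon size).
#' @examples
#' p <- amplicon_panel()
#' with(p[p$species == "seabass" & p$gene == "vgll3", ], end - start)
#' @export
amplicon_panel <- function() {
  tibble(
    species = rep(c("seabass", "seabream"), each = 8L),
    gene = rep(rep(c("vgll3", "six6"), each = 4L), 2L),
    start = c(9203305, 9202574, 9201705, 9201381,
              11589507, 11590632, 11588596, 11592056,
              24911798, 24910950, 24910316, 24909934,
              14404868, 14406022, 14403964, 14407370),
    end = c(9203951, 9203170, 9202720, 9201802,
            11590303, 11591488, 11589739, 11592572,
            24912208, 24911675, 24911343, 24910621,
            14405650, 14406799, 14405087, 14407840),
    annealing_c = c(63, 61, 63, 61, 61, 63, 61, 61,
                    63, 63, 63, 61, 61, 63, 63, 63),
    size_bp = c(646, 596, 1015, 421, 796, 856, 1149, 515,
                410, 725, 1027, 687, 782, 777, 1123, 470)
  )
}

#' Pool layout of the Mediterranean Pool-Seq survey
#'
#' Number of individuals per DNA pool and number of technical replicate
#' libraries prepared for each farmed and wild population of the published
#' Mediterranean pooled-sequencing design that the chromosome-level track
#' re-analyses. Pools hold 11--25 individuals with 1--2 replicates each.
#'
#' @param species `"seabream"` or `"seabass"`.
#' @return A tibble with columns `pool_id`, `origin`, `country`,
#'   `n_individuals` and `n_replicates`.
#' @export
pool_layout <- function(species = c("seabream", "seabass")) {
  species <- match.arg(species)
  if (species == "seabream") {
    tibble(
      pool_id = c(paste0("seabream_f", 1:12), paste0("seabream_w", 1:12)),
      origin = rep(c("farmed", "wild"), each = 12L),
      country = c("France", "Spain", "Spain", "Italy", "Croatia", "Greece",
                  "Greece", "Greece", "Greece", "Greece", "Israel", "Egypt",
                  "Spain", "Spain", "Tunisia", "Italy", "Italy", "Greece",
                  "Greece", "Greece", "Greece", "Greece", "Turkey", "Turkey"),
      n_individuals = c(25, 25, 25, 25, 25, 14, 13, 25, 25, 25, 25, 15,
                        25, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25),
      n_replicates = c(2, 2, 2, 1, 2, 1, 1, 2, 2, 2, 2, 1,
                       2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2)
    )
  } else {
    tibble(
      pool_id = c(paste0("seabass_f", 1:14), paste0("seabass_w", 1:10)),
      origin = rep(c("farmed", "wild"), c(14L, 10L)),
      country = c("France", "Spain", "Spain", "Italy", "Croatia", "Croatia",
                  "Greece", "Greece", "Greece", "Greece", "Greece", "Greece",
                  "Cyprus", "Egypt",
                  "France", "Spain", "Morocco", "Italy", "Croatia", "Greece",
                  "Greece", "Cyprus", "Turkey", "Turkey"),
      n_individuals = c(12, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25, 25, 15,
                        25, 11, 25, 25, 12, 25, 25, 15, 25, 25),
      n_replicates = c(1, 2, 2, 2, 2, 2, 2, 2, 2, 2, 2, 1, 2, 1,
                       2, 1, 2, 2, 1, 2, 2, 1, 2, 2)
    )
  }
}
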