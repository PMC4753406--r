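#' Tabulate genotype counts at one locus
#'
#' @param pairs Tibble/data frame with columns `a1`, `a2` (unordered
#'   allele pair per individual; order-insensitive).
#' @return Tibble `a1`, `a2`, `count` with `a1 <= a2`.
#' @export
genotype_counts <- function(pairs) {
  tibble::tibble(a1 = pmin(pairs$a1, pairs$a2),
                 a2 = pmax(pairs$a1, pairs$a2)) |>
    dplyr::count(.data$a1, .data$a2, name = "count")
}

## merge duplicate categories after sorting each pair
.canon_counts <- function(counts) {
  tibble::tibble(a1 = pmin(counts$a1, counts$a2),
                 a2 = pmax(counts$a1, counts$a2),
                 count = counts$count) |>
    dplyr::summarise(count = sum(.data$count), .by = c("a1", "a2"))
}

## allele frequencies from a genotype count table
.allele_freqs <- function(counts) {
  n <- sum(counts$count)
  tot <- rowsum(c(counts$count, counts$count), c(counts$a1, counts$a2))
  stats::setNames(tot[, 1] / (2 * n), rownames(tot))
}

#' Effect-size statistic for deviation from Hardy-Weinberg equilibrium
#'
#' A bounded chi-square-based effect size: with allele frequencies `p_i`
#' derived from the genotype counts, expected counts under HWE are
#' `n p_i^2` (homozygotes) and `2 n p_i p_j` (heterozygotes); the
#' statistic is `sqrt(X^2 / (n (k - 1)))` over all genotype categories
#' with non-zero expectation, clipped to `[0, 1]`, where `k` is the
#' number of distinct alleles. It is 0 exactly at HWE proportions and
#' approaches 1 under maximal disequilibrium (e.g. complete heterozygote
#' deficit at two equifrequent alleles).
#'
#' @param counts Genotype count table (`a1`, `a2`, `count`), e.g. from
#'   [genotype_counts()].
#' @return Effect size in `[0, 1]`.
#' @export
wn_statistic <- function(counts) {
  counts <- .canon_counts(counts)
  n <- sum(counts$count)
  if (n == 0) rlang::abort("empty genotype table")
  p <- .allele_freqs(counts)
  alleles <- names(p)
  k <- length(alleles)
  if (k == 1L) return(0)
  cats <- tidyr::expand_grid(a1 = alleles, a2 = alleles) |>
    dplyr::filter(.data$a1 <= .data$a2) |>
    dplyr::left_join(counts, by = c("a1", "a2")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  expected = ifelse(.data$a1 == .data$a2,
                                    n * p[.data$a1]^2,
                                    2 * n * p[.data$a1] * p[.data$a2])) |>
    dplyr::filter(.data$expected > 0)
  x2 <- sum((cats$count - cats$expected)^2 / cats$expected)
  min(1, sqrt(x2 / (n * (k - 1))))
}

#' Observed and expected homozygosity
#'
#' Observed: share of individuals carrying two identical codes.
#' Expected under HWE: `sum(p_i^2)` with allele frequencies derived from
#' the genotype counts.
#'
#' @inheritParams wn_statistic
#' @return Named numeric vector `c(observed = , expected = )`.
#' @export
homozygosity <- function(counts) {
  counts <- .canon_counts(counts)
  n <- sum(counts$count)
  if (n == 0) rlang::abort("empty genotype table")
  obs <- sum(counts$count[counts$a1 == counts$a2]) / n
  p <- .allele_freqs(counts)
  c(observed = obs, expected = sum(p^2))
}

#' Per-locus Hardy-Weinberg report at broad-antigen resolution
#'
#' Converts phenotypes to broad serological genotype pairs per locus
#' (see [to_broad()]) and reports the effect size [wn_statistic()] and
#' observed/expected homozygosities, with `delta = observed - expected`
#' (positive delta = excess homozygosity).
#'
#' @param phenotypes Character vector of phenotype strings.
#' @param map A [resolution_map()] with broad codes.
#' @param loci Loci to analyze (default all five).
#' @return Tibble: `locus`, `w_n`, `observed_homozygosity`,
#'   `expected_homozygosity`, `delta`.
#' @export
hwe_report <- function(phenotypes, map, loci = hla_loci()) {
  purrr::map_dfr(loci, function(l) {
    counts <- genotype_counts(to_broad(phenotypes, map, l))
    hz <- homozygosity(counts)
    tibble::tibble(locus = l,
                   w_n = wn_statistic(counts),
                   observed_homozygosity = hz[["observed"]],
                   expected_homozygosity = hz[["expected"]],
                   delta = hz[["observed"]] - hz[["expected"]])
  })
}
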