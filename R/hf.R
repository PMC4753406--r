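#' Construct a haplotype-frequency set
#'
#' The generative engine of every simulation: a normalized frequency
#' table over distinct five-locus haplotypes, sorted by descending
#' frequency (ties broken lexicographically for determinism).
#'
#' @param haplotype Character vector of `~`-joined haplotype strings, or
#'   a data frame with columns `haplotype` and `frequency`.
#' @param frequency Numeric vector of frequencies (ignored when
#'   `haplotype` is a data frame).
#' @param renormalize If `TRUE`, frequencies are rescaled to sum to 1;
#'   otherwise a sum outside `1 +- 1e-9` is an error.
#' @param label Provenance label carried as an attribute.
#' @return A tibble of class `hf_set` with columns `haplotype`,
#'   `frequency`.
#' @export
hf_set <- function(haplotype, frequency = NULL, renormalize = FALSE,
                   label = "unlabelled") {
  if (is.data.frame(haplotype)) {
    frequency <- haplotype$frequency
    haplotype <- haplotype$haplotype
  }
  if (length(haplotype) != length(frequency) || length(haplotype) < 1L) {
    rlang::abort("haplotype and frequency must be non-empty and equal length")
  }
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    rlang::abort("frequencies must be finite and > 0")
  }
  if (anyDuplicated(haplotype)) {
    rlang::abort("duplicate haplotype in frequency set")
  }
  parse_haplotypes(haplotype)  # validates structure
  s <- sum(frequency)
  if (renormalize) {
    frequency <- frequency / s
  } else if (abs(s - 1) > 1e-9) {
    rlang::abort(paste0("frequencies sum to ", format(s),
                        "; use renormalize = TRUE to rescale"))
  } else {
    frequency <- frequency / s
  }
  ord <- order(-frequency, haplotype)
  out <- tibble::tibble(haplotype = haplotype[ord], frequency = frequency[ord])
  class(out) <- c("hf_set", class(out))
  attr(out, "label") <- label
  out
}

#' @export
print.hf_set <- function(x, ...) {
  cat("<hf_set '", attr(x, "label"), "': ", nrow(x), " haplotypes, top-1 = ",
      signif(x$frequency[1], 4), ">\n", sep = "")
  NextMethod()
}

## internal: cached allele matrix for an hf_set
.hf_hapmat <- function(hfs) parse_haplotypes(hfs$haplotype)

#' Generate a synthetic haplotype-frequency distribution
#'
#' Draws `n_haplotypes` distinct random five-locus haplotypes from
#' per-locus allele pools and assigns them a normalized rank-decay
#' frequency law: power decay (`rank^-decay_shape`) or geometric decay
#' (`decay_shape^(rank-1)`, shape in (0,1)). Allele codes are synthetic
#' two-field tokens (`"group:protein"`) so that first-field truncation
#' yields a meaningful low-resolution image.
#'
#' @param n_haplotypes Number of distinct haplotypes (>= 1).
#' @param decay_shape Positive decay parameter (power exponent, or
#'   geometric ratio in (0,1)).
#' @param decay `"power"` or `"geometric"`.
#' @param allele_pool_sizes Named integer vector (by locus) of allele
#'   pool sizes.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An [hf_set()].
#' @export
gen_hf_distribution <- function(n_haplotypes,
                                decay_shape = 1,
                                decay = c("power", "geometric"),
                                allele_pool_sizes = c(A = 30, B = 50, C = 35,
                                                      DRB1 = 35, DQB1 = 15),
                                seed = 1L) {
  decay <- match.arg(decay)
  if (n_haplotypes < 1) rlang::abort("n_haplotypes must be >= 1")
  if (decay_shape <= 0) rlang::abort("decay_shape must be > 0")
  if (decay == "geometric" && decay_shape >= 1) {
    rlang::abort("geometric decay requires shape in (0, 1)")
  }
  pools <- lapply(hla_loci(), function(l) .allele_pool(allele_pool_sizes[[l]]))
  names(pools) <- hla_loci()
  if (prod(vapply(pools, length, 1L)) < n_haplotypes) {
    rlang::abort("allele pools too small to form the requested number of distinct haplotypes")
  }
  haps <- .with_seed(seed, {
    out <- character(0)
    tries <- 0L
    while (length(out) < n_haplotypes) {
      tries <- tries + 1L
      if (tries > 100L) rlang::abort("failed to generate enough distinct haplotypes")
      need <- n_haplotypes - length(out)
      m <- vapply(pools, function(p) sample(p, 2L * need + 10L, replace = TRUE),
                  character(2L * need + 10L))
      out <- unique(c(out, format_haplotypes(m)))
    }
    out[seq_len(n_haplotypes)]
  })
  r <- seq_len(n_haplotypes)
  w <- switch(decay,
    power = r^(-decay_shape),
    geometric = decay_shape^(r - 1)
  )
  hf_set(haps, w, renormalize = TRUE,
         label = sprintf("synthetic-%s-%g", decay, decay_shape))
}

## synthetic two-field allele pool of a given size
.allele_pool <- function(size) {
  size <- as.integer(size)
  g <- max(2L, ceiling(size / 3))
  k <- seq_len(size) - 1L
  sprintf("%02d:%02d", (k %% g) + 1L, (k %/% g) + 1L)
}

#' Reshape the diversity of a frequency distribution
#'
#' Applies the one-parameter exponent-tilt family
#' `f_i^gamma / sum_j f_j^gamma` and solves for `gamma > 0` (monotone
#' root-finding) so that the cumulative frequency of the `top_k` most
#' common haplotypes equals `target_cumulative` within `1e-6`.
#' `gamma > 1` steepens the distribution (less diverse), `gamma < 1`
#' flattens it (more diverse); rank order is preserved.
#'
#' @param hfs An [hf_set()] with more than `top_k` entries.
#' @param top_k Number of top-ranked haplotypes the target refers to
#'   (default 50).
#' @param target_cumulative Desired cumulative frequency of the top `top_k`
#'   haplotypes, strictly between `top_k / n` and 1.
#' @return A reshaped, renormalized [hf_set()].
#' @export
reshape_diversity <- function(hfs, top_k = 50, target_cumulative) {
  stopifnot(inherits(hfs, "hf_set"))
  n <- nrow(hfs)
  if (top_k >= n) rlang::abort("top_k must be smaller than the number of haplotypes")
  lo_bound <- top_k / n
  if (target_cumulative <= lo_bound || target_cumulative >= 1) {
    rlang::abort(sprintf(
      "target_cumulative %.6g unattainable; attainable range is (%.6g, 1)",
      target_cumulative, lo_bound))
  }
  lf <- log(hfs$frequency)
  topk_cum <- function(gamma) {
    w <- exp(gamma * (lf - max(lf)))
    sum(w[seq_len(top_k)]) / sum(w)
  }
  g <- function(gamma) topk_cum(gamma) - target_cumulative
  lo <- 1e-8; hi <- 1
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
  if (g(hi) < 0) rlang::abort("target_cumulative too close to 1 to attain numerically")
  gamma <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  if (abs(topk_cum(gamma) - target_cumulative) > 1e-6) {
    rlang::abort("root-finding failed to reach the diversity target")
  }
  w <- exp(gamma * (lf - max(lf)))
  out <- hf_set(hfs$haplotype, w, renormalize = TRUE,
                label = sprintf("%s|tilt-%.4g", attr(hfs, "label"), gamma))
  attr(out, "gamma") <- gamma
  out
}

#' Sample unphased phenotypes under random mating
#'
#' Each individual is formed from two i.i.d. haplotype draws (with
#' replacement) from the frequency set, so the sampled population
#' satisfies Hardy-Weinberg equilibrium by construction.
#'
#' @param hfs An [hf_set()].
#' @param n Number of individuals (>= 1).
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `h1`, `h2` (row indices into `hfs`)
#'   and `phenotype` (canonical phenotype string).
#' @export
sample_phenotypes <- function(hfs, n, seed = 1L) {
  stopifnot(inherits(hfs, "hf_set"))
  if (n < 1) rlang::abort("n must be >= 1")
  k <- nrow(hfs)
  idx <- .with_seed(seed, sample.int(k, 2L * n, replace = TRUE, prob = hfs$frequency))
  h1 <- idx[seq_len(n)]
  h2 <- idx[n + seq_len(n)]
  hapmat <- .hf_hapmat(hfs)
  tibble::tibble(id = seq_len(n), h1 = h1, h2 = h2,
                 phenotype = .phenotype_keys(hapmat, h1, h2))
}

#' The TOY3 three-haplotype fixture
#'
#' A canonical miniature world used throughout the test suite and the
#' documentation: three haplotypes H1, H2, H3 with frequencies
#' (0.5, 0.3, 0.2), where H1 and H2 share low-resolution HLA-A and -B
#' codes (so low-resolution typings cannot separate them) and H3 differs
#' everywhere; plus the explicit resolution map.
#'
#' @return List with elements `hfs` (an [hf_set()]) and `map`
#'   (a [resolution_map()]).
#' @export
make_toy_fixture <- function() {
  haps <- c(
    H1 = "01:01~07:01~01:01~01:01~02:01",
    H2 = "01:02~07:02~02:01~04:01~03:01",
    H3 = "02:01~08:01~03:01~07:01~05:01"
  )
  hfs <- hf_set(unname(haps), c(0.5, 0.3, 0.2), label = "TOY3")
  map <- default_resolution_map(unname(haps))
  list(hfs = hfs, map = map)
}

#' Synthetic registry-grade haplotype-frequency distribution
#'
#' Generates a heavy-tailed five-locus distribution and tilts it so that
#' the cumulative frequency of its 20 most common haplotypes equals the
#' value published for the German donor population (25.1%), giving the
#' scaled simulations the same head concentration as the reference
#' registry.
#'
#' @param n_haplotypes Number of haplotypes (default 5000).
#' @param seed Integer seed.
#' @param top20_cumulative Calibration target for the top-20 cumulative
#'   frequency (default 0.251).
#' @return An [hf_set()].
#' @export
gen_reference_hf <- function(n_haplotypes = 5000, seed = 1L,
                             top20_cumulative = 0.251) {
  base <- gen_hf_distribution(n_haplotypes, decay_shape = 1, decay = "power",
                              seed = seed)
  out <- reshape_diversity(base, top_k = 20, target_cumulative = top20_cumulative)
  attr(out, "label") <- sprintf("reference-synthetic-n%d-seed%d", n_haplotypes,
                                as.integer(seed))
  out
}
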