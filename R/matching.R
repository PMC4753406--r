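## ---------------------------------------------------------------------------
## Matching probabilities from population haplotype frequencies.
##
## Under random mating an individual's phenotype is the union of two i.i.d.
## haplotype draws. The probability that a donor with partial typing `obs` is
## a complete 10/10 match for a fully typed patient is
##     MP = P(phenotype = patient AND mask(phenotype) = obs) / P(mask = obs)
## All sums run over the finite haplotype support of the frequency set;
## phenotypes outside the support have probability zero and contribute
## nothing.
##
## The efficient path indexes haplotypes by their masked image per typing
## spec: an ordered haplotype pair (i, j) reproduces a given observation iff
## at every typed locus the pair of images {img_i, img_j} equals the observed
## pair, so P(obs) = sum over candidate i of f_i * F(complement image of i),
## where F() is the aggregated frequency of the image bucket.
## ---------------------------------------------------------------------------

## build a matching-probability index over an hf_set (+ resolution map)
.mp_index <- function(hfs, map = NULL) {
  idx <- new.env(parent = emptyenv())
  idx$hfs <- hfs
  idx$map <- map
  idx$hapmat <- .hf_hapmat(hfs)
  idx$f <- hfs$frequency
  idx$specs <- new.env(parent = emptyenv())
  idx
}

## signature string for a per-locus resolution spec
.spec_sig <- function(res) paste(ifelse(is.na(res), "-", res), collapse = ",")

## per-spec image matrix, image keys and bucket frequency sums (cached)
.mp_spec <- function(idx, res) {
  res <- res[hla_loci()]
  sig <- .spec_sig(res)
  if (!is.null(idx$specs[[sig]])) return(idx$specs[[sig]])
  typed <- hla_loci()[!is.na(res)]
  k <- nrow(idx$hapmat)
  if (length(typed) == 0L) {
    entry <- list(typed = typed, img = NULL, key = rep("", k),
                  bucket = c(`(all)` = 1))
    idx$specs[[sig]] <- entry
    return(entry)
  }
  img <- matrix("", nrow = k, ncol = length(typed),
                dimnames = list(NULL, typed))
  for (l in typed) {
    img[, l] <- if (res[[l]] == "high") idx$hapmat[, l]
                else .map_codes(idx$hapmat[, l], l, idx$map, "low_code")
  }
  key <- do.call(paste, c(lapply(seq_along(typed), function(c) img[, c]),
                          list(sep = "~")))
  bf <- rowsum(idx$f, key)
  bucket <- stats::setNames(bf[, 1], rownames(bf))
  entry <- list(typed = typed, img = img, key = key, bucket = bucket)
  idx$specs[[sig]] <- entry
  entry
}

## probability mass of an observation given per-locus sorted image pairs
## pairs: list named by typed loci, each a sorted length-2 character vector
.obs_mass <- function(idx, entry, pairs) {
  typed <- entry$typed
  if (length(typed) == 0L) return(1)
  k <- nrow(entry$img)
  cand <- rep(TRUE, k)
  for (l in typed) {
    pr <- pairs[[l]]
    cand <- cand & (entry$img[, l] == pr[1] | entry$img[, l] == pr[2])
    if (!any(cand)) return(0)
  }
  ids <- which(cand)
  comp <- matrix("", nrow = length(ids), ncol = length(typed))
  for (c in seq_along(typed)) {
    l <- typed[c]
    pr <- pairs[[l]]
    im <- entry$img[ids, l]
    comp[, c] <- ifelse(im == pr[1], pr[2], pr[1])
  }
  ckey <- do.call(paste, c(lapply(seq_len(ncol(comp)), function(c) comp[, c]),
                           list(sep = "~")))
  fb <- entry$bucket[ckey]
  fb[is.na(fb)] <- 0
  sum(idx$f[ids] * fb)
}

#' Probability of a fully typed phenotype under random mating
#'
#' Sums, over all unordered haplotype pairs of the frequency set whose
#' union reproduces the phenotype, `2 f1 f2` (heterozygous pair) or
#' `f^2` (homozygous pair). All pair decompositions of the phenotype are
#' included.
#'
#' @param phenotype Phenotype string.
#' @param hfs An [hf_set()].
#' @return Probability in `[0, 1]`; 0 when the phenotype cannot be formed
#'   from the support.
#' @export
phenotype_probability <- function(phenotype, hfs) {
  idx <- .mp_index(hfs)
  .phenotype_probability_idx(idx, phenotype)
}

.phenotype_probability_idx <- function(idx, phenotype) {
  res <- stats::setNames(rep("high", 5L), hla_loci())
  entry <- .mp_spec(idx, res)
  p <- .parse_phenotype_matrices(phenotype)
  pairs <- lapply(hla_loci(), function(l) c(p$lo[1L, l], p$hi[1L, l]))
  names(pairs) <- hla_loci()
  .obs_mass(idx, entry, pairs)
}

#' Probability mass of an observed typing
#'
#' Total phenotype probability of all phenotypes (over the haplotype
#' support) compatible with the observation; the normalizing constant of
#' the matching probability. A fully untyped observation has mass 1.
#'
#' @param obs An [observed_typing()].
#' @param hfs An [hf_set()].
#' @param map A [resolution_map()] (needed for low-resolution loci).
#' @return Probability in `[0, 1]`.
#' @export
observation_probability <- function(obs, hfs, map = NULL) {
  idx <- .mp_index(hfs, map)
  .observation_probability_idx(idx, obs)
}

.observation_probability_idx <- function(idx, obs) {
  entry <- .mp_spec(idx, obs$resolution)
  pairs <- obs$codes[entry$typed]
  .obs_mass(idx, entry, pairs)
}

#' Matching probability of a partially typed donor for a patient
#'
#' The probability that a donor known only through an observed typing is
#' a complete 10/10 match for a fully typed high-resolution patient,
#' given population haplotype frequencies: the patient's phenotype
#' probability divided by the observation's probability mass, or 0 when
#' the patient could not have produced the observation. No probability
#' floor is applied: arbitrarily small positive values remain rankable.
#'
#' @param patient Fully typed patient phenotype string.
#' @param obs Donor [observed_typing()].
#' @param hfs An [hf_set()].
#' @param map A [resolution_map()].
#' @return One-row tibble with columns `value`, `numerator`,
#'   `denominator`.
#' @export
matching_probability <- function(patient, obs, hfs, map = NULL) {
  idx <- .mp_index(hfs, map)
  if (!compatible(obs, patient, map)) {
    return(tibble::tibble(value = 0,
                          numerator = .phenotype_probability_idx(idx, patient),
                          denominator = .observation_probability_idx(idx, obs)))
  }
  num <- .phenotype_probability_idx(idx, patient)
  den <- .observation_probability_idx(idx, obs)
  if (den <= 0) {
    if (num > 0) {
      rlang::abort("inconsistent observation: compatible patient but zero observation mass")
    }
    return(tibble::tibble(value = 0, numerator = num, denominator = den))
  }
  tibble::tibble(value = num / den, numerator = num, denominator = den)
}

#' Brute-force matching-probability oracle
#'
#' Independent reference computation used in tests: enumerates every
#' ordered haplotype pair of the support, builds its phenotype, masks it
#' object-by-object under the observation's resolution spec, and
#' accumulates probability masses. Refuses supports larger than 200
#' haplotypes.
#'
#' @inheritParams matching_probability
#' @return Matching probability as a bare number.
#' @export
mp_bruteforce_oracle <- function(patient, obs, hfs, map = NULL) {
  k <- nrow(hfs)
  if (k > 200) rlang::abort("oracle guard: support too large (> 200 haplotypes)")
  hapmat <- .hf_hapmat(hfs)
  f <- hfs$frequency
  patient_key <- canonical_phenotype(patient)
  obs_str <- format(obs)
  ## mask each distinct phenotype once
  grid <- expand.grid(i = seq_len(k), j = seq_len(k))
  phen <- .phenotype_keys(hapmat, grid$i, grid$j)
  uph <- unique(phen)
  masked <- vapply(uph, function(p) format(mask_phenotype(p, obs$resolution, map)),
                   character(1))
  hit_obs <- masked[phen] == obs_str
  mass <- f[grid$i] * f[grid$j]
  den <- sum(mass[hit_obs])
  num <- sum(mass[hit_obs & phen == patient_key])
  if (den <= 0) return(0)
  num / den
}
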