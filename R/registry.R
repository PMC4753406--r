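## canonical observed-typing keys for haplotype index pairs under a spec entry
## (typed-loci cells "lo,hi" joined "|"; for the all-high spec this equals the
## canonical phenotype key)
.pair_obs_keys <- function(entry, i, j) {
  typed <- entry$typed
  if (length(typed) == 0L) return(rep("", max(length(i), length(j))))
  cells <- lapply(typed, function(l) {
    a <- entry$img[i, l]; b <- entry$img[j, l]
    paste0(pmin(a, b), ",", pmax(a, b))
  })
  do.call(paste, c(cells, list(sep = "|")))
}

#' Resolve a typing-profile mix
#'
#' @param mix `"reference"`, `"low_quality"`, `"high_quality"`, or a
#'   numeric vector of five shares (fractions summing to 1 or percents
#'   summing to 100) for profiles 1--5.
#' @return Named numeric vector of fractions over profiles 1--5.
#' @export
resolve_profile_mix <- function(mix) {
  if (is.character(mix) && length(mix) == 1L) {
    cols <- profile_mixes()
    if (!mix %in% names(cols)) {
      rlang::abort(paste0("unknown profile mix label: ", mix))
    }
    return(stats::setNames(cols[[mix]], cols$profile))
  }
  if (!is.numeric(mix) || length(mix) != 5L) {
    rlang::abort("mix must be a label or five numeric shares")
  }
  s <- sum(mix)
  if (abs(s - 100) < 1e-6) mix <- mix / 100
  else if (abs(s - 1) > 1e-9) rlang::abort("profile mix must sum to 1 (or 100%)")
  stats::setNames(mix / sum(mix), 1:5)
}

## largest-remainder apportionment of `size` donors over profile shares
.apportion <- function(size, shares) {
  raw <- size * shares
  base <- floor(raw)
  rem <- size - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(shares))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(shares))
}

#' Build a virtual donor registry
#'
#' Samples `size` donor phenotypes from the haplotype frequencies under
#' random mating, assigns typing profiles by deterministic stratification
#' (largest-remainder apportionment of the mix, then a seeded shuffle),
#' and masks each donor's typing according to its profile. True
#' phenotypes are kept in a separate hidden table that the search
#' ranking never consults.
#'
#' @param hfs An [hf_set()].
#' @param size Number of donors (>= 1).
#' @param profile_mix Mix label or five shares (see
#'   [resolve_profile_mix()]).
#' @param map A [resolution_map()]; defaults to first-field truncation
#'   over the haplotype set.
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `donor_registry`.
#' @export
build_registry <- function(hfs, size, profile_mix = "reference", map = NULL,
                           seed = 1L) {
  stopifnot(inherits(hfs, "hf_set"))
  if (size < 1) rlang::abort("size must be >= 1")
  if (is.null(map)) map <- default_resolution_map(hfs)
  shares <- resolve_profile_mix(profile_mix)
  counts <- .apportion(size, shares)
  phen <- sample_phenotypes(hfs, size, seed = .derive_seed(seed, 1))
  profile <- .with_seed(.derive_seed(seed, 2),
                        sample(rep.int(1:5, counts)))
  idx <- .mp_index(hfs, map)
  profs <- typing_profiles()
  obs_key <- character(size)
  for (p in 1:5) {
    sel <- profile == p
    if (!any(sel)) next
    spec <- .profile_spec(p)
    entry <- .mp_spec(idx, spec)
    obs_key[sel] <- .pair_obs_keys(entry, phen$h1[sel], phen$h2[sel])
  }
  structure(list(
    observed = tibble::tibble(id = phen$id, profile = profile, obs_key = obs_key),
    hidden = tibble::tibble(id = phen$id, h1 = phen$h1, h2 = phen$h2,
                            phenotype = phen$phenotype),
    hfs = hfs, map = map, mix = shares, seed = as.integer(seed),
    size = as.integer(size)
  ), class = "donor_registry")
}

#' @export
print.donor_registry <- function(x, ...) {
  cat("<donor_registry: ", x$size, " donors over ", nrow(x$hfs),
      " haplotypes; mix ", paste(round(100 * x$mix), collapse = "/"),
      "; seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

#' Observed donor table of a registry
#' @param registry A `donor_registry`.
#' @return Tibble `id`, `profile`, `obs_key`.
#' @export
observed_donors <- function(registry) registry$observed

#' Hidden true phenotypes of a registry
#'
#' Exposed for outcome labeling and serialization only; search ranking
#' must never consult it.
#'
#' @param registry A `donor_registry`.
#' @return Tibble `id`, `h1`, `h2`, `phenotype`.
#' @export
hidden_phenotypes <- function(registry) registry$hidden

#' Build a virtual patient panel
#'
#' Patients are fully typed at high resolution and drawn from the same
#' haplotype frequencies as the donor pool.
#'
#' @param hfs An [hf_set()].
#' @param n Number of patients (0 gives an empty panel).
#' @param seed Integer seed.
#' @return Tibble `id`, `h1`, `h2`, `phenotype`.
#' @export
build_patients <- function(hfs, n, seed = 1L) {
  if (n == 0) {
    return(tibble::tibble(id = integer(0), h1 = integer(0), h2 = integer(0),
                          phenotype = character(0)))
  }
  sample_phenotypes(hfs, n, seed = seed)
}

#' Share of patients whose alleles are all on a CWD list
#'
#' @param panel Patient panel from [build_patients()].
#' @param cwd_alleles Character vector of allele codes regarded as
#'   common and well-defined.
#' @return Fraction in `[0, 1]` of patients all ten of whose alleles are
#'   in `cwd_alleles`.
#' @export
cwd_share <- function(panel, cwd_alleles) {
  if (nrow(panel) == 0) return(NaN)
  p <- .parse_phenotype_matrices(panel$phenotype)
  ok <- matrix(p$lo %in% cwd_alleles, nrow = nrow(p$lo)) &
        matrix(p$hi %in% cwd_alleles, nrow = nrow(p$hi))
  mean(rowSums(ok) == 5L)
}
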