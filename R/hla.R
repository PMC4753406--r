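#' The five HLA loci relevant for 10/10 matching
#'
#' Locus order is fixed throughout the package: every haplotype,
#' phenotype and typing-profile representation lists loci in this order.
#'
#' @return Character vector `c("A", "B", "C", "DRB1", "DQB1")`.
#' @export
hla_loci <- function() c("A", "B", "C", "DRB1", "DQB1")

#' Registry typing profiles
#'
#' The five donor typing profiles used to model heterogeneous HLA
#' information in a registry, from complete five-locus high-resolution
#' typing (profile 1) down to low-resolution HLA-A and -B only
#' (profiles 4 and 5). Profiles 4 and 5 carry identical per-locus
#' specifications and differ only by label: profile 5 marks the donors
#' a search strategy may exclude from typing requests.
#'
#' @return A tibble with columns `profile` (1--5) and one column per
#'   locus holding `"high"`, `"low"` or `NA` (untyped).
#' @export
typing_profiles <- function() {
  tibble::tibble(
    profile = 1:5,
    A    = c("high", "high", "low", "low", "low"),
    B    = c("high", "high", "low", "low", "low"),
    C    = c("high", "high", NA,    NA,    NA),
    DRB1 = c("high", NA,     "high", NA,   NA),
    DQB1 = c("high", NA,     NA,     NA,   NA)
  )
}

#' Typing-profile composition of the simulated registries
#'
#' Shares (as fractions summing to 1) of the five typing profiles in the
#' reference registry and in the low- and high-data-quality variants.
#'
#' @return A tibble with columns `profile`, `reference`, `low_quality`,
#'   `high_quality`.
#' @export
profile_mixes <- function() {
  tibble::tibble(
    profile      = 1:5,
    reference    = c(30, 28, 18, 17, 7) / 100,
    low_quality  = c(25, 18, 23, 27, 7) / 100,
    high_quality = c(35, 38, 13, 7, 7) / 100
  )
}

## internal: profile spec (named chr vector over loci) from id or spec row
.profile_spec <- function(profile) {
  if (is.numeric(profile) && length(profile) == 1L) {
    profs <- typing_profiles()
    if (!profile %in% profs$profile) {
      rlang::abort(paste0("unknown typing profile: ", profile))
    }
    row <- profs[profs$profile == profile, hla_loci()]
    spec <- as.character(unlist(row))
    names(spec) <- hla_loci()
    return(spec)
  }
  if (is.character(profile) && !is.null(names(profile))) {
    if (!setequal(names(profile), hla_loci())) {
      rlang::abort("profile spec must be named by the five HLA loci")
    }
    return(profile[hla_loci()])
  }
  rlang::abort("profile must be a profile id (1-5) or a named per-locus spec")
}

# ---------------------------------------------------------------------------
# haplotype and phenotype string representations
# ---------------------------------------------------------------------------

#' Parse haplotype strings into an allele matrix
#'
#' Haplotypes are serialized as the five allele codes joined by `~`
#' (e.g. `"01:01~08:01~07:01~03:01~02:01"`), loci in [hla_loci()] order.
#' Whitespace around codes is tolerated.
#'
#' @param x Character vector of haplotype strings.
#' @return Character matrix with one row per haplotype and one column
#'   per locus.
#' @export
parse_haplotypes <- function(x) {
  parts <- strsplit(as.character(x), "~", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) {
    rlang::abort(paste0(
      "haplotype must have exactly 5 '~'-separated codes; offending entry: ",
      x[which(bad)[1]]
    ))
  }
  m <- matrix(trimws(unlist(parts)), ncol = 5L, byrow = TRUE)
  colnames(m) <- hla_loci()
  if (any(m == "")) rlang::abort("empty allele code in haplotype string")
  m
}

#' Format an allele matrix as haplotype strings
#' @param m Character matrix, one row per haplotype, loci as columns.
#' @return Character vector of `~`-joined haplotype strings.
#' @export
format_haplotypes <- function(m) {
  apply(m, 1L, paste, collapse = "~")
}

#' Build canonical phenotype strings from two haplotypes
#'
#' A phenotype is the unordered allele pair at each locus; it is stored
#' canonically with the two codes of each locus sorted lexicographically
#' and loci joined by `|`, e.g. `"01:01,02:01|07:02,08:01|..."`.
#' The function is symmetric in its arguments.
#'
#' @param hap1,hap2 Character vectors of haplotype strings (recycled).
#' @return Character vector of canonical phenotype strings.
#' @export
phenotype_from_haplotypes <- function(hap1, hap2) {
  n <- max(length(hap1), length(hap2))
  hap1 <- rep_len(hap1, n); hap2 <- rep_len(hap2, n)
  m1 <- parse_haplotypes(hap1)
  m2 <- parse_haplotypes(hap2)
  lo <- pmin(m1, m2)
  hi <- pmax(m1, m2)
  cells <- matrix(paste0(lo, ",", hi), ncol = 5L)
  apply(cells, 1L, paste, collapse = "|")
}

## internal: parse phenotype strings into two n x 5 matrices (sorted pairs)
.parse_phenotype_matrices <- function(x) {
  loci <- strsplit(as.character(x), "|", fixed = TRUE)
  bad <- lengths(loci) != 5L
  if (any(bad)) {
    rlang::abort(paste0(
      "phenotype must have exactly 5 '|'-separated loci; offending entry: ",
      x[which(bad)[1]]
    ))
  }
  cells <- matrix(trimws(unlist(loci)), ncol = 5L, byrow = TRUE)
  pairs <- strsplit(cells, ",", fixed = TRUE)
  if (any(lengths(pairs) != 2L)) {
    rlang::abort("each phenotype locus must carry exactly two comma-separated codes")
  }
  flat <- matrix(trimws(unlist(pairs)), nrow = 2L)
  a <- matrix(flat[1L, ], ncol = 5L)
  b <- matrix(flat[2L, ], ncol = 5L)
  if (any(a == "") || any(b == "")) rlang::abort("empty allele code in phenotype")
  lo <- pmin(a, b); hi <- pmax(a, b)
  colnames(lo) <- colnames(hi) <- hla_loci()
  list(lo = lo, hi = hi)
}

#' Canonicalize phenotype strings
#'
#' Re-sorts the per-locus allele pairs so that equality of canonical
#' strings is equality of phenotypes.
#'
#' @param x Character vector of phenotype strings (any per-locus order).
#' @return Canonical phenotype strings.
#' @export
canonical_phenotype <- function(x) {
  p <- .parse_phenotype_matrices(x)
  cells <- matrix(paste0(p$lo, ",", p$hi), ncol = 5L)
  apply(cells, 1L, paste, collapse = "|")
}

#' Test complete high-resolution (10/10) phenotype identity
#'
#' Two fully typed phenotypes match when their unordered allele pairs are
#' equal at all five loci. Order of the two alleles within a locus is
#' irrelevant.
#'
#' @param a,b Character vectors of phenotype strings (recycled).
#' @return Logical vector.
#' @export
phenotypes_match <- function(a, b) {
  canonical_phenotype(a) == canonical_phenotype(b)
}

# ---------------------------------------------------------------------------
# resolution maps
# ---------------------------------------------------------------------------

#' Construct a resolution map
#'
#' A resolution map gives, per locus, the low-resolution and broad
#' serological images of every high-resolution allele code. It must be
#' total on every allele it is applied to.
#'
#' @param tbl Data frame with columns `locus`, `high_code`, `low_code`
#'   and optionally `broad_code` (defaults to `low_code`).
#' @return A tibble of class `resolution_map`.
#' @export
resolution_map <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("locus", "high_code", "low_code")
  if (!all(need %in% names(tbl))) {
    rlang::abort("resolution map needs columns locus, high_code, low_code")
  }
  if (!"broad_code" %in% names(tbl)) tbl$broad_code <- tbl$low_code
  tbl$broad_code <- dplyr::coalesce(tbl$broad_code, tbl$low_code)
  if (anyDuplicated(paste(tbl$locus, tbl$high_code))) {
    rlang::abort("duplicate (locus, high_code) entry in resolution map")
  }
  structure(tbl[, c("locus", "high_code", "low_code", "broad_code")],
            class = c("resolution_map", class(tibble::tibble())))
}

#' First-field truncation resolution map
#'
#' Builds a [resolution_map()] for all alleles appearing in a haplotype
#' set by truncating each high-resolution code at the first `:`
#' (molecular first-field as the low-resolution dialect); broad codes
#' default to the same truncation. Trailing `g`-group markers are carried
#' verbatim on the high-resolution code and stripped from the truncated
#' image only if the separator is absent.
#'
#' @param haplotypes Character vector of haplotype strings, or an
#'   `hf_set` (its haplotypes are used).
#' @return A `resolution_map` covering every allele in the input.
#' @export
default_resolution_map <- function(haplotypes) {
  if (inherits(haplotypes, "hf_set")) haplotypes <- haplotypes$haplotype
  m <- parse_haplotypes(haplotypes)
  tbl <- tibble::tibble(
    locus = rep(hla_loci(), each = nrow(m)),
    high_code = as.character(m)
  )
  tbl <- dplyr::distinct(tbl)
  tbl$low_code <- sub(":.*$", "", tbl$high_code)
  tbl$broad_code <- tbl$low_code
  resolution_map(tbl)
}

## internal: named lookup vectors for a locus
.map_lookup <- function(map, locus, what = c("low_code", "broad_code")) {
  what <- match.arg(what)
  sub <- map[map$locus == locus, ]
  stats::setNames(sub[[what]], sub$high_code)
}

## internal: map a matrix of high-res codes to low/broad images
.map_codes <- function(codes, locus, map, what = "low_code") {
  lk <- .map_lookup(map, locus, what)
  out <- unname(lk[codes])
  if (anyNA(out)) {
    missing <- unique(codes[is.na(out)])
    rlang::abort(paste0(
      "resolution map has no entry for locus ", locus, ", code(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  out
}

# ---------------------------------------------------------------------------
# observed typings and masking
# ---------------------------------------------------------------------------

#' Construct an observed typing
#'
#' @param codes Named list (by locus); each element `NULL` (untyped) or a
#'   length-2 character vector of codes (stored sorted).
#' @param resolution Named character vector (by locus): `"high"`, `"low"`
#'   or `NA` for untyped loci.
#' @param profile Optional typing-profile id the observation was produced
#'   under.
#' @return Object of class `observed_typing`.
#' @export
observed_typing <- function(codes, resolution, profile = NA_integer_) {
  loci <- hla_loci()
  codes <- codes[loci]
  names(codes) <- loci
  resolution <- resolution[loci]
  names(resolution) <- loci
  for (l in loci) {
    if (is.null(codes[[l]])) {
      resolution[[l]] <- NA_character_
    } else {
      if (length(codes[[l]]) != 2L) {
        rlang::abort("typed locus must carry exactly two codes")
      }
      codes[[l]] <- unname(sort(codes[[l]]))
      if (is.na(resolution[[l]])) {
        rlang::abort(paste0("typed locus ", l, " needs a declared resolution"))
      }
    }
  }
  structure(list(codes = codes, resolution = resolution,
                 profile = as.integer(profile)),
            class = "observed_typing")
}

#' @export
format.observed_typing <- function(x, ...) {
  cells <- vapply(hla_loci(), function(l) {
    if (is.null(x$codes[[l]])) "-"
    else paste0(x$resolution[[l]], "=", paste(x$codes[[l]], collapse = ","))
  }, character(1))
  paste(cells, collapse = "|")
}

#' @export
print.observed_typing <- function(x, ...) {
  cat("<observed_typing", if (!is.na(x$profile)) paste0(" profile #", x$profile),
      "> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.observed_typing <- function(x, ...) format(x)

#' Parse an observed-typing string
#'
#' Inverse of `format()` on [observed_typing()] objects: five
#' `|`-separated cells, each `-` (untyped) or `res=code1,code2`.
#'
#' @param x Single observed-typing string.
#' @param profile Optional profile id to attach.
#' @return An `observed_typing`.
#' @export
parse_observed_typing <- function(x, profile = NA_integer_) {
  cells <- strsplit(x, "|", fixed = TRUE)[[1]]
  if (length(cells) != 5L) rlang::abort("observed typing must have 5 loci")
  codes <- vector("list", 5L); names(codes) <- hla_loci()
  res <- rep(NA_character_, 5L); names(res) <- hla_loci()
  for (i in seq_len(5L)) {
    cell <- trimws(cells[i])
    if (cell == "-" || cell == "") next
    eq <- regexpr("=", cell, fixed = TRUE)
    if (eq < 0) rlang::abort("typed cell must be 'res=code1,code2'")
    res[i] <- substr(cell, 1L, eq - 1L)
    codes[[i]] <- sort(trimws(strsplit(substring(cell, eq + 1L), ",")[[1]]))
  }
  observed_typing(codes, res, profile)
}

#' Mask a phenotype according to a typing profile
#'
#' Models what a registry knows about a donor: loci untyped in the
#' profile are dropped; loci typed at low resolution carry the
#' low-resolution images of both alleles; high-resolution loci carry the
#' original codes. The result never contains information absent from the
#' source phenotype.
#'
#' @param phenotype Phenotype string.
#' @param profile Typing-profile id (1--5) or a named per-locus spec
#'   (`"high"`, `"low"`, `NA`).
#' @param map A [resolution_map()]; required when any locus is typed at
#'   low resolution.
#' @return An [observed_typing()].
#' @export
mask_phenotype <- function(phenotype, profile, map = NULL) {
  spec <- .profile_spec(profile)
  p <- .parse_phenotype_matrices(phenotype)
  codes <- vector("list", 5L); names(codes) <- hla_loci()
  for (l in hla_loci()) {
    s <- spec[[l]]
    if (is.na(s)) next
    pair <- c(p$lo[1L, l], p$hi[1L, l])
    if (s == "low") {
      if (is.null(map)) rlang::abort("a resolution map is required for low-resolution masking")
      pair <- .map_codes(pair, l, map, "low_code")
    } else if (s != "high") {
      rlang::abort(paste0("unknown resolution spec '", s, "' at locus ", l))
    }
    codes[[l]] <- sort(pair)
  }
  pid <- if (is.numeric(profile) && length(profile) == 1L) as.integer(profile) else NA_integer_
  observed_typing(codes, spec, pid)
}

#' Could a phenotype have produced an observed typing?
#'
#' True iff masking `phenotype` under the observation's per-locus
#' resolution spec reproduces the observation exactly. This is the
#' support predicate of the matching-probability model.
#'
#' @param obs An [observed_typing()].
#' @param phenotype Phenotype string.
#' @param map A [resolution_map()].
#' @return Logical scalar.
#' @export
compatible <- function(obs, phenotype, map = NULL) {
  masked <- mask_phenotype(phenotype, obs$resolution, map)
  identical(masked$codes, obs$codes)
}

#' Convert phenotypes to broad-antigen genotype pairs at one locus
#'
#' Maps both alleles of each phenotype at `locus` to their broad
#' serological codes; used for Hardy-Weinberg diagnostics on typing data
#' of mixed original resolution.
#'
#' @param phenotypes Character vector of phenotype strings.
#' @param map A [resolution_map()] defining broad images at `locus`.
#' @param locus One of [hla_loci()].
#' @return Tibble with columns `a1`, `a2` (sorted broad codes), one row
#'   per input phenotype.
#' @export
to_broad <- function(phenotypes, map, locus) {
  stopifnot(locus %in% hla_loci())
  p <- .parse_phenotype_matrices(phenotypes)
  b1 <- .map_codes(p$lo[, locus], locus, map, "broad_code")
  b2 <- .map_codes(p$hi[, locus], locus, map, "broad_code")
  tibble::tibble(a1 = pmin(b1, b2), a2 = pmax(b1, b2))
}
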