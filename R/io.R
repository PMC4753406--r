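## header comment written by every table writer; readers skip '#' lines
.file_header <- function(kind) {
  sprintf("# ufsim %s %s | written %s",
          as.character(utils::packageVersion("ufsim")), kind,
          format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
}

.write_tsv <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(kind), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.read_tsv <- function(path, colClasses = NA) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "",
                    check.names = FALSE, colClasses = colClasses) |>
    tibble::as_tibble()
}

#' Read a haplotype-frequency table
#'
#' TSV with columns `haplotype` (`~`-joined five-locus strings, optional
#' whitespace tolerated) and `frequency` (decimals; pass
#' `percent = TRUE` for a percent column). Comment lines starting with
#' `#` are ignored.
#'
#' @param path File path.
#' @param renormalize Rescale frequencies to sum to 1; without it, a sum
#'   outside `[0.99, 1.01]` is a validation error.
#' @param percent Input column is in percent.
#' @return An [hf_set()].
#' @export
read_hf_table <- function(path, renormalize = FALSE, percent = FALSE) {
  tbl <- .read_tsv(path)
  if (nrow(tbl) == 0) rlang::abort(paste0("empty haplotype-frequency file: ", path))
  if (!all(c("haplotype", "frequency") %in% names(tbl))) {
    rlang::abort("haplotype-frequency table needs columns 'haplotype' and 'frequency'")
  }
  hap <- gsub("[[:space:]]", "", tbl$haplotype)
  if (anyDuplicated(hap)) {
    line <- which(duplicated(hap))[1]
    rlang::abort(paste0("duplicate haplotype at data line ", line, ": ", hap[line]))
  }
  f <- as.numeric(tbl$frequency)
  if (percent) f <- f / 100
  s <- sum(f)
  if (!renormalize && (s < 0.99 || s > 1.01)) {
    rlang::abort(sprintf(
      "frequencies sum to %.6g (outside [0.99, 1.01]); use renormalize = TRUE", s))
  }
  hf_set(hap, f, renormalize = TRUE, label = basename(path))
}

#' Read a haplotype-frequency fragment without normalization
#'
#' Published frequency tables often list only the head of a
#' distribution (e.g. the 20 most frequent haplotypes), so their
#' frequencies deliberately do not sum to 1. This reader keeps the
#' printed scale, for cumulative-frequency arithmetic on fragments.
#'
#' @param path File path.
#' @return Tibble `haplotype`, `frequency` (printed scale), `cumulative`.
#' @export
read_hf_fragment <- function(path) {
  tbl <- .read_tsv(path)
  if (nrow(tbl) == 0) rlang::abort(paste0("empty haplotype-frequency file: ", path))
  hap <- gsub("[[:space:]]", "", tbl$haplotype)
  if (anyDuplicated(hap)) rlang::abort("duplicate haplotype in fragment")
  tibble::tibble(haplotype = hap, frequency = as.numeric(tbl$frequency),
                 cumulative = cumsum(as.numeric(tbl$frequency)))
}

#' Write a haplotype-frequency table
#' @param hfs An [hf_set()].
#' @param path Output path (TSV).
#' @export
write_hf_table <- function(hfs, path) {
  .write_tsv(tibble::tibble(haplotype = hfs$haplotype,
                            frequency = format(hfs$frequency, digits = 17)),
             path, "haplotype-frequency table")
  invisible(path)
}

#' Read / write a resolution map
#' @param path TSV with columns `locus`, `high_code`, `low_code` and
#'   optional `broad_code`.
#' @return A [resolution_map()].
#' @export
read_resolution_map <- function(path) {
  resolution_map(.read_tsv(path, colClasses = "character"))
}

#' @rdname read_resolution_map
#' @param map A [resolution_map()].
#' @export
write_resolution_map <- function(map, path) {
  .write_tsv(map, path, "resolution map")
  invisible(path)
}

#' Write a registry to observed and hidden files
#'
#' The observed file (what a real registry would know) carries donor id,
#' profile and per-locus observed codes (empty cell = untyped); the
#' hidden file carries the true phenotypes (plus the haplotype indices
#' used to form them) and is read only for outcome labeling.
#'
#' @param registry A `donor_registry`.
#' @param observed_path,hidden_path Output paths.
#' @export
write_registry <- function(registry, observed_path, hidden_path) {
  obs <- registry$observed
  profs <- typing_profiles()
  cells <- matrix("", nrow = nrow(obs), ncol = 5L,
                  dimnames = list(NULL, hla_loci()))
  for (p in 1:5) {
    sel <- obs$profile == p
    if (!any(sel)) next
    typed <- hla_loci()[!is.na(unlist(profs[profs$profile == p, hla_loci()]))]
    parts <- strsplit(obs$obs_key[sel], "|", fixed = TRUE)
    pm <- matrix(unlist(parts), ncol = length(typed), byrow = TRUE)
    for (c in seq_along(typed)) cells[sel, typed[c]] <- pm[, c]
  }
  .write_tsv(tibble::tibble(id = obs$id, profile = obs$profile,
                            tibble::as_tibble(cells)),
             observed_path, "registry observed typings")
  .write_tsv(registry$hidden, hidden_path, "registry hidden phenotypes")
  invisible(c(observed_path, hidden_path))
}

#' Read a registry written by [write_registry()]
#'
#' @param observed_path,hidden_path Paths written by [write_registry()].
#' @param hfs The [hf_set()] the registry was built from.
#' @param map The [resolution_map()] used for masking.
#' @return A `donor_registry`.
#' @export
read_registry <- function(observed_path, hidden_path, hfs, map = NULL) {
  if (is.null(map)) map <- default_resolution_map(hfs)
  obs <- .read_tsv(observed_path)
  hid <- .read_tsv(hidden_path)
  profs <- typing_profiles()
  cells <- as.matrix(obs[, hla_loci()])
  cells[is.na(cells)] <- ""
  obs_key <- character(nrow(obs))
  for (p in 1:5) {
    sel <- obs$profile == p
    if (!any(sel)) next
    typed <- hla_loci()[!is.na(unlist(profs[profs$profile == p, hla_loci()]))]
    obs_key[sel] <- apply(cells[sel, typed, drop = FALSE], 1L, paste,
                          collapse = "|")
  }
  structure(list(
    observed = tibble::tibble(id = as.integer(obs$id),
                              profile = as.integer(obs$profile),
                              obs_key = obs_key),
    hidden = tibble::tibble(id = as.integer(hid$id),
                            h1 = as.integer(hid$h1), h2 = as.integer(hid$h2),
                            phenotype = hid$phenotype),
    hfs = hfs, map = map, mix = NULL, seed = NA_integer_,
    size = nrow(obs)
  ), class = "donor_registry")
}

#' Write / read a patient panel
#' @param panel Panel from [build_patients()].
#' @param path TSV path.
#' @export
write_patients <- function(panel, path) {
  .write_tsv(panel, path, "patient panel")
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  tbl <- .read_tsv(path)
  tibble::tibble(id = as.integer(tbl$id), h1 = as.integer(tbl$h1),
                 h2 = as.integer(tbl$h2), phenotype = tbl$phenotype)
}

#' Read a scenario configuration from YAML
#'
#' Recognized keys: `size`, `mix`, `hf`, `strategy`, `requests`,
#' `patients`, `repeats`, `seed`, `n_haplotypes`, `label`.
#'
#' @param path YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("size", "seed")
  if (!all(need %in% names(y))) {
    rlang::abort("scenario config needs at least 'size' and 'seed'")
  }
  scenario_config(
    size = y$size,
    mix = y$mix %||% "reference",
    hf = y$hf %||% "reference",
    strategy = y$strategy %||% "A",
    max_requests = y$requests %||% 3L,
    n_patients = y$patients %||% 2000L,
    repeats = y$repeats %||% 3L,
    seed = y$seed,
    n_haplotypes = y$n_haplotypes %||% 5000L,
    label = y$label %||% NULL
  )
}

#' Run manifest for reproducibility
#'
#' Collects everything needed to reproduce a run bit-for-bit: package
#' version, input-file MD5 digests, seeds, scenario descriptor and a
#' timestamp.
#'
#' @param inputs Character vector of input file paths.
#' @param seeds Named list/vector of seeds.
#' @param scenario Optional scenario descriptor (label or config).
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(inputs = character(0), seeds = list(),
                         scenario = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  structure(list(
    tool = "ufsim",
    version = as.character(utils::packageVersion("ufsim")),
    inputs = digests,
    seeds = seeds,
    scenario = if (inherits(scenario, "scenario_config")) scenario$label else scenario,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
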