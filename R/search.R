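#' Search configuration
#'
#' @param max_requests Typing-request budget T (>= 0).
#' @param strategy `"A"` (profile-5 donors may receive typing requests)
#'   or `"B"` (profile-5 donors are never requested).
#' @param seed Integer seed driving the random tie-breaks; each patient
#'   gets an independent derived stream so results do not depend on
#'   processing order.
#' @return List of class `search_config`.
#' @export
search_config <- function(max_requests = 3L, strategy = c("A", "B"), seed = 1L) {
  strategy <- match.arg(strategy)
  if (max_requests < 0) rlang::abort("max_requests must be >= 0")
  structure(list(max_requests = as.integer(max_requests), strategy = strategy,
                 seed = as.integer(seed)), class = "search_config")
}

## ---------------------------------------------------------------------------
## precomputed search state for a registry
## ---------------------------------------------------------------------------
.search_prep <- function(registry) {
  idx <- .mp_index(registry$hfs, registry$map)
  pheno_entry <- .mp_spec(idx, stats::setNames(rep("high", 5L), hla_loci()))
  profile_entries <- lapply(stats::setNames(2:5, 2:5),
                            function(p) .mp_spec(idx, .profile_spec(p)))
  obs <- registry$observed
  donor_groups <- lapply(stats::setNames(2:5, 2:5), function(p) {
    sel <- obs$profile == p
    split(obs$id[sel], obs$obs_key[sel])
  })
  p1 <- obs$profile == 1L
  p1_min <- if (any(p1)) {
    tapply(obs$id[p1], obs$obs_key[p1], min)
  } else {
    stats::setNames(integer(0), character(0))
  }
  hidden <- registry$hidden
  true_key <- character(max(hidden$id))
  true_key[hidden$id] <- hidden$phenotype
  key_counts <- table(hidden$phenotype)
  list(idx = idx, pheno_entry = pheno_entry, profile_entries = profile_entries,
       donor_groups = donor_groups, p1_min = p1_min, true_key = true_key,
       key_counts = key_counts)
}

## per-locus sorted image pairs of a patient under a spec entry
.patient_pairs <- function(entry, i, j) {
  typed <- entry$typed
  out <- lapply(typed, function(l) sort(c(entry$img[i, l], entry$img[j, l])))
  names(out) <- typed
  out
}

#' Find a readily identifiable matching donor
#'
#' Returns a fully typed (profile 1) donor whose observed -- hence true
#' -- phenotype matches the patient, if one exists; the lowest donor id
#' wins ties. Such a patient needs no typing requests.
#'
#' @param registry A `donor_registry`.
#' @param patient Patient phenotype string.
#' @return Donor id, or `NA` if none.
#' @export
find_ready_match <- function(registry, patient) {
  key <- canonical_phenotype(patient)
  obs <- registry$observed
  sel <- obs$profile == 1L & obs$obs_key == key
  if (!any(sel)) return(NA_integer_)
  min(obs$id[sel])
}

#' Does any registered donor truly match the patient?
#'
#' Scans the hidden true phenotypes (any profile); used only for
#' post-hoc outcome labeling, never for ranking.
#'
#' @inheritParams find_ready_match
#' @return Logical scalar.
#' @export
true_match_exists <- function(registry, patient) {
  key <- canonical_phenotype(patient)
  any(registry$hidden$phenotype == key)
}

## MP-ordered candidate groups for one patient (internal core)
## returns list of groups: each list(mp, ids) in walk order, tie-groups merged
.candidate_groups <- function(prep, h1, h2, pheno_key, strategy) {
  profiles <- if (strategy == "B") 2:4 else 2:5
  cand <- list()
  num <- NULL
  for (p in profiles) {
    entry <- prep$profile_entries[[as.character(p)]]
    key <- .pair_obs_keys(entry, h1, h2)
    ids <- prep$donor_groups[[as.character(p)]][[key]]
    if (is.null(ids) || length(ids) == 0L) next
    if (is.null(num)) {
      num <- .obs_mass(prep$idx, prep$pheno_entry,
                       .patient_pairs(prep$pheno_entry, h1, h2))
    }
    den <- .obs_mass(prep$idx, entry, .patient_pairs(entry, h1, h2))
    mp <- if (den > 0) num / den else 0
    if (mp > 0) {
      cand[[length(cand) + 1L]] <- list(profile = p, mp = mp, ids = ids)
    }
  }
  if (length(cand) == 0L) return(list())
  mps <- vapply(cand, `[[`, 1, "mp")
  tie <- signif(mps, 12)
  ## order tie groups by mp descending; merge members (profile ascending)
  lev <- sort(unique(tie), decreasing = TRUE)
  lapply(lev, function(tv) {
    members <- which(tie == tv)
    members <- members[order(vapply(cand[members], `[[`, 1, "profile"))]
    list(mp = tv,
         ids = unlist(lapply(cand[members], `[[`, "ids"), use.names = FALSE),
         profiles = unlist(lapply(cand[members], function(m)
           rep(m$profile, length(m$ids))), use.names = FALSE))
  })
}

#' Rank typing-request candidates for a patient
#'
#' All incompletely typed donors compatible with the patient (positive
#' matching probability), ordered by MP descending; donors whose MP is
#' identical after rounding to 12 significant digits form a tie group
#' whose internal order is a seeded random permutation. Under strategy
#' `"B"` profile-5 donors are excluded.
#'
#' @inheritParams find_ready_match
#' @param strategy `"A"` or `"B"`.
#' @param seed Integer seed for the tie-break permutation.
#' @return Tibble `donor_id`, `profile`, `mp` in request order.
#' @export
rank_candidates <- function(registry, patient, strategy = c("A", "B"),
                            seed = 1L) {
  strategy <- match.arg(strategy)
  prep <- .search_prep(registry)
  key <- canonical_phenotype(patient)
  hp <- .match_patient_haplotypes(registry, patient)
  groups <- .candidate_groups(prep, hp[1], hp[2], key, strategy)
  if (length(groups) == 0L) {
    return(tibble::tibble(donor_id = integer(0), profile = integer(0),
                          mp = numeric(0)))
  }
  .with_seed(seed, {
    rows <- lapply(groups, function(g) {
      perm <- sample.int(length(g$ids))
      tibble::tibble(donor_id = g$ids[perm], profile = g$profiles[perm],
                     mp = g$mp)
    })
    dplyr::bind_rows(rows)
  })
}

## a patient phenotype must decompose into two support haplotypes for the
## fast image machinery; find one decomposition (error if none)
.match_patient_haplotypes <- function(registry, patient) {
  hapmat <- .hf_hapmat(registry$hfs)
  p <- .parse_phenotype_matrices(patient)
  k <- nrow(hapmat)
  cand <- rep(TRUE, k)
  for (l in hla_loci()) {
    cand <- cand & (hapmat[, l] == p$lo[1L, l] | hapmat[, l] == p$hi[1L, l])
  }
  ids <- which(cand)
  for (i in ids) {
    comp <- ifelse(hapmat[i, ] == p$lo[1L, ], p$hi[1L, ], p$lo[1L, ])
    j <- ids[vapply(ids, function(j) all(hapmat[j, ] == comp), TRUE)]
    if (length(j) > 0) return(c(i, j[1]))
  }
  rlang::abort("patient phenotype cannot be formed from the haplotype support")
}

#' Simulate one patient's donor search
#'
#' (1) If a fully typed matching donor exists the search is `READY` with
#' zero requests. (2) Otherwise candidates are walked in
#' [rank_candidates()] order; each typing request unmasks the donor's
#' true phenotype, stopping at the first confirmed match
#' (`FOUND_IN_SEARCH`) or after `min(T, available)` requests. (3) A
#' failed search is `UFS` when a truly matching donor exists anywhere in
#' the registry, else `NO_MATCH_EXISTS`.
#'
#' @inheritParams find_ready_match
#' @param config A [search_config()].
#' @return List of class `search_result`: `outcome`, `requests_used`,
#'   `matched_donor_id`, `request_log` (tibble `rank`, `donor_id`,
#'   `profile`, `mp`, `hit`).
#' @export
run_search <- function(registry, patient, config = search_config()) {
  key <- canonical_phenotype(patient)
  ready <- find_ready_match(registry, patient)
  empty_log <- tibble::tibble(rank = integer(0), donor_id = integer(0),
                              profile = integer(0), mp = numeric(0),
                              hit = logical(0))
  if (!is.na(ready)) {
    return(structure(list(outcome = "READY", requests_used = 0L,
                          matched_donor_id = ready, request_log = empty_log),
                     class = "search_result"))
  }
  order_tbl <- rank_candidates(registry, patient, config$strategy, config$seed)
  t_max <- min(config$max_requests, nrow(order_tbl))
  hidden <- registry$hidden
  true_key <- stats::setNames(hidden$phenotype, hidden$id)
  hit_at <- NA_integer_
  n_used <- 0L
  log <- order_tbl[seq_len(t_max), ]
  log$rank <- seq_len(t_max)
  log$hit <- FALSE
  for (r in seq_len(t_max)) {
    n_used <- r
    if (true_key[[as.character(log$donor_id[r])]] == key) {
      log$hit[r] <- TRUE
      hit_at <- r
      break
    }
  }
  log <- log[seq_len(n_used), c("rank", "donor_id", "profile", "mp", "hit")]
  if (!is.na(hit_at)) {
    outcome <- "FOUND_IN_SEARCH"
    matched <- log$donor_id[hit_at]
  } else {
    matched <- NA_integer_
    outcome <- if (true_match_exists(registry, patient)) "UFS" else "NO_MATCH_EXISTS"
  }
  structure(list(outcome = outcome, requests_used = n_used,
                 matched_donor_id = matched, request_log = log),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result: ", x$outcome, ", ", x$requests_used, " requests",
      if (!is.na(x$matched_donor_id)) paste0(", donor ", x$matched_donor_id),
      ">\n", sep = "")
  invisible(x)
}

#' Simulate donor searches for a whole patient panel
#'
#' Vectorized panel-level driver used by the scenario experiments: runs
#' [run_search()] semantics for every patient against one registry.
#' Per-patient tie-break streams are derived from `(seed, patient id)`,
#' so results are independent of processing order, and the request
#' sequence of a patient is a prefix extension as the budget grows
#' (outcomes for any smaller budget can be derived from the logs, see
#' [outcomes_by_budget()]).
#'
#' @param registry A `donor_registry`.
#' @param panel Patient panel from [build_patients()] (same haplotype
#'   set as the registry).
#' @param config A [search_config()].
#' @return List with `results` (tibble: `patient_id`, `outcome`,
#'   `requests_used`, `matched_donor_id`, `first_hit_rank`,
#'   `n_candidates`, `match_exists`) and `log` (tibble: `patient_id`,
#'   `rank`, `donor_id`, `profile`, `mp`, `hit`).
#' @export
run_panel_search <- function(registry, panel, config = search_config()) {
  prep <- .search_prep(registry)
  n <- nrow(panel)
  t_budget <- config$max_requests
  ## vectorized patient keys per profile spec
  pheno_keys <- panel$phenotype
  ready_id <- prep$p1_min[pheno_keys]
  exists_n <- as.integer(prep$key_counts[pheno_keys])
  exists_n[is.na(exists_n)] <- 0L
  outcome <- character(n)
  requests_used <- integer(n)
  matched <- rep(NA_integer_, n)
  first_hit <- rep(NA_integer_, n)
  n_cand <- integer(n)
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(ready_id[i])) {
      outcome[i] <- "READY"
      matched[i] <- as.integer(ready_id[i])
      next
    }
    groups <- .candidate_groups(prep, panel$h1[i], panel$h2[i],
                                pheno_keys[i], config$strategy)
    n_cand[i] <- sum(vapply(groups, function(g) length(g$ids), 1L))
    hit_rank <- NA_integer_
    used <- 0L
    if (t_budget > 0L && length(groups) > 0L) {
      lg_rank <- integer(0); lg_id <- integer(0); lg_prof <- integer(0)
      lg_mp <- numeric(0)
      .with_seed(.derive_seed(config$seed, panel$id[i]), {
        for (g in groups) {
          perm <- sample.int(length(g$ids))
          ids <- g$ids[perm]; profs <- g$profiles[perm]
          take <- min(length(ids), t_budget - used)
          if (take <= 0L) break
          seg <- seq_len(take)
          hits <- prep$true_key[ids[seg]] == pheno_keys[i]
          h <- which(hits)[1]
          stopn <- if (!is.na(h)) h else take
          lg_rank <- c(lg_rank, used + seq_len(stopn))
          lg_id <- c(lg_id, ids[seq_len(stopn)])
          lg_prof <- c(lg_prof, profs[seq_len(stopn)])
          lg_mp <- c(lg_mp, rep(g$mp, stopn))
          used <- used + stopn
          if (!is.na(h)) {
            hit_rank <- used
            break
          }
          if (used >= t_budget) break
        }
      })
      logs[[i]] <- tibble::tibble(patient_id = panel$id[i], rank = lg_rank,
                                  donor_id = lg_id, profile = lg_prof,
                                  mp = lg_mp,
                                  hit = !is.na(hit_rank) & lg_rank == hit_rank)
    }
    requests_used[i] <- used
    first_hit[i] <- hit_rank
    if (!is.na(hit_rank)) {
      outcome[i] <- "FOUND_IN_SEARCH"
      matched[i] <- logs[[i]]$donor_id[hit_rank == logs[[i]]$rank]
    } else {
      outcome[i] <- if (exists_n[i] > 0L) "UFS" else "NO_MATCH_EXISTS"
    }
  }
  list(
    results = tibble::tibble(patient_id = panel$id, outcome = outcome,
                             requests_used = requests_used,
                             matched_donor_id = matched,
                             first_hit_rank = first_hit,
                             n_candidates = n_cand,
                             match_exists = exists_n > 0L),
    log = dplyr::bind_rows(logs)
  )
}
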