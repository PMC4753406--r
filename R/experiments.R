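.OUTCOMES <- c("READY", "FOUND_IN_SEARCH", "NO_MATCH_EXISTS", "UFS")

#' Scenario configuration
#'
#' Describes one simulation scenario: registry size, typing-profile
#' mix, haplotype-frequency variant, search strategy, typing-request
#' budget, patient count and number of repeats. Each repeat regenerates
#' the registry and the patient panel with seeds derived from the base
#' seed, and the across-repeat standard deviation is reported.
#'
#' @param size Registry size (number of donors).
#' @param mix Profile mix label or five shares (see
#'   [resolve_profile_mix()]).
#' @param hf `"reference"`, `"more_diverse"`, `"less_diverse"`, or an
#'   [hf_set()] to use directly.
#' @param strategy `"A"` or `"B"`.
#' @param max_requests Typing-request budget per search.
#' @param n_patients Patients per repeat (>= 1).
#' @param repeats Number of repeats (>= 1).
#' @param seed Base seed of the scenario.
#' @param n_haplotypes Size of the synthetic haplotype pool.
#' @param hf_seed Seed of the haplotype-frequency generation (shared
#'   across scenarios so that variants differ only where intended).
#' @param diversity_targets Length-2 numeric: target top-50 cumulative
#'   frequency of the `more_diverse` and `less_diverse` variants.
#' @param label Scenario label.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(size, mix = "reference", hf = "reference",
                            strategy = "A", max_requests = 3L,
                            n_patients = 2000L, repeats = 3L, seed = 1L,
                            n_haplotypes = 5000L, hf_seed = 101L,
                            diversity_targets = c(more_diverse = 0.22,
                                                  less_diverse = 0.48),
                            label = NULL) {
  if (n_patients < 1) rlang::abort("n_patients must be >= 1 (empty panels are not summarizable)")
  if (repeats < 1) rlang::abort("repeats must be >= 1")
  if (is.null(label)) {
    hf_lab <- if (inherits(hf, "hf_set")) attr(hf, "label") else hf
    label <- sprintf("N%d_%s_%s_%s_T%d", size,
                     if (is.character(mix)) mix else "custom",
                     hf_lab, strategy, max_requests)
  }
  structure(list(size = as.integer(size), mix = mix, hf = hf,
                 strategy = strategy, max_requests = as.integer(max_requests),
                 n_patients = as.integer(n_patients),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 n_haplotypes = as.integer(n_haplotypes),
                 hf_seed = as.integer(hf_seed),
                 diversity_targets = diversity_targets, label = label),
            class = "scenario_config")
}

#' Resolve the haplotype-frequency set of a scenario
#'
#' @param cfg A [scenario_config()].
#' @return An [hf_set()]: the calibrated synthetic reference
#'   distribution, or its diversity-reshaped variant.
#' @export
resolve_scenario_hf <- function(cfg) {
  if (inherits(cfg$hf, "hf_set")) return(cfg$hf)
  ref <- gen_reference_hf(cfg$n_haplotypes, seed = cfg$hf_seed)
  switch(cfg$hf,
    reference = ref,
    more_diverse = reshape_diversity(ref, top_k = 50,
      target_cumulative = cfg$diversity_targets[["more_diverse"]]),
    less_diverse = reshape_diversity(ref, top_k = 50,
      target_cumulative = cfg$diversity_targets[["less_diverse"]]),
    rlang::abort(paste0("unknown hf variant: ", cfg$hf))
  )
}

## outcome shares of one repeat's results table
.outcome_shares <- function(results) {
  tab <- table(factor(results$outcome, levels = .OUTCOMES))
  as.numeric(tab) / nrow(results)
}

#' Run one scenario
#'
#' For every repeat, regenerates registry and patient panel with derived
#' seeds, simulates all donor searches, and tabulates outcome shares;
#' aggregates mean and across-repeat standard deviation.
#'
#' @param cfg A [scenario_config()].
#' @param hfs Optional pre-resolved [hf_set()] (otherwise
#'   [resolve_scenario_hf()] is used).
#' @param keep_runs Keep per-repeat search results and request logs
#'   (needed for [outcomes_by_budget()] and
#'   [request_success_by_rank()]).
#' @return Object of class `outcome_summary`.
#' @export
run_scenario <- function(cfg, hfs = NULL, keep_runs = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.null(hfs)) hfs <- resolve_scenario_hf(cfg)
  map <- default_resolution_map(hfs)
  tidy_rows <- list()
  runs <- list()
  for (r in seq_len(cfg$repeats)) {
    reg <- build_registry(hfs, cfg$size, cfg$mix, map,
                          seed = .derive_seed(cfg$seed, r, 1))
    panel <- build_patients(hfs, cfg$n_patients,
                            seed = .derive_seed(cfg$seed, r, 2))
    run <- run_panel_search(reg, panel,
                            search_config(cfg$max_requests, cfg$strategy,
                                          seed = .derive_seed(cfg$seed, r, 3)))
    shares <- .outcome_shares(run$results)
    tidy_rows[[r]] <- tibble::tibble(scenario = cfg$label, rep = r,
                                     outcome = .OUTCOMES, share = shares)
    if (keep_runs) runs[[r]] <- run
  }
  tidy <- dplyr::bind_rows(tidy_rows)
  summary <- tidy |>
    dplyr::summarise(mean = mean(.data$share),
                     sd = stats::sd(.data$share),
                     .by = "outcome")
  cond <- tidy |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "share") |>
    dplyr::mutate(conditional_ufs = conditional_ufs(100 * .data$UFS,
                                                    100 * .data$FOUND_IN_SEARCH))
  structure(list(config = cfg, tidy = tidy, summary = summary,
                 conditional = cond[, c("scenario", "rep", "conditional_ufs")],
                 runs = runs),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat("<outcome_summary '", x$config$label, "' (", x$config$repeats,
      " repeats x ", x$config$n_patients, " patients)>\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_scenario
#' @param x An `outcome_summary`.
#' @param ... Unused.
#' @method tidy outcome_summary
#' @export
tidy.outcome_summary <- function(x, ...) x$tidy

#' @rdname run_scenario
#' @method glance outcome_summary
#' @export
glance.outcome_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary[, c("outcome", "mean")],
                             names_from = "outcome", values_from = "mean")
  tibble::tibble(scenario = x$config$label, wide,
                 ufs_sd = x$summary$sd[x$summary$outcome == "UFS"],
                 conditional_ufs = mean(x$conditional$conditional_ufs))
}

#' Conditional UFS share among coordinator-dependent searches
#'
#' Restricts attention to patients whose search outcome depended on the
#' search coordinator: those without a readily identifiable fully typed
#' match but with at least one matching donor in the registry. The
#' conditional UFS share is `UFS / (FOUND_IN_SEARCH + UFS)`, expressed
#' in percent. Shares may be given on any common scale (fractions or
#' percents).
#'
#' @param ufs UFS share(s).
#' @param found `FOUND_IN_SEARCH` share(s) on the same scale.
#' @return Percent value(s); `NA` where the denominator is zero
#'   (undefined, not an error).
#' @export
conditional_ufs <- function(ufs, found) {
  den <- ufs + found
  ifelse(den > 0, 100 * ufs / den, NA_real_)
}

#' Derive outcome shares for smaller typing-request budgets
#'
#' Because each patient's request sequence under a smaller budget is a
#' prefix of the sequence already simulated, outcomes for any budget
#' `T <= max_requests` can be derived from a single panel run without
#' re-simulation.
#'
#' @param run A single-panel result from [run_panel_search()].
#' @param budgets Integer vector of budgets, all `<=` the simulated
#'   budget.
#' @return Tibble `budget`, `outcome`, `share`.
#' @export
outcomes_by_budget <- function(run, budgets) {
  res <- run$results
  purrr::map_dfr(sort(budgets), function(tt) {
    outcome <- dplyr::case_when(
      res$outcome == "READY" ~ "READY",
      !is.na(res$first_hit_rank) & res$first_hit_rank <= tt ~ "FOUND_IN_SEARCH",
      res$match_exists ~ "UFS",
      TRUE ~ "NO_MATCH_EXISTS"
    )
    tab <- table(factor(outcome, levels = .OUTCOMES))
    tibble::tibble(budget = tt, outcome = .OUTCOMES,
                   share = as.numeric(tab) / nrow(res))
  })
}

#' Typing-request success rates by request rank and donor profile
#'
#' For each donor typing profile and request rank, the share of typing
#' requests at that rank (to donors of that profile) that uncovered a
#' complete match. Patients with READY outcomes issue no requests and
#' are naturally excluded. Cells without any request are absent rather
#' than zero.
#'
#' @param log Request log from [run_panel_search()] (or several,
#'   row-bound).
#' @param max_rank Largest request rank to report.
#' @return Tibble `profile`, `rank`, `requests`, `hits`, `success`.
#' @export
request_success_by_rank <- function(log, max_rank = 3L) {
  log |>
    dplyr::filter(.data$rank <= max_rank) |>
    dplyr::summarise(requests = dplyr::n(), hits = sum(.data$hit),
                     .by = c("profile", "rank")) |>
    dplyr::mutate(success = .data$hits / .data$requests) |>
    dplyr::arrange(.data$profile, .data$rank)
}

#' Run the study's scenario suite
#'
#' Runs the full factorial comparison around a shared reference
#' scenario: a registry-size grid, low- and high-data-quality profile
#' mixes, more- and less-diverse haplotype-frequency variants, and both
#' search strategies across a budget sweep. The default `"scaled"`
#' suite uses a 5,000-haplotype synthetic frequency distribution,
#' registries around N = 50,000, 2,000 patients and 3 repeats; the
#' `"full"` suite reproduces the original design (registries of
#' 0.6M--4.6M donors, 10,000 patients) and runs for hours.
#'
#' @param scale `"scaled"` or `"full"`.
#' @param seed Base seed.
#' @param n_patients,repeats,budget Overrides for the suite parameters.
#' @param budget_max Budget simulated for the strategy comparison (the
#'   budget sweep is derived from it).
#' @return List with `tidy` (scenario, rep, outcome, share),
#'   `summary` (per scenario/outcome mean and sd), `budget_sweep`
#'   (strategy, rep, budget, UFS share), `request_success`, and
#'   `scenarios` (the configurations used).
#' @export
scenario_grid <- function(scale = c("scaled", "full"), seed = 1L,
                          n_patients = NULL, repeats = 3L, budget = 3L,
                          budget_max = 10L) {
  scale <- match.arg(scale)
  if (scale == "scaled") {
    sizes <- c(20000L, 50000L, 100000L)
    ref_size <- 50000L
    n_hap <- 5000L
    if (is.null(n_patients)) n_patients <- 2000L
  } else {
    sizes <- c(600000L, 1600000L, 2600000L, 3600000L, 4600000L)
    ref_size <- 2600000L
    n_hap <- 30000L
    if (is.null(n_patients)) n_patients <- 10000L
  }
  base_cfg <- function(...) {
    scenario_config(..., n_patients = n_patients, repeats = repeats,
                    seed = seed, n_haplotypes = n_hap)
  }
  ref_hf <- resolve_scenario_hf(base_cfg(size = ref_size))
  summaries <- list()
  ## size grid (includes the reference size)
  for (s in sizes) {
    cfg <- base_cfg(size = s, max_requests = budget,
                    label = sprintf("size_%d", s))
    summaries[[cfg$label]] <- run_scenario(cfg, hfs = ref_hf)
  }
  ## profile-mix variants
  for (m in c("low_quality", "high_quality")) {
    cfg <- base_cfg(size = ref_size, mix = m, max_requests = budget,
                    label = paste0("mix_", m))
    summaries[[cfg$label]] <- run_scenario(cfg, hfs = ref_hf)
  }
  ## diversity variants (patients follow the donor population)
  for (d in c("more_diverse", "less_diverse")) {
    cfg <- base_cfg(size = ref_size, hf = d, max_requests = budget,
                    label = paste0("hf_", d))
    summaries[[cfg$label]] <- run_scenario(cfg)
  }
  ## strategy comparison at budget_max on the reference registry;
  ## smaller budgets derived from the logs
  sweep_rows <- list()
  req_success <- NULL
  for (strat in c("A", "B")) {
    cfg <- base_cfg(size = ref_size, strategy = strat,
                    max_requests = budget_max,
                    label = paste0("strategy_", strat))
    sm <- run_scenario(cfg, hfs = ref_hf, keep_runs = TRUE)
    summaries[[cfg$label]] <- sm
    for (r in seq_along(sm$runs)) {
      ob <- outcomes_by_budget(sm$runs[[r]], seq_len(budget_max))
      sweep_rows[[paste(strat, r)]] <- ob |>
        dplyr::filter(.data$outcome == "UFS") |>
        dplyr::transmute(strategy = strat, rep = r, budget = .data$budget,
                         ufs_share = .data$share)
    }
    if (strat == "A") {
      req_success <- request_success_by_rank(
        dplyr::bind_rows(lapply(sm$runs, `[[`, "log")), max_rank = 3L)
    }
  }
  for (nm in names(summaries)) summaries[[nm]]$runs <- list()
  tidy <- dplyr::bind_rows(lapply(summaries, `[[`, "tidy"))
  summary <- dplyr::bind_rows(lapply(summaries, function(s) {
    dplyr::mutate(s$summary, scenario = s$config$label, .before = 1)
  }))
  list(tidy = tidy, summary = summary,
       budget_sweep = dplyr::bind_rows(sweep_rows),
       request_success = req_success,
       scenarios = lapply(summaries, `[[`, "config"))
}
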