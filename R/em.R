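#' Smallest meaningfully estimable haplotype frequency
#'
#' The resolution limit of a haplotype-frequency estimate from a sample
#' of `n` individuals is `1/n`; estimated haplotypes with lower frequency
#' are typically EM artifacts.
#'
#' @param n Sample size (integer >= 1).
#' @return `1/n`.
#' @export
resolution_limit <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    rlang::abort("n must be a single integer >= 1")
  }
  1 / n
}

#' Rank-cumulative summaries of a frequency distribution
#'
#' @param hfs An [hf_set()].
#' @param thresholds Cumulative-frequency thresholds in (0, 1]; for each,
#'   the smallest number of top-ranked haplotypes reaching it.
#' @param top_ks Ranks k; for each, the cumulative frequency of the k
#'   most frequent haplotypes.
#' @param freq_floor Optional frequency floor; reports how many
#'   haplotypes lie above it and their cumulative mass.
#' @return List of tibbles `ranks`, `top_k` and (if requested) `floor`.
#' @export
cumulative_rank_summary <- function(hfs, thresholds = c(0.5, 0.75),
                                    top_ks = c(20, 50), freq_floor = NULL) {
  stopifnot(inherits(hfs, "hf_set"))
  if (any(thresholds <= 0 | thresholds > 1)) {
    rlang::abort("thresholds must lie in (0, 1]")
  }
  cum <- cumsum(hfs$frequency)
  ranks <- tibble::tibble(
    threshold = thresholds,
    n_haplotypes = vapply(thresholds, function(t) which(cum >= t - 1e-12)[1], 1L)
  )
  top_ks <- pmin(top_ks, nrow(hfs))
  topk <- tibble::tibble(top_k = top_ks, cumulative = cum[top_ks])
  out <- list(ranks = ranks, top_k = topk)
  if (!is.null(freq_floor)) {
    above <- hfs$frequency > freq_floor
    out$floor <- tibble::tibble(freq_floor = freq_floor,
                                n_above = sum(above),
                                cumulative_above = sum(hfs$frequency[above]))
  }
  out
}

#' Serialize fully typed phenotypes as observation strings
#'
#' Convenience converter for [em_estimate()]: a complete high-resolution
#' phenotype becomes an observed-typing string with every locus
#' `high=code1,code2`.
#'
#' @param phenotypes Character vector of phenotype strings.
#' @return Character vector of observed-typing strings.
#' @export
observations_from_phenotypes <- function(phenotypes) {
  p <- .parse_phenotype_matrices(phenotypes)
  cells <- matrix(paste0("high=", p$lo, ",", p$hi), ncol = 5L)
  apply(cells, 1L, paste, collapse = "|")
}

## admissible ordered code pairs at one locus for one observation cell
## returns list(c1 = chr, c2 = chr)
.locus_pairs <- function(res, codes, universe, low_of) {
  if (is.na(res)) {
    g <- expand.grid(c1 = universe, c2 = universe, stringsAsFactors = FALSE)
    return(list(c1 = g$c1, c2 = g$c2))
  }
  if (res == "high") {
    a <- codes[1]; b <- codes[2]
    if (length(universe) > 0 && !all(c(a, b) %in% universe)) {
      return(list(c1 = character(0), c2 = character(0)))
    }
    if (a == b) return(list(c1 = a, c2 = b))
    return(list(c1 = c(a, b), c2 = c(b, a)))
  }
  if (res == "low") {
    lu <- low_of[universe]
    x <- codes[1]; y <- codes[2]
    ux <- universe[!is.na(lu) & lu == x]
    uy <- universe[!is.na(lu) & lu == y]
    if (x == y) {
      g <- expand.grid(c1 = ux, c2 = ux, stringsAsFactors = FALSE)
      return(list(c1 = g$c1, c2 = g$c2))
    }
    g1 <- expand.grid(c1 = ux, c2 = uy, stringsAsFactors = FALSE)
    g2 <- expand.grid(c1 = uy, c2 = ux, stringsAsFactors = FALSE)
    return(list(c1 = c(g1$c1, g2$c1), c2 = c(g1$c2, g2$c2)))
  }
  rlang::abort(paste0("unknown resolution '", res, "'"))
}

#' EM estimation of haplotype frequencies from unphased phenotypes
#'
#' Maximum-likelihood estimation of multilocus haplotype frequencies
#' from unphased, possibly masked observations. Each observation's
#' weight is distributed in the E-step over the ordered haplotype pairs
#' consistent with it, proportionally to the current `f(h1) f(h2)`; the
#' M-step sets frequencies proportional to expected haplotype counts.
#' The log-likelihood is non-decreasing across iterations (asserted).
#' The support is restricted to haplotypes consistent with at least one
#' observation.
#'
#' @param observations Character vector of observed-typing strings
#'   (see [observations_from_phenotypes()] and
#'   [parse_observed_typing()]); identical observations are pooled.
#' @param count Optional positive weights (default 1 per record).
#' @param universe Optional named list (by locus) of admissible
#'   high-resolution codes; defaults to the map's high codes, or to the
#'   high-resolution codes present in the data when no map is given.
#' @param map A [resolution_map()]; required when observations contain
#'   low-resolution loci.
#' @param init `"uniform"` (default) or `"random"` (seeded Dirichlet
#'   draw).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param seed Seed for random initialization.
#' @return Object of class `em_result`: estimated [hf_set()], the
#'   log-likelihood trace, iteration count and convergence flag.
#' @export
em_estimate <- function(observations, count = NULL, universe = NULL,
                        map = NULL, init = c("uniform", "random"),
                        tol = 1e-8, max_iter = 1000L, seed = NULL) {
  init <- match.arg(init)
  if (tol <= 0) rlang::abort("tol must be > 0")
  if (is.null(count)) count <- rep(1, length(observations))
  if (any(count <= 0)) rlang::abort("counts must be positive")
  ## pool identical observations
  agg <- rowsum(count, observations)
  obs_str <- rownames(agg)
  w <- agg[, 1]
  parsed <- lapply(obs_str, parse_observed_typing)

  ## allele universe per locus
  loci <- hla_loci()
  if (is.null(universe)) {
    universe <- if (!is.null(map)) {
      lapply(stats::setNames(loci, loci),
             function(l) sort(unique(map$high_code[map$locus == l])))
    } else {
      lapply(stats::setNames(loci, loci), function(l) {
        codes <- unlist(lapply(parsed, function(o) {
          if (!is.null(o$codes[[l]]) && o$resolution[[l]] == "high") o$codes[[l]]
        }))
        sort(unique(codes))
      })
    }
  }
  low_of <- lapply(stats::setNames(loci, loci), function(l) {
    if (is.null(map)) NULL else .map_lookup(map, l, "low_code")
  })

  ## enumerate consistent ordered haplotype pairs per observation
  hap_env <- new.env(parent = emptyenv())
  hap_strings <- character(0)
  hap_id <- function(strs) {
    new <- !vapply(strs, function(s) !is.null(hap_env[[s]]), TRUE)
    if (any(new)) {
      for (s in unique(strs[new])) {
        if (is.null(hap_env[[s]])) {
          hap_strings[[length(hap_strings) + 1L]] <<- s
          hap_env[[s]] <- length(hap_strings)
        }
      }
    }
    vapply(strs, function(s) hap_env[[s]], 1L, USE.NAMES = FALSE)
  }
  I <- integer(0); J <- integer(0); O <- integer(0)
  for (o in seq_along(parsed)) {
    ot <- parsed[[o]]
    per_locus <- lapply(loci, function(l) {
      if (!is.na(ot$resolution[[l]]) && ot$resolution[[l]] == "low" && is.null(map)) {
        rlang::abort("a resolution map is required for low-resolution observations")
      }
      if (length(universe[[l]]) == 0L && is.na(ot$resolution[[l]])) {
        rlang::abort(paste0("empty allele universe at untyped locus ", l))
      }
      .locus_pairs(ot$resolution[[l]], ot$codes[[l]], universe[[l]], low_of[[l]])
    })
    sizes <- vapply(per_locus, function(p) length(p$c1), 1L)
    if (any(sizes == 0L)) {
      rlang::abort(paste0("observation inconsistent with the allele universe: ",
                          obs_str[o]))
    }
    if (prod(sizes) > 1e6) {
      rlang::abort(paste0("observation too ambiguous to enumerate: ", obs_str[o]))
    }
    g <- expand.grid(lapply(sizes, seq_len))
    h1 <- do.call(paste, c(lapply(seq_len(5L), function(l) per_locus[[l]]$c1[g[[l]]]),
                           list(sep = "~")))
    h2 <- do.call(paste, c(lapply(seq_len(5L), function(l) per_locus[[l]]$c2[g[[l]]]),
                           list(sep = "~")))
    I <- c(I, hap_id(h1)); J <- c(J, hap_id(h2)); O <- c(O, rep(o, length(h1)))
  }
  nh <- length(hap_strings)
  n_total <- sum(w)

  f <- if (init == "uniform") rep(1 / nh, nh) else .with_seed(seed, {
    g <- stats::rgamma(nh, shape = 1); g / sum(g)
  })
  ll_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pp <- f[I] * f[J]
    po <- rowsum(pp, O)[, 1]
    if (any(po <= 0) || any(!is.finite(po))) {
      rlang::abort("non-finite or zero observation likelihood in EM")
    }
    ll <- sum(w * log(po))
    if (ll < prev - 1e-9 * max(1, abs(prev))) {
      rlang::abort("EM log-likelihood decreased; numerical failure")
    }
    ll_trace <- c(ll_trace, ll)
    q <- pp * (w / po)[O]
    cnt <- rowsum(c(q, q), c(I, J))
    newf <- numeric(nh)
    newf[as.integer(rownames(cnt))] <- cnt[, 1]
    f <- newf / (2 * n_total)
    if (is.finite(prev) && abs(ll - prev) < tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  keep <- f > 1e-15
  est <- hf_set(hap_strings[keep], f[keep], renormalize = TRUE,
                label = "em-estimate")
  structure(list(hfs = est, loglik = ll_trace, iterations = iter,
                 converged = converged, n = n_total),
            class = "em_result")
}

#' @export
print.em_result <- function(x, ...) {
  cat("<em_result: ", nrow(x$hfs), " haplotypes, ", x$iterations,
      " iterations, logLik = ", format(utils::tail(x$loglik, 1)),
      if (x$converged) ", converged" else ", NOT converged", ">\n", sep = "")
  invisible(x)
}

#' Tidy an EM haplotype-frequency estimate
#'
#' @param x An `em_result`.
#' @param ... Unused.
#' @return Tibble with `haplotype`, `frequency` and `possible_artifact`
#'   (frequency below the `1/n` resolution limit of the sample).
#' @method tidy em_result
#' @export
tidy.em_result <- function(x, ...) {
  lim <- resolution_limit(max(1, round(x$n)))
  tibble::tibble(haplotype = x$hfs$haplotype,
                 frequency = x$hfs$frequency,
                 possible_artifact = x$hfs$frequency < lim)
}

#' One-row summary of an EM fit
#' @param x An `em_result`.
#' @param ... Unused.
#' @return Tibble with `iterations`, `converged`, `loglik`, `n`,
#'   `n_haplotypes`.
#' @method glance em_result
#' @export
glance.em_result <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 loglik = utils::tail(x$loglik, 1), n = x$n,
                 n_haplotypes = nrow(x$hfs))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
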