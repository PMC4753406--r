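## helper: phenotype string with varying A/B and constant other loci
two_locus_pheno <- function(a1, a2, b1, b2) {
  paste(c(paste0(sort(c(a1, a2)), collapse = ","),
          paste0(sort(c(b1, b2)), collapse = ","),
          "09:01,09:01", "09:01,09:01", "09:01,09:01"), collapse = "|")
}

test_that("resolution limit is the reciprocal sample size", {
  expect_equal(resolution_limit(4), 0.25)
  expect_equal(resolution_limit(1), 1)
  expect_equal(resolution_limit(370856), 1 / 370856)
  expect_error(resolution_limit(0), "integer")
  expect_error(resolution_limit(2.5), "integer")
})

test_that("cumulative rank summaries count top-ranked haplotypes", {
  one <- gen_hf_distribution(1, seed = 1)
  expect_identical(cumulative_rank_summary(one, thresholds = 0.5)$ranks$n_haplotypes, 1L)
  s <- cumulative_rank_summary(toy3$hfs, thresholds = c(0.5, 0.75), top_ks = 2,
                               freq_floor = 0.25)
  expect_identical(s$ranks$n_haplotypes, c(1L, 2L))
  expect_equal(s$top_k$cumulative, 0.8)
  expect_identical(s$floor$n_above, 2L)
  expect_error(cumulative_rank_summary(toy3$hfs, thresholds = 1.5), "0, 1")
})

test_that("EM equals direct counting when phase is determined", {
  phens <- toy3_phenotypes()
  hom1 <- phens$phenotype[phens$i == 1 & phens$j == 1]
  hom3 <- phens$phenotype[phens$i == 3 & phens$j == 3]
  fit <- em_estimate(observations_from_phenotypes(c(hom1, hom3)),
                     count = c(70, 30))
  expect_equal(sort(fit$hfs$frequency, decreasing = TRUE), c(0.7, 0.3),
               tolerance = 1e-9)
  expect_lte(fit$iterations, 3L)
})

test_that("EM attains the maximum found by dense grid search on the two-locus toy", {
  obs <- c(two_locus_pheno("01:01", "01:01", "01:01", "01:01"),
           two_locus_pheno("01:01", "02:01", "01:01", "02:01"),
           two_locus_pheno("02:01", "02:01", "02:01", "02:01"))
  fit <- em_estimate(observations_from_phenotypes(obs), count = c(60, 20, 20))
  ## independent oracle: grid over the 4-haplotype simplex
  ## haplotypes: (A1B1, A2B2, A1B2, A2B1); data likelihood
  step <- 0.01
  grid <- expand.grid(f11 = seq(step, 1, step), f22 = seq(step, 1, step),
                      f12 = seq(0, 1, step))
  grid <- grid[grid$f11 + grid$f22 + grid$f12 <= 1, ]
  grid$f21 <- 1 - grid$f11 - grid$f22 - grid$f12
  ll <- 120 * log(grid$f11) + 40 * log(grid$f22) +
    20 * log(2 * (grid$f11 * grid$f22 + grid$f12 * grid$f21))
  best <- grid[which.max(ll), ]
  ## EM solution within grid resolution of the oracle argmax
  est <- stats::setNames(fit$hfs$frequency, fit$hfs$haplotype)
  h <- function(a, b) paste(c(a, b, "09:01", "09:01", "09:01"), collapse = "~")
  get <- function(nm) if (nm %in% names(est)) unname(est[nm]) else 0
  expect_lt(abs(get(h("01:01", "01:01")) - best$f11), step + 1e-9)
  expect_lt(abs(get(h("02:01", "02:01")) - best$f22), step + 1e-9)
  expect_lt(abs(get(h("01:01", "02:01")) - best$f12), step + 1e-9)
  expect_lt(abs(get(h("02:01", "01:01")) - best$f21), step + 1e-9)
  ## and its likelihood is no worse than the grid maximum
  expect_gte(utils::tail(fit$loglik, 1), max(ll) - 1e-6)
})

test_that("EM recovers TOY3 frequencies within 3 bootstrap SEs at n = 5000", {
  fit_once <- function(seed) {
    ph <- sample_phenotypes(toy3$hfs, 5000, seed = seed)
    fit <- em_estimate(observations_from_phenotypes(ph$phenotype))
    est <- stats::setNames(fit$hfs$frequency, fit$hfs$haplotype)
    vapply(toy3$hfs$haplotype,
           function(hp) if (hp %in% names(est)) unname(est[hp]) else 0, 1)
  }
  reps <- vapply(1:25, fit_once, numeric(3))
  se <- apply(reps, 1, stats::sd)
  est1 <- fit_once(999)
  expect_true(all(abs(est1 - toy3$hfs$frequency) < 3 * se))
})

test_that("EM log-likelihood is monotone, order-invariant and improves with data", {
  ## monotone trace, including on partially masked data
  ph <- sample_phenotypes(toy3$hfs, 400, seed = 17)
  full <- observations_from_phenotypes(ph$phenotype[1:200])
  masked <- vapply(ph$phenotype[201:400],
                   function(p) format(mask_phenotype(p, 3, toy3$map)),
                   character(1))
  fit <- em_estimate(c(full, unname(masked)), map = toy3$map)
  expect_true(all(diff(fit$loglik) >= -1e-9))
  expect_equal(sum(fit$hfs$frequency), 1, tolerance = 1e-9)
  ## order invariance
  shuf <- c(full, unname(masked))[sample(400)]
  fit2 <- em_estimate(shuf, map = toy3$map)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(fit$hfs), haplotype)$frequency,
    dplyr::arrange(tibble::as_tibble(fit2$hfs), haplotype)$frequency,
    tolerance = 1e-9)
  ## recovery RMSE decreases from n = 500 to n = 5000
  rmse <- function(n, seed) {
    ph <- sample_phenotypes(toy3$hfs, n, seed = seed)
    fit <- em_estimate(observations_from_phenotypes(ph$phenotype))
    est <- stats::setNames(fit$hfs$frequency, fit$hfs$haplotype)
    got <- vapply(toy3$hfs$haplotype,
                  function(hp) if (hp %in% names(est)) unname(est[hp]) else 0, 1)
    sqrt(mean((got - toy3$hfs$frequency)^2))
  }
  r500 <- mean(vapply(1:8, function(s) rmse(500, s), 1))
  r5000 <- mean(vapply(1:8, function(s) rmse(5000, s + 100), 1))
  expect_lt(r5000, r500)
})

test_that("EM rejects inconsistent observations and flags sub-limit frequencies", {
  ## allele universe that cannot produce the observation
  uni <- lapply(stats::setNames(hla_loci(), hla_loci()), function(l) "09:01")
  expect_error(
    em_estimate("high=01:01,01:01|high=09:01,09:01|high=09:01,09:01|high=09:01,09:01|high=09:01,09:01",
                universe = uni),
    "inconsistent")
  ## artifact flag follows the 1/n limit
  phens <- toy3_phenotypes()
  fit <- em_estimate(observations_from_phenotypes(
    c(phens$phenotype[1], phens$phenotype[6])), count = c(3, 1))
  td <- tidy(fit)
  expect_identical(td$possible_artifact, td$frequency < resolution_limit(4))
  g <- glance(fit)
  expect_true(g$converged)
  expect_identical(g$n, 4)
})
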