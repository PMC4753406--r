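test_that("ready matches use only fully typed donors, lowest id on ties", {
  fx <- search_fixture()
  patient <- phenotype_from_haplotypes(fx$haps["G1"], fx$haps["G1"])
  donors <- tibble::tibble(
    id = 1:5,
    profile = c(1L, 1L, 4L, 1L, 2L),
    h1 = c(1L, 1L, 1L, 2L, 2L),
    h2 = c(1L, 1L, 1L, 2L, 2L)
  )
  reg <- manual_registry(fx$hfs, fx$map, donors)
  expect_identical(find_ready_match(reg, patient), 1L)
  ## only a partially typed true match: not ready
  reg2 <- manual_registry(fx$hfs, fx$map,
                          tibble::tibble(id = 1L, profile = 4L, h1 = 1L, h2 = 1L))
  expect_true(is.na(find_ready_match(reg2, patient)))
  expect_true(true_match_exists(reg2, patient))
  expect_false(true_match_exists(
    manual_registry(fx$hfs, fx$map,
                    tibble::tibble(id = 1L, profile = 1L, h1 = 4L, h2 = 4L)),
    patient))
})

test_that("candidates are ranked by matching probability with the oracle's values", {
  ## G1-homozygote patient; a profile-2 donor confirming A, B, C outranks a
  ## profile-4 donor that is only compatible at low resolution
  fx <- search_fixture()
  patient <- phenotype_from_haplotypes(fx$haps["G1"], fx$haps["G1"])
  donors <- tibble::tibble(id = 1:2, profile = c(4L, 2L),
                           h1 = c(1L, 1L), h2 = c(1L, 1L))
  reg <- manual_registry(fx$hfs, fx$map, donors)
  ranked <- rank_candidates(reg, patient, "A", seed = 1)
  expect_identical(ranked$donor_id, c(2L, 1L))
  ## values agree with the independent brute-force oracle
  for (k in 1:2) {
    obs <- mask_phenotype(reg$hidden$phenotype[ranked$donor_id[k]],
                          ranked$profile[k], fx$map)
    expect_equal(ranked$mp[k],
                 signif(mp_bruteforce_oracle(patient, obs, fx$hfs, fx$map), 12),
                 tolerance = 1e-9)
  }
  ## incompatible donors are excluded entirely
  donors2 <- tibble::tibble(id = 1L, profile = 2L, h1 = 4L, h2 = 4L)
  expect_identical(nrow(rank_candidates(manual_registry(fx$hfs, fx$map, donors2),
                                        patient, "A", seed = 1)), 0L)
})

test_that("strategy B never requests profile-5 donors", {
  fx <- search_fixture()
  patient <- phenotype_from_haplotypes(fx$haps["G1"], fx$haps["G1"])
  donors <- tibble::tibble(id = 1:3, profile = c(5L, 5L, 4L),
                           h1 = c(1L, 2L, 1L), h2 = c(1L, 2L, 2L))
  reg <- manual_registry(fx$hfs, fx$map, donors)
  a <- rank_candidates(reg, patient, "A", seed = 2)
  b <- rank_candidates(reg, patient, "B", seed = 2)
  expect_true(5L %in% a$profile)
  expect_false(5L %in% b$profile)
  ## with only profile-5 compatible donors, strategy B has nothing to request
  reg5 <- manual_registry(fx$hfs, fx$map,
                          tibble::tibble(id = 1:2, profile = 5L,
                                         h1 = c(1L, 1L), h2 = c(1L, 2L)))
  expect_identical(nrow(rank_candidates(reg5, patient, "B", seed = 1)), 0L)
})

test_that("identical matching probabilities are tie-broken at random", {
  fx <- search_fixture()
  patient <- phenotype_from_haplotypes(fx$haps["G1"], fx$haps["G1"])
  ## two clones of the same profile-4 observation
  donors <- tibble::tibble(id = 1:2, profile = 4L, h1 = c(1L, 1L), h2 = c(1L, 1L))
  reg <- manual_registry(fx$hfs, fx$map, donors)
  firsts <- vapply(1:100, function(s) {
    rank_candidates(reg, patient, "A", seed = s)$donor_id[1]
  }, 1L)
  ## both orders occur; two-sided binomial bound at p = 0.5
  expect_gt(sum(firsts == 1L), 20)
  expect_lt(sum(firsts == 1L), 80)
})

test_that("a hidden true match below the budget horizon yields a UFS", {
  ## three profile-2 decoys (compatible, MP ~ 0.51, non-matching) outrank the
  ## sole true match, a profile-4 donor; with budget 3 it is never reached
  fx <- search_fixture()
  patient <- phenotype_from_haplotypes(fx$haps["G1"], fx$haps["G1"])
  donors <- tibble::tibble(
    id = 1:4,
    profile = c(2L, 2L, 2L, 4L),
    h1 = c(1L, 2L, 1L, 1L),
    h2 = c(2L, 2L, 2L, 1L)
  )
  reg <- manual_registry(fx$hfs, fx$map, donors)
  ranked <- rank_candidates(reg, patient, "A", seed = 5)
  expect_identical(ranked$donor_id[4], 4L)
  expect_true(all(ranked$mp[1:3] > ranked$mp[4]))
  r3 <- run_search(reg, patient, search_config(3, "A", seed = 5))
  expect_identical(r3$outcome, "UFS")
  expect_identical(r3$requests_used, 3L)
  expect_false(any(r3$request_log$hit))
  ## a larger budget reaches the hidden donor
  r10 <- run_search(reg, patient, search_config(10, "A", seed = 5))
  expect_identical(r10$outcome, "FOUND_IN_SEARCH")
  expect_identical(r10$requests_used, 4L)
  expect_identical(r10$matched_donor_id, 4L)
  expect_true(r10$request_log$hit[4])
  ## with no requests allowed, nothing can be found in search
  r0 <- run_search(reg, patient, search_config(0, "A", seed = 5))
  expect_identical(r0$outcome, "UFS")
  expect_identical(r0$requests_used, 0L)
  ## with no true match anywhere the same walk ends in NO_MATCH_EXISTS
  reg_nm <- manual_registry(fx$hfs, fx$map, donors[1:3, ])
  rn <- run_search(reg_nm, patient, search_config(3, "A", seed = 5))
  expect_identical(rn$outcome, "NO_MATCH_EXISTS")
})

test_that("ranking never reads hidden phenotypes", {
  fx <- search_fixture()
  patient <- phenotype_from_haplotypes(fx$haps["G1"], fx$haps["G1"])
  donors <- tibble::tibble(id = 1:4, profile = c(2L, 2L, 4L, 4L),
                           h1 = c(1L, 2L, 1L, 2L), h2 = c(2L, 2L, 1L, 2L))
  reg <- manual_registry(fx$hfs, fx$map, donors)
  ranked <- rank_candidates(reg, patient, "A", seed = 6)
  ## scramble the hidden table: identical ranking must come out
  reg_scrambled <- reg
  reg_scrambled$hidden$phenotype <- rev(reg$hidden$phenotype)
  reg_scrambled$hidden$h1 <- rev(reg$hidden$h1)
  reg_scrambled$hidden$h2 <- rev(reg$hidden$h2)
  expect_identical(rank_candidates(reg_scrambled, patient, "A", seed = 6),
                   ranked)
})

test_that("panel searches partition outcomes and agree with single searches", {
  fx <- random_fixture(30, seed = 13)
  reg <- build_registry(fx$hfs, 3000, "reference", fx$map, seed = 14)
  panel <- build_patients(fx$hfs, 150, seed = 15)
  run <- run_panel_search(reg, panel, search_config(3, "A", seed = 16))
  expect_identical(nrow(run$results), 150L)
  expect_true(all(run$results$outcome %in%
                    c("READY", "FOUND_IN_SEARCH", "NO_MATCH_EXISTS", "UFS")))
  ## READY implies zero requests; FOUND implies final hit
  expect_true(all(run$results$requests_used[run$results$outcome == "READY"] == 0L))
  found <- run$results$outcome == "FOUND_IN_SEARCH"
  expect_identical(run$results$requests_used[found],
                   run$results$first_hit_rank[found])
  ## READY share is independently recomputable by brute force
  p1 <- reg$observed$profile == 1L
  ready_brute <- vapply(panel$phenotype, function(p) {
    any(reg$hidden$phenotype[p1] == p)
  }, TRUE)
  expect_identical(unname(ready_brute), run$results$outcome == "READY")
  ## match_exists agrees with an exhaustive phenotype scan
  exists_brute <- vapply(panel$phenotype,
                         function(p) any(reg$hidden$phenotype == p), TRUE)
  expect_identical(unname(exists_brute), run$results$match_exists)
  ## UFS only when a match exists but was not found
  expect_true(all(run$results$match_exists[run$results$outcome == "UFS"]))
  expect_true(all(!run$results$match_exists[run$results$outcome == "NO_MATCH_EXISTS"]))
})
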