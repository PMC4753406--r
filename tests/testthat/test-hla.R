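test_that("phenotype canonicalization is insensitive to per-locus allele order", {
  haps <- toy3$hfs$haplotype
  p <- phenotype_from_haplotypes(haps[1], haps[2])
  ## brute force over all 2^5 per-locus orderings
  m1 <- parse_haplotypes(haps[1])
  m2 <- parse_haplotypes(haps[2])
  for (mask in 0:31) {
    bits <- as.logical(bitwAnd(mask, 2^(0:4)))
    first <- ifelse(bits, m2[1, ], m1[1, ])
    second <- ifelse(bits, m1[1, ], m2[1, ])
    scrambled <- paste(paste0(first, ",", second), collapse = "|")
    expect_true(phenotypes_match(scrambled, p))
  }
  ## symmetry of construction
  expect_identical(phenotype_from_haplotypes(haps[2], haps[1]), p)
})

test_that("phenotypes_match is an equivalence relation and detects single mismatches", {
  fx <- random_fixture(12, seed = 5)
  ph <- sample_phenotypes(fx$hfs, 9, seed = 3)$phenotype
  ## reflexive, symmetric, transitive on random triples
  for (k in seq(1, 9, by = 3)) {
    a <- ph[k]; b <- ph[k + 1]; c <- ph[k + 2]
    expect_true(phenotypes_match(a, a))
    expect_identical(phenotypes_match(a, b), phenotypes_match(b, a))
    if (phenotypes_match(a, b) && phenotypes_match(b, c)) {
      expect_true(phenotypes_match(a, c))
    }
  }
  ## one-allele difference at DQB1 breaks the match
  a <- phenotype_from_haplotypes(toy3$hfs$haplotype[1], toy3$hfs$haplotype[1])
  b <- sub("02:01,02:01$", "02:01,03:01", a)
  expect_false(phenotypes_match(a, b))
  ## malformed input errors
  expect_error(phenotypes_match("01:01,01:01|02:01,02:01", a), "5")
})

test_that("masking follows the typing-profile table", {
  p <- phenotype_from_haplotypes(toy3$hfs$haplotype[1], toy3$hfs$haplotype[2])
  ## profile 1: identity at high resolution on all loci
  o1 <- mask_phenotype(p, 1, toy3$map)
  expect_identical(format(o1),
                   paste(paste0("high=", strsplit(p, "|", fixed = TRUE)[[1]]),
                         collapse = "|"))
  ## profile 2: A, B, C high; DRB1, DQB1 absent
  o2 <- mask_phenotype(p, 2, toy3$map)
  expect_identical(unname(o2$resolution),
                   c("high", "high", "high", NA, NA))
  expect_identical(o2$codes$A, c("01:01", "01:02"))
  expect_null(o2$codes$DRB1)
  ## profile 4: only A and B, at low resolution
  o4 <- mask_phenotype(p, 4, toy3$map)
  expect_identical(format(o4), "low=01,01|low=07,07|-|-|-")
  ## profiles 4 and 5 share the per-locus spec
  expect_identical(mask_phenotype(p, 5, toy3$map)$codes, o4$codes)
  ## unmapped allele names locus and code
  bad_map <- resolution_map(toy3$map[toy3$map$high_code != "01:02", ])
  expect_error(mask_phenotype(p, 4, bad_map), "A.*01:02")
})

test_that("compatibility round-trips through masking and respects information ordering", {
  phens <- toy3_phenotypes()
  ## round trip: every masked phenotype stays compatible, for all profiles
  for (k in seq_len(nrow(phens))) {
    for (pr in 1:5) {
      obs <- mask_phenotype(phens$phenotype[k], pr, toy3$map)
      expect_true(compatible(obs, phens$phenotype[k], toy3$map))
    }
  }
  ## exhaustive enumeration: profile-4 view of an H1 homozygote is compatible
  ## with exactly the three phenotypes over {H1, H2}
  obs4 <- mask_phenotype(phens$phenotype[phens$i == 1 & phens$j == 1], 4, toy3$map)
  comp <- vapply(phens$phenotype, function(q) compatible(obs4, q, toy3$map), TRUE)
  expect_identical(unname(comp), phens$i <= 2 & phens$j <= 2)
  ## a profile-1 observation pins down the phenotype uniquely
  obs1 <- mask_phenotype(phens$phenotype[2], 1, toy3$map)
  comp1 <- vapply(phens$phenotype, function(q) compatible(obs1, q, toy3$map), TRUE)
  expect_identical(sum(comp1), 1L)
  ## nested profiles widen the compatible set: #1 subset of #2, #3 subset of #4
  for (k in seq_len(nrow(phens))) {
    o1 <- mask_phenotype(phens$phenotype[k], 1, toy3$map)
    o2 <- mask_phenotype(phens$phenotype[k], 2, toy3$map)
    o3 <- mask_phenotype(phens$phenotype[k], 3, toy3$map)
    o4 <- mask_phenotype(phens$phenotype[k], 4, toy3$map)
    for (q in phens$phenotype) {
      expect_true(!compatible(o1, q, toy3$map) || compatible(o2, q, toy3$map))
      expect_true(!compatible(o3, q, toy3$map) || compatible(o4, q, toy3$map))
    }
  }
})

test_that("broad conversion maps allele pairs element-wise", {
  ## fixture map collapsing 4 alleles into 2 broads at locus A
  fx_map <- resolution_map(tibble::tibble(
    locus = "A",
    high_code = c("01:01", "01:02", "02:01", "02:02"),
    low_code = c("01", "01", "02", "02"),
    broad_code = c("b1", "b1", "b2", "b2")
  ))
  mk <- function(a1, a2) {
    paste(c(paste0(sort(c(a1, a2)), collapse = ","),
            "09:01,09:01", "09:01,09:01", "09:01,09:01", "09:01,09:01"),
          collapse = "|")
  }
  phenos <- c(mk("01:01", "01:01"), mk("01:01", "01:02"), mk("01:01", "02:01"),
              mk("01:02", "02:02"), mk("02:01", "02:02"), mk("02:02", "02:02"))
  out <- to_broad(phenos, fx_map, "A")
  expect_identical(nrow(out), 6L)
  ## hand-enumerated images
  expect_identical(out$a1, c("b1", "b1", "b1", "b1", "b2", "b2"))
  expect_identical(out$a2, c("b1", "b1", "b2", "b2", "b2", "b2"))
  ## heterozygote sharing a broad maps to a homozygous broad pair
  expect_identical(out$a1[2], out$a2[2])
  ## unmapped allele errors
  expect_error(to_broad(mk("03:01", "03:01"), fx_map, "A"), "03:01")
})

test_that("observed typings serialize and parse losslessly", {
  p <- phenotype_from_haplotypes(toy3$hfs$haplotype[2], toy3$hfs$haplotype[3])
  for (pr in 1:5) {
    obs <- mask_phenotype(p, pr, toy3$map)
    back <- parse_observed_typing(format(obs), profile = pr)
    expect_identical(back$codes, obs$codes)
    expect_identical(back$resolution, obs$resolution)
  }
})
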