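## shared fixtures built in code

toy3 <- make_toy_fixture()

## all six unordered phenotypes of TOY3 (H1H1, H1H2, H1H3, H2H2, H2H3, H3H3)
toy3_phenotypes <- function() {
  haps <- toy3$hfs$haplotype
  combos <- expand.grid(i = 1:3, j = 1:3)
  combos <- combos[combos$i <= combos$j, ]
  tibble::tibble(
    i = combos$i, j = combos$j,
    phenotype = phenotype_from_haplotypes(haps[combos$i], haps[combos$j]),
    prob = ifelse(combos$i == combos$j,
                  toy3$hfs$frequency[combos$i]^2,
                  2 * toy3$hfs$frequency[combos$i] * toy3$hfs$frequency[combos$j])
  )
}

## random small haplotype world for fuzz tests
random_fixture <- function(n_hap = 20, seed = 42) {
  hfs <- gen_hf_distribution(n_hap, decay_shape = 1, seed = seed)
  list(hfs = hfs, map = default_resolution_map(hfs))
}

## assemble a registry with hand-chosen donors (id, profile, h1, h2)
manual_registry <- function(hfs, map, donors) {
  idx <- ufsim:::.mp_index(hfs, map)
  hapmat <- ufsim:::.hf_hapmat(hfs)
  obs_key <- character(nrow(donors))
  for (p in sort(unique(donors$profile))) {
    sel <- donors$profile == p
    entry <- ufsim:::.mp_spec(idx, ufsim:::.profile_spec(p))
    obs_key[sel] <- ufsim:::.pair_obs_keys(entry, donors$h1[sel], donors$h2[sel])
  }
  structure(list(
    observed = tibble::tibble(id = donors$id, profile = donors$profile,
                              obs_key = obs_key),
    hidden = tibble::tibble(id = donors$id, h1 = donors$h1, h2 = donors$h2,
                            phenotype = phenotype_from_haplotypes(
                              hfs$haplotype[donors$h1], hfs$haplotype[donors$h2])),
    hfs = hfs, map = map, mix = NULL, seed = NA_integer_,
    size = nrow(donors)
  ), class = "donor_registry")
}

## four-haplotype world for hand-built search scenarios:
## G1, G2 share A, B, C at high resolution; G3 shares only the low-resolution
## A and B first fields; G4 differs everywhere.
search_fixture <- function() {
  haps <- c(
    G1 = "01:01~01:01~01:01~01:01~01:01",
    G2 = "01:01~01:01~01:01~02:01~02:01",
    G3 = "01:02~01:02~02:01~03:01~03:01",
    G4 = "02:01~02:01~03:01~04:01~04:01"
  )
  hfs <- hf_set(unname(haps), c(0.5, 0.2, 0.2, 0.1))
  list(hfs = hfs, map = default_resolution_map(hfs), haps = haps)
}
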