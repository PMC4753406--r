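## run code under a temporary RNG seed, restoring global RNG state afterwards
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

## deterministic derived seed, kept inside 32-bit integer range
.derive_seed <- function(base, ...) {
  parts <- c(as.numeric(base), as.numeric(c(...)))
  h <- 0
  for (p in parts) h <- (h * 2654435 + (p %% 2147483647)) %% 2147483647
  as.integer(h)
}

## fast canonical phenotype keys from haplotype allele matrix + index pairs
.phenotype_keys <- function(hapmat, i, j) {
  a <- hapmat[i, , drop = FALSE]
  b <- hapmat[j, , drop = FALSE]
  lo <- pmin(a, b); hi <- pmax(a, b)
  cells <- paste0(lo, ",", hi)
  dim(cells) <- dim(lo)
  do.call(paste, c(lapply(seq_len(ncol(cells)), function(k) cells[, k]),
                   list(sep = "|")))
}
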