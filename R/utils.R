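# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed when one is given, without
# disturbing the caller's RNG state; with seed = NULL the global stream is
# used as-is.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds (< 2^31) from one master seed, so that
# replicate r of a simulation is reproducible in isolation.
.childSeeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  withr::with_seed(as.integer(seed),
                   as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Match observation sites into a panel by full (chrom,pos,ref,alt) key.
# Returns integer indices into the panel (NA where absent).
.matchPanel <- function(obs, panel) {
  match(siteKeys(obs), siteKeys(panel))
}
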