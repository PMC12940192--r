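# Shared fixtures: toy frequency tables, kits, profile constructors.

toy_freqs <- function() allele_frequencies(list(
  L1 = c(`10` = 0.1, `11` = 0.4, `12` = 0.5),
  L2 = c(`8` = 0.25, `9` = 0.25, `10` = 0.2, `11` = 0.3)))

toy_kit <- function(loci = c("L1", "L2"),
                    intercepts = c(L1 = 100, L2 = 220))
  synthetic_kit("K", loci, intercepts)

# Replicate profile from a compact description: peaks = named list of
# list(alleles=..., heights=...)
make_rep <- function(peaks, sample_id = "s", kit = toy_kit(),
                     replicate_id = 1L) {
  pk <- lapply(names(peaks), function(l) {
    p <- peaks[[l]]
    data.frame(allele = as.character(p$alleles), height = p$heights,
               size = allele_size(kit, l, p$alleles))
  })
  names(pk) <- names(peaks)
  replicate_profile(sample_id, kit$kit_id, replicate_id, pk, loci = kit$loci)
}

# Consensus profile built directly (bypassing build_consensus) for LR tests.
make_cons <- function(states, sample_id = "s", kit_id = "K") {
  loci <- lapply(states, function(st) {
    if (is.null(st)) return(list(status = "excluded", alleles = character(),
                                 d = NA_real_, height_used = NA_real_))
    alleles <- format_allele(st$alleles)
    if (length(alleles) == 2L)
      list(status = "double", alleles = alleles, d = 0,
           height_used = NA_real_)
    else list(status = "single", alleles = alleles, d = st$d,
              height_used = NA_real_)
  })
  structure(list(sample_id = sample_id, kit_id = kit_id, loci = loci),
            class = "consensus_profile")
}

# A flat drop-out model with fixed probability (for consensus plumbing).
flat_dropout_model <- function(d = 0.2, kit_id = "K")
  dropout_model(kit_id, b0 = stats::qlogis(d), b1 = 0)

# random point on the simplex (property tests)
random_simplex <- function(k) {
  x <- stats::rgamma(k, shape = 1)
  x / sum(x)
}
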