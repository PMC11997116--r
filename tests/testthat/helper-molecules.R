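# deterministic hand-built molecules used across tests

flat_adapter <- function(seq = "ACGTACGTACGTACG", value = 0.3) {
  n <- nchar(seq)
  list(sequence = seq, ipd_w = rep(value, n), pw_w = rep(value, n),
       ipd_c = rep(value, n), pw_c = rep(value, n))
}

# molecule with constant kinetics everywhere, optional adapters
flat_molecule <- function(sequence, value = 0.2, depth = 5L, adapters = TRUE,
                          id = "flat") {
  n <- nchar(sequence)
  molecule_kinetics(id, sequence,
                    rep(value, n), rep(value, n), rep(value, n), rep(value, n),
                    depth, depth,
                    adapter_left = if (adapters) flat_adapter() else NULL,
                    adapter_right = if (adapters) flat_adapter() else NULL)
}

# random-kinetics molecule (seeded by caller)
noisy_molecule <- function(sequence, depth = 5L, adapters = TRUE, id = "noisy") {
  n <- nchar(sequence)
  r <- function() runif(n, 0.05, 0.6)
  molecule_kinetics(id, sequence, r(), r(), r(), r(), depth, depth,
                    adapter_left = if (adapters) flat_adapter() else NULL,
                    adapter_right = if (adapters) flat_adapter() else NULL)
}

tiny_scorer_config <- function(strand_mode = "watson", width = 11L,
                               mod_type = NA_character_) {
  scorer_config(width = width, n_conv = 2L, filters = 16L, kernel = 3L,
                n_transformer = 1L, n_heads = 2L, ff_dim = 24L, fc_units = 16L,
                dropout = 0.1, mod_type = mod_type, strand_mode = strand_mode)
}
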