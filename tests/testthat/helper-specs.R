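# shared simulation fixtures, all built in code at test time

# two-entity chain IV -> M1 -> M2
chain_spec <- function(w = 0.5, alpha = 1, noise = 1) {
  A <- matrix(0, 2, 2, dimnames = list(c("M1", "M2"), c("M1", "M2")))
  A["M1", "M2"] <- w
  sem_spec(A,
           iv_map = tibble::tibble(entity = "M1", instrument = "iv1",
                                   alpha = alpha),
           noise_sd = noise)
}

# three-entity chain M1 -> M2 -> M3 with one instrument per entity
chain3_spec <- function(w = 0.6, alpha = 1) {
  ids <- c("M1", "M2", "M3")
  A <- matrix(0, 3, 3, dimnames = list(ids, ids))
  A["M1", "M2"] <- w
  A["M2", "M3"] <- w
  sem_spec(A,
           iv_map = tibble::tibble(entity = ids,
                                   instrument = paste0("iv", 1:3), alpha = alpha))
}

# simulate genotypes + omics for a spec in one call
sim_spec_data <- function(spec, n, seed) {
  variants <- unique(c(spec$iv_map$instrument, spec$pleiotropy$instrument))
  g <- simulate_genotypes(n, length(variants), maf = unname(spec$maf[variants]),
                          variant_ids = variants, seed = seed)
  list(genotypes = g,
       omics = simulate_sem(spec, g, seed = seed + 997))
}

# fully instrumented random sem at the study scale used across tests
instrumented_spec <- function(p, d = 1.5, seed = 1) {
  sample_random_dag(p, d, seed = seed, instrument_alpha = 1)
}
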