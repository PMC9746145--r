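# Small in-code fixtures shared across test files.

plate_obs <- function(sample_id = "s1", d, vol = 100, count, selective = 0L) {
  data.frame(sample_id = sample_id, dilution_exponent = d,
             plated_volume_ul = vol, selective = selective,
             colony_count = count, stringsAsFactors = FALSE)
}

mono_sample <- function(sample_id = "s1", strain = "A",
                        cells = 2.5e8, resusp = 1000, replicate = "r1") {
  data.frame(sample_id = sample_id, assay_type = "monoculture",
             strain_i = strain, strain_j = NA_character_,
             initial_cells_total = cells, initial_fraction_i = 1,
             resuspension_volume_ul = resusp, replicate_id = replicate,
             stringsAsFactors = FALSE)
}

mix_sample <- function(sample_id = "m1", strain_i = "A", strain_j = "B",
                       cells = 2.5e8, frac = 0.01, resusp = 1000,
                       replicate = "r1") {
  data.frame(sample_id = sample_id, assay_type = "mixture",
             strain_i = strain_i, strain_j = strain_j,
             initial_cells_total = cells, initial_fraction_i = frac,
             resuspension_volume_ul = resusp, replicate_id = replicate,
             stringsAsFactors = FALSE)
}

# A tiny deterministic dataset: strain A (minority, marked) and B mixed
# 1:99 plus monocultures, built from exact expected plate counts so the
# pipeline's arithmetic can be checked in closed form.
exact_tiny_dataset <- function(n_reps = 3, log10_eff = c(A = -2, B = -1),
                               w_shift = 0) {
  cfg <- simulation_config(
    strains = data.frame(strain_id = c("A", "B"),
                         log10_efficiency = unname(log10_eff),
                         resistance_marker = c("kanamycin", "none"),
                         stringsAsFactors = FALSE),
    interactions = data.frame(minority = "A", majority = "B",
                              shift_minority = w_shift, shift_majority = 0,
                              stringsAsFactors = FALSE),
    replicate_noise_sd = 0, n_replicates = n_reps, exact_counts = TRUE,
    seed = 1L)
  simulate_dataset(cfg)
}
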