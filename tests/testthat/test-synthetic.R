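test_that("simulation is deterministic for a fixed seed and config", {
  cfg <- make_preset("cheater_vs_parent", seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$plates, d2$plates)
  expect_identical(d1$samples, d2$samples)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(make_preset("cheater_vs_parent", seed = 100))
  expect_false(identical(d1$plates, d3$plates))
})

test_that("per-sample sub-seeding keeps existing samples stable when strains are added", {
  base_strains <- data.frame(strain_id = c("A", "B"),
                             log10_efficiency = c(-2, -1),
                             resistance_marker = c("kanamycin", "none"))
  cfg1 <- simulation_config(base_strains,
                            data.frame(minority = "A", majority = "B",
                                       shift_minority = 1),
                            n_replicates = 2, seed = 5)
  cfg2 <- simulation_config(rbind(base_strains,
                                  data.frame(strain_id = "C",
                                             log10_efficiency = -1.2,
                                             resistance_marker = "none")),
                            data.frame(minority = c("A", "A"),
                                       majority = c("B", "C"),
                                       shift_minority = c(1, 0)),
                            n_replicates = 2, seed = 5)
  d1 <- simulate_dataset(cfg1)
  d2 <- simulate_dataset(cfg2)
  shared <- d1$plates$sample_id
  expect_identical(d1$plates,
                   d2$plates[d2$plates$sample_id %in% shared, ],
                   ignore_attr = TRUE)
})

test_that("noise-free exact counts recover the configured log-efficiency difference", {
  d <- exact_tiny_dataset(n_reps = 2, log10_eff = c(A = -3, B = -1),
                          w_shift = 1)
  counts <- count_samples(d$plates, d$samples)
  fit <- compute_fitness(counts, d$samples)
  w <- fit$value[fit$metric == "W_ij"]
  expect_equal(w, rep((-3 + 1) - (-1), 2), tolerance = 0.02)
})

test_that("the antagonism regime censors every minority mixture count", {
  cfg <- make_preset("natural_isolate_panel", seed = 8)
  d <- simulate_dataset(cfg)
  counts <- count_samples(d$plates, d$samples)
  is_mix <- grepl("^mix_", counts$sample_id)
  minority <- is_mix & counts$strain_id == "DK5208" &
    !grepl("_GJV1_", counts$sample_id)
  expect_true(all(counts$censored[minority]))
  expect_true(all(counts$spores_total[minority] == 9))
})

test_that("presets are well-formed and unknown names fail", {
  for (nm in c("cheater_vs_parent", "natural_isolate_panel",
               "evolved_clone_panel", "csgA_background_panel")) {
    cfg <- make_preset(nm, seed = 1)
    expect_s3_class(cfg, "simulation_config")
    expect_true(all(c(cfg$interactions$minority, cfg$interactions$majority)
                    %in% cfg$strains$strain_id))
  }
  expect_error(make_preset("no_such_panel"), "arg")
  # structural guarantees the panels encode
  nat <- make_preset("natural_isolate_panel", seed = 1)
  non_parent <- nat$interactions$majority != "GJV1"
  expect_true(all(nat$interactions$shift_minority[non_parent] <= -6))
  bg <- make_preset("csgA_background_panel", seed = 1)
  eff <- setNames(bg$strains$log10_efficiency, bg$strains$strain_id)
  expect_equal(eff[["GJV1-csgA"]], eff[["GJV1"]])   # no defect in GJV1
  expect_lt(eff[["N2-csgA"]], -8)                    # complete loss in N2
})

test_that("config validation rejects inconsistent inputs", {
  strains <- data.frame(strain_id = "A", log10_efficiency = -1)
  expect_error(simulation_config(strains, seed = NA), "seed")
  expect_error(simulation_config(strains, dilution_exponents = integer(0),
                                 seed = 1), "non-empty")
  expect_error(simulation_config(strains,
                                 data.frame(minority = "A", majority = "Z"),
                                 seed = 1), "unknown strains")
  expect_error(simulation_config(rbind(strains, strains), seed = 1),
               "unique")
})

test_that("simulation configs round-trip through YAML", {
  cfg <- make_preset("evolved_clone_panel", seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$strains, cfg$strains)
  expect_equal(back$interactions, cfg$interactions, ignore_attr = TRUE)
  expect_identical(simulate_dataset(back)$plates,
                   simulate_dataset(cfg)$plates)
})

test_that("censoring frequency rises as true mixture efficiency falls", {
  shifts <- c(-1, -3, -5, -7)   # minority mixture log10 efficiency -3..-9
  frac <- vapply(seq_along(shifts), function(i) {
    cfg <- simulation_config(
      strains = data.frame(strain_id = c("A", "B"),
                           log10_efficiency = c(-2, -1),
                           resistance_marker = c("kanamycin", "none")),
      interactions = data.frame(minority = "A", majority = "B",
                                shift_minority = shifts[i]),
      replicate_noise_sd = 0.3, n_replicates = 30, seed = 100 + i)
    d <- simulate_dataset(cfg)
    counts <- count_samples(d$plates, d$samples)
    mix_min <- grepl("^mix_", counts$sample_id) & counts$strain_id == "A"
    mean(counts$censored[mix_min])
  }, numeric(1))
  expect_true(all(diff(frac) >= -0.05))
  expect_lt(frac[1], 0.5)
  expect_equal(frac[length(frac)], 1)
})

test_that("full-pipeline W estimates are nearly unbiased without censoring", {
  bias <- vapply(1:200, function(s) {
    cfg <- make_preset("cheater_vs_parent", seed = 5000 + s)
    cfg$n_replicates <- 4L
    d <- simulate_dataset(cfg)
    counts <- suppressWarnings(count_samples(d$plates, d$samples))
    fit <- suppressWarnings(compute_fitness(counts, d$samples))
    mean(fit$value[fit$metric == "W_ij"]) - d$truth$pairs$true_W
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.1)
})
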