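# Synthetic plate-count generator. Emulates the statistical structure of a
# starvation-assay dataset: per-strain log10 sporulation efficiencies
# spanning several orders of magnitude, additive log10 interaction shifts in
# mixture (antagonism < 0, complementation > 0), log-normal replicate noise,
# binomial 1:99 inoculum composition, and Poisson colony counts over a
# dilution series with a ~10-spore detection limit.

#' Build a simulation configuration
#'
#' @param strains Data frame with at least `strain_id` and
#'   `log10_efficiency` (true monoculture log10 sporulation efficiency);
#'   optional `display_name`, `resistance_marker`, `role_hint`, `mutation`,
#'   `background` columns are filled with defaults.
#' @param interactions Data frame of mixture assays to simulate, one row per
#'   ordered (minority, majority) pair: columns `minority`, `majority`,
#'   `shift_minority` (additive log10 shift on the minority's efficiency in
#'   that mix), `shift_majority` (default 0).
#' @param replicate_noise_sd SD of the log10 efficiency across biological
#'   replicates (default 0.3).
#' @param n_replicates Biological replicates per assay (default 4).
#' @param mix_fraction Initial minority fraction in mixtures (default 0.01,
#'   i.e. a 1:99 mix).
#' @param inoculum_total Cells inoculated per assay (default 2.5e8: 50 ul at
#'   ~5e9 cells/ml).
#' @param dilution_exponents Dilution series plated (default `2:7`).
#' @param plated_volume_ul Volume plated per plate (default 100).
#' @param resuspension_volume_ul Harvest resuspension volume (default 1000).
#' @param detection_limit Detection limit in spores (default 10).
#' @param exact_counts If `TRUE`, bypass binomial/Poisson noise (expected
#'   counts, rounded) — useful for noise-free pipeline checks.
#' @param seed Mandatory integer seed; every sample derives its own RNG
#'   sub-stream from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(strains, interactions = NULL,
                              replicate_noise_sd = 0.3, n_replicates = 4,
                              mix_fraction = 0.01, inoculum_total = 2.5e8,
                              dilution_exponents = 2:7,
                              plated_volume_ul = 100,
                              resuspension_volume_ul = 1000,
                              detection_limit = 10, exact_counts = FALSE,
                              seed) {
  stopifnot(is.data.frame(strains),
            all(c("strain_id", "log10_efficiency") %in% names(strains)))
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for simulation configs")
  if (length(dilution_exponents) == 0L)
    stop("dilution_exponents must be non-empty")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (anyDuplicated(strains$strain_id))
    stop("strain ids must be unique")
  for (col in c("display_name", "resistance_marker", "role_hint",
                "mutation", "background")) {
    if (is.null(strains[[col]]))
      strains[[col]] <- switch(col,
                               display_name = as.character(strains$strain_id),
                               resistance_marker = "none",
                               role_hint = "unknown",
                               "")
  }
  if (!is.null(interactions)) {
    stopifnot(all(c("minority", "majority") %in% names(interactions)))
    if (is.null(interactions$shift_minority)) interactions$shift_minority <- 0
    if (is.null(interactions$shift_majority)) interactions$shift_majority <- 0
    unknown <- setdiff(c(interactions$minority, interactions$majority),
                       strains$strain_id)
    if (length(unknown))
      stop("interactions reference unknown strains: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(strains = strains, interactions = interactions,
                 replicate_noise_sd = replicate_noise_sd,
                 n_replicates = as.integer(n_replicates),
                 mix_fraction = mix_fraction,
                 inoculum_total = inoculum_total,
                 dilution_exponents = as.integer(dilution_exponents),
                 plated_volume_ul = plated_volume_ul,
                 resuspension_volume_ul = resuspension_volume_ul,
                 detection_limit = detection_limit,
                 exact_counts = isTRUE(exact_counts),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic 31-bit string hash; combined with the config seed it gives
# each sample its own RNG sub-stream, so adding samples to a config never
# perturbs the draws of existing ones.
.hash_string <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

.sub_seed <- function(seed, sample_id) {
  as.integer((abs(as.numeric(seed)) * 48271 + .hash_string(sample_id)) %%
               2147483647)
}

#' Simulate a plate-count dataset with ground truth
#'
#' For every strain a monoculture assay and for every configured
#' (minority, majority) pair a 1:99 mixture assay is generated per
#' replicate. Each strain's realized log10 efficiency in a sample is
#' `truth + interaction shift + Normal(0, replicate_noise_sd)`; the minority
#' inoculum is Binomial(total, fraction); colonies on plate k are
#' Poisson(spores x sampled fraction). With `exact_counts` the binomial and
#' Poisson draws are replaced by rounded expectations.
#'
#' @param config A [simulation_config()].
#' @return `list(plates, samples, strains, truth)` where `truth` has
#'   components `strains` (true efficiencies), `samples` (realized per-sample
#'   efficiencies and spore counts) and `pairs` (true `C_i(j)` and `W_ij`
#'   per configured mixture).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  eff <- setNames(cf$strains$log10_efficiency, cf$strains$strain_id)
  marker <- setNames(cf$strains$resistance_marker, cf$strains$strain_id)

  plate_rows <- list(); sample_rows <- list(); truth_rows <- list()

  draw_sample <- function(sample_id, assay_type, strain_i, strain_j,
                          shift_i, shift_j, replicate_id) {
    with_seed(.sub_seed(cf$seed, sample_id), {
      if (assay_type == "mixture") {
        n_i <- if (cf$exact_counts) round(cf$inoculum_total * cf$mix_fraction)
        else rbinom(1, cf$inoculum_total, cf$mix_fraction)
        n_j <- cf$inoculum_total - n_i
        frac_i <- cf$mix_fraction
      } else {
        n_i <- cf$inoculum_total; n_j <- 0; frac_i <- 1
      }
      noise <- function() if (cf$replicate_noise_sd > 0)
        rnorm(1, 0, cf$replicate_noise_sd) else 0
      le_i <- eff[[strain_i]] + shift_i + noise()
      spores_i <- 10^le_i * n_i
      le_j <- NA_real_; spores_j <- 0
      if (assay_type == "mixture") {
        le_j <- eff[[strain_j]] + shift_j + noise()
        spores_j <- 10^le_j * n_j
      }
      draw <- function(lambda) if (cf$exact_counts) round(lambda)
      else rpois(length(lambda), lambda)
      f <- cf$plated_volume_ul / cf$resuspension_volume_ul *
        10^(-cf$dilution_exponents)
      if (assay_type == "mixture") {
        plate_rows[[length(plate_rows) + 1L]] <<- data.frame(
          sample_id = sample_id,
          dilution_exponent = rep(cf$dilution_exponents, 2L),
          plated_volume_ul = cf$plated_volume_ul,
          selective = rep(c(1L, 0L), each = length(f)),
          colony_count = c(draw(spores_i * f),
                           draw((spores_i + spores_j) * f)),
          stringsAsFactors = FALSE)
      } else {
        plate_rows[[length(plate_rows) + 1L]] <<- data.frame(
          sample_id = sample_id,
          dilution_exponent = cf$dilution_exponents,
          plated_volume_ul = cf$plated_volume_ul,
          selective = if (marker[[strain_i]] != "none") 1L else 0L,
          colony_count = draw(spores_i * f),
          stringsAsFactors = FALSE)
      }
      sample_rows[[length(sample_rows) + 1L]] <<- data.frame(
        sample_id = sample_id, assay_type = assay_type,
        strain_i = strain_i, strain_j = strain_j %||% NA_character_,
        initial_cells_total = cf$inoculum_total,
        initial_fraction_i = frac_i,
        resuspension_volume_ul = cf$resuspension_volume_ul,
        replicate_id = replicate_id, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        sample_id = rep(sample_id, if (assay_type == "mixture") 2L else 1L),
        strain_id = if (assay_type == "mixture") c(strain_i, strain_j)
        else strain_i,
        realized_log10_efficiency = if (assay_type == "mixture")
          c(le_i, le_j) else le_i,
        cells_inoculated = if (assay_type == "mixture") c(n_i, n_j) else n_i,
        spores_true = if (assay_type == "mixture") c(spores_i, spores_j)
        else spores_i,
        stringsAsFactors = FALSE)
    })
  }

  reps <- paste0("r", seq_len(cf$n_replicates))
  for (st in cf$strains$strain_id)
    for (rep_id in reps)
      draw_sample(paste0("mono_", st, "_", rep_id), "monoculture",
                  st, NULL, 0, 0, rep_id)
  if (!is.null(cf$interactions)) {
    for (r in seq_len(nrow(cf$interactions))) {
      it <- cf$interactions[r, ]
      for (rep_id in reps)
        draw_sample(paste0("mix_", it$minority, "_", it$majority, "_", rep_id),
                    "mixture", it$minority, it$majority,
                    it$shift_minority, it$shift_majority, rep_id)
    }
  }

  truth_pairs <- NULL
  if (!is.null(cf$interactions)) {
    it <- cf$interactions
    truth_pairs <- data.frame(
      minority = it$minority, majority = it$majority,
      true_C = it$shift_minority,
      true_W = (eff[it$minority] + it$shift_minority) -
        (eff[it$majority] + it$shift_majority),
      stringsAsFactors = FALSE)
    rownames(truth_pairs) <- NULL
  }

  plates <- do.call(rbind, plate_rows); rownames(plates) <- NULL
  samples <- do.call(rbind, sample_rows); rownames(samples) <- NULL
  truth_samples <- do.call(rbind, truth_rows); rownames(truth_samples) <- NULL
  list(plates = plates, samples = samples, strains = cf$strains,
       truth = list(strains = cf$strains[, c("strain_id", "log10_efficiency")],
                    samples = truth_samples, pairs = truth_pairs),
       config = cf)
}

#' Preset simulation scenarios
#'
#' Ready-made configurations matching the qualitative regimes of classic
#' cooperator-cheater competition panels:
#' \describe{
#'   \item{`cheater_vs_parent`}{A signaling defector with a ~3 log10
#'     monoculture sporulation deficit that is complemented by and
#'     outcompetes its parent in a 1:99 mix (true `W = +0.8`); 8 replicates.}
#'   \item{`natural_isolate_panel`}{The same defector against its parent and
#'     23 diverged natural-isolate cooperators whose antagonisms suppress
#'     the minority by 6 log10 — every minority mixture count falls below
#'     the detection limit.}
#'   \item{`evolved_clone_panel`}{The defector against its parent and nine
#'     closely related lab-evolved cooperator clones; relative fitness
#'     drops below the parental value for eight of the nine clones, with
#'     two clones (E2, E4) outcompeting the defector outright.}
#'   \item{`csgA_background_panel`}{One signaling-gene disruption placed in
#'     five cooperator backgrounds: no defect in one background, complete
#'     sporulation loss in another, intermediate ~2 log10 defects elsewhere;
#'     each mutant is fully complemented by its own parent.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned config (default 1).
#' @return A [simulation_config()].
#' @export
make_preset <- function(name = c("cheater_vs_parent", "natural_isolate_panel",
                                 "evolved_clone_panel",
                                 "csgA_background_panel"),
                        seed = 1L) {
  name <- match.arg(name)
  coop_eff <- -1.5   # proficient cooperator: a few percent of cells sporulate
  defect <- -3       # obligate defector: ~3 orders of magnitude deficit
  comp_shift <- 3.8  # parental complementation of the defector in mixture

  if (name == "cheater_vs_parent") {
    strains <- data.frame(
      strain_id = c("GJV1", "DK5208"),
      display_name = c("GJV1", "DK5208 (csgA::Tn5)"),
      log10_efficiency = c(coop_eff, coop_eff + defect),
      resistance_marker = c("none", "oxytetracycline"),
      role_hint = c("cooperator", "defector_candidate"),
      stringsAsFactors = FALSE)
    inter <- data.frame(minority = "DK5208", majority = "GJV1",
                        shift_minority = comp_shift, shift_majority = 0,
                        stringsAsFactors = FALSE)
    return(simulation_config(strains, inter, n_replicates = 8, seed = seed))
  }

  if (name == "natural_isolate_panel") {
    n_iso <- 23
    iso <- paste0("N", seq_len(n_iso))
    strains <- data.frame(
      strain_id = c("GJV1", "DK5208", iso),
      display_name = c("GJV1", "DK5208 (csgA::Tn5)", iso),
      log10_efficiency = c(coop_eff, coop_eff + defect,
                           seq(-1.0, -2.0, length.out = n_iso)),
      resistance_marker = c("none", "oxytetracycline", rep("none", n_iso)),
      role_hint = c("cooperator", "defector_candidate",
                    rep("cooperator", n_iso)),
      stringsAsFactors = FALSE)
    inter <- rbind(
      data.frame(minority = "DK5208", majority = "GJV1",
                 shift_minority = comp_shift, shift_majority = 0,
                 stringsAsFactors = FALSE),
      data.frame(minority = "DK5208", majority = iso,
                 shift_minority = -6, shift_majority = 0,
                 stringsAsFactors = FALSE))
    return(simulation_config(strains, inter, seed = seed))
  }

  if (name == "evolved_clone_panel") {
    clones <- paste0("E", 1:9)
    # True W of the defector against each partner; parental value +0.8,
    # below it for all clones except E6, with E2 and E4 outcompeting the
    # defector outright.
    w_true <- c(GJV1 = 0.8, E1 = 0.45, E2 = -0.7, E3 = 0.35, E4 = -2.1,
                E5 = 0.25, E6 = 0.9, E7 = 0.15, E8 = 0.05, E9 = 0.3)
    strains <- data.frame(
      strain_id = c("GJV1", "DK5208", clones),
      display_name = c("GJV1", "DK5208 (csgA::Tn5)", clones),
      log10_efficiency = c(coop_eff, coop_eff + defect, rep(coop_eff, 9)),
      resistance_marker = c("none", "oxytetracycline", rep("none", 9)),
      role_hint = c("cooperator", "defector_candidate",
                    rep("cooperator", 9)),
      stringsAsFactors = FALSE)
    partners <- names(w_true)
    inter <- data.frame(
      minority = "DK5208", majority = partners,
      # shift so that (eff_i + shift) - eff_j = w_true for each partner
      shift_minority = w_true + strains$log10_efficiency[
        match(partners, strains$strain_id)] - (coop_eff + defect),
      shift_majority = 0, stringsAsFactors = FALSE)
    return(simulation_config(strains, inter, seed = seed))
  }

  # csgA_background_panel
  backgrounds <- c("GJV1", "N2", "N10", "N16", "N23")
  bg_eff <- c(-1.4, -1.2, -1.5, -1.6, -1.3)
  mutants <- paste0(backgrounds, "-csgA")
  # identical disruption, background-dependent phenotype: no defect in
  # GJV1, complete loss in N2, ~2 log10 deficits elsewhere
  mut_eff <- c(bg_eff[1], -9, bg_eff[3] - 2, bg_eff[4] - 2, bg_eff[5] - 2.5)
  strains <- data.frame(
    strain_id = c(backgrounds, mutants),
    display_name = c(backgrounds, paste0(backgrounds, " csgA::pCR")),
    log10_efficiency = c(bg_eff, mut_eff),
    resistance_marker = c(rep("none", 5), rep("kanamycin", 5)),
    role_hint = c(rep("cooperator", 5), rep("defector_candidate", 5)),
    mutation = c(rep("", 5), rep("csgA413", 5)),
    background = c(rep("", 5), backgrounds),
    stringsAsFactors = FALSE)
  inter <- data.frame(
    minority = mutants, majority = backgrounds,
    shift_minority = bg_eff - mut_eff,  # full parental complementation
    shift_majority = 0, stringsAsFactors = FALSE)
  simulation_config(strains, inter, seed = seed)
}
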