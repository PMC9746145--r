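#' Spore-count estimate for one strain class in one sample
#'
#' Lightweight record holding the estimated number of viable spores in a
#' whole harvested developmental sample, together with its censoring and
#' imputation status.
#'
#' @param sample_id Sample identifier.
#' @param strain_id Strain the estimate refers to (`NA` for a total-population
#'   estimate from nonselective plates).
#' @param spores_total Estimated viable spores in the whole sample (>= 0).
#' @param censored `TRUE` iff no colonies were observed on any usable plate.
#' @param imputed `TRUE` once a censored estimate has been replaced by the
#'   detection-limit imputation value.
#' @param detection_limit Detection limit, in spores, recorded on the
#'   estimate when the limit rule is applied.
#' @param note Free-text provenance note (e.g. clamping during subtraction).
#'
#' @return An object of class `count_estimate`.
#' @export
count_estimate <- function(sample_id, strain_id = NA_character_, spores_total,
                           censored = FALSE, imputed = FALSE,
                           detection_limit = NA_real_, note = "") {
  stopifnot(length(spores_total) == 1L, spores_total >= 0)
  structure(
    list(sample_id = as.character(sample_id),
         strain_id = as.character(strain_id),
         spores_total = as.numeric(spores_total),
         censored = isTRUE(censored),
         imputed = isTRUE(imputed),
         detection_limit = as.numeric(detection_limit),
         note = as.character(note)),
    class = "count_estimate"
  )
}

#' @export
print.count_estimate <- function(x, ...) {
  cat(sprintf("<count_estimate> sample %s strain %s: %.4g spores%s%s\n",
              x$sample_id, x$strain_id, x$spores_total,
              if (x$censored) " [censored]" else "",
              if (x$imputed) " [imputed]" else ""))
  invisible(x)
}

#' Estimate total viable spores from a dilution series
#'
#' Pools all countable plates of one strain class into a single Poisson
#' maximum-likelihood estimate. Plate `k` examines a fraction
#' `f_k = (plated_volume_k / resuspension_volume) * 10^(-d_k)` of the
#' harvested sample, so with counts `c_k ~ Poisson(N * f_k)` the MLE of the
#' total `N` is `sum(c_k) / sum(f_k)`. Plates whose colony count exceeds the
#' countability ceiling are dropped from both sums (crowded plates cannot be
#' counted reliably).
#'
#' @param observations Data frame of plate observations for one strain class
#'   of one sample, with columns `sample_id`, `dilution_exponent`
#'   (non-negative integer `d`; the plate receives a `10^-d` dilution),
#'   `plated_volume_ul`, `colony_count`.
#' @param resuspension_volume Volume, in microlitres, the harvested sample
#'   was resuspended in (default 1000).
#' @param count_ceiling Countability ceiling in colonies per plate
#'   (default 400); plates above it are excluded.
#' @param strain_id Strain label attached to the returned estimate.
#'
#' @return A [count_estimate()] with `censored = TRUE` iff every usable plate
#'   had zero colonies (the estimate is then a provisional 0 awaiting
#'   [apply_detection_limit()]).
#' @export
estimate_population <- function(observations, resuspension_volume = 1000,
                                count_ceiling = 400,
                                strain_id = NA_character_) {
  stopifnot(is.data.frame(observations))
  req <- c("sample_id", "dilution_exponent", "plated_volume_ul", "colony_count")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("observations lack required columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(observations) < 1L) stop("at least one plate observation required")
  sid <- unique(as.character(observations$sample_id))
  if (length(sid) != 1L)
    stop("observations span multiple samples: ", paste(sid, collapse = ", "))
  cnt <- observations$colony_count
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop(sprintf("sample %s: colony counts must be non-negative integers", sid))
  if (any(observations$plated_volume_ul <= 0) || resuspension_volume <= 0)
    stop(sprintf("sample %s: volumes must be positive", sid))
  if (any(observations$dilution_exponent < 0))
    stop(sprintf("sample %s: dilution exponents must be >= 0", sid))

  f <- observations$plated_volume_ul / resuspension_volume *
    10^(-observations$dilution_exponent)
  usable <- cnt <= count_ceiling
  if (!any(usable))
    stop(sprintf(
      "sample %s: no usable plates (all %d counts above ceiling %g)",
      sid, length(cnt), count_ceiling))
  f_tot <- sum(f[usable])
  if (f_tot >= 1)
    warning(sprintf(
      "sample %s: total sampled fraction %.3g >= 1 (over-sampling)",
      sid, f_tot))
  count_estimate(sid, strain_id,
                 spores_total = sum(cnt[usable]) / f_tot,
                 censored = all(cnt[usable] == 0))
}

#' Resolve mixture counts into minority and majority strain estimates
#'
#' In mixed competitions the minority (marked) strain is counted on selective
#' plates and the total population on nonselective plates; the unmarked
#' majority partner is obtained by subtraction. Counting noise can make the
#' subtraction negative, in which case the majority estimate is clamped to 0,
#' flagged censored, and a warning is raised.
#'
#' @param total [count_estimate()] from nonselective plates (whole mixture).
#' @param minority [count_estimate()] from selective plates (marked strain).
#' @param majority_strain Strain id to attach to the majority estimate.
#'
#' @return `list(minority = , majority = )` of [count_estimate()] objects.
#' @export
split_mixture_counts <- function(total, minority,
                                 majority_strain = NA_character_) {
  stopifnot(inherits(total, "count_estimate"),
            inherits(minority, "count_estimate"))
  if (!identical(total$sample_id, minority$sample_id))
    stop(sprintf("sample id mismatch: total '%s' vs minority '%s'",
                 total$sample_id, minority$sample_id))
  maj <- total$spores_total - minority$spores_total
  note <- ""
  if (maj < 0) {
    warning(sprintf(
      "sample %s: minority estimate (%.4g) exceeds total (%.4g); majority clamped to 0 and censored",
      total$sample_id, minority$spores_total, total$spores_total))
    note <- "clamped negative subtraction"
    maj <- 0
  }
  list(
    minority = minority,
    majority = count_estimate(total$sample_id, majority_strain,
                              spores_total = maj,
                              censored = maj <= 0,
                              note = note)
  )
}

#' Apply the detection-limit rule to a censored estimate
#'
#' Samples for which no colonies were seen are assumed to have produced the
#' maximum number of spores that would still have gone undetected. With an
#' integer detection limit `DL` that maximum is `DL - 1` (default policy
#' `"dl_minus_one"`); policy `"dl"` uses `DL` itself. Uncensored estimates
#' pass through unchanged.
#'
#' @param estimate A [count_estimate()].
#' @param detection_limit Detection limit in spores (> 0, default 10).
#' @param policy `"dl_minus_one"` (default) or `"dl"`.
#'
#' @return The (possibly imputed) [count_estimate()].
#' @export
apply_detection_limit <- function(estimate, detection_limit = 10,
                                  policy = c("dl_minus_one", "dl")) {
  stopifnot(inherits(estimate, "count_estimate"), detection_limit > 0)
  policy <- match.arg(policy)
  estimate$detection_limit <- detection_limit
  if (!estimate$censored) return(estimate)
  estimate$spores_total <-
    if (policy == "dl_minus_one") detection_limit - 1 else detection_limit
  estimate$imputed <- TRUE
  estimate
}

#' Sporulation efficiency of one strain in one assay
#'
#' Fraction of the cells inoculated *for that strain* recovered as viable
#' spores. In mixtures the per-strain inoculum is the total inoculum times
#' the strain's initial fraction, so monoculture and mixture efficiencies
#' share a common scale.
#'
#' @param estimate A [count_estimate()] for the strain in the sample.
#' @param sample One assay sample as a list or one-row data frame with
#'   fields `strain_i`, `strain_j`, `initial_cells_total`,
#'   `initial_fraction_i`.
#'
#' @return The efficiency (may exceed 1 when counts exceed the inoculum;
#'   warned, never clamped).
#' @export
sporulation_efficiency <- function(estimate, sample) {
  stopifnot(inherits(estimate, "count_estimate"))
  s <- as.list(sample)
  frac <- if (!is.null(s$strain_j) && !is.na(s$strain_j) &&
              identical(estimate$strain_id, as.character(s$strain_j))) {
    1 - s$initial_fraction_i
  } else {
    s$initial_fraction_i
  }
  cells <- s$initial_cells_total * frac
  if (!is.finite(cells) || cells <= 0)
    stop(sprintf("sample %s strain %s: zero cells inoculated",
                 estimate$sample_id, estimate$strain_id))
  eff <- estimate$spores_total / cells
  if (eff > 1)
    warning(sprintf(
      "sample %s strain %s: efficiency %.3g > 1 (counts exceed inoculum)",
      estimate$sample_id, estimate$strain_id, eff))
  eff
}

#' Estimate spore counts for every sample of a dataset
#'
#' Runs [estimate_population()] per sample (resolving mixtures with
#' [split_mixture_counts()]) and applies the detection-limit rule, producing
#' the per-strain count table the fitness statistics consume.
#'
#' @param plates Plate-observation table (see [read_plates()] for schema).
#' @param samples Assay-sample table (see [read_samples()]).
#' @param detection_limit,policy,count_ceiling Passed to
#'   [apply_detection_limit()] / [estimate_population()].
#'
#' @return Data frame with columns `sample_id`, `strain_id`, `spores_total`,
#'   `censored`, `imputed`, `detection_limit`; attribute `"log"` holds a
#'   character vector tracing every imputation and clamp.
#' @export
count_samples <- function(plates, samples, detection_limit = 10,
                          policy = "dl_minus_one", count_ceiling = 400) {
  stopifnot(is.data.frame(plates), is.data.frame(samples))
  log_lines <- character(0)
  out <- vector("list", nrow(samples))
  sel <- as.logical(plates$selective)

  finish <- function(est) {
    est2 <- apply_detection_limit(est, detection_limit, policy)
    if (est2$imputed)
      log_lines[[length(log_lines) + 1L]] <<- sprintf(
        "impute: sample %s strain %s censored at detection limit %g -> %g spores",
        est2$sample_id, est2$strain_id, detection_limit, est2$spores_total)
    if (nzchar(est2$note))
      log_lines[[length(log_lines) + 1L]] <<- sprintf(
        "clamp: sample %s strain %s: %s", est2$sample_id, est2$strain_id,
        est2$note)
    est2
  }
  as_row <- function(est) {
    data.frame(sample_id = est$sample_id, strain_id = est$strain_id,
               spores_total = est$spores_total, censored = est$censored,
               imputed = est$imputed, detection_limit = est$detection_limit,
               stringsAsFactors = FALSE)
  }

  for (r in seq_len(nrow(samples))) {
    s <- samples[r, ]
    keep <- plates$sample_id == s$sample_id
    obs <- plates[keep, , drop = FALSE]
    if (nrow(obs) == 0L)
      stop(sprintf("sample %s has no plate observations", s$sample_id))
    if (identical(as.character(s$assay_type), "monoculture")) {
      est <- estimate_population(obs, s$resuspension_volume_ul, count_ceiling,
                                 strain_id = s$strain_i)
      out[[r]] <- as_row(finish(est))
    } else {
      obs_sel <- obs[sel[keep], , drop = FALSE]
      obs_non <- obs[!sel[keep], , drop = FALSE]
      if (nrow(obs_sel) == 0L || nrow(obs_non) == 0L)
        stop(sprintf(
          "mixture sample %s needs both selective and nonselective plates",
          s$sample_id))
      total <- estimate_population(obs_non, s$resuspension_volume_ul,
                                   count_ceiling, strain_id = NA_character_)
      minority <- estimate_population(obs_sel, s$resuspension_volume_ul,
                                      count_ceiling, strain_id = s$strain_i)
      parts <- split_mixture_counts(total, minority,
                                    majority_strain = s$strain_j)
      out[[r]] <- rbind(as_row(finish(parts$minority)),
                        as_row(finish(parts$majority)))
    }
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  attr(counts, "log") <- log_lines
  counts
}
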