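#' One-way mixing effect C_i(j)
#'
#' Log ratio of a strain's sporulation efficiency in mixture to its
#' efficiency in pure culture. Positive values mean the strain benefits from
#' the presence of its partner (social exploitation when significant).
#'
#' @param eff_mix_i Efficiency of strain i in the mixture (> 0).
#' @param eff_pure_i Efficiency of strain i in pure culture (> 0).
#' @param log_base Logarithm base (default 10).
#' @return `log(eff_mix_i / eff_pure_i)` in the requested base; vectorized.
#' @export
mixing_effect <- function(eff_mix_i, eff_pure_i, log_base = 10) {
  .check_pos(c(eff_mix_i, eff_pure_i))
  log(eff_mix_i / eff_pure_i, base = log_base)
}

#' Relative fitness in mixture W_ij
#'
#' Log ratio of the minority strain's sporulation efficiency to the majority
#' partner's, within the same mixed group. `W_ij > 0` means the minority
#' strain converted a greater proportion of its cells into spores than its
#' partner did.
#'
#' @param eff_mix_i Efficiency of the minority strain in the mix (> 0).
#' @param eff_mix_j Efficiency of the majority partner in the mix (> 0).
#' @param log_base Logarithm base (default 10).
#' @return `log(eff_mix_i / eff_mix_j)` in the requested base; vectorized.
#' @export
relative_fitness <- function(eff_mix_i, eff_mix_j, log_base = 10) {
  .check_pos(c(eff_mix_i, eff_mix_j))
  log(eff_mix_i / eff_mix_j, base = log_base)
}

.check_pos <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("efficiencies must be positive; impute censored counts first ",
         "(see apply_detection_limit)")
  invisible(TRUE)
}

#' Aggregate replicate fitness values
#'
#' Arithmetic mean with a two-sided Student-t confidence interval
#' (`mean +/- t_{1-(1-level)/2, n-1} * sd / sqrt(n)`); the interval is absent
#' (`NA`) for a single replicate.
#'
#' @param replicate_values Numeric vector of replicate-level values (n >= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return `list(n, mean, ci_low, ci_high)`.
#' @export
aggregate_fitness <- function(replicate_values, conf_level = 0.95) {
  x <- replicate_values[!is.na(replicate_values)]
  n <- length(x)
  if (n < 1L) stop("no replicate values to aggregate")
  m <- mean(x)
  if (n < 2L) return(list(n = n, mean = m, ci_low = NA_real_,
                          ci_high = NA_real_))
  half <- qt(1 - (1 - conf_level) / 2, n - 1) * sd(x) / sqrt(n)
  list(n = n, mean = m, ci_low = m - half, ci_high = m + half)
}

# Pure-culture efficiency for a strain: the replicate-matched monoculture if
# one exists, otherwise the geometric mean across that strain's monoculture
# replicates (the analysis lives on the log scale).
.pure_efficiency <- function(mono, strain, replicate_id) {
  rows <- mono[mono$strain_id == strain, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  matched <- rows[rows$replicate_id == replicate_id, , drop = FALSE]
  if (nrow(matched) >= 1L)
    return(list(eff = exp(mean(log(matched$efficiency))),
                imputed = any(matched$imputed)))
  list(eff = exp(mean(log(rows$efficiency))), imputed = any(rows$imputed))
}

#' Per-strain sporulation efficiencies for a dataset
#'
#' Joins the count table with the sample metadata and divides each spore
#' estimate by that strain's inoculum.
#'
#' @param counts Output of [count_samples()].
#' @param samples Assay-sample table.
#' @return Data frame with one row per (sample, strain): `sample_id`,
#'   `strain_id`, `assay_type`, `replicate_id`, `efficiency`, `imputed`,
#'   `censored`.
#' @export
compute_efficiencies <- function(counts, samples) {
  idx <- match(counts$sample_id, samples$sample_id)
  if (anyNA(idx))
    stop("counts reference unknown samples: ",
         paste(unique(counts$sample_id[is.na(idx)]), collapse = ", "))
  eff <- numeric(nrow(counts))
  for (r in seq_len(nrow(counts))) {
    est <- count_estimate(counts$sample_id[r], counts$strain_id[r],
                          counts$spores_total[r],
                          censored = counts$censored[r],
                          imputed = counts$imputed[r])
    eff[r] <- sporulation_efficiency(est, samples[idx[r], ])
  }
  data.frame(sample_id = counts$sample_id,
             strain_id = counts$strain_id,
             assay_type = as.character(samples$assay_type[idx]),
             replicate_id = as.character(samples$replicate_id[idx]),
             efficiency = eff,
             imputed = counts$imputed,
             censored = counts$censored,
             stringsAsFactors = FALSE)
}

#' Replicate-level fitness statistics for every mixture
#'
#' For each mixture sample computes `W_ij` from the two within-mix
#' efficiencies and `C_i(j)` against the minority strain's pure-culture
#' efficiency (replicate-paired monoculture when available, geometric mean
#' of that strain's monocultures otherwise; `C` is skipped when the strain
#' was never assayed in monoculture).
#'
#' @param counts Output of [count_samples()].
#' @param samples Assay-sample table.
#' @param log_base Logarithm base for both statistics (default 10).
#' @return Data frame with columns `strain_i`, `strain_j`, `metric`
#'   (`"W_ij"` or `"C_i_of_j"`), `replicate_id`, `sample_id`, `value`,
#'   `any_imputed`, `log_base`.
#' @export
compute_fitness <- function(counts, samples, log_base = 10) {
  effs <- compute_efficiencies(counts, samples)
  mono <- effs[effs$assay_type == "monoculture", , drop = FALSE]
  mixes <- samples[samples$assay_type == "mixture", , drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(mixes))) {
    s <- mixes[r, ]
    here <- effs[effs$sample_id == s$sample_id, , drop = FALSE]
    ei <- here[here$strain_id == s$strain_i, , drop = FALSE]
    ej <- here[here$strain_id == s$strain_j, , drop = FALSE]
    if (nrow(ei) != 1L || nrow(ej) != 1L)
      stop(sprintf("mixture sample %s lacks per-strain counts", s$sample_id))
    w <- relative_fitness(ei$efficiency, ej$efficiency, log_base)
    rows[[length(rows) + 1L]] <- data.frame(
      strain_i = s$strain_i, strain_j = s$strain_j, metric = "W_ij",
      replicate_id = as.character(s$replicate_id), sample_id = s$sample_id,
      value = w, any_imputed = ei$imputed || ej$imputed,
      log_base = log_base, stringsAsFactors = FALSE)
    pure <- .pure_efficiency(mono, s$strain_i, as.character(s$replicate_id))
    if (!is.null(pure)) {
      cval <- mixing_effect(ei$efficiency, pure$eff, log_base)
      rows[[length(rows) + 1L]] <- data.frame(
        strain_i = s$strain_i, strain_j = s$strain_j, metric = "C_i_of_j",
        replicate_id = as.character(s$replicate_id), sample_id = s$sample_id,
        value = cval, any_imputed = ei$imputed || pure$imputed,
        log_base = log_base, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate replicate fitness values per strain pair and metric
#'
#' @param fitness Output of [compute_fitness()].
#' @param conf_level Confidence level for the Student-t interval.
#' @return Data frame with `strain_i`, `strain_j`, `metric`, `n`, `mean`,
#'   `ci_low`, `ci_high`, `any_imputed`, `log_base`.
#' @export
summarize_fitness <- function(fitness, conf_level = 0.95) {
  key <- interaction(fitness$strain_i, fitness$strain_j, fitness$metric,
                     drop = TRUE)
  rows <- lapply(split(seq_len(nrow(fitness)), key), function(ii) {
    g <- fitness[ii, , drop = FALSE]
    agg <- aggregate_fitness(g$value, conf_level)
    data.frame(strain_i = g$strain_i[1], strain_j = g$strain_j[1],
               metric = g$metric[1], n = agg$n, mean = agg$mean,
               ci_low = agg$ci_low, ci_high = agg$ci_high,
               any_imputed = any(g$any_imputed), log_base = g$log_base[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$strain_i, out$strain_j, out$metric), , drop = FALSE]
}
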