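# End-to-end orchestration: counts -> fitness -> test battery -> phenotype
# calls -> ranges -> report, with every imputation, clamp and family
# adjustment traced in a run log.

#' Build the statistical test battery for a dataset
#'
#' Runs, per mixture pair (minority i, majority j):
#' \itemize{
#'   \item a two-sided one-sample t on replicate `W_ij` vs 0, Holm-adjusted
#'     across all pairs (family `"W_vs_0"`);
#'   \item a one-sided (`greater`) t on `W_ij` (the cheating gate, raw p);
#'   \item a one-sided (`greater`) t on `C_i(j)` (the exploitation gate);
#'   \item a one-sided monoculture defect test of strain i against its
#'     reference (its recorded genetic background when known, otherwise its
#'     mixture partner), Holm-adjusted across unique mutant-reference pairs
#'     (family `"monoculture_defect"`);
#'   \item a two-sided Welch complementation test (mixture efficiency of i
#'     vs the partner's monoculture efficiency).
#' }
#' When `dunnett_control` names a partner strain and the focal minority
#' strain was mixed with at least one other partner, a Dunnett many-to-one
#' comparison of `W` across partners against that control is added, plus a
#' one-tailed exact sign test of how many partners yield a lower mean `W`
#' than the control.
#'
#' @param fitness Output of [compute_fitness()].
#' @param counts Output of [count_samples()].
#' @param samples,strains Input tables.
#' @param alpha Significance level recorded on the calls.
#' @param dunnett_control Optional partner strain id used as the Dunnett
#'   control.
#' @param dunnett_draws Monte Carlo draws for [dunnett_test()].
#' @param seed Seed for the Dunnett draws.
#' @return `list(tests, w_gate, c_gate, defect, complement, pairs)`;
#'   `tests` is a flat list of every [test_result()], the others are lookup
#'   lists keyed by `"i|j"` (or `"mutant|reference"` for `defect`).
#' @export
build_test_battery <- function(fitness, counts, samples, strains = NULL,
                               alpha = 0.05, dunnett_control = NULL,
                               dunnett_draws = 1e5, seed = 1L) {
  effs <- compute_efficiencies(counts, samples)
  mono <- effs[effs$assay_type == "monoculture", , drop = FALSE]
  wdat <- fitness[fitness$metric == "W_ij", , drop = FALSE]
  cdat <- fitness[fitness$metric == "C_i_of_j", , drop = FALSE]
  pairs <- unique(wdat[, c("strain_i", "strain_j")])
  key <- function(i, j) paste(i, j, sep = "|")

  background_of <- function(strain) {
    if (is.null(strains) || is.null(strains$background)) return(NA_character_)
    bg <- strains$background[strains$strain_id == strain]
    if (length(bg) == 1L && nzchar(bg)) bg else NA_character_
  }

  w_two <- list(); w_gate <- list(); c_gate <- list(); complement <- list()
  defect_raw <- list()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$strain_i[r]; j <- pairs$strain_j[r]; k <- key(i, j)
    wv <- wdat$value[wdat$strain_i == i & wdat$strain_j == j]
    cv <- cdat$value[cdat$strain_i == i & cdat$strain_j == j]
    w_two[[k]] <- .t_or_note(wv, 0, "two_sided",
                             sprintf("W(%s|%s) vs 0", i, j))
    w_gate[[k]] <- .t_or_note(wv, 0, "greater",
                              sprintf("W(%s|%s) > 0", i, j))
    c_gate[[k]] <- if (length(cv))
      .t_or_note(cv, 0, "greater", sprintf("C_%s(%s) > 0", i, j)) else NULL

    mix_ids <- wdat$sample_id[wdat$strain_i == i & wdat$strain_j == j]
    mix_eff <- effs$efficiency[effs$sample_id %in% mix_ids &
                                 effs$strain_id == i]
    partner_mono <- mono$efficiency[mono$strain_id == j]
    complement[[k]] <- if (length(mix_eff) >= 2L && length(partner_mono) >= 2L)
      tryCatch(t_welch(log10(mix_eff), log10(partner_mono), "two_sided",
                       sprintf("mixture eff of %s vs monoculture eff of %s",
                               i, j)),
               error = function(e) NULL) else NULL

    ref <- background_of(i)
    if (is.na(ref)) ref <- j
    dk <- key(i, ref)
    if (is.null(defect_raw[[dk]])) {
      mut_pure <- mono$efficiency[mono$strain_id == i]
      ref_pure <- mono$efficiency[mono$strain_id == ref]
      if (length(mut_pure) >= 1L && length(ref_pure) >= 1L) {
        cl <- call_defector(mut_pure, ref_pure, alpha)
        cl$test$comparison <- sprintf("monoculture defect: %s vs %s", i, ref)
        defect_raw[[dk]] <- cl$test
      }
    }
  }

  w_two <- run_family(w_two, "W_vs_0")
  defect <- if (length(defect_raw)) run_family(defect_raw,
                                               "monoculture_defect")
  else defect_raw

  tests <- c(unname(w_two), unname(w_gate),
             unname(Filter(Negate(is.null), c_gate)),
             unname(defect), unname(Filter(Negate(is.null), complement)))

  # Dunnett across partners of each focal minority strain, plus the sign
  # test on mean W ordering relative to the control partner.
  if (!is.null(dunnett_control)) {
    for (i in unique(pairs$strain_i)) {
      partners <- pairs$strain_j[pairs$strain_i == i]
      if (!(dunnett_control %in% partners) || length(partners) < 2L) next
      wv_by <- lapply(partners, function(j)
        wdat$value[wdat$strain_i == i & wdat$strain_j == j])
      names(wv_by) <- partners
      ctrl <- wv_by[[dunnett_control]]
      trt <- wv_by[setdiff(partners, dunnett_control)]
      ok <- vapply(trt, function(v) length(v) >= 2L, logical(1))
      if (length(ctrl) >= 2L && any(ok)) {
        dt <- tryCatch(
          dunnett_test(trt[ok], ctrl, "two_sided", dunnett_draws, seed),
          error = function(e) NULL)
        if (!is.null(dt)) {
          for (ii in seq_along(dt))
            dt[[ii]]$comparison <- sprintf("W(%s|%s) - W(%s|%s)", i,
                                           names(trt[ok])[ii], i,
                                           dunnett_control)
          tests <- c(tests, dt)
        }
        below <- vapply(trt[ok], function(v) mean(v) < mean(ctrl), logical(1))
        st <- sign_test_exact(sum(below), length(below), "greater",
                              sprintf("partners with mean W below %s for %s",
                                      dunnett_control, i))
        tests <- c(tests, list(st))
      }
    }
  }

  list(tests = tests, w_gate = w_gate, c_gate = c_gate, defect = defect,
       complement = complement, pairs = pairs)
}

#' Classify the social phenotype of every mixture pair
#'
#' Combines the battery's per-pair tests through [call_defector()],
#' [call_cheating()] and [call_exploitation()].
#'
#' @param battery Output of [build_test_battery()].
#' @param strains Strain table (for background lookups), or `NULL`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per pair: `mutant`, `partner`,
#'   `reference`, `defector`, `cheating`, `exploitation`, `complemented`,
#'   `fully_complemented`, the gate p-values, and `alpha`.
#' @export
classify_pairs <- function(battery, strains = NULL, alpha = 0.05) {
  pairs <- battery$pairs
  key <- function(i, j) paste(i, j, sep = "|")
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$strain_i[r]; j <- pairs$strain_j[r]; k <- key(i, j)
    ref <- NA_character_
    if (!is.null(strains) && !is.null(strains$background)) {
      bg <- strains$background[strains$strain_id == i]
      if (length(bg) == 1L && nzchar(bg)) ref <- bg
    }
    if (is.na(ref)) ref <- j
    dtest <- battery$defect[[key(i, ref)]]
    dcall <- if (is.null(dtest)) {
      list(defector = "indeterminate", p = NA_real_)
    } else {
      p <- .gate_p(dtest)
      list(defector = if (is.na(p)) "indeterminate"
           else if (p < alpha) "defector" else "non_defector", p = p)
    }
    ccall <- call_cheating(dcall, battery$w_gate[[k]], alpha)
    ecall <- call_exploitation(battery$c_gate[[k]], alpha,
                               defector = identical(dcall$defector,
                                                    "defector"),
                               complement_test = battery$complement[[k]])
    rows[[r]] <- data.frame(
      mutant = i, partner = j, reference = ref,
      defector = dcall$defector, cheating = ccall$cheating,
      exploitation = ecall$exploitation,
      complemented = ecall$complemented,
      fully_complemented = ecall$fully_complemented,
      p_defect = dcall$p, p_w_greater = ccall$p, p_c_greater = ecall$p,
      alpha = alpha, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.ranges_table <- function(phenotypes, strains = NULL) {
  rows <- list()
  for (focal in unique(phenotypes$mutant)) {
    sub <- phenotypes[phenotypes$mutant == focal, , drop = FALSE]
    rng <- cheating_range(focal, data.frame(partner = sub$partner,
                                            cheating = sub$cheating))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = rng$kind, focal = focal, strain = rng$tested,
      in_range = rng$tested %in% rng$members, note = rng$note,
      stringsAsFactors = FALSE)
  }
  if (!is.null(strains) && any(nzchar(strains$mutation))) {
    for (mut in unique(strains$mutation[nzchar(strains$mutation)])) {
      mutants <- strains$strain_id[strains$mutation == mut]
      sub <- phenotypes[phenotypes$mutant %in% mutants &
                          phenotypes$partner == phenotypes$reference, ,
                        drop = FALSE]
      if (nrow(sub) == 0L) next
      rng <- defection_range(mut, data.frame(background = sub$reference,
                                             defector = sub$defector))
      rows[[length(rows) + 1L]] <- data.frame(
        kind = rng$kind, focal = mut, strain = rng$tested,
        in_range = rng$tested %in% rng$members, note = rng$note,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), focal = character(0),
                      strain = character(0), in_range = logical(0),
                      note = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.report_lines <- function(phenotypes, ranges) {
  lines <- c("Social phenotype report", "=======================", "")
  for (r in seq_len(nrow(phenotypes))) {
    p <- phenotypes[r, ]
    lines <- c(lines, sprintf(
      "%s mixed 1:99 into %s: %s, %s, %s%s", p$mutant, p$partner,
      p$defector, p$cheating, p$exploitation,
      if (isTRUE(p$complemented))
        sprintf(" (complemented%s)", if (isTRUE(p$fully_complemented))
          ", fully" else "") else ""),
      sprintf("  evidence: p_defect=%.3g, p[W>0]=%.3g, p[C>0]=%.3g (alpha=%g)",
              p$p_defect, p$p_w_greater, p$p_c_greater, p$alpha))
  }
  lines <- c(lines, "", "Ranges", "------")
  for (k in unique(paste(ranges$kind, ranges$focal))) {
    sub <- ranges[paste(ranges$kind, ranges$focal) == k, , drop = FALSE]
    lines <- c(lines, sprintf("%s of %s: {%s} out of %d tested",
                              sub$kind[1], sub$focal[1],
                              paste(sub$strain[sub$in_range], collapse = ", "),
                              nrow(sub)))
  }
  lines
}

#' Run the full analysis pipeline
#'
#' simulate/ingest -> estimate counts -> fitness statistics -> test battery
#' -> phenotype calls -> ranges -> files. Identical config and inputs give
#' identical outputs (all randomness flows from `config$seed`). On failure,
#' any partially written outputs are removed.
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   fields: `plates`, `samples`, `strains` (paths to the input CSVs, or
#'   data frames when called programmatically; `strains` may be omitted),
#'   `out_dir`, and optionally `detection_limit` (10), `imputation_policy`
#'   (`"dl_minus_one"`), `count_ceiling` (400), `log_base` (10), `alpha`
#'   (0.05), `conf_level` (0.95), `dunnett_control` (partner strain id),
#'   `dunnett_draws` (1e5), `seed` (1).
#' @return Invisibly, a list with every computed table
#'   (`counts`, `fitness`, `fitness_summary`, `tests`, `phenotypes`,
#'   `ranges`, `log`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir))
  cf <- list(detection_limit = config$detection_limit %||% 10,
             imputation_policy = config$imputation_policy %||% "dl_minus_one",
             count_ceiling = config$count_ceiling %||% 400,
             log_base = config$log_base %||% 10,
             alpha = config$alpha %||% 0.05,
             conf_level = config$conf_level %||% 0.95,
             dunnett_control = config$dunnett_control,
             dunnett_draws = config$dunnett_draws %||% 1e5,
             seed = config$seed %||% 1L)

  load_tbl <- function(x, reader) if (is.data.frame(x)) x else reader(x)
  plates <- load_tbl(config$plates, read_plates)
  samples <- load_tbl(config$samples, read_samples)
  strains <- if (is.null(config$strains)) NULL
  else load_tbl(config$strains, read_strains)
  if (!is.null(strains)) {
    refd <- unique(c(samples$strain_i,
                     samples$strain_j[!is.na(samples$strain_j)]))
    unknown <- setdiff(refd, strains$strain_id)
    if (length(unknown))
      stop("samples reference strains absent from strains table: ",
           paste(unknown, collapse = ", "))
  }

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))

  counts <- count_samples(plates, samples, cf$detection_limit,
                          cf$imputation_policy, cf$count_ceiling)
  run_log <- attr(counts, "log") %||% character(0)
  fitness <- compute_fitness(counts, samples, cf$log_base)
  fit_sum <- summarize_fitness(fitness, cf$conf_level)
  battery <- build_test_battery(fitness, counts, samples, strains,
                                alpha = cf$alpha,
                                dunnett_control = cf$dunnett_control,
                                dunnett_draws = cf$dunnett_draws,
                                seed = cf$seed)
  tests <- results_table(battery$tests)
  adjusted <- !is.na(tests$family_id) & tests$family_id != ""
  run_log <- c(run_log, sprintf(
    "family %s: %s adjusted from p=%.4g to p=%.4g",
    tests$family_id[adjusted], tests$comparison[adjusted],
    tests$p_raw[adjusted], tests$p_adjusted[adjusted]))
  phenotypes <- classify_pairs(battery, strains, cf$alpha)
  ranges <- .ranges_table(phenotypes, strains)
  report <- .report_lines(phenotypes, ranges)

  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    write.csv(df, p, row.names = FALSE)
  }
  emit(counts, "counts.csv")
  emit(fitness, "fitness.csv")
  emit(fit_sum, "fitness_summary.csv")
  emit(tests, "tests.csv")
  emit(phenotypes, "phenotypes.csv")
  emit(ranges, "ranges.csv")
  rp <- file.path(out_dir, "report.txt"); written <- c(written, rp)
  writeLines(report, rp)
  lp <- file.path(out_dir, "run.log"); written <- c(written, lp)
  writeLines(run_log, lp)
  ok <- TRUE

  invisible(list(counts = counts, fitness = fitness,
                 fitness_summary = fit_sum, tests = tests,
                 phenotypes = phenotypes, ranges = ranges, log = run_log))
}
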