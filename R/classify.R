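# Social-phenotype classification: defector / cheater / social exploitation
# and the derived range constructs.
#
# Vocabulary: a *defector* is intrinsically deficient at the cooperative
# trait (here, monoculture sporulation) relative to a reference cooperator;
# *cheating* is a defector gaining a relative-fitness advantage (W_ij > 0)
# over a cooperator in mixture; *social exploitation* is any absolute-fitness
# benefit from mixing (C_i(j) > 0), whether or not the partner is harmed.

# One-sample t that degrades gracefully for classification use: a sample
# constant at the null value carries no evidence (t = 0, p = 1); a sample
# constant away from the null has no valid t and yields an NA-p result.
.t_or_note <- function(values, mu0 = 0, alternative, comparison) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2L)
    return(test_result("t_one_sample", comparison, alternative, NA_real_,
                       p_raw = NA_real_, n = n,
                       notes = "insufficient replicates"))
  if (sd(x) == 0) {
    if (isTRUE(all.equal(mean(x), mu0)))
      return(test_result("t_one_sample", comparison, alternative, 0,
                         df = n - 1, p_raw = 1, n = n,
                         notes = "constant at null"))
    return(test_result("t_one_sample", comparison, alternative, NA_real_,
                       p_raw = NA_real_, n = n,
                       notes = "degenerate variance"))
  }
  t_one_sample(x, mu0, alternative, comparison)
}

.gate_p <- function(test) {
  if (is.null(test)) return(NA_real_)
  if (!is.na(test$p_adjusted)) test$p_adjusted else test$p_raw
}

#' Call the defector component of a social phenotype
#'
#' A mutant is a defector when its monoculture sporulation is significantly
#' below the reference cooperator's: one-sided test of
#' `log10(mutant / parent) < 0`. Replicate efficiencies of equal length are
#' treated as paired (per-replicate log ratios, one-sample t); unequal
#' lengths fall back to a Welch t on log10 efficiencies.
#'
#' @param mutant_pure Replicate monoculture efficiencies of the mutant.
#' @param parent_pure Replicate monoculture efficiencies of the reference.
#' @param alpha Significance level (default 0.05).
#' @param p_adjusted Optional family-adjusted p-value overriding the raw p
#'   (used when the test belongs to a declared Holm family).
#' @return `list(defector = "defector"|"non_defector"|"indeterminate",
#'   test = <test_result>, p = <gate p>, alpha = alpha)`.
#' @export
call_defector <- function(mutant_pure, parent_pure, alpha = 0.05,
                          p_adjusted = NULL) {
  if (length(mutant_pure) == length(parent_pure)) {
    tr <- .t_or_note(log10(mutant_pure / parent_pure), 0, "less",
                     "monoculture log10(mutant/parent) vs 0")
  } else {
    tr <- tryCatch(
      t_welch(log10(mutant_pure), log10(parent_pure), "less",
              "monoculture log10 efficiency, mutant vs parent"),
      error = function(e)
        test_result("t_welch", "monoculture log10 efficiency", "less",
                    NA_real_, p_raw = NA_real_,
                    n = length(mutant_pure) + length(parent_pure),
                    notes = conditionMessage(e)))
  }
  p <- p_adjusted %||% .gate_p(tr)
  defector <- if (is.na(p)) "indeterminate"
  else if (p < alpha) "defector" else "non_defector"
  list(defector = defector, test = tr, p = p, alpha = alpha)
}

#' Call the cheating component of a social phenotype
#'
#' Cheating requires both an intrinsic defect and a significant relative-
#' fitness advantage in mixture: `cheater` iff the defector call is
#' `"defector"` and the one-sided test for `W_ij > 0` is significant at
#' `alpha` (family-adjusted p when present). A non-defector with significant
#' `W > 0` is a facultative exploiter, which is excluded from cheating by
#' definition.
#'
#' @param defector_call Output of [call_defector()].
#' @param w_test [test_result()] of the one-sided (`greater`) test on
#'   replicate `W_ij` values.
#' @param alpha Significance level (default 0.05).
#' @return `list(cheating = "cheater"|"not_cheating"|"indeterminate",
#'   p = <gate p>)`.
#' @export
call_cheating <- function(defector_call, w_test, alpha = 0.05) {
  p <- .gate_p(w_test)
  cheating <-
    if (is.na(p)) "indeterminate"
    else if (identical(defector_call$defector, "defector") && p < alpha) "cheater"
    else if (identical(defector_call$defector, "indeterminate") && p < alpha)
      "indeterminate"
    else "not_cheating"
  list(cheating = cheating, p = p)
}

#' Call the social-exploitation component of a phenotype
#'
#' Exploitation is judged from the one-way mixing effect alone: `exploits`
#' iff the one-sided test for `C_i(j) > 0` is significant at `alpha`,
#' irrespective of relative fitness. When the focal strain is a defector and
#' exploits, it is recorded as complemented by its partner; a separate
#' "fully complemented" note is attached when the mutant's mixture
#' efficiency is statistically indistinguishable from the partner's
#' monoculture level (two-sided Welch test not significant).
#'
#' @param c_test [test_result()] of the one-sided (`greater`) test on
#'   replicate `C_i(j)` values.
#' @param alpha Significance level (default 0.05).
#' @param defector `TRUE` when the focal strain was called a defector.
#' @param complement_test Optional two-sided [test_result()] comparing the
#'   mutant's mixture efficiency with the partner's monoculture efficiency.
#' @return `list(exploitation, complemented, fully_complemented, p)`.
#' @export
call_exploitation <- function(c_test, alpha = 0.05, defector = FALSE,
                              complement_test = NULL) {
  p <- .gate_p(c_test)
  exploitation <- if (is.na(p)) "indeterminate"
  else if (p < alpha) "exploits" else "no_benefit"
  complemented <- isTRUE(defector) && identical(exploitation, "exploits")
  fully <- NA
  if (complemented && !is.null(complement_test)) {
    pc <- .gate_p(complement_test)
    fully <- !is.na(pc) && pc >= alpha
  }
  list(exploitation = exploitation, complemented = complemented,
       fully_complemented = fully, p = p)
}

#' Cheating range of a focal defector
#'
#' The set of cooperator genotypes on which the focal defector cheats,
#' among those assayed against it.
#'
#' @param focal Focal strain id.
#' @param calls Data frame with columns `partner` and `cheating` (one row
#'   per assayed partner).
#' @return `list(focal, kind = "cheating_range", members, tested, note)`
#'   of class `range_report`; `members` is always a subset of `tested`.
#' @export
cheating_range <- function(focal, calls) {
  stopifnot(all(c("partner", "cheating") %in% names(calls)))
  tested <- unique(as.character(calls$partner))
  members <- unique(as.character(calls$partner[calls$cheating == "cheater"]))
  indet <- unique(as.character(calls$partner[calls$cheating == "indeterminate"]))
  structure(list(focal = focal, kind = "cheating_range",
                 members = members, tested = tested,
                 note = if (length(indet))
                   paste("indeterminate:", paste(indet, collapse = ", "))
                 else ""),
            class = "range_report")
}

#' Defection-phenotype range of a mutation
#'
#' The set of genetic backgrounds in which a given mutation produces a
#' social defector. Indeterminate backgrounds stay in `tested` but never
#' enter `members`.
#'
#' @param mutation Mutation label.
#' @param calls Data frame with columns `background` and `defector`.
#' @return A `range_report` with `kind = "defection_phenotype_range"`.
#' @export
defection_range <- function(mutation, calls) {
  stopifnot(all(c("background", "defector") %in% names(calls)))
  tested <- unique(as.character(calls$background))
  members <- unique(as.character(calls$background[calls$defector == "defector"]))
  indet <- unique(as.character(calls$background[calls$defector == "indeterminate"]))
  structure(list(focal = mutation, kind = "defection_phenotype_range",
                 members = members, tested = tested,
                 note = if (length(indet))
                   paste("indeterminate:", paste(indet, collapse = ", "))
                 else ""),
            class = "range_report")
}

#' @export
print.range_report <- function(x, ...) {
  cat(sprintf("<%s> %s: %d of %d tested in range {%s}\n", x$kind, x$focal,
              length(x$members), length(x$tested),
              paste(x$members, collapse = ", ")))
  invisible(x)
}
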