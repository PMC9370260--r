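#' Harmonize exposure and outcome summary statistics
#'
#' Joins exposure and outcome records by variant id and re-expresses the
#' outcome effect on the exposure's effect allele, so that every downstream
#' estimator sees `beta_exp` and `beta_out` for the same allele.
#'
#' Matching rules, applied per shared variant:
#' * identical allele pair: kept as is (`status = "kept"`);
#' * swapped alleles (outcome EA equals exposure OA and vice versa): outcome
#'   beta negated, `status = "flipped"`;
#' * strand-complement pair (e.g. A/G vs T/C): treated as the same variant
#'   reported on the opposite strand — kept, or flipped when additionally
#'   swapped;
#' * palindromic pair (A/T or C/G, where strand cannot be resolved from the
#'   alleles): resolved by effect-allele frequency when both EAFs are present
#'   and both lie outside `0.5 +/- palindromic_window`; same side of 0.5
#'   keeps the sign, opposite sides flips it (`status =
#'   "palindromic_resolved"`); otherwise `status = "dropped_palindromic"`;
#' * irreconcilable allele pairs are dropped (`status = "dropped_missing"`,
#'   `reason = "allele_mismatch"`), never silently altered.
#'
#' Exposure variants absent from the outcome are retained in the result with
#' `status = "dropped_missing"` so the decision trail is explicit; rows whose
#' status starts with `"dropped"` are excluded from all estimation. An
#' optional proxy table substitutes an outcome-present proxy variant for a
#' missing one before the join.
#'
#' @param exposure,outcome Summary-statistics data frames (see
#'   [read_summary_stats()]).
#' @param palindromic_window Half-width of the EAF ambiguity zone around 0.5
#'   within which a palindromic variant is considered unresolvable (default
#'   0.08, i.e. drop when EAF is in \[0.42, 0.58\]).
#' @param proxies Optional two-column data frame (`missing_snp`,
#'   `proxy_snp`): when an exposure variant is absent from the outcome, the
#'   proxy's outcome record is used in its place (alleles and all).
#' @return A tibble with columns `snp`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`, `eaf_exp`, `eaf_out`, `pvalue_exp`, `n_exp`, `status`,
#'   `reason`.
#' @export
harmonize <- function(exposure, outcome, palindromic_window = 0.08,
                      proxies = NULL) {
  exposure <- as_tibble(exposure)
  outcome <- as_tibble(outcome)
  if (nrow(exposure) == 0L || nrow(outcome) == 0L) {
    abort("Both exposure and outcome collections must be non-empty.")
  }

  if (!is.null(proxies)) {
    proxies <- as_tibble(proxies)
    for (i in seq_len(nrow(proxies))) {
      want <- proxies$missing_snp[i]
      have <- proxies$proxy_snp[i]
      if (!want %in% outcome$snp && have %in% outcome$snp &&
          want %in% exposure$snp) {
        sub <- outcome[outcome$snp == have, ][1, ]
        sub$snp <- want
        outcome <- bind_rows(outcome, sub)
        inform(sprintf("Proxy %s substituted for missing outcome variant %s.",
                       have, want))
      }
    }
  }

  merged <- left_join(
    exposure, outcome,
    by = "snp", suffix = c("_exp", "_out")
  )

  rows <- purrr::pmap(merged, harmonize_one,
                      window = palindromic_window)
  out <- bind_rows(rows)
  n_missing <- sum(out$reason == "absent_from_outcome")
  if (n_missing > 0) {
    inform(sprintf("%d exposure variant(s) absent from outcome were excluded.",
                   n_missing))
  }
  out
}

# One merged row -> one harmonized record. Arguments come from pmap over the
# suffixed join, plus the EAF window.
harmonize_one <- function(snp, effect_allele_exp, other_allele_exp,
                          eaf_exp, beta_exp, se_exp, pvalue_exp, n_exp,
                          effect_allele_out = NA, other_allele_out = NA,
                          eaf_out = NA, beta_out = NA, se_out = NA,
                          pvalue_out = NA, n_out = NA,
                          window = 0.08, ...) {
  res <- function(status, reason, b_out = NA_real_, s_out = NA_real_,
                  e_out = NA_real_) {
    tibble(
      snp = snp, beta_exp = beta_exp, se_exp = se_exp,
      beta_out = b_out, se_out = s_out,
      eaf_exp = eaf_exp, eaf_out = e_out,
      pvalue_exp = pvalue_exp, n_exp = n_exp,
      status = status, reason = reason
    )
  }
  if (is.na(effect_allele_out) || !is.finite(beta_out) || !is.finite(se_out)) {
    return(res("dropped_missing", "absent_from_outcome"))
  }

  ea_x <- effect_allele_exp; oa_x <- other_allele_exp
  ea_y <- effect_allele_out; oa_y <- other_allele_out
  pal <- is_palindromic(ea_x, oa_x)

  if (pal) {
    # Alleles alone cannot distinguish strand from swap; only an A/T-vs-A/T
    # (or C/G-vs-C/G) pair is even the same variant class.
    same_pair <- (ea_y == ea_x && oa_y == oa_x) ||
      (ea_y == oa_x && oa_y == ea_x)
    if (!same_pair) return(res("dropped_missing", "allele_mismatch"))
    if (is.na(eaf_exp) || is.na(eaf_out)) {
      return(res("dropped_palindromic", "missing_eaf"))
    }
    # Frequency of the *exposure* effect allele in the outcome file: if the
    # outcome lists the swapped labels, its EAF refers to the other allele.
    eaf_out_aligned <- if (ea_y == ea_x) eaf_out else 1 - eaf_out
    in_window <- function(f) abs(f - 0.5) <= window
    if (in_window(eaf_exp) || in_window(eaf_out_aligned)) {
      return(res("dropped_palindromic", "eaf_near_0.5"))
    }
    same_side <- (eaf_exp - 0.5) * (eaf_out_aligned - 0.5) > 0
    if (same_side) {
      return(res("palindromic_resolved", "eaf_concordant",
                 beta_out, se_out, eaf_out_aligned))
    }
    # Opposite sides of 0.5: the outcome's stated effect allele is the
    # exposure's other allele on the opposite strand.
    return(res("palindromic_resolved", "eaf_discordant_flip",
               -beta_out, se_out, 1 - eaf_out_aligned))
  }

  if (ea_y == ea_x && oa_y == oa_x) {
    return(res("kept", "exact_match", beta_out, se_out, eaf_out))
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    return(res("flipped", "swapped_alleles", -beta_out, se_out,
               if (is.na(eaf_out)) NA_real_ else 1 - eaf_out))
  }
  cx <- complement_allele(ea_x); cox <- complement_allele(oa_x)
  if (ea_y == cx && oa_y == cox) {
    return(res("kept", "strand_complement", beta_out, se_out, eaf_out))
  }
  if (ea_y == cox && oa_y == cx) {
    return(res("flipped", "strand_complement_swapped", -beta_out, se_out,
               if (is.na(eaf_out)) NA_real_ else 1 - eaf_out))
  }
  res("dropped_missing", "allele_mismatch")
}
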