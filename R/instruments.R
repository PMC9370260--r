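#' Per-variant explained variance
#'
#' Proportion of exposure variance explained by one variant, computed from
#' summary statistics as
#' \deqn{R^2 = \frac{2\,EAF(1-EAF)\beta^2}{2\,EAF(1-EAF)\beta^2 +
#'   2\,EAF(1-EAF)\,N\,SE^2}}
#' which simplifies to `F / (F + N)` with `F = beta^2/se^2`.
#'
#' @param eaf Effect-allele frequency, strictly inside (0, 1).
#' @param beta Per-allele effect estimate.
#' @param se Standard error of `beta` (> 0).
#' @param n GWAS sample size (>= 2).
#' @return Explained-variance proportion in \[0, 1). Vectorised.
#' @export
#' @examples
#' compute_r2(0.5, 0.1, 0.01, 1000) # 0.0909...
compute_r2 <- function(eaf, beta, se, n) {
  if (any(!is.finite(eaf) | eaf <= 0 | eaf >= 1)) {
    abort("`eaf` must lie strictly between 0 and 1 (degenerate variant).")
  }
  assert_positive(se, "se")
  if (any(n < 2)) abort("`n` must be at least 2.")
  het <- 2 * eaf * (1 - eaf)
  num <- het * beta^2
  num / (num + het * n * se^2)
}

#' Per-variant F-statistic
#'
#' Instrument-strength statistic `beta^2 / se^2`; values at or below 10
#' conventionally mark weak instruments.
#'
#' @inheritParams compute_r2
#' @return Nonnegative F-statistic. Vectorised.
#' @export
compute_f <- function(beta, se) {
  assert_positive(se, "se")
  beta^2 / se^2
}

#' Select genetic instruments by significance and strength
#'
#' Retains variants with `pvalue < p_threshold` and F-statistic strictly
#' greater than `f_min`, reporting how many each rule removed. Default
#' thresholds follow the phenotype class: genome-wide significance 5e-8 for
#' absolute trait levels, 1e-5 for metabolite concentrations.
#'
#' @param stats Summary-statistics data frame.
#' @param p_threshold Significance threshold; when `NULL`, derived from
#'   `phenotype_class`.
#' @param f_min Weak-instrument bound; variants with `F <= f_min` are removed
#'   (default 10).
#' @param phenotype_class `"absolute"` (default) or `"metabolite"`.
#' @return The retained rows, with an added `f_stat` column.
#' @export
select_instruments <- function(stats, p_threshold = NULL, f_min = 10,
                               phenotype_class = c("absolute", "metabolite")) {
  phenotype_class <- match.arg(phenotype_class)
  if (is.null(p_threshold)) {
    p_threshold <- if (phenotype_class == "absolute") 5e-8 else 1e-5
  }
  stats <- as_tibble(stats)
  stats$f_stat <- compute_f(stats$beta, stats$se)
  sig <- !is.na(stats$pvalue) & stats$pvalue < p_threshold
  strong <- stats$f_stat > f_min
  n_weak <- sum(sig & !strong)
  if (n_weak > 0) {
    inform(sprintf("%d variant(s) passed p < %g but were weak (F <= %g): %s",
                   n_weak, p_threshold, f_min,
                   paste(stats$snp[sig & !strong], collapse = ", ")))
  }
  n_nonsig <- sum(!sig)
  if (n_nonsig > 0) {
    inform(sprintf("%d variant(s) failed p < %g.", n_nonsig, p_threshold))
  }
  out <- stats[sig & strong, ]
  if (nrow(out) == 0L) {
    abort("No valid instruments after significance and strength filtering.",
          class = "mrpipe_no_instruments")
  }
  out
}

#' Greedy LD/distance clumping
#'
#' Orders candidates by ascending p-value and keeps each in turn unless it
#' falls within `window_kb` of an already-kept variant on the same
#' chromosome and is in linkage disequilibrium with it (pairwise `r^2 >
#' r2_max`). Without LD information, distance alone decides (conservative:
#' nearby variants are assumed correlated); a candidate with neither a
#' position nor LD information against a kept variant is dropped with a
#' warning.
#'
#' @param stats Summary-statistics data frame (needs `pvalue`).
#' @param positions Data frame `snp`, `chrom`, `pos` (1-based basepair).
#' @param ld Optional data frame `snp_a`, `snp_b`, `r2` of pairwise LD.
#' @param r2_max LD threshold (default 0.001).
#' @param window_kb Clump window in kilobases (default 10000).
#' @return The retained rows, in ascending p-value order.
#' @export
clump_greedy <- function(stats, positions, ld = NULL, r2_max = 0.001,
                         window_kb = 10000) {
  stats <- as_tibble(stats)
  positions <- as_tibble(positions)
  ord <- order(stats$pvalue, stats$snp) # snp id breaks p ties deterministically
  stats <- stats[ord, ]
  pos <- setNames(positions$pos, positions$snp)
  chrom <- setNames(as.character(positions$chrom), positions$snp)

  ld_lookup <- function(a, b) {
    if (is.null(ld)) return(NA_real_)
    hit <- ld[(ld$snp_a == a & ld$snp_b == b) |
                (ld$snp_a == b & ld$snp_b == a), ]
    if (nrow(hit) == 0L) NA_real_ else hit$r2[1]
  }

  kept <- character(0)
  for (s in stats$snp) {
    drop <- FALSE
    for (k in kept) {
      have_pos <- s %in% names(pos) && k %in% names(pos)
      r2 <- ld_lookup(s, k)
      if (!have_pos && is.na(r2)) {
        warn(sprintf("No position or LD for %s vs kept %s; dropping %s.",
                     s, k, s))
        drop <- TRUE
        break
      }
      near <- have_pos && chrom[s] == chrom[k] &&
        abs(pos[s] - pos[k]) <= window_kb * 1000
      # Removal needs proximity AND correlation; unknown LD within the window
      # is assumed correlated (conservative). With LD but no positions, the
      # r2 threshold alone decides.
      if ((near && (is.na(r2) || r2 > r2_max)) ||
          (!have_pos && !is.na(r2) && r2 > r2_max)) {
        drop <- TRUE
        break
      }
    }
    if (!drop) kept <- c(kept, s)
  }
  stats[stats$snp %in% kept, ]
}

#' Rescale the exposure unit
#'
#' Divides exposure effects and their SEs by `factor`, so downstream causal
#' log-odds ratios are reported per `factor` units of the exposure (e.g.
#' `factor = 0.1` reports the OR per 10% of one unit of an ln-transformed
#' trait). All estimators inherit the rescaling through the harmonized data.
#'
#' @param harmonized Harmonized-instruments data frame.
#' @param factor Positive unit multiplier.
#' @return The rescaled tibble.
#' @export
scale_exposure <- function(harmonized, factor = 1) {
  assert_positive(factor, "factor")
  harmonized <- as_tibble(harmonized)
  harmonized$beta_exp <- harmonized$beta_exp / factor
  harmonized$se_exp <- harmonized$se_exp / factor
  harmonized
}

#' Summarise an instrument set
#'
#' Convenience wrapper producing the per-exposure instrument summary used in
#' study tables: number of instruments, total explained variance (percent,
#' one decimal), and the minimum F-statistic.
#'
#' @param stats Selected instruments (summary-statistics layout with `eaf`
#'   and `n` present).
#' @param exposure_name Label for the exposure.
#' @return One-row tibble with `exposure`, `n_snps`, `r2_total_pct`, `min_f`.
#' @export
instrument_summary <- function(stats, exposure_name = "exposure") {
  stats <- as_tibble(stats)
  r2 <- compute_r2(stats$eaf, stats$beta, stats$se, stats$n)
  tibble(
    exposure = exposure_name,
    n_snps = nrow(stats),
    r2_total_pct = round(100 * sum(r2), 1),
    min_f = min(compute_f(stats$beta, stats$se))
  )
}
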