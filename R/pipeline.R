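#' Pipeline configuration
#'
#' Collects every tunable of [mr_pipeline()] in one list with the study
#' defaults: genome-wide significance 5e-8 (1e-5 for metabolite
#' concentrations), weak-instrument bound F > 10, palindromic EAF window
#' 0.08, pleiotropy and heterogeneity gates at 0.05, PRESSO with 1000
#' simulations, median/Egger bootstraps of 5000/1000 draws.
#'
#' @param phenotype_class `"absolute"` or `"metabolite"`; sets the default
#'   significance threshold.
#' @param p_threshold Override for the instrument significance threshold.
#' @param f_min Weak-instrument bound (instruments need F strictly above
#'   it).
#' @param palindromic_window EAF ambiguity half-width for palindromic
#'   variants.
#' @param scale_factor Exposure unit divisor (e.g. 0.1 reports ORs per 10%
#'   of one exposure unit); applied before estimation so every method
#'   inherits it.
#' @param pleiotropy_alpha Egger-intercept gate level: below it, Egger
#'   replaces IVW as the primary estimator.
#' @param heterogeneity_alpha Cochran's Q gate level for fixed vs random
#'   effects (within cohorts and across them).
#' @param bootstrap_median,bootstrap_egger Bootstrap draws for the median
#'   estimators' SEs and the Egger SEs.
#' @param presso_n_sim,presso_alpha MR-PRESSO simulation count and outlier
#'   level.
#' @param seed RNG seed used by every stochastic component.
#' @param proxies Optional proxy table passed to [harmonize()].
#' @return A list of class `"mr_pipeline_config"`.
#' @export
mr_config <- function(phenotype_class = "absolute", p_threshold = NULL,
                      f_min = 10, palindromic_window = 0.08,
                      scale_factor = 1, pleiotropy_alpha = 0.05,
                      heterogeneity_alpha = 0.05,
                      bootstrap_median = 5000, bootstrap_egger = 1000,
                      presso_n_sim = 1000, presso_alpha = 0.05, seed = 1,
                      proxies = NULL) {
  structure(as.list(environment()), class = "mr_pipeline_config")
}

read_if_path <- function(x) {
  if (is.character(x) && length(x) == 1L) read_summary_stats(x) else
    as_tibble(x)
}

#' Run the full per-cohort decision tree and cross-cohort meta-analysis
#'
#' For each outcome cohort: harmonize the selected instruments to the
#' outcome, rescale the exposure unit, and run every estimator the
#' instrument count allows (J = 1: Wald ratio; J = 2: IVW and maximum
#' likelihood; J >= 3: plus Egger and both median estimators; J >= 4: plus
#' MR-PRESSO). The primary estimate is MR-Egger when the intercept test
#' signals directional pleiotropy (p below `pleiotropy_alpha`), otherwise
#' IVW; IVW itself uses random effects when Cochran's Q signals
#' heterogeneity. Per-cohort primary estimates are then combined by
#' inverse-variance meta-analysis (fixed, or DerSimonian-Laird random
#' effects under cross-cohort heterogeneity) and assigned a Bonferroni tier.
#' Every gate outcome is recorded in a decision trace.
#'
#' @param exposure Exposure summary statistics (data frame or file path).
#' @param outcomes Named list of outcome summary statistics (data frames or
#'   file paths), one per cohort.
#' @param config A [mr_config()] list.
#' @param exposure_name,outcome_name Labels carried into the report.
#' @param select Whether to apply significance/strength instrument selection
#'   to the exposure statistics first (`TRUE` by default; set `FALSE` when
#'   the input is already a final instrument list without p-values).
#' @return An object of class `"mr_pipeline"`: list with `estimates` (all
#'   methods, all cohorts), `primary` (one row per cohort), `meta` (one-row
#'   [meta_combine()] result), `presso` (per-cohort [mr_presso()] objects or
#'   `NULL`), `trace` (decision log tibble), `harmonized` (per-cohort
#'   instrument tables), and `config`.
#' @export
mr_pipeline <- function(exposure, outcomes, config = mr_config(),
                        exposure_name = "exposure",
                        outcome_name = "outcome", select = TRUE) {
  stopifnot(length(outcomes) >= 1)
  if (is.null(names(outcomes)) || any(!nzchar(names(outcomes)))) {
    abort("`outcomes` must be a named list (one name per cohort).")
  }
  exposure <- read_if_path(exposure)

  trace <- list()
  note <- function(cohort, gate, value, decision) {
    trace[[length(trace) + 1]] <<- tibble(
      cohort = cohort, gate = gate, value = value, decision = decision
    )
  }

  if (select) {
    exposure <- select_instruments(
      exposure,
      p_threshold = config$p_threshold, f_min = config$f_min,
      phenotype_class = config$phenotype_class
    )
    note("(exposure)", "instrument_selection",
         sprintf("%d retained", nrow(exposure)),
         sprintf("p<%s and F>%g", format(
           config$p_threshold %||%
             (if (config$phenotype_class == "absolute") 5e-8 else 1e-5)
         ), config$f_min))
  }

  estimates <- list()
  primary <- list()
  presso_res <- list()
  harmonized_all <- list()

  for (cohort in names(outcomes)) {
    out_stats <- read_if_path(outcomes[[cohort]])
    h <- harmonize(exposure, out_stats,
                   palindromic_window = config$palindromic_window,
                   proxies = config$proxies)
    kept <- kept_instruments(h)
    note(cohort, "harmonization",
         sprintf("%d/%d usable", nrow(kept), nrow(h)),
         paste(unique(h$status), collapse = ","))
    if (nrow(kept) == 0L) {
      note(cohort, "cohort_gate", "0 instruments", "cohort skipped")
      next
    }
    kept <- scale_exposure(kept, config$scale_factor)
    harmonized_all[[cohort]] <- kept
    J <- nrow(kept)

    if (J == 1) {
      est <- wald_ratio(kept)
      note(cohort, "method_gate", "J=1",
           "wald ratio only; IVW/ML/Egger/medians suppressed")
      prim <- est
      note(cohort, "pleiotropy_gate", "not testable (J<3)", "primary=wald")
    } else {
      est <- mr_all_methods(
        kept, model = "auto",
        bootstrap_reps = list(median = config$bootstrap_median,
                              egger = config$bootstrap_egger),
        seed = config$seed
      )
      if (J == 2) {
        note(cohort, "method_gate", "J=2",
             "IVW+max_likelihood; Egger/medians suppressed (need J>2)")
      } else {
        note(cohort, "method_gate", sprintf("J=%d", J), "all estimators")
      }
      ivw_row <- est[est$method == "ivw", ]
      note(cohort, "heterogeneity_gate",
           sprintf("Q p=%.3g", ivw_row$q_pvalue),
           sprintf("IVW %s-effect model", ivw_row$model))
      if (J >= 3 && "egger" %in% est$method) {
        ipt_p <- est$intercept_pvalue[est$method == "egger"]
        if (is.finite(ipt_p) && ipt_p < config$pleiotropy_alpha) {
          prim <- est[est$method == "egger", ]
          note(cohort, "pleiotropy_gate",
               sprintf("intercept p=%.3g", ipt_p),
               "directional pleiotropy: primary=egger")
        } else {
          prim <- ivw_row
          note(cohort, "pleiotropy_gate",
               sprintf("intercept p=%.3g", ipt_p),
               "no pleiotropy: primary=ivw")
        }
      } else {
        prim <- ivw_row
        note(cohort, "pleiotropy_gate", "not testable (J<3)", "primary=ivw")
      }
      if (J >= 4) {
        pr <- mr_presso(kept, n_sim = config$presso_n_sim,
                        outlier_alpha = config$presso_alpha,
                        seed = config$seed)
        presso_res[[cohort]] <- pr
        note(cohort, "presso_gate",
             sprintf("global p=%.3g", pr$global_pvalue),
             if (length(pr$outlier_indices) > 0) {
               sprintf("outliers removed: %s",
                       paste(pr$outlier_snps, collapse = ","))
             } else "no outliers")
      } else {
        note(cohort, "presso_gate", sprintf("J=%d", J),
             "PRESSO suppressed (need J>3)")
      }
    }
    est$cohort <- cohort
    estimates[[cohort]] <- est
    prim$cohort <- cohort
    primary[[cohort]] <- prim
  }

  if (length(primary) == 0L) {
    abort("Every cohort was skipped; nothing to estimate.",
          class = "mrpipe_no_instruments")
  }
  primary_tbl <- bind_rows(primary) %>%
    mutate(exposure = exposure_name, outcome = outcome_name,
           source = "computed")
  meta <- suppressWarnings(meta_combine(primary_tbl, model = "auto"))
  note("(meta)", "meta_heterogeneity_gate",
       sprintf("Q p=%s", format(meta$q_pvalue, digits = 3)),
       sprintf("%s-effect meta-analysis", meta$model))
  note("(meta)", "tier", sprintf("p=%.3g", meta$pvalue), meta$tier)

  structure(
    list(
      estimates = bind_rows(estimates),
      primary = primary_tbl,
      meta = meta,
      presso = presso_res,
      trace = bind_rows(trace),
      harmonized = harmonized_all,
      exposure_name = exposure_name,
      outcome_name = outcome_name,
      config = config
    ),
    class = "mr_pipeline"
  )
}

#' @export
print.mr_pipeline <- function(x, ...) {
  cat(sprintf("Two-sample MR pipeline: %s -> %s\n", x$exposure_name,
              x$outcome_name))
  cat(sprintf("Cohorts analysed: %s\n",
              paste(unique(x$primary$cohort), collapse = ", ")))
  for (i in seq_len(nrow(x$primary))) {
    p <- x$primary[i, ]
    cat(sprintf("  %s [%s]: OR %.3f (%.3f-%.3f), p = %.3f\n",
                p$cohort, p$method, p$or, p$ci_low, p$ci_high, p$pvalue))
  }
  m <- x$meta
  cat(sprintf("Combined (%s effects): OR %.3f (%.3f-%.3f), p = %.3f [%s]\n",
              m$model, m$or, m$ci_low, m$ci_high, m$pvalue, m$tier))
  invisible(x)
}
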