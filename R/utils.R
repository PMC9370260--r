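# 95% normal quantile used throughout for CI construction and reconstruction.
# Kept at 6 decimals (not 1.96): the difference moves reconstructed SEs in the
# third decimal, which matters when reproducing printed OR/CI tables.
Z95 <- 1.959964

DNA_BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

complement_allele <- function(x) unname(COMPLEMENT[x])

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so seeded bootstraps never perturb the surrounding stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
assert_positive <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) {
    abort(sprintf("`%s` must be finite and positive.", what))
  }
  invisible(x)
}

# One-row estimate tibble shared by every estimator; OR-scale CI uses Z95.
new_mr_estimate <- function(method, beta, se, pvalue, n_snps, model, ...) {
  out <- tibble(
    method = method,
    n_snps = as.integer(n_snps),
    model = model,
    beta = beta,
    se = se,
    or = exp(beta),
    ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se),
    pvalue = pvalue,
    ...
  )
  class(out) <- c("mr_estimate", class(out))
  out
}

# Two-sided normal p-value from an estimate and its SE.
p_normal <- function(beta, se) 2 * pnorm(-abs(beta / se))

# Filter a harmonized table down to usable instruments.
kept_instruments <- function(harmonized) {
  harmonized <- as_tibble(harmonized)
  req <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(req, names(harmonized))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "harmonized data lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if ("status" %in% names(harmonized)) {
    harmonized <- dplyr::filter(harmonized, !startsWith(.data$status, "dropped"))
  }
  harmonized
}

check_n_instruments <- function(h, min, method) {
  if (nrow(h) < min) {
    abort(
      sprintf(
        "%s requires at least %d instruments (%d supplied).",
        method, min, nrow(h)
      ),
      class = "mrpipe_insufficient_instruments"
    )
  }
  invisible(h)
}
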