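# Shared fixture builders. Everything is generated in code at test time.

# Hand-built harmonized instrument table (already allele-aligned).
h_table <- function(beta_exp, se_exp, beta_out, se_out,
                    snp = sprintf("rs%03d", seq_along(beta_exp))) {
  tibble::tibble(
    snp = snp, beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out, status = "kept"
  )
}

# Harmonized table straight from a simulation with aligned alleles
# (bypasses harmonize() where allele logic is not what is under test).
sim_h <- function(sim) {
  tibble::tibble(
    snp = sim$exposure$snp,
    beta_exp = sim$exposure$beta, se_exp = sim$exposure$se,
    beta_out = sim$outcome$beta, se_out = sim$outcome$se,
    status = "kept"
  )
}

# Small summary-stats tibble for IO/harmonization tests.
stats_table <- function(snp, ea, oa, eaf, beta, se,
                        pvalue = 2 * pnorm(-abs(beta / se)), n = 50000) {
  tibble::tibble(
    snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = n
  )
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
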