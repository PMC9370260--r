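#' Read GWAS summary statistics
#'
#' Reads a delimited text file of per-variant association records (one
#' exposure or one outcome GWAS) into the tidy summary-statistics layout used
#' throughout the package: columns `snp`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pvalue`, `n`.
#'
#' Rows that cannot be used are cleaned up on the way in: alleles are
#' uppercased; rows with unparseable or non-positive `se`, unparseable `beta`,
#' or alleles outside A/C/G/T are dropped with a warning; duplicated variant
#' ids keep the record with the smallest p-value. A p-value that disagrees
#' with the two-sided normal approximation `2*pnorm(-|beta/se|)` by more than
#' a factor of 10 triggers a warning (the stated value is kept).
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping roles to column names in
#'   the file, e.g. `c(snp = "rsid", beta = "b", se = "se", ...)`. Roles
#'   `snp`, `effect_allele`, `other_allele`, `beta`, `se` are mandatory;
#'   `eaf`, `pvalue`, `n` are optional. When `NULL`, common header names
#'   (SNP/EA/OA/EAF/BETA/SE/P/N and a few synonyms) are matched
#'   case-insensitively.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects tab vs
#'   comma from the header line.
#' @return A tibble with one row per retained variant.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
#'   "rs1\tA\tG\t0.3\t0.11\t0.01\t1e-30\t50000"
#' ), tf)
#' read_summary_stats(tf)
read_summary_stats <- function(path, column_map = NULL, delimiter = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    abort(sprintf("Empty summary-statistics file: %s", path))
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(
    path,
    delim = delimiter, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  if (nrow(raw) == 0L) abort(sprintf("No data rows in %s", path))
  column_map <- resolve_column_map(names(raw), column_map)

  out <- tibble(
    snp = as.character(raw[[column_map[["snp"]]]]),
    effect_allele = toupper(as.character(raw[[column_map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[column_map[["other_allele"]]]])),
    eaf = pick_num(raw, column_map, "eaf"),
    beta = pick_num(raw, column_map, "beta"),
    se = pick_num(raw, column_map, "se"),
    pvalue = pick_num(raw, column_map, "pvalue"),
    n = pick_num(raw, column_map, "n")
  )
  validate_summary_stats(out)
}

resolve_column_map <- function(cols, column_map) {
  roles <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
             "pvalue", "n")
  mandatory <- c("snp", "effect_allele", "other_allele", "beta", "se")
  if (is.null(column_map)) {
    synonyms <- list(
      snp = c("snp", "rsid", "variant", "variant_id", "snp_id", "markername"),
      effect_allele = c("ea", "effect_allele", "a1", "allele1"),
      other_allele = c("oa", "other_allele", "a2", "allele2", "ref_allele"),
      eaf = c("eaf", "af", "effect_allele_frequency", "freq", "maf"),
      beta = c("beta", "b", "effect", "log_or", "logor"),
      se = c("se", "stderr", "standard_error"),
      pvalue = c("p", "pval", "pvalue", "p_value"),
      n = c("n", "samplesize", "sample_size", "n_total")
    )
    lower <- tolower(cols)
    column_map <- purrr::map_chr(synonyms, function(syn) {
      hit <- which(lower %in% syn)
      if (length(hit) > 0) cols[hit[1]] else NA_character_
    })
    column_map <- column_map[!is.na(column_map)]
  }
  miss <- setdiff(mandatory, names(column_map))
  if (length(miss) > 0) {
    abort(sprintf(
      "column_map does not cover mandatory role(s): %s",
      paste(miss, collapse = ", ")
    ))
  }
  bad <- setdiff(unname(column_map), cols)
  if (length(bad) > 0) {
    abort(sprintf("Mapped column(s) absent from file: %s",
                  paste(bad, collapse = ", ")))
  }
  column_map[intersect(roles, names(column_map))]
}

pick_num <- function(raw, column_map, role) {
  if (!role %in% names(column_map)) return(rep(NA_real_, nrow(raw)))
  suppressWarnings(as.numeric(raw[[column_map[[role]]]]))
}

#' Validate and clean a summary-statistics table
#'
#' Enforces the per-record invariants (valid distinct alleles, `se > 0`,
#' `eaf` in \[0, 1\] when present), drops offending rows with a warning,
#' deduplicates variant ids keeping the smallest p-value, and warns when a
#' stated p-value is inconsistent with `|beta/se|` under the two-sided normal
#' approximation by more than a factor of 10.
#'
#' @param stats A data frame in the summary-statistics layout.
#' @return A cleaned tibble.
#' @export
validate_summary_stats <- function(stats) {
  stats <- as_tibble(stats)
  ok_allele <- stats$effect_allele %in% DNA_BASES &
    stats$other_allele %in% DNA_BASES &
    stats$effect_allele != stats$other_allele
  ok_beta <- is.finite(stats$beta)
  ok_se <- is.finite(stats$se) & stats$se > 0
  ok_eaf <- is.na(stats$eaf) | (stats$eaf >= 0 & stats$eaf <= 1)
  keep <- ok_allele & ok_beta & ok_se & ok_eaf
  if (any(!keep)) {
    warn(sprintf(
      "Dropped %d row(s) failing summary-statistic invariants (%s).",
      sum(!keep),
      paste(stats$snp[!keep], collapse = ", ")
    ))
    stats <- stats[keep, ]
  }
  if (nrow(stats) == 0L) abort("No valid summary-statistic rows remain.")

  if (anyDuplicated(stats$snp)) {
    n_before <- nrow(stats)
    stats <- stats %>%
      group_by(.data$snp) %>%
      slice_min(
        order_by = dplyr::coalesce(.data$pvalue, Inf),
        n = 1, with_ties = FALSE
      ) %>%
      ungroup()
    warn(sprintf("Removed %d duplicated variant id(s), keeping smallest p.",
                 n_before - nrow(stats)))
  }

  has_p <- !is.na(stats$pvalue) & stats$pvalue > 0
  if (any(has_p)) {
    implied <- p_normal(stats$beta[has_p], stats$se[has_p])
    ratio <- pmax(implied, 1e-300) / pmax(stats$pvalue[has_p], 1e-300)
    off <- abs(log10(ratio)) > 1
    if (any(off)) {
      warn(sprintf(
        "%d p-value(s) differ from the normal approximation by >10x (e.g. %s).",
        sum(off), stats$snp[has_p][which(off)[1]]
      ))
    }
  }
  stats
}

#' Write summary statistics to delimited text
#'
#' Writes the canonical header order `SNP, EA, OA, EAF, BETA, SE, P, N` so a
#' file written here is read back unchanged by [read_summary_stats()].
#'
#' @param stats A summary-statistics data frame.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path, delimiter = "\t") {
  stats <- as_tibble(stats)
  if (nrow(stats) == 0L) warn("Writing a header-only summary-statistics file.")
  for (col in c("eaf", "pvalue", "n")) {
    if (!col %in% names(stats)) stats[[col]] <- NA_real_
  }
  out <- tibble(
    SNP = stats$snp, EA = stats$effect_allele, OA = stats$other_allele,
    EAF = stats$eaf, BETA = stats$beta, SE = stats$se,
    P = stats$pvalue, N = stats$n
  )
  readr::write_delim(out, path, delim = delimiter, na = "NA", progress = FALSE)
  invisible(path)
}
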