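# Cohort prevalence bounds. The clinically diagnosed count gives the
# upper prevalence bound (smaller 1-in-N denominator); the genetically
# confirmed count gives the lower bound.

#' Prevalence bounds from cohort counts
#'
#' The upper bound divides the population size by the clinically
#' diagnosed count, the lower bound by the genetically confirmed count.
#' 1-in-N denominators are rounded to the nearest `denom_rounding`
#' (default 1000); per-100,000 rates are truncated — not rounded — to
#' `per100k_decimals` decimals, the convention under which
#' 76 / 9,656,000 prints as 0.78 per 100,000. Raw unrounded values are
#' always carried alongside. Optional exact Poisson 95% intervals on the
#' case counts are attached with `poisson_ci = TRUE`.
#'
#' @param population Population size (positive integer).
#' @param n_clinical Clinically diagnosed cases.
#' @param n_genetic Genetically confirmed cases (`<= n_clinical`).
#' @param denom_rounding Granularity for the 1-in-N denominators; use 1
#'   for exact denominators.
#' @param per100k_decimals Decimals kept (by truncation) on per-100,000
#'   rates.
#' @param poisson_ci Attach exact Poisson 95% intervals per 100,000?
#' @return A `prevalence_bounds` list: `one_in_upper`, `one_in_lower`
#'   (rounded denominators), `one_in_upper_raw`, `one_in_lower_raw`,
#'   `per100k_upper`, `per100k_lower` (truncated), raw per-100k values,
#'   and the formatting metadata.
#' @examples
#' prevalence_bounds(9656000, 134, 76)
#' @export
prevalence_bounds <- function(population, n_clinical, n_genetic,
                              denom_rounding = 1000L, per100k_decimals = 2L,
                              poisson_ci = FALSE) {
  population <- as.numeric(population)
  if (is.na(population) || population < 1) stop("population must be positive")
  if (n_genetic > n_clinical || n_clinical > population)
    stop("counts must satisfy n_genetic <= n_clinical <= population")
  if (n_clinical == 0) stop("prevalence bounds undefined with n_clinical = 0")
  round_to <- function(x, g) if (g <= 1) x else round(x / g) * g
  trunc_to <- function(x, d) floor(x * 10^d) / 10^d
  lower_defined <- n_genetic >= 1
  upper_raw <- population / n_clinical
  lower_raw <- if (lower_defined) population / n_genetic else NA_real_
  out <- list(
    population = population, n_clinical = n_clinical, n_genetic = n_genetic,
    one_in_upper = round_to(upper_raw, denom_rounding),
    one_in_lower = if (lower_defined) round_to(lower_raw, denom_rounding)
                   else NA_real_,
    one_in_upper_raw = upper_raw, one_in_lower_raw = lower_raw,
    per100k_upper = trunc_to(1e5 * n_clinical / population, per100k_decimals),
    per100k_lower = if (lower_defined)
      trunc_to(1e5 * n_genetic / population, per100k_decimals) else NA_real_,
    per100k_upper_raw = 1e5 * n_clinical / population,
    per100k_lower_raw = if (lower_defined) 1e5 * n_genetic / population
                        else NA_real_,
    lower_defined = lower_defined,
    formatting = list(denom_rounding = denom_rounding,
                      per100k_decimals = per100k_decimals,
                      per100k_convention = "truncated"))
  if (poisson_ci) {
    ci <- function(k) if (k >= 1)
      1e5 * stats::poisson.test(k)$conf.int / population else c(NA_real_, NA_real_)
    out$per100k_ci_clinical <- ci(n_clinical)
    out$per100k_ci_genetic <- ci(n_genetic)
  }
  structure(out, class = "prevalence_bounds")
}

#' @export
print.prevalence_bounds <- function(x, ...) {
  cat("<prevalence_bounds> 1 in ", format(x$one_in_upper, big.mark = ","),
      " (clinical) to 1 in ",
      if (x$lower_defined) format(x$one_in_lower, big.mark = ",") else "undefined",
      " (genetic); ", x$per100k_lower, "-", x$per100k_upper,
      " per 100,000\n", sep = "")
  invisible(x)
}

#' Read a cohort count table
#'
#' TSV with columns `stratum`, `population`, `n_clinical`, `n_genetic`.
#'
#' @param path TSV path.
#' @return Data frame of cohort counts.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("stratum", "population", "n_clinical", "n_genetic")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  df$population <- as.numeric(df$population)
  df$n_clinical <- as.integer(df$n_clinical)
  df$n_genetic <- as.integer(df$n_genetic)
  df
}

#' Stratified prevalence bounds
#'
#' Per-stratum bounds plus a pooled row. When a stratum named `all` (or
#' `pooled`) is present it is used as the pooled row; otherwise the pooled
#' row sums the strata.
#'
#' @param counts Data frame with columns `stratum`, `population`,
#'   `n_clinical`, `n_genetic` (strata must be disjoint and uniquely
#'   named).
#' @param ... Passed on to [prevalence_bounds()] (rounding conventions).
#' @return Data frame with one row per stratum plus `pooled`, carrying the
#'   rounded and raw bounds.
#' @export
stratified_prevalence <- function(counts, ...) {
  stopifnot(is.data.frame(counts))
  if (nrow(counts) == 0)
    return(data.frame(stratum = character(0), population = numeric(0),
                      n_clinical = integer(0), n_genetic = integer(0),
                      one_in_upper = numeric(0), one_in_lower = numeric(0),
                      per100k_upper = numeric(0), per100k_lower = numeric(0)))
  if (anyDuplicated(counts$stratum))
    stop("duplicate stratum names: ",
         paste(unique(counts$stratum[duplicated(counts$stratum)]),
               collapse = ", "))
  pooled_idx <- which(tolower(counts$stratum) %in% c("all", "pooled"))
  strata <- if (length(pooled_idx)) counts[-pooled_idx, , drop = FALSE]
            else counts
  pooled <- if (length(pooled_idx)) counts[pooled_idx, , drop = FALSE]
  else data.frame(stratum = "pooled",
                  population = sum(counts$population),
                  n_clinical = sum(counts$n_clinical),
                  n_genetic = sum(counts$n_genetic))
  rows <- rbind(strata, pooled)
  bounds <- lapply(seq_len(nrow(rows)), function(i)
    prevalence_bounds(rows$population[i], rows$n_clinical[i],
                      rows$n_genetic[i], ...))
  cbind(rows[c("stratum", "population", "n_clinical", "n_genetic")],
        data.frame(
          one_in_upper = vapply(bounds, `[[`, numeric(1), "one_in_upper"),
          one_in_lower = vapply(bounds, `[[`, numeric(1), "one_in_lower"),
          one_in_upper_raw = vapply(bounds, `[[`, numeric(1), "one_in_upper_raw"),
          one_in_lower_raw = vapply(bounds, `[[`, numeric(1), "one_in_lower_raw"),
          per100k_upper = vapply(bounds, `[[`, numeric(1), "per100k_upper"),
          per100k_lower = vapply(bounds, `[[`, numeric(1), "per100k_lower")),
        row.names = NULL)
}

#' Cohort yield and allele-composition fractions
#'
#' Summary fractions of a clinical/genetic screening cohort, in percent
#' and at full precision. Allele accounting follows inheritance: a
#' dominant (heterozygous) patient contributes one pathogenic allele, a
#' recessive (biallelic) patient two. The printed-value helpers
#' [pct_round()] and [pct_trunc()] apply the two formatting conventions in
#' circulation (reports mix them).
#'
#' @param n_clinical Clinically diagnosed patients.
#' @param n_genetic Patients with a confirmed genetic diagnosis in the
#'   gene.
#' @param n_families_screened Index families screened.
#' @param n_families_solved Families in which a likely pathogenic mutation
#'   was found.
#' @param n_dominant_patients,n_recessive_patients Genetically confirmed
#'   patients by inheritance pattern.
#' @param n_missense_alleles Pathogenic alleles that are missense.
#' @return A list of counts and full-precision percentages:
#'   `solve_rate_pct`, `family_yield_pct`, `alleles_dominant`,
#'   `alleles_recessive`, `alleles_total`, `frac_recessive_alleles_pct`,
#'   `frac_missense_alleles_pct`.
#' @examples
#' cohort_fractions(134, 76, 56, 43, 58, 18, 84)
#' @export
cohort_fractions <- function(n_clinical, n_genetic, n_families_screened,
                             n_families_solved, n_dominant_patients,
                             n_recessive_patients, n_missense_alleles) {
  if (n_genetic > n_clinical)
    stop("n_genetic must not exceed n_clinical")
  if (n_families_solved > n_families_screened)
    stop("solved families must not exceed screened families")
  alleles_dominant <- n_dominant_patients          # one mutant allele each
  alleles_recessive <- 2L * n_recessive_patients   # biallelic
  alleles_total <- alleles_dominant + alleles_recessive
  if (n_missense_alleles > alleles_total)
    stop("missense alleles exceed the allele total implied by patient counts")
  list(n_clinical = n_clinical, n_genetic = n_genetic,
       solve_rate_pct = 100 * n_genetic / n_clinical,
       family_yield_pct = 100 * n_families_solved / n_families_screened,
       alleles_dominant = alleles_dominant,
       alleles_recessive = alleles_recessive,
       alleles_total = alleles_total,
       frac_recessive_alleles_pct = 100 * alleles_recessive / alleles_total,
       frac_missense_alleles_pct = 100 * n_missense_alleles / alleles_total)
}

#' Printed-percentage conventions
#'
#' `pct_round()` rounds to `digits` decimals; `pct_trunc()` truncates
#' (floors) instead. Published tables mix both conventions, so both are
#' provided and every report carries the full-precision value too.
#'
#' @param x Percentage value(s).
#' @param digits Decimals to keep.
#' @return Numeric vector.
#' @export
pct_round <- function(x, digits = 1L) round(x, digits)

#' @rdname pct_round
#' @export
pct_trunc <- function(x, digits = 1L) floor(x * 10^digits) / 10^digits
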