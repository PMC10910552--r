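# Catalogue curation: the inclusion/exclusion rules applied before any
# region or conservation statistic, and the per-category tallies.

#' Curation configuration
#'
#' Thresholds and switches for catalogue curation. Defaults follow the
#' standard bestrophinopathy curation practice: records whose frequency in
#' any population database exceeds 0.005 are excluded (strict `>`), as are
#' records seen in a single patient with neither segregation support nor
#' an established clinical characterisation, and silent variants. The
#' novelty gate for newly observed variants requires a frequency strictly
#' below 0.5% for recessive and 0.05% for dominant variants.
#'
#' @param max_af_any_db Exclusion threshold applied to every per-database
#'   frequency column; a record is excluded if any frequency exceeds it.
#' @param max_af_novel_recessive,max_af_novel_dominant Novelty-gate
#'   thresholds (strictly below passes). The dominant threshold must not
#'   exceed the recessive one.
#' @param drop_silent Exclude silent variants?
#' @param drop_single_patient_unsupported Exclude single-patient records
#'   without supporting evidence?
#' @param single_patient_rule `"conjunction"` (default) excludes a
#'   single-patient record only when segregation AND clinical
#'   characterisation are both missing; `"disjunction"` when either is.
#' @return A `curation_config` list.
#' @export
curation_config <- function(max_af_any_db = 0.005,
                            max_af_novel_recessive = 0.005,
                            max_af_novel_dominant = 0.0005,
                            drop_silent = TRUE,
                            drop_single_patient_unsupported = TRUE,
                            single_patient_rule = c("conjunction", "disjunction")) {
  single_patient_rule <- match.arg(single_patient_rule)
  thr <- c(max_af_any_db, max_af_novel_recessive, max_af_novel_dominant)
  if (any(thr < 0 | thr > 1)) stop("curation thresholds must lie in [0, 1]")
  if (max_af_novel_dominant > max_af_novel_recessive)
    stop("dominant novelty threshold must not exceed the recessive one")
  structure(list(max_af_any_db = max_af_any_db,
                 max_af_novel_recessive = max_af_novel_recessive,
                 max_af_novel_dominant = max_af_novel_dominant,
                 drop_silent = isTRUE(drop_silent),
                 drop_single_patient_unsupported =
                   isTRUE(drop_single_patient_unsupported),
                 single_patient_rule = single_patient_rule),
            class = "curation_config")
}

.record_ids <- function(df) {
  if ("id" %in% names(df) && !anyNA(df$id)) as.character(df$id)
  else if ("cdna_norm" %in% names(df)) df$cdna_norm
  else df$cdna_hgvs
}

.max_af <- function(df) {
  af_cols <- grep("^af_", names(df), value = TRUE)
  if (!length(af_cols)) return(rep(0, nrow(df)))
  m <- as.matrix(df[af_cols])
  mode(m) <- "numeric"
  m[is.na(m)] <- 0  # not observed in a database = frequency 0
  if (nrow(df) == 0) return(numeric(0))
  apply(m, 1L, max)
}

#' Apply curation filters to a catalogue
#'
#' Exclusion rules, tested in fixed order so that every excluded record is
#' attributed to exactly one (first-triggering) rule:
#' (a) `high_allele_frequency` — any per-database frequency strictly above
#' `max_af_any_db`; (b) `single_patient_unsupported` — one patient and no
#' supporting evidence (see [curation_config()] for the conjunction /
#' disjunction reading); (c) `silent`. Retained records keep their input
#' order.
#'
#' @param df Annotated variant data frame (see [read_variants()]).
#' @param cfg A [curation_config()].
#' @return A list with `retained` (the filtered data frame) and `report`
#'   (a `curation_report`: `n_input`, `n_retained`, `exclusions` as a rule
#'   -> record-id map, and `tallies` from [tally_variants()]).
#' @export
apply_filters <- function(df, cfg = curation_config()) {
  stopifnot(is.data.frame(df), inherits(cfg, "curation_config"))
  n <- nrow(df)
  ids <- .record_ids(df)
  rule <- rep(NA_character_, n)
  if (n) {
    af_hit <- .max_af(df) > cfg$max_af_any_db
    rule[af_hit] <- "high_allele_frequency"
    if (cfg$drop_single_patient_unsupported) {
      no_seg <- !df$has_segregation %in% TRUE
      no_clin <- !df$has_clinical_characterization %in% TRUE
      missing_support <- if (cfg$single_patient_rule == "conjunction")
        no_seg & no_clin else no_seg | no_clin
      sp_hit <- df$n_patients %in% 1L & missing_support
      rule[is.na(rule) & sp_hit] <- "single_patient_unsupported"
    }
    if (cfg$drop_silent)
      rule[is.na(rule) & df$mutation_type == "silent"] <- "silent"
  }
  retained <- df[is.na(rule), , drop = FALSE]
  exclusions <- list(
    high_allele_frequency = ids[rule %in% "high_allele_frequency"],
    single_patient_unsupported = ids[rule %in% "single_patient_unsupported"],
    silent = ids[rule %in% "silent"])
  report <- structure(
    list(n_input = n, n_retained = nrow(retained), exclusions = exclusions,
         tallies = tally_variants(retained), config = unclass(cfg)),
    class = "curation_report")
  list(retained = retained, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("<curation_report> ", x$n_retained, "/", x$n_input, " records retained\n",
      sep = "")
  for (r in names(x$exclusions))
    if (length(x$exclusions[[r]]))
      cat("  excluded by ", r, ": ", length(x$exclusions[[r]]), "\n", sep = "")
  cat("  distinct mutations: ", x$tallies$n_mutations_total,
      "; alleles: ", x$tallies$n_alleles_total, "\n", sep = "")
  invisible(x)
}

#' Novelty gate for newly observed variants
#'
#' A variant passes the gate when its maximum per-database frequency is
#' strictly below the inheritance-specific threshold: the recessive
#' threshold for recessive (and dual-inheritance) variants, the stricter
#' dominant threshold for dominant ones. Boundary values fail (the
#' criterion is "less than"). An unobserved variant (all frequencies
#' missing) has frequency 0 and always passes.
#'
#' @param df Variant data frame with `inheritance` and `af_*` columns.
#' @param cfg A [curation_config()].
#' @return Logical vector, one element per record.
#' @export
novelty_gate <- function(df, cfg = curation_config()) {
  stopifnot(is.data.frame(df), inherits(cfg, "curation_config"))
  if (any(df$inheritance == "unknown"))
    stop("novelty gate requires an explicit inheritance label; ",
         sum(df$inheritance == "unknown"), " record(s) are 'unknown'")
  thr <- ifelse(df$inheritance == "dominant", cfg$max_af_novel_dominant,
                cfg$max_af_novel_recessive)
  .max_af(df) < thr
}

#' Tally distinct mutations and alleles per category
#'
#' Distinct mutations key on the normalised cDNA HGVS string; allele
#' counts sum the records' `allele_count`. Records sharing a normalised
#' cDNA are merged, but only when their annotations (mutation type,
#' inheritance, disease) agree — a conflict is an error naming the
#' offending variant, never a silent pick. Inheritance tallies use the
#' three-way split dominant / recessive / both.
#'
#' @param df Variant data frame (typically the retained set).
#' @return A list with `by_type` and `by_inheritance` data frames
#'   (`n_mutations`, `n_alleles` per level) and scalar totals.
#' @export
tally_variants <- function(df) {
  stopifnot(is.data.frame(df))
  key <- if ("cdna_norm" %in% names(df)) df$cdna_norm else df$cdna_hgvs
  if (nrow(df)) {
    ann <- paste(df$mutation_type, df$inheritance, df$disease, sep = "|")
    conflict <- tapply(ann, key, function(a) length(unique(a)) > 1L)
    if (any(conflict))
      stop("conflicting annotations for the same normalised cDNA HGVS: ",
           paste(names(conflict)[conflict], collapse = ", "))
  }
  first <- !duplicated(key)
  alleles_by_key <- if (nrow(df))
    tapply(df$allele_count, key, sum) else integer(0)
  dedup <- df[first, , drop = FALSE]
  dedup_alleles <- as.integer(alleles_by_key[if (nrow(dedup))
    (if ("cdna_norm" %in% names(dedup)) dedup$cdna_norm else dedup$cdna_hgvs)
    else character(0)])
  level_tally <- function(values, levels) {
    data.frame(level = levels,
               n_mutations = vapply(levels, function(l)
                 sum(values == l), integer(1)),
               n_alleles = vapply(levels, function(l)
                 sum(dedup_alleles[values == l]), integer(1)),
               row.names = NULL)
  }
  by_type <- level_tally(dedup$mutation_type, MUTATION_TYPES)
  names(by_type)[1] <- "mutation_type"
  by_inh <- level_tally(dedup$inheritance, c("dominant", "recessive", "both"))
  names(by_inh)[1] <- "inheritance"
  list(by_type = by_type, by_inheritance = by_inh,
       n_mutations_total = nrow(dedup),
       n_alleles_total = sum(dedup_alleles))
}

#' Serialise a curation report
#'
#' Writes the report as JSON and, optionally, the exclusion list as a TSV
#' of (record id, rule).
#'
#' @param report A `curation_report`.
#' @param json_path Output JSON path.
#' @param exclusions_tsv Optional TSV path for the exclusion list.
#' @return `json_path`, invisibly.
#' @export
write_curation_report <- function(report, json_path, exclusions_tsv = NULL) {
  stopifnot(inherits(report, "curation_report"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(exclusions_tsv)) {
    rows <- do.call(rbind, lapply(names(report$exclusions), function(r) {
      ids <- report$exclusions[[r]]
      if (!length(ids)) return(NULL)
      data.frame(record_id = ids, rule = r)
    }))
    if (is.null(rows)) rows <- data.frame(record_id = character(0),
                                          rule = character(0))
    utils::write.table(rows, exclusions_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
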