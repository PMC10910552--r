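# Variant-catalogue table I/O. One row per catalogue record; the analysis
# key is the normalised cDNA HGVS string.

VARIANT_REQUIRED_COLS <- c("cdna_hgvs", "inheritance", "disease",
                           "allele_count", "n_patients", "has_segregation",
                           "has_clinical_characterization")
VARIANT_AF_COLS <- c("af_gnomad", "af_jpn", "af_genomeasia", "af_gme")

.as_bool <- function(x) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read a variant catalogue TSV
#'
#' Reads the tab-separated catalogue dialect: columns `cdna_hgvs`,
#' `protein_hgvs` (optional), `mutation_type` (optional override),
#' `inheritance`, `disease`, `allele_count`, `n_patients`,
#' `has_segregation`, `has_clinical_characterization`, and per-database
#' allele-frequency columns `af_gnomad`, `af_jpn`, `af_genomeasia`,
#' `af_gme`. `.` or blank marks a missing value; a blank frequency means
#' "not observed in that database". Each cDNA string is parsed, the residue
#' position derived by codon arithmetic, and the mutation type taken from
#' the override column when present or classified from the HGVS otherwise.
#' A catalogue `mutation_type` label of missense is kept even when the
#' change sits in a splice region; such rows gain `splice_predicted = TRUE`
#' instead of being reclassified, so catalogue counting is preserved.
#'
#' @param path Path to the TSV file.
#' @param exon_boundaries Optional coding positions of exon edges, used by
#'   the classifier for splice-proximal calls.
#' @return A `data.frame` of validated variant records with derived columns
#'   `cdna_norm` (normalised HGVS, the distinctness key), `aa_position`
#'   (NA for intronic/splicing changes), `mutation_type`, and
#'   `splice_predicted`.
#' @export
read_variants <- function(path, exon_boundaries = NULL) {
  raw <- utils::read.delim(path, na.strings = c(".", "", "NA"),
                           colClasses = "character", check.names = TRUE)
  missing_cols <- setdiff(VARIANT_REQUIRED_COLS, names(raw))
  if (length(missing_cols))
    stop("variant table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- raw
  df$allele_count <- as.integer(raw$allele_count)
  df$n_patients <- as.integer(raw$n_patients)
  df$has_segregation <- .as_bool(raw$has_segregation)
  df$has_clinical_characterization <- .as_bool(raw$has_clinical_characterization)
  for (col in intersect(VARIANT_AF_COLS, names(raw)))
    df[[col]] <- as.numeric(raw[[col]])
  if (!"protein_hgvs" %in% names(df)) df$protein_hgvs <- NA_character_
  if (!"mutation_type" %in% names(df)) df$mutation_type <- NA_character_
  if (!"id" %in% names(df)) df$id <- NA_character_
  validate_variants(annotate_variants(df, exon_boundaries = exon_boundaries))
}

#' Derive normalised HGVS, residue positions and mutation types
#'
#' @param df A variant data frame with at least `cdna_hgvs`; `protein_hgvs`
#'   and `mutation_type` are used when present.
#' @param exon_boundaries Optional coding positions of exon edges.
#' @return The data frame with `cdna_norm`, `aa_position`, `mutation_type`
#'   and `splice_predicted` filled in.
#' @export
annotate_variants <- function(df, exon_boundaries = NULL) {
  stopifnot(is.data.frame(df), "cdna_hgvs" %in% names(df))
  n <- nrow(df)
  if (!"protein_hgvs" %in% names(df)) df$protein_hgvs <- NA_character_
  if (!"mutation_type" %in% names(df)) df$mutation_type <- NA_character_
  cdna_norm <- character(n)
  aa_position <- integer(n)
  classified <- character(n)
  for (i in seq_len(n)) {
    cd <- tryCatch(parse_cdna(df$cdna_hgvs[i]), error = function(e)
      stop("record ", i, " (", df$cdna_hgvs[i], "): ", conditionMessage(e),
           call. = FALSE))
    pr <- if (!is.na(df$protein_hgvs[i])) parse_protein(df$protein_hgvs[i]) else NULL
    cdna_norm[i] <- format(cd)
    aa_position[i] <- map_to_protein_position(cd)
    classified[i] <- suppressWarnings(
      classify_mutation_type(cd, pr, exon_boundaries = exon_boundaries))
  }
  override <- df$mutation_type
  bad_type <- !is.na(override) & !override %in% MUTATION_TYPES
  if (any(bad_type))
    stop("unknown mutation_type label(s): ",
         paste(unique(override[bad_type]), collapse = ", "))
  df$cdna_norm <- cdna_norm
  df$mutation_type <- ifelse(is.na(override), classified, override)
  df$splice_predicted <- !is.na(override) & override == "missense" &
    classified == "splicing"
  # splicing has no residue; everything else keeps its codon-derived residue
  df$aa_position <- ifelse(df$mutation_type == "splicing", NA_integer_,
                           aa_position)
  df
}

#' Validate a variant data frame's invariants
#'
#' Checks value domains (inheritance, disease, mutation type), frequency
#' ranges, non-negative counts, and the splicing/residue correspondence
#' (a splicing record has no residue position and vice versa).
#'
#' @param df An annotated variant data frame.
#' @return `df`, invisibly validated (errors on violation).
#' @export
validate_variants <- function(df) {
  stopifnot(is.data.frame(df))
  bad <- !df$inheritance %in% INHERITANCE_LEVELS
  if (any(bad))
    stop("inheritance labels outside {",
         paste(INHERITANCE_LEVELS, collapse = ", "), "}: ",
         paste(unique(df$inheritance[bad]), collapse = ", "),
         " (unknown must be explicit, never defaulted)")
  bad <- !df$disease %in% DISEASE_LEVELS
  if (any(bad))
    stop("disease labels outside {", paste(DISEASE_LEVELS, collapse = ", "),
         "}: ", paste(unique(df$disease[bad]), collapse = ", "))
  for (col in intersect(VARIANT_AF_COLS, names(df))) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop("allele frequencies in ", col, " outside [0, 1]")
  }
  if (any(!is.na(df$allele_count) & df$allele_count < 0L))
    stop("negative allele_count")
  if (any(!is.na(df$n_patients) & df$n_patients < 0L))
    stop("negative n_patients")
  splice <- df$mutation_type == "splicing"
  if (any(splice & !is.na(df$aa_position)))
    stop("splicing records must not carry a residue position")
  df
}

#' Write a variant catalogue TSV
#'
#' Inverse of [read_variants()]: missing values become `.`, logicals
#' `true`/`false`. Byte-stable for identical inputs, so seeded synthetic
#' catalogues reproduce exactly.
#'
#' @param df Variant data frame.
#' @param path Output path.
#' @param derived Keep derived columns (`cdna_norm`, `aa_position`,
#'   `splice_predicted`)? Default drops them.
#' @return `path`, invisibly.
#' @export
write_variants <- function(df, path, derived = FALSE) {
  out <- df
  if (!derived)
    out <- out[setdiff(names(out), c("cdna_norm", "aa_position",
                                     "splice_predicted"))]
  for (col in names(out)) {
    v <- out[[col]]
    if (is.logical(v)) v <- ifelse(is.na(v), NA, ifelse(v, "true", "false"))
    if (is.numeric(v) && !is.integer(v)) v <- format(v, trim = TRUE, digits = 15)
    v <- as.character(v)
    v[is.na(v) | v == "NA"] <- "."
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
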