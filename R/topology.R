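# Protein topology model: ordered, non-overlapping named regions jointly
# covering the whole protein, plus per-region mutation statistics.

REGION_CLASSES <- c("TM", "EC", "IC")

#' Construct and validate a topology model
#'
#' @param regions A data frame with columns `name`, `class` (TM, EC or
#'   IC), `start`, `end` (1-based inclusive residue coordinates). Regions
#'   must be sorted, non-overlapping, and jointly cover
#'   `1..protein_length` without gaps.
#' @param protein_length Total protein length in residues.
#' @param subregions Optional named list of `c(start, end)` sub-intervals
#'   of interest (they may overlap regions and each other).
#' @return A `topology_model`.
#' @export
topology_model <- function(regions, protein_length, subregions = list()) {
  stopifnot(is.data.frame(regions),
            all(c("name", "class", "start", "end") %in% names(regions)))
  regions <- regions[c("name", "class", "start", "end")]
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  protein_length <- as.integer(protein_length)
  if (protein_length < 1L) stop("protein_length must be positive")
  if (any(!regions$class %in% REGION_CLASSES))
    stop("region class must be one of ", paste(REGION_CLASSES, collapse = ", "))
  if (any(regions$start > regions$end)) stop("region start after end")
  if (anyDuplicated(regions$name)) stop("duplicate region names")
  o <- order(regions$start)
  regions <- regions[o, , drop = FALSE]
  rownames(regions) <- NULL
  expected_start <- c(1L, regions$end[-nrow(regions)] + 1L)
  if (regions$start[1] != 1L || regions$end[nrow(regions)] != protein_length ||
      any(regions$start != expected_start))
    stop("regions must partition 1..", protein_length,
         " (sorted, no gaps, no overlaps)")
  for (s in subregions) {
    s <- as.integer(s)
    if (length(s) != 2L || s[1] < 1L || s[2] > protein_length || s[1] > s[2])
      stop("subregions must be c(start, end) within 1..", protein_length)
  }
  structure(list(protein_length = protein_length, regions = regions,
                 subregions = lapply(subregions, as.integer)),
            class = "topology_model")
}

#' Built-in bestrophin-1 topology
#'
#' The nine-region model of the 585-residue bestrophin-1 channel: four
#' transmembrane segments (TM1 31-50, TM2 71-94, TM3 235-257, TM4 269-287),
#' two short extracellular loops (EC1 51-70, EC2 258-268), and three
#' intracellular regions (IC1 1-30, IC2 95-234, IC3 288-585). Named
#' subregions of interest cover the C-terminal calcium machinery: the
#' acidic Ca-binding stretch (293-308), the EF-hand (312-323), and the
#' TM4-proximal part of IC3 (288-323).
#'
#' @return A `topology_model`.
#' @examples
#' best1_topology()
#' @export
best1_topology <- function() {
  regions <- data.frame(
    name  = c("IC1", "TM1", "EC1", "TM2", "IC2", "TM3", "EC2", "TM4", "IC3"),
    class = c("IC",  "TM",  "EC",  "TM",  "IC",  "TM",  "EC",  "TM",  "IC"),
    start = c(1L, 31L, 51L, 71L, 95L, 235L, 258L, 269L, 288L),
    end   = c(30L, 50L, 70L, 94L, 234L, 257L, 268L, 287L, 585L))
  topology_model(regions, protein_length = 585L,
                 subregions = list(ca_binding = c(293L, 308L),
                                   ef_hand = c(312L, 323L),
                                   ic3_proximal = c(288L, 323L)))
}

#' @export
print.topology_model <- function(x, ...) {
  cat("<topology_model> ", nrow(x$regions), " regions over 1..",
      x$protein_length, "\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' Read / write a topology model as JSON
#'
#' Schema: `{"protein_length": int, "regions": [{"name", "class",
#' "start", "end"}, ...], "subregions": {"name": [start, end], ...}}`.
#'
#' @param path JSON file path.
#' @return A `topology_model` (for the reader); `path` invisibly (writer).
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$protein_length) || is.null(obj$regions))
    stop("topology JSON must contain protein_length and regions: ", path)
  subs <- if (is.null(obj$subregions)) list() else obj$subregions
  topology_model(as.data.frame(obj$regions), obj$protein_length, subs)
}

#' @rdname read_topology_json
#' @param model A `topology_model` to serialise.
#' @export
write_topology_json <- function(model, path) {
  stopifnot(inherits(model, "topology_model"))
  jsonlite::write_json(list(protein_length = model$protein_length,
                            regions = model$regions,
                            subregions = model$subregions),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Region covering a residue
#'
#' @param model A `topology_model`.
#' @param aa_position Residue index (1-based); vectorised.
#' @return Character vector of region names.
#' @examples
#' assign_region(best1_topology(), 323)  # "IC3"
#' @export
assign_region <- function(model, aa_position) {
  stopifnot(inherits(model, "topology_model"))
  p <- as.integer(aa_position)
  if (any(is.na(p) | p < 1L | p > model$protein_length))
    stop("residue position outside 1..", model$protein_length)
  idx <- findInterval(p, model$regions$start)
  model$regions$name[idx]
}

.dedup_mutations <- function(df) {
  key <- if ("cdna_norm" %in% names(df)) df$cdna_norm else df$cdna_hgvs
  df[!duplicated(key), , drop = FALSE]
}

#' Per-region mutation statistics
#'
#' For each topology region (and a global `ALL` row spanning the whole
#' protein): distinct-mutation counts overall and for missense,
#' missense prevalence (missense mutations per residue of region length),
#' the two-way dominant/recessive split among missense mutations
#' (dual-inheritance "both" records are reported separately and excluded
#' from the two-way denominator), and the disease composition over all
#' placed mutations. Splicing records carry no residue: they are excluded
#' from per-region placement and reported in the `n_splice_unplaced`
#' attribute, but remain in the catalogue-level tallies.
#'
#' @param model A `topology_model`.
#' @param df Retained variant data frame with `aa_position`.
#' @param weight `"mutations"` counts distinct mutations (default);
#'   `"alleles"` weights each distinct mutation by its summed allele count.
#' @param conservation Optional `conservation_profile` (or bare per-site
#'   vector in `[0,1]`); adds `mean_conservation` (percent) per region.
#' @return A list of class `region_stats`: `regions` (one row per region
#'   plus `ALL`), `disease_composition` (region x disease fractions),
#'   `n_splice_unplaced`, and `weight`.
#' @export
region_statistics <- function(model, df, weight = c("mutations", "alleles"),
                              conservation = NULL) {
  stopifnot(inherits(model, "topology_model"), is.data.frame(df))
  weight <- match.arg(weight)
  placed_rows <- df[!is.na(df$aa_position), , drop = FALSE]
  if (any(placed_rows$aa_position > model$protein_length))
    stop("variant residue position beyond protein length ",
         model$protein_length)
  mu <- .dedup_mutations(placed_rows)
  if (nrow(mu) && weight == "alleles") {
    key_all <- if ("cdna_norm" %in% names(placed_rows)) placed_rows$cdna_norm
               else placed_rows$cdna_hgvs
    key_mu <- if ("cdna_norm" %in% names(mu)) mu$cdna_norm else mu$cdna_hgvs
    w <- as.numeric(tapply(placed_rows$allele_count, key_all, sum)[key_mu])
  } else {
    w <- rep(1, nrow(mu))
  }
  n_splice_unplaced <- sum(df$mutation_type == "splicing" &
                             is.na(df$aa_position))
  per_site <- if (inherits(conservation, "conservation_profile"))
    conservation$per_site else conservation

  reg <- model$regions
  bounds <- rbind(reg[c("name", "start", "end")],
                  data.frame(name = "ALL", start = 1L,
                             end = model$protein_length))
  stats <- lapply(seq_len(nrow(bounds)), function(i) {
    s <- bounds$start[i]; e <- bounds$end[i]
    inside <- mu$aa_position >= s & mu$aa_position <= e
    sub <- mu[inside, , drop = FALSE]
    wi <- w[inside]
    len <- e - s + 1L
    mis <- sub$mutation_type == "missense"
    n_missense <- sum(wi[mis])
    nd <- sum(wi[mis & sub$inheritance == "dominant"])
    nr <- sum(wi[mis & sub$inheritance == "recessive"])
    nb <- sum(wi[mis & sub$inheritance == "both"])
    data.frame(
      region = bounds$name[i], class = if (i <= nrow(reg)) reg$class[i] else NA,
      start = s, end = e, length = len,
      n_total = sum(wi), n_missense = n_missense,
      missense_prevalence = n_missense / len,
      frac_dominant = if (nd + nr > 0) nd / (nd + nr) else NA_real_,
      frac_recessive = if (nd + nr > 0) nr / (nd + nr) else NA_real_,
      frac_both = if (n_missense > 0) nb / n_missense else NA_real_,
      mean_conservation = if (!is.null(per_site))
        100 * mean(per_site[s:min(e, length(per_site))]) else NA_real_)
  })
  regions_df <- do.call(rbind, stats)
  rownames(regions_df) <- NULL

  disease <- t(vapply(seq_len(nrow(bounds)), function(i) {
    inside <- mu$aa_position >= bounds$start[i] & mu$aa_position <= bounds$end[i]
    wi <- w[inside]
    d <- mu$disease[inside]
    tot <- sum(wi)
    vapply(DISEASE_LEVELS, function(lv)
      if (tot > 0) sum(wi[d == lv]) / tot else NA_real_, numeric(1))
  }, numeric(length(DISEASE_LEVELS))))
  disease_df <- data.frame(region = bounds$name, disease,
                           check.names = FALSE, row.names = NULL)

  structure(list(regions = regions_df, disease_composition = disease_df,
                 n_splice_unplaced = n_splice_unplaced, weight = weight),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  cat("<region_stats> weighted by ", x$weight, "; ",
      x$n_splice_unplaced, " splice record(s) unplaced\n", sep = "")
  print(x$regions, digits = 3)
  invisible(x)
}

#' Hotspot regions by density and inheritance skew
#'
#' Flags regions whose missense prevalence exceeds
#' `prevalence_threshold` (strictly) and whose two-way dominant or
#' recessive fraction exceeds `dominance_threshold` (strictly), reported
#' separately for the dominant-enriched and recessive-enriched direction.
#' The global `ALL` row is never flagged.
#'
#' @param stats A `region_stats`.
#' @param prevalence_threshold Missense mutations per residue; may exceed
#'   1 (dense regions can carry several mutations per residue).
#' @param dominance_threshold Fraction in `[0, 1]` applied to the
#'   two-way inheritance split.
#' @return A list with character vectors `dominant` and `recessive`.
#' @export
hotspot_report <- function(stats, prevalence_threshold = 0,
                           dominance_threshold = 0.75) {
  stopifnot(inherits(stats, "region_stats"))
  if (dominance_threshold < 0 || dominance_threshold > 1)
    stop("dominance_threshold is a fraction and must lie in [0, 1]")
  r <- stats$regions[stats$regions$region != "ALL", , drop = FALSE]
  dense <- r$n_missense > 0 & r$missense_prevalence > prevalence_threshold
  dom <- dense & !is.na(r$frac_dominant) & r$frac_dominant > dominance_threshold
  rec <- dense & !is.na(r$frac_recessive) & r$frac_recessive > dominance_threshold
  list(dominant = r$region[dom], recessive = r$region[rec])
}

#' Plot-ready per-variant table
#'
#' One row per placed distinct mutation: residue position, mutation type,
#' inheritance and disease — the columns a lollipop-style distribution
#' plot needs.
#'
#' @param df Retained variant data frame.
#' @return A data frame sorted by residue position.
#' @export
lollipop_table <- function(df) {
  mu <- .dedup_mutations(df[!is.na(df$aa_position), , drop = FALSE])
  out <- mu[order(mu$aa_position),
            c("aa_position", "mutation_type", "inheritance", "disease")]
  rownames(out) <- NULL
  out
}
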