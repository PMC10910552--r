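# Synthetic-data generators with recorded ground truth: variant
# catalogues with region-specific densities and dominant/recessive mixes
# plus decoy records for the curation filters, ortholog families with
# region-specific conservation, and stratified cohort counts. Seeded runs
# are bit-reproducible; every generated HGVS string parses.

AA_CODES_1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.BASES <- c("A", "C", "G", "T")

.default_missense_rate <- c(IC1 = 1.2, TM1 = 0.8, EC1 = 0.25, TM2 = 1.2,
                            IC2 = 0.7, TM3 = 0.8, EC2 = 0.25, TM4 = 0.8,
                            IC3 = 0.35)
.default_dominant_frac <- c(IC1 = 0.95, TM1 = 0.2, EC1 = 0.25, TM2 = 0.95,
                            IC2 = 0.7, TM3 = 0.7, EC2 = 0.5, TM4 = 0.2,
                            IC3 = 0.92)

.expand_by_region <- function(x, topology, what) {
  reg <- topology$regions
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(as.numeric(x), nrow(reg)), reg$name))
  if (!is.null(names(x)) && all(reg$class %in% names(x)))
    if (!all(reg$name %in% names(x)))
      return(stats::setNames(as.numeric(x[reg$class]), reg$name))
  if (is.null(names(x)) || !all(reg$name %in% names(x)))
    stop(what, " must be a scalar, a per-class (TM/EC/IC), or a per-region ",
         "named vector")
  stats::setNames(as.numeric(x[reg$name]), reg$name)
}

.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

#' Generate a synthetic variant catalogue with ground truth
#'
#' Emits catalogue records whose cDNA and protein HGVS strings are
#' arithmetically consistent (the coding position falls in the stated
#' residue's codon), with missense density and dominant fraction set per
#' topology region, fixed numbers of nonsense / splicing / frameshift /
#' in-frame mutations scattered uniformly, and decoy records planted to
#' trip each curation rule (high allele frequency, unsupported single
#' patient, silent). Defaults emulate the published BEST1 landscape:
#' missense concentrated in the N-terminal intracellular and
#' transmembrane regions and the TM4-proximal part of IC3, dominant-rich
#' IC1/TM2/IC3 versus recessive-rich TM1/TM4, sparse extracellular loops,
#' 17 nonsense / 16 splicing / 27 frameshift / 16 in-frame mutations, and
#' in-frame deletions starting in residues 295-304 inheriting dominantly.
#'
#' @param topology A `topology_model` (default [best1_topology()]).
#' @param missense_rate Expected missense mutations per residue; scalar,
#'   per-class (`TM`/`EC`/`IC`), or per-region named vector.
#' @param dominant_frac Probability that a missense mutation is dominant,
#'   same shapes as `missense_rate`.
#' @param both_frac Probability that a missense mutation carries the dual
#'   dominant-and-recessive label.
#' @param n_nonsense,n_splicing,n_frameshift,n_inframe Counts of the
#'   non-missense classes, scattered uniformly along the protein.
#' @param decoys Named integer vector with entries `high_af`,
#'   `single_patient`, `silent`.
#' @param mean_extra_alleles Poisson mean of the allele count above 1 per
#'   distinct mutation.
#' @param seed Integer seed; recorded in the ground truth.
#' @return A list with `variants` (annotated, validated data frame) and
#'   `truth` (per-record planted type / inheritance / region / decoy rule,
#'   the per-region planted parameters, and the seed).
#' @export
simulate_catalogue <- function(topology = best1_topology(),
                               missense_rate = .default_missense_rate,
                               dominant_frac = .default_dominant_frac,
                               both_frac = 0.03,
                               n_nonsense = 17L, n_splicing = 16L,
                               n_frameshift = 27L, n_inframe = 16L,
                               decoys = c(high_af = 1L, single_patient = 1L,
                                          silent = 1L),
                               mean_extra_alleles = 3,
                               seed = 1L) {
  stopifnot(inherits(topology, "topology_model"))
  rate <- .expand_by_region(missense_rate, topology, "missense_rate")
  dfrac <- .expand_by_region(dominant_frac, topology, "dominant_frac")
  if (any(rate < 0)) stop("missense rates must be >= 0")
  if (any(dfrac < 0 | dfrac > 1) || both_frac < 0 || both_frac > 1)
    stop("fractions must lie in [0, 1]")
  set.seed(as.integer(seed))
  L <- topology$protein_length
  reg <- topology$regions
  used <- character(0)
  rows <- list()
  truth_rows <- list()

  fresh_cdna <- function(make) {
    for (i in 1:100) {
      cand <- make()
      if (!cand$cdna %in% used) {
        used <<- c(used, cand$cdna)
        return(cand)
      }
    }
    stop("could not place a unique variant after 100 retries; ",
         "rates imply too many mutations per codon")
  }

  draw_disease <- function(inh) {
    if (inh == "dominant")
      .sample1(c("BVMD", "AVMD", "ADVIRC", "RP", "other"),
               prob = c(0.75, 0.10, 0.05, 0.05, 0.05))
    else if (inh == "recessive")
      .sample1(c("AR_bestrophinopathy", "BVMD", "RP"), prob = c(0.8, 0.1, 0.1))
    else "BVMD"
  }

  add_record <- function(cdna, protein, type, inh, disease, region,
                         decoy = NA_character_) {
    i <- length(rows) + 1L
    af <- if (identical(decoy, "high_af")) stats::runif(1, 0.006, 0.05)
          else if (stats::runif(1) < 0.3) stats::runif(1, 0, 0.0004) else NA_real_
    single <- identical(decoy, "single_patient")
    rows[[i]] <<- data.frame(
      id = sprintf("V%04d", i), cdna_hgvs = cdna, protein_hgvs = protein,
      mutation_type = type, inheritance = inh, disease = disease,
      allele_count = 1L + stats::rpois(1, mean_extra_alleles),
      n_patients = if (single) 1L else 1L + .sample1(1:5),
      has_segregation = !single, has_clinical_characterization = !single,
      af_gnomad = af, af_jpn = NA_real_, af_genomeasia = NA_real_,
      af_gme = NA_real_, stringsAsFactors = FALSE)
    truth_rows[[i]] <<- data.frame(
      id = sprintf("V%04d", i), planted_type = type, planted_inheritance = inh,
      planted_disease = disease, planted_region = region, decoy_rule = decoy,
      stringsAsFactors = FALSE)
  }

  missense_at <- function(r) {
    fresh_cdna(function() {
      offset <- .sample1(1:3)
      pos <- 3L * (r - 1L) + offset
      ref <- .sample1(.BASES); alt <- .sample1(setdiff(.BASES, ref))
      aa_ref <- .sample1(AA_CODES_3); aa_alt <- .sample1(setdiff(AA_CODES_3, aa_ref))
      list(cdna = paste0("c.", pos, ref, ">", alt),
           protein = paste0("p.", aa_ref, r, aa_alt))
    })
  }

  # region-specific missense
  for (k in seq_len(nrow(reg))) {
    len <- reg$end[k] - reg$start[k] + 1L
    n_mis <- stats::rpois(1, rate[reg$name[k]] * len)
    for (j in seq_len(n_mis)) {
      r <- .sample1(reg$start[k]:reg$end[k])
      v <- missense_at(r)
      u <- stats::runif(1)
      inh <- if (u < both_frac) "both"
             else if (stats::runif(1) < dfrac[reg$name[k]]) "dominant"
             else "recessive"
      add_record(v$cdna, v$protein, "missense", inh, draw_disease(inh),
                 reg$name[k])
    }
  }
  # nonsense: recessive, scattered
  for (j in seq_len(n_nonsense)) {
    r <- .sample1(2:(L - 1L))
    v <- fresh_cdna(function() {
      pos <- 3L * (r - 1L) + .sample1(1:3)
      ref <- .sample1(.BASES); alt <- .sample1(setdiff(.BASES, ref))
      list(cdna = paste0("c.", pos, ref, ">", alt),
           protein = paste0("p.", .sample1(AA_CODES_3), r, "Ter"))
    })
    add_record(v$cdna, v$protein, "nonsense", "recessive",
               draw_disease("recessive"), assign_region(topology, r))
  }
  # splicing: intron-offset substitutions, no protein annotation
  for (j in seq_len(n_splicing)) {
    v <- fresh_cdna(function() {
      pos <- .sample1(seq(30L, 3L * L, by = 150L))
      off <- .sample1(c(-2L, -1L, 1L, 2L))
      ref <- .sample1(.BASES); alt <- .sample1(setdiff(.BASES, ref))
      list(cdna = paste0("c.", pos, if (off > 0) paste0("+", off) else off,
                         ref, ">", alt),
           protein = NA_character_)
    })
    add_record(v$cdna, v$protein, "splicing", "recessive",
               draw_disease("recessive"), NA_character_)
  }
  # frameshift: 1- or 2-nt deletions, recessive
  for (j in seq_len(n_frameshift)) {
    r <- .sample1(2:(L - 2L))
    v <- fresh_cdna(function() {
      pos <- 3L * (r - 1L) + .sample1(1:3)
      wid <- .sample1(1:2)
      cd <- if (wid == 1L) paste0("c.", pos, "del")
            else paste0("c.", pos, "_", pos + 1L, "del")
      list(cdna = cd, protein = paste0("p.", .sample1(AA_CODES_3), r, "fs"))
    })
    add_record(v$cdna, v$protein, "frameshift", "recessive",
               draw_disease("recessive"), assign_region(topology, r))
  }
  # in-frame deletions: dominant when starting in 295-304
  for (j in seq_len(n_inframe)) {
    v <- fresh_cdna(function() {
      r <- .sample1(2:(L - 3L))
      n_codons <- .sample1(1:2)
      pos <- 3L * (r - 1L) + 1L
      aa1 <- .sample1(AA_CODES_3)
      if (n_codons == 1L)
        list(cdna = paste0("c.", pos, "_", pos + 2L, "del"),
             protein = paste0("p.", aa1, r, "del"), r = r)
      else
        list(cdna = paste0("c.", pos, "_", pos + 5L, "del"),
             protein = paste0("p.", aa1, r, "_", .sample1(AA_CODES_3),
                              r + 1L, "del"), r = r)
    })
    inh <- if (v$r >= 295L && v$r <= 304L) "dominant" else "recessive"
    add_record(v$cdna, v$protein, "inframe_indel", inh, draw_disease(inh),
               assign_region(topology, v$r))
  }
  # decoys
  dk <- c(high_af = 0L, single_patient = 0L, silent = 0L)
  unknown <- setdiff(names(decoys), names(dk))
  if (length(unknown) || is.null(names(decoys)))
    stop("decoys must be named among high_af, single_patient, silent")
  dk[names(decoys)] <- as.integer(decoys)
  decoys <- dk
  for (j in seq_len(decoys[["high_af"]])) {
    r <- .sample1(2:(L - 1L)); v <- missense_at(r)
    add_record(v$cdna, v$protein, "missense", "dominant", "BVMD",
               assign_region(topology, r), decoy = "high_af")
  }
  for (j in seq_len(decoys[["single_patient"]])) {
    r <- .sample1(2:(L - 1L)); v <- missense_at(r)
    add_record(v$cdna, v$protein, "missense", "recessive",
               "AR_bestrophinopathy", assign_region(topology, r),
               decoy = "single_patient")
  }
  for (j in seq_len(decoys[["silent"]])) {
    r <- .sample1(2:(L - 1L))
    v <- fresh_cdna(function() {
      pos <- 3L * r  # third codon base, typical synonymous site
      ref <- .sample1(.BASES); alt <- .sample1(setdiff(.BASES, ref))
      list(cdna = paste0("c.", pos, ref, ">", alt),
           protein = paste0("p.", .sample1(AA_CODES_3), r, "="))
    })
    add_record(v$cdna, v$protein, "silent", "unknown", "other",
               assign_region(topology, r), decoy = "silent")
  }

  variants <- do.call(rbind, rows)
  variants <- validate_variants(annotate_variants(variants))
  truth <- list(seed = as.integer(seed),
                params = list(missense_rate = as.list(rate),
                              dominant_frac = as.list(dfrac),
                              both_frac = both_frac,
                              n_nonsense = n_nonsense, n_splicing = n_splicing,
                              n_frameshift = n_frameshift,
                              n_inframe = n_inframe,
                              decoys = as.list(decoys)),
                records = do.call(rbind, truth_rows))
  list(variants = variants, truth = truth)
}

#' Generate a synthetic ortholog family with ground truth
#'
#' Builds a random human-like reference and `n_orthologs` derived
#' sequences. Each ortholog carries a divergence scale (by default a
#' ladder from 0, a chimp-like identical ortholog, upward), multiplied by
#' a per-region substitution probability — extracellular loops substitute
#' far more often than transmembrane or intracellular segments under the
#' defaults, reproducing the conservation gradient of the real panel.
#' Substituted residues are drawn uniformly from the 19 non-identical
#' amino acids; indels are single-column gaps in the ortholog at
#' `gap_prob` (also scaled), so the output is aligned by construction.
#'
#' @param topology A `topology_model` giving protein length and regions.
#' @param n_orthologs Number of orthologs (default 12).
#' @param sub_prob Per-site substitution probability at scale 1; scalar,
#'   per-class, or per-region named vector.
#' @param ortholog_scale Numeric vector of per-ortholog divergence
#'   multipliers. The default for 12 orthologs is a ladder anchored to
#'   the identity gradient of the real vertebrate-to-fly panel (about
#'   100% down to 35-40% mean identity); other panel sizes get an evenly
#'   spaced ladder over the same range. Effective probabilities are
#'   capped at 1.
#' @param gap_prob Per-site single-column gap probability at scale 1.
#' @param seed Integer seed; recorded in the ground truth.
#' @return A list with `reference` (human sequence), `orthologs` (named
#'   character vector, aligned), `pairs` (list of [aligned_pair()]), and
#'   `truth` (per-ortholog substituted/gapped site indices, effective
#'   per-site probabilities, and the seed).
#' @export
simulate_orthologs <- function(topology = best1_topology(),
                               n_orthologs = 12L,
                               sub_prob = c(TM = 0.08, EC = 0.45, IC = 0.12),
                               ortholog_scale = NULL,
                               gap_prob = 0.01,
                               seed = 1L) {
  stopifnot(inherits(topology, "topology_model"))
  n_orthologs <- as.integer(n_orthologs)
  p_region <- .expand_by_region(sub_prob, topology, "sub_prob")
  if (any(p_region < 0 | p_region > 1) || gap_prob < 0 || gap_prob > 1)
    stop("probabilities must lie in [0, 1]")
  if (is.null(ortholog_scale)) {
    # divergence ladder emulating chimp (identical) through fruit fly
    ortholog_scale <- if (n_orthologs == 12L)
      c(0, 0.23, 1.37, 1.52, 1.60, 2.20, 2.74, 3.04, 3.34, 3.72, 3.72, 4.94)
    else seq(0, 4.94, length.out = n_orthologs)
  }
  if (length(ortholog_scale) != n_orthologs)
    stop("ortholog_scale must have one entry per ortholog")
  set.seed(as.integer(seed))
  L <- topology$protein_length
  reg <- topology$regions
  site_region <- assign_region(topology, seq_len(L))
  p_site <- p_region[site_region]
  ref <- sample(AA_CODES_1, L, replace = TRUE)
  names_o <- sprintf("orth%02d", seq_len(n_orthologs))
  orthologs <- character(n_orthologs)
  truth_sites <- vector("list", n_orthologs)
  for (k in seq_len(n_orthologs)) {
    p_eff <- pmin(1, p_site * ortholog_scale[k])
    g_eff <- min(1, gap_prob * ortholog_scale[k])
    o <- ref
    sub_sites <- which(stats::runif(L) < p_eff)
    for (s in sub_sites) o[s] <- .sample1(setdiff(AA_CODES_1, ref[s]))
    gap_sites <- which(stats::runif(L) < g_eff)
    o[gap_sites] <- "-"
    orthologs[k] <- paste(o, collapse = "")
    truth_sites[[k]] <- list(substituted = setdiff(sub_sites, gap_sites),
                             gapped = gap_sites)
  }
  names(orthologs) <- names_o
  names(truth_sites) <- names_o
  reference <- paste(ref, collapse = "")
  pairs <- lapply(names_o, function(nm)
    aligned_pair(reference, orthologs[[nm]], ortholog_name = nm))
  list(reference = reference, orthologs = orthologs, pairs = pairs,
       truth = list(seed = as.integer(seed),
                    sub_prob = as.list(p_region), gap_prob = gap_prob,
                    ortholog_scale = ortholog_scale, sites = truth_sites))
}

#' Write a simulated ortholog family as aligned FASTA
#'
#' The human reference is written first (named
#' `human_synthetic_reference`), followed by the orthologs; the human row
#' name contains the default `human_id` pattern consumed by
#' [read_ortholog_panel()].
#'
#' @param sim Result of [simulate_orthologs()].
#' @param path Output FASTA path.
#' @param human_name Record name for the reference row.
#' @return `path`, invisibly.
#' @export
write_orthologs_fasta <- function(sim, path,
                                  human_name = "human_synthetic_reference") {
  seqs <- c(stats::setNames(sim$reference, human_name), sim$orthologs)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Generate stratified cohort counts with known prevalence
#'
#' Draws clinically diagnosed counts per stratum from a Poisson at the
#' specified true prevalence and genetically confirmed counts from a
#' binomial at the specified solve rate — the structure of a stratified
#' national cohort with partial genetic confirmation.
#'
#' @param populations Named vector of stratum population sizes.
#' @param prev_per100k True clinical prevalence per 100,000 (scalar or per
#'   stratum).
#' @param solve_rate Probability that a clinical case is genetically
#'   confirmed (scalar or per stratum).
#' @param seed Integer seed.
#' @return A list with `counts` (data frame: stratum, population,
#'   n_clinical, n_genetic) and `truth` (the generating parameters).
#' @export
simulate_cohort <- function(populations = c(jewish = 7200000,
                                            arab_muslim = 1700000,
                                            other = 756000),
                            prev_per100k = 1.4, solve_rate = 0.57,
                            seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(populations)
  prev <- rep_len(prev_per100k, n)
  sr <- rep_len(solve_rate, n)
  n_clin <- stats::rpois(n, populations * prev / 1e5)
  n_gen <- stats::rbinom(n, n_clin, sr)
  counts <- data.frame(stratum = names(populations),
                       population = as.numeric(populations),
                       n_clinical = n_clin, n_genetic = n_gen,
                       row.names = NULL)
  list(counts = counts,
       truth = list(seed = as.integer(seed), prev_per100k = prev,
                    solve_rate = sr))
}

#' Serialise generator ground truth as JSON
#'
#' @param truth The `truth` element of a generator result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
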