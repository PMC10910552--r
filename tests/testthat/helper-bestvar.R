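# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixture is the 10-record decoy catalogue under inst/extdata.

# Build an annotated, validated variant data frame from parallel vectors.
mk_variants <- function(cdna, protein = NA_character_, type = NA_character_,
                        inheritance = "dominant", disease = "BVMD",
                        allele_count = 1L, n_patients = 2L,
                        seg = TRUE, clin = TRUE, af_gnomad = NA_real_) {
  n <- length(cdna)
  df <- data.frame(
    cdna_hgvs = cdna,
    protein_hgvs = rep_len(protein, n),
    mutation_type = rep_len(type, n),
    inheritance = rep_len(inheritance, n),
    disease = rep_len(disease, n),
    allele_count = as.integer(rep_len(allele_count, n)),
    n_patients = as.integer(rep_len(n_patients, n)),
    has_segregation = rep_len(seg, n),
    has_clinical_characterization = rep_len(clin, n),
    af_gnomad = rep_len(af_gnomad, n),
    stringsAsFactors = FALSE)
  validate_variants(annotate_variants(df))
}

# A missense record at a given residue (codon-consistent cDNA position).
mk_missense <- function(aa_pos, inheritance = "dominant", disease = "BVMD",
                        base_offset = 1L, ref = "G", alt = "A",
                        allele_count = 1L, af_gnomad = NA_real_) {
  pos <- 3L * (aa_pos - 1L) + base_offset
  mk_variants(paste0("c.", pos, ref, ">", alt),
              protein = paste0("p.Ala", aa_pos, "Val"),
              type = "missense", inheritance = inheritance,
              disease = disease, allele_count = allele_count,
              af_gnomad = af_gnomad)
}

decoy_fixture_path <- function() {
  p <- system.file("extdata", "variants_decoy10.tsv", package = "bestvar")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata",
                                 "variants_decoy10.tsv")
  p
}

# Random well-formed HGVS cDNA strings over the supported grammar.
random_cdna <- function(n, max_pos = 1755L) {
  bases <- c("A", "C", "G", "T")
  vapply(seq_len(n), function(i) {
    pos <- sample.int(max_pos, 1L)
    kind <- sample(c("sub", "sub_off", "del", "del_range", "dup", "ins",
                     "delins"), 1L)
    rb <- sample(bases, 1L)
    ab <- sample(setdiff(bases, rb), 1L)
    seq <- paste(sample(bases, sample.int(4L, 1L), replace = TRUE),
                 collapse = "")
    switch(kind,
      sub = paste0("c.", pos, rb, ">", ab),
      sub_off = paste0("c.", pos,
                       sample(c("-2", "-1", "+1", "+5"), 1L), rb, ">", ab),
      del = paste0("c.", pos, "del"),
      del_range = paste0("c.", pos, "_", pos + sample.int(8L, 1L), "del"),
      dup = paste0("c.", pos, "dup"),
      ins = paste0("c.", pos, "_", pos + 1L, "ins", seq),
      delins = paste0("c.", pos, "_", pos + sample.int(5L, 1L), "delins", seq))
  }, character(1))
}

# Gap-free ortholog panel with one shared human sequence.
mk_gapfree_panel <- function(n_orth = 5L, len = 40L, p_sub = 0.3) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  human <- paste(sample(aa, len, replace = TRUE), collapse = "")
  hs <- strsplit(human, "")[[1]]
  lapply(seq_len(n_orth), function(k) {
    o <- hs
    flip <- which(stats::runif(len) < p_sub)
    for (s in flip) o[s] <- sample(setdiff(aa, hs[s]), 1L)
    aligned_pair(human, paste(o, collapse = ""),
                 ortholog_name = paste0("o", k))
  })
}
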