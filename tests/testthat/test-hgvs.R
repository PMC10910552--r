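test_that("cDNA parsing recovers position, bases, offsets and op kind", {
  x <- parse_cdna("c.967G>A")
  expect_equal(x$op_kind, "substitution")
  expect_equal(x$position, 967L)
  expect_equal(x$ref_base, "G")
  expect_equal(x$alt_base, "A")
  expect_true(is.na(x$intron_offset))

  y <- parse_cdna("c.1740-1G>C")
  expect_equal(y$position, 1740L)
  expect_equal(y$intron_offset, -1L)

  z <- parse_cdna("c.1622del")
  expect_equal(z$op_kind, "deletion")
  expect_equal(z$position, 1622L)
  expect_true(is.na(z$end_position))

  w <- parse_cdna("c.74G>A")
  expect_equal(w$position, 74L)

  r <- parse_cdna("c.300_308del")
  expect_equal(r$end_position, 308L)
  expect_equal(parse_cdna("c.10_11insACT")$seq, "ACT")
  expect_equal(parse_cdna("c.5_8delinsTT")$op_kind, "delins")
  expect_equal(parse_cdna("c.12dup")$op_kind, "duplication")
})

test_that("malformed or out-of-subset cDNA input fails loudly", {
  expect_error(parse_cdna("p.Asp323Asn"), "protein-level")
  expect_error(parse_cdna("g.12345A>T"), "prefix")
  expect_error(parse_cdna("c.967G>"), "offending token")
  expect_error(parse_cdna("c.967G>A;c.968T>C"), "offending token")
  expect_error(parse_cdna("c.100+0G>A"))          # zero offset is invalid
  expect_error(parse_cdna("c.(90_100)del"), "offending token")
  expect_error(parse_cdna("c.200_100del"), "end before start")
})

test_that("protein parsing classifies missense, nonsense, frameshift, silent", {
  p <- parse_protein("p.Asp323Asn")
  expect_equal(p$residue_position, 323L)
  expect_equal(p$ref_aa, "Asp")
  expect_equal(p$alt_aa, "Asn")
  expect_equal(p$consequence, "missense")

  expect_equal(parse_protein("p.Trp93Ter")$consequence, "nonsense")
  expect_equal(parse_protein("p.Trp93*")$consequence, "nonsense")
  expect_equal(parse_protein("p.Leu100fs")$consequence, "frameshift")
  expect_equal(parse_protein("p.Leu100ProfsTer12")$consequence, "frameshift")
  expect_equal(parse_protein("p.(Asp323Asn)")$residue_position, 323L)

  s <- parse_protein("p.Leu100=")
  expect_equal(s$consequence, "unknown")
  expect_true(s$silent_candidate)
  s2 <- parse_protein("p.Leu100Leu")
  expect_true(s2$silent_candidate)

  d <- parse_protein("p.Gly299_Ala304del")
  expect_equal(d$consequence, "inframe")
  expect_equal(d$end_position, 304L)

  expect_error(parse_protein("p.Xyz100Ala"), "malformed 3-letter")
  expect_error(parse_protein("c.967G>A"), "cDNA-level")
})

test_that("parse -> format -> parse is the identity on the synthetic grammar", {
  set.seed(11)
  for (s in random_cdna(300)) {
    x <- parse_cdna(s)
    y <- parse_cdna(format(x))
    x$raw <- y$raw <- NULL
    x$seq <- if (x$op_kind %in% c("insertion", "delins")) x$seq else NULL
    y$seq <- if (y$op_kind %in% c("insertion", "delins")) y$seq else NULL
    expect_identical(unclass(x), unclass(y), label = s)
  }
})

test_that("codon arithmetic maps all three codon positions to one residue", {
  for (k in c(1L, 2L, 25L, 218L, 323L, 585L)) {
    expect_equal(map_to_protein_position(parse_cdna(paste0("c.", 3 * k - 2, "A>G"))), k)
    expect_equal(map_to_protein_position(parse_cdna(paste0("c.", 3 * k - 1, "A>G"))), k)
    expect_equal(map_to_protein_position(parse_cdna(paste0("c.", 3 * k, "A>G"))), k)
  }
  expect_equal(map_to_protein_position(parse_cdna("c.967G>A")), 323L)
  expect_equal(map_to_protein_position(parse_cdna("c.653G>A")), 218L)
  expect_true(is.na(map_to_protein_position(parse_cdna("c.1740-1G>C"))))
})

test_that("mutation-type classification follows splice/protein/indel rules", {
  expect_equal(classify_mutation_type(parse_cdna("c.1740-1G>C")), "splicing")
  expect_equal(classify_mutation_type(parse_cdna("c.967G>A"),
                                      parse_protein("p.Asp323Asn")), "missense")
  expect_equal(classify_mutation_type(parse_cdna("c.300_308del"),
                                      parse_protein("p.Gly100_Ala102del")),
               "inframe_indel")
  expect_equal(classify_mutation_type(parse_cdna("c.300_308del")),
               "inframe_indel")                      # 9 nt, no fs annotation
  expect_equal(classify_mutation_type(parse_cdna("c.1622del"),
                                      parse_protein("p.Leu541fs")), "frameshift")
  expect_equal(classify_mutation_type(parse_cdna("c.1622del")), "frameshift")
  expect_equal(classify_mutation_type(parse_cdna("c.300G>A"),
                                      parse_protein("p.Leu100=")), "silent")
  # exon-boundary proximity reclassifies only when a table is supplied
  expect_equal(classify_mutation_type(parse_cdna("c.100G>A"),
                                      parse_protein("p.Gly34Ser"),
                                      exon_boundaries = c(101L)), "splicing")
  expect_warning(out <- classify_mutation_type(parse_cdna("c.100G>A")),
                 "unknown")
  expect_equal(out, "unknown")
})

test_that("classification never returns silent when ref and alt residues differ", {
  set.seed(5)
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  for (i in 1:100) {
    r <- sample(aa, 1); a <- sample(setdiff(aa, r), 1)
    pos <- sample.int(585L, 1L)
    cls <- classify_mutation_type(
      parse_cdna(paste0("c.", 3 * pos - 2, "G>A")),
      parse_protein(paste0("p.", r, pos, a)))
    expect_false(cls == "silent")
  }
})

test_that("catalogue reading derives keys and keeps splice-predicted labels", {
  df <- read_variants(decoy_fixture_path())
  expect_equal(nrow(df), 10L)
  expect_equal(df$aa_position[df$id == "V001"], 323L)
  expect_true(is.na(df$aa_position[df$id == "V003"]))   # splicing, no residue
  expect_equal(df$cdna_norm[df$id == "V004"], "c.1622del")
  expect_false(any(df$splice_predicted))
  # a missense catalogue label survives a splice-proximal classification
  df2 <- annotate_variants(
    data.frame(cdna_hgvs = "c.100G>A", protein_hgvs = "p.Gly34Ser",
               mutation_type = "missense", inheritance = "dominant",
               disease = "BVMD", allele_count = 1L, n_patients = 2L,
               has_segregation = TRUE, has_clinical_characterization = TRUE),
    exon_boundaries = 101L)
  expect_equal(df2$mutation_type, "missense")
  expect_true(df2$splice_predicted)
})
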