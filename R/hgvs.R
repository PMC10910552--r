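# HGVS-style parsing for the variant-description subset found in
# bestrophinopathy catalogues: substitutions, del, dup, ins, delins,
# frameshifts, Ter/nonsense, and intron offsets. Anything outside that
# subset is a hard parse error, never a silent skip.

#' Three-letter amino-acid codes
#'
#' The twenty standard residues in IUPAC three-letter notation, used to
#' validate HGVS protein descriptions.
#' @keywords internal
AA_CODES_3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                "Thr", "Trp", "Tyr", "Val")

MUTATION_TYPES <- c("missense", "nonsense", "splicing", "frameshift",
                    "inframe_indel", "silent", "unknown")
INHERITANCE_LEVELS <- c("dominant", "recessive", "both", "unknown")
DISEASE_LEVELS <- c("BVMD", "AR_bestrophinopathy", "AVMD", "ADVIRC",
                    "RP", "AMD", "other")

.regex_groups <- function(pattern, x) {
  m <- regexec(pattern, x)
  if (m[[1]][1] == -1L) return(NULL)
  regmatches(x, m)[[1]]
}

new_cdna_change <- function(raw, op_kind, position, end_position = NA_integer_,
                            intron_offset = NA_integer_, ref_base = NA_character_,
                            alt_base = NA_character_, seq = NA_character_) {
  position <- as.integer(position)
  end_position <- as.integer(end_position)
  intron_offset <- as.integer(intron_offset)
  if (is.na(position) || position < 1L)
    stop("cDNA position must be a positive integer: ", raw)
  if (!is.na(end_position) && end_position < position)
    stop("cDNA range end before start: ", raw)
  if (!is.na(intron_offset) && intron_offset == 0L)
    stop("intron offset of 0 is not a valid HGVS offset: ", raw)
  structure(
    list(raw = raw, op_kind = op_kind, position = position,
         end_position = end_position, intron_offset = intron_offset,
         ref_base = ref_base, alt_base = alt_base, seq = seq),
    class = "cdna_change")
}

#' Parse an HGVS cDNA variant description
#'
#' Supports the subset of HGVS coding-DNA descriptions used in BEST1
#' catalogues: substitutions (`c.967G>A`, including intron offsets such as
#' `c.1740-1G>C`), deletions (`c.1622del`, `c.300_308del`), duplications,
#' insertions (`c.10_11insACT`) and deletion-insertions. Coordinates are
#' 1-based on the coding sequence (the A of the ATG is position 1); ranges
#' are inclusive.
#'
#' @param text A single HGVS string beginning with `"c."`.
#' @return An object of class `cdna_change` with fields `raw`, `op_kind`
#'   (one of substitution, deletion, duplication, insertion, delins),
#'   `position`, `end_position`, `intron_offset`, `ref_base`, `alt_base`
#'   and `seq` (inserted or annotated sequence, when given).
#' @examples
#' parse_cdna("c.967G>A")
#' parse_cdna("c.1740-1G>C")$intron_offset
#' parse_cdna("c.1622del")
#' @export
parse_cdna <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (startsWith(text, "p."))
    stop("protein-level (p.) description passed to parse_cdna(): ", text)
  if (!startsWith(text, "c."))
    stop("not a cDNA HGVS description (missing 'c.' prefix): '", text, "'")
  body <- substr(text, 3L, nchar(text))
  pos <- "(\\d+)([+-]\\d+)?"

  g <- .regex_groups(paste0("^", pos, "([ACGT])>([ACGT])$"), body)
  if (!is.null(g)) {
    return(new_cdna_change(text, "substitution", g[2],
                           intron_offset = .parse_offset(g[3]),
                           ref_base = g[4], alt_base = g[5]))
  }
  g <- .regex_groups(paste0("^", pos, "(?:_", pos, ")?(del|dup)([ACGT]*)$"), body)
  if (!is.null(g)) {
    op <- if (g[6] == "del") "deletion" else "duplication"
    if (nzchar(g[5]))
      stop("intron offsets on range ends are not supported: '", text, "'")
    return(new_cdna_change(text, op, g[2],
                           end_position = if (nzchar(g[4])) g[4] else NA,
                           intron_offset = .parse_offset(g[3]),
                           seq = if (nzchar(g[7])) g[7] else NA))
  }
  g <- .regex_groups("^(\\d+)(?:_(\\d+))?delins([ACGT]+)$", body)
  if (!is.null(g)) {
    return(new_cdna_change(text, "delins", g[2],
                           end_position = if (nzchar(g[3])) g[3] else NA,
                           seq = g[4]))
  }
  g <- .regex_groups("^(\\d+)_(\\d+)ins([ACGT]+)$", body)
  if (!is.null(g)) {
    return(new_cdna_change(text, "insertion", g[2], end_position = g[3],
                           seq = g[4]))
  }
  stop("cannot parse cDNA HGVS description: '", text,
       "' (offending token: '", body, "')")
}

.parse_offset <- function(tok) {
  if (is.null(tok) || !nzchar(tok)) return(NA_integer_)
  as.integer(tok)
}

.format_offset <- function(off) {
  if (is.na(off)) return("")
  if (off > 0) paste0("+", off) else as.character(off)
}

#' Normalised HGVS string for a parsed cDNA change
#'
#' Formats a `cdna_change` back into HGVS notation. Deletion/duplication
#' sequence annotations (e.g. the `A` of `c.1622delA`) are dropped in the
#' normalised form; inserted sequences are kept. `parse_cdna()` and
#' `format()` round-trip on normalised strings.
#'
#' @param x A `cdna_change`.
#' @param ... Unused.
#' @return A single HGVS string.
#' @export
format.cdna_change <- function(x, ...) {
  loc <- paste0(x$position, .format_offset(x$intron_offset))
  if (!is.na(x$end_position)) loc <- paste0(loc, "_", x$end_position)
  switch(x$op_kind,
    substitution = paste0("c.", loc, x$ref_base, ">", x$alt_base),
    deletion     = paste0("c.", loc, "del"),
    duplication  = paste0("c.", loc, "dup"),
    insertion    = paste0("c.", loc, "ins", x$seq),
    delins       = paste0("c.", loc, "delins", x$seq),
    stop("unknown op_kind: ", x$op_kind))
}

#' @export
print.cdna_change <- function(x, ...) {
  cat("<cdna_change> ", format(x), " [", x$op_kind, "]\n", sep = "")
  invisible(x)
}

new_protein_change <- function(raw, residue_position, ref_aa = NA_character_,
                               alt_aa = NA_character_, consequence = "unknown",
                               end_position = NA_integer_,
                               end_ref_aa = NA_character_,
                               silent_candidate = FALSE) {
  residue_position <- as.integer(residue_position)
  if (is.na(residue_position) || residue_position < 1L)
    stop("protein residue position must be a positive integer: ", raw)
  structure(
    list(raw = raw, residue_position = residue_position, ref_aa = ref_aa,
         alt_aa = alt_aa, consequence = consequence,
         end_position = as.integer(end_position), end_ref_aa = end_ref_aa,
         silent_candidate = silent_candidate),
    class = "protein_change")
}

.check_aa3 <- function(code, raw, allow_ter = FALSE) {
  ok <- code %in% AA_CODES_3 || (allow_ter && code %in% c("Ter"))
  if (!ok) stop("malformed 3-letter amino-acid code '", code, "' in '", raw, "'")
  code
}

#' Parse an HGVS protein variant description
#'
#' Handles the catalogue subset: missense (`p.Asp323Asn`), nonsense
#' (`p.Trp93Ter` or `p.Trp93*`), frameshift (`p.Leu100fs`,
#' `p.Leu100ProfsTer12`), synonymous (`p.Leu100=` or equal ref/alt, flagged
#' as silent candidates), and in-frame deletions/duplications/insertions
#' over residue ranges. Surrounding parentheses (`p.(Asp323Asn)`) are
#' accepted and stripped.
#'
#' @param text A single HGVS string beginning with `"p."`.
#' @return An object of class `protein_change` with `residue_position`
#'   (1-based), `ref_aa`/`alt_aa` (3-letter codes), and `consequence`
#'   (missense, nonsense, frameshift, inframe, or unknown).
#' @examples
#' parse_protein("p.Asp323Asn")
#' parse_protein("p.Trp93Ter")$consequence
#' @export
parse_protein <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (startsWith(text, "c."))
    stop("cDNA-level (c.) description passed to parse_protein(): ", text)
  if (!startsWith(text, "p."))
    stop("not a protein HGVS description (missing 'p.' prefix): '", text, "'")
  body <- sub("^\\((.*)\\)$", "\\1", substr(text, 3L, nchar(text)))
  aa <- "([A-Z][a-z]{2})"

  # frameshift: p.Leu100fs / p.Leu100ProfsTer12 / p.Leu100fs*12
  g <- .regex_groups(paste0("^", aa, "(\\d+)", aa, "?fs(?:(?:Ter|\\*)\\d*)?$"), body)
  if (!is.null(g)) {
    return(new_protein_change(text, g[3], ref_aa = .check_aa3(g[2], text),
                              alt_aa = if (nzchar(g[4])) .check_aa3(g[4], text) else NA,
                              consequence = "frameshift"))
  }
  # single-residue substitution incl. Ter / * / =
  g <- .regex_groups(paste0("^", aa, "(\\d+)(", aa, "|Ter|\\*|=)$"), body)
  if (!is.null(g)) {
    ref <- .check_aa3(g[2], text)
    alt_tok <- g[4]
    if (alt_tok %in% c("Ter", "*")) {
      return(new_protein_change(text, g[3], ref, "Ter", "nonsense"))
    }
    if (alt_tok == "=" || identical(alt_tok, ref)) {
      return(new_protein_change(text, g[3], ref,
                                alt_aa = if (alt_tok == "=") ref else alt_tok,
                                consequence = "unknown", silent_candidate = TRUE))
    }
    return(new_protein_change(text, g[3], ref, .check_aa3(alt_tok, text),
                              "missense"))
  }
  # in-frame del/dup over one residue or a range: p.Gly299_Ala304del
  g <- .regex_groups(paste0("^", aa, "(\\d+)(?:_", aa, "(\\d+))?(del|dup)$"), body)
  if (!is.null(g)) {
    return(new_protein_change(text, g[3], ref_aa = .check_aa3(g[2], text),
                              consequence = "inframe",
                              end_position = if (nzchar(g[5])) g[5] else NA,
                              end_ref_aa = if (nzchar(g[4])) .check_aa3(g[4], text) else NA))
  }
  # in-frame insertion: p.Lys100_Leu101insGlnSer
  g <- .regex_groups(paste0("^", aa, "(\\d+)_", aa, "(\\d+)ins((?:[A-Z][a-z]{2})+)$"), body)
  if (!is.null(g)) {
    return(new_protein_change(text, g[3], ref_aa = .check_aa3(g[2], text),
                              consequence = "inframe", end_position = g[5],
                              end_ref_aa = .check_aa3(g[4], text)))
  }
  stop("cannot parse protein HGVS description: '", text, "'")
}

#' @export
format.protein_change <- function(x, ...) x$raw

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change> ", x$raw, " [", x$consequence, "]\n", sep = "")
  invisible(x)
}

#' Map a coding-DNA position to its protein residue
#'
#' Standard codon arithmetic: coding position n lies in codon
#' `ceiling(n / 3)`. Intron-offset (splice-region) changes have no residue
#' and return `NA`. For ranges the residue of the start position is
#' returned; the end is exposed on the parsed object.
#'
#' @param cdna A `cdna_change` as returned by [parse_cdna()].
#' @return Integer residue index, or `NA_integer_` for intronic changes.
#' @examples
#' map_to_protein_position(parse_cdna("c.967G>A"))  # 323
#' @export
map_to_protein_position <- function(cdna) {
  stopifnot(inherits(cdna, "cdna_change"))
  if (cdna$position < 1L) stop("coding position must be >= 1")
  if (!is.na(cdna$intron_offset)) return(NA_integer_)
  as.integer(ceiling(cdna$position / 3))
}

.indel_net_length <- function(cdna) {
  span <- function() {
    if (!is.na(cdna$end_position)) cdna$end_position - cdna$position + 1L
    else if (!is.na(cdna$seq)) nchar(cdna$seq)
    else 1L
  }
  switch(cdna$op_kind,
    deletion = -span(),
    duplication = span(),
    insertion = nchar(cdna$seq),
    delins = nchar(cdna$seq) - span(),
    0L)
}

#' Classify a variant's mutation type
#'
#' Applies the classification used for catalogue tallies and region
#' statistics: intron-offset changes (and, when an exon table is supplied,
#' exonic changes within 2 nt of an exon boundary) are splicing; otherwise
#' the protein-level consequence wins (missense / nonsense / frameshift /
#' silent); indels without a frameshift annotation are in-frame when their
#' net length is divisible by 3 and frameshift otherwise. A substitution
#' with no protein annotation and no applicable rule classifies as
#' `"unknown"` with a warning — never a guess.
#'
#' @param cdna A `cdna_change`.
#' @param protein Optional `protein_change`.
#' @param exon_boundaries Optional integer vector of coding positions that
#'   are exon edges; exonic changes within 2 nt of one classify as splicing.
#' @return One of "missense", "nonsense", "splicing", "frameshift",
#'   "inframe_indel", "silent", "unknown".
#' @examples
#' classify_mutation_type(parse_cdna("c.1740-1G>C"))            # splicing
#' classify_mutation_type(parse_cdna("c.967G>A"),
#'                        parse_protein("p.Asp323Asn"))          # missense
#' @export
classify_mutation_type <- function(cdna, protein = NULL, exon_boundaries = NULL) {
  stopifnot(inherits(cdna, "cdna_change"))
  if (!is.na(cdna$intron_offset)) return("splicing")
  if (!is.null(exon_boundaries) && length(exon_boundaries) &&
      any(abs(cdna$position - as.integer(exon_boundaries)) <= 2L))
    return("splicing")
  if (!is.null(protein)) {
    stopifnot(inherits(protein, "protein_change"))
    if (protein$silent_candidate) return("silent")
    if (protein$consequence == "frameshift") return("frameshift")
    if (protein$consequence == "nonsense") return("nonsense")
    if (protein$consequence == "missense") return("missense")
    if (protein$consequence == "inframe") return("inframe_indel")
  }
  if (cdna$op_kind %in% c("deletion", "duplication", "insertion", "delins")) {
    net <- .indel_net_length(cdna)
    return(if (net %% 3L == 0L) "inframe_indel" else "frameshift")
  }
  warning("cannot classify '", format(cdna),
          "' without a protein annotation; returning \"unknown\"")
  "unknown"
}
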