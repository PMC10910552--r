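# Ortholog conservation: pairwise global alignment (delegated to
# Biostrings), sliding-window percent identity over human positions,
# per-site conservation across an ortholog panel, and region means.

AA_ALPHABET_20X <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.check_aa_string <- function(s, what) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), AA_ALPHABET_20X)
  if (length(bad))
    stop("illegal character(s) in ", what, " sequence: ",
         paste(bad, collapse = ", "))
  ch
}

#' Aligned human/ortholog sequence pair
#'
#' Two equal-length strings over the amino-acid alphabet plus the gap
#' character `-`. Columns gapped in both sequences are dropped on
#' construction so the invariant "no gap-in-both column" always holds.
#'
#' @param human_aligned,ortholog_aligned Aligned sequences (same length).
#' @param ortholog_name Label for the ortholog.
#' @return An `aligned_pair`.
#' @export
aligned_pair <- function(human_aligned, ortholog_aligned,
                         ortholog_name = "ortholog") {
  if (nchar(human_aligned) != nchar(ortholog_aligned))
    stop("aligned sequences must have equal length")
  h <- strsplit(human_aligned, "", fixed = TRUE)[[1]]
  o <- strsplit(ortholog_aligned, "", fixed = TRUE)[[1]]
  keep <- !(h == "-" & o == "-")
  h <- h[keep]; o <- o[keep]
  bad <- setdiff(unique(c(h, o)), c(AA_ALPHABET_20X, "-"))
  if (length(bad))
    stop("illegal character(s) in aligned pair: ", paste(bad, collapse = ", "))
  structure(list(human = h, ortholog = o, ortholog_name = ortholog_name),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("<aligned_pair> vs ", x$ortholog_name, ", ", length(x$human),
      " columns, ", sum(x$human != "-"), " human residues\n", sep = "")
  invisible(x)
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()]
#' with a BLOSUM62 substitution matrix and affine gap penalties
#' (open 10, extend 0.5 by default). Used when orthologs are supplied as
#' unaligned FASTA; a precomputed MSA bypasses alignment entirely.
#'
#' @param human,ortholog Amino-acid strings (the 20 residues plus `X`).
#' @param ortholog_name Label carried on the result.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param substitution_matrix Scoring matrix; defaults to BLOSUM62.
#' @return An [aligned_pair()].
#' @examples
#' global_align("ACDE", "ACE")
#' @export
global_align <- function(human, ortholog, ortholog_name = "ortholog",
                         gap_open = 10, gap_extend = 0.5,
                         substitution_matrix = NULL) {
  .check_aa_string(human, "human")
  .check_aa_string(ortholog, "ortholog")
  if (!nzchar(human) || !nzchar(ortholog)) stop("empty sequence")
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(human), Biostrings::AAString(ortholog),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  aligned_pair(as.character(Biostrings::alignedPattern(pa)),
               as.character(Biostrings::alignedSubject(pa)),
               ortholog_name = ortholog_name)
}

.human_positions <- function(pair) which(pair$human != "-")

.match_vector <- function(pair) {
  cols <- .human_positions(pair)
  h <- pair$human[cols]
  o <- pair$ortholog[cols]
  h == o & o != "-"  # a gap (or different residue) is a non-match
}

#' Sliding-window percent identity along the human sequence
#'
#' Windows of `window` consecutive human (non-gap) residues, advanced one
#' residue at a time; the value `100 * matches / window` is assigned to
#' the window's first human position. An aligned ortholog gap counts as a
#' mismatch and does not shrink the denominator.
#'
#' @param pair An [aligned_pair()].
#' @param window Window length in residues (default 30).
#' @return Numeric vector indexed by human position, `NA` where no full
#'   window fits (the last `window - 1` positions).
#' @export
sliding_window_identity <- function(pair, window = 30L) {
  stopifnot(inherits(pair, "aligned_pair"))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  m <- .match_vector(pair)
  L <- length(m)
  if (window > L)
    stop("window (", window, ") larger than the human sequence (", L, ")")
  cs <- cumsum(c(0L, m))
  track <- rep(NA_real_, L)
  starts <- seq_len(L - window + 1L)
  track[starts] <- 100 * (cs[starts + window] - cs[starts]) / window
  track
}

#' Per-site conservation across an ortholog panel
#'
#' For each human position, the fraction of orthologs whose aligned
#' residue is identical to the human residue. The denominator is the
#' number of orthologs, not the per-site coverage: an aligned gap is a
#' non-match.
#'
#' @param pairs List of [aligned_pair()] objects sharing one human
#'   sequence (an error otherwise).
#' @return Numeric vector in `[0, 1]`, one value per human residue, with
#'   the human sequence attached as attribute `human`.
#' @export
per_site_conservation <- function(pairs) {
  stopifnot(is.list(pairs), length(pairs) >= 1L,
            all(vapply(pairs, inherits, logical(1), "aligned_pair")))
  humans <- vapply(pairs, function(p)
    paste(p$human[p$human != "-"], collapse = ""), character(1))
  if (length(unique(humans)) != 1L)
    stop("all pairs must share the same human sequence")
  L <- nchar(humans[1])
  mm <- matrix(vapply(pairs, .match_vector, logical(L)), nrow = L)
  per_site <- rowMeans(mm)
  attr(per_site, "human") <- humans[1]
  per_site
}

#' Full conservation profile for an ortholog panel
#'
#' Bundles the per-site conservation vector, the per-ortholog
#' sliding-window tracks, and per-ortholog mean identities. The mean
#' identity reported per ortholog is, by default, the mean of its
#' sliding-window track; `mean_method = "overall"` instead uses the
#' whole-sequence identity (matches over all human residues).
#'
#' @param pairs List of [aligned_pair()] objects on one human sequence.
#' @param window Window length for the windowed tracks (default 30).
#' @param mean_method `"windowed"` (default) or `"overall"`.
#' @return A `conservation_profile` with elements `per_site`, `windowed`
#'   (named list of tracks), `ortholog_means` (percent), `window_size`,
#'   and `human`.
#' @export
conservation_profile <- function(pairs, window = 30L,
                                 mean_method = c("windowed", "overall")) {
  mean_method <- match.arg(mean_method)
  per_site <- per_site_conservation(pairs)
  nm <- vapply(pairs, `[[`, character(1), "ortholog_name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  windowed <- lapply(pairs, sliding_window_identity, window = window)
  names(windowed) <- nm
  means <- if (mean_method == "windowed")
    vapply(windowed, function(t) mean(t, na.rm = TRUE), numeric(1))
  else
    vapply(pairs, function(p) 100 * mean(.match_vector(p)), numeric(1))
  names(means) <- nm
  structure(list(per_site = as.numeric(per_site), windowed = windowed,
                 ortholog_means = means, window_size = as.integer(window),
                 human = attr(per_site, "human"),
                 mean_method = mean_method),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> ", length(x$windowed), " orthologs, ",
      length(x$per_site), " residues, window ", x$window_size, "\n", sep = "")
  print(round(sort(x$ortholog_means, decreasing = TRUE), 1))
  invisible(x)
}

#' Mean conservation over a residue interval
#'
#' Two candidate definitions are available for an interval's average
#' conservation: `"per_site"` (default) averages the per-site match
#' fractions over the interval and scales to percent; `"windowed"`
#' averages, over orthologs, each ortholog's sliding-window values at
#' window-start positions inside the interval. On gap-free panels the two
#' differ only through window-edge effects.
#'
#' @param profile A `conservation_profile` (or a bare per-site vector,
#'   `"per_site"` method only).
#' @param start,end 1-based inclusive interval bounds.
#' @param method `"per_site"` or `"windowed"`.
#' @return Mean conservation of the interval, in percent.
#' @export
region_mean_conservation <- function(profile, start, end,
                                     method = c("per_site", "windowed")) {
  method <- match.arg(method)
  start <- as.integer(start); end <- as.integer(end)
  per_site <- if (inherits(profile, "conservation_profile"))
    profile$per_site else as.numeric(profile)
  L <- length(per_site)
  if (is.na(start) || is.na(end) || start < 1L || end > L || start > end)
    stop("interval must satisfy 1 <= start <= end <= ", L)
  if (method == "per_site") return(100 * mean(per_site[start:end]))
  if (!inherits(profile, "conservation_profile"))
    stop("windowed method needs a conservation_profile")
  vals <- vapply(profile$windowed, function(t)
    mean(t[start:end], na.rm = TRUE), numeric(1))
  mean(vals)
}

#' Read an ortholog panel from FASTA or a precomputed MSA
#'
#' Aligned FASTA or Clustal (`.aln`) input is consumed as-is: each
#' non-human row is paired with the human row (columns gapped in both are
#' dropped per pair). Unaligned FASTA input triggers the built-in pairwise
#' [global_align()] of every ortholog against the human sequence.
#'
#' @param path FASTA or Clustal file.
#' @param human_id Identifier (substring match against record names) of
#'   the human sequence; default `"NP_004174"`.
#' @param format `"auto"` (by extension and content), `"fasta"`,
#'   `"clustal"`.
#' @return List of [aligned_pair()] objects, one per ortholog.
#' @export
read_ortholog_panel <- function(path, human_id = "NP_004174",
                                format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.aln$|\\.clustal$", path)) "clustal" else "fasta"
  seqs <- if (format == "clustal") {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    as.character(Biostrings::unmasked(msa))
  } else {
    as.character(Biostrings::readAAStringSet(path))
  }
  if (length(seqs) < 2L) stop("ortholog panel needs >= 2 sequences: ", path)
  hit <- grepl(human_id, names(seqs), fixed = TRUE)
  if (sum(hit) != 1L)
    stop("exactly one sequence name must match human_id '", human_id,
         "'; found ", sum(hit))
  human <- seqs[[which(hit)]]
  others <- seqs[!hit]
  aligned_input <- any(grepl("-", unlist(seqs), fixed = TRUE)) ||
    length(unique(nchar(seqs))) == 1L
  lapply(names(others), function(nm) {
    if (aligned_input) aligned_pair(human, others[[nm]], ortholog_name = nm)
    else global_align(human, others[[nm]], ortholog_name = nm)
  })
}

#' Write conservation outputs as TSV/JSON
#'
#' `per_site_tsv`: position, human residue, conservation fraction.
#' `tracks_tsv`: one row per (ortholog, position) with the windowed
#' identity. `means_json`: per-ortholog mean identities.
#'
#' @param profile A `conservation_profile`.
#' @param per_site_tsv,tracks_tsv,means_json Output paths (NULL to skip).
#' @return Invisibly, the profile.
#' @export
write_conservation <- function(profile, per_site_tsv = NULL,
                               tracks_tsv = NULL, means_json = NULL) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (!is.null(per_site_tsv)) {
    res <- strsplit(profile$human, "", fixed = TRUE)[[1]]
    utils::write.table(
      data.frame(position = seq_along(profile$per_site),
                 human_residue = res,
                 conservation_fraction = profile$per_site),
      per_site_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tracks_tsv)) {
    rows <- do.call(rbind, lapply(names(profile$windowed), function(nm) {
      t <- profile$windowed[[nm]]
      data.frame(ortholog = nm, position = seq_along(t),
                 window_identity_pct = t)
    }))
    utils::write.table(rows, tracks_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(means_json))
    jsonlite::write_json(as.list(profile$ortholog_means), means_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(profile)
}
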