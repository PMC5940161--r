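# Read-vs-amplicon alignment. Single known amplicon references make read
# mapping unnecessary: each read is aligned globally (whole read) against a
# local window of the reference with affine gap costs
# (match +2, mismatch -3, gap open 5, gap extend 2). The same alignment is
# used for coordinate projection during classification and for indel calls.
# Terminal gaps (read overhang / incomplete coverage) are not counted as
# indels: they reflect read length, not editing outcomes.

.dna_score_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- c("A", "C", "G", "T", "N")
      m <- matrix(-3, 5L, 5L, dimnames = list(b, b))
      diag(m) <- 2
      m["N", ] <- 0
      m[, "N"] <- 0
      cache <<- m
    }
    cache
  }
})

# Align unique read sequences to one reference. Returns per read: aligned
# pattern/subject strings (with "-" gaps), reference start/end of the
# aligned span, and whether the alignment contains an internal gap.
align_reads <- function(bases, reference) {
  reference <- normalize_bases(reference)
  if (nchar(reference) == 0L) stop("empty reference sequence", call. = FALSE)
  if (!length(bases)) {
    return(list(pattern = character(0), subject = character(0),
                start = integer(0), end = integer(0), indel = logical(0)))
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(bases),
    subject = Biostrings::DNAString(reference),
    type = "global-local",
    substitutionMatrix = .dna_score_matrix(),
    gapOpening = 5, gapExtension = 2)
  pstr <- as.character(Biostrings::pattern(aln))
  sstr <- as.character(Biostrings::subject(aln))
  sstart <- BiocGenerics::start(Biostrings::subject(aln))
  send <- BiocGenerics::end(Biostrings::subject(aln))
  indel <- mapply(.has_internal_gap, pstr, sstr, USE.NAMES = FALSE)
  list(pattern = pstr, subject = sstr, start = sstart, end = send,
       indel = indel)
}

.has_internal_gap <- function(p, s) {
  if (!grepl("-", p, fixed = TRUE) && !grepl("-", s, fixed = TRUE)) {
    return(FALSE)
  }
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  gap <- pc == "-" | sc == "-"
  ng <- which(!gap)
  if (!length(ng)) return(FALSE)
  any(gap[ng[1L]:ng[length(ng)]])
}

# Read characters observed at given reference positions for one aligned
# read; NA outside the aligned span, "-" where the read has a deletion.
.read_chars_at <- function(bases_i, p, s, sstart, send, positions) {
  out <- rep(NA_character_, length(positions))
  inside <- positions >= sstart & positions <= send
  if (!any(inside)) return(out)
  if (!grepl("-", p, fixed = TRUE) && !grepl("-", s, fixed = TRUE)) {
    off <- positions[inside] - sstart + 1L
    out[inside] <- substring(p, off, off)
    return(out)
  }
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  is_ref <- sc != "-"
  refpos <- sstart + cumsum(is_ref) - 1L
  m <- match(positions[inside], refpos[is_ref])
  out[inside] <- pc[is_ref][m]
  out
}
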