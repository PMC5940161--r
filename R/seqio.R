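#' Normalize a nucleotide string
#'
#' Upper-cases the input, replaces U with T (RNA input), and verifies that
#' only the alphabet \code{A,C,G,T,N} remains. IUPAC ambiguity codes other
#' than N are rejected: downstream deaminase-editing logic is defined only on
#' concrete bases.
#'
#' @param x Character vector of nucleotide strings.
#' @param ids Optional identifiers used in error messages.
#' @return The normalized character vector.
#' @export
normalize_bases <- function(x, ids = NULL) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- regexpr("[^ACGTN]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    who <- if (!is.null(ids)) paste0(" in sequence '", ids[i], "'") else ""
    stop(sprintf("disallowed character '%s' at offset %d%s",
                 substr(x[i], bad[i], bad[i]), bad[i], who), call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' Watson-Crick reverse complement over the alphabet \code{A,C,G,T,N}
#' (N maps to N). An involution: applying it twice returns the input.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("CCA")  # "TGG"
#' @export
reverse_complement <- function(x) {
  x <- normalize_bases(x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Build a CDS record table
#'
#' @param gene_id Character vector of identifiers.
#' @param seq Character vector of coding sequences (normalized).
#' @return A \code{cds_set} data frame with columns \code{gene_id},
#'   \code{seq}, \code{length_nt}, \code{frame_valid} (length divisible by 3
#'   and non-empty) and \code{empty}. Frame-broken or empty records are
#'   flagged, never silently dropped.
#' @export
cds_set <- function(gene_id, seq) {
  seq <- normalize_bases(seq, ids = gene_id)
  len <- nchar(seq)
  out <- data.frame(
    gene_id = as.character(gene_id),
    seq = seq,
    length_nt = len,
    frame_valid = len > 0L & len %% 3L == 0L,
    empty = len == 0L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cds_set", "data.frame")
  out
}

#' Read coding sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header.
#' Lower-case and RNA (U) input is normalized; empty records are flagged in
#' the returned table rather than dropped.
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @return A \code{\link{cds_set}} data frame in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) && !startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop(sprintf("malformed FASTA header at line %d: expected '>'",
                 nonblank[1L]), call. = FALSE)
  }
  if (!length(nonblank)) return(cds_set(character(0), character(0)))
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  cds_set(ids, as.character(x))
}

#' Write sequences to a FASTA file
#'
#' @param cds A \code{\link{cds_set}} data frame (or any data frame with
#'   \code{gene_id} and \code{seq} columns).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(cds, path, width = 70L) {
  x <- Biostrings::BStringSet(structure(cds$seq, names = cds$gene_id))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Build a read table
#'
#' @param id Read identifiers.
#' @param bases Read sequences.
#' @param qual Phred+33-encoded quality strings (same lengths as
#'   \code{bases}).
#' @return A \code{fastq_reads} data frame with columns \code{id},
#'   \code{bases}, \code{qual}.
#' @export
fastq_reads <- function(id, bases, qual) {
  stopifnot(length(id) == length(bases), length(bases) == length(qual))
  if (length(bases) && any(nchar(bases) != nchar(qual))) {
    i <- which(nchar(bases) != nchar(qual))[1L]
    stop(sprintf("read '%s': sequence and quality lengths differ (%d vs %d)",
                 id[i], nchar(bases[i]), nchar(qual[i])), call. = FALSE)
  }
  out <- data.frame(id = as.character(id), bases = as.character(bases),
                    qual = as.character(qual), stringsAsFactors = FALSE)
  class(out) <- c("fastq_reads", "data.frame")
  out
}

#' Read a FASTQ file
#'
#' Four-line records, Phred+33 quality encoding (modern Illumina). A
#' sequence/quality length mismatch raises a parse error naming the read.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A \code{\link{fastq_reads}} data frame.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(fastq_reads(character(0), character(0), character(0)))
  }
  # the reader warns about dropping its own (empty) metadata columns when
  # the set is converted back to character; that warning is cosmetic
  tryCatch(suppressWarnings({
    x <- Biostrings::readQualityScaledDNAStringSet(path)
    # the C parser accepts records whose quality width differs from the
    # sequence width; reject them explicitly, naming the offending read
    wb <- BiocGenerics::width(x)
    wq <- BiocGenerics::width(Biostrings::quality(x))
    if (any(wb != wq)) {
      i <- which(wb != wq)[1L]
      stop(sprintf(
        "FASTQ record '%s': sequence and quality lengths differ (%d vs %d)",
        sub("\\s.*$", "", names(x)[i]), wb[i], wq[i]), call. = FALSE)
    }
    fastq_reads(sub("\\s.*$", "", names(x)), as.character(x),
                as.character(Biostrings::quality(x)))
  }), error = function(e) {
    if (grepl("sequence and quality lengths differ", conditionMessage(e))) {
      stop(e)
    }
    .fastq_diagnose(path, e)
  })
}

# Re-parse a failing FASTQ by hand to produce an error naming the read.
.fastq_diagnose <- function(path, orig) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  for (i in seq(1L, n - n %% 4L, by = 4L)) {
    id <- sub("^@", "", sub("\\s.*$", "", lines[i]))
    if (i + 3L <= n && nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      stop(sprintf(
        "FASTQ record '%s': sequence and quality lengths differ (%d vs %d)",
        id, nchar(lines[i + 1L]), nchar(lines[i + 3L])), call. = FALSE)
    }
  }
  stop(conditionMessage(orig), call. = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads A \code{\link{fastq_reads}} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(structure(reads$bases, names = reads$id))
  suppressWarnings(
    Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                                qualities = Biostrings::BStringSet(reads$qual)))
  invisible(path)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual Character vector of quality strings.
#' @return A list of integer vectors (all scores >= 0).
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) {
    if (!nchar(q)) return(integer(0)) else utf8ToInt(q) - 33L
  })
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores Integer vector of quality scores.
#' @return A single quality string.
#' @export
phred_encode <- function(scores) {
  if (!length(scores)) return("")
  intToUtf8(as.integer(scores) + 33L)
}

#' Map CDS identifiers to gene identifiers using a GFF3 file
#'
#' Convenience for reporting: extracts \code{ID}/\code{Parent} (or
#' \code{gene_id}) attributes of CDS and mRNA features. Requires the
#' rtracklayer package.
#'
#' @param path Path to a GFF3 file.
#' @return A data frame with columns \code{cds_id} and \code{gene_id}.
#' @export
read_gene_map <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gene_map() requires the rtracklayer package", call. = FALSE)
  }
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  is_cds <- tolower(g$type) %in% c("cds", "mrna")
  ids <- as.character(g$ID)
  parent <- if ("Parent" %in% names(g)) {
    vapply(g$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(g))
  gene <- if ("gene_id" %in% names(g)) as.character(g$gene_id) else parent
  out <- data.frame(cds_id = ids[is_cds],
                    gene_id = ifelse(is.na(gene[is_cds]), ids[is_cds], gene[is_cds]),
                    stringsAsFactors = FALSE)
  out[!is.na(out$cds_id) & !duplicated(out$cds_id), , drop = FALSE]
}
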