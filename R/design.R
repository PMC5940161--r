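# Knockout-site design: scan coding sequences for NGG-PAM protospacers in
# which cytidine deamination inside the editing window converts an in-frame
# CAA/CAG/CGA/TGG codon into a premature stop codon (TAA/TAG/TGA).
#
# Protospacer positions are numbered 1..20 from the PAM-distal end ("C5" is
# a cytosine at position 5). Internally all arithmetic is on 1-based sense
# coordinates of the supplied CDS; user-facing reports use the same 1-based
# inclusive convention.

TARGET_CODONS <- c("CAA", "CAG", "CGA", "TGG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Validate an editing window
#'
#' @param window Integer vector \code{c(first, last)} of protospacer
#'   positions, \code{1 <= first <= last <= 20}. The default \code{c(1, 13)}
#'   is the window observed for BE3 in \emph{Bombyx mori}; the canonical
#'   in-vitro window is \code{c(4, 8)}.
#' @return The validated integer window.
#' @export
edit_window <- function(window = c(1L, 13L)) {
  window <- as.integer(window)
  if (length(window) != 2L || anyNA(window) ||
      window[1L] < 1L || window[2L] > 20L || window[1L] > window[2L]) {
    stop("editing window must satisfy 1 <= first <= last <= 20", call. = FALSE)
  }
  window
}

#' Find all NGG protospacers in a sequence
#'
#' Returns every 20-mer lying immediately 5' of an NGG PAM, on the sense
#' strand and (by default) the antisense strand, each reported exactly once.
#' Overlapping protospacers are all reported. Protospacers containing N are
#' discarded. Sequences shorter than 23 nt yield an empty table.
#'
#' @param seq A single nucleotide string (the sense strand).
#' @param id Identifier recorded in \code{parent_id}.
#' @param both_strands Scan the antisense strand as well?
#' @return A data frame with one row per protospacer: \code{parent_id},
#'   \code{strand} (+/-, relative to the supplied sense strand),
#'   \code{start} (sense-strand position of protospacer base 1, the
#'   PAM-distal end), \code{span_start}/\code{span_end} (sense-strand extent
#'   of the 20-mer), \code{spacer} (5'->3' on the protospacer strand) and
#'   \code{pam}. Ordered by \code{span_start}, then strand.
#' @export
find_protospacers <- function(seq, id = "seq", both_strands = TRUE) {
  seq <- normalize_bases(seq, ids = id)
  L <- nchar(seq)
  empty <- data.frame(parent_id = character(0), strand = character(0),
                      start = integer(0), span_start = integer(0),
                      span_end = integer(0), spacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE)
  if (L < 23L) return(empty)

  rows <- list()
  gg <- as.integer(gregexpr("(?=GG)", seq, perl = TRUE)[[1L]])
  gg <- gg[gg >= 22L]  # GG at m => PAM is (m-1, m, m+1), spacer (m-21 .. m-2)
  if (length(gg)) {
    spacer <- substring(seq, gg - 21L, gg - 2L)
    keep <- !grepl("N", spacer, fixed = TRUE)
    if (any(keep)) {
      m <- gg[keep]
      rows[[1L]] <- data.frame(
        parent_id = id, strand = "+", start = m - 21L,
        span_start = m - 21L, span_end = m - 2L,
        spacer = spacer[keep], pam = substring(seq, m - 1L, m + 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (both_strands) {
    cc <- as.integer(gregexpr("(?=CC)", seq, perl = TRUE)[[1L]])
    cc <- cc[cc > 0L & cc + 22L <= L]  # CC at m => PAM sense (m..m+2), spacer (m+3 .. m+22)
    if (length(cc)) {
      sense_slice <- substring(seq, cc + 3L, cc + 22L)
      keep <- !grepl("N", sense_slice, fixed = TRUE)
      if (any(keep)) {
        m <- cc[keep]
        rows[[2L]] <- data.frame(
          parent_id = id, strand = "-", start = m + 22L,
          span_start = m + 3L, span_end = m + 22L,
          spacer = reverse_complement(sense_slice[keep]),
          pam = reverse_complement(substring(seq, m, m + 2L)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$span_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate stop-codon conversions of a codon
#'
#' Lists every way a set of same-strand C-to-T deaminations turns a codon
#' into TAA, TAG or TGA: sense-strand Cs for a plus-strand protospacer, or
#' sense-strand Gs (antisense Cs, edited G-to-A on the sense strand) for a
#' minus-strand protospacer. Over all 64 codons, exactly CAA, CAG, CGA and
#' TGG admit at least one route.
#'
#' @param codon A 3-nt string over \code{A,C,G,T} (codons containing N are
#'   untargetable and yield no routes). Codons that are already stop codons
#'   yield no routes: no premature stop can be introduced into them.
#' @return A data frame with columns \code{strand}, \code{positions}
#'   (list column of edited codon positions, 1..3) and \code{stop}.
#' @examples
#' stop_codon_conversions("CAA")  # + strand, position 1 -> TAA
#' stop_codon_conversions("TGG")  # three antisense routes
#' @export
stop_codon_conversions <- function(codon) {
  codon <- normalize_bases(codon)
  if (nchar(codon) != 3L) {
    stop("codon must be exactly 3 nt, got '", codon, "'", call. = FALSE)
  }
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  res <- list()
  if (!any(chars == "N") && !codon %in% STOP_CODONS) {
    for (strand in c("+", "-")) {
      from <- if (strand == "+") "C" else "G"
      to <- if (strand == "+") "T" else "A"
      pos <- which(chars == from)
      n <- length(pos)
      if (n == 0L) next
      for (mask in seq_len(2L^n - 1L)) {
        sel <- pos[bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L]
        tmp <- chars
        tmp[sel] <- to
        cand <- paste(tmp, collapse = "")
        if (cand %in% STOP_CODONS) {
          res[[length(res) + 1L]] <-
            data.frame(strand = strand, positions = I(list(sel)),
                       stop = cand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(strand = character(0), positions = I(list()),
                      stop = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.empty_sites <- function() {
  out <- data.frame(
    gene_id = character(0), codon_index = integer(0), codon = character(0),
    resulting_stop = character(0), strand = character(0),
    proto_start = integer(0), span_start = integer(0), span_end = integer(0),
    spacer = character(0), pam = character(0), edited_positions = character(0),
    relative_position = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("knockout_sites", "data.frame")
  out
}

#' Scan one CDS for stop-codon knockout sites
#'
#' Emits a site for every (in-frame CAA/CAG/CGA/TGG codon, protospacer)
#' pair such that all codon positions that must be edited fall, as Cs on
#' the protospacer strand, inside the editing window. With
#' \code{strict_window = TRUE} the whole codon must additionally lie inside
#' the window (a stricter reading of "motif at positions first..last").
#' The scan operates on the supplied CDS only; protospacers extending past
#' its ends are not searched, so sites spanning splice junctions are missed.
#'
#' @param seq The coding sequence (sense strand). Must be frame-valid
#'   (non-empty length divisible by 3), otherwise an error names the gene.
#' @param gene_id Identifier recorded in the output.
#' @param window Editing window, see \code{\link{edit_window}}.
#' @param strict_window Require the whole codon inside the window?
#' @return A \code{knockout_sites} data frame; one row per
#'   (codon, protospacer, resulting stop) route, with \code{edited_positions}
#'   the comma-joined protospacer positions whose C-to-T edits produce the
#'   stop, and \code{relative_position} = codon_index / total codons.
#' @export
scan_cds <- function(seq, gene_id = "cds", window = c(1L, 13L),
                     strict_window = FALSE) {
  seq <- normalize_bases(seq, ids = gene_id)
  L <- nchar(seq)
  if (L == 0L || L %% 3L != 0L) {
    stop(sprintf("CDS '%s' is not frame-valid (length %d nt)", gene_id, L),
         call. = FALSE)
  }
  window <- edit_window(window)
  protos <- find_protospacers(seq, id = gene_id)
  n_codons <- L %/% 3L
  codons <- substring(seq, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
  hits <- which(codons %in% TARGET_CODONS)
  if (!length(hits) || !nrow(protos)) return(.empty_sites())

  rows <- list()
  for (k in hits) {
    routes <- stop_codon_conversions(codons[k])
    p0 <- 3L * (k - 1L)
    for (r in seq_len(nrow(routes))) {
      st <- routes$strand[r]
      sense_pos <- p0 + routes$positions[[r]]
      cand <- protos[protos$strand == st &
                       protos$span_start <= min(sense_pos) &
                       protos$span_end >= max(sense_pos), , drop = FALSE]
      if (!nrow(cand)) next
      for (j in seq_len(nrow(cand))) {
        protopos <- if (st == "+") {
          sense_pos - cand$span_start[j] + 1L
        } else {
          cand$span_end[j] - sense_pos + 1L
        }
        ok <- all(protopos >= window[1L] & protopos <= window[2L])
        if (ok && strict_window) {
          codon_sense <- p0 + 1:3
          cod_protopos <- if (st == "+") {
            codon_sense - cand$span_start[j] + 1L
          } else {
            cand$span_end[j] - codon_sense + 1L
          }
          ok <- all(codon_sense >= cand$span_start[j] &
                      codon_sense <= cand$span_end[j]) &&
            all(cod_protopos >= window[1L] & cod_protopos <= window[2L])
        }
        if (!ok) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, codon_index = k, codon = codons[k],
          resulting_stop = routes$stop[r], strand = st,
          proto_start = cand$start[j], span_start = cand$span_start[j],
          span_end = cand$span_end[j], spacer = cand$spacer[j],
          pam = cand$pam[j],
          edited_positions = paste(sort(protopos), collapse = ","),
          relative_position = k / n_codons,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.empty_sites())
  out <- do.call(rbind, rows)
  out <- unique(out)
  out <- out[order(out$codon_index, out$span_start, out$strand,
                   out$resulting_stop), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("knockout_sites", "data.frame")
  out
}

#' Scan a set of CDS records
#'
#' Frame-broken or empty records are skipped with a warning listing their
#' identifiers (they remain flagged in the input table).
#'
#' @param cds A \code{\link{cds_set}} data frame.
#' @inheritParams scan_cds
#' @return A \code{knockout_sites} data frame over all frame-valid records.
#' @export
scan_cds_set <- function(cds, window = c(1L, 13L), strict_window = FALSE) {
  bad <- cds$gene_id[!cds$frame_valid]
  if (length(bad)) {
    warning("skipping frame-broken CDS record(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  keep <- cds[cds$frame_valid, , drop = FALSE]
  res <- lapply(seq_len(nrow(keep)), function(i) {
    scan_cds(keep$seq[i], gene_id = keep$gene_id[i], window = window,
             strict_window = strict_window)
  })
  out <- if (length(res)) do.call(rbind, res) else .empty_sites()
  class(out) <- c("knockout_sites", "data.frame")
  out
}

# A "site" is a place you can target: unique (gene, codon, protospacer),
# counting multi-route TGG codons once. Route-level detail stays in the
# sites table.
.unique_site_key <- function(sites) {
  paste(sites$gene_id, sites$codon_index, sites$strand, sites$proto_start,
        sep = "\r")
}

#' Summarize genome-wide targetability
#'
#' Per-gene knockout-site counts and their distribution. Multi-route codons
#' (TGG) count once per (codon, protospacer) pair. The median is computed
#' over targetable genes (those with at least one site); the percentage is
#' over all supplied genes.
#'
#' @param sites A \code{knockout_sites} data frame.
#' @param all_genes Character vector of all gene identifiers scanned,
#'   including untargetable ones.
#' @return A \code{genome_summary} list with \code{total_sites},
#'   \code{targetable_genes}, \code{total_genes}, \code{percent_targetable}
#'   (1 d.p.), \code{median_sites_per_targetable_gene},
#'   \code{sites_per_gene_histogram} (count -> number of genes) and
#'   \code{relative_position_histogram} (decile x codon class).
#' @export
summarize_genome <- function(sites, all_genes) {
  all_genes <- as.character(all_genes)
  if (nrow(sites) && !all(sites$gene_id %in% all_genes)) {
    stop("sites reference gene ids absent from all_genes", call. = FALSE)
  }
  u <- sites[!duplicated(.unique_site_key(sites)), , drop = FALSE]
  counts <- table(factor(u$gene_id, levels = all_genes))
  counts <- as.integer(counts)
  targetable <- sum(counts > 0L)
  total <- length(all_genes)
  decile <- pmax(pmin(ceiling(u$relative_position * 10), 10L), 1L)
  relpos <- table(factor(decile, levels = 1:10),
                  factor(u$codon, levels = TARGET_CODONS))
  out <- list(
    total_sites = sum(counts),
    targetable_genes = targetable,
    total_genes = total,
    percent_targetable = if (total > 0L) round_half_up(100 * targetable / total, 1) else 0,
    median_sites_per_targetable_gene =
      if (targetable > 0L) stats::median(counts[counts > 0L]) else NA_real_,
    sites_per_gene_histogram = table(counts),
    relative_position_histogram = relpos
  )
  class(out) <- "genome_summary"
  out
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("Genome-wide knockout-site summary\n")
  cat(sprintf("  targetable sites : %d\n", x$total_sites))
  cat(sprintf("  targetable genes : %d of %d (%.1f%%)\n",
              x$targetable_genes, x$total_genes, x$percent_targetable))
  if (!is.na(x$median_sites_per_targetable_gene)) {
    cat(sprintf("  median sites per targetable gene: %g\n",
                x$median_sites_per_targetable_gene))
  }
  invisible(x)
}

#' Export protospacer spans as BED
#'
#' BED uses 0-based half-open coordinates; internal 1-based inclusive spans
#' are converted accordingly.
#'
#' @param sites A \code{knockout_sites} data frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
sites_to_bed <- function(sites, path) {
  bed <- data.frame(
    chrom = sites$gene_id,
    start = sites$span_start - 1L,
    end = sites$span_end,
    name = sprintf("%s_codon%d_%s>%s", sites$gene_id, sites$codon_index,
                   sites$codon, sites$resulting_stop),
    score = 0L,
    strand = sites$strand,
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
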