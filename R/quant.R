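# Amplicon deep-sequencing quantification of base-editing outcomes:
# quality trimming, paired-barcode demultiplexing, read classification by
# C:G -> T:A conversion inside the 20-bp target site, per-guide efficiency,
# per-position substitution matrices, editing-window probabilities,
# multiplex substitution counting, and indel frequency.

#' Quality-trimming parameters
#'
#' Defaults reproduce Trimmomatic's
#' \code{LEADING:3 TRAILING:3 SLIDINGWINDOW:4:15 MINLEN:50}: leading and
#' trailing bases below Q3 are removed, the read is cut at the start of the
#' first 4-base window whose mean quality falls below 15, and reads shorter
#' than 50 nt are discarded.
#'
#' @param leading_q,trailing_q Minimum quality to keep at the read ends.
#' @param window_len,window_q Sliding-window length and mean-quality cutoff.
#' @param min_len Minimum surviving read length.
#' @return A \code{trim_params} list.
#' @export
trim_params <- function(leading_q = 3, trailing_q = 3, window_len = 4,
                        window_q = 15, min_len = 50) {
  p <- list(leading_q = leading_q, trailing_q = trailing_q,
            window_len = as.integer(window_len), window_q = window_q,
            min_len = as.integer(min_len))
  if (any(vapply(p, function(v) is.na(v) || v < 0, logical(1)))) {
    stop("trimming parameters must be non-negative", call. = FALSE)
  }
  class(p) <- "trim_params"
  p
}

#' Quality-trim reads
#'
#' Applies, in order: removal of leading/trailing bases below the end
#' quality cutoffs; a 5'->3' sliding window cut at the start of the first
#' window of \code{window_len} bases whose mean quality is below
#' \code{window_q}; and a minimum-length filter. Trimmed reads are always
#' contiguous substrings of the input (no bases reordered).
#'
#' @param reads A \code{\link{fastq_reads}} data frame.
#' @param params A \code{\link{trim_params}} list.
#' @return A list with \code{reads} (surviving, trimmed), \code{n_input},
#'   \code{n_discarded} and \code{discarded_ids}.
#' @export
trim_reads <- function(reads, params = trim_params()) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(reads = reads, n_input = 0L, n_discarded = 0L,
                discarded_ids = character(0)))
  }
  quals <- phred_decode(reads$qual)
  from <- integer(n); to <- integer(n); keep <- logical(n)
  for (i in seq_len(n)) {
    q <- quals[[i]]
    len <- length(q)
    a <- 1L
    while (a <= len && q[a] < params$leading_q) a <- a + 1L
    b <- len
    while (b >= a && q[b] < params$trailing_q) b <- b - 1L
    if (a <= b) {
      qs <- q[a:b]
      m <- length(qs)
      if (m >= params$window_len) {
        cs <- cumsum(c(0, qs))
        w <- params$window_len
        means <- (cs[(w + 1L):(m + 1L)] - cs[1:(m - w + 1L)]) / w
        cut <- which(means < params$window_q)
        if (length(cut)) b <- a + cut[1L] - 2L
      }
    }
    keep[i] <- a <= b && (b - a + 1L) >= params$min_len
    from[i] <- a; to[i] <- b
  }
  kept <- reads[keep, , drop = FALSE]
  kept$bases <- substring(kept$bases, from[keep], to[keep])
  kept$qual <- substring(kept$qual, from[keep], to[keep])
  rownames(kept) <- NULL
  list(reads = kept, n_input = n, n_discarded = sum(!keep),
       discarded_ids = reads$id[!keep])
}

#' Demultiplex reads by paired barcodes
#'
#' Each sample corresponds to a unique (left prefix, right suffix) barcode
#' pair. Assignment is exact-match on both barcodes jointly (0 mismatches);
#' reads matching neither, or only one, barcode of a pair are counted as
#' unassigned. Barcodes are stripped from assigned reads.
#'
#' @param reads A \code{\link{fastq_reads}} data frame.
#' @param barcode_map Data frame with columns \code{sample_id}, \code{left},
#'   \code{right}. Barcodes must be fixed-length within each side and the
#'   pairs unique.
#' @return A list with \code{samples} (named list of read tables, barcodes
#'   stripped), \code{unassigned} (read table) and \code{counts}.
#' @export
demultiplex <- function(reads, barcode_map) {
  stopifnot(all(c("sample_id", "left", "right") %in% names(barcode_map)))
  key_map <- paste(barcode_map$left, barcode_map$right, sep = "\r")
  if (anyDuplicated(key_map)) {
    stop("duplicate barcode pair in barcode map", call. = FALSE)
  }
  ll <- unique(nchar(barcode_map$left))
  rl <- unique(nchar(barcode_map$right))
  if (length(ll) != 1L || length(rl) != 1L) {
    stop("barcodes must be fixed-length within each side", call. = FALSE)
  }
  len <- nchar(reads$bases)
  long_enough <- len >= ll + rl + 1L
  key_reads <- rep(NA_character_, nrow(reads))
  key_reads[long_enough] <- paste(
    substring(reads$bases[long_enough], 1L, ll),
    substring(reads$bases[long_enough], len[long_enough] - rl + 1L,
              len[long_enough]),
    sep = "\r")
  m <- match(key_reads, key_map)
  samples <- lapply(seq_len(nrow(barcode_map)), function(j) {
    r <- reads[which(m == j), , drop = FALSE]
    n <- nchar(r$bases)
    r$bases <- substring(r$bases, ll + 1L, n - rl)
    r$qual <- substring(r$qual, ll + 1L, n - rl)
    rownames(r) <- NULL
    r
  })
  names(samples) <- barcode_map$sample_id
  unassigned <- reads[is.na(m), , drop = FALSE]
  rownames(unassigned) <- NULL
  counts <- c(vapply(samples, nrow, integer(1)),
              unassigned = nrow(unassigned))
  list(samples = samples, unassigned = unassigned, counts = counts)
}

#' Define a gRNA target site on an amplicon reference
#'
#' Records where a protospacer sits on the amplicon and which protospacer
#' positions carry a C on the protospacer strand (the editable positions).
#' For a minus-strand site those are Gs on the amplicon reference, read as
#' G-to-A conversions.
#'
#' @param gRNA_id Identifier.
#' @param reference The amplicon reference sequence (plus strand).
#' @param proto_start Amplicon position of protospacer base 1 (the
#'   PAM-distal end): the 5' end of the 20-mer for a plus-strand site, the
#'   3'-most sense position for a minus-strand site.
#' @param strand "+" or "-".
#' @param amplicon_id Optional amplicon identifier.
#' @return A \code{target_site} list with \code{spacer}, \code{pam},
#'   \code{c_positions} (protospacer positions 1..20 holding C) and
#'   \code{amp_positions} (amplicon coordinate of each protospacer
#'   position).
#' @export
target_site <- function(gRNA_id, reference, proto_start, strand = "+",
                        amplicon_id = "amplicon") {
  reference <- normalize_bases(reference)
  L <- nchar(reference)
  proto_start <- as.integer(proto_start)
  if (strand == "+") {
    amp_positions <- proto_start + 0:19
    pam_span <- proto_start + 20:22
  } else if (strand == "-") {
    amp_positions <- proto_start - 0:19
    pam_span <- proto_start - 20:22
  } else stop("strand must be '+' or '-'", call. = FALSE)
  if (min(amp_positions, pam_span) < 1L || max(amp_positions, pam_span) > L) {
    stop(sprintf("target site '%s' lies outside the amplicon (1..%d)",
                 gRNA_id, L), call. = FALSE)
  }
  slice <- function(pos) paste(strsplit(reference, "", fixed = TRUE)[[1L]][pos],
                               collapse = "")
  spacer <- if (strand == "+") slice(amp_positions) else
    reverse_complement(slice(rev(amp_positions)))
  pam <- if (strand == "+") slice(pam_span) else
    reverse_complement(slice(rev(pam_span)))
  if (substring(pam, 2L, 3L) != "GG") {
    warning(sprintf("site '%s': PAM '%s' is not NGG", gRNA_id, pam),
            call. = FALSE)
  }
  cpos <- which(strsplit(spacer, "", fixed = TRUE)[[1L]] == "C")
  out <- list(gRNA_id = gRNA_id, amplicon_id = amplicon_id, strand = strand,
              proto_start = proto_start, spacer = spacer, pam = pam,
              c_positions = cpos, amp_positions = amp_positions)
  class(out) <- "target_site"
  out
}

# Shared classification core: which reads cover [span_lo, span_hi] of the
# reference, and which of the targeted (amplicon position, edited base)
# events each read shows. Reads are deduplicated before alignment.
.classify_core <- function(bases, reference, tpos, tchar, span_lo, span_hi) {
  n <- length(bases)
  nt <- length(tpos)
  if (n == 0L) {
    return(list(covers = logical(0), indel = logical(0),
                conv = matrix(logical(0), 0L, nt)))
  }
  ub <- unique(bases)
  idx <- match(bases, ub)
  al <- align_reads(ub, reference)
  covers_u <- al$start <= span_lo & al$end >= span_hi
  conv_u <- matrix(FALSE, length(ub), nt)
  for (i in seq_along(ub)) {
    ch <- .read_chars_at(ub[i], al$pattern[i], al$subject[i],
                         al$start[i], al$end[i], tpos)
    conv_u[i, ] <- !is.na(ch) & ch == tchar
  }
  list(covers = covers_u[idx], indel = al$indel[idx],
       conv = conv_u[idx, , drop = FALSE])
}

#' Classify reads at a target site
#'
#' Each read is aligned to the amplicon reference and classified as
#' \code{not_covering} (alignment does not span the full 20-bp protospacer),
#' \code{edited} (at least one targeted C shows the C-to-T conversion, in
#' protospacer-strand orientation: T at a plus-strand C, A at a minus-strand
#' G) or \code{unedited}. Substitutions other than the targeted C-to-T do
#' not make a read edited.
#'
#' @param reads A \code{\link{fastq_reads}} data frame (already trimmed) or
#'   a character vector of read sequences.
#' @param reference The amplicon reference sequence.
#' @param site A \code{\link{target_site}}.
#' @return A data frame with one row per read: \code{status} (factor:
#'   edited / unedited / not_covering), \code{n_converted}, \code{indel},
#'   plus a logical matrix attribute \code{"conversions"} (read x targeted
#'   C position).
#' @export
classify_reads <- function(reads, reference, site) {
  bases <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  reference <- normalize_bases(reference)
  tpos <- site$amp_positions[site$c_positions]
  tchar <- if (site$strand == "+") "T" else "A"
  refc <- strsplit(reference, "", fixed = TRUE)[[1L]]
  want <- if (site$strand == "+") "C" else "G"
  if (length(tpos) && !all(refc[tpos] == want)) {
    stop(sprintf("site '%s' is inconsistent with the amplicon reference",
                 site$gRNA_id), call. = FALSE)
  }
  span <- range(site$amp_positions)
  cl <- .classify_core(bases, reference, tpos, tchar, span[1L], span[2L])
  n_conv <- if (ncol(cl$conv)) rowSums(cl$conv) else rep(0L, length(bases))
  status <- ifelse(!cl$covers, "not_covering",
                   ifelse(n_conv > 0L, "edited", "unedited"))
  out <- data.frame(
    status = factor(status, levels = c("edited", "unedited", "not_covering")),
    n_converted = as.integer(n_conv),
    indel = cl$indel)
  if (is.data.frame(reads)) out <- cbind(id = reads$id, out)
  colnames(cl$conv) <- site$c_positions
  attr(out, "conversions") <- cl$conv
  out
}

#' Quantify editing in one demultiplexed sample
#'
#' Optionally trims, then classifies every read at the sample's target
#' site and tallies clean/edited/indel counts and per-position conversion
#' counts. Classification is conservative: edited + unedited + not_covering
#' equals the number of clean reads.
#'
#' @param reads A \code{\link{fastq_reads}} data frame for one sample
#'   (barcodes already stripped).
#' @param reference The amplicon reference sequence.
#' @param site A \code{\link{target_site}}.
#' @param trim A \code{\link{trim_params}} list, or NULL if the reads are
#'   already quality-trimmed.
#' @return A \code{sample_edit_stats} list: \code{gRNA_id}, \code{n_raw},
#'   \code{n_clean}, \code{n_edited}, \code{n_unedited},
#'   \code{n_not_covering}, \code{n_indel}, \code{per_position_edited}
#'   (length-20 integer vector, NA at positions without a C) and the
#'   \code{site}.
#' @export
quantify_sample <- function(reads, reference, site, trim = NULL) {
  n_raw <- nrow(reads)
  if (!is.null(trim)) {
    reads <- trim_reads(reads, trim)$reads
  }
  n_clean <- nrow(reads)
  cl <- classify_reads(reads, reference, site)
  conv <- attr(cl, "conversions")
  covering <- cl$status != "not_covering"
  per_pos <- rep(NA_integer_, 20L)
  if (length(site$c_positions)) {
    per_pos[site$c_positions] <-
      as.integer(colSums(conv[covering, , drop = FALSE]))
  }
  out <- list(
    gRNA_id = site$gRNA_id,
    n_raw = n_raw,
    n_clean = n_clean,
    n_edited = sum(cl$status == "edited"),
    n_unedited = sum(cl$status == "unedited"),
    n_not_covering = sum(cl$status == "not_covering"),
    n_indel = sum(cl$indel),
    per_position_edited = per_pos,
    site = site)
  class(out) <- "sample_edit_stats"
  out
}

#' @export
print.sample_edit_stats <- function(x, ...) {
  cat(sprintf("Sample '%s': %d clean reads, %d edited (%.1f%%), %d indel\n",
              x$gRNA_id, x$n_clean, x$n_edited,
              ifelse(x$n_clean > 0, 100 * x$n_edited / x$n_clean, NA),
              x$n_indel))
  invisible(x)
}

#' Editing efficiency of a sample
#'
#' The proportion of reads with at least one targeted C:G -> T:A conversion
#' among all clean reads, as a percentage to 1 decimal place.
#'
#' @param stats A \code{sample_edit_stats} list from
#'   \code{\link{quantify_sample}}.
#' @return Percentage (0..100, 1 d.p.), or NA when there are no clean reads.
#' @export
compute_efficiency <- function(stats) {
  if (stats$n_clean == 0L) return(NA_real_)
  round_half_up(100 * stats$n_edited / stats$n_clean, 1)
}

#' Per-position substitution matrix for a gRNA panel
#'
#' @param stats_list List of \code{sample_edit_stats}, one per gRNA.
#' @return A numeric matrix (gRNA x protospacer position 1..20) of the
#'   fraction of clean reads converted at each position; NA where the gRNA
#'   carries no C. All entries lie in [0, 1] or are NA.
#' @export
per_position_matrix <- function(stats_list) {
  mat <- t(vapply(stats_list, function(s) {
    if (s$n_clean > 0L) s$per_position_edited / s$n_clean
    else rep(NA_real_, 20L)
  }, numeric(20L)))
  rownames(mat) <- vapply(stats_list, function(s) s$gRNA_id, character(1))
  colnames(mat) <- paste0("C", 1:20)
  mat
}

#' Editing-window probability profile
#'
#' For each protospacer position n, counts the designed gRNAs carrying a C
#' at n and those whose observed per-position conversion fraction exceeds
#' the detection threshold; their ratio estimates the probability that a C
#' at position n is edited. With a control sample, the threshold at each
#' position is \code{max(detection_threshold, 3 * control rate)} to
#' separate editing signal from sequencing error.
#'
#' @param mat Matrix from \code{\link{per_position_matrix}}.
#' @param detection_threshold Minimum conversion fraction to call a
#'   position substituted (default 0.005, i.e. 0.5\%).
#' @param control_rates Optional length-20 vector of per-position
#'   conversion fractions in an unedited control.
#' @return An \code{editing_window_profile} list with per-position
#'   \code{designed}, \code{edited}, \code{probability} (NA where no gRNA
#'   carries a C) and the thresholds used.
#' @export
window_profile <- function(mat, detection_threshold = 0.005,
                           control_rates = NULL) {
  thr <- rep(detection_threshold, 20L)
  if (!is.null(control_rates)) {
    stopifnot(length(control_rates) == 20L)
    thr <- pmax(thr, 3 * ifelse(is.na(control_rates), 0, control_rates))
  }
  designed <- unname(colSums(!is.na(mat)))
  edited <- vapply(1:20, function(j) {
    sum(!is.na(mat[, j]) & mat[, j] >= thr[j])
  }, numeric(1))
  prob <- ifelse(designed > 0, edited / designed, NA_real_)
  out <- list(position = 1:20, designed = as.integer(designed),
              edited = as.integer(edited), probability = prob,
              threshold = thr)
  class(out) <- "editing_window_profile"
  out
}

#' @export
print.editing_window_profile <- function(x, ...) {
  cat("Editing-window probability profile (C1..C20)\n")
  df <- data.frame(position = x$position, designed = x$designed,
                   edited = x$edited, probability = round(x$probability, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.editing_window_profile <- function(x, ...) {
  p <- ifelse(is.na(x$probability), 0, x$probability)
  graphics::barplot(p, names.arg = paste0("C", x$position), las = 2,
                    ylab = "P(substitution | C at position)",
                    xlab = "protospacer position",
                    col = ifelse(is.na(x$probability), "grey85", "steelblue"),
                    ...)
  invisible(x)
}

#' Multiplex substitution histogram
#'
#' For pooled-guide experiments: counts, per read, how many distinct
#' targeted C positions (the union over all sites; shared positions count
#' once) show the C-to-T conversion, and tabulates reads by that number k.
#' Reads whose alignment does not span all targeted positions are excluded
#' and reported separately.
#'
#' @param reads A \code{\link{fastq_reads}} data frame (trimmed) or
#'   character vector of read sequences.
#' @param reference The common amplicon reference.
#' @param sites List of \code{\link{target_site}} objects on this
#'   reference.
#' @return A \code{multiplex_histogram} list: \code{counts} (named vector
#'   over k = 0..max), \code{n_reads}, \code{n_not_covering},
#'   \code{n_targeted_positions} and \code{max_k}.
#' @export
multiplex_histogram <- function(reads, reference, sites) {
  bases <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  reference <- normalize_bases(reference)
  tab <- unique(do.call(rbind, lapply(sites, function(s) {
    data.frame(pos = s$amp_positions[s$c_positions],
               char = if (s$strand == "+") "T" else "A",
               stringsAsFactors = FALSE)
  })))
  if (anyDuplicated(tab$pos)) {
    stop("conflicting targeted bases at one amplicon position", call. = FALSE)
  }
  span <- range(tab$pos)
  cl <- .classify_core(bases, reference, tab$pos, tab$char, span[1L], span[2L])
  k <- rowSums(cl$conv[cl$covers, , drop = FALSE])
  max_k <- if (length(k)) max(k) else 0L
  counts <- tabulate(factor(k, levels = 0:max_k), nbins = max_k + 1L)
  names(counts) <- 0:max_k
  out <- list(counts = counts, n_reads = length(k),
              n_not_covering = sum(!cl$covers),
              n_targeted_positions = nrow(tab), max_k = as.integer(max_k))
  class(out) <- "multiplex_histogram"
  out
}

#' @export
print.multiplex_histogram <- function(x, ...) {
  cat(sprintf(
    "Multiplex substitutions: %d reads over %d targeted positions, max %d per read\n",
    x$n_reads, x$n_targeted_positions, x$max_k))
  print(x$counts)
  invisible(x)
}

#' @export
plot.multiplex_histogram <- function(x, log = "", ...) {
  graphics::barplot(x$counts, xlab = "substituted positions per read",
                    ylab = "reads", col = "firebrick", log = log, ...)
  invisible(x)
}

#' Indel frequency among clean reads
#'
#' Each read is globally aligned to the amplicon reference with affine gap
#' costs; a read is an indel read iff its best alignment contains at least
#' one internal gap (terminal gaps from incomplete coverage are not
#' counted).
#'
#' @param reads A \code{\link{fastq_reads}} data frame (trimmed) or
#'   character vector of read sequences.
#' @param reference The amplicon reference sequence (non-empty).
#' @return A list with \code{percent} (1 d.p.), \code{n_indel},
#'   \code{n_reads} and per-read logical \code{flags}.
#' @export
indel_frequency <- function(reads, reference) {
  bases <- if (is.data.frame(reads)) reads$bases else as.character(reads)
  reference <- normalize_bases(reference)
  if (nchar(reference) == 0L) stop("empty reference sequence", call. = FALSE)
  if (!length(bases)) {
    return(list(percent = NA_real_, n_indel = 0L, n_reads = 0L,
                flags = logical(0)))
  }
  ub <- unique(bases)
  idx <- match(bases, ub)
  al <- align_reads(ub, reference)
  flags <- al$indel[idx]
  list(percent = round_half_up(100 * sum(flags) / length(flags), 1),
       n_indel = sum(flags), n_reads = length(flags), flags = flags)
}

#' Clone-level knockout efficiency
#'
#' The percentage of sequenced clones carrying the intended mutation,
#' reported the way clone counts are conventionally printed: truncated to
#' one decimal place (7/12 -> 58.3, 3/11 -> 27.2, 2/5 -> 40.0,
#' 21/41 -> 51.2).
#'
#' @param n_mut Number of mutant clones (0 <= n_mut <= n_total).
#' @param n_total Number of clones examined (> 0).
#' @return Percentage truncated to 1 d.p.; NA when n_total is 0.
#' @export
clone_efficiency <- function(n_mut, n_total) {
  if (length(n_mut) != 1L || length(n_total) != 1L ||
      is.na(n_mut) || is.na(n_total) || n_mut < 0 || n_mut > n_total) {
    stop("need 0 <= n_mut <= n_total", call. = FALSE)
  }
  if (n_total == 0) return(NA_real_)
  trunc_decimal(100 * n_mut / n_total, 1)
}
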