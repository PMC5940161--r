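# Seeded generators for every input the pipeline needs: coding sequences
# with planted knockout sites, and barcoded amplicon reads with specified
# per-position editing probabilities, indel rates and sequencing error.
# Identical seeds yield byte-identical output.

.BASES <- c("A", "C", "G", "T")

.random_codons <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(.BASES, 3L, replace = TRUE, prob = p), collapse = "")
      if (!cod %in% STOP_CODONS) break
    }
    out[i] <- cod
  }
  out
}

# Geometry of a planted site: which sequence positions must be locked so
# that the editable C of `codon` sits at protospacer position `proto_pos`
# of a real NGG protospacer.
.plant_geometry <- function(codon, proto_pos, p, L) {
  w <- as.integer(proto_pos)
  if (w < 1L || w > 20L) stop("proto_pos must be in 1..20", call. = FALSE)
  if (codon %in% c("CAA", "CAG", "CGA")) {
    # plus strand: codon C at sense position p, PAM GG at (p-w+22, p-w+23)
    stopifnot(codon %in% TARGET_CODONS)
    stop_codon <- c(CAA = "TAA", CAG = "TAG", CGA = "TGA")[[codon]]
    lock_pos <- c(p - w + 22L, p - w + 23L)
    feasible <- p >= w && (p - w + 23L) <= L - 3L
    list(strand = "+", stop = stop_codon, sense_c = p,
         lock_pos = lock_pos, lock_base = c("G", "G"),
         proto_start = p - w + 1L, feasible = feasible)
  } else if (codon == "TGG") {
    # minus strand: edit the sense G at codon position 2; PAM is CC on the
    # sense strand upstream of the protospacer span
    g <- p + 1L
    s1 <- g + w - 1L
    lock_pos <- c(s1 - 22L, s1 - 21L)
    feasible <- (s1 - 22L) >= 4L && s1 <= L - 3L
    list(strand = "-", stop = "TAG", sense_c = g,
         lock_pos = lock_pos, lock_base = c("C", "C"),
         proto_start = s1, feasible = feasible)
  } else {
    stop("planted codon must be one of CAA, CAG, CGA, TGG", call. = FALSE)
  }
}

#' Generate a synthetic CDS set with planted knockout sites
#'
#' Each generated CDS starts with ATG, ends with a stop codon, contains no
#' internal stop codon and has length divisible by 3. Planted codons appear
#' at recorded in-frame positions with an NGG PAM placing the editable C at
#' the recorded protospacer position. Incidental targetable sites arise
#' naturally in the random background and are allowed: oracle comparisons
#' should use full enumeration, not the truth table alone.
#'
#' @param n_genes Number of genes.
#' @param length_codons Length range (codons), minimum 10.
#' @param planted Optional data frame with columns \code{gene} (1-based
#'   gene index), \code{codon} (CAA/CAG/CGA/TGG) and \code{proto_pos}
#'   (protospacer position, 1..20, of the editable C); optionally
#'   \code{codon_index} (NA picks a random feasible in-frame position).
#' @param background_gc Background GC content of the random codons.
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @param max_retries Attempts at resolving planting collisions before
#'   declaring the spec infeasible.
#' @return A list with \code{cds} (a \code{\link{cds_set}}) and
#'   \code{truth} (one row per planted site: gene_id, codon_index, codon,
#'   strand, proto_pos, proto_start, resulting_stop, sense_c_pos).
#' @export
generate_cds_set <- function(n_genes = 20L, length_codons = c(100L, 400L),
                             planted = NULL, background_gc = 0.4,
                             seed = 1L, max_retries = 50L) {
  stopifnot(n_genes >= 0L, length_codons[1L] >= 10L,
            length_codons[1L] <= length_codons[2L])
  with_seed(seed, {
    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    seqs <- character(n_genes)
    truth <- list()
    for (gi in seq_len(n_genes)) {
      n_cod <- sample1(length_codons[1L]:length_codons[2L])
      L <- 3L * n_cod
      plants <- if (!is.null(planted)) {
        planted[planted$gene == gi, , drop = FALSE]
      } else planted
      lock_pos <- integer(0); lock_base <- character(0)
      plant_rows <- list()
      used_codons <- c(1L, n_cod)
      if (!is.null(plants) && nrow(plants)) {
        for (r in seq_len(nrow(plants))) {
          codon <- normalize_bases(plants$codon[r])
          w <- plants$proto_pos[r]
          want_k <- if ("codon_index" %in% names(plants)) plants$codon_index[r] else NA
          placed <- FALSE
          for (try in seq_len(max_retries)) {
            k <- if (!is.na(want_k)) want_k else
              sample1(2:(n_cod - 1L))
            if (k %in% used_codons) {
              if (!is.na(want_k)) break else next
            }
            p <- 3L * k - 2L
            geo <- .plant_geometry(codon, w, p, L)
            if (!geo$feasible) {
              if (!is.na(want_k)) break else next
            }
            new_lock <- c(p + 0:2, geo$lock_pos)
            if (any(new_lock %in% lock_pos)) {
              if (!is.na(want_k)) break else next
            }
            lock_pos <- c(lock_pos, new_lock)
            lock_base <- c(lock_base,
                           strsplit(codon, "", fixed = TRUE)[[1L]],
                           geo$lock_base)
            used_codons <- c(used_codons, k)
            plant_rows[[length(plant_rows) + 1L]] <- data.frame(
              gene_id = gene_ids[gi], codon_index = k, codon = codon,
              strand = geo$strand, proto_pos = w,
              proto_start = geo$proto_start, resulting_stop = geo$stop,
              sense_c_pos = geo$sense_c, stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed) {
            stop(sprintf(
              "infeasible planting spec for gene %d (codon %s at C%d)",
              gi, codon, w), call. = FALSE)
          }
        }
      }
      codons <- .random_codons(n_cod, background_gc)
      codons[1L] <- "ATG"
      codons[n_cod] <- sample(STOP_CODONS, 1L)
      for (pr in plant_rows) {
        codons[pr$codon_index] <- pr$codon
      }
      chars <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
      chars[lock_pos] <- lock_base
      # PAM locks may have cut across background codons; repair any internal
      # stop codon they created by resampling its unlocked positions
      for (j in 2:(n_cod - 1L)) {
        idx <- (3L * j - 2L):(3L * j)
        free <- setdiff(idx, lock_pos)
        tries <- 0L
        while (paste(chars[idx], collapse = "") %in% STOP_CODONS) {
          if (!length(free) || tries >= max_retries) {
            stop(sprintf("infeasible planting spec for gene %d: %s",
                         gi, "locked bases force an internal stop codon"),
                 call. = FALSE)
          }
          chars[free] <- sample(.BASES, length(free), replace = TRUE)
          tries <- tries + 1L
        }
      }
      seqs[gi] <- paste(chars, collapse = "")
      truth <- c(truth, plant_rows)
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
      gene_id = character(0), codon_index = integer(0), codon = character(0),
      strand = character(0), proto_pos = integer(0), proto_start = integer(0),
      resulting_stop = character(0), sense_c_pos = integer(0),
      stringsAsFactors = FALSE)
    list(cds = cds_set(gene_ids, seqs), truth = truth_df)
  })
}

#' Random protospacer sequence with Cs at chosen positions
#'
#' All other positions are drawn from A/G/T so the editable C content is
#' exactly the requested set; useful for building controlled amplicons.
#'
#' @param c_at Integer positions (1..20) to hold C.
#' @param length Spacer length.
#' @return A nucleotide string.
#' @export
random_spacer <- function(c_at = integer(0), length = 20L) {
  ch <- sample(c("A", "G", "T"), length, replace = TRUE)
  ch[c_at] <- "C"
  paste(ch, collapse = "")
}

#' Build an amplicon reference around one protospacer
#'
#' Embeds \code{spacer + pam} (or its reverse complement for a minus-strand
#' site) between random flanks and returns the reference together with the
#' corresponding \code{\link{target_site}}.
#'
#' @param spacer 20-nt protospacer sequence (protospacer strand).
#' @param pam 3-nt PAM (NGG).
#' @param strand "+" or "-".
#' @param flank Flank length on each side.
#' @param gc Flank GC content.
#' @param gRNA_id Identifier for the site.
#' @return A list with \code{reference} and \code{site}.
#' @export
make_amplicon <- function(spacer, pam = "AGG", strand = "+", flank = 80L,
                          gc = 0.5, gRNA_id = "gRNA1") {
  spacer <- normalize_bases(spacer)
  pam <- normalize_bases(pam)
  stopifnot(nchar(spacer) == 20L, nchar(pam) == 3L)
  fl <- random_dna(1L, flank, gc)
  fr <- random_dna(1L, flank, gc)
  if (strand == "+") {
    reference <- paste0(fl, spacer, pam, fr)
    proto_start <- flank + 1L
  } else {
    reference <- paste0(fl, reverse_complement(pam),
                        reverse_complement(spacer), fr)
    proto_start <- flank + 3L + 20L
  }
  list(reference = reference,
       site = target_site(gRNA_id, reference, proto_start, strand))
}

#' Build one amplicon carrying several tiled protospacers
#'
#' Concatenates \code{spacer+PAM} blocks between random flanks, as in
#' pooled-guide (multiplex) experiments on a single region.
#'
#' @param spacers Character vector of 20-nt spacers (plus strand).
#' @param pam PAM appended to each spacer.
#' @param flank Flank length on each side.
#' @param gc Flank GC content.
#' @return A list with \code{reference} and \code{sites} (list of
#'   \code{\link{target_site}}).
#' @export
make_tiled_amplicon <- function(spacers, pam = "AGG", flank = 30L, gc = 0.5) {
  spacers <- normalize_bases(spacers)
  stopifnot(all(nchar(spacers) == 20L))
  fl <- random_dna(1L, flank, gc)
  fr <- random_dna(1L, flank, gc)
  body <- paste(vapply(spacers, function(s) paste0(s, pam), character(1)),
                collapse = "")
  reference <- paste0(fl, body, fr)
  starts <- flank + 1L + (seq_along(spacers) - 1L) * (20L + nchar(pam))
  sites <- lapply(seq_along(spacers), function(i) {
    target_site(sprintf("gRNA%02d", i), reference, starts[i], "+")
  })
  list(reference = reference, sites = sites)
}

#' Simulate amplicon reads for one sample
#'
#' Per read, independently per targeted position, applies the C-to-T (or
#' G-to-A) conversion with its stated probability; with probability
#' \code{indel_prob} applies one contiguous insertion or deletion of
#' uniform size at a uniform position; applies uniform substitution
#' sequencing errors; then attaches the barcodes. Qualities are constant
#' Q35 unless 3' degradation is enabled. Editing events are independent
#' across positions and reads. The truth table records every applied event.
#'
#' @param reference Amplicon reference sequence (the read template).
#' @param edits Data frame with columns \code{pos} (reference position),
#'   \code{to} (edited base) and \code{prob}. Build from a site with
#'   \code{\link{site_edits}}.
#' @param depth Number of reads.
#' @param indel_prob Per-read probability of one indel.
#' @param indel_len Inclusive range of indel lengths.
#' @param subst_error Per-base substitution error probability.
#' @param left_bc,right_bc Barcodes attached as prefix/suffix ("" for none).
#' @param id_prefix Read-id prefix.
#' @param degrade_3prime Linearly degrade qualities toward the 3' end
#'   (Q35 down to Q10 over the final 50 bases), to exercise trimming.
#' @param seed RNG seed, or NULL to use the current RNG state.
#' @return A list with \code{reads} (a \code{\link{fastq_reads}}) and
#'   \code{truth} (per read: edited positions, error count, indel flag).
#' @export
simulate_sample_reads <- function(reference, edits, depth,
                                  indel_prob = 0, indel_len = c(1L, 10L),
                                  subst_error = 0.001,
                                  left_bc = "", right_bc = "",
                                  id_prefix = "r", degrade_3prime = FALSE,
                                  seed = NULL) {
  run <- function() {
    .simulate_sample_reads(reference, edits, depth, indel_prob, indel_len,
                           subst_error, left_bc, right_bc, id_prefix,
                           degrade_3prime)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

.simulate_sample_reads <- function(reference, edits, depth, indel_prob,
                                   indel_len, subst_error, left_bc, right_bc,
                                   id_prefix, degrade_3prime) {
  reference <- normalize_bases(reference)
  template <- strsplit(reference, "", fixed = TRUE)[[1L]]
  L <- length(template)
  stopifnot(depth >= 0L, all(edits$prob >= 0 & edits$prob <= 1),
            indel_prob >= 0, indel_prob <= 1)
  if (nrow(edits) && (min(edits$pos) < 1L || max(edits$pos) > L)) {
    stop("edit positions outside the reference", call. = FALSE)
  }
  ne <- nrow(edits)
  base_qual <- rep(35L, L)
  if (degrade_3prime) {
    tail_len <- min(50L, L)
    ramp <- round(seq(35L, 10L, length.out = tail_len))
    base_qual[(L - tail_len + 1L):L] <- ramp
  }
  ids <- sprintf("%s%06d", id_prefix, seq_len(depth))
  bases <- character(depth)
  qual <- character(depth)
  edited_pos <- character(depth)
  n_edits <- integer(depth)
  n_errors <- integer(depth)
  indel <- logical(depth)
  indel_type <- rep(NA_character_, depth)
  indel_size <- rep(NA_integer_, depth)
  bq <- phred_encode(base_qual)
  lq <- phred_encode(rep(35L, nchar(left_bc)))
  rq <- phred_encode(rep(35L, nchar(right_bc)))
  for (i in seq_len(depth)) {
    ch <- template
    qv <- base_qual
    if (ne) {
      conv <- stats::runif(ne) < edits$prob
      if (any(conv)) ch[edits$pos[conv]] <- edits$to[conv]
      edited_pos[i] <- paste(edits$pos[conv], collapse = ";")
      n_edits[i] <- sum(conv)
    }
    if (subst_error > 0) {
      errs <- which(stats::runif(L) < subst_error)
      for (e in errs) ch[e] <- sample(setdiff(.BASES, ch[e]), 1L)
      n_errors[i] <- length(errs)
    }
    if (indel_prob > 0 && stats::runif(1L) < indel_prob) {
      indel[i] <- TRUE
      size <- if (indel_len[1L] == indel_len[2L]) indel_len[1L] else
        sample1(indel_len[1L]:indel_len[2L])
      indel_size[i] <- size
      if (stats::runif(1L) < 0.5 && size < length(ch)) {
        indel_type[i] <- "del"
        at <- sample1(seq_len(length(ch) - size + 1L))
        ch <- ch[-(at:(at + size - 1L))]
        qv <- qv[-(at:(at + size - 1L))]
      } else {
        indel_type[i] <- "ins"
        at <- sample1(0:length(ch))
        ins <- sample(.BASES, size, replace = TRUE)
        ch <- append(ch, ins, after = at)
        qv <- append(qv, rep(35L, size), after = at)
      }
    }
    bases[i] <- paste0(left_bc, paste(ch, collapse = ""), right_bc)
    qual[i] <- if (indel[i] || degrade_3prime) {
      paste0(lq, phred_encode(qv), rq)
    } else {
      paste0(lq, bq, rq)
    }
  }
  truth <- data.frame(read_id = ids, n_edits = n_edits,
                      edited_pos = edited_pos, n_errors = n_errors,
                      indel = indel, indel_type = indel_type,
                      indel_len = indel_size, stringsAsFactors = FALSE)
  list(reads = fastq_reads(ids, bases, qual), truth = truth)
}

#' Targeted-edit table for a site
#'
#' Expands a \code{\link{target_site}} into the per-position edit events
#' the simulator applies: the amplicon coordinate of every protospacer C,
#' the converted base (T on plus-strand sites, A on minus-strand sites) and
#' its probability.
#'
#' @param site A \code{\link{target_site}}.
#' @param prob Either one probability recycled over the site's C positions,
#'   or a vector named by protospacer position (e.g. \code{c("5" = 0.25)});
#'   unnamed positions get 0.
#' @return A data frame with columns \code{pos}, \code{to}, \code{prob}.
#' @export
site_edits <- function(site, prob) {
  cpos <- site$c_positions
  if (!length(cpos)) {
    return(data.frame(pos = integer(0), to = character(0),
                      prob = numeric(0), stringsAsFactors = FALSE))
  }
  if (!is.null(names(prob))) {
    p <- rep(0, length(cpos))
    m <- match(names(prob), as.character(cpos))
    if (anyNA(m)) stop("named probability at a position without a C",
                       call. = FALSE)
    p[m] <- unname(prob)
  } else {
    p <- rep(prob, length.out = length(cpos))
  }
  data.frame(pos = site$amp_positions[cpos],
             to = if (site$strand == "+") "T" else "A",
             prob = p, stringsAsFactors = FALSE)
}

#' Simulate a barcoded multi-sample sequencing run
#'
#' One sample per barcode pair; each sample's reads carry edits at its own
#' gRNA's target site. Mirrors the single-guide experimental design in
#' which each barcoded sample was co-transfected with one gRNA.
#'
#' @param reference Common amplicon reference.
#' @param sites Named list of \code{\link{target_site}} objects; names (or
#'   the sites' \code{gRNA_id}) must match \code{barcode_map$sample_id}.
#' @param prob Per-site editing probability passed to
#'   \code{\link{site_edits}} (recycled, or a list named by sample).
#' @param barcode_map Data frame with \code{sample_id}, \code{left},
#'   \code{right}.
#' @param depth Reads per sample.
#' @param seed Top-level RNG seed.
#' @param ... Further arguments to \code{\link{simulate_sample_reads}}.
#' @return A list with pooled \code{reads} and \code{truth} (with
#'   \code{sample_id}).
#' @export
simulate_panel <- function(reference, sites, prob, barcode_map, depth,
                           seed = 1L, ...) {
  ids <- vapply(sites, function(s) s$gRNA_id, character(1))
  names(sites) <- ids
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(barcode_map)), function(j) {
      sid <- barcode_map$sample_id[j]
      site <- sites[[sid]]
      if (is.null(site)) stop("no target site for sample ", sid, call. = FALSE)
      p <- if (is.list(prob)) prob[[sid]] else prob
      sim <- simulate_sample_reads(
        reference, site_edits(site, p), depth,
        left_bc = barcode_map$left[j], right_bc = barcode_map$right[j],
        id_prefix = paste0(sid, "_"), ...)
      sim$truth$sample_id <- sid
      sim
    })
    list(reads = do.call(rbind, lapply(parts, `[[`, "reads")),
         truth = do.call(rbind, lapply(parts, `[[`, "truth")))
  })
}
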