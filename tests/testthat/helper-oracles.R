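# Independent brute-force oracles, written as naive enumerations so they
# share no code path with the implementation under test.

oracle_revcomp <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(comp[ch], collapse = "")
}

# Every 20-mer immediately 5' of an NGG, testing each offset and strand
# independently by substring inspection.
oracle_protospacers <- function(seq, id = "seq") {
  L <- nchar(seq)
  rows <- list()
  for (i in seq_len(max(L - 22, 0))) {
    pam <- substr(seq, i + 20, i + 22)
    spacer <- substr(seq, i, i + 19)
    if (substr(pam, 2, 3) == "GG" && !grepl("N", spacer)) {
      rows[[length(rows) + 1]] <- data.frame(
        parent_id = id, strand = "+", start = i,
        span_start = i, span_end = i + 19, spacer = spacer, pam = pam,
        stringsAsFactors = FALSE)
    }
  }
  rc <- oracle_revcomp(seq)
  for (i in seq_len(max(L - 22, 0))) {
    pam <- substr(rc, i + 20, i + 22)
    spacer <- substr(rc, i, i + 19)
    if (substr(pam, 2, 3) == "GG" && !grepl("N", spacer)) {
      # position j on the reverse complement maps to L - j + 1 on the sense
      rows[[length(rows) + 1]] <- data.frame(
        parent_id = id, strand = "-", start = L - i + 1,
        span_start = L - (i + 19) + 1, span_end = L - i + 1,
        spacer = spacer, pam = pam, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(parent_id = character(0), strand = character(0),
                      start = integer(0), span_start = integer(0),
                      span_end = integer(0), spacer = character(0),
                      pam = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$span_start, out$strand), , drop = FALSE]
}

# All ways same-strand C->T deaminations turn `codon` into a stop, by
# enumerating every subset of positions explicitly.
oracle_conversions <- function(codon) {
  stops <- c("TAA", "TAG", "TGA")
  ch <- strsplit(codon, "")[[1]]
  out <- list()
  if (codon %in% stops) return(out)  # already a stop: nothing to introduce
  for (strand in c("+", "-")) {
    editable <- which(ch == if (strand == "+") "C" else "G")
    if (!length(editable)) next
    for (k in seq_along(editable)) {
      # combn(x, k) with scalar x would enumerate seq_len(x)
      combos <- if (length(editable) == 1) list(editable) else
        utils::combn(editable, k, simplify = FALSE)
      for (sel in combos) {
        tmp <- ch
        tmp[sel] <- if (strand == "+") "T" else "A"
        res <- paste(tmp, collapse = "")
        if (res %in% stops) {
          out[[length(out) + 1]] <- list(strand = strand, positions = sel,
                                         stop = res)
        }
      }
    }
  }
  out
}

# Exhaustive knockout-site scan: every protospacer x every in-frame codon x
# every conversion route, with the window rule applied per design choice
# (all required edited positions inside the window; strict = whole codon).
oracle_scan <- function(seq, gene_id = "cds", window = c(1, 13),
                        strict = FALSE) {
  L <- nchar(seq)
  stopifnot(L %% 3 == 0)
  protos <- oracle_protospacers(seq, gene_id)
  rows <- list()
  for (k in seq_len(L / 3)) {
    codon <- substr(seq, 3 * k - 2, 3 * k)
    for (route in oracle_conversions(codon)) {
      sense_pos <- 3 * (k - 1) + route$positions
      if (nrow(protos) == 0) next
      for (j in seq_len(nrow(protos))) {
        if (protos$strand[j] != route$strand) next
        if (any(sense_pos < protos$span_start[j] |
                  sense_pos > protos$span_end[j])) next
        pp <- if (route$strand == "+") sense_pos - protos$span_start[j] + 1
              else protos$span_end[j] - sense_pos + 1
        ok <- all(pp >= window[1] & pp <= window[2])
        if (ok && strict) {
          cod_sense <- 3 * (k - 1) + 1:3
          cpp <- if (route$strand == "+") cod_sense - protos$span_start[j] + 1
                 else protos$span_end[j] - cod_sense + 1
          ok <- all(cod_sense >= protos$span_start[j] &
                      cod_sense <= protos$span_end[j]) &&
            all(cpp >= window[1] & cpp <= window[2])
        }
        if (!ok) next
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = gene_id, codon_index = k, codon = codon,
          resulting_stop = route$stop, strand = route$strand,
          proto_start = protos$start[j],
          edited_positions = paste(sort(pp), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), codon_index = integer(0),
                      codon = character(0), resulting_stop = character(0),
                      strand = character(0), proto_start = integer(0),
                      edited_positions = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(do.call(rbind, rows))
}

# Canonical string form of a site set for equality checks.
site_key <- function(df) {
  sort(paste(df$gene_id, df$codon_index, df$strand, df$proto_start,
             df$resulting_stop, df$edited_positions, sep = "|"))
}

# Step-by-step re-implementation of the trimming rule.
oracle_trim <- function(q, leading = 3, trailing = 3, wlen = 4, wq = 15,
                        minlen = 50) {
  a <- 1
  while (a <= length(q) && q[a] < leading) a <- a + 1
  b <- length(q)
  while (b >= a && q[b] < trailing) b <- b - 1
  if (a > b) return(NULL)
  qs <- q[a:b]
  if (length(qs) >= wlen) {
    for (i in 1:(length(qs) - wlen + 1)) {
      if (mean(qs[i:(i + wlen - 1)]) < wq) {
        b <- a + i - 2
        break
      }
    }
  }
  if (a > b || (b - a + 1) < minlen) return(NULL)
  c(a, b)
}

random_cds <- function(n_codons, gc = 0.4) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  stops <- c("TAA", "TAG", "TGA")
  cods <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste(sample(names(p), 3, replace = TRUE, prob = p),
                   collapse = "")
      if (!(cod %in% stops)) break
    }
    cods[i] <- cod
  }
  cods[1] <- "ATG"
  cods[n_codons] <- sample(stops, 1)
  paste(cods, collapse = "")
}
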