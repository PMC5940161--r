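# End-to-end runs over files on disk. Every figure has a TSV twin holding
# exactly the plotted numbers; a JSON manifest lists each output with a
# content checksum so re-runs can be verified bit-for-bit. Outputs are
# written with a ".partial" suffix and renamed only when the whole run
# succeeds, so a failed run leaves clearly-marked partial files behind.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stage writer: accumulates ".partial" files, renames them on success.
.output_stage <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  list(
    path = function(name) {
      p <- file.path(out_dir, paste0(name, ".partial"))
      files[[length(files) + 1L]] <<- p
      p
    },
    finalize = function() {
      final <- sub("\\.partial$", "", files)
      ok <- file.rename(files, final)
      if (!all(ok)) stop("failed to finalize outputs", call. = FALSE)
      final
    })
}

.write_manifest <- function(out_dir, subcommand, config, counts, files) {
  manifest <- list(
    tool = "bestop",
    version = as.character(utils::packageVersion("bestop")),
    subcommand = subcommand,
    config = config,
    counts = counts,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the knockout-site design scan
#'
#' Reads a CDS FASTA, scans every frame-valid record for stop-codon
#' knockout sites, and writes the sites table, a BED of protospacer spans,
#' the genome summary, the per-gene and relative-position histograms, and a
#' checksummed manifest.
#'
#' @param cds_fasta Path to a CDS FASTA file.
#' @param out_dir Output directory (created if needed).
#' @param window Editing window (\code{\link{edit_window}}).
#' @param strict_window Require the whole codon inside the window?
#' @param figures Also write PNG figures (histograms)?
#' @return Invisibly, a list with \code{sites}, \code{summary} and
#'   \code{manifest} (path).
#' @export
run_scan <- function(cds_fasta, out_dir, window = c(1L, 13L),
                     strict_window = FALSE, figures = TRUE) {
  cds <- read_fasta(cds_fasta)
  sites <- scan_cds_set(cds, window = window, strict_window = strict_window)
  summ <- summarize_genome(sites, cds$gene_id)
  stage <- .output_stage(out_dir)

  .write_tsv(as.data.frame(sites), stage$path("sites.tsv"))
  sites_to_bed(sites, stage$path("protospacers.bed"))
  .write_tsv(data.frame(
    metric = c("total_sites", "targetable_genes", "total_genes",
               "percent_targetable", "median_sites_per_targetable_gene"),
    value = c(summ$total_sites, summ$targetable_genes, summ$total_genes,
              summ$percent_targetable, summ$median_sites_per_targetable_gene)),
    stage$path("summary.tsv"))
  hist_df <- data.frame(sites_per_gene = as.integer(names(summ$sites_per_gene_histogram)),
                        n_genes = as.integer(summ$sites_per_gene_histogram))
  .write_tsv(hist_df, stage$path("sites_per_gene_hist.tsv"))
  rp <- as.data.frame(summ$relative_position_histogram)
  names(rp) <- c("decile", "codon", "n_sites")
  .write_tsv(rp, stage$path("relative_position_hist.tsv"))
  if (figures) {
    grDevices::png(stage$path("sites_per_gene.png"), width = 800, height = 500)
    plot_sites_per_gene(summ)
    grDevices::dev.off()
    grDevices::png(stage$path("relative_positions.png"), width = 800, height = 500)
    plot_relative_positions(summ)
    grDevices::dev.off()
  }
  files <- stage$finalize()
  manifest <- .write_manifest(
    out_dir, "scan",
    config = list(cds_fasta = cds_fasta, window = window,
                  strict_window = strict_window),
    counts = list(n_cds = nrow(cds), n_frame_valid = sum(cds$frame_valid),
                  n_sites = nrow(sites)),
    files = files)
  invisible(list(sites = sites, summary = summ, manifest = manifest))
}

#' Read a gRNA target table
#'
#' Expected TSV columns: \code{gRNA_id}, \code{amplicon_id}, \code{strand}
#' and \code{proto_start} (amplicon coordinate of protospacer base 1). An
#' optional \code{spacer} column is checked against the reference.
#'
#' @param path Path to the TSV.
#' @param references Named character vector of amplicon sequences.
#' @return A named list of \code{\link{target_site}} objects.
#' @export
load_targets <- function(path, references) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gRNA_id", "amplicon_id", "strand", "proto_start")
  if (!all(need %in% names(tab))) {
    stop("target table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sites <- lapply(seq_len(nrow(tab)), function(i) {
    ref <- references[[tab$amplicon_id[i]]]
    if (is.null(ref) || is.na(ref)) {
      stop("unknown amplicon_id: ", tab$amplicon_id[i], call. = FALSE)
    }
    s <- target_site(tab$gRNA_id[i], ref, tab$proto_start[i], tab$strand[i],
                     amplicon_id = tab$amplicon_id[i])
    if ("spacer" %in% names(tab) && nzchar(tab$spacer[i]) &&
        normalize_bases(tab$spacer[i]) != s$spacer) {
      stop(sprintf("site '%s': spacer in table does not match the reference",
                   s$gRNA_id), call. = FALSE)
    }
    s
  })
  names(sites) <- tab$gRNA_id
  sites
}

#' Run per-sample editing quantification
#'
#' Trims, demultiplexes by paired barcodes, classifies each sample's reads
#' at its gRNA target site, and writes per-sample statistics, the
#' per-position substitution matrix, the editing-window profile, and a
#' checksummed manifest. Sample identifiers in the barcode map must match
#' gRNA identifiers in the target table. With a control FASTQ (cells
#' without gRNA), per-position control conversion rates raise the window
#' detection threshold at noisy positions.
#'
#' @param fastq Path to the pooled FASTQ.
#' @param ref_fasta Path to the amplicon reference FASTA.
#' @param targets_tsv Path to the target table (\code{\link{load_targets}}).
#' @param barcodes_tsv TSV with columns \code{sample_id}, \code{left},
#'   \code{right}.
#' @param out_dir Output directory.
#' @param trim \code{\link{trim_params}} used on the raw reads.
#' @param detection_threshold Window-profile detection threshold.
#' @param control_fastq Optional control FASTQ (demultiplexed against the
#'   same barcodes; all control reads are pooled per site).
#' @param figures Also write the per-position heatmap PNG?
#' @return Invisibly, a list with \code{stats} (per-sample list),
#'   \code{matrix}, \code{profile} and \code{manifest}.
#' @export
run_quant <- function(fastq, ref_fasta, targets_tsv, barcodes_tsv, out_dir,
                      trim = trim_params(), detection_threshold = 0.005,
                      control_fastq = NULL, figures = TRUE) {
  refs_df <- read_fasta(ref_fasta)
  refs <- structure(refs_df$seq, names = refs_df$gene_id)
  sites <- load_targets(targets_tsv, refs)
  barcodes <- utils::read.delim(barcodes_tsv, stringsAsFactors = FALSE)

  reads <- read_fastq(fastq)
  tr <- trim_reads(reads, trim)
  dm <- demultiplex(tr$reads, barcodes)

  stats <- lapply(barcodes$sample_id, function(sid) {
    site <- sites[[sid]]
    if (is.null(site)) stop("no target site for sample ", sid, call. = FALSE)
    quantify_sample(dm$samples[[sid]], refs[[site$amplicon_id]], site)
  })
  names(stats) <- barcodes$sample_id
  mat <- per_position_matrix(stats)

  control_rates <- NULL
  if (!is.null(control_fastq)) {
    ctrl <- trim_reads(read_fastq(control_fastq), trim)$reads
    cdm <- demultiplex(ctrl, barcodes)
    cstats <- lapply(barcodes$sample_id, function(sid) {
      site <- sites[[sid]]
      quantify_sample(cdm$samples[[sid]], refs[[site$amplicon_id]], site)
    })
    cmat <- per_position_matrix(cstats)
    control_rates <- suppressWarnings(
      apply(cmat, 2, function(v) if (all(is.na(v))) NA_real_ else
        mean(v, na.rm = TRUE)))
  }
  profile <- window_profile(mat, detection_threshold, control_rates)

  stage <- .output_stage(out_dir)
  stats_df <- do.call(rbind, lapply(stats, function(s) data.frame(
    gRNA_id = s$gRNA_id, n_raw = s$n_raw, n_clean = s$n_clean,
    n_edited = s$n_edited, n_unedited = s$n_unedited,
    n_not_covering = s$n_not_covering,
    efficiency_pct = compute_efficiency(s),
    n_indel = s$n_indel,
    indel_pct = if (s$n_clean > 0)
      round_half_up(100 * s$n_indel / s$n_clean, 1) else NA_real_,
    stringsAsFactors = FALSE)))
  .write_tsv(stats_df, stage$path("sample_stats.tsv"))
  mat_df <- data.frame(gRNA_id = rownames(mat), round(mat, 6),
                       check.names = FALSE)
  .write_tsv(mat_df, stage$path("per_position_matrix.tsv"))
  .write_tsv(data.frame(position = profile$position,
                        designed = profile$designed,
                        edited = profile$edited,
                        probability = round(profile$probability, 6),
                        threshold = profile$threshold),
             stage$path("window_profile.tsv"))
  if (figures) {
    # pheatmap infers the file type from the extension, so render to a
    # proper .png first and move it into the staged ".partial" slot
    tmp <- file.path(out_dir, ".heatmap_tmp.png")
    plot_position_heatmap(mat, file = tmp)
    file.rename(tmp, stage$path("per_position_heatmap.png"))
  }
  files <- stage$finalize()
  manifest <- .write_manifest(
    out_dir, "quant",
    config = list(fastq = fastq, ref_fasta = ref_fasta,
                  targets = targets_tsv, barcodes = barcodes_tsv,
                  trim = unclass(trim),
                  detection_threshold = detection_threshold,
                  control_fastq = control_fastq),
    counts = list(n_raw = tr$n_input, n_discarded = tr$n_discarded,
                  n_unassigned = nrow(dm$unassigned),
                  per_sample = as.list(dm$counts)),
    files = files)
  invisible(list(stats = stats, matrix = mat, profile = profile,
                 manifest = manifest))
}

#' Run multiplex substitution counting
#'
#' For pooled-guide runs: trims (and optionally demultiplexes down to one
#' barcoded sample), counts per-read substituted target positions over the
#' union of all sites, calls indel frequency, and writes the histogram TSV,
#' an indel summary and a manifest.
#'
#' @inheritParams run_quant
#' @param sample_id With \code{barcodes_tsv}, which sample carries the
#'   pooled reads (default: the first).
#' @param barcodes_tsv Optional barcode TSV; NULL treats all reads as one
#'   sample without barcodes.
#' @return Invisibly, a list with \code{histogram}, \code{indel} and
#'   \code{manifest}.
#' @export
run_multiplex <- function(fastq, ref_fasta, targets_tsv, out_dir,
                          trim = trim_params(), barcodes_tsv = NULL,
                          sample_id = NULL, figures = TRUE) {
  refs_df <- read_fasta(ref_fasta)
  refs <- structure(refs_df$seq, names = refs_df$gene_id)
  sites <- load_targets(targets_tsv, refs)
  amp <- unique(vapply(sites, function(s) s$amplicon_id, character(1)))
  if (length(amp) != 1L) {
    stop("multiplex counting requires all sites on one amplicon", call. = FALSE)
  }
  reference <- refs[[amp]]
  reads <- trim_reads(read_fastq(fastq), trim)$reads
  n_clean <- nrow(reads)
  if (!is.null(barcodes_tsv)) {
    barcodes <- utils::read.delim(barcodes_tsv, stringsAsFactors = FALSE)
    dm <- demultiplex(reads, barcodes)
    sid <- sample_id %||% barcodes$sample_id[1L]
    reads <- dm$samples[[sid]]
  }
  hist <- multiplex_histogram(reads, reference, sites)
  indel <- indel_frequency(reads, reference)

  stage <- .output_stage(out_dir)
  .write_tsv(data.frame(n_substitutions = as.integer(names(hist$counts)),
                        n_reads = as.integer(hist$counts)),
             stage$path("multiplex_histogram.tsv"))
  .write_tsv(data.frame(n_reads = indel$n_reads, n_indel = indel$n_indel,
                        indel_pct = indel$percent),
             stage$path("indel_summary.tsv"))
  if (figures) {
    grDevices::png(stage$path("multiplex_histogram.png"),
                   width = 800, height = 500)
    plot(hist)
    grDevices::dev.off()
  }
  files <- stage$finalize()
  manifest <- .write_manifest(
    out_dir, "multiplex",
    config = list(fastq = fastq, ref_fasta = ref_fasta,
                  targets = targets_tsv, trim = unclass(trim)),
    counts = list(n_clean = n_clean, n_counted = hist$n_reads,
                  n_not_covering = hist$n_not_covering),
    files = files)
  invisible(list(histogram = hist, indel = indel, manifest = manifest))
}

#' Simulate inputs to disk
#'
#' Writes a synthetic CDS FASTA plus truth table, or a simulated barcoded
#' FASTQ run plus reference/targets/barcodes/truth tables, ready to feed
#' back into \code{\link{run_scan}} / \code{\link{run_quant}}.
#'
#' @param what "cds" or "reads".
#' @param out_dir Output directory.
#' @param seed Top-level RNG seed (recorded in the manifest).
#' @param ... Arguments passed to \code{\link{generate_cds_set}} (for
#'   "cds") or: \code{n_guides}, \code{c_positions} (list per guide),
#'   \code{prob}, \code{depth}, and further arguments of
#'   \code{\link{simulate_sample_reads}} (for "reads").
#' @return Invisibly, the manifest path.
#' @export
run_simulate <- function(what = c("cds", "reads"), out_dir, seed = 1L, ...) {
  what <- match.arg(what)
  stage <- .output_stage(out_dir)
  args <- list(...)
  if (what == "cds") {
    sim <- generate_cds_set(seed = seed, ...)
    write_fasta(sim$cds, stage$path("cds.fa"))
    .write_tsv(sim$truth, stage$path("cds_truth.tsv"))
    counts <- list(n_genes = nrow(sim$cds), n_planted = nrow(sim$truth))
  } else {
    n_guides <- args$n_guides %||% 4L
    prob <- args$prob %||% 0.2
    depth <- args$depth %||% 1000L
    sim <- with_seed(seed, {
      spacers <- vapply(seq_len(n_guides), function(i) {
        random_spacer(c_at = sample(1:13, sample(2:4, 1L)))
      }, character(1))
      tiled <- make_tiled_amplicon(spacers)
      bc <- data.frame(
        sample_id = vapply(tiled$sites, `[[`, character(1), "gRNA_id"),
        left = random_dna(n_guides, 6L),
        right = random_dna(n_guides, 6L), stringsAsFactors = FALSE)
      panel <- simulate_panel(tiled$reference, tiled$sites, prob, bc, depth,
                              seed = seed + 1L)
      list(tiled = tiled, bc = bc, panel = panel)
    })
    write_fasta(cds_set("amplicon1", sim$tiled$reference),
                stage$path("reference.fa"))
    write_fastq(sim$panel$reads, stage$path("reads.fq"))
    .write_tsv(data.frame(
      gRNA_id = vapply(sim$tiled$sites, `[[`, character(1), "gRNA_id"),
      amplicon_id = "amplicon1",
      strand = vapply(sim$tiled$sites, `[[`, character(1), "strand"),
      proto_start = vapply(sim$tiled$sites, `[[`, integer(1), "proto_start"),
      spacer = vapply(sim$tiled$sites, `[[`, character(1), "spacer")),
      stage$path("targets.tsv"))
    .write_tsv(sim$bc, stage$path("barcodes.tsv"))
    .write_tsv(sim$panel$truth, stage$path("truth.tsv"))
    counts <- list(n_reads = nrow(sim$panel$reads),
                   n_samples = nrow(sim$bc))
  }
  files <- stage$finalize()
  manifest <- .write_manifest(out_dir, paste0("simulate-", what),
                              config = c(list(seed = seed),
                                         args[!vapply(args, is.list, logical(1))]),
                              counts = counts, files = files)
  invisible(manifest)
}
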