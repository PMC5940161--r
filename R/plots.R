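# Figure helpers. Every figure drawn by the pipeline has a TSV twin with
# exactly the plotted numbers; these functions only render.

#' Histogram of knockout sites per gene
#'
#' @param summary A \code{genome_summary} from \code{\link{summarize_genome}}.
#' @param max_sites Right-truncate the x axis at this site count.
#' @return Invisibly, the plotted counts.
#' @export
plot_sites_per_gene <- function(summary, max_sites = 50L) {
  h <- summary$sites_per_gene_histogram
  k <- as.integer(names(h))
  keep <- k <= max_sites
  graphics::barplot(as.integer(h[keep]), names.arg = k[keep], las = 2,
                    xlab = "targetable knockout sites per gene",
                    ylab = "genes", col = "steelblue",
                    main = "Targetable sites per gene")
  invisible(h)
}

#' Relative positions of knockout sites within CDSs
#'
#' Decile histogram of site position along the CDS, one bar group per
#' targetable codon class.
#'
#' @param summary A \code{genome_summary}.
#' @return Invisibly, the plotted matrix.
#' @export
plot_relative_positions <- function(summary) {
  m <- t(as.matrix(summary$relative_position_histogram))
  cols <- c(CAA = "#1b9e77", CAG = "#d95f02", CGA = "#7570b3", TGG = "#e7298a")
  graphics::barplot(m, beside = TRUE, col = cols[rownames(m)],
                    names.arg = paste0(seq(10, 100, 10), "%"),
                    xlab = "relative position in CDS", ylab = "sites",
                    main = "Relative positions of knockout sites")
  graphics::legend("topright", legend = rownames(m), fill = cols[rownames(m)],
                   bty = "n")
  invisible(m)
}

#' Per-position substitution heatmap
#'
#' Sequential colour scale (darker = more efficient substitution); cells
#' where the gRNA carries no C are rendered grey. Rows are kept in panel
#' order (no clustering).
#'
#' @param mat Matrix from \code{\link{per_position_matrix}}.
#' @param file Optional output file (PNG/PDF chosen by extension); NULL
#'   draws to the current device.
#' @return Invisibly, \code{mat}.
#' @export
plot_position_heatmap <- function(mat, file = NULL) {
  pal <- grDevices::colorRampPalette(c("white", "firebrick4"))(100)
  args <- list(mat = mat, cluster_rows = FALSE, cluster_cols = FALSE,
               color = pal, na_col = "grey80", border_color = "grey90",
               main = "Per-position substitution efficiency")
  if (!is.null(file)) args$filename <- file
  do.call(pheatmap::pheatmap, args)
  invisible(mat)
}
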