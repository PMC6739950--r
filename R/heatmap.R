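# Genome-wide gain/loss heatmap: one row per clone, chromosomes
# concatenated chr1..chr22, chrX, chrY on the x axis.
#
# Colors follow the reporting convention: gains red, hemizygous losses
# blue, homozygous losses yellow, neutral background.

HEATMAP_STATES <- c(neutral = 0L, gain = 1L, hemi_loss = 2L, homo_loss = 3L)
HEATMAP_COLORS <- c("grey95", "red", "blue", "yellow")

segment_state <- function(type, zygosity) {
  ifelse(type == "Gain", HEATMAP_STATES[["gain"]],
         ifelse(zygosity == "homozygous", HEATMAP_STATES[["homo_loss"]],
                HEATMAP_STATES[["hemi_loss"]]))
}

#' Binned heatmap state matrix
#'
#' Bins the concatenated genome at `bin_size` and assigns each (clone, bin)
#' the state covering the most bases in the bin; ties break toward loss
#' (homozygous over hemizygous over gain) so losses are never visually
#' swallowed.
#'
#' @param profiles list of `cn_profile` objects.
#' @param map a `band_map`.
#' @param bin_size bin width in bases (default 1 Mb).
#' @return integer matrix (clones x bins; 0 neutral, 1 gain, 2 hemizygous
#'   loss, 3 homozygous loss) with attributes "chrom_offsets" and
#'   "bin_size".
#' @export
heatmap_matrix <- function(profiles, map, bin_size = 1e6) {
  stopifnot(length(profiles) >= 1L, bin_size >= 1)
  lens <- map$chrom_lengths
  if (!length(lens) || sum(lens) <= 0) stop("zero-width genome", call. = FALSE)
  offsets <- cumsum(c(0, as.numeric(lens)))[seq_along(lens)]
  names(offsets) <- names(lens)
  n_bins <- ceiling(sum(as.numeric(lens)) / bin_size)
  ids <- vapply(profiles, `[[`, character(1), "clone_id")
  mat <- matrix(0L, nrow = length(profiles), ncol = n_bins,
                dimnames = list(ids, NULL))
  for (r in seq_along(profiles)) {
    s <- profiles[[r]]$segments
    if (!nrow(s)) next
    st <- segment_state(s$type, s$zygosity)
    gstart <- offsets[s$chrom] + s$start
    gend <- offsets[s$chrom] + s$end
    first <- floor(gstart / bin_size) + 1L
    last <- ceiling(gend / bin_size)
    touched <- sort(unique(unlist(Map(seq, first, last))))
    for (b in touched) {
      blo <- (b - 1L) * bin_size; bhi <- b * bin_size
      cover <- pmax(0, pmin(gend, bhi) - pmax(gstart, blo))
      by_state <- tapply(cover, st, sum)
      by_state <- by_state[by_state > 0]
      if (!length(by_state)) next
      best <- max(by_state)
      # ties toward loss: pick the highest state code among the maxima
      mat[r, b] <- max(as.integer(names(by_state)[by_state == best]))
    }
  }
  attr(mat, "chrom_offsets") <- offsets
  attr(mat, "bin_size") <- bin_size
  mat
}

#' Render the genome gain/loss heatmap to an image file
#'
#' Rows are clones (in list order, top to bottom), columns genomic bins
#' across the concatenated genome with chromosome boundaries drawn.
#' Output format follows the file extension (.png or .svg); rendering is
#' deterministic for fixed input and bin size.
#'
#' @param profiles list of `cn_profile` objects (or a `karyo_result`).
#' @param map a `band_map`.
#' @param path output image path ending in .png or .svg.
#' @param bin_size bin width in bases (default 1 Mb).
#' @return the state matrix from [heatmap_matrix], invisibly.
#' @export
render_heatmap <- function(profiles, map, path, bin_size = 1e6) {
  if (inherits(profiles, "karyo_result")) profiles <- profiles$profiles
  mat <- heatmap_matrix(profiles, map, bin_size)
  offsets <- attr(mat, "chrom_offsets")
  lens <- map$chrom_lengths
  n <- nrow(mat)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") grDevices::svg(path, width = 10, height = max(2, 0.5 * n + 1.5))
  else grDevices::png(path, width = 1200, height = max(200, 40 * n + 150))
  on.exit(grDevices::dev.off(), add = TRUE)
  op <- graphics::par(mar = c(4.5, 8, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::image(
    x = seq_len(ncol(mat)) * attr(mat, "bin_size"),
    y = seq_len(n), z = t(mat[n:1, , drop = FALSE]),
    zlim = c(0, 3), col = HEATMAP_COLORS, axes = FALSE,
    xlab = "", ylab = "", useRaster = TRUE)
  graphics::abline(v = c(offsets, sum(as.numeric(lens))), col = "grey60")
  mids <- offsets + as.numeric(lens) / 2
  graphics::axis(1, at = mids, labels = sub("^chr", "", names(lens)),
                 tick = FALSE, cex.axis = 0.7, las = 2)
  graphics::axis(2, at = n:1, labels = rownames(mat), tick = FALSE,
                 las = 2, cex.axis = 0.8)
  graphics::legend(
    "topright", inset = c(0, -0.08), xpd = TRUE, horiz = TRUE, bty = "n",
    fill = HEATMAP_COLORS[2:4],
    legend = c("gain", "hemizygous loss", "homozygous loss"),
    cex = 0.8)
  graphics::title(xlab = "chromosome (bin majority state; ties favor loss)")
  invisible(mat)
}
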