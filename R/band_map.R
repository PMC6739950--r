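# Cytoband reference tables: loading, validation, and band -> coordinate lookup.
#
# Coordinates are 0-based half-open throughout, exactly as in UCSC cytoBand.txt.

CANONICAL_CHROMS <- paste0("chr", c(1:22, "X", "Y"))

#' Normalize chromosome names
#'
#' Accepts "1", "chr1", "X", "chrx" and returns the canonical UCSC form
#' ("chr1".."chr22", "chrX", "chrY"), or `NA` for anything non-canonical.
#'
#' @param x character vector of chromosome names.
#' @return character vector of canonical names, `NA` where unrecognized.
#' @export
normalize_chrom <- function(x) {
  x <- gsub("[[:space:]]", "", as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x <- toupper(x)
  out <- paste0("chr", x)
  out[!out %in% CANONICAL_CHROMS] <- NA_character_
  out
}

chrom_rank <- function(chrom) match(chrom, CANONICAL_CHROMS)

new_band_map <- function(bands, assembly) {
  # bands: data.frame chrom/start/end/name/stain, canonical chroms only
  bands <- bands[order(chrom_rank(bands$chrom), bands$start), , drop = FALSE]
  rownames(bands) <- NULL
  bands$arm <- substr(bands$name, 1L, 1L)
  for (ch in unique(bands$chrom)) {
    b <- bands[bands$chrom == ch, ]
    if (b$start[1L] != 0L)
      stop("band table does not start at 0 on ", ch, call. = FALSE)
    if (nrow(b) > 1L && any(b$end[-nrow(b)] != b$start[-1L]))
      stop("band table has a gap or overlap on ", ch, call. = FALSE)
    if (any(b$start >= b$end))
      stop("empty or inverted band on ", ch, call. = FALSE)
    if (!all(b$arm %in% c("p", "q")) || is.unsorted(match(b$arm, c("p", "q"))))
      stop("arm labels out of order on ", ch, call. = FALSE)
    acen <- which(b$stain == "acen")
    if (length(acen) != 2L || diff(acen) != 1L ||
        b$arm[acen[1L]] != "p" || b$arm[acen[2L]] != "q")
      stop("expected an adjacent p/q acen pair on ", ch, call. = FALSE)
  }
  lens <- vapply(split(bands$end, bands$chrom), max, numeric(1))
  acen_p <- bands[bands$stain == "acen" & bands$arm == "p", ]
  boundary <- stats::setNames(acen_p$end, acen_p$chrom)
  structure(
    list(assembly = assembly, bands = bands,
         chrom_lengths = lens[order(chrom_rank(names(lens)))],
         acen_boundary = boundary),
    class = "band_map")
}

#' Load a UCSC cytoBand table
#'
#' Reads a 5-column tab-delimited band table (chrom, start, end, band name,
#' Giemsa stain) as distributed by the UCSC Genome Browser. Non-canonical
#' contigs (chrN_random, alt scaffolds, chrM, ...) are dropped silently;
#' malformed rows and chromosomes that do not tile contiguously are errors.
#'
#' @param con path to a cytoBand file, or a character vector of its lines.
#' @param assembly assembly label to record on the map (e.g. "hg19").
#' @return a `band_map` object.
#' @export
load_band_table <- function(con, assembly = "custom") {
  lines <- if (length(con) == 1L && !grepl("\t", con)) readLines(con) else con
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty band table", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 5L)
  if (length(bad))
    stop("malformed band table row at line ", bad[1L], call. = FALSE)
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-numeric coordinates at line ", bad[1L], call. = FALSE)
  bands <- data.frame(chrom = m[, 1L], start = start, end = end,
                      name = m[, 4L], stain = m[, 5L],
                      stringsAsFactors = FALSE)
  bands <- bands[bands$chrom %in% CANONICAL_CHROMS, , drop = FALSE]
  if (!nrow(bands)) stop("no canonical chromosomes in band table", call. = FALSE)
  new_band_map(bands, assembly)
}

.band_map_cache <- new.env(parent = emptyenv())

#' Get a vendored band map
#'
#' Returns the cytoband map for one of the assemblies shipped with the
#' package ("hg19", the default everywhere, plus "hg18" and "grch38"),
#' or loads a user-supplied cytoBand file.
#'
#' @param assembly "hg19", "hg18", "grch38", or a path to a cytoBand file.
#' @return a `band_map` object.
#' @export
band_map <- function(assembly = "hg19") {
  key <- tolower(assembly)
  if (key %in% c("hg18", "hg19", "grch38", "hg38")) {
    if (key == "hg38") key <- "grch38"
    if (!is.null(.band_map_cache[[key]])) return(.band_map_cache[[key]])
    path <- system.file("extdata", paste0("cytoBand.", key, ".txt"),
                        package = "karyoconvert", mustWork = TRUE)
    map <- load_band_table(path, assembly = key)
    .band_map_cache[[key]] <- map
    return(map)
  }
  if (!file.exists(assembly))
    stop("unknown assembly and no such file: ", assembly, call. = FALSE)
  load_band_table(assembly, assembly = "custom")
}

#' @export
print.band_map <- function(x, ...) {
  cat("<band_map ", x$assembly, ": ", nrow(x$bands), " bands, ",
      length(x$chrom_lengths), " chromosomes>\n", sep = "")
  invisible(x)
}

genomic_interval <- function(chrom, start, end) {
  list(chrom = chrom, start = as.numeric(start), end = as.numeric(end))
}

band_error <- function(chrom, label) {
  structure(
    class = c("kc_band_error", "error", "condition"),
    list(message = sprintf("cannot resolve band '%s' on %s", label, chrom),
         call = NULL, chrom = chrom, label = label))
}

#' Chromosome arm interval
#'
#' The p arm is `[0, centromere]` and the q arm `[centromere, length]`,
#' where the centromere is the shared edge of the two acen bands.
#'
#' @param map a `band_map`.
#' @param chrom chromosome name (any accepted spelling).
#' @param arm "p" or "q".
#' @return list with `chrom`, `start`, `end`.
#' @export
arm_interval <- function(map, chrom, arm) {
  chrom <- normalize_chrom(chrom)
  if (is.na(chrom) || !chrom %in% names(map$chrom_lengths))
    stop("unknown chromosome", call. = FALSE)
  arm <- tolower(arm)
  stopifnot(arm %in% c("p", "q"))
  b <- map$acen_boundary[[chrom]]
  if (arm == "p") genomic_interval(chrom, 0, b)
  else genomic_interval(chrom, b, map$chrom_lengths[[chrom]])
}

normalize_band_label <- function(label) {
  lab <- gsub("[[:space:]]", "", tolower(label))
  lab <- sub("^([pq])\\.", "\\1", lab)   # tolerate "q.21.31"
  lab
}

#' Resolve a band label to coordinates
#'
#' Exact table labels map to their band. A label coarser than the table
#' (e.g. "q21" where the table holds q21.1/q21.2/q21.31...) maps to the
#' union of all finer bands it prefixes. A label finer than the table
#' (e.g. a sub-sub-band) falls back to the finest enclosing table band.
#' "p10"/"q10" denote the centromere and resolve to the zero-width point
#' at the acen boundary; a bare arm letter resolves to the whole arm.
#'
#' @param map a `band_map`.
#' @param chrom chromosome name.
#' @param band_label band string without the chromosome, e.g. "q21.31".
#' @return list with `chrom`, `start`, `end` (start == end for p10/q10).
#' @export
resolve_band <- function(map, chrom, band_label) {
  chrom <- normalize_chrom(chrom)
  lab <- normalize_band_label(band_label)
  if (is.na(chrom) || !chrom %in% names(map$chrom_lengths))
    stop(band_error(if (is.na(chrom)) "?" else chrom, band_label))
  if (!grepl("^[pq]([0-9]+(\\.[0-9]+)?)?$", lab))
    stop(band_error(chrom, band_label))
  if (lab %in% c("p", "q")) return(arm_interval(map, chrom, lab))
  if (lab %in% c("p10", "q10")) {
    b <- map$acen_boundary[[chrom]]
    return(genomic_interval(chrom, b, b))
  }
  b <- map$bands[map$bands$chrom == chrom, ]
  labs <- tolower(b$name)
  hit <- which(labs == lab)
  if (!length(hit)) {
    # coarse query: union of finer bands extending it (dot-insensitive prefix)
    nod <- gsub(".", "", labs, fixed = TRUE)
    qn <- gsub(".", "", lab, fixed = TRUE)
    hit <- which(startsWith(nod, qn))
    if (!length(hit)) {
      # finer query than the table: fall back to the finest enclosing band
      enc <- which(startsWith(qn, nod))
      if (length(enc)) hit <- enc[which.max(nchar(nod[enc]))]
    }
  }
  if (!length(hit)) stop(band_error(chrom, band_label))
  genomic_interval(chrom, min(b$start[hit]), max(b$end[hit]))
}

#' Serialize a band map back to UCSC cytoBand lines
#'
#' @param map a `band_map`.
#' @return character vector of 5-column tab-separated lines.
#' @export
serialize_band_table <- function(map) {
  b <- map$bands
  sprintf("%s\t%d\t%d\t%s\t%s", b$chrom, as.integer(b$start),
          as.integer(b$end), b$name, b$stain)
}
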