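# Batch input reading, the gain/loss report table, and cell-count strings.

#' Read a two-column sample/karyotype table
#'
#' The table is tab-delimited with exactly two columns: sample name and
#' karyotype. A header row is auto-detected (its second field does not
#' look like a karyotype). Duplicate sample names are uniquified with a
#' numeric suffix and a warning.
#'
#' @param con path to the file, or a character vector of its lines.
#' @return data.frame with columns sample, karyotype; attribute "warnings".
#' @export
read_batch <- function(con) {
  lines <- if (length(con) == 1L && !grepl("\t", con) && file.exists(con))
    readLines(con) else con
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input table", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("expected exactly two tab-separated columns at line ", bad[1L],
         call. = FALSE)
  m <- do.call(rbind, parts)
  looks_like_karyotype <- grepl("^\\s*[0-9?<]", m[, 2L]) | grepl(",", m[, 2L])
  if (!looks_like_karyotype[1L] && nrow(m) > 1L) m <- m[-1L, , drop = FALSE]
  warnings <- character()
  ids <- trimws(m[, 1L])
  if (anyDuplicated(ids)) {
    warnings <- c(warnings, paste0("duplicate sample name(s) uniquified: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    ids <- make.unique(ids, sep = "_dup")
  }
  out <- data.frame(sample = ids, karyotype = trimws(m[, 2L]),
                    stringsAsFactors = FALSE)
  attr(out, "warnings") <- warnings
  out
}

#' Cell-count string for one clone
#'
#' @param count the clone's cell count (NA for unknown).
#' @param total sum of known clone counts for the sample.
#' @return "k of N" when the clone count is known, else "unknown".
#' @export
cells_string <- function(count, total) {
  if (is.na(count)) "unknown" else paste0(count, " of ", total)
}

#' Convert karyotypes to a gain/loss report
#'
#' The main pipeline: parses each karyotype into clones, builds each
#' clone's net copy-number profile against the chosen assembly's cytoband
#' map, and assembles the tabular report (one row per contiguous gained or
#' lost segment). Clone ids are always "<sample>_<n>".
#'
#' @param karyotypes character vector of ISCN karyotype strings, or a
#'   data.frame as returned by [read_batch].
#' @param sample_ids sample names (defaults to "sample_1", "sample_2", ...).
#' @param assembly "hg19" (default), "hg18", "grch38", or a band file path.
#' @param map optionally a pre-loaded `band_map` (overrides `assembly`).
#' @return a `karyo_result`: `table` (Sample ID/Chr/Start/End/Type/Cells
#'   Present as columns sample_clone, chrom, start, end, type, cells),
#'   `warnings` (sample/clone/term/message), and `profiles` (list of
#'   `cn_profile`, one per clone).
#' @export
karyo_convert <- function(karyotypes, sample_ids = NULL, assembly = "hg19",
                          map = NULL) {
  if (is.data.frame(karyotypes)) {
    sample_ids <- karyotypes$sample
    karyotypes <- karyotypes$karyotype
  }
  if (is.null(sample_ids))
    sample_ids <- if (length(karyotypes) == 1L) "sample_1"
      else paste0("sample_", seq_along(karyotypes))
  stopifnot(length(sample_ids) == length(karyotypes))
  if (is.null(map)) map <- band_map(assembly)

  rows <- list()
  profiles <- list()
  warns <- list()
  note <- function(sample, clone, term, message) {
    warns[[length(warns) + 1L]] <<- data.frame(
      sample = sample, clone = clone, term = term, message = message,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(karyotypes)) {
    sid <- sample_ids[i]
    rec <- tryCatch(parse_karyotype(karyotypes[i], sample_id = sid),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      note(sid, NA_integer_, karyotypes[i], conditionMessage(rec))
      next
    }
    for (j in seq_len(nrow(rec$warnings)))
      note(sid, rec$warnings$clone[j], rec$warnings$term[j],
           rec$warnings$message[j])
    counts <- vapply(rec$clones, function(cl) cl$cells$count, integer(1))
    known <- !is.na(counts)
    total <- if (any(known)) sum(counts[known]) else NA_integer_
    if (any(known) && any(!known))
      note(sid, NA_integer_, "[cells]",
           "clones without cell counts are excluded from the sample total")
    for (cl in rec$clones) {
      cid <- paste0(sid, "_", cl$ordinal)
      prof <- clone_profile(cl, map, clone_id = cid)
      profiles[[cid]] <- prof
      for (w in prof$warnings) note(sid, cl$ordinal, "", w)
      if (nrow(prof$segments)) {
        s <- prof$segments
        rows[[length(rows) + 1L]] <- data.frame(
          sample_clone = cid, chrom = s$chrom, start = s$start, end = s$end,
          type = s$type, cells = cells_string(cl$cells$count, total),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_clone = character(), chrom = character(),
               start = numeric(), end = numeric(), type = character(),
               cells = character(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  warns <- if (length(warns)) do.call(rbind, warns) else
    data.frame(sample = character(), clone = integer(), term = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(table = tab, warnings = warns, profiles = profiles,
                 assembly = map$assembly),
            class = "karyo_result")
}

#' @export
print.karyo_result <- function(x, ...) {
  cat("<karyo_result: ", length(x$profiles), " clone(s), ",
      nrow(x$table), " gain/loss row(s), ", nrow(x$warnings),
      " warning(s), assembly ", x$assembly, ">\n", sep = "")
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Write the gain/loss report as tab-delimited text
#'
#' Columns: Sample ID, Chr, Start, End, Type, Cells Present. Coordinates
#' are plain integers; `pretty = TRUE` adds thousands separators for
#' display.
#'
#' @param x a `karyo_result` or its `table` data.frame.
#' @param path output file; "" returns the lines invisibly without writing.
#' @param pretty add thousands separators to coordinates.
#' @return the output lines, invisibly.
#' @export
write_table <- function(x, path = "", pretty = FALSE) {
  tab <- if (inherits(x, "karyo_result")) x$table else x
  fmt <- function(v) {
    if (pretty) formatC(v, big.mark = ",", format = "d")
    else sprintf("%d", as.integer(v))
  }
  lines <- c(paste(c("Sample ID", "Chr", "Start", "End", "Type",
                     "Cells Present"), collapse = "\t"))
  if (nrow(tab))
    lines <- c(lines, paste(tab$sample_clone, tab$chrom, fmt(tab$start),
                            fmt(tab$end), tab$type, tab$cells, sep = "\t"))
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write the warnings side-channel as tab-delimited text
#'
#' @param x a `karyo_result`.
#' @param path output file.
#' @return the output lines, invisibly.
#' @export
write_warnings <- function(x, path = "") {
  w <- x$warnings
  lines <- c("Sample\tClone\tTerm\tMessage",
             if (nrow(w)) paste(w$sample, w$clone, w$term, w$message, sep = "\t"))
  if (nzchar(path)) writeLines(lines, path)
  invisible(lines)
}
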