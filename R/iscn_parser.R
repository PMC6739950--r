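# ISCN karyotype string parsing: clone splitting, clone headers, and a
# recursive tokenizer for individual aberration terms.
#
# Parsing is deliberately forgiving: anything unrecognized degrades to an
# unknown_term carried on the warnings channel, so a large batch never
# aborts on one odd string.

# split on sep characters at depth 0 of () and []
split_top_level <- function(s, sep) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  depth <- 0L
  cut <- logical(length(chars))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% c("(", "[")) depth <- depth + 1L
    else if (ch %in% c(")", "]")) depth <- max(0L, depth - 1L)
    else if (ch == sep && depth == 0L) cut[i] <- TRUE
  }
  if (!any(cut)) return(s)
  idx <- cumsum(cut)
  vapply(split(chars[!cut], idx[!cut]), paste, character(1), collapse = "")
}

#' Split a karyotype into clones
#'
#' Clones are separated by "/" at the top level (never inside parentheses
#' or brackets). A trailing "[n]" or "[cp n]" is the clone's cell count;
#' absent counts are reported as unknown.
#'
#' @param karyotype an ISCN karyotype string.
#' @return list of `list(text, cells = list(count, composite))` per clone.
#' @export
split_clones <- function(karyotype) {
  s <- trimws(karyotype)
  if (!nzchar(s)) stop("empty karyotype string", call. = FALSE)
  parts <- split_top_level(s, "/")
  lapply(parts, function(p) {
    p <- trimws(p)
    cells <- list(count = NA_integer_, composite = FALSE)
    m <- regexpr("\\[\\s*(cp)?\\s*([0-9]+)\\s*\\]\\s*$", p, perl = TRUE)
    if (m > 0L) {
      tail <- substr(p, m, nchar(p))
      cells$composite <- grepl("cp", tail, fixed = TRUE)
      cells$count <- as.integer(gsub("[^0-9]", "", tail))
      p <- trimws(substr(p, 1L, m - 1L))
    }
    list(text = p, cells = cells)
  })
}

new_aberration <- function(operator = "none", kind = "unknown_term",
                           chroms = character(), breakpoints = list(),
                           uncertain = FALSE, constitutional = FALSE,
                           mult = 1L, raw = "", segments = NULL) {
  structure(list(operator = operator, kind = kind, chroms = chroms,
                 breakpoints = breakpoints, uncertain = uncertain,
                 constitutional = constitutional, mult = mult,
                 raw = raw, segments = segments),
            class = "iscn_aberration")
}

#' @export
format.iscn_aberration <- function(x, ...) {
  bp <- vapply(x$breakpoints, paste, character(1), collapse = ",")
  sprintf("%s%s(%s)(%s)", switch(x$operator, plus = "+", minus = "-", ""),
          x$kind, paste(x$chroms, collapse = ";"), paste(bp, collapse = ";"))
}

#' @export
print.iscn_aberration <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

# "q21.31q27.2" -> c("q21.31","q27.2"); also handles a single label
split_band_labels <- function(s) {
  s <- gsub("([pq])\\.", "\\1", s)   # tolerate a stray dot after the arm letter
  m <- gregexpr("[pq][0-9]*(\\.[0-9]+)?", s)[[1L]]
  if (m[1L] < 0L) return(character())
  out <- regmatches(s, list(m))[[1L]]
  if (sum(nchar(out)) != nchar(s)) return(character())  # leftover junk
  out
}

# tokens of a structured term: heads ("der","t",...) and "(...)" groups
term_tokens <- function(s) {
  m <- gregexpr("[a-z]+|\\([^()]*\\)", s)[[1L]]
  if (m[1L] < 0L) return(character())
  toks <- regmatches(s, list(m))[[1L]]
  if (sum(nchar(toks)) != nchar(s)) return(character())
  toks
}

group_content <- function(tok) substr(tok, 2L, nchar(tok) - 1L)
is_group <- function(tok) startsWith(tok, "(")

#' Parse one ISCN aberration term
#'
#' Recognizes the common ISCN 2016 forms (whole-chromosome gains/losses,
#' del/dup/trp, isochromosomes, whole-arm and translocation derivatives,
#' add, balanced t/inv/ins, rings, markers, dmin, hsr, idem). Whitespace
#' is ignored, "?" marks the term uncertain, a trailing "c" marks it
#' constitutional, and a "xN" suffix records multiplicity. Anything else
#' becomes `kind = "unknown_term"` — this function never throws.
#'
#' @param term one comma-field of a clone designation, e.g. "+der(10)t(10;21)(p13;q21)".
#' @return an `iscn_aberration` object.
#' @export
parse_term <- function(term) {
  raw <- term
  s <- gsub("[[:space:]]", "", term)
  ab <- new_aberration(raw = raw)
  if (!nzchar(s)) return(ab)

  m <- regexpr("[xX]([0-9]+)$", s)
  if (m > 0L && nchar(s) > attr(m, "match.length")) {
    ab$mult <- as.integer(sub("^[xX]", "", substr(s, m, nchar(s))))
    s <- substr(s, 1L, m - 1L)
  }
  if (grepl("?", s, fixed = TRUE)) {
    ab$uncertain <- TRUE
    if (grepl("\\(\\?+\\)", s)) return(ab)       # fully unknown breakpoints
    s <- gsub("?", "", s, fixed = TRUE)
    if (!nzchar(s)) return(ab)
  }
  if (grepl("[)0-9XYxy]c$", s)) {
    ab$constitutional <- TRUE
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  if (startsWith(s, "+")) { ab$operator <- "plus"; s <- substring(s, 2L) }
  else if (startsWith(s, "-")) { ab$operator <- "minus"; s <- substring(s, 2L) }
  if (!nzchar(s)) return(ab)

  # whole-chromosome gain/loss: needs the +/- operator
  if (grepl("^([0-9]{1,2}|[XYxy])$", s)) {
    chrom <- normalize_chrom(s)
    if (ab$operator != "none" && !is.na(chrom)) {
      ab$kind <- "whole_chrom"; ab$chroms <- chrom
      return(ab)
    }
    return(ab)   # bare chromosome with no operator: unknown_term
  }
  low <- tolower(s)
  if (low == "idem") { ab$kind <- "idem"; return(ab) }
  if (grepl("^[0-9]*mar$", low)) { ab$kind <- "marker"; return(ab) }
  if (grepl("^[0-9]*dmin$", low)) { ab$kind <- "dmin"; return(ab) }
  if (startsWith(low, "hsr")) { ab$kind <- "hsr"; return(ab) }
  if (low == "r") { ab$kind <- "ring"; return(ab) }

  toks <- term_tokens(low)
  if (length(toks) < 2L || is_group(toks[1L])) return(ab)
  head <- toks[1L]
  groups <- toks[-1L]
  if (!all(vapply(groups[!grepl("^[a-z]+$", groups)], is_group, logical(1))))
    return(ab)

  parse_chroms <- function(g) {
    cs <- normalize_chrom(strsplit(group_content(g), ";", fixed = TRUE)[[1L]])
    if (any(is.na(cs))) NULL else cs
  }

  if (head == "i" || head == "ider") {
    # i(17q) shorthand, or i(17)(q10)
    g1 <- group_content(groups[1L])
    mm <- regmatches(g1, regexec("^([0-9]{1,2}|[xy])([pq])$", g1))[[1L]]
    if (length(mm) == 3L) {
      chrom <- normalize_chrom(mm[2L]); arm <- mm[3L]
    } else if (length(groups) >= 2L) {
      chrom <- normalize_chrom(g1)
      bp <- split_band_labels(group_content(groups[2L]))
      if (length(bp) != 1L || !grepl("^[pq]10$", bp)) return(ab)
      arm <- substr(bp, 1L, 1L)
    } else return(ab)
    if (is.na(chrom)) return(ab)
    ab$kind <- if (head == "ider") "ider" else "iso"
    ab$chroms <- chrom
    ab$breakpoints <- list(paste0(arm, "10"))
    return(ab)
  }

  if (head %in% c("del", "dup", "trp", "inv", "add", "r")) {
    if (length(groups) < 2L || !is_group(groups[2L])) {
      if (head == "r" && length(groups) == 1L) {  # r(c) without breakpoints
        cs <- parse_chroms(groups[1L])
        if (is.null(cs) || length(cs) != 1L) return(ab)
        ab$kind <- "ring"; ab$chroms <- cs
        return(ab)
      }
      return(ab)
    }
    cs <- parse_chroms(groups[1L])
    bp <- split_band_labels(group_content(groups[2L]))
    if (is.null(cs) || length(cs) != 1L || !length(bp)) return(ab)
    nbp <- c(del = 2L, dup = 2L, trp = 2L, inv = 2L, add = 1L, r = 2L)[[head]]
    if (length(bp) > nbp || (head != "del" && length(bp) < nbp)) return(ab)
    ab$kind <- switch(head, del = "del", dup = "dup", trp = "trp",
                      inv = "inversion", add = "add", r = "ring")
    ab$chroms <- cs
    ab$breakpoints <- list(bp)
    return(ab)
  }

  if (head == "t") {
    cs <- parse_chroms(groups[1L])
    if (is.null(cs) || length(cs) < 2L) return(ab)
    ab$kind <- "translocation"; ab$chroms <- cs
    if (length(groups) >= 2L && is_group(groups[2L])) {
      bp <- strsplit(group_content(groups[2L]), ";", fixed = TRUE)[[1L]]
      if (length(bp) == length(cs)) ab$breakpoints <- as.list(bp)
    }
    return(ab)
  }

  if (head == "ins") {
    cs <- parse_chroms(groups[1L])
    if (is.null(cs)) return(ab)
    ab$kind <- "insertion"; ab$chroms <- cs
    return(ab)
  }

  if (head == "der") {
    cs <- parse_chroms(groups[1L])
    if (is.null(cs)) return(ab)
    if (length(cs) == 2L) {
      # whole-arm derivative der(1;19)(q10;p10)
      if (length(groups) < 2L || !is_group(groups[2L])) return(ab)
      bp <- strsplit(group_content(groups[2L]), ";", fixed = TRUE)[[1L]]
      if (length(bp) != 2L || !all(grepl("^[pq]10$", bp))) return(ab)
      ab$kind <- "der_whole_arm"; ab$chroms <- cs
      ab$breakpoints <- list(bp[1L], bp[2L])
      return(ab)
    }
    if (length(cs) != 1L) return(ab)
    # der(c) followed by one or more t(a;b)(b1;b2) segments
    rest <- groups[-1L]
    segs <- list()
    i <- 1L
    while (i <= length(rest)) {
      if (rest[i] != "t" || i + 2L > length(rest) ||
          !is_group(rest[i + 1L]) || !is_group(rest[i + 2L])) return(ab)
      tc <- parse_chroms(rest[i + 1L])
      tb <- strsplit(group_content(rest[i + 2L]), ";", fixed = TRUE)[[1L]]
      if (is.null(tc) || length(tc) != 2L || length(tb) != 2L ||
          !all(grepl("^[pq][0-9]*(\\.[0-9]+)?$", tb))) return(ab)
      segs[[length(segs) + 1L]] <- list(chroms = tc, bkpts = tb)
      i <- i + 3L
    }
    if (!length(segs)) return(ab)
    ab$kind <- "der_translocation"
    ab$segments <- segs
    # flattened view: base chrom with its own breakpoint, then each joined piece
    ch <- cs; bps <- list()
    cur <- cs
    for (k in seq_along(segs)) {
      sc <- segs[[k]]$chroms; sb <- segs[[k]]$bkpts
      if (sc[1L] == cur) { own <- sb[1L]; nxt <- sc[2L]; nb <- sb[2L] }
      else if (sc[2L] == cur) { own <- sb[2L]; nxt <- sc[1L]; nb <- sb[1L] }
      else return(ab)    # unchainable three-way
      if (k == 1L) bps[[1L]] <- own
      ch <- c(ch, nxt); bps[[length(bps) + 1L]] <- nb
      cur <- nxt
    }
    ab$chroms <- ch
    ab$breakpoints <- bps
    return(ab)
  }

  ab
}

new_clone_spec <- function(ordinal) {
  structure(list(ordinal = ordinal, modal_low = NA_integer_,
                 modal_high = NA_integer_, ploidy = 2L,
                 sex = character(), aberrations = list(),
                 cells = list(count = NA_integer_, composite = FALSE),
                 idem = FALSE, warnings = list()),
            class = "clone_spec")
}

clone_warn <- function(clone, term, msg) {
  clone$warnings[[length(clone$warnings) + 1L]] <-
    list(term = term, message = msg)
  clone
}

#' Parse one clone designation
#'
#' The first comma-field is the modal number (an integer, a range "44~46",
#' optionally with a ploidy marker like "<2n>"); the second, when made of
#' X/Y characters only, is the sex designation; every remaining field is
#' parsed as an aberration term. Commas inside parentheses never split.
#'
#' @param clone_text one clone's designation, without the cell-count bracket.
#' @param ordinal 1-based clone index within the karyotype.
#' @return a `clone_spec` object.
#' @export
parse_clone <- function(clone_text, ordinal = 1L) {
  clone <- new_clone_spec(ordinal)
  fields <- trimws(split_top_level(trimws(clone_text), ","))
  fields <- fields[nzchar(fields)]
  if (!length(fields)) {
    return(clone_warn(clone, clone_text, "empty clone designation"))
  }
  f1 <- gsub("[[:space:]]", "", fields[1L])
  m <- regmatches(f1, regexec(
    "^\\??([0-9]+)(~([0-9]+))?(<([0-9]+)n>)?\\??$", f1))[[1L]]
  if (length(m)) {
    clone$modal_low <- as.integer(m[2L])
    clone$modal_high <- if (nzchar(m[4L])) as.integer(m[4L]) else clone$modal_low
    if (nzchar(m[6L])) clone$ploidy <- as.integer(m[6L])
    fields <- fields[-1L]
  } else {
    clone <- clone_warn(clone, fields[1L],
                        "unparseable modal number; clone kept with modal unknown")
    # the field stays in line and is parsed as sex or a term below
  }
  if (length(fields)) {
    f <- gsub("[[:space:]]", "", fields[1L])
    if (grepl("^[XYxy?]+$", f) && grepl("[XYxy]", f)) {
      clone$sex <- strsplit(toupper(gsub("\\?", "", f)), "")[[1L]]
      fields <- fields[-1L]
    }
  }
  for (f in fields) {
    ab <- parse_term(f)
    if (ab$kind == "idem") {
      clone$idem <- TRUE
      next
    }
    if (ab$kind == "unknown_term")
      clone <- clone_warn(clone, f, "unrecognized term")
    else if (ab$uncertain)
      clone <- clone_warn(clone, f, "term marked uncertain ('?'); processed as written")
    if (ab$constitutional)
      clone <- clone_warn(clone, f, "constitutional aberration; included in output")
    reps <- max(1L, ab$mult)
    ab$mult <- 1L
    for (i in seq_len(reps))
      clone$aberrations[[length(clone$aberrations) + 1L]] <- ab
  }
  clone
}

#' Parse a full karyotype into a record of clones
#'
#' Splits the karyotype on "/", parses each clone, expands "idem" (a later
#' clone inheriting the stemline's aberration list), and collects all
#' per-term warnings into one table. Warnings never abort the record.
#'
#' @param karyotype an ISCN karyotype string.
#' @param sample_id sample name used in output ("sample_1" by default).
#' @return a `karyotype_record`: list of clones plus a warnings data.frame.
#' @export
parse_karyotype <- function(karyotype, sample_id = "sample_1") {
  pieces <- split_clones(karyotype)
  clones <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    cl <- parse_clone(pieces[[i]]$text, ordinal = i)
    cl$cells <- pieces[[i]]$cells
    clones[[i]] <- cl
  }
  for (i in seq_along(clones)) {
    if (clones[[i]]$idem && i > 1L) {
      clones[[i]]$aberrations <-
        c(clones[[1L]]$aberrations, clones[[i]]$aberrations)
    } else if (clones[[i]]$idem) {
      clones[[i]] <- clone_warn(clones[[i]], "idem",
                                "'idem' in the first clone has no stemline to copy")
    }
  }
  w <- do.call(rbind, lapply(clones, function(cl) {
    if (!length(cl$warnings)) return(NULL)
    data.frame(clone = cl$ordinal,
               term = vapply(cl$warnings, `[[`, character(1), "term"),
               message = vapply(cl$warnings, `[[`, character(1), "message"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(w))
    w <- data.frame(clone = integer(), term = character(),
                    message = character(), stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, clones = clones, warnings = w),
            class = "karyotype_record")
}

#' One-line-per-term diagnostic dump of a parsed karyotype
#'
#' @param record a `karyotype_record`.
#' @return character vector, one line per clone header and term.
#' @export
iscn_dump <- function(record) {
  out <- character()
  for (cl in record$clones) {
    out <- c(out, sprintf(
      "clone %d: modal=%s%s sex=%s cells=%s%s", cl$ordinal,
      ifelse(is.na(cl$modal_low), "?", cl$modal_low),
      ifelse(!is.na(cl$modal_high) && !is.na(cl$modal_low) &&
               cl$modal_high != cl$modal_low, paste0("~", cl$modal_high), ""),
      if (length(cl$sex)) paste(cl$sex, collapse = "") else "-",
      ifelse(is.na(cl$cells$count), "unknown", cl$cells$count),
      if (cl$idem) " idem" else ""))
    for (ab in cl$aberrations)
      out <- c(out, sprintf("  [%s] %s <- %s", ab$kind, format(ab), ab$raw))
  }
  out
}

#' @export
print.karyotype_record <- function(x, ...) {
  cat(x$sample_id, ": ", length(x$clones), " clone(s), ",
      nrow(x$warnings), " warning(s)\n", sep = "")
  cat(iscn_dump(x), sep = "\n")
  invisible(x)
}
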