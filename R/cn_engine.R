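# Copy-number engine: aberration terms -> signed copy deltas on genomic
# intervals, an interval sweep that accumulates them into a net per-clone
# profile, and gain / hemizygous-loss / homozygous-loss classification.
#
# Only explicit aberration terms generate deltas; the modal number and the
# sex designation never do on their own. Everything is net change relative
# to the clone's baseline (diploid autosomes unless a <kn> ploidy marker
# says otherwise; sex chromosomes counted from the sex designation plus
# the homologs consumed by structural terms).

delta_row <- function(chrom, start, end, delta) {
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             delta = as.integer(delta), stringsAsFactors = FALSE)
}

other_arm <- function(arm) if (arm == "p") "q" else "p"

arm_of <- function(label) substr(normalize_band_label(label), 1L, 1L)

# interval from a breakpoint band to the telomere of the band's own arm,
# band wholly included
distal_span <- function(map, chrom, band) {
  b <- resolve_band(map, chrom, band)
  if (arm_of(band) == "p") genomic_interval(chrom, 0, b$end)
  else genomic_interval(chrom, b$start, map$chrom_lengths[[chrom]])
}

# interval from a breakpoint band through the centromere to the far
# telomere, band wholly included (the piece a derivative retains)
retained_span <- function(map, chrom, band) {
  b <- resolve_band(map, chrom, band)
  if (arm_of(band) == "p") genomic_interval(chrom, b$start, map$chrom_lengths[[chrom]])
  else genomic_interval(chrom, 0, b$end)
}

span_between <- function(map, chrom, band1, band2) {
  b1 <- resolve_band(map, chrom, band1)
  b2 <- resolve_band(map, chrom, band2)
  genomic_interval(chrom, min(b1$start, b2$start), max(b1$end, b2$end))
}

#' Copy-number deltas implied by one aberration
#'
#' Maps a parsed aberration to a list of signed copy deltas over genomic
#' intervals. Balanced events (translocations, inversions, insertions)
#' produce none; markers, dmin, hsr and bare rings produce none but carry
#' a warning; breakpoint bands are always wholly included in the segment
#' the event describes. Unresolvable bands skip the aberration with a
#' warning rather than failing.
#'
#' @param ab an `iscn_aberration` (kind != "unknown_term").
#' @param map a `band_map`.
#' @return data.frame chrom/start/end/delta with a "warnings" attribute.
#' @export
event_deltas <- function(ab, map) {
  warn <- character()
  add_warn <- function(msg) warn <<- c(warn, paste0(ab$raw, ": ", msg))
  rows <- list()
  push <- function(iv, delta) {
    if (iv$end > iv$start)
      rows[[length(rows) + 1L]] <<- delta_row(iv$chrom, iv$start, iv$end, delta)
  }
  done <- function() {
    out <- if (length(rows)) do.call(rbind, rows) else delta_row(character(), numeric(), numeric(), integer())
    attr(out, "warnings") <- warn
    out
  }
  op <- ab$operator
  res <- try(switch(
    ab$kind,
    whole_chrom = {
      ch <- ab$chroms[1L]
      if (!ch %in% names(map$chrom_lengths)) stop(band_error(ch, "<whole>"))
      push(genomic_interval(ch, 0, map$chrom_lengths[[ch]]),
           if (op == "minus") -1L else 1L)
    },
    del = {
      ch <- ab$chroms[1L]; bp <- ab$breakpoints[[1L]]
      iv <- if (length(bp) == 1L) distal_span(map, ch, bp)
            else span_between(map, ch, bp[1L], bp[2L])
      push(iv, -1L)
    },
    dup = {
      ch <- ab$chroms[1L]; bp <- ab$breakpoints[[1L]]
      push(span_between(map, ch, bp[1L], bp[2L]), 1L)
    },
    trp = {
      ch <- ab$chroms[1L]; bp <- ab$breakpoints[[1L]]
      push(span_between(map, ch, bp[1L], bp[2L]), 2L)
    },
    iso = ,
    ider = {
      ch <- ab$chroms[1L]; arm <- arm_of(ab$breakpoints[[1L]])
      if (ab$kind == "ider" && !is.null(ab$segments))
        add_warn("translocation segments on ider ignored; treated as isochromosome")
      if (op == "plus") {
        push(arm_interval(map, ch, arm), 2L)
      } else if (op == "minus") {
        add_warn("loss of an isochromosome; counted as -2 on the doubled arm")
        push(arm_interval(map, ch, arm), -2L)
      } else {
        push(arm_interval(map, ch, arm), 1L)
        push(arm_interval(map, ch, other_arm(arm)), -1L)
      }
    },
    der_whole_arm = {
      a1 <- arm_of(ab$breakpoints[[1L]]); a2 <- arm_of(ab$breakpoints[[2L]])
      c1 <- ab$chroms[1L]; c2 <- ab$chroms[2L]
      if (op == "plus") {
        push(arm_interval(map, c1, a1), 1L)
        push(arm_interval(map, c2, a2), 1L)
      } else {
        if (op == "minus")
          add_warn("loss of a whole-arm derivative; counted as loss of its retained arms")
        if (op == "minus") {
          push(arm_interval(map, c1, a1), -1L)
          push(arm_interval(map, c2, a2), -1L)
        } else {
          push(arm_interval(map, c1, other_arm(a1)), -1L)
          push(arm_interval(map, c2, other_arm(a2)), -1L)
        }
      }
    },
    der_translocation = {
      base <- ab$chroms[1L]
      segs <- ab$segments
      # walk the t() chain, assembling the retained pieces
      first <- segs[[1L]]
      if (first$chroms[1L] == base) { b_own <- first$bkpts[1L]; cur <- first$chroms[2L]; b_cur <- first$bkpts[2L] }
      else { b_own <- first$bkpts[2L]; cur <- first$chroms[1L]; b_cur <- first$bkpts[1L] }
      kept <- retained_span(map, base, b_own)
      lost <- if (arm_of(b_own) == "p")
        genomic_interval(base, 0, kept$start)
      else genomic_interval(base, kept$end, map$chrom_lengths[[base]])
      pieces <- list()
      for (sg in segs[-1L]) {
        if (sg$chroms[1L] == cur) { b2 <- sg$bkpts[1L]; nxt <- sg$chroms[2L]; b_nxt <- sg$bkpts[2L] }
        else if (sg$chroms[2L] == cur) { b2 <- sg$bkpts[2L]; nxt <- sg$chroms[1L]; b_nxt <- sg$bkpts[1L] }
        else stop(band_error(cur, "unchainable der() segment"))
        pieces[[length(pieces) + 1L]] <- span_between(map, cur, b_cur, b2)
        cur <- nxt; b_cur <- b_nxt
      }
      pieces[[length(pieces) + 1L]] <- distal_span(map, cur, b_cur)
      if (op == "plus") {
        push(kept, 1L)
        for (p in pieces) push(p, 1L)
      } else if (op == "minus") {
        add_warn("loss of a translocation derivative; counted as loss of its pieces")
        push(kept, -1L)
        for (p in pieces) push(p, -1L)
      } else {
        push(lost, -1L)
        for (p in pieces) push(p, 1L)
      }
    },
    add = {
      ch <- ab$chroms[1L]; b <- ab$breakpoints[[1L]][1L]
      ret <- retained_span(map, ch, b)
      if (op == "plus") {
        push(ret, 1L)
      } else {
        iv <- resolve_band(map, ch, b)
        if (arm_of(b) == "p") push(genomic_interval(ch, 0, iv$start), -1L)
        else push(genomic_interval(ch, iv$end, map$chrom_lengths[[ch]]), -1L)
      }
    },
    ring = {
      if (!length(ab$breakpoints)) {
        add_warn("ring without breakpoints; no net change inferred")
      } else {
        ch <- ab$chroms[1L]; bp <- ab$breakpoints[[1L]]
        b1 <- resolve_band(map, ch, bp[1L]); b2 <- resolve_band(map, ch, bp[2L])
        lo <- min(b1$start, b2$start); hi <- max(b1$end, b2$end)
        if (op == "plus") {
          push(genomic_interval(ch, lo, hi), 1L)
        } else {
          push(genomic_interval(ch, 0, lo), -1L)
          push(genomic_interval(ch, hi, map$chrom_lengths[[ch]]), -1L)
        }
      }
    },
    translocation = ,
    inversion = ,
    insertion = NULL,   # balanced: no net change
    marker = add_warn("marker chromosome of unknown content; no net change inferred"),
    dmin = add_warn("double minutes; no net change inferred"),
    hsr = add_warn("homogeneously staining region; no net change inferred"),
    idem = NULL,
    stop(band_error(ab$chroms[1L], ab$raw))
  ), silent = TRUE)
  if (inherits(res, "try-error")) {
    cond <- attr(res, "condition")
    rows <- list()
    add_warn(paste0("skipped: ", conditionMessage(cond)))
  }
  done()
}

#' Per-chromosome baseline copy counts for a clone
#'
#' Autosomes sit at the clone's ploidy (2 unless a `<kn>` marker says
#' otherwise). A sex chromosome's baseline is its count in the sex
#' designation plus one for every structural aberration (without a "+"
#' operator) whose base chromosome it is — ISCN leaves the rearranged
#' homolog out of the sex field, so "46,X,del(X)(...)" still has two X's.
#'
#' @param clone a `clone_spec`.
#' @param map a `band_map`.
#' @return named integer vector of baseline copy counts (zero-copy
#'   chromosomes omitted).
#' @export
clone_baseline <- function(clone, map) {
  chroms <- names(map$chrom_lengths)
  base <- stats::setNames(rep(clone$ploidy, length(chroms)), chroms)
  for (sx in c("chrX", "chrY")) {
    if (!sx %in% chroms) next
    n <- sum(paste0("chr", clone$sex) == sx)
    structural <- c("del", "dup", "trp", "iso", "ider", "der_whole_arm",
                    "der_translocation", "add", "ring", "inversion")
    for (ab in clone$aberrations) {
      if (ab$operator != "plus" && ab$kind %in% structural &&
          length(ab$chroms) && ab$chroms[1L] == sx)
        n <- n + 1L
    }
    base[[sx]] <- n
  }
  base[base > 0L]
}

#' Accumulate copy deltas into maximal constant segments
#'
#' A sweep over interval endpoints sums overlapping deltas per chromosome;
#' maximal runs of equal nonzero net delta become segments, zero regions
#' are dropped, and adjacent equal segments merge.
#'
#' @param deltas data.frame chrom/start/end/delta (as from [event_deltas]).
#' @param map a `band_map` (for bounds checking).
#' @return data.frame chrom/start/end/delta, sorted by chromosome then start.
#' @export
accumulate_deltas <- function(deltas, map) {
  empty <- delta_row(character(), numeric(), numeric(), integer())
  if (is.null(deltas) || !nrow(deltas)) return(empty)
  stopifnot(all(deltas$start >= 0),
            all(deltas$end <= map$chrom_lengths[deltas$chrom]))
  deltas <- deltas[deltas$end > deltas$start & deltas$delta != 0L, , drop = FALSE]
  out <- list()
  for (ch in unique(deltas$chrom)) {
    d <- deltas[deltas$chrom == ch, , drop = FALSE]
    pos <- sort(unique(c(d$start, d$end)))
    step <- numeric(length(pos))
    for (i in seq_len(nrow(d))) {
      step[match(d$start[i], pos)] <- step[match(d$start[i], pos)] + d$delta[i]
      step[match(d$end[i], pos)] <- step[match(d$end[i], pos)] - d$delta[i]
    }
    net <- cumsum(step)        # value on [pos[i], pos[i+1])
    n <- length(pos) - 1L
    if (n < 1L) next
    seg_start <- pos[1L]; cur <- net[1L]
    for (i in seq_len(n)) {
      nxt_val <- if (i < n) net[i + 1L] else NA
      if (i == n || nxt_val != cur) {
        if (cur != 0)
          out[[length(out) + 1L]] <- delta_row(ch, seg_start, pos[i + 1L], cur)
        if (i < n) { seg_start <- pos[i + 1L]; cur <- nxt_val }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify a net copy delta against its baseline
#'
#' Net copies above baseline are a Gain; below baseline but still positive,
#' a hemizygous Loss; at or below zero, a homozygous Loss (net copies clamp
#' at zero).
#'
#' @param delta nonzero integer net copy change.
#' @param baseline reference copy count (>= 1).
#' @return list with `label` ("Gain"/"Loss") and `zygosity`
#'   ("hemizygous"/"homozygous"/"not_applicable").
#' @export
classify_segment <- function(delta, baseline) {
  stopifnot(baseline >= 1, delta != 0)
  net <- baseline + delta
  if (net > baseline) list(label = "Gain", zygosity = "not_applicable")
  else if (net > 0) list(label = "Loss", zygosity = "hemizygous")
  else list(label = "Loss", zygosity = "homozygous")
}

# rough implied chromosome count, for the modal-consistency warning only
implied_count <- function(clone) {
  n <- 22L * clone$ploidy + length(clone$sex)
  structural <- c("del", "dup", "trp", "iso", "ider", "der_translocation",
                  "add", "ring", "inversion")
  for (ab in clone$aberrations) {
    if (length(ab$chroms) && ab$chroms[1L] %in% c("chrX", "chrY") &&
        ab$operator != "plus" &&
        ab$kind %in% c(structural, "der_whole_arm"))
      n <- n + 1L   # the rearranged homolog missing from the sex field
    n <- n + switch(ab$kind,
      whole_chrom = if (ab$operator == "minus") -1L else 1L,
      der_whole_arm = if (ab$operator == "plus") 1L else -1L,
      marker = , dmin = , ring = if (ab$operator == "plus") 1L else 0L,
      iso = , ider = , der_translocation = if (ab$operator == "plus") 1L else 0L,
      0L)
  }
  n
}

#' Net copy-number profile of one clone
#'
#' Runs [event_deltas] over the clone's aberrations, accumulates the deltas
#' into maximal segments, and classifies each against the chromosome's
#' baseline. Deltas on a chromosome with baseline zero are dropped with a
#' warning; over-subtraction below zero copies is clamped and warned about.
#'
#' @param clone a `clone_spec`.
#' @param map a `band_map`.
#' @param clone_id label for the profile (e.g. "sample_1").
#' @return a `cn_profile`: clone_id, segments data.frame
#'   (chrom/start/end/delta/baseline/type/zygosity), baseline vector,
#'   warnings character vector.
#' @export
clone_profile <- function(clone, map, clone_id = "sample_1") {
  warn <- character()
  deltas <- list()
  for (ab in clone$aberrations) {
    if (ab$kind %in% c("unknown_term", "idem")) next
    d <- event_deltas(ab, map)
    warn <- c(warn, attr(d, "warnings"))
    if (nrow(d)) deltas[[length(deltas) + 1L]] <- d
  }
  deltas <- if (length(deltas)) do.call(rbind, deltas) else NULL
  base <- clone_baseline(clone, map)
  segs <- accumulate_deltas(deltas, map)
  keep <- segs$chrom %in% names(base)
  if (any(!keep)) {
    warn <- c(warn, paste0("dropped change on zero-baseline chromosome ",
                           unique(segs$chrom[!keep])))
    segs <- segs[keep, , drop = FALSE]
  }
  if (nrow(segs)) {
    segs$baseline <- as.integer(base[segs$chrom])
    cls <- Map(classify_segment, segs$delta, segs$baseline)
    segs$type <- vapply(cls, `[[`, character(1), "label")
    segs$zygosity <- vapply(cls, `[[`, character(1), "zygosity")
    over <- segs$delta < -segs$baseline
    if (any(over))
      warn <- c(warn, sprintf("%s:%d-%d loses more copies than the baseline holds; clamped at zero",
                              segs$chrom[over], segs$start[over], segs$end[over]))
  } else {
    segs$baseline <- integer(); segs$type <- character(); segs$zygosity <- character()
  }
  if (!is.na(clone$modal_low)) {
    imp <- implied_count(clone)
    if (imp < clone$modal_low || imp > clone$modal_high)
      warn <- c(warn, sprintf(
        "modal number %s inconsistent with aberration list (implies %d chromosomes)",
        clone$modal_low, imp))
  }
  if (!length(clone$aberrations) && length(clone$sex) == 1L &&
      clone$sex[1L] == "X" && !is.na(clone$modal_low) && clone$modal_low == 45L)
    warn <- c(warn, "45,X without an explicit -X term: sex-chromosome loss is not reported")
  rownames(segs) <- NULL
  structure(list(clone_id = clone_id, segments = segs, baseline = base,
                 warnings = warn),
            class = "cn_profile")
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("<cn_profile ", x$clone_id, ": ", nrow(x$segments), " segment(s)>\n", sep = "")
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}
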