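# Synthetic fixtures: toy band maps, a random valid-karyotype generator,
# and a constructive copy-number oracle.
#
# The generator assembles every clone as an explicit list of homologs,
# each a list of (chrom, start, end) pieces. Events always target a fresh,
# untouched homolog, so the clone state is never self-contradictory, and
# the expected gain/loss segments ("truth") fall out of simple per-base
# piece coverage minus the starting copy counts — no parsing and no
# interval-delta logic shared with the engine under test.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Build a small valid toy band map
#'
#' Every chromosome gets `bands_per_arm` bands per arm, the innermost pair
#' ("p11"/"q11") carrying the acen stain, with the centromere fixed at the
#' chromosome midpoint and remaining band edges drawn at random. The
#' result always satisfies full band-map validation and is deterministic
#' for a given seed.
#'
#' @param n_chroms number of chromosomes (1..22, named chr1..chrN).
#' @param bands_per_arm bands per arm including the acen band (1..9).
#' @param chrom_length length of every chromosome in bases.
#' @param seed RNG seed.
#' @return a `band_map` with assembly "toy".
#' @export
make_toy_bandmap <- function(n_chroms, bands_per_arm, chrom_length, seed = 1L) {
  stopifnot(n_chroms >= 1, n_chroms <= 22, bands_per_arm >= 1,
            bands_per_arm <= 9, chrom_length >= 4 * bands_per_arm)
  m <- bands_per_arm
  with_seed(seed, {
    rows <- list()
    for (ci in seq_len(n_chroms)) {
      ch <- paste0("chr", ci)
      half <- chrom_length %/% 2L
      cut_arm <- function(lo, hi) {
        if (m == 1L) return(c(lo, hi))
        c(lo, lo + sort(sample(seq_len(hi - lo - 1L), m - 1L)), hi)
      }
      pe <- cut_arm(0L, half)
      qe <- cut_arm(half, chrom_length)
      plabs <- paste0("p1", m:1)        # telomere-first: p13 p12 p11
      qlabs <- paste0("q1", 1:m)
      stain <- function(labs) ifelse(labs %in% c("p11", "q11"), "acen",
                                     rep_len(c("gneg", "gpos50"), length(labs)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = c(pe[-(m + 1L)], qe[-(m + 1L)]),
        end = c(pe[-1L], qe[-1L]), name = c(plabs, qlabs),
        stain = c(stain(plabs), stain(qlabs)), stringsAsFactors = FALSE)
    }
    new_band_map(do.call(rbind, rows), assembly = "toy")
  })
}

#' Specification for the synthetic karyotype generator
#'
#' @param seed RNG seed.
#' @param n_samples number of samples to draw.
#' @param clones_per_sample inclusive range, e.g. c(1, 2).
#' @param events_per_clone inclusive range, e.g. c(1, 4).
#' @param weights named probabilities over event kinds (normalized; see
#'   `default_event_weights()`).
#' @param map band map to draw coordinates from (default hg19).
#' @param p_cells probability a clone gets a "[n]" cell count.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(seed = 1L, n_samples = 10L,
                       clones_per_sample = c(1L, 2L),
                       events_per_clone = c(1L, 4L),
                       weights = default_event_weights(),
                       map = band_map("hg19"), p_cells = 0.7) {
  stopifnot(length(clones_per_sample) == 2L, clones_per_sample[1L] >= 1L,
            clones_per_sample[1L] <= clones_per_sample[2L],
            length(events_per_clone) == 2L, events_per_clone[1L] >= 0L,
            events_per_clone[1L] <= events_per_clone[2L],
            all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  structure(list(seed = seed, n_samples = n_samples,
                 clones_per_sample = clones_per_sample,
                 events_per_clone = events_per_clone,
                 weights = weights, map = map, p_cells = p_cells),
            class = "synth_spec")
}

#' @rdname synth_spec
#' @export
default_event_weights <- function() {
  c(whole_gain = 0.12, whole_loss = 0.10, del1 = 0.08, del2 = 0.08,
    dup = 0.08, trp = 0.03, iso = 0.05, iso_plus = 0.03,
    der_whole_arm = 0.06, der_whole_arm_plus = 0.03,
    der_trans = 0.08, der_trans_plus = 0.05, der_trans3 = 0.03,
    add = 0.06, ring = 0.04, transl = 0.05, inv = 0.03)
}

strip_chr <- function(ch) sub("^chr", "", ch)

# sample() treats a scalar n as 1:n; avoid that for inclusive ranges
sample_range <- function(lo, hi) {
  if (lo == hi) as.integer(lo) else sample(seq(lo, hi), 1L)
}

# ---- constructive clone assembly -------------------------------------------

piece <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
             stringsAsFactors = FALSE)
}

# draw one random band row of a chromosome (optionally restricted to an arm)
pick_band <- function(map, chrom, arm = NULL) {
  b <- map$bands[map$bands$chrom == chrom, ]
  if (!is.null(arm)) b <- b[b$arm == arm, ]
  b[sample(nrow(b), 1L), ]
}

# assemble one clone; returns ISCN clone text plus truth structures
sample_clone <- function(spec) {
  map <- spec$map
  chroms <- names(map$chrom_lengths)
  has_sex <- "chrX" %in% chroms
  sex <- if (has_sex) {
    if (stats::runif(1) < 0.5) c("X", "X") else c("X", "Y")
  } else character()
  sex <- sex[paste0("chr", sex) %in% chroms]

  full <- function(ch) piece(ch, 0, map$chrom_lengths[[ch]])
  homologs <- list()
  for (ch in setdiff(chroms, c("chrX", "chrY")))
    for (k in 1:2)
      homologs[[length(homologs) + 1L]] <- list(chrom = ch, normal = TRUE,
                                                pieces = full(ch))
  for (s in sex)
    homologs[[length(homologs) + 1L]] <- list(chrom = paste0("chr", s),
                                              normal = TRUE,
                                              pieces = full(paste0("chr", s)))
  init_count <- table(vapply(homologs, `[[`, character(1), "chrom"))

  targetable <- function(ch) {
    which(vapply(homologs, function(h) h$normal && h$chrom == ch, logical(1)))
  }
  take <- function(ch) {
    i <- targetable(ch)
    if (!length(i)) return(NA_integer_)
    i[sample.int(length(i), 1L)]
  }
  arm_iv <- function(ch, arm) {
    b <- map$acen_boundary[[ch]]
    if (arm == "p") piece(ch, 0, b) else piece(ch, b, map$chrom_lengths[[ch]])
  }
  # piece a derivative retains: from the breakpoint band through the
  # centromere to the far telomere (band included)
  kept_piece <- function(ch, band) {
    if (band$arm == "p") piece(ch, band$start, map$chrom_lengths[[ch]])
    else piece(ch, 0, band$end)
  }
  # translocated-on piece: breakpoint band to its own arm's telomere
  distal_piece <- function(ch, band) {
    if (band$arm == "p") piece(ch, 0, band$end)
    else piece(ch, band$start, map$chrom_lengths[[ch]])
  }

  n_events <- sample_range(spec$events_per_clone[1L], spec$events_per_clone[2L])
  terms <- character()
  expected <- list()   # per term: operator/kind/chroms/breakpoints
  sex_rendered <- sex
  # never touch chrY; only draw X when a symbol and homolog remain
  autosomes <- setdiff(chroms, c("chrX", "chrY"))

  draw_chrom <- function(allow_x = TRUE) {
    pool <- autosomes
    if (allow_x && has_sex && length(targetable("chrX")) &&
        sum(sex_rendered == "X") > 0L)
      pool <- c(pool, "chrX")
    pool[sample.int(length(pool), 1L)]
  }
  consume_sex_symbol <- function(ch) {
    if (ch == "chrX") {
      i <- which(sex_rendered == "X")[1L]
      sex_rendered <<- sex_rendered[-i]
    }
  }
  record <- function(term, operator, kind, tchroms, bkpts) {
    terms <<- c(terms, term)
    expected[[length(expected) + 1L]] <<- list(
      operator = operator, kind = kind, chroms = tchroms, breakpoints = bkpts)
  }

  kinds <- names(spec$weights)
  if (length(chroms) < 2L)
    kinds <- setdiff(kinds, c("der_whole_arm", "der_whole_arm_plus",
                              "der_trans", "der_trans_plus", "transl"))
  if (length(chroms) < 3L) kinds <- setdiff(kinds, "der_trans3")
  w <- spec$weights[kinds]

  tries <- 0L
  while (length(terms) < n_events && tries < 50L * n_events) {
    tries <- tries + 1L
    kind <- sample(kinds, 1L, prob = w)
    switch(kind,
      whole_gain = {
        ch <- draw_chrom()
        homologs[[length(homologs) + 1L]] <- list(chrom = ch, normal = FALSE,
                                                  pieces = full(ch))
        record(paste0("+", strip_chr(ch)), "plus", "whole_chrom", ch, list())
      },
      whole_loss = {
        ch <- autosomes[sample.int(length(autosomes), 1L)]
        i <- take(ch); if (is.na(i)) next
        homologs[[i]] <- NULL
        record(paste0("-", strip_chr(ch)), "minus", "whole_chrom", ch, list())
      },
      del1 = {
        ch <- draw_chrom(); i <- take(ch); if (is.na(i)) next
        b <- pick_band(map, ch)
        homologs[[i]]$normal <- FALSE
        homologs[[i]]$pieces <- if (b$arm == "p")
          piece(ch, b$end, map$chrom_lengths[[ch]]) else piece(ch, 0, b$start)
        consume_sex_symbol(ch)
        record(sprintf("del(%s)(%s)", strip_chr(ch), b$name), "none", "del",
               ch, list(b$name))
      },
      del2 = {
        ch <- draw_chrom(); i <- take(ch); if (is.na(i)) next
        b1 <- pick_band(map, ch); b2 <- pick_band(map, ch)
        if (b1$start > b2$start) { tmp <- b1; b1 <- b2; b2 <- tmp }
        homologs[[i]]$normal <- FALSE
        homologs[[i]]$pieces <- rbind(
          piece(ch, 0, b1$start), piece(ch, b2$end, map$chrom_lengths[[ch]]))
        consume_sex_symbol(ch)
        record(sprintf("del(%s)(%s%s)", strip_chr(ch), b1$name, b2$name),
               "none", "del", ch, list(c(b1$name, b2$name)))
      },
      dup = ,
      trp = {
        ch <- draw_chrom(); i <- take(ch); if (is.na(i)) next
        b1 <- pick_band(map, ch); b2 <- pick_band(map, ch)
        if (b1$start > b2$start) { tmp <- b1; b1 <- b2; b2 <- tmp }
        extra <- if (kind == "dup") 1L else 2L
        homologs[[i]]$normal <- FALSE
        homologs[[i]]$pieces <- rbind(
          full(ch), do.call(rbind, rep(list(piece(ch, b1$start, b2$end)), extra)))
        consume_sex_symbol(ch)
        record(sprintf("%s(%s)(%s%s)", kind, strip_chr(ch), b1$name, b2$name),
               "none", kind, ch, list(c(b1$name, b2$name)))
      },
      iso = ,
      iso_plus = {
        ch <- draw_chrom(); arm <- sample(c("p", "q"), 1L)
        body <- if (stats::runif(1) < 0.5)
          sprintf("i(%s%s)", strip_chr(ch), arm)
        else sprintf("i(%s)(%s10)", strip_chr(ch), arm)
        pieces <- rbind(arm_iv(ch, arm), arm_iv(ch, arm))
        if (kind == "iso") {
          i <- take(ch); if (is.na(i)) next
          homologs[[i]]$normal <- FALSE
          homologs[[i]]$pieces <- pieces
          consume_sex_symbol(ch)
          record(body, "none", "iso", ch, list(paste0(arm, "10")))
        } else {
          homologs[[length(homologs) + 1L]] <- list(chrom = ch, normal = FALSE,
                                                    pieces = pieces)
          record(paste0("+", body), "plus", "iso", ch, list(paste0(arm, "10")))
        }
      },
      der_whole_arm = ,
      der_whole_arm_plus = {
        c1 <- draw_chrom()
        c2 <- autosomes[sample.int(length(autosomes), 1L)]
        if (c2 == c1) next
        a1 <- sample(c("p", "q"), 1L); a2 <- sample(c("p", "q"), 1L)
        body <- sprintf("der(%s;%s)(%s10;%s10)", strip_chr(c1), strip_chr(c2),
                        a1, a2)
        pieces <- rbind(arm_iv(c1, a1), arm_iv(c2, a2))
        if (kind == "der_whole_arm") {
          i1 <- take(c1); if (is.na(i1)) next
          i2 <- take(c2); if (is.na(i2)) next
          homologs[[i1]]$normal <- FALSE
          homologs[[i1]]$pieces <- pieces
          homologs[[i2]] <- NULL
          consume_sex_symbol(c1)
          record(body, "none", "der_whole_arm", c(c1, c2),
                 list(paste0(a1, "10"), paste0(a2, "10")))
        } else {
          homologs[[length(homologs) + 1L]] <- list(chrom = c1, normal = FALSE,
                                                    pieces = pieces)
          record(paste0("+", body), "plus", "der_whole_arm", c(c1, c2),
                 list(paste0(a1, "10"), paste0(a2, "10")))
        }
      },
      der_trans = ,
      der_trans_plus = {
        c1 <- draw_chrom(allow_x = (kind == "der_trans"))
        pool <- setdiff(c(autosomes, if (has_sex) "chrX"), c1)
        c2 <- pool[sample.int(length(pool), 1L)]
        b1 <- pick_band(map, c1); b2 <- pick_band(map, c2)
        body <- sprintf("der(%s)t(%s;%s)(%s;%s)", strip_chr(c1),
                        strip_chr(c1), strip_chr(c2), b1$name, b2$name)
        pieces <- rbind(kept_piece(c1, b1), distal_piece(c2, b2))
        if (kind == "der_trans") {
          i <- take(c1); if (is.na(i)) next
          homologs[[i]]$normal <- FALSE
          homologs[[i]]$pieces <- pieces
          consume_sex_symbol(c1)
          record(body, "none", "der_translocation", c(c1, c2),
                 list(b1$name, b2$name))
        } else {
          homologs[[length(homologs) + 1L]] <- list(chrom = c1, normal = FALSE,
                                                    pieces = pieces)
          record(paste0("+", body), "plus", "der_translocation", c(c1, c2),
                 list(b1$name, b2$name))
        }
      },
      der_trans3 = {
        pool <- autosomes
        if (length(pool) < 3L) next
        cs <- sample(pool, 3L)
        c1 <- cs[1L]; c2 <- cs[2L]; c3 <- cs[3L]
        b1 <- pick_band(map, c1)
        b2a <- pick_band(map, c2); b2b <- pick_band(map, c2)
        b3 <- pick_band(map, c3)
        i <- take(c1); if (is.na(i)) next
        span <- piece(c2, min(b2a$start, b2b$start), max(b2a$end, b2b$end))
        homologs[[i]]$normal <- FALSE
        homologs[[i]]$pieces <- rbind(kept_piece(c1, b1), span,
                                      distal_piece(c3, b3))
        body <- sprintf("der(%s)t(%s;%s)(%s;%s)t(%s;%s)(%s;%s)",
                        strip_chr(c1), strip_chr(c1), strip_chr(c2),
                        b1$name, b2a$name, strip_chr(c2), strip_chr(c3),
                        b2b$name, b3$name)
        record(body, "none", "der_translocation", c(c1, c2, c3),
               list(b1$name, b2a$name, b3$name))
      },
      add = {
        ch <- draw_chrom(); i <- take(ch); if (is.na(i)) next
        b <- pick_band(map, ch)
        homologs[[i]]$normal <- FALSE
        homologs[[i]]$pieces <- kept_piece(ch, b)
        consume_sex_symbol(ch)
        record(sprintf("add(%s)(%s)", strip_chr(ch), b$name), "none", "add",
               ch, list(b$name))
      },
      ring = {
        ch <- draw_chrom(); i <- take(ch); if (is.na(i)) next
        bp <- pick_band(map, ch, "p"); bq <- pick_band(map, ch, "q")
        homologs[[i]]$normal <- FALSE
        homologs[[i]]$pieces <- piece(ch, bp$start, bq$end)
        consume_sex_symbol(ch)
        record(sprintf("r(%s)(%s%s)", strip_chr(ch), bp$name, bq$name),
               "none", "ring", ch, list(c(bp$name, bq$name)))
      },
      transl = {
        cs <- sample(autosomes, 2L)
        b1 <- pick_band(map, cs[1L]); b2 <- pick_band(map, cs[2L])
        record(sprintf("t(%s;%s)(%s;%s)", strip_chr(cs[1L]), strip_chr(cs[2L]),
                       b1$name, b2$name),
               "none", "translocation", cs, list(b1$name, b2$name))
      },
      inv = {
        ch <- autosomes[sample.int(length(autosomes), 1L)]
        i <- take(ch); if (is.na(i)) next
        b1 <- pick_band(map, ch); b2 <- pick_band(map, ch)
        if (b1$start > b2$start) { tmp <- b1; b1 <- b2; b2 <- tmp }
        homologs[[i]]$normal <- FALSE   # rearranged but copy-neutral
        record(sprintf("inv(%s)(%s%s)", strip_chr(ch), b1$name, b2$name),
               "none", "inversion", ch, list(c(b1$name, b2$name)))
      }
    )
  }

  modal <- length(homologs)
  header <- c(as.character(modal),
              if (length(sex_rendered)) paste(sex_rendered, collapse = ""))
  list(text = paste(c(header, terms), collapse = ","),
       expected = expected,
       sex_rendered = sex_rendered,
       pieces = do.call(rbind, c(lapply(homologs, `[[`, "pieces"),
                                 list(piece(character(), numeric(), numeric())))),
       init_count = init_count)
}

# independent truth: per-chromosome piece coverage minus starting copies,
# merged into maximal nonzero runs
coverage_segments <- function(pieces, init_count, map) {
  out <- list()
  for (ch in names(map$chrom_lengths)) {
    base <- if (ch %in% names(init_count)) as.integer(init_count[[ch]]) else 0L
    p <- pieces[pieces$chrom == ch, , drop = FALSE]
    len <- map$chrom_lengths[[ch]]
    cuts <- sort(unique(c(0, len, p$start, p$end)))
    lo <- cuts[-length(cuts)]; hi <- cuts[-1L]
    cov <- vapply(seq_along(lo), function(i)
      sum(p$start <= lo[i] & p$end >= hi[i]), integer(1))
    delta <- cov - base
    if (base == 0L) next         # chromosome absent from the clone entirely
    keep <- delta != 0L
    if (!any(keep)) next
    # merge adjacent equal-delta runs
    r <- rle(delta)
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (k in seq_along(r$values)) {
      if (r$values[k] == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = lo[starts[k]], end = hi[ends[k]],
        delta = r$values[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      delta = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(chrom_rank(res$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Draw random karyotypes with constructive ground truth
#'
#' Each sample is assembled homolog-by-homolog (see the module comments),
#' rendered as an ISCN string, and returned together with the expected
#' parse of every term and the expected net gain/loss segments computed by
#' per-base piece coverage — an oracle wholly independent of the parsing
#' and delta machinery it is used to test.
#'
#' @param spec a `synth_spec`.
#' @return list of samples; each has `iscn`, `clones` (per clone: expected
#'   term list, cell count, truth segments data.frame), and `cell_counts`.
#' @export
sample_karyotype <- function(spec) {
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_samples), function(si) {
      n_clones <- sample_range(spec$clones_per_sample[1L],
                               spec$clones_per_sample[2L])
      clones <- lapply(seq_len(n_clones), function(ci) {
        cl <- sample_clone(spec)
        cl$cells <- if (stats::runif(1) < spec$p_cells)
          sample(5:200, 1L) else NA_integer_
        cl$truth <- coverage_segments(cl$pieces, cl$init_count, spec$map)
        cl
      })
      texts <- vapply(clones, function(cl) {
        paste0(cl$text, if (!is.na(cl$cells)) sprintf("[%d]", cl$cells) else "")
      }, character(1))
      list(iscn = paste(texts, collapse = "/"),
           clones = clones,
           cell_counts = vapply(clones, `[[`, integer(1), "cells"))
    })
  })
}
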