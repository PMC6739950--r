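test_that("clones split on top-level slashes with bracketed cell counts", {
  cl <- split_clones("47,X,+X[30]/48,XX,+7,+9[50]")
  expect_length(cl, 2)
  expect_equal(cl[[1]]$cells$count, 30L)
  expect_equal(cl[[2]]$cells$count, 50L)
  expect_equal(cl[[1]]$text, "47,X,+X")

  cl <- split_clones("46,XX")
  expect_length(cl, 1)
  expect_true(is.na(cl[[1]]$cells$count))

  cl <- split_clones("49<2n>,XX,+3,+6,+8,+13,i(17q)")
  expect_length(cl, 1)
  expect_true(is.na(cl[[1]]$cells$count))

  cl <- split_clones("46,XX,t(9;22)(q34;q11)[cp 12]")
  expect_equal(cl[[1]]$cells$count, 12L)
  expect_true(cl[[1]]$cells$composite)

  expect_error(split_clones("   "), "empty")
})

test_that("slashes and commas inside brackets or parentheses never split", {
  expect_length(split_clones("46,XX,t(1;2)(p11;q11)[10]"), 1)
  cl <- parse_clone("46,XY,t(10;21)(p13;q21)")
  expect_length(cl$aberrations, 1)
  expect_equal(cl$aberrations[[1]]$kind, "translocation")
})

test_that("clone headers parse modal number, ploidy, range, and sex field", {
  cl <- parse_clone("46,XY,der(1;19)(q10;p10)")
  expect_equal(cl$modal_low, 46L)
  expect_equal(cl$sex, c("X", "Y"))
  ab <- cl$aberrations[[1]]
  expect_equal(ab$kind, "der_whole_arm")
  expect_equal(ab$chroms, c("chr1", "chr19"))
  expect_equal(ab$breakpoints, list("q10", "p10"))

  cl <- parse_clone("49<2n>,XX,+3,+6,+8,+13,i(17q)")
  expect_equal(cl$modal_low, 49L)
  expect_equal(cl$ploidy, 2L)
  expect_equal(cl$sex, c("X", "X"))
  expect_length(cl$aberrations, 5)
  expect_equal(vapply(cl$aberrations, `[[`, character(1), "kind"),
               c(rep("whole_chrom", 4), "iso"))

  cl <- parse_clone("44~46,XX")
  expect_equal(c(cl$modal_low, cl$modal_high), c(44L, 46L))

  cl <- parse_clone("47,X,+X")
  expect_equal(cl$sex, "X")
  expect_equal(cl$aberrations[[1]]$operator, "plus")
  expect_equal(cl$aberrations[[1]]$chroms, "chrX")

  # unparseable modal number keeps the clone, with a warning
  cl <- parse_clone("XX,+8")
  expect_true(is.na(cl$modal_low))
  expect_equal(cl$sex, c("X", "X"))
  expect_length(cl$aberrations, 1)
  expect_gte(length(cl$warnings), 1)
})

test_that("individual terms parse into the right kinds and fields", {
  cases <- list(
    list("+der(10)t(10;21)(p13;q21)", "plus", "der_translocation",
         c("chr10", "chr21"), list("p13", "q21")),
    list("i(17q)", "none", "iso", "chr17", list("q10")),
    list("i(17)(q10)", "none", "iso", "chr17", list("q10")),
    list("ider(17)(q10)", "none", "ider", "chr17", list("q10")),
    list("del(5)(q13)", "none", "del", "chr5", list("q13")),
    list("del(X)(q21.31q27.2)", "none", "del", "chrX",
         list(c("q21.31", "q27.2"))),
    list("dup(1)(q21q32)", "none", "dup", "chr1", list(c("q21", "q32"))),
    list("trp(8)(q21q24)", "none", "trp", "chr8", list(c("q21", "q24"))),
    list("add(19)(p13)", "none", "add", "chr19", list("p13")),
    list("t(9;22)(q34;q11)", "none", "translocation", c("chr9", "chr22"),
         list("q34", "q11")),
    list("inv(16)(p13q22)", "none", "inversion", "chr16",
         list(c("p13", "q22"))),
    list("r(7)(p11q36)", "none", "ring", "chr7", list(c("p11", "q36"))),
    list("-7", "minus", "whole_chrom", "chr7", list()),
    list("+X", "plus", "whole_chrom", "chrX", list()),
    list("der(1)t(1;3)(p32;q21)t(3;7)(q26;q22)", "none", "der_translocation",
         c("chr1", "chr3", "chr7"), list("p32", "q21", "q22")))
  for (cs in cases) {
    ab <- parse_term(cs[[1]])
    expect_equal(ab$operator, cs[[2]], label = cs[[1]])
    expect_equal(ab$kind, cs[[3]], label = cs[[1]])
    expect_equal(ab$chroms, cs[[4]], label = cs[[1]])
    expect_equal(ab$breakpoints, cs[[5]], label = cs[[1]])
  }
})

test_that("flags, multiplicity and fallbacks behave as specified", {
  expect_equal(parse_term("+mar")$kind, "marker")
  expect_equal(parse_term("dmin")$kind, "dmin")
  expect_equal(parse_term("hsr")$kind, "hsr")
  expect_equal(parse_term("idem")$kind, "idem")
  expect_equal(parse_term("r")$kind, "ring")

  ab <- parse_term("?del(5)(q13)")
  expect_equal(ab$kind, "del")
  expect_true(ab$uncertain)
  expect_equal(parse_term("del(5)(?)")$kind, "unknown_term")

  ab <- parse_term("+21c")
  expect_true(ab$constitutional)
  expect_equal(ab$kind, "whole_chrom")

  expect_equal(parse_term("del(5)(q13)x2")$mult, 2L)
  cl <- parse_clone("46,XX,del(5)(q13)x2")
  expect_length(cl$aberrations, 2)

  ab <- parse_term("banana(3)")
  expect_equal(ab$kind, "unknown_term")
  expect_equal(ab$raw, "banana(3)")
  expect_equal(parse_term("8")$kind, "unknown_term")  # no operator
})

test_that("parsing is whitespace-insensitive", {
  pairs <- c("49<2n>,XX,+3,+6,+8,+13,i(17q)" = "49 <2n>, XX, + 3, + 6, + 8, + 13, i (17q)",
             "47,XX,+der(10)t(10;21)(p13;q21)" = "47, XX, + der(10) t (10;21) (p13; q21)",
             "46,X,del(X)(q21.31q27.2)" = "46, X, del( X )( q21.31 q27.2 )")
  for (i in seq_along(pairs)) {
    a <- parse_karyotype(names(pairs)[i])
    b <- parse_karyotype(pairs[[i]])
    for (k in seq_along(a$clones)) {
      ab_a <- a$clones[[k]]$aberrations
      ab_b <- b$clones[[k]]$aberrations
      expect_equal(lapply(ab_a, `[`, c("operator", "kind", "chroms", "breakpoints")),
                   lapply(ab_b, `[`, c("operator", "kind", "chroms", "breakpoints")))
    }
  }
})

test_that("clone count equals one plus the number of top-level slashes", {
  for (s in c("46,XX", "46,XX[10]/47,XX,+8[5]",
              "45,X[3]/46,XX[4]/47,XXX[5]")) {
    expect_length(split_clones(s), lengths(regmatches(s, gregexpr("/", s))) + 1)
  }
})

test_that("every input term is typed or lands on the warnings channel", {
  rec <- parse_karyotype("46,XX,del(5)(q13),gibberish,+8,alsobad(1)")
  kinds <- vapply(rec$clones[[1]]$aberrations, `[[`, character(1), "kind")
  expect_equal(sum(kinds != "unknown_term"), 2)
  expect_equal(sum(kinds == "unknown_term"), 2)
  expect_setequal(rec$warnings$term[rec$warnings$message == "unrecognized term"],
                  c("gibberish", "alsobad(1)"))
})

test_that("idem expands to the stemline aberrations plus the clone's own", {
  rec <- parse_karyotype("46,XX,del(5)(q13)[10]/47,XX,idem,+8[5]")
  kinds <- vapply(rec$clones[[2]]$aberrations, `[[`, character(1), "kind")
  expect_equal(kinds, c("del", "whole_chrom"))
  expect_equal(rec$clones[[2]]$aberrations[[1]]$raw, "del(5)(q13)")
})

test_that("the diagnostic dump lists one line per clone header and term", {
  rec <- parse_karyotype("46,XY,der(1;19)(q10;p10)[12]")
  dump <- iscn_dump(rec)
  expect_length(dump, 2)
  expect_match(dump[1], "modal=46")
  expect_match(dump[1], "cells=12")
  expect_match(dump[2], "der_whole_arm")
})

test_that("parser round-trips the generator's rendered terms", {
  spec <- synth_spec(seed = 42, n_samples = 120, map = hg19(),
                     events_per_clone = c(1, 5))
  samples <- sample_karyotype(spec)
  n_terms <- 0
  for (s in samples) {
    rec <- parse_karyotype(s$iscn)
    expect_length(rec$clones, length(s$clones))
    for (ci in seq_along(s$clones)) {
      got <- rec$clones[[ci]]$aberrations
      want <- s$clones[[ci]]$expected
      expect_length(got, length(want))
      for (k in seq_along(want)) {
        expect_equal(got[[k]]$operator, want[[k]]$operator, label = s$iscn)
        expect_equal(got[[k]]$kind, want[[k]]$kind, label = s$iscn)
        expect_equal(got[[k]]$chroms, want[[k]]$chroms, label = s$iscn)
        expect_equal(got[[k]]$breakpoints, want[[k]]$breakpoints, label = s$iscn)
        n_terms <- n_terms + 1
      }
      expect_equal(rec$clones[[ci]]$cells$count, s$clones[[ci]]$cells)
    }
  }
  expect_gte(n_terms, 500)
})
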