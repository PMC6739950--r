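deltas_of <- function(term, map = hg19()) {
  event_deltas(parse_term(term), map)
}

test_that("whole-arm derivative loses both untranscribed arms", {
  d <- deltas_of("der(1;19)(q10;p10)")
  expect_equal(d$chrom, c("chr1", "chr19"))
  expect_equal(d$start, c(0, 26500000))
  expect_equal(d$end, c(125000000, 59128983))
  expect_equal(d$delta, c(-1L, -1L))
})

test_that("supernumerary translocation derivative gains both retained pieces", {
  d <- deltas_of("+der(10)t(10;21)(p13;q21)")
  expect_equal(d$chrom, c("chr10", "chr21"))
  expect_equal(d$start, c(12200000, 16400000))
  expect_equal(d$end, c(135534747, 48129895))
  expect_equal(d$delta, c(1L, 1L))
})

test_that("a non-supernumerary translocation derivative swaps material", {
  d <- deltas_of("der(10)t(10;21)(p13;q21)")
  # loses 10pter..p13 (exclusive of the retained band), gains the 21 piece
  expect_equal(d$chrom, c("chr10", "chr21"))
  expect_equal(d$start, c(0, 16400000))
  expect_equal(d$end, c(12200000, 48129895))
  expect_equal(d$delta, c(-1L, 1L))
})

test_that("balanced events and content-free terms yield no deltas", {
  for (term in c("t(9;22)(q34;q11)", "inv(16)(p13q22)", "t(1;3;5)(p13;q21;q22)")) {
    d <- deltas_of(term)
    expect_equal(nrow(d), 0, label = term)
    expect_length(attr(d, "warnings"), 0)
  }
  for (term in c("+mar", "dmin", "hsr", "+r")) {
    d <- deltas_of(term)
    expect_equal(nrow(d), 0, label = term)
    expect_gte(length(attr(d, "warnings")), 1)
  }
})

test_that("deletion spans follow the whole-band-included convention", {
  map <- hg19()
  # interstitial: both breakpoint bands wholly included
  d <- deltas_of("del(X)(q21.31q27.2)")
  expect_equal(d$start, 86200000)   # start of Xq21.31
  expect_equal(d$end, 142100000)    # end of Xq27.2
  expect_equal(d$delta, -1L)
  # terminal q deletion runs to the telomere
  b <- resolve_band(map, "chr5", "q13")
  d <- deltas_of("del(5)(q13)")
  expect_equal(c(d$start, d$end), c(b$start, map$chrom_lengths[["chr5"]]))
  # terminal p deletion runs to the p telomere
  b <- resolve_band(map, "chr17", "p12")
  d <- deltas_of("del(17)(p12)")
  expect_equal(c(d$start, d$end), c(0, b$end))
})

test_that("dup, trp, add and ring deltas match their definitions", {
  map <- hg19()
  span <- c(resolve_band(map, "chr1", "q21")$start,
            resolve_band(map, "chr1", "q32")$end)
  d <- deltas_of("dup(1)(q21q32)")
  expect_equal(c(d$start, d$end, d$delta), c(span, 1))
  d <- deltas_of("trp(1)(q21q32)")
  expect_equal(c(d$start, d$end, d$delta), c(span, 2))
  # add: distal material lost, unknown added material contributes nothing
  b <- resolve_band(map, "chr10", "p13")
  d <- deltas_of("add(10)(p13)")
  expect_equal(c(d$start, d$end, d$delta), c(0, b$start, -1))
  # ring: both tips lost
  bp <- resolve_band(map, "chr7", "p15")
  bq <- resolve_band(map, "chr7", "q35")
  d <- deltas_of("r(7)(p15q35)")
  expect_equal(d$start, c(0, bq$end))
  expect_equal(d$end, c(bp$start, map$chrom_lengths[["chr7"]]))
  expect_equal(d$delta, c(-1L, -1L))
})

test_that("isochromosome semantics depend on the operator", {
  map <- hg19()
  q <- arm_interval(map, "chr17", "q")
  p <- arm_interval(map, "chr17", "p")
  d <- deltas_of("i(17q)")
  expect_equal(d[d$delta == 1, ]$start, q$start)
  expect_equal(d[d$delta == 1, ]$end, q$end)
  expect_equal(d[d$delta == -1, ]$start, p$start)
  expect_equal(d[d$delta == -1, ]$end, p$end)
  # material is conserved at whole-chromosome scale: +1 arm, -1 arm
  expect_equal(sum(d$delta), 0)
  d <- deltas_of("+i(17q)")
  expect_equal(d$delta, 2L)
  expect_equal(c(d$start, d$end), c(q$start, q$end))
  # mirrored for a p-arm iso
  d <- deltas_of("i(9p)")
  expect_equal(d$delta[d$chrom == "chr9" & d$start == 0][1], 1L)
})

test_that("unresolvable bands skip the aberration with a warning", {
  d <- deltas_of("del(5)(q99)")
  expect_equal(nrow(d), 0)
  expect_match(attr(d, "warnings"), "del\\(5\\)\\(q99\\)")
})

test_that("baselines come from ploidy, sex field, and consumed homologs", {
  map <- hg19()
  cl <- parse_clone("46,X,del(X)(q21.31q27.2)")
  expect_equal(clone_baseline(cl, map)[["chrX"]], 2L)
  expect_false("chrY" %in% names(clone_baseline(cl, map)))
  cl <- parse_clone("46,XY,del(5)(q13)")
  b <- clone_baseline(cl, map)
  expect_equal(b[["chrX"]], 1L)
  expect_equal(b[["chrY"]], 1L)
  expect_equal(b[["chr5"]], 2L)
  cl <- parse_clone("49<2n>,XX,+3")
  expect_equal(clone_baseline(cl, map)[["chr3"]], 2L)
  # a supernumerary derivative does not add to the baseline
  cl <- parse_clone("47,X,+der(X)t(X;1)(q21;q21)")
  expect_equal(clone_baseline(cl, map)[["chrX"]], 1L)
  # ploidy marker scales autosomes
  cl <- parse_clone("69<3n>,XXY")
  b <- clone_baseline(cl, map)
  expect_equal(b[["chr1"]], 3L)
  expect_equal(b[["chrX"]], 2L)
})

test_that("accumulate merges overlapping deltas into maximal segments", {
  map <- make_toy_bandmap(1, 1, 100, seed = 1)
  d <- rbind(data.frame(chrom = "chr1", start = 0, end = 100, delta = 1L),
             data.frame(chrom = "chr1", start = 0, end = 100, delta = -1L))
  expect_equal(nrow(accumulate_deltas(d, map)), 0)

  d <- rbind(data.frame(chrom = "chr1", start = 0, end = 60, delta = -1L),
             data.frame(chrom = "chr1", start = 40, end = 100, delta = -1L))
  got <- accumulate_deltas(d, map)
  expect_equal(got$start, c(0, 40, 60))
  expect_equal(got$end, c(40, 60, 100))
  expect_equal(got$delta, c(-1L, -2L, -1L))

  # adjacent equal segments merge
  d <- rbind(data.frame(chrom = "chr1", start = 0, end = 50, delta = 1L),
             data.frame(chrom = "chr1", start = 50, end = 100, delta = 1L))
  got <- accumulate_deltas(d, map)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(0, 100))
})

test_that("accumulate equals per-base counting on random toy delta sets", {
  map <- make_toy_bandmap(1, 1, 1000, seed = 3)
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(1:8, 1)
    s <- sample(0:999, n, replace = TRUE)
    e <- pmin(1000, s + sample(1:500, n, replace = TRUE))
    d <- data.frame(chrom = "chr1", start = s, end = e,
                    delta = sample(c(-2L, -1L, 1L, 2L), n, replace = TRUE))
    got <- accumulate_deltas(d, map)
    want <- per_base_segments(d, 1000)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$delta, want$delta)
  }
})

test_that("classification follows net copies against the baseline", {
  expect_equal(classify_segment(1, 2), list(label = "Gain", zygosity = "not_applicable"))
  expect_equal(classify_segment(-1, 2), list(label = "Loss", zygosity = "hemizygous"))
  expect_equal(classify_segment(-2, 2), list(label = "Loss", zygosity = "homozygous"))
  expect_equal(classify_segment(-3, 2)$zygosity, "homozygous")  # clamped
  expect_equal(classify_segment(-1, 1)$zygosity, "homozygous")
  expect_equal(classify_segment(2, 4)$label, "Gain")
})

test_that("normal karyotypes and cancelling events produce empty output", {
  map <- hg19()
  for (k in c("46,XX", "46,XY")) {
    prof <- clone_profile(parse_clone(k), map)
    expect_equal(nrow(prof$segments), 0, label = k)
  }
  prof <- clone_profile(parse_clone("46,XX,dup(1)(q21q32),del(1)(q21q32)"), map)
  expect_equal(nrow(prof$segments), 0)
})

test_that("profiles stay within bounds, never overlap, and carry classes", {
  map <- hg19()
  prof <- clone_profile(parse_clone("46,XX,del(5)(q13),dup(5)(q31q33),+8,-21"), map)
  s <- prof$segments
  expect_true(all(s$start >= 0))
  expect_true(all(s$end <= map$chrom_lengths[s$chrom]))
  for (ch in unique(s$chrom)) {
    x <- s[s$chrom == ch, ]
    if (nrow(x) > 1)
      expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  expect_true(all(s$type %in% c("Gain", "Loss")))
  expect_true(all(s$zygosity[s$type == "Gain"] == "not_applicable"))
})

test_that("sex-field-only losses are not reported, but warned about", {
  prof <- clone_profile(parse_clone("45,X"), hg19())
  expect_equal(nrow(prof$segments), 0)
  expect_match(paste(prof$warnings, collapse = " "), "45,X")
})

test_that("over-subtraction clamps at zero with a homozygous call and warning", {
  prof <- clone_profile(parse_clone("44,XX,-7,-7,del(7)(q11)"), hg19())
  s <- prof$segments[prof$segments$chrom == "chr7", ]
  expect_true(all(s$type == "Loss"))
  expect_true(any(s$zygosity == "homozygous"))
  expect_match(paste(prof$warnings, collapse = " "), "clamped")
})
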