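# Shared fixtures: maps are cached by band_map(), so repeated calls are cheap.

hg19 <- function() band_map("hg19")

# the minimal two-band chromosome: chr1 = p11 acen [0,50) + q11 acen [50,100)
tiny_map <- function() {
  load_band_table(c("chr1\t0\t50\tp11\tacen",
                    "chr1\t50\t100\tq11\tacen"), assembly = "tiny")
}

# brute-force band lookup used as the independent oracle for resolve_band:
# union of all bands whose dot-stripped label extends the query
brute_union <- function(map, chrom, label) {
  b <- map$bands[map$bands$chrom == chrom, ]
  nod <- gsub(".", "", tolower(b$name), fixed = TRUE)
  q <- gsub(".", "", tolower(label), fixed = TRUE)
  hit <- startsWith(nod, q)
  if (!any(hit)) return(NULL)
  c(min(b$start[hit]), max(b$end[hit]))
}

# per-base copy counting on a small chromosome: the accumulate oracle
per_base_segments <- function(deltas, len) {
  cov <- integer(len)
  for (i in seq_len(nrow(deltas))) {
    s <- deltas$start[i]; e <- deltas$end[i]
    if (e > s) cov[(s + 1):e] <- cov[(s + 1):e] + deltas$delta[i]
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- c(0L, utils::head(ends, -1L))
  keep <- r$values != 0L
  data.frame(start = starts[keep], end = ends[keep],
             delta = r$values[keep], row.names = NULL)
}

table1_karyotypes <- function() {
  data.frame(
    sample = c("ABC", "DEF", "P_10"),
    karyotype = c("46,XY,der(1;19)(q10;p10)",
                  "47,XX,+der(10)t(10;21)(p13;q21)",
                  "47,X,+X[30]/48,XX,+ 7,+ 9 [50]"),
    stringsAsFactors = FALSE)
}

table2_expected <- function() {
  data.frame(
    sample_clone = c("ABC_1", "ABC_1", "DEF_1", "DEF_1", "P_10_1", "P_10_2", "P_10_2"),
    chrom = c("chr1", "chr19", "chr10", "chr21", "chrX", "chr7", "chr9"),
    start = c(0, 26500000, 12200000, 16400000, 0, 0, 0),
    end = c(125000000, 59128983, 135534747, 48129895, 155270560, 159138663, 141213431),
    type = c("Loss", "Loss", "Gain", "Gain", "Gain", "Gain", "Gain"),
    cells = c("unknown", "unknown", "unknown", "unknown", "30 of 80", "50 of 80", "50 of 80"),
    stringsAsFactors = FALSE)
}
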