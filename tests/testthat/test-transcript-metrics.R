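test_that("CIGAR semantics produce the documented blocks", {
  sam <- tempfile(fileext = ".sam")
  writeTestSam(sam, c(
    samRow("r1", 100, "50M"),
    samRow("r2", 461, "20M300N30M"),
    samRow("r3", 100, "5S45M"),
    samRow("r4", 200, "10M5D10M"),       # D stays inside one block
    samRow("r5", 300, "10M5I10M")))      # I consumes the read only
  reads <- parseAlignments(sam, testCassette())
  bl <- readBlocks(reads)
  names(bl) <- reads@readId
  expect_equal(unname(as.matrix(as.data.frame(bl[["r1"]])[, 1:2])),
               matrix(c(100L, 149L), 1))
  b2 <- as.data.frame(bl[["r2"]])
  expect_equal(b2$start, c(461L, 781L))
  expect_equal(b2$end, c(480L, 810L))
  b3 <- as.data.frame(bl[["r3"]])
  expect_equal(c(b3$start, b3$end), c(100L, 144L))  # soft clip: no shift
  b4 <- as.data.frame(bl[["r4"]])
  expect_equal(c(b4$start, b4$end), c(200L, 224L))  # one 25 nt block
  b5 <- as.data.frame(bl[["r5"]])
  expect_equal(c(b5$start, b5$end), c(300L, 319L))  # insertion: 20 nt block
})

test_that("unique-mapping and adapter filters behave as configured", {
  sam <- tempfile(fileext = ".sam")
  writeTestSam(sam, c(
    samRow("ok5", 100, "50M", tag = "XA:Z:5"),
    samRow("ok3", 100, "50M", tag = "XA:Z:3"),
    samRow("okBoth", 100, "50M", tag = "XA:Z:53"),
    samRow("noTag", 100, "50M"),
    samRow("lowMapq", 100, "50M", mapq = 0L),
    samRow("secondary", 100, "50M", flag = 256L),
    samRow("supplementary", 100, "50M", flag = 2048L)))
  reads <- parseAlignments(sam, testCassette())
  expect_setequal(reads@readId, c("ok5", "ok3", "okBoth", "noTag"))
  expect_equal(sum(hasAdapter5(reads)), 2L)
  expect_equal(sum(hasAdapter3(reads)), 2L)
  # escape hatch for pre-filtered pipelines
  readsAll5 <- parseAlignments(sam, testCassette(), assumeAll5prime = TRUE)
  expect_true(all(hasAdapter5(readsAll5)))
  # unknown reference is a hard error
  other <- cassetteModel("other", 1400L, 1L)
  expect_error(parseAlignments(sam, other), "unknown reference")
  # malformed SAM is a hard error naming the file
  bad <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:cas1\tLN:1400", "not a sam line"), bad)
  expect_error(parseAlignments(bad, testCassette()), "malformed SAM")
})

test_that("junction extraction counts each gap of each read", {
  sam <- tempfile(fileext = ".sam")
  writeTestSam(sam, c(
    samRow("a", 461, "50M343N50M"),           # blocks 461..510, 854..903
    samRow("b", 461, "50M343N50M"),
    samRow("c", 400, "20M30N20M50N20M")))     # two gaps in one read
  reads <- parseAlignments(sam, testCassette())
  j <- extractJunctions(reads)
  expect_equal(j$count[j$donor == 511 & j$acceptor == 853], 2L)
  expect_equal(j$count[j$donor == 420 & j$acceptor == 449], 1L)
  expect_equal(j$count[j$donor == 470 & j$acceptor == 519], 1L)
  expect_equal(sum(j$count), 4L)
})

test_that("junction tables equal a per-read brute-force scan on simulated reads", {
  sim <- simulateTestReads(nReads = 1000, seed = 77)
  expect_equal(extractJunctions(sim$reads), oracleJunctions(sim$reads))
})

test_that("splice usage reproduces the published accounting conventions", {
  # simple single-intron case with no unexpected junctions
  j <- data.frame(donor = 511L, acceptor = 853L, count = 5432L)
  rep <- spliceUsageFromCounts(j, data.frame(p5 = 511L, p3 = 853L),
                               65L, 80L)
  u <- as.data.frame(intendedUsage(rep))
  expect_equal(u$pct_expected_5, 98.8)
  expect_equal(u$pct_expected_3, 98.5)
  expect_equal(u$pct_unspliced_5, 1.2)
  expect_equal(u$pct_unspliced_3, 1.5)
  # categories at each intended position sum to 100 within rounding
  expect_equal(u$pct_expected_5 + u$pct_unspliced_5, 100, tolerance = 0.1)
  expect_equal(u$pct_expected_3 + u$pct_unspliced_3, 100, tolerance = 0.1)
  # junctions touching neither intended position stay out of denominators
  j2 <- rbind(j, data.frame(donor = 600L, acceptor = 700L, count = 1000L))
  rep2 <- spliceUsageFromCounts(j2, data.frame(p5 = 511L, p3 = 853L),
                                65L, 80L)
  expect_equal(as.data.frame(intendedUsage(rep2))$pct_expected_5, 98.8)
  cat2 <- as.data.frame(usageCategories(rep2))
  stray <- cat2[cat2$donor == 600, ]
  expect_true(is.na(stray$pct_5) && is.na(stray$pct_3))
  # zero informative reads: undefined markers, not zeros
  rep3 <- spliceUsageFromCounts(
    data.frame(donor = integer(0), acceptor = integer(0),
               count = integer(0)),
    data.frame(p5 = 511L, p3 = 853L), 0L, 0L)
  expect_true(is.na(as.data.frame(intendedUsage(rep3))$pct_expected_5))
})

test_that("unspliced counting requires contiguous coverage of the boundary", {
  sam <- tempfile(fileext = ".sam")
  writeTestSam(sam, c(
    samRow("span5", 500, "30M"),       # covers 510/511: unspliced at 5'
    samRow("end5", 481, "30M"),        # ends at 510: uninformative
    samRow("junc", 461, "50M304N50M"), # expected junction 511..814
    samRow("span3", 800, "30M")))      # covers 814/815: unspliced at 3'
  cass <- cassetteModel("cas1", 1400L, 481L,
                        data.frame(p5 = 511L, p3 = 814L))
  reads <- parseAlignments(sam, cass)
  rep <- spliceUsage(reads, cass)
  u <- as.data.frame(intendedUsage(rep))
  expect_equal(u$unspliced5_count, 1L)
  expect_equal(u$unspliced3_count, 1L)
  expect_equal(u$expected_count, 1L)
  expect_equal(u$den5, 2L)   # junction + span5; end5 excluded
})

test_that("TSS and polyA distributions use only adapter-carrying reads", {
  sam <- tempfile(fileext = ".sam")
  rows <- c(
    vapply(1:18, function(i) samRow(sprintf("t%02d", i), 481, "60M",
                                    tag = "XA:Z:5"), character(1)),
    vapply(1:2, function(i) samRow(sprintf("u%02d", i), 483, "60M",
                                   tag = "XA:Z:5"), character(1)),
    samRow("x1", 999, "60M"))           # no adapter: excluded
  writeTestSam(sam, rows)
  reads <- parseAlignments(sam, testCassette())
  d <- tssDistribution(reads)
  tb <- as.data.frame(siteTable(d))
  expect_equal(d@total, 20L)
  expect_equal(tb$pct[tb$position == 481], 90)
  expect_equal(tb$pct[tb$position == 483], 10)
  expect_equal(dominantSite(d), 481L)
  expect_false(999 %in% tb$position)
  # polyA side: last aligned base of the last block, junction reads included
  sam2 <- tempfile(fileext = ".sam")
  writeTestSam(sam2, c(
    samRow("p1", 1100, "27M", tag = "XA:Z:3"),     # ends 1126
    samRow("p2", 1100, "27M", tag = "XA:Z:3"),
    samRow("p3", 461, "50M303N373M", tag = "XA:Z:3")))  # ends 1186
  reads2 <- parseAlignments(sam2, testCassette())
  d2 <- polyaDistribution(reads2)
  tb2 <- as.data.frame(siteTable(d2))
  expect_equal(tb2$count[tb2$position == 1126], 2L)
  expect_equal(tb2$count[tb2$position == 1186], 1L)
  expect_equal(dominantSite(d2), 1126L)
  # no informative reads is a hard error
  expect_error(polyaDistribution(reads), "3' adapter")
})

test_that("window fractions follow the brute-force window scan", {
  mk <- function(pos, cnt) {
    new("SiteDistribution", kind = "TSS", total = sum(cnt),
        table = S4Vectors::DataFrame(
          position = pos, count = cnt,
          pct = roundHalfUp(100 * cnt / sum(cnt), 2L)),
        dominantSite = min(pos[cnt == max(cnt)]))
  }
  # all reads at one position: fraction 100 for any width
  expect_equal(windowFraction(mk(500L, 50L), width = 1L)$fraction_pct, 100)
  expect_equal(windowFraction(mk(500L, 50L), width = 10L)$fraction_pct, 100)
  # uniform over 20 positions, width 10: fraction 50
  u <- mk(seq(101L, 120L), rep(5L, 20))
  wf <- windowFraction(u, width = 10L)
  expect_equal(wf$fraction_pct, 50)
  expect_equal(wf$window_start, 101L)   # leftmost on ties
  # random distribution equals a brute-force scan
  set.seed(70)
  pos <- sort(sample(200:260, 15))
  cnt <- sample(1:50, 15, replace = TRUE)
  d <- mk(pos, cnt)
  got <- windowFraction(d, width = 10L)
  brute <- max(vapply(min(pos):max(pos), function(s)
    sum(cnt[pos >= s & pos <= s + 9L]), integer(1)))
  expect_equal(got$fraction_pct, roundHalfUp(100 * brute / sum(cnt), 1L))
})

test_that("read-through percentages follow the ddCt arithmetic", {
  q <- data.frame(sample_id = rep("s1", 3),
                  target = c("GUS", "READTHROUGH", "NORMALIZER_1"),
                  ct = c(20, 20, 18))
  expect_equal(readthroughPercent(q)$pct_readthrough, 100)
  q$ct <- c(20, 22, 18)
  expect_equal(readthroughPercent(q)$pct_readthrough, 25)
  # five synthetic samples with hand-computed fold differences
  set.seed(71)
  tab <- do.call(rbind, lapply(1:5, function(i) {
    norm <- runif(2, 15, 20)
    gus <- runif(1, 18, 24)
    delta <- runif(1, 0, 5)
    data.frame(sample_id = sprintf("s%d", i),
               target = c("GUS", "READTHROUGH", "NORMALIZER_1",
                          "NORMALIZER_2"),
               ct = c(gus, gus + delta, norm))
  }))
  res <- readthroughPercent(tab)
  for (i in 1:5) {
    d <- tab[tab$sample_id == sprintf("s%d", i), ]
    hand <- 100 * 2^(-(d$ct[d$target == "READTHROUGH"] -
                       d$ct[d$target == "GUS"]))
    expect_equal(res$pct_readthrough[res$sample_id == sprintf("s%d", i)],
                 hand, tolerance = 1e-12)
  }
  expect_error(readthroughPercent(
    data.frame(sample_id = "s1", target = c("GUS", "NORMALIZER_1"),
               ct = c(20, 18))), "READTHROUGH")
  expect_error(readthroughPercent(
    data.frame(sample_id = "s1",
               target = c("GUS", "READTHROUGH", "NORMALIZER_1"),
               ct = c(-1, 20, 18))), "positive")
})

test_that("report writers emit readable TSV", {
  sim <- simulateTestReads(nReads = 300, seed = 5)
  rep <- spliceUsage(sim$reads, sim$cassette)
  f <- tempfile(fileext = ".tsv")
  writeSpliceUsage(rep, f)
  tab <- read.delim(f, na.strings = "-")
  expect_true(all(c("category", "count", "pct_5", "pct_3") %in%
                  colnames(tab)))
  d <- tssDistribution(sim$reads)
  f2 <- tempfile(fileext = ".tsv")
  writeSiteDistribution(d, f2)
  expect_equal(sum(read.delim(f2)$count), d@total)
})
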