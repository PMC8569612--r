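flatProfile <- function(L, anchor = L, n = 50L) {
  m <- matrix(0.25, nrow = 4, ncol = L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  new("PositionalProfile", profile = m, pseudocount = 1,
      anchorOffset = as.integer(anchor), n = n)
}

featByName <- function(el, name) {
  f <- elementFeatures(el)
  f[S4Vectors::mcols(f)$feature == name]
}

test_that("designed promoters satisfy the structural contract", {
  prof <- flatProfile(1050L, anchor = 1000L)
  cons <- designConstraints("PROMOTER")
  el <- designPromoter(prof, constraints = cons, seed = 101)
  expect_equal(length(elementSequence(el)), 500L)
  tata <- featByName(el, "TATA_BOX")
  tss <- featByName(el, "PREDICTED_TSS")
  # exactly 30 bases strictly between the TATA box and the predicted TSS
  expect_equal(BiocGenerics::start(tss) - BiocGenerics::end(tata) - 1L, 30L)
  s <- as.character(elementSequence(el))
  expect_equal(substr(s, BiocGenerics::start(tata), BiocGenerics::end(tata)),
               "TATAAA")
  # zero ATG from the predicted TSS to the element end
  tail <- substr(s, BiocGenerics::start(tss), nchar(s))
  expect_false(grepl("ATG", tail, fixed = TRUE))
  # initiator: pyrimidine then the TSS base A
  tssPos <- BiocGenerics::start(tss)
  expect_true(substr(s, tssPos - 1L, tssPos - 1L) %in% c("C", "T"))
  expect_equal(substr(s, tssPos, tssPos), "A")
  # leader runs from the TSS to the element end
  leader <- featByName(el, "LEADER")
  expect_equal(BiocGenerics::start(leader), tssPos)
  expect_equal(BiocGenerics::end(leader), 500L)
})

test_that("designs are deterministic per seed and vary across seeds", {
  prof <- flatProfile(1050L, anchor = 1000L)
  a <- designPromoter(prof, seed = 7)
  b <- designPromoter(prof, seed = 7)
  c <- designPromoter(prof, seed = 8)
  expect_identical(as.character(elementSequence(a)),
                   as.character(elementSequence(b)))
  expect_false(identical(as.character(elementSequence(a)),
                         as.character(elementSequence(c))))
  expect_equal(provenance(a)$seed, 7)
})

test_that("designed introns have canonical sites and clean interiors", {
  prof <- flatProfile(310L, anchor = 5L)
  cons <- designConstraints("INTRON")
  el <- designIntron(prof, constraints = cons, seed = 5)
  s <- as.character(elementSequence(el))
  expect_equal(nchar(s), 310L)
  expect_equal(substr(s, 6, 7), "GT")      # donor at intron start
  expect_equal(substr(s, 304, 305), "AG")  # acceptor at intron end
  # forbidden donor-like word absent strictly between the sites
  interior <- substr(s, 8, 303)
  expect_false(grepl("GTAAG", interior, fixed = TRUE))
  expect_false(grepl("[CT]{6}CAG", interior))
  # IME motif feature present inside its placement window
  ime <- featByName(el, "IME_MOTIF")
  expect_equal(length(ime), 1L)
  rel <- BiocGenerics::start(ime) - 5L   # 1-based within the intron
  expect_gte(rel, cons$imeWindow[1])
  expect_lte(BiocGenerics::end(ime) - 5L, cons$imeWindow[2])
})

test_that("designed terminators place NUE, YA sites and the T tract", {
  prof <- flatProfile(600L, anchor = 400L)
  cons <- designConstraints("TERMINATOR")
  el <- designTerminator(prof, constraints = cons, seed = 31)
  s <- as.character(elementSequence(el))
  cleave <- featByName(el, "CLEAVAGE_SITE")
  expect_equal(length(cleave), 2L)
  for (ci in BiocGenerics::start(cleave)) {
    expect_equal(substr(s, ci, ci), "A")
    expect_true(substr(s, ci - 1L, ci - 1L) %in% c("C", "T"))
    # an AATAAA ends 10-30 bases upstream
    spacings <- vapply(10:30, function(sp) {
      e <- ci - sp - 1L
      substr(s, e - 5L, e) == "AATAAA"
    }, logical(1))
    expect_true(any(spacings))
  }
  distal <- max(BiocGenerics::start(cleave))
  expect_equal(substr(s, distal - cons$tTractMinRun, distal - 1L),
               strrep("T", cons$tTractMinRun))
})

test_that("every design operation round-trips through its validator", {
  profP <- flatProfile(1050L, anchor = 1000L)
  profI <- flatProfile(310L, anchor = 5L)
  profT <- flatProfile(600L, anchor = 400L)
  for (seed in 1:25) {
    expect_true(passed(validateElement(
      designPromoter(profP, seed = seed),
      constraints = designConstraints("PROMOTER"))))
    expect_true(passed(validateElement(
      designIntron(profI, seed = seed),
      constraints = designConstraints("INTRON"))))
    expect_true(passed(validateElement(
      designTerminator(profT, seed = seed),
      constraints = designConstraints("TERMINATOR"))))
  }
})

test_that("the validator reports violations with named constraints", {
  prof <- flatProfile(1050L, anchor = 1000L)
  el <- designPromoter(prof, seed = 3)
  s <- as.character(elementSequence(el))
  # plant an ATG in the leader
  tss <- BiocGenerics::start(featByName(el, "PREDICTED_TSS"))
  substr(s, tss + 5L, tss + 7L) <- "ATG"
  rep <- validateElement(s, elementFeatures(el),
                         designConstraints("PROMOTER"))
  expect_false(passed(rep))
  v <- as.data.frame(violations(rep))
  expect_true("ATG_FREE_LEADER" %in% v$constraint)
  expect_equal(v$start[v$constraint == "ATG_FREE_LEADER"][1], tss + 5L)
  # intron with a GC donor fails the donor consensus check
  profI <- flatProfile(310L, anchor = 5L)
  it <- designIntron(profI, seed = 4)
  s2 <- as.character(elementSequence(it))
  substr(s2, 6L, 7L) <- "GC"
  rep2 <- validateElement(s2, elementFeatures(it),
                          designConstraints("INTRON"))
  expect_true("DONOR_CONSENSUS" %in%
              as.data.frame(violations(rep2))$constraint)
})

test_that("profiles carrying a planted motif are recapitulated in designs", {
  # profile built from sequences with a fixed motif at offsets 700..705
  # (0-based) of a 1050-window; >= 90% of designs must contain it in-bin
  set.seed(400)
  L <- 1050L
  seqs <- vapply(1:150, function(i) {
    s <- randomDna(L)
    substr(s, 701, 706) <- "GCGTAC"
    s
  }, character(1))
  recs <- S4Vectors::DataFrame(gene_id = sprintf("s%d", 1:150),
                               chrom = "chr1", gstart = 1L, gend = L,
                               strand = "+", anchor_offset = 1000L)
  ss <- Biostrings::DNAStringSet(seqs); names(ss) <- recs$gene_id
  ts <- new("TrainingSet", sequences = ss, records = recs, anchor = "TSS",
            upstream = 1000L, downstream = 50L)
  prof <- buildPositionalProfile(ts, pseudocount = 0.1)
  hits <- vapply(1:100, function(seed) {
    el <- designPromoter(prof, seed = seed)
    s <- as.character(elementSequence(el))
    # profile offset 700 maps to element position 700 - (1000 - 450) = 150
    grepl("GCGTAC", substr(s, 140, 170), fixed = TRUE)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("constraint configuration round-trips through YAML", {
  txt <- dumpDesignConfig(file = tempfile())
  cfg <- yaml::yaml.load(txt)
  expect_equal(cfg$promoter$tataToTssSpacing, 30L)
  expect_equal(cfg$terminator$nPolyaSites, 2L)
  path <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(list(promoter = list(leaderLength = 40L))), path)
  cons <- readDesignConfig(path, "PROMOTER")
  expect_equal(cons$leaderLength, 40L)
  expect_equal(cons$tataToTssSpacing, 30L)   # untouched default
  expect_error(designConstraints("PROMOTER", nonsense = 1),
               "unknown constraint")
})

test_that("elements round-trip through FASTA + GFF3", {
  prof <- flatProfile(310L, anchor = 5L)
  el <- designIntron(prof, seed = 12)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  writeElements(el, fa, gff)
  back <- readElements(fa, gff)[[1]]
  expect_equal(as.character(elementSequence(back)),
               as.character(elementSequence(el)))
  expect_equal(elementClass(back), "INTRON")
  expect_true(passed(validateElement(back,
                                     constraints = designConstraints("INTRON"))))
})
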