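test_that("genome assembly validates names, lengths and sequences", {
  expect_error(genome_assembly(data.frame(name = c("a", "a"), length = c(1, 2))),
               "unique")
  expect_error(genome_assembly(data.frame(name = "a", length = 0)), "positive")
  expect_error(genome_assembly(data.frame(name = "a", length = 5),
                               c(a = "ACGT")), "disagrees")
  g <- genome_assembly(data.frame(name = "a", length = 4), c(a = "ACGT"))
  expect_s3_class(g, "genome_assembly")
})

test_that("digestion matches hand-traced and degenerate cases", {
  mboi <- enzyme("MboI", "GATC", 0)
  g <- genome_assembly(data.frame(name = "chr1", length = 8),
                       c(chr1 = "AAGATCAA"))
  rm <- digest(g, mboi)
  expect_equal(rm$cut_sites$chr1, 2)
  expect_equal(rm$fragments$start, c(0, 2))
  expect_equal(rm$fragments$end, c(2, 8))

  # no recognition site: one fragment spanning the chromosome
  set.seed(1)
  s <- paste(sample(c("A", "C", "T"), 1000, replace = TRUE), collapse = "")
  g0 <- genome_assembly(data.frame(name = "c", length = 1000), c(c = s))
  f0 <- digest(g0, mboi)$fragments
  expect_equal(nrow(f0), 1)
  expect_equal(c(f0$start, f0$end), c(0, 1000))

  # ambiguity bases never match
  gn <- genome_assembly(data.frame(name = "c", length = 8), c(c = "AAGNTCAA"))
  expect_equal(nrow(digest(gn, mboi)$fragments), 1)

  # sequences are mandatory
  glen <- genome_assembly(data.frame(name = "c", length = 10))
  expect_error(digest(glen, mboi), "chromosome")
})

test_that("digestion agrees with a brute-force substring scan", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  g <- genome_assembly(data.frame(name = "c", length = 10000), c(c = s))
  for (enz in list(enzyme("MboI", "GATC", 0), enzyme("AluI", "AGCT", 2))) {
    rm <- digest(g, enz)
    cuts <- integer(0)
    for (i in seq_len(10000 - nchar(enz$site) + 1)) {
      if (substr(s, i, i + nchar(enz$site) - 1) == enz$site) {
        cuts <- c(cuts, i - 1 + enz$cut_offset)
      }
    }
    cuts <- cuts[cuts > 0 & cuts < 10000]
    expect_equal(rm$cut_sites$c, cuts)
    # tiling: fragments partition the chromosome exactly
    fr <- rm$fragments
    expect_equal(fr$start[1], 0)
    expect_equal(fr$end[nrow(fr)], 10000)
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])
    expect_equal(sum(fr$end - fr$start), 10000)
    # pure function of (sequence, enzyme)
    expect_identical(rm$fragments, digest(g, enz)$fragments)
  }
})

test_that("non-palindromic sites are cut on both strands", {
  enz <- enzyme("TestI", "GGTCTC", 1)
  # site at 4 on + strand; reverse-complement GAGACC at 20 on + strand
  s <- paste0("AAAA", "GGTCTC", "AACCCCCCCC", "GAGACC", "AAAA")
  g <- genome_assembly(data.frame(name = "c", length = nchar(s)), c(c = s))
  cuts <- digest(g, enz)$cut_sites$c
  expect_equal(cuts, c(4 + 1, 20 + 6 - 1))
})

test_that("fragment lookup is consistent with a linear scan", {
  rm <- test_rmap()
  g <- test_genome()
  expect_equal(fragment_of(rm, "chr1", 0), 1)
  fr <- rm$fragments[rm$fragments$chrom == "chr1", ]
  expect_equal(fragment_of(rm, "chr1", fr$start[nrow(fr)]), nrow(fr))
  expect_error(fragment_of(rm, "chr1", 2e5), "range")
  expect_error(fragment_of(rm, "chrX", 5), "unknown")
  set.seed(7)
  pos <- floor(runif(1000) * 2e5)
  fr2 <- rm$fragments[rm$fragments$chrom == "chr2", ]
  got <- fragment_of(rm, "chr2", pos)
  linear <- vapply(pos, function(p) {
    which(fr2$start <= p & p < fr2$end)[1]
  }, 0L, USE.NAMES = FALSE)
  expect_equal(got, linear)
})

test_that("junction construction follows enzyme geometry", {
  expect_equal(junction_sequence(enzyme("MboI", "GATC", 0)), "GATCGATC")
  expect_equal(junction_sequence(enzyme("DpnII", "GATC", 0)), "GATCGATC")
  # no fill-in: sticky-end religation regenerates the single site
  expect_equal(junction_sequence(enzyme("MboI", "GATC", 0, fill_in = FALSE)),
               "GATC")
  # blunt cutter: nothing to fill
  expect_equal(junction_sequence(enzyme("AluI", "AGCT", 2)), "AGCT")
})

test_that("bundled enzyme definitions load", {
  e <- load_enzyme("MboI")
  expect_equal(e$site, "GATC")
  expect_equal(e$cut_offset, 0L)
  expect_true(e$fill_in)
  expect_equal(load_enzyme("AluI")$cut_offset, 2L)
  expect_error(load_enzyme("NoSuchEnzyme"), "not found")
  expect_false(load_enzyme("MboI", fill_in = FALSE)$fill_in)
})
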