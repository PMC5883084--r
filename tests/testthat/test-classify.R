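# Designed chromosome: fragment bounds known by construction.
# Segments 300, 200, 250, 400, 150 joined by GATC give cuts at
# 300, 504, 758, 1162 and five fragments.
dg <- function() fixture_get("designed", {
  g <- designed_genome(c(300, 200, 250, 400, 150))
  list(genome = g, rmap = digest(g, enzyme("MboI", "GATC", 0)))
})

test_that("pair classification follows the filter cascade in order", {
  rmap <- dg()$rmap
  expect_equal(rmap$cut_sites$chrD, c(300, 504, 758, 1162))
  p <- dplyr::bind_rows(
    mpair("unm", mend("chrD", 10, "+"), mend("chrD", 10, "+", "unmapped")),
    mpair("amb", mend("chrD", 10, "+", "ambiguous"), mend("chrD", 400, "-")),
    # both in fragment 2 [300,504): inward (+ before -) = internal
    mpair("int", mend("chrD", 320, "+"), mend("chrD", 470, "-")),
    # same fragment, outward (- before +) = circularisation
    mpair("circ", mend("chrD", 350, "-"), mend("chrD", 480, "+")),
    # same fragment, same position: tie resolves to internal
    mpair("tie", mend("chrD", 400, "-"), mend("chrD", 400, "+")),
    # same fragment, same strand: no junction evidence, internal
    mpair("sstr", mend("chrD", 320, "+"), mend("chrD", 470, "+")),
    # fragments 2 and 3: adjacent re-ligation
    mpair("adj", mend("chrD", 320, "+"), mend("chrD", 600, "-")),
    # fragments 2 and 4, sizes 20+21: below the 50 bp minimum
    mpair("small", mend("chrD", 484, "+"), mend("chrD", 778, "-")),
    # fragments 1 and 4: size 300 + 38 = 338, accepted
    mpair("acc", mend("chrD", 0, "+"), mend("chrD", 795, "-")))
  cl <- classify_pairs(p, rmap, size_range = c(50, 5000))
  expect_equal(cl$category,
               c("unmapped", "ambiguous", "internal", "circular", "internal",
                 "internal", "adjacent", "too_small", "accepted"))
  expect_equal(cl$inferred_size[cl$id == "small"], (504 - 484) + (778 - 758 + 1))
  expect_equal(cl$frag1[cl$id == "acc"], 1)
  expect_equal(cl$frag2[cl$id == "acc"], 4)

  # too_large under the command-line size window
  big <- classify_pairs(
    mpair("huge", mend("chrD", 310, "+"), mend("chrD", 1100, "-")),
    rmap, size_range = c(50, 500))
  expect_equal(big$inferred_size, (504 - 310) + (1100 - 758 + 1))
  expect_equal(big$category, "too_large")
})

test_that("secondary-enzyme map takes over molecule-size inference", {
  # AGCT sites inside fragments change distances to the next cut
  set.seed(9)
  g <- designed_genome(c(300, 200, 250, 400, 150), seed = 11)
  rmap <- digest(g, enzyme("MboI", "GATC", 0))
  seq <- g$sequences[[1]]
  # plant an AluI site by editing four bases inside fragment 1
  substr(seq, 101, 104) <- "AGCT"
  g2 <- genome_assembly(g$chromosomes, c(chrD = seq))
  rmap1 <- digest(g2, enzyme("MboI", "GATC", 0))
  rmap2 <- digest(g2, enzyme("AluI", "AGCT", 2))
  p <- mpair("x", mend("chrD", 10, "+"), mend("chrD", 795, "-"))
  with_re1 <- classify_pairs(p, rmap1)
  with_re2 <- classify_pairs(p, rmap1, rmap2 = rmap2)
  expect_equal(with_re1$inferred_size, (300 - 10) + (795 - 758 + 1))
  # under RE2 both distances run to the single AluI cut at 100 + 2 = 102
  expect_equal(with_re2$inferred_size, (102 - 10) + (795 - 102 + 1))
})

test_that("support grouping collapses ligation events and drops singletons", {
  rmap <- dg()$rmap
  pr <- function(id, p1, s1, p2, s2) {
    mpair(id, mend("chrD", p1, s1), mend("chrD", p2, s2))
  }
  # group 1: fragment1 R end with fragment4 L end, 5 read pairs
  g1 <- lapply(1:5, function(i) pr(paste0("a", i), 280 - i, "+", 790 + i, "-"))
  # group 2: fragment1 L with fragment5 L, 4 read pairs
  g2 <- lapply(1:4, function(i) pr(paste0("b", i), 30 + i, "-", 1190 + i, "-"))
  # singleton group
  g3 <- list(pr("c1", 100, "+", 1300, "-"))
  pairs <- classify_pairs(dplyr::bind_rows(c(g1, g2, g3)), rmap)
  expect_true(all(pairs$category == "accepted"))
  contacts <- dedup_and_support(pairs, rmap, cell_id = "t")
  expect_equal(nrow(contacts), 2)
  expect_setequal(contacts$support, c(5L, 4L))
  expect_true(all(contacts$posA <= contacts$posB))
  # representative position is the group's first pair in coordinate order
  expect_equal(sort(contacts$posA), c(30 + 1, 280 - 5))

  # two identical pairs collapse to one contact with support 2
  two <- classify_pairs(dplyr::bind_rows(
    pr("d1", 200, "+", 900, "-"), pr("d2", 200, "+", 900, "-")), rmap)
  c2 <- dedup_and_support(two, rmap)
  expect_equal(nrow(c2), 1)
  expect_equal(c2$support, 2L)

  # a single unsupported event yields no contact
  one <- classify_pairs(dplyr::bind_rows(pr("e1", 200, "+", 900, "-")), rmap)
  expect_equal(nrow(dedup_and_support(one, rmap)), 0)
})

test_that("contacts and reports are invariant to read order", {
  fx <- fixture_get("mini_cell", {
    make_fixture_cell(n_chrom = 2, chrom_length = 1e6, n_contacts = 40,
                      noise = noise_spec(0.1, 0.1, 0.05, 0.1, 0.05, 0.1),
                      seed = 404)
  })
  res1 <- process_cell(fx$reads$r1, fx$reads$r2, fx$genome, fx$enzyme,
                       rmap = fx$rmap, cell_id = "c")
  set.seed(1)
  ord <- sample.int(nrow(fx$reads$r1))
  res2 <- process_cell(fx$reads$r1[ord, ], fx$reads$r2[ord, ], fx$genome,
                       fx$enzyme, rmap = fx$rmap, cell_id = "c")
  expect_equal(res1$contacts, res2$contacts)
  expect_equal(res1$qc, res2$qc)
})

test_that("promiscuity exclusion removes every contact of an over-used end", {
  base <- random_contacts(6, seed = 3)
  base$fragA <- 1:6; base$fragB <- 101:106
  base$sideA <- "R"; base$sideB <- "L"
  # all ends distinct: nothing removed for any ploidy
  r <- remove_promiscuous(base, ploidy = 1)
  expect_equal(nrow(r$contacts), 6)
  expect_equal(r$n_promiscuous, 0L)

  # one end shared by three contacts: all three excluded in a haploid
  shared <- base
  shared$chromA <- "chr1"; shared$fragA[1:3] <- 7L
  r1 <- remove_promiscuous(shared, ploidy = 1)
  expect_equal(r1$n_promiscuous, 3L)
  expect_equal(nrow(r1$contacts), 3)
  # the allowance scales with ploidy
  shared2 <- base
  shared2$chromA <- "chr1"; shared2$fragA[1:2] <- 7L
  expect_equal(remove_promiscuous(shared2, ploidy = 2)$n_promiscuous, 0L)
  expect_equal(remove_promiscuous(shared2, ploidy = 1)$n_promiscuous, 2L)

  # idempotence: a second pass removes nothing
  again <- remove_promiscuous(r1$contacts, ploidy = 1)
  expect_equal(again$contacts, r1$contacts)
  expect_equal(again$n_promiscuous, 0L)
})
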