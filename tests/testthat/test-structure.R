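test_that("isolated-contact filter keeps mutually supported contacts", {
  expect_equal(nrow(filter_isolated_contacts(random_contacts(0, 1))), 0)
  # two contacts whose ends lie 1 Mb apart support each other; a third
  # contact far from everything is dropped
  cc <- tibble::tibble(
    chromA = "chr1", posA = c(10e6, 11e6, 60e6),
    chromB = "chr1", posB = c(30e6, 31e6, 90e6),
    support = 2L, cell_id = "t")
  out <- filter_isolated_contacts(cc, 2e6)
  expect_equal(out$posA, c(10e6, 11e6))
  # crossed orientation also counts as support for cis contacts
  cr <- tibble::tibble(chromA = "chr1", posA = c(10e6, 30.5e6),
                       chromB = "chr1", posB = c(30e6, 10.5e6),
                       support = 2L, cell_id = "t")
  expect_equal(nrow(filter_isolated_contacts(cr, 2e6)), 2)
  # order is stable
  set.seed(1)
  cc2 <- random_contacts(60, seed = 21, len = 3e7)
  out2 <- filter_isolated_contacts(cc2, 2e6)
  expect_equal(out2, brute_isolated_filter(cc2, 2e6))
})

test_that("restraint building maps contacts to deduplicated particle pairs", {
  g <- genome_assembly(tibble::tibble(name = c("chr1", "chr2"),
                                      length = c(1e6, 5.5e5)))
  cc <- tibble::tibble(
    chromA = c("chr1", "chr1", "chr1", "chr1"),
    posA = c(5e4, 1.5e5, 1.6e5, 2.5e5),
    chromB = c("chr1", "chr2", "chr2", "chr1"),
    posB = c(1.9e5, 3.5e5, 3.6e5, 2.6e5),
    support = 2L, cell_id = "t")
  rs <- contacts_to_restraints(cc, 1e5, g)
  # particles tile both chromosomes (10 + 6, last one short)
  expect_equal(nrow(rs$particles), 16)
  expect_equal(rs$particles$end[16], 5.5e5)
  # contact 1 joins two particles of chr1; contacts 2-3 duplicate one
  # inter-chromosomal pair; contact 4 is within one particle (dropped)
  expect_equal(nrow(rs$restraints), 2)
  expect_true(all(rs$restraints$lower == 0.8 & rs$restraints$upper == 1.2))
  expect_setequal(paste(rs$restraints$i, rs$restraints$j),
                  c("1 2", "2 14"))
  # backbone joins sequential particles within chromosomes only
  expect_equal(nrow(rs$backbone), 14)
  # oracle: brute-force particle mapping on random contacts
  cc2 <- random_contacts(300, seed = 9, len = 9.9e5)
  cc2$chromA <- "chr1"
  cc2$chromB <- "chr1"
  rs2 <- contacts_to_restraints(cc2, 1e5, g)
  brute <- unique(t(apply(cbind(floor(cc2$posA / 1e5), floor(cc2$posB / 1e5)),
                          1, sort)) + 1)
  brute <- brute[brute[, 1] != brute[, 2], , drop = FALSE]
  expect_equal(nrow(rs2$restraints), nrow(brute))
  expect_setequal(paste(rs2$restraints$i, rs2$restraints$j),
                  paste(brute[, 1], brute[, 2]))
})

test_that("a single restraint anneals to its flat-bottom window", {
  g <- genome_assembly(tibble::tibble(name = "chr1", length = 2e5))
  cc <- tibble::tibble(chromA = "chr1", posA = 5e4, chromB = "chr1",
                       posB = 1.5e5, support = 2L, cell_id = "t")
  st <- anneal_genome(cc, g, anneal_schedule(particle_sizes = 1e5),
                      n_models = 1, seed = 5, restarts = 1)
  d <- sqrt(sum((st$coords[[1]][1, ] - st$coords[[1]][2, ])^2))
  expect_gte(d, 0.75)
  expect_lte(d, 1.25)
})

test_that("the annealing core realises analytic ring geometry", {
  # Every particle pair of a 30-particle ring is restrained to its ideal
  # unit-edge 30-gon chord length, so the circle is the unique minimum up
  # to isometry and the analytic ring is an exact oracle for the
  # optimiser.
  n <- 30
  th <- 2 * pi * (0:(n - 1)) / n
  R <- 1 / (2 * sin(pi / n))
  ideal <- cbind(R * cos(th), R * sin(th), 0)
  pr <- t(combn(n, 2))
  chord <- sqrt(rowSums((ideal[pr[, 1], ] - ideal[pr[, 2], ])^2))
  set.seed(41)
  start <- matrix(rnorm(3 * n, sd = 3), ncol = 3)
  temps <- c(exp(seq(log(5000), log(10), length.out = 40)), rep(0, 5))
  res <- schic3d:::anneal_stage_cpp(
    start, pr[, 1] - 1L, pr[, 2] - 1L, chord * 0.98, chord * 1.02,
    0:(n - 2), 1:(n - 1), rep(0.8, n - 1), rep(1.2, n - 1),
    temps, 200, 25, 25, 50, 0.8, 0.01, 0.25, 0.05, 99L)
  al <- align_pair(ideal, res$coords)
  expect_lt(al$rmsd, 0.5)
})

test_that("a closed ring anneals with its backbone and closure satisfied", {
  g <- genome_assembly(tibble::tibble(name = "chr1", length = 3e6))
  cc <- tibble::tibble(chromA = "chr1", posA = 5e4, chromB = "chr1",
                       posB = 2.95e6, support = 2L, cell_id = "t")
  st <- anneal_genome(cc, g, anneal_schedule(particle_sizes = c(4e5, 1e5)),
                      n_models = 1, seed = 11, restarts = 1)
  co <- st$coords[[1]]
  D <- as.matrix(dist(co))
  bonds <- D[cbind(1:29, 2:30)]
  expect_true(all(bonds >= 0.75 & bonds <= 1.25))
  expect_lte(D[1, 30], 1.25)
})

test_that("annealing is deterministic and model starts differ", {
  fx <- mini_structure_fixture()
  st <- fx$st
  expect_identical(st$coords, fx$st2$coords)
  expect_false(isTRUE(all.equal(st$coords[[1]], st$coords[[2]])))
  expect_equal(length(st$coords), 3)
  expect_equal(nrow(st$particles), 40)
})

test_that("annealed models satisfy the engine's physical invariants", {
  st <- mini_structure_fixture()$st
  # cost decreases within every stage for every model
  expect_true(all(st$energies$e_final <= st$energies$e_init))
  chrom <- st$particles$chrom
  for (co in st$coords) {
    D <- as.matrix(dist(co))
    # backbone integrity
    bonded <- cbind(seq_len(nrow(co) - 1), seq_len(nrow(co) - 1) + 1)
    bonded <- bonded[chrom[bonded[, 1]] == chrom[bonded[, 2]], ]
    expect_true(all(D[bonded] >= 0.5 & D[bonded] <= 2.0))
    # excluded volume: almost no non-bonded pair closer than half a radius
    nb <- D[upper.tri(D)]
    expect_lt(mean(nb < 0.5), 0.01)
    expect_true(all(is.finite(co)))
  }
  # particles without contact restraints are flagged low-confidence
  expect_type(st$has_restraint, "logical")
  expect_equal(length(st$has_restraint), nrow(st$particles))
})

test_that("the structure pipeline filters, anneals and writes N3D", {
  fx <- mini_structure_fixture()
  path <- withr::local_tempfile(fileext = ".n3d")
  run <- run_structure_pipeline(fx$cell$contacts, fx$cell$genome, fx$sch,
                                n_models = 2, seed = 9, out_n3d = path,
                                engine = list())
  expect_s3_class(run$structure, "genome_structure")
  expect_equal(length(run$structure$coords), 2)
  expect_lte(run$report$n_used, run$report$n_input)
  expect_true(file.exists(path))
  # same seed reruns byte-identically
  path2 <- withr::local_tempfile(fileext = ".n3d")
  run_structure_pipeline(fx$cell$contacts, fx$cell$genome, fx$sch,
                         n_models = 2, seed = 9, out_n3d = path2,
                         engine = list())
  expect_identical(readLines(path), readLines(path2))
  # n_models = 1 still yields valid N3D
  p1 <- withr::local_tempfile(fileext = ".n3d")
  r1 <- run_structure_pipeline(fx$cell$contacts, fx$cell$genome, fx$sch,
                               n_models = 1, seed = 9, out_n3d = p1)
  expect_equal(length(read_n3d(p1)$coords), 1)
  expect_error(run_structure_pipeline(random_contacts(0, 1), fx$cell$genome),
               "empty")
  # sparse input continues with a recorded warning
  few <- fx$cell$contacts[1:40, ]
  expect_warning(
    rs <- run_structure_pipeline(few, fx$cell$genome, fx$sch, n_models = 1,
                                 seed = 2, min_contacts = 100),
    "isolated-contact")
  expect_true(rs$report$low_data)
})

test_that("N3D files round-trip coordinates and particle tables", {
  st <- mini_structure_fixture()$st
  path <- withr::local_tempfile(fileext = ".n3d")
  write_n3d(st, path)
  back <- read_n3d(path)
  expect_equal(back$particle_size, st$particle_size)
  expect_equal(back$particles$chrom, st$particles$chrom)
  expect_equal(back$particles$start, st$particles$start)
  expect_equal(length(back$coords), length(st$coords))
  for (m in seq_along(st$coords)) {
    expect_equal(back$coords[[m]], st$coords[[m]], tolerance = 1e-5)
  }
})

test_that("tidy and glance summarise structures", {
  st <- mini_structure_fixture()$st
  td <- tidy(st)
  expect_equal(nrow(td), 3 * nrow(st$particles))
  expect_named(td, c("model", "chrom", "start", "x", "y", "z",
                     "has_restraint"))
  gl <- glance(st)
  expect_equal(gl$n_models, 3)
  expect_equal(gl$particle_size, 1e5)
})
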