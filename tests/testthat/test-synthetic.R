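test_that("random genomes are reproducible with the expected site density", {
  g1 <- make_genome(2, c(1e6, 5e5), seed = 3)
  g2 <- make_genome(2, c(1e6, 5e5), seed = 3)
  expect_identical(g1$sequences, g2$sequences)
  expect_equal(g1$chromosomes$name, c("chr1", "chr2"))
  expect_equal(nchar(g1$sequences[["chr2"]]), 5e5)
  # GATC occurrences ~ Binomial(L, 1/256): within 4 sigma of L/256
  n_sites <- length(gregexpr("GATC", g1$sequences[["chr1"]],
                             fixed = TRUE)[[1]])
  expected <- 1e6 / 256
  sigma <- sqrt(1e6 * (1 / 256) * (255 / 256))
  expect_lt(abs(n_sites - expected), 4 * sigma)
})

test_that("ground-truth conformations form walkable, confined territories", {
  g <- make_genome(2, 2e6, seed = 14)
  conf <- make_conformation(g, 1e5, seed = 15)
  expect_equal(nrow(conf$coords), 40)
  # unit steps along each chromosome backbone
  for (ch in unique(conf$particles$chrom)) {
    sel <- conf$particles$chrom == ch
    steps <- sqrt(rowSums(diff(conf$coords[sel, ])^2))
    expect_true(all(abs(steps - 1) < 0.01))
  }
  # confinement: every particle inside its territory sphere
  for (i in seq_len(2)) {
    sel <- conf$particles$chrom == paste0("chr", i)
    d <- sqrt(rowSums(sweep(conf$coords[sel, ], 2, conf$centers[i, ])^2))
    expect_true(all(d <= conf$radius + 1e-9))
  }
  # territories: centroids separated by more than the mean radius of gyration
  cen <- vapply(c("chr1", "chr2"), function(ch) {
    colMeans(conf$coords[conf$particles$chrom == ch, ])
  }, numeric(3))
  rg <- vapply(c("chr1", "chr2"), function(ch) {
    co <- conf$coords[conf$particles$chrom == ch, ]
    sqrt(mean(rowSums(sweep(co, 2, colMeans(co))^2)))
  }, 0)
  expect_gt(sqrt(sum((cen[, 1] - cen[, 2])^2)), mean(rg))
})

test_that("proximity sampling respects the capture kernel", {
  fx <- fixture_get("sim_cell", {
    g <- make_genome(2, 2e6, seed = 24)
    rmap <- digest(g, load_enzyme("MboI"))
    conf <- make_conformation(g, 1e5, seed = 25)
    list(g = g, rmap = rmap, conf = conf)
  })
  sim <- simulate_contacts(fx$conf, fx$rmap, 400, capture_radius = 1.2,
                           seed = 26)
  expect_equal(nrow(sim$contacts), 400)
  expect_equal(nrow(sim$ledger), 400)
  # every sampled pair lies within twice the capture radius
  expect_true(all(sim$ledger$distance < 2 * 1.2))
  # determinism
  sim2 <- simulate_contacts(fx$conf, fx$rmap, 400, capture_radius = 1.2,
                            seed = 26)
  expect_identical(sim$contacts, sim2$contacts)
  # contact positions fall inside their fragment
  expect_true(all(sim$contacts$posA >= sim$contacts$fragStartA &
                    sim$contacts$posA < sim$contacts$fragEndA))
  # no fragment end reused: promiscuity-free by construction
  keys <- c(paste(sim$contacts$chromA, sim$contacts$fragA, sim$contacts$sideA),
            paste(sim$contacts$chromB, sim$contacts$fragB, sim$contacts$sideB))
  expect_equal(anyDuplicated(keys), 0L)

  # narrow capture: sampling collapses onto bonded neighbours
  tight <- simulate_contacts(fx$conf, fx$rmap, 150, capture_radius = 0.55,
                             seed = 27)
  expect_true(all(tight$ledger$distance < 1.1))
  # backbone neighbours (the only pairs guaranteed close) dominate
  seps <- abs(tight$ledger$particle_i - tight$ledger$particle_j)
  expect_equal(as.integer(names(which.max(table(seps)))), 1L)

  # P(s) of a large sample decays with separation
  big <- simulate_contacts(fx$conf, fx$rmap, 3000, capture_radius = 1.2,
                           seed = 28)
  cv <- contact_probability_curve(big$contacts, fx$g)
  fit <- fit_powerlaw_slope(cv)
  expect_lt(fit$slope, 0)
})

test_that("noise specification validates fractions", {
  expect_error(noise_spec(frac_internal = -0.1), "non-negative")
  expect_error(noise_spec(0.5, 0.4, 0.2), "sum")
  ns <- noise_spec(0.1, 0.1, 0.05, 0.1, 0.05, 0.1)
  expect_equal(sum(unlist(ns)), 0.5)
})

test_that("noise-free cells pass the filters losslessly", {
  fx <- fixture_get("clean_cell", {
    make_fixture_cell(n_chrom = 2, chrom_length = 1e6, n_contacts = 60,
                      noise = noise_spec(), seed = 500)
  })
  res <- process_cell(fx$reads$r1, fx$reads$r2, fx$genome, fx$enzyme,
                      rmap = fx$rmap, cell_id = "clean")
  expect_equal(res$qc$pct_unique, 100)
  expect_equal(res$qc$pct_accepted, 100)
  expect_equal(nrow(res$contacts), nrow(fx$contacts))
  expect_equal(res$n_singleton_discarded, 0)
  expect_equal(res$n_promiscuous, 0)
  # recovered ligation events are exactly the simulated fragment-end pairs
  key <- function(d) sort(paste(d$chromA, d$fragA, d$sideA, d$chromB,
                                d$fragB, d$sideB))
  expect_equal(key(res$contacts), key(fx$contacts))
})

test_that("singleton and promiscuous labels drive their filters exactly", {
  fx <- fixture_get("noisy_small_cell", {
    make_fixture_cell(n_chrom = 2, chrom_length = 1e6, n_contacts = 50,
                      noise = noise_spec(frac_singleton = 0.2,
                                         frac_promiscuous = 0.1),
                      seed = 600)
  })
  res <- process_cell(fx$reads$r1, fx$reads$r2, fx$genome, fx$enzyme,
                      rmap = fx$rmap)
  truth <- fx$reads$truth
  n_singleton <- sum(truth$label == "singleton")
  n_prom_contacts <- length(unique(
    sub(":[0-9]+$", "", truth$id[truth$label == "promiscuous"])))
  expect_equal(res$n_singleton_discarded, n_singleton)
  expect_equal(res$n_promiscuous, n_prom_contacts)
  expect_equal(nrow(res$contacts), nrow(fx$contacts))
})
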