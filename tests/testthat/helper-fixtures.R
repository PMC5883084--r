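# Shared fixtures, built in code and cached for the duration of a test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture_get <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

mini_structure_fixture <- function() {
  fixture_get("mini_structure", {
    cell <- make_structure_cell(n_chrom = 2, chrom_length = 2e6,
                                n_contacts = 500, seed = 77)
    sch <- anneal_schedule(particle_sizes = c(8e5, 4e5, 1e5),
                           n_temps = 20, steps_per_temp = 80,
                           quench_steps = 300)
    st <- anneal_genome(cell$contacts, cell$genome, sch, n_models = 3,
                        seed = 31, restarts = 1)
    st2 <- anneal_genome(cell$contacts, cell$genome, sch, n_models = 3,
                         seed = 31, restarts = 1)
    list(cell = cell, sch = sch, st = st, st2 = st2)
  })
}

test_genome <- function() {
  fixture_get("genome_small", make_genome(2, 2e5, seed = 101))
}

test_rmap <- function() {
  fixture_get("rmap_small", digest(test_genome(), load_enzyme("MboI")))
}

# A designed chromosome: segments of known length joined by GATC sites, so
# cut positions and fragment bounds are known by construction.
designed_genome <- function(seg_lengths, seed = 5) {
  set.seed(seed)
  segs <- vapply(seg_lengths, function(L) {
    repeat {
      s <- paste(sample(c("A", "C", "T"), L, replace = TRUE), collapse = "")
      if (!grepl("GATC", s, fixed = TRUE)) return(s)
    }
  }, "")
  seq <- paste0(segs[1], paste0("GATC", segs[-1], collapse = ""))
  genome_assembly(tibble::tibble(name = "chrD", length = nchar(seq)),
                  c(chrD = seq))
}

# mapped-end row constructor for classification tests
mend <- function(chrom, pos, strand, status = "unique") {
  tibble::tibble(chrom = chrom, pos = pos, strand = strand,
                 n_hits = if (status == "unique") 1L else 2L,
                 status = status, unique = status == "unique")
}

mpair <- function(id, e1, e2) {
  m1 <- dplyr::bind_cols(tibble::tibble(id = id), e1)
  m2 <- dplyr::bind_cols(tibble::tibble(id = id), e2)
  pair_ends(m1, m2)
}

random_contacts <- function(n, seed, n_chrom = 2, len = 1e7) {
  set.seed(seed)
  tibble::tibble(
    chromA = paste0("chr", sample(n_chrom, n, replace = TRUE)),
    posA = floor(runif(n) * len), strandA = "+",
    chromB = paste0("chr", sample(n_chrom, n, replace = TRUE)),
    posB = floor(runif(n) * len), strandB = "-",
    support = 2L, cell_id = "rnd")
}

# brute-force oracle for the isolated-contact filter
brute_isolated_filter <- function(contacts, window = 2e6) {
  n <- nrow(contacts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == i) next
      same_direct <- contacts$chromA[i] == contacts$chromA[k] &&
        contacts$chromB[i] == contacts$chromB[k] &&
        abs(contacts$posA[i] - contacts$posA[k]) <= window &&
        abs(contacts$posB[i] - contacts$posB[k]) <= window
      same_cross <- contacts$chromA[i] == contacts$chromB[k] &&
        contacts$chromB[i] == contacts$chromA[k] &&
        abs(contacts$posA[i] - contacts$posB[k]) <= window &&
        abs(contacts$posB[i] - contacts$posA[k]) <= window
      if (same_direct || same_cross) { keep[i] <- TRUE; break }
    }
  }
  contacts[keep, , drop = FALSE]
}

# independent superposition oracle: quaternion grid search + Nelder-Mead
# refinement of the unweighted RMSD
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

oracle_rmsd <- function(ref, mov, n_grid = 4000, seed = 1) {
  set.seed(seed)
  A <- sweep(mov, 2, colMeans(mov))
  B <- sweep(ref, 2, colMeans(ref))
  obj <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  best <- qs[which.min(vals), ]
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  fit2$value
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  quat_to_rot(rnorm(4))
}
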