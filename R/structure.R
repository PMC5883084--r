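#' Remove isolated contacts
#'
#' To reduce noise before structure calculation, a contact is kept only
#' if some other contact has both of its ends within `window` of the
#' corresponding ends of this contact (same chromosome pairing, matched
#' in either orientation for cis contacts). Isolated contacts -- with no
#' such support -- are discarded. Input order is preserved.
#'
#' @param contacts Contacts tibble.
#' @param window Genomic support window in bp (default 2 Mb).
#' @return The supported subset of `contacts`.
#' @export
filter_isolated_contacts <- function(contacts, window = 2e6) {
  stopifnot(window > 0)
  n <- nrow(contacts)
  if (n == 0) return(contacts)
  # orient each contact by (chrom, pos) so grouping is orientation-free
  swap <- (contacts$chromA > contacts$chromB) |
    (contacts$chromA == contacts$chromB & contacts$posA > contacts$posB)
  cA <- ifelse(swap, contacts$chromB, contacts$chromA)
  cB <- ifelse(swap, contacts$chromA, contacts$chromB)
  pA <- ifelse(swap, contacts$posB, contacts$posA)
  pB <- ifelse(swap, contacts$posA, contacts$posB)
  grp <- paste(cA, cB)
  keep <- logical(n)
  for (g in unique(grp)) {
    sel <- which(grp == g)
    if (length(sel) < 2) next
    a <- pA[sel]; b <- pB[sel]
    near <- function(u, v) abs(outer(u, v, "-")) <= window
    supp <- near(a, a) & near(b, b)
    if (cA[sel[1]] == cB[sel[1]]) {
      supp <- supp | (near(a, b) & near(b, a))
    }
    diag(supp) <- FALSE
    keep[sel] <- rowSums(supp) > 0
  }
  contacts[keep, , drop = FALSE]
}

particle_table <- function(genome, particle_size) {
  ch <- genome$chromosomes
  purrr::map2_dfr(ch$name, ch$length, function(nm, len) {
    starts <- seq(0, by = particle_size, length.out = ceiling(len / particle_size))
    tibble::tibble(chrom = nm, start = starts,
                   end = pmin(starts + particle_size, len))
  })
}

#' Convert contacts to distance restraints at a particle size
#'
#' Particles tile each chromosome in `particle_size` steps. Each contact
#' maps its two representative positions to particle indices; duplicate
#' particle pairs collapse to one restraint and self-pairs are dropped.
#' Contact restraints get flat-bottom bounds `[0.8, 1.2]` particle radii
#' (contacting chromatin touches); sequential particles are joined by
#' backbone bonds with the same bounds in the current stage's radius
#' unit.
#'
#' @param contacts Contacts tibble.
#' @param particle_size Particle size in bp.
#' @param genome A [genome_assembly()].
#' @param lower,upper Contact restraint bounds in particle radii.
#' @return A `restraint_set`: list with `particles` (tibble `chrom`,
#'   `start`, `end`), `restraints` (tibble `i`, `j`, `lower`, `upper`,
#'   1-based particle indices), `backbone` (same shape) and
#'   `particle_size`.
#' @export
contacts_to_restraints <- function(contacts, particle_size, genome,
                                   lower = 0.8, upper = 1.2) {
  stopifnot(particle_size > 0, lower > 0, lower <= upper)
  parts <- particle_table(genome, particle_size)
  nb <- table(factor(parts$chrom, levels = genome$chromosomes$name))
  offs <- stats::setNames(cumsum(c(0, as.numeric(nb[-length(nb)]))),
                          names(nb))
  pidx <- function(chrom, pos) {
    o <- offs[chrom]
    if (anyNA(o)) rlang::abort("contact on unknown chromosome")
    unname(o + pmin(floor(pos / particle_size), as.numeric(nb[chrom]) - 1) + 1)
  }
  if (nrow(contacts)) {
    pi_ <- pidx(contacts$chromA, contacts$posA)
    pj <- pidx(contacts$chromB, contacts$posB)
    lo <- pmin(pi_, pj); hi <- pmax(pi_, pj)
    keep <- lo != hi
    restr <- dplyr::distinct(tibble::tibble(i = lo[keep], j = hi[keep])) |>
      dplyr::mutate(lower = lower, upper = upper)
  } else {
    restr <- tibble::tibble(i = integer(0), j = integer(0),
                            lower = numeric(0), upper = numeric(0))
  }
  backbone <- parts |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(i = .data$idx[-dplyr::n()], j = .data$idx[-1]) |>
    dplyr::transmute(.data$i, .data$j, lower = 0.8, upper = 1.2)
  structure(list(particles = parts, restraints = restr, backbone = backbone,
                 particle_size = particle_size),
            class = "restraint_set")
}

#' Hierarchical annealing schedule
#'
#' Structures are solved coarse-to-fine: each stage anneals a
#' particle-on-a-string model at one particle size under a geometric
#' temperature ladder, then subdivides particles for the next stage.
#'
#' @param particle_sizes Strictly decreasing particle sizes in bp;
#'   default 8, 4, 2, 0.4, 0.2 Mb then a final 0.1 Mb stage.
#' @param temp_start,temp_end Temperature ladder endpoints (arbitrary
#'   units), geometric and strictly decreasing.
#' @param n_temps Ladder length per stage.
#' @param steps_per_temp Dynamics steps at each temperature.
#' @param quench_steps Zero-temperature steps appended to each stage to
#'   settle into the local minimum.
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(particle_sizes = c(8e6, 4e6, 2e6, 4e5, 2e5, 1e5),
                            temp_start = 5000, temp_end = 10,
                            n_temps = 40, steps_per_temp = 200,
                            quench_steps = 1500) {
  stopifnot(all(diff(particle_sizes) < 0), temp_start > temp_end,
            temp_end > 0, n_temps >= 2, steps_per_temp >= 1)
  temps <- exp(seq(log(temp_start), log(temp_end), length.out = n_temps))
  structure(list(particle_sizes = particle_sizes, temps = temps,
                 steps_per_temp = as.integer(steps_per_temp),
                 quench_steps = as.integer(quench_steps)),
            class = "anneal_schedule")
}

default_engine <- function() {
  list(k_restraint = 25, k_backbone = 25, k_repulsion = 50,
       repulsion_dist = 0.8, dt = 0.01, max_step = 0.25,
       noise_scale = 0.05, jitter = 0.1, init_radius_factor = 1.5)
}

# Point inversion of one chromosome about its centroid: preserves every
# intra-chromosome distance while flipping the chromosome's hand.
invert_chromosome <- function(coords, parts, ch) {
  sel <- parts$chrom == ch
  ctr <- colMeans(coords[sel, , drop = FALSE])
  coords[sel, ] <- sweep(-coords[sel, , drop = FALSE], 2, 2 * ctr, "+")
  coords
}

random_sphere <- function(n, radius) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * radius * stats::runif(n)^(1 / 3)
}

interp_subdivide <- function(parts_old, coords_old, parts_new, scale, jitter) {
  out <- matrix(0, nrow(parts_new), 3)
  coords_old <- coords_old * scale
  for (ch in unique(parts_new$chrom)) {
    io <- which(parts_old$chrom == ch)
    in_ <- which(parts_new$chrom == ch)
    co <- (parts_old$start[io] + parts_old$end[io]) / 2
    cn <- (parts_new$start[in_] + parts_new$end[in_]) / 2
    if (length(io) == 1) {
      out[in_, ] <- matrix(coords_old[io, ], length(in_), 3, byrow = TRUE)
    } else {
      for (d in 1:3) {
        out[in_, d] <- stats::approx(co, coords_old[io, d], xout = cn,
                                     rule = 2)$y
      }
    }
  }
  out + matrix(stats::rnorm(length(out), sd = jitter), nrow(out), 3)
}

#' Compute genome structures by hierarchical simulated annealing
#'
#' For each model, particles of the coarsest stage start at
#' uniform-random positions inside a sphere (radius proportional to the
#' cube root of the particle count; a different random start per model).
#' At each stage a composite cost -- flat-bottom harmonics on contact
#' restraints and backbone bonds plus a soft short-range repulsion that
#' prevents superposition -- is minimised by noisy steepest descent under
#' a decreasing temperature ladder, ending in a zero-temperature quench.
#' Between stages every particle is subdivided: child particles are
#' placed by linear interpolation along the chromosome backbone (with
#' small random jitter to break symmetry), coordinates are rescaled to
#' the finer stage's radius unit, and restraints are rebuilt at the finer
#' particle size. Coordinates are in units of the current-stage particle
#' radius.
#'
#' @param contacts Contacts tibble (non-empty after restraint mapping).
#' @param genome A [genome_assembly()].
#' @param schedule An [anneal_schedule()].
#' @param n_models Number of independent models (random starts).
#' @param seed Integer seed; the run is fully deterministic given
#'   (inputs, schedule, seed).
#' @param restarts Annealing chains per model: each model is the
#'   lowest-final-cost result of `restarts` independent chains (from
#'   different random starts), a convergence safeguard against rare
#'   chains that freeze into a poor local minimum.
#' @param hand_branching Distance restraints are mirror-invariant within
#'   a chromosome, so a chain can freeze with one chromosome's hand
#'   inconsistent with its trans contacts -- a near-degenerate minimum
#'   that independent restarts resolve only unreliably. With
#'   `hand_branching = TRUE` (the default, for multi-chromosome genomes
#'   with at least three stages) each chain branches two stages before
#'   the end: for every chromosome after the first, a variant with that
#'   chromosome's hand flipped (point inversion about its centroid,
#'   briefly re-annealed) is carried through the remaining stages, and
#'   the lower-final-cost branch is kept. The paired comparison shares
#'   subdivision jitter and stage seeds, so it isolates the hand choice
#'   from chain-to-chain noise.
#' @param engine Engine parameters (force constants, step size, noise
#'   scale); see `schic3d:::default_engine()`.
#' @return A `genome_structure`: list with `particle_size`, `particles`
#'   (tibble, final stage), `coords` (list of N x 3 matrices, one per
#'   model), `has_restraint` (logical per particle; particles without
#'   contact restraints are positioned by backbone and repulsion only and
#'   are low-confidence), `energies` (per model and stage), `seed`,
#'   `schedule`.
#' @export
anneal_genome <- function(contacts, genome, schedule = anneal_schedule(),
                          n_models = 5, seed = 1, restarts = 3,
                          hand_branching = TRUE,
                          engine = default_engine()) {
  stopifnot(n_models >= 1, restarts >= 1)
  eng <- utils::modifyList(default_engine(), engine)
  sizes <- schedule$particle_sizes
  n_stages <- length(sizes)
  rsets <- lapply(sizes, function(s) contacts_to_restraints(contacts, s, genome))
  if (nrow(rsets[[n_stages]]$restraints) == 0) {
    rlang::abort("empty restraint graph: no usable contacts")
  }
  n_temps_q <- ceiling(schedule$quench_steps / schedule$steps_per_temp)
  temps <- c(schedule$temps, rep(0, n_temps_q))
  relax_temps <- c(exp(seq(log(200), log(min(schedule$temps)),
                           length.out = 10)), 0, 0)
  chroms <- unique(rsets[[1]]$particles$chrom)
  branch_after <- if (hand_branching && length(chroms) > 1 && n_stages >= 3) {
    n_stages - 2L
  } else 0L
  models <- vector("list", n_models)
  energies <- list()
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  hseed <- function(...) {
    v <- c(abs(seed) %% 100003L, ...)
    as.integer(sum(v * (3L + seq_along(v) * 104729L)) %% .Machine$integer.max)
  }
  stage_anneal <- function(coords, st, sd, temps_v = temps) {
    rs <- rsets[[st]]
    anneal_stage_cpp(coords,
                     rs$restraints$i - 1L, rs$restraints$j - 1L,
                     rs$restraints$lower, rs$restraints$upper,
                     rs$backbone$i - 1L, rs$backbone$j - 1L,
                     rs$backbone$lower, rs$backbone$upper,
                     temps_v, schedule$steps_per_temp,
                     eng$k_restraint, eng$k_backbone, eng$k_repulsion,
                     eng$repulsion_dist, eng$dt, eng$max_step,
                     eng$noise_scale, sd)
  }
  subdivide <- function(coords, st, sd) {
    set.seed(sd)
    interp_subdivide(rsets[[st - 1]]$particles, coords, rsets[[st]]$particles,
                     (sizes[st - 1] / sizes[st])^(1 / 3), eng$jitter)
  }
  # anneal stages `from`..n_stages; subdivision jitter and stage seeds
  # depend on (m, r) only, so branches of one chain are paired exactly
  run_stages <- function(coords, from, m, r) {
    en <- vector("list", n_stages - from + 1)
    for (st in from:n_stages) {
      if (st > 1) coords <- subdivide(coords, st, hseed(m, r, st, 1L))
      res <- stage_anneal(coords, st, hseed(m, r, st, 2L))
      coords <- res$coords
      en[[st - from + 1]] <- tibble::tibble(
        model = m, stage = st, particle_size = sizes[st],
        e_init = res$e_init, e_final = res$e_final,
        e_restraint = res$e_restraint)
    }
    list(coords = coords, energies = dplyr::bind_rows(en),
         e_last = en[[n_stages - from + 1]]$e_final)
  }
  run_chain <- function(m, r) {
    set.seed(hseed(m, r, 0L, 0L))
    coords <- random_sphere(nrow(rsets[[1]]$particles),
                            eng$init_radius_factor *
                              nrow(rsets[[1]]$particles)^(1 / 3))
    en_prefix <- list()
    last_stage <- if (branch_after > 0L) branch_after else n_stages
    for (st in seq_len(last_stage)) {
      if (st > 1) coords <- subdivide(coords, st, hseed(m, r, st, 1L))
      res <- stage_anneal(coords, st, hseed(m, r, st, 2L))
      coords <- res$coords
      en_prefix[[st]] <- tibble::tibble(
        model = m, stage = st, particle_size = sizes[st],
        e_init = res$e_init, e_final = res$e_final,
        e_restraint = res$e_restraint)
    }
    if (branch_after == 0L) {
      return(list(coords = coords, energies = dplyr::bind_rows(en_prefix),
                  e_last = en_prefix[[n_stages]]$e_final))
    }
    parts_b <- rsets[[branch_after]]$particles
    best <- run_stages(coords, branch_after + 1L, m, r)
    for (ci in seq_along(chroms)[-1]) {
      cand0 <- invert_chromosome(coords, parts_b, chroms[ci])
      cand0 <- stage_anneal(cand0, branch_after,
                            hseed(m, r, branch_after, 2L + ci),
                            relax_temps)$coords
      cand <- run_stages(cand0, branch_after + 1L, m, r)
      if (cand$e_last < best$e_last) best <- cand
    }
    list(coords = best$coords,
         energies = dplyr::bind_rows(c(en_prefix, list(best$energies))),
         e_last = best$e_last)
  }
  for (m in seq_len(n_models)) {
    chains <- lapply(seq_len(restarts), function(r) run_chain(m, r))
    finals <- vapply(chains, function(ch) ch$e_last, 0)
    best <- chains[[which.min(finals)]]
    models[[m]] <- best$coords
    energies[[m]] <- best$energies
  }
  final_rs <- rsets[[length(sizes)]]
  has_restraint <- seq_len(nrow(final_rs$particles)) %in%
    c(final_rs$restraints$i, final_rs$restraints$j)
  structure(list(particle_size = sizes[length(sizes)],
                 particles = final_rs$particles,
                 coords = models,
                 has_restraint = has_restraint,
                 energies = dplyr::bind_rows(energies),
                 seed = seed, schedule = schedule),
            class = "genome_structure")
}

#' @export
print.genome_structure <- function(x, ...) {
  cat("<genome_structure> ", length(x$coords), " model(s), ",
      nrow(x$particles), " particles at ",
      format(x$particle_size, big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Tidy a genome structure into a long tibble
#'
#' @param x A `genome_structure`.
#' @param ... Unused.
#' @return Tibble `model`, `chrom`, `start`, `x`, `y`, `z`,
#'   `has_restraint`.
#' @export
tidy.genome_structure <- function(x, ...) {
  parts <- x$particles
  hr <- x$has_restraint
  purrr::imap_dfr(x$coords, function(co, m) {
    tibble::tibble(model = m, chrom = parts$chrom, start = parts$start,
                   x = co[, 1], y = co[, 2], z = co[, 3],
                   has_restraint = hr)
  })
}

#' One-row summary of a genome structure
#'
#' @param x A `genome_structure`.
#' @param ... Unused.
#' @return Tibble with particle and model counts, particle size, and the
#'   final-stage energy range across models.
#' @export
glance.genome_structure <- function(x, ...) {
  ef <- x$energies[x$energies$stage == max(x$energies$stage), ]
  tibble::tibble(n_particles = nrow(x$particles),
                 n_models = length(x$coords),
                 particle_size = x$particle_size,
                 e_final_min = min(ef$e_final),
                 e_final_max = max(ef$e_final))
}

#' Run the contact-to-structure pipeline
#'
#' Applies the isolated-contact filter, then hierarchical annealing, and
#' optionally writes the multi-model N3D output. With fewer than
#' `min_contacts` after filtering a warning is recorded in the report
#' and the run continues.
#'
#' @param contacts Contacts tibble or path to an NCC file.
#' @param genome A [genome_assembly()].
#' @param schedule An [anneal_schedule()].
#' @param n_models Number of models (default 10).
#' @param seed Integer seed.
#' @param out_n3d Optional N3D output path.
#' @param isolation_window Support window for
#'   [filter_isolated_contacts()].
#' @param min_contacts Threshold below which a low-data warning is
#'   recorded.
#' @param engine Engine parameter overrides, see [anneal_genome()].
#' @return List of class `structure_run`: `structure`
#'   (`genome_structure`), `report` (tibble `n_input`, `n_used`,
#'   `low_data`), `contacts_used`.
#' @export
run_structure_pipeline <- function(contacts, genome,
                                   schedule = anneal_schedule(),
                                   n_models = 10, seed = 1, out_n3d = NULL,
                                   isolation_window = 2e6,
                                   min_contacts = 100, restarts = 3,
                                   hand_branching = TRUE,
                                   engine = default_engine()) {
  if (is.character(contacts)) contacts <- read_ncc(contacts)
  if (!nrow(contacts)) rlang::abort("empty contact list")
  used <- filter_isolated_contacts(contacts, isolation_window)
  low <- nrow(used) < min_contacts
  if (low) {
    rlang::warn(paste0("only ", nrow(used), " contacts remain after the ",
                       "isolated-contact filter (minimum ", min_contacts, ")"))
  }
  st <- anneal_genome(used, genome, schedule, n_models, seed, restarts,
                      hand_branching, engine)
  if (!is.null(out_n3d)) write_n3d(st, out_n3d)
  structure(list(structure = st,
                 report = tibble::tibble(n_input = nrow(contacts),
                                         n_used = nrow(used), low_data = low),
                 contacts_used = used),
            class = "structure_run")
}
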