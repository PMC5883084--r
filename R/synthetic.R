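with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a random genome
#'
#' Uniform-random A/T/G/C sequences, so a 4-bp recognition site such as
#' GATC occurs with expected density 1/256 per position (mean fragment
#' size 256 bp, as for a typical 4-cutter). Deterministic per seed.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chrom`).
#' @param seed Integer seed.
#' @return A [genome_assembly()] with chromosomes `chr1`, `chr2`, ...
#' @export
make_genome <- function(n_chrom = 2, lengths = 1e7, seed = 1) {
  stopifnot(all(lengths > 0))
  lengths <- rep_len(lengths, n_chrom)
  with_seed_local(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, "")
    names(seqs) <- paste0("chr", seq_len(n_chrom))
    genome_assembly(tibble::tibble(name = names(seqs), length = lengths), seqs)
  })
}

#' Generate a ground-truth genome conformation
#'
#' Emulates interphase chromosome territories: each chromosome is a
#' confined random walk with unit step (one particle radius between
#' sequential particles) and short-range self-avoidance (candidate steps
#' closer than 0.8 radii to recent particles are rejected), grown inside
#' a chromosome-specific sphere; the spheres are offset to distinct
#' sub-volumes so chromosomes occupy discrete yet touching territories.
#'
#' @param genome A [genome_assembly()].
#' @param particle_size Particle size in bp (default 100 kb).
#' @param seed Integer seed.
#' @param territory_sep Centre-to-centre distance between neighbouring
#'   chromosome territories, in units of the territory radius. The
#'   default, together with `radius_factor`, makes territories dense and
#'   overlapping enough that a realistic share of proximity contacts is
#'   trans-chromosomal while centroids stay further apart than the mean
#'   radius of gyration.
#' @param radius_factor Territory sphere radius as a multiple of the
#'   cube root of the chromosome's particle count (smaller = denser).
#' @param avoid_dist Self-avoidance distance in radii.
#' @param avoid_window Number of recent particles checked for
#'   self-avoidance.
#' @return List with `particles` (tibble `chrom`, `start`, `end`) and
#'   `coords` (N x 3 matrix, particle-radius units), plus `centers`.
#' @export
make_conformation <- function(genome, particle_size = 1e5, seed = 1,
                              territory_sep = 1.2, radius_factor = 0.75,
                              avoid_dist = 0.8, avoid_window = 30) {
  parts <- particle_table(genome, particle_size)
  chs <- genome$chromosomes$name
  n_per <- table(factor(parts$chrom, levels = chs))
  radius <- radius_factor * max(n_per)^(1 / 3)
  # territory centres on a line through the origin, territory_sep*radius apart
  offs <- (seq_along(chs) - (length(chs) + 1) / 2) * territory_sep * radius
  centers <- cbind(offs, 0, 0)
  with_seed_local(seed, {
    coords <- matrix(0, nrow(parts), 3)
    row <- 1
    for (ci in seq_along(chs)) {
      n <- as.integer(n_per[ci])
      ctr <- centers[ci, ]
      pts <- matrix(0, n, 3)
      pts[1, ] <- ctr + stats::rnorm(3, sd = 0.3 * radius)
      for (k in seq_len(n - 1)) {
        best <- NULL; best_min <- -Inf
        for (try in 1:200) {
          step <- stats::rnorm(3)
          step <- step / sqrt(sum(step^2))
          cand <- pts[k, ] + step
          if (sqrt(sum((cand - ctr)^2)) > radius) next
          lo <- max(1, k - avoid_window)
          prev <- pts[lo:max(lo, k - 1), , drop = FALSE]
          dmin <- if (k == 1) Inf else
            sqrt(min(rowSums(sweep(prev, 2, cand)^2)))
          if (dmin >= avoid_dist) { best <- cand; break }
          if (dmin > best_min) { best_min <- dmin; best <- cand }
        }
        pts[k + 1, ] <- best
      }
      coords[row:(row + n - 1), ] <- pts
      row <- row + n
    }
    list(particles = parts, coords = coords, centers = centers,
         radius = radius, particle_size = particle_size)
  })
}

#' Sample proximity contacts from a ground-truth conformation
#'
#' Emulates proximity ligation: particle pairs at 3D distance `d` below
#' `2 * capture_radius` are sampled with probability proportional to
#' `exp(-(d / capture_radius)^2)`, so close loci ligate preferentially.
#' Each sampled pair is realised as a ligation between one restriction
#' fragment end inside each particle; ends are drawn without reuse (a
#' fragment end joins at most one contact), fragments are internal,
#' long enough to carry a junction-spanning read, and cis pairs at least
#' two fragments apart, so downstream filters classify every clean
#' contact as accepted.
#'
#' @param conf A [make_conformation()] result.
#' @param rmap A [digest()] map of the same genome.
#' @param n_contacts Number of contacts to sample.
#' @param capture_radius Ligation capture scale in particle radii.
#' @param seed Integer seed.
#' @param min_frag_len Minimum fragment length eligible to carry an end.
#' @return List with `contacts` (contacts tibble, `support = 2`) and
#'   `ledger` (tibble `contact`, `particle_i`, `particle_j`,
#'   `distance`).
#' @export
simulate_contacts <- function(conf, rmap, n_contacts = 3000,
                              capture_radius = 1.5, seed = 1,
                              min_frag_len = 100) {
  stopifnot(capture_radius > 0)
  parts <- conf$particles
  co <- conf$coords
  n <- nrow(parts)
  # candidate pairs within 2 * capture_radius
  cut <- 2 * capture_radius
  pair_i <- integer(0); pair_j <- integer(0); pair_d <- numeric(0)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    dx <- co[js, 1] - co[i, 1]; dy <- co[js, 2] - co[i, 2]
    dz <- co[js, 3] - co[i, 3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    sel <- which(d < cut)
    pair_i <- c(pair_i, rep(i, length(sel)))
    pair_j <- c(pair_j, js[sel])
    pair_d <- c(pair_d, d[sel])
  }
  if (!length(pair_i)) rlang::abort("no particle pairs within capture distance")
  w <- exp(-(pair_d / capture_radius)^2)
  fr <- rmap$fragments
  with_seed_local(seed, {
    picks <- sample.int(length(pair_i), n_contacts, replace = TRUE, prob = w)
    used_ends <- new.env(hash = TRUE)
    # eligible fragments per particle: internal (both boundaries are cuts)
    # and long enough for junction-spanning reads
    elig <- lapply(seq_len(n), function(p) {
      ch <- parts$chrom[p]
      sel <- fr$chrom == ch & fr$start >= parts$start[p] &
        fr$end <= parts$end[p] & (fr$end - fr$start) >= min_frag_len &
        fr$frag > 1
      ok <- which(sel)
      nfr <- sum(fr$chrom == ch)
      ok[fr$frag[ok] < nfr]
    })
    draw_end <- function(p, avoid_frags = integer(0)) {
      cand <- elig[[p]]
      cand <- cand[!fr$frag[cand] %in% avoid_frags]
      cand <- cand[sample.int(length(cand))]
      for (f in cand) {
        for (side in sample(c("L", "R"))) {
          key <- paste(f, side)
          if (is.null(used_ends[[key]])) {
            used_ends[[key]] <- TRUE
            return(list(row = f, side = side))
          }
        }
      }
      NULL
    }
    rows <- vector("list", n_contacts)
    ledger <- vector("list", n_contacts)
    got <- 0
    for (k in picks) {
      i <- pair_i[k]; j <- pair_j[k]
      same_chrom <- parts$chrom[i] == parts$chrom[j]
      eA <- draw_end(i)
      if (is.null(eA)) next
      avoid <- if (same_chrom && !is.null(eA)) {
        fr$frag[eA$row] + (-1:1)
      } else integer(0)
      eB <- draw_end(j, avoid)
      if (is.null(eB)) next
      got <- got + 1
      mk <- function(e, ch) {
        s <- fr$start[e$row]; en <- fr$end[e$row]
        list(chrom = ch, frag = fr$frag[e$row], side = e$side,
             fragStart = s, fragEnd = en,
             pos = if (e$side == "R") en - 1 else s,
             strand = if (e$side == "R") "+" else "-")
      }
      a <- mk(eA, parts$chrom[i]); b <- mk(eB, parts$chrom[j])
      rows[[got]] <- tibble::tibble(
        chromA = a$chrom, fragA = a$frag, sideA = a$side,
        fragStartA = a$fragStart, fragEndA = a$fragEnd,
        posA = a$pos, strandA = a$strand,
        chromB = b$chrom, fragB = b$frag, sideB = b$side,
        fragStartB = b$fragStart, fragEndB = b$fragEnd,
        posB = b$pos, strandB = b$strand,
        support = 2L, cell_id = "synthetic")
      ledger[[got]] <- tibble::tibble(contact = got, particle_i = i,
                                      particle_j = j, distance = pair_d[k])
    }
    contacts <- dplyr::bind_rows(rows[seq_len(got)])
    # canonical end order (chromosome rank, then position)
    rk <- function(ch) match(ch, rmap$chrom_order)
    swap <- (rk(contacts$chromB) < rk(contacts$chromA)) |
      (contacts$chromA == contacts$chromB & contacts$posB < contacts$posA)
    acols <- c("chromA", "fragA", "sideA", "fragStartA", "fragEndA",
               "posA", "strandA")
    bcols <- sub("A", "B", acols)
    tmp <- contacts[swap, acols]
    contacts[swap, acols] <- contacts[swap, bcols]
    contacts[swap, bcols] <- tmp
    list(contacts = contacts,
         ledger = dplyr::bind_rows(ledger[seq_len(got)]))
  })
}

#' Noise specification for read-pair simulation
#'
#' Fractions of generated events per illegitimate class; the remainder
#' are clean supported contacts. Classes mirror the filter cascade:
#' read pairs internal to one fragment, re-ligation of adjacent
#' fragments, self-circularised fragments, uniformly random
#' trans-chromosomal ligations (which pass all filters), promiscuous
#' shared-end triplets, and accepted-geometry events supported by a
#' single read pair.
#'
#' @param frac_internal,frac_adjacent,frac_circular,frac_random_trans,frac_promiscuous,frac_singleton
#'   Non-negative fractions with sum at most 1.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(frac_internal = 0, frac_adjacent = 0,
                       frac_circular = 0, frac_random_trans = 0,
                       frac_promiscuous = 0, frac_singleton = 0) {
  fr <- c(internal = frac_internal, adjacent = frac_adjacent,
          circular = frac_circular, random_trans = frac_random_trans,
          promiscuous = frac_promiscuous, singleton = frac_singleton)
  if (any(fr < 0)) rlang::abort("noise fractions must be non-negative")
  if (sum(fr) > 1) rlang::abort("noise fractions sum to more than 1")
  structure(as.list(fr), class = "noise_spec")
}
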