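# Read-pair construction for synthetic cells.
#
# A ligation product is modelled as the join of two restriction-fragment
# ends. For an end ligated at its 3' cut (side R) the molecule carries the
# fragment sequence up to the cut plus the filled-in overhang; for an end
# ligated at its 5' cut (side L) it carries the fragment sequence from the
# cut. Reads are taken from the two molecule ends, so reads close enough to
# the junction run through it and must be clipped before mapping.

# Outward-reading sequence of one end: for side L the fragment's first
# `len` bases; for side R the reverse complement of (last `len` bases +
# filled overhang). The chimeric molecule joining ends E1, E2 is
# rc(W(E1)) + W(E2).
end_sequence <- function(genome, chrom, fragStart, fragEnd, side, len, fill) {
  seq <- chrom_sequence(genome, chrom)
  if (side == "L") {
    substr(seq, fragStart + 1, fragStart + len)
  } else {
    revcomp(paste0(substr(seq, fragEnd - len + 1, fragEnd), fill))
  }
}

ligation_molecule <- function(genome, endA, endB, lenA, lenB, fill) {
  wa <- end_sequence(genome, endA$chrom, endA$fragStart, endA$fragEnd,
                     endA$side, lenA, fill)
  wb <- end_sequence(genome, endB$chrom, endB$fragStart, endB$fragEnd,
                     endB$side, lenB, fill)
  paste0(revcomp(wa), wb)
}

read_pair_from_molecule <- function(mol, read_len) {
  n <- nchar(mol)
  stopifnot(n >= read_len)
  list(seq1 = substr(mol, 1, read_len),
       seq2 = substr(revcomp(mol), 1, read_len))
}

#' Simulate paired-end reads for a synthetic cell
#'
#' Clean events emit two read pairs each, with sequences crossing a
#' constructed ligation junction between the two fragment ends of the
#' contact (junction per the enzyme's fill-in flag). Noise classes
#' construct read pairs matching each filter's trigger geometry exactly:
#' pairs inside one fragment facing inward (`internal`), facing outward
#' (`circular`), pairs on adjacent fragments (`adjacent`), random
#' cross-chromosome junction events with support two (`random_trans`),
#' shared-end triplets (`promiscuous`, three contacts sharing one
#' fragment end, two read pairs each) and accepted-geometry events with a
#' single read pair (`singleton`). The truth ledger labels every read
#' pair.
#'
#' @param contacts Clean contacts from [simulate_contacts()].
#' @param genome The [genome_assembly()] the contacts refer to.
#' @param rmap The primary [digest()] map.
#' @param enz The primary [enzyme()] (fill-in protocols only).
#' @param read_len Read length in bp (default 70; must exceed the
#'   junction length by at least 10).
#' @param noise A [noise_spec()]; fractions are per generated event, the
#'   clean contacts being the remainder.
#' @param seed Integer seed.
#' @param cell_id Cell identifier used in read ids.
#' @return List with `r1`, `r2` (read tibbles), `truth` (tibble `id`,
#'   `label`, `event`), and `counts` (events per class).
#' @export
simulate_read_pairs <- function(contacts, genome, rmap, enz, read_len = 70,
                                noise = noise_spec(), seed = 1,
                                cell_id = "cell1") {
  stopifnot(inherits(noise, "noise_spec"))
  junction <- junction_sequence(enz)
  if (read_len < nchar(junction) + 10) {
    rlang::abort("read_len must be at least the junction length plus 10")
  }
  fill <- substr(junction, 1, nchar(junction) - nchar(enz$site))
  if (!nzchar(fill)) fill <- ""
  n_clean <- nrow(contacts)
  frac_clean <- 1 - sum(unlist(noise))
  stopifnot(frac_clean > 0)
  n_total <- round(n_clean / frac_clean)
  n_class <- vapply(noise, function(f) round(f * n_total), 0)
  fr <- rmap$fragments
  n_frag_chrom <- table(factor(fr$chrom, levels = rmap$chrom_order))
  internal_ok <- fr$frag > 1 & fr$frag < as.integer(n_frag_chrom[fr$chrom]) &
    (fr$end - fr$start) >= 100
  long_ok <- internal_ok & (fr$end - fr$start) >= 2 * read_len + 20
  with_seed_local(seed, {
    reads1 <- list(); reads2 <- list(); truth <- list()
    emit <- function(id, s1, s2, label, event) {
      k <- length(reads1) + 1
      reads1[[k]] <<- tibble::tibble(id = id, seq = s1,
                                     qual = strrep("I", nchar(s1)))
      reads2[[k]] <<- tibble::tibble(id = id, seq = s2,
                                     qual = strrep("I", nchar(s2)))
      truth[[k]] <<- tibble::tibble(id = id, label = label, event = event)
    }
    junction_pair <- function(endA, endB) {
      lenA <- sample(40:62, 1); lenB <- sample(40:62, 1)
      mol <- ligation_molecule(genome, endA, endB, lenA, lenB, fill)
      read_pair_from_molecule(mol, read_len)
    }
    as_end <- function(row, suffix) {
      list(chrom = row[[paste0("chrom", suffix)]],
           fragStart = row[[paste0("fragStart", suffix)]],
           fragEnd = row[[paste0("fragEnd", suffix)]],
           side = row[[paste0("side", suffix)]])
    }
    # clean supported contacts: two read pairs each
    for (i in seq_len(n_clean)) {
      row <- contacts[i, ]
      for (rep_ in 1:2) {
        rp <- junction_pair(as_end(row, "A"), as_end(row, "B"))
        emit(sprintf("%s:clean:%d:%d", cell_id, i, rep_), rp$seq1, rp$seq2,
             "clean", i)
      }
    }
    genomic_read <- function(chrom, start0) {
      substr(chrom_sequence(genome, chrom), start0 + 1, start0 + read_len)
    }
    pick_frag <- function(ok) {
      w <- which(ok)
      fr[w[sample.int(length(w), 1)], ]
    }
    # internal: both reads inside one fragment, facing inward
    for (i in seq_len(n_class[["internal"]])) {
      f <- pick_frag(long_ok)
      d1 <- sample(0:8, 1); d2 <- sample(0:8, 1)
      s1 <- genomic_read(f$chrom, f$start + d1)
      s2 <- revcomp(genomic_read(f$chrom, f$end - read_len - d2))
      emit(sprintf("%s:internal:%d", cell_id, i), s1, s2, "internal", NA)
    }
    # circular: both reads inside one fragment, facing outward
    for (i in seq_len(n_class[["circular"]])) {
      f <- pick_frag(long_ok)
      d1 <- sample(0:8, 1); d2 <- sample(0:8, 1)
      s1 <- revcomp(genomic_read(f$chrom, f$start + d1))
      s2 <- genomic_read(f$chrom, f$end - read_len - d2)
      emit(sprintf("%s:circular:%d", cell_id, i), s1, s2, "circular", NA)
    }
    # adjacent: reads on neighbouring fragments, facing inward
    for (i in seq_len(n_class[["adjacent"]])) {
      repeat {
        f <- pick_frag(long_ok)
        idx <- which(fr$chrom == f$chrom & fr$frag == f$frag + 1)
        if (length(idx) && long_ok[idx]) break
      }
      g <- fr[idx, ]
      s1 <- genomic_read(f$chrom, f$start + sample(0:8, 1))
      s2 <- revcomp(genomic_read(g$chrom, g$end - read_len - sample(0:8, 1)))
      emit(sprintf("%s:adjacent:%d", cell_id, i), s1, s2, "adjacent", NA)
    }
    used <- new.env(hash = TRUE)
    for (i in seq_len(n_clean)) {
      row <- contacts[i, ]
      assign(paste(row$chromA, row$fragA, row$sideA), TRUE, envir = used)
      assign(paste(row$chromB, row$fragB, row$sideB), TRUE, envir = used)
    }
    fresh_end <- function(chrom_not = NULL, chrom_is = NULL) {
      repeat {
        ok <- internal_ok
        if (!is.null(chrom_not)) ok <- ok & fr$chrom != chrom_not
        if (!is.null(chrom_is)) ok <- ok & fr$chrom == chrom_is
        f <- pick_frag(ok)
        side <- sample(c("L", "R"), 1)
        key <- paste(f$chrom, f$frag, side)
        if (!exists(key, envir = used)) {
          assign(key, TRUE, envir = used)
          return(list(chrom = f$chrom, frag = f$frag,
                      fragStart = f$start, fragEnd = f$end, side = side))
        }
      }
    }
    # random trans ligations: pass every filter, support 2
    for (i in seq_len(n_class[["random_trans"]])) {
      eA <- fresh_end()
      eB <- fresh_end(chrom_not = eA$chrom)
      for (rep_ in 1:2) {
        rp <- junction_pair(eA, eB)
        emit(sprintf("%s:random_trans:%d:%d", cell_id, i, rep_),
             rp$seq1, rp$seq2, "random_trans", NA)
      }
    }
    # promiscuous: one shared end in three distinct contacts
    for (i in seq_len(n_class[["promiscuous"]])) {
      e0 <- fresh_end()
      for (p in 1:3) {
        ep <- fresh_end(chrom_not = e0$chrom)
        for (rep_ in 1:2) {
          rp <- junction_pair(e0, ep)
          emit(sprintf("%s:promiscuous:%d:%d:%d", cell_id, i, p, rep_),
               rp$seq1, rp$seq2, "promiscuous", NA)
        }
      }
    }
    # singleton: accepted geometry, single read pair
    for (i in seq_len(n_class[["singleton"]])) {
      eA <- fresh_end()
      eB <- fresh_end(chrom_not = eA$chrom)
      rp <- junction_pair(eA, eB)
      emit(sprintf("%s:singleton:%d", cell_id, i), rp$seq1, rp$seq2,
           "singleton", NA)
    }
    r1 <- dplyr::bind_rows(reads1)
    r2 <- dplyr::bind_rows(reads2)
    truth <- dplyr::bind_rows(truth)
    # shuffle read order: downstream results must be order-independent
    ord <- sample.int(nrow(r1))
    list(r1 = r1[ord, ], r2 = r2[ord, ], truth = truth[ord, ],
         counts = c(clean = n_clean, n_class))
  })
}

#' Generate a structure-grade synthetic cell
#'
#' Builds a genome, digest, ground-truth conformation and clean
#' proximity contacts, redrawing the conformation (deterministically,
#' from seeds derived from `seed`) until the sampled contacts contain at
#' least `min_trans_frac` trans contacts -- the data condition under
#' which repeat structure models are expected to agree. With a
#' single-chromosome genome the floor is ignored.
#'
#' @param n_chrom,chrom_length Genome shape (default 2 x 10 Mb).
#' @param particle_size Conformation particle size in bp.
#' @param n_contacts Number of clean contacts.
#' @param capture_radius Ligation capture scale in radii.
#' @param min_trans_frac Minimum trans share of the sampled contacts
#'   (default 5%).
#' @param seed Integer seed.
#' @param max_attempts Conformation redraws allowed before giving up
#'   with a warning.
#' @return List: `genome`, `enzyme`, `rmap`, `conformation`, `contacts`,
#'   `contact_ledger`, `attempts`.
#' @export
make_structure_cell <- function(n_chrom = 2, chrom_length = 1e7,
                                particle_size = 1e5, n_contacts = 3000,
                                capture_radius = 1.2, min_trans_frac = 0.05,
                                seed = 1, max_attempts = 20) {
  genome <- make_genome(n_chrom, chrom_length, seed = seed)
  enz <- load_enzyme("MboI")
  rmap <- digest(genome, enz)
  floor_ <- if (n_chrom > 1) min_trans_frac else 0
  for (a in seq_len(max_attempts)) {
    s <- seed + 7919L * (a - 1L)
    conf <- make_conformation(genome, particle_size, seed = s + 1L)
    sim <- simulate_contacts(conf, rmap, n_contacts, capture_radius,
                             seed = s + 2L)
    trans <- mean(sim$contacts$chromA != sim$contacts$chromB)
    if (trans >= floor_) {
      return(list(genome = genome, enzyme = enz, rmap = rmap,
                  conformation = conf, contacts = sim$contacts,
                  contact_ledger = sim$ledger, attempts = a))
    }
  }
  rlang::warn("trans-contact floor not reached; returning last draw")
  list(genome = genome, enzyme = enz, rmap = rmap, conformation = conf,
       contacts = sim$contacts, contact_ledger = sim$ledger,
       attempts = max_attempts)
}

#' Generate a complete toy single-cell fixture
#'
#' One call produces a genome, its digest, a ground-truth conformation,
#' clean proximity contacts, and paired reads with labelled noise, so the
#' whole processing pipeline can be exercised end to end.
#'
#' @param n_chrom,chrom_length Genome shape (default 2 x 10 Mb).
#' @param particle_size Conformation particle size (default 100 kb).
#' @param n_contacts Number of clean contacts.
#' @param noise A [noise_spec()].
#' @param read_len Read length.
#' @param capture_radius Ligation capture scale in radii.
#' @param seed Integer seed (drives genome, conformation, contacts and
#'   reads deterministically).
#' @param cell_id Cell identifier.
#' @return List: `genome`, `enzyme`, `rmap`, `conformation`, `contacts`,
#'   `contact_ledger`, `reads` (`r1`, `r2`, `truth`, `counts`).
#' @export
make_fixture_cell <- function(n_chrom = 2, chrom_length = 1e7,
                              particle_size = 1e5, n_contacts = 600,
                              noise = noise_spec(), read_len = 70,
                              capture_radius = 1.2, seed = 1,
                              cell_id = "cell1") {
  cell <- make_structure_cell(n_chrom, chrom_length, particle_size,
                              n_contacts, capture_radius, seed = seed)
  cell$reads <- simulate_read_pairs(cell$contacts, cell$genome, cell$rmap,
                                    cell$enzyme, read_len, noise,
                                    seed = seed + 3, cell_id = cell_id)
  cell
}
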