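N3D_HEADER <- "#N3D/1 schic3d dialect: per chromosome a 'chrom <name> <particle_size> <n_particles> <n_models>' line, then one line per particle: start_bp followed by n_models x y z triplets"

#' Write a genome structure to an N3D text file
#'
#' @param structure A `genome_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_n3d <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(N3D_HEADER, con)
  m <- length(structure$coords)
  parts <- structure$particles
  for (ch in unique(parts$chrom)) {
    sel <- which(parts$chrom == ch)
    writeLines(paste("chrom", ch,
                     format(structure$particle_size, scientific = FALSE),
                     length(sel), m), con)
    block <- do.call(cbind, lapply(structure$coords, function(co) co[sel, , drop = FALSE]))
    lines <- paste(format(parts$start[sel], scientific = FALSE, trim = TRUE),
                   apply(block, 1, function(r) paste(sprintf("%.6f", r),
                                                     collapse = " ")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a genome structure from an N3D text file
#'
#' @param path N3D file path.
#' @return A `genome_structure` (without annealing metadata).
#' @export
read_n3d <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  i <- 1
  parts <- list(); blocks <- list()
  particle_size <- NA_real_; n_models <- NA_integer_
  while (i <= length(lines)) {
    hd <- strsplit(lines[i], "\\s+")[[1]]
    if (hd[1] != "chrom") rlang::abort(paste0("malformed N3D header line: ", lines[i]))
    ch <- hd[2]; particle_size <- as.numeric(hd[3])
    np <- as.integer(hd[4]); n_models <- as.integer(hd[5])
    body <- lines[(i + 1):(i + np)]
    vals <- do.call(rbind, lapply(strsplit(body, "\\s+"), as.numeric))
    parts[[ch]] <- tibble::tibble(chrom = ch, start = vals[, 1],
                                  end = vals[, 1] + particle_size)
    blocks[[ch]] <- vals[, -1, drop = FALSE]
    i <- i + np + 1
  }
  particles <- dplyr::bind_rows(parts)
  coords <- lapply(seq_len(n_models), function(m) {
    do.call(rbind, lapply(blocks, function(b) {
      b[, (3 * (m - 1) + 1):(3 * m), drop = FALSE]
    }))
  })
  coords <- lapply(coords, function(co) { dimnames(co) <- NULL; co })
  structure(list(particle_size = particle_size, particles = particles,
                 coords = coords,
                 has_restraint = rep(NA, nrow(particles)),
                 energies = NULL, seed = NA_integer_, schedule = NULL),
            class = "genome_structure")
}
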