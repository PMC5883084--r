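#' Define a restriction enzyme
#'
#' An enzyme is described by its recognition site, the cut offset from the
#' start of the site on the top strand, and whether the library protocol
#' end-fills the overhang before ligation (`fill_in`). MboI cuts `^GATC`
#' (offset 0, 4-nt 5' overhang); AluI cuts `AG^CT` (offset 2, blunt).
#' `fill_in = FALSE` describes protocols that omit the biotin end-filling
#' step, in which sticky-end religation regenerates the bare site.
#'
#' @param name Enzyme name.
#' @param site Recognition site (DNA, non-empty).
#' @param cut_offset Cut position in bp from the site start, in
#'   `[0, nchar(site)]`.
#' @param fill_in Logical; whether ligation junctions are end-filled.
#' @return An object of class `enzyme`.
#' @examples
#' enzyme("MboI", "GATC", 0)
#' @export
enzyme <- function(name, site, cut_offset, fill_in = TRUE) {
  site <- toupper(site)
  stopifnot(nzchar(site), cut_offset >= 0, cut_offset <= nchar(site))
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset),
                 fill_in = isTRUE(fill_in)),
            class = "enzyme")
}

#' @export
print.enzyme <- function(x, ...) {
  cut <- paste0(substr(x$site, 0, x$cut_offset), "^",
                substr(x$site, x$cut_offset + 1, nchar(x$site)))
  cat("<enzyme> ", x$name, " (", cut, ", fill_in=", x$fill_in, ")\n", sep = "")
  invisible(x)
}

#' Load a bundled or user-defined enzyme
#'
#' MboI, DpnII (isoschizomers, site GATC) and AluI (AGCT) ship with the
#' package; additional enzymes can be supplied in a tab-separated config
#' with columns `name`, `site`, `cut_offset`, `fill_in`.
#'
#' @param name Enzyme name (case sensitive).
#' @param fill_in Optional override of the configured fill-in flag.
#' @param config Path to an enzyme definition TSV; defaults to the bundled
#'   table.
#' @return An [enzyme()].
#' @export
load_enzyme <- function(name, fill_in = NULL,
                        config = system.file("extdata", "enzymes.tsv",
                                             package = "schic3d")) {
  tab <- utils::read.delim(config, stringsAsFactors = FALSE)
  i <- match(name, tab$name)
  if (is.na(i)) {
    rlang::abort(paste0("enzyme '", name, "' not found in ", config))
  }
  enzyme(tab$name[i], tab$site[i], tab$cut_offset[i],
         if (is.null(fill_in)) tab$fill_in[i] else fill_in)
}

#' Digest a genome in silico
#'
#' Scans each chromosome for every occurrence of the enzyme's recognition
#' site and converts them to cut positions (`site_start + cut_offset`).
#' Palindromic sites need only a top-strand scan; for non-palindromic
#' sites both strands are scanned. Ambiguity bases (N) never match.
#'
#' @param genome A [genome_assembly()] with sequences.
#' @param enz An [enzyme()].
#' @return A `restriction_map`: list with `enzyme`, `cut_sites` (named
#'   list of sorted 0-based cut positions per chromosome) and `fragments`
#'   (tibble `chrom`, `frag`, `start`, `end` with 0-based half-open
#'   intervals tiling each chromosome; `frag` is a 1-based index within
#'   its chromosome).
#' @examples
#' g <- genome_assembly(data.frame(name = "chr1", length = 8),
#'                      c(chr1 = "AAGATCAA"))
#' digest(g, enzyme("MboI", "GATC", 0))$fragments
#' @export
digest <- function(genome, enz) {
  stopifnot(inherits(genome, "genome_assembly"), inherits(enz, "enzyme"))
  if (is.null(genome$sequences)) {
    rlang::abort(paste0("cannot digest: no sequence for chromosome ",
                        genome$chromosomes$name[1]))
  }
  site <- Biostrings::DNAString(enz$site)
  palindromic <- as.character(Biostrings::reverseComplement(site)) == enz$site
  cut_sites <- lapply(genome$chromosomes$name, function(ch) {
    seq <- Biostrings::DNAString(chrom_sequence(genome, ch))
    # fixed = TRUE: N in the subject matches nothing in an ACGT site
    hits <- Biostrings::start(Biostrings::matchPattern(site, seq, fixed = TRUE))
    cuts <- hits - 1L + enz$cut_offset
    if (!palindromic) {
      rc <- Biostrings::reverseComplement(site)
      hits2 <- Biostrings::start(Biostrings::matchPattern(rc, seq, fixed = TRUE))
      cuts2 <- hits2 - 1L + (nchar(enz$site) - enz$cut_offset)
      cuts <- sort(unique(c(cuts, cuts2)))
    }
    len <- chrom_length(genome, ch)
    sort(unique(cuts[cuts > 0 & cuts < len]))
  })
  names(cut_sites) <- genome$chromosomes$name
  fragments <- purrr::map2_dfr(genome$chromosomes$name, cut_sites, function(ch, cuts) {
    len <- chrom_length(genome, ch)
    bounds <- c(0, cuts, len)
    tibble::tibble(chrom = ch, frag = seq_len(length(bounds) - 1L),
                   start = bounds[-length(bounds)], end = bounds[-1])
  })
  structure(list(enzyme = enz, cut_sites = cut_sites, fragments = fragments,
                 chrom_order = genome$chromosomes$name,
                 chrom_lengths = stats::setNames(genome$chromosomes$length,
                                                 genome$chromosomes$name)),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("<restriction_map> ", x$enzyme$name, ": ",
      format(nrow(x$fragments), big.mark = ","), " fragments over ",
      length(x$cut_sites), " chromosome(s)\n", sep = "")
  invisible(x)
}

frag_bounds <- function(rmap, chrom) {
  cuts <- rmap$cut_sites[[chrom]]
  if (is.null(cuts) && !chrom %in% names(rmap$cut_sites)) {
    rlang::abort(paste0("unknown chromosome: ", chrom))
  }
  c(0, cuts, rmap$chrom_lengths[[chrom]])
}

#' Locate the restriction fragment containing a position
#'
#' Binary-search lookup of positions against the fragment tiling of a
#' digested chromosome.
#'
#' @param rmap A `restriction_map` from [digest()].
#' @param chrom Chromosome name (scalar).
#' @param pos Numeric vector of 0-based positions, each in
#'   `[0, chromosome length)`.
#' @return Integer vector of 1-based fragment indices `i` such that
#'   `fragments[i].start <= pos < fragments[i].end`.
#' @export
fragment_of <- function(rmap, chrom, pos) {
  if (!chrom %in% names(rmap$chrom_lengths)) {
    rlang::abort(paste0("unknown chromosome: ", chrom))
  }
  len <- rmap$chrom_lengths[[chrom]]
  if (any(pos < 0 | pos >= len)) {
    rlang::abort(paste0("position out of range for ", chrom,
                        " (length ", len, ")"))
  }
  bounds <- frag_bounds(rmap, chrom)
  findInterval(pos, bounds, rightmost.closed = FALSE, left.open = FALSE)
}

#' Ligation junction sequence for an enzyme
#'
#' The chimeric sequence created where two restriction fragments join.
#' With end-filling (`fill_in = TRUE`) a 5' overhang is duplicated by the
#' fill-in reaction, so MboI (`^GATC`) yields `GATCGATC`; a blunt cutter
#' has nothing to fill and yields the site itself. Without end-filling,
#' sticky-end religation regenerates the single site.
#'
#' @param enz An [enzyme()].
#' @return The junction DNA string.
#' @examples
#' junction_sequence(enzyme("MboI", "GATC", 0))          # "GATCGATC"
#' junction_sequence(enzyme("MboI", "GATC", 0, FALSE))   # "GATC"
#' @export
junction_sequence <- function(enz) {
  n <- nchar(enz$site)
  c_off <- enz$cut_offset
  overhang <- n - 2L * c_off
  if (enz$fill_in && overhang > 0) {
    # left fragment keeps site[1..c] and gains the filled overhang
    # site[(c+1)..(n-c)]; the right fragment starts at site[(c+1)..n]
    paste0(substr(enz$site, 1, n - c_off), substr(enz$site, c_off + 1, n))
  } else {
    enz$site
  }
}
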