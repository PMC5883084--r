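#' Create a genome assembly
#'
#' A genome assembly is the package's container for a set of chromosomes:
#' an ordered table of names and lengths, optionally with the DNA sequence
#' of each chromosome. Sequences are required for in-silico digestion and
#' read mapping; lengths alone suffice for binning and structure
#' calculation. All coordinates in this package are 0-based, half-open;
#' 1-based external formats (NCC) are converted at the I/O boundary.
#'
#' @param chromosomes A data frame with columns `name` and `length` (bp),
#'   in the desired chromosome order.
#' @param sequences Optional named character vector of DNA sequences
#'   (names matching `chromosomes$name`).
#' @return An object of class `genome_assembly`: a list with elements
#'   `chromosomes` (tibble) and `sequences` (named character or `NULL`).
#' @examples
#' genome_assembly(data.frame(name = "chr1", length = 8),
#'                 c(chr1 = "AAGATCAA"))
#' @export
genome_assembly <- function(chromosomes, sequences = NULL) {
  chromosomes <- tibble::as_tibble(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name)) {
    rlang::abort("chromosome names must be unique")
  }
  if (any(chromosomes$length <= 0)) {
    rlang::abort("chromosome lengths must be positive")
  }
  if (!is.null(sequences)) {
    sequences <- unlist(sequences)
    missing <- setdiff(chromosomes$name, names(sequences))
    if (length(missing)) {
      rlang::abort(paste0("no sequence for chromosome(s): ",
                          paste(missing, collapse = ", ")))
    }
    sequences <- sequences[chromosomes$name]
    lens <- nchar(sequences)
    bad <- which(lens != chromosomes$length)
    if (length(bad)) {
      rlang::abort(paste0("sequence length disagrees with declared length for: ",
                          paste(chromosomes$name[bad], collapse = ", ")))
    }
  }
  structure(list(chromosomes = chromosomes, sequences = sequences),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", nrow(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes$length), big.mark = ","), " bp",
      if (is.null(x$sequences)) " (lengths only)" else " (with sequence)",
      "\n", sep = "")
  print(x$chromosomes, n = 10)
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Multi-record, wrapped or unwrapped FASTA is supported (parsed with
#' Biostrings). Record order defines chromosome order.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_assembly()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  seqs <- stats::setNames(as.character(ss), nm)
  genome_assembly(tibble::tibble(name = nm, length = nchar(seqs)), seqs)
}

#' Write a genome assembly to FASTA
#'
#' @param genome A [genome_assembly()] with sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequences)) rlang::abort("genome has no sequences")
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) {
    rlang::abort(paste0("unknown chromosome(s): ",
                        paste(unique(chrom[is.na(i)]), collapse = ", ")))
  }
  genome$chromosomes$length[i]
}

chrom_sequence <- function(genome, chrom) {
  if (is.null(genome$sequences) || is.na(match(chrom, names(genome$sequences)))) {
    rlang::abort(paste0("no sequence available for chromosome ", chrom))
  }
  genome$sequences[[chrom]]
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
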