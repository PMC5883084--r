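#' Read a FASTQ file into a tibble
#'
#' Gzip-transparent (via Biostrings). Read identifiers are truncated at
#' the first whitespace.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble::tibble(id = sub("\\s.*$", "", names(ss)),
                 seq = unname(as.character(ss)),
                 qual = unname(as.character(S4Vectors::mcols(ss)$qualities)))
}

#' Write a tibble of reads to FASTQ
#'
#' @param reads Tibble with columns `id`, `seq` and optionally `qual`
#'   (defaults to maximum quality).
#' @param path Output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Demultiplex paired reads by inline cell barcode
#'
#' Routes each read pair to exactly one cell, by exact match of the first
#' `barcode_length` bases of read 1 against the barcode table, or to an
#' `"unassigned"` bin. The barcode bases are stripped from assigned
#' read-1 sequences and qualities.
#'
#' @param r1,r2 Read tibbles (`id`, `seq`, `qual`), pair-ordered.
#' @param barcodes Data frame with columns `cell_id` and `barcode`
#'   (unique, equal length).
#' @param barcode_length Barcode length; defaults to the barcode width.
#' @return Named list (one element per cell plus `"unassigned"`), each a
#'   list with elements `r1` and `r2`.
#' @export
demultiplex <- function(r1, r2, barcodes, barcode_length = NULL) {
  barcodes <- tibble::as_tibble(barcodes)
  if (anyDuplicated(barcodes$barcode)) rlang::abort("duplicate barcodes")
  bl <- barcode_length %||% nchar(barcodes$barcode[1])
  if (any(nchar(barcodes$barcode) != bl)) {
    rlang::abort("all barcodes must have length barcode_length")
  }
  stopifnot(nrow(r1) == nrow(r2))
  bc <- substr(r1$seq, 1, bl)
  cell <- barcodes$cell_id[match(bc, barcodes$barcode)]
  cell[is.na(cell)] <- "unassigned"
  out <- lapply(c(barcodes$cell_id, "unassigned"), function(cid) {
    sel <- which(cell == cid)
    r1s <- r1[sel, , drop = FALSE]
    if (cid != "unassigned" && nrow(r1s)) {
      r1s$seq <- substr(r1s$seq, bl + 1, nchar(r1s$seq))
      if ("qual" %in% names(r1s)) {
        r1s$qual <- substr(r1s$qual, bl + 1, nchar(r1s$qual))
      }
    }
    list(r1 = r1s, r2 = r2[sel, , drop = FALSE])
  })
  stats::setNames(out, c(barcodes$cell_id, "unassigned"))
}

#' Clip reads at a ligation junction
#'
#' If the junction occurs in a read, the read is truncated to retain the
#' 5' portion up to and including the first half of the junction, which
#' restores the native restriction terminus so the clipped read maps
#' contiguously to the reference. Reads without the junction are
#' unchanged.
#'
#' @param x Character vector of read sequences.
#' @param junction Junction sequence (see [junction_sequence()]).
#' @return Character vector of clipped sequences.
#' @examples
#' clip_at_junction("AAAAGATCGATCCCCC", "GATCGATC")  # "AAAAGATC"
#' @export
clip_at_junction <- function(x, junction) {
  stopifnot(nzchar(junction))
  keep <- nchar(junction) %/% 2
  hit <- regexpr(junction, x, fixed = TRUE)
  clip <- which(hit > 0)
  x[clip] <- substr(x[clip], 1, hit[clip] - 1L + keep)
  x
}

#' Map reads to a genome
#'
#' The built-in mapper declares an end uniquely mapped iff its full
#' (clipped) sequence, or its reverse complement, occurs exactly once in
#' the genome. It seeds candidate loci with a 16-bp prefix dictionary
#' scan and verifies each candidate over the full read, which yields
#' exactly the set of full-length occurrences. The reported position is
#' the 5'-most mapped base (0-based): the leftmost base for `+` strand
#' alignments, the rightmost for `-`.
#'
#' The `"bam"` backend ingests external alignments instead (see
#' [mapped_ends_from_bam()]); an end is then unique iff its best
#' alignment score strictly beats the second best.
#'
#' @param reads Tibble with columns `id`, `seq` (already clipped).
#' @param genome A [genome_assembly()] with sequences.
#' @param backend `"builtin"` or `"bam"`.
#' @param bam BAM path, required for the `"bam"` backend.
#' @return Tibble `id`, `chrom`, `pos`, `strand`, `n_hits`, `status`
#'   (`"unique"`, `"ambiguous"` or `"unmapped"`), `unique`.
#' @export
map_reads <- function(reads, genome, backend = c("builtin", "bam"), bam = NULL) {
  backend <- match.arg(backend)
  if (backend == "bam") {
    if (is.null(bam)) rlang::abort("backend 'bam' requires a bam= path")
    return(mapped_ends_from_bam(bam, reads$id))
  }
  if (is.null(genome$sequences)) rlang::abort("built-in mapper needs genome sequences")
  seed_w <- 16L
  n <- nrow(reads)
  seqs <- toupper(reads$seq)
  lens <- nchar(seqs)
  mappable <- lens >= seed_w & !grepl("[^ACGT]", seqs)
  hit_read <- integer(0); hit_chrom <- character(0)
  hit_pos <- numeric(0); hit_strand <- character(0)
  if (any(mappable)) {
    idx <- which(mappable)
    fwd <- seqs[idx]
    rev <- revcomp(fwd)
    pats <- c(substr(fwd, 1, seed_w), substr(rev, 1, seed_w))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
    full <- c(fwd, rev)
    qlen <- nchar(full)
    for (ch in genome$chromosomes$name) {
      subj_chr <- chrom_sequence(genome, ch)
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj_chr))
      st <- Biostrings::startIndex(m)
      cnt <- S4Vectors::elementNROWS(st)
      pat <- rep.int(seq_along(cnt), cnt)
      st <- unlist(st, use.names = FALSE)
      if (!length(st)) next
      L <- qlen[pat]
      ok <- st + L - 1L <= nchar(subj_chr)
      pat <- pat[ok]; st <- st[ok]; L <- L[ok]
      ver <- substring(subj_chr, st, st + L - 1L) == full[pat]
      pat <- pat[ver]; st <- st[ver]; L <- L[ver]
      if (!length(st)) next
      ori <- ifelse(pat <= length(idx), "+", "-")
      hit_read <- c(hit_read, idx[(pat - 1L) %% length(idx) + 1L])
      hit_chrom <- c(hit_chrom, rep(ch, length(st)))
      hit_pos <- c(hit_pos, ifelse(ori == "+", st - 1L, st - 1L + L - 1L))
      hit_strand <- c(hit_strand, ori)
    }
  }
  n_hits <- tabulate(hit_read, nbins = n)
  status <- ifelse(n_hits == 0L, "unmapped",
                   ifelse(n_hits == 1L, "unique", "ambiguous"))
  chrom <- rep(NA_character_, n); pos <- rep(NA_real_, n)
  strand <- rep(NA_character_, n)
  uni <- n_hits[hit_read] == 1L
  chrom[hit_read[uni]] <- hit_chrom[uni]
  pos[hit_read[uni]] <- hit_pos[uni]
  strand[hit_read[uni]] <- hit_strand[uni]
  tibble::tibble(id = reads$id, chrom = chrom, pos = pos, strand = strand,
                 n_hits = n_hits, status = status, unique = status == "unique")
}

#' Import externally aligned reads from a BAM file
#'
#' Adapter for reads mapped with an external aligner reporting best and
#' second-best alignment scores (AS/XS tags, as bowtie2 does with
#' `-k 2`). An end is unique iff it is mapped and its AS strictly exceeds
#' XS (or XS is absent).
#'
#' @param path BAM file path.
#' @param ids Optional read id vector defining output order.
#' @return Same shape as [map_reads()].
#' @export
mapped_ends_from_bam <- function(path, ids = NULL) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    rlang::abort("the BAM adapter requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "flag", "qwidth"),
    tag = c("AS", "XS"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  mapped <- !bitwAnd(b$flag, 4L)
  as_tag <- b$tag$AS
  xs_tag <- b$tag$XS
  uniq <- mapped & !is.na(as_tag) & (is.na(xs_tag) | as_tag > xs_tag)
  pos0 <- ifelse(b$strand == "-", b$pos - 1L + b$qwidth - 1L, b$pos - 1L)
  out <- tibble::tibble(
    id = b$qname,
    chrom = ifelse(mapped, as.character(b$rname), NA_character_),
    pos = ifelse(mapped, pos0, NA_real_),
    strand = ifelse(mapped, as.character(b$strand), NA_character_),
    n_hits = ifelse(mapped, ifelse(uniq, 1L, 2L), 0L),
    status = ifelse(!mapped, "unmapped", ifelse(uniq, "unique", "ambiguous")),
    unique = mapped & uniq)
  if (!is.null(ids)) out <- out[match(ids, out$id), , drop = FALSE]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
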