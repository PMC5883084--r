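genome_bins <- function(genome, bin_size) {
  ch <- genome$chromosomes
  nbins <- ceiling(ch$length / bin_size)
  tibble::tibble(chrom = ch$name, n_bins = nbins,
                 offset = cumsum(c(0, nbins[-length(nbins)])))
}

#' Bin contacts into a genome-wide contact matrix
#'
#' Each contact increments the symmetric cell pair given by the bins of
#' its two representative positions, on a whole-genome concatenated axis
#' ordered by the genome's chromosome order. The matrix is stored
#' sparsely as its upper triangle, so the upper-triangle total equals the
#' number of input contacts.
#'
#' @param contacts Contacts tibble.
#' @param bin_size Bin size in bp (e.g. `5e6` for a 5 Mb map).
#' @param genome A [genome_assembly()] (lengths suffice).
#' @return A `contact_matrix`: tibble `bin1`, `bin2` (`bin1 <= bin2`,
#'   0-based global bins), `count`; attributes `bin_size`,
#'   `chrom_offsets`, `n_contacts`.
#' @export
bin_contacts <- function(contacts, bin_size, genome) {
  stopifnot(bin_size > 0)
  bins <- genome_bins(genome, bin_size)
  gbin <- function(chrom, pos) {
    i <- match(chrom, bins$chrom)
    if (anyNA(i)) {
      rlang::abort(paste0("contact on unknown chromosome: ",
                          paste(unique(chrom[is.na(i)]), collapse = ", ")))
    }
    bins$offset[i] + pmin(floor(pos / bin_size), bins$n_bins[i] - 1)
  }
  b1 <- gbin(contacts$chromA, contacts$posA)
  b2 <- gbin(contacts$chromB, contacts$posB)
  lo <- pmin(b1, b2); hi <- pmax(b1, b2)
  out <- tibble::tibble(bin1 = lo, bin2 = hi) |>
    dplyr::count(.data$bin1, .data$bin2, name = "count")
  attr(out, "bin_size") <- bin_size
  attr(out, "chrom_offsets") <- bins
  attr(out, "n_contacts") <- nrow(contacts)
  class(out) <- c("contact_matrix", class(out))
  out
}

#' Cis/trans breakdown of a contact set
#'
#' A contact is trans iff its two ends are on different chromosomes; cis
#' contacts are split at 10 kb separation of the representative
#' positions (half-open: separations below 10,000 bp count as short
#' range).
#'
#' @param contacts Contacts tibble.
#' @return One-row tibble `pct_cis_lt10kb`, `pct_cis_ge10kb`,
#'   `pct_trans`, `n_contacts`.
#' @export
cis_trans_breakdown <- function(contacts) {
  n <- nrow(contacts)
  trans <- contacts$chromA != contacts$chromB
  sep <- abs(contacts$posB - contacts$posA)
  pct <- function(x) if (n > 0) 100 * sum(x) / n else 0
  tibble::tibble(pct_cis_lt10kb = pct(!trans & sep < 1e4),
                 pct_cis_ge10kb = pct(!trans & sep >= 1e4),
                 pct_trans = pct(trans),
                 n_contacts = n)
}

#' Pool contact sets from multiple cells
#'
#' Simple concatenation preserving `cell_id`; counts are additive.
#'
#' @param cells List of contacts tibbles.
#' @return A single contacts tibble.
#' @export
pool_cells <- function(cells) {
  dplyr::bind_rows(cells)
}

log_bin_edges <- function(lo, hi, bin_width, bins_per_decade = 8) {
  f <- 10^(1 / bins_per_decade)
  edges <- lo
  while (edges[length(edges)] < hi) {
    e <- edges[length(edges)]
    edges <- c(edges, max(e * f, e + bin_width))
  }
  edges
}

# Number of locus pairs (loci on a bin_width lattice) at separations
# within [lo, hi), summed over chromosomes.
possible_pairs <- function(chrom_lengths, lo, hi, w) {
  total <- 0
  for (L in chrom_lengths) {
    nloci <- floor(L / w)
    a <- max(1, ceiling(lo / w))
    b <- min(nloci - 1, ceiling(hi / w) - 1)
    if (b >= a) {
      ks <- a:b
      total <- total + sum(nloci - ks)
    }
  }
  total
}

#' Contact probability versus sequence separation
#'
#' Cis contacts are binned by genomic separation into log-spaced bins of
#' at least `bin_width` width, starting at `min_sep` (below which
#' fragment-scale effects dominate). Per-bin counts are divided by the
#' number of possible locus pairs at that separation (loci on a
#' `bin_width` lattice, summed over chromosomes) and normalised to unit
#' sum, giving a curve whose log-log slope is comparable to the polymer
#' reference exponents (-1.0 fractal globule, -1.5 equilibrium globule).
#'
#' @param contacts Contacts tibble (at least one cis contact at or above
#'   `min_sep`).
#' @param genome A [genome_assembly()].
#' @param bin_width Minimum bin width in bp (default 100 kb).
#' @param min_sep Smallest separation plotted (default 100 kb).
#' @param bins_per_decade Log-bin density once wider than `bin_width`.
#' @return A `separation_curve`: tibble `bin_lo`, `bin_hi`, `bin_mid`
#'   (geometric midpoint), `n`, `possible`, `probability`; attribute
#'   `n_contacts_used`.
#' @export
contact_probability_curve <- function(contacts, genome, bin_width = 1e5,
                                      min_sep = 1e5, bins_per_decade = 8) {
  cis <- contacts[contacts$chromA == contacts$chromB, , drop = FALSE]
  sep <- abs(cis$posB - cis$posA)
  sep <- sep[sep >= min_sep]
  if (!length(sep)) rlang::abort("no cis contacts at or above min_sep")
  maxsep <- max(genome$chromosomes$length)
  edges <- log_bin_edges(min_sep, maxsep, bin_width, bins_per_decade)
  idx <- findInterval(sep, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  poss <- vapply(seq_len(length(edges) - 1), function(i) {
    possible_pairs(genome$chromosomes$length, edges[i], edges[i + 1], bin_width)
  }, 0)
  prob <- ifelse(poss > 0, counts / poss, 0)
  prob <- prob / sum(prob)
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        bin_mid = sqrt(edges[-length(edges)] * edges[-1]),
                        n = counts, possible = poss, probability = prob)
  attr(out, "n_contacts_used") <- length(sep)
  class(out) <- c("separation_curve", class(out))
  out
}

#' Fit a power-law slope to a separation curve
#'
#' Ordinary least squares of log10(probability) on log10(separation)
#' over the occupied bins within `fit_range`.
#'
#' @param curve A [contact_probability_curve()] result.
#' @param fit_range Length-2 numeric range of separations (bp) to fit;
#'   default the whole curve.
#' @return One-row tibble `slope`, `intercept`, `r_squared`, `n_bins`.
#' @export
fit_powerlaw_slope <- function(curve, fit_range = NULL) {
  d <- curve[curve$n > 0 & curve$probability > 0, , drop = FALSE]
  if (!is.null(fit_range)) {
    d <- d[d$bin_mid >= fit_range[1] & d$bin_mid <= fit_range[2], , drop = FALSE]
  }
  if (nrow(d) < 3) rlang::abort("need at least 3 occupied bins to fit a slope")
  fit <- stats::lm(log10(probability) ~ log10(bin_mid), data = d)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_bins = nrow(d))
}

#' Export a separation curve as TSV
#'
#' Writes `bin_mid_bp` and `probability` for the occupied bins.
#'
#' @param curve A `separation_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_separation_curve <- function(curve, path) {
  d <- curve[curve$n > 0, c("bin_mid", "probability")]
  names(d) <- c("bin_mid_bp", "probability")
  readr::write_tsv(d, path)
  invisible(path)
}
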