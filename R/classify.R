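frag_lookup <- function(rmap, chrom, pos) {
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    out[sel] <- fragment_of(rmap, ch, pos[sel])
  }
  out
}

# Distance from a mapped 5' position to the next cut site in the read's
# 3' direction (the inferred extent of the sequenced molecule on that side).
dist_to_cut_3p <- function(rmap, chrom, pos, strand) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    bounds <- frag_bounds(rmap, ch)
    i <- findInterval(pos[sel], bounds)
    plus <- strand[sel] == "+"
    out[sel] <- ifelse(plus, bounds[i + 1L] - pos[sel], pos[sel] - bounds[i] + 1)
  }
  out
}

#' Pair mapped ends into read-pair records
#'
#' Joins the two mapped ends of each read pair by identifier, requiring a
#' one-to-one pairing.
#'
#' @param m1,m2 Mapped-end tibbles from [map_reads()] for reads 1 and 2.
#' @return Tibble with suffixed end columns (`chrom1`, `pos1`, ...).
#' @export
pair_ends <- function(m1, m2) {
  if (nrow(m1) != nrow(m2) || !all(m1$id == m2$id)) {
    m2 <- m2[match(m1$id, m2$id), , drop = FALSE]
    if (anyNA(m2$id)) rlang::abort("read 1 and read 2 ids do not pair one-to-one")
  }
  names(m1)[-1] <- paste0(names(m1)[-1], "1")
  names(m2)[-1] <- paste0(names(m2)[-1], "2")
  dplyr::bind_cols(m1, m2[-1])
}

#' Classify read pairs into molecular-event categories
#'
#' Applies the filter cascade that separates informative Hi-C ligation
#' products from aberrant molecular events. Categories are assigned by
#' the first matching rule, in order: `unmapped` / `ambiguous` (either
#' end), `internal` (both ends in one primary-enzyme fragment, facing
#' inward; ties and same-strand cases resolve to internal), `circular`
#' (one fragment, facing outward: self-circularised fragment),
#' `adjacent` (neighbouring fragments on one chromosome: re-ligation),
#' `too_small` / `too_large` (inferred molecule size outside
#' `size_range`), else `accepted`.
#'
#' The inferred molecule size is the sum over both ends of the distance
#' from the mapped 5' base to the next cut site in the read's 3'
#' direction, using the secondary-enzyme map when supplied (`rmap2`) and
#' the primary map otherwise.
#'
#' @param pairs Paired ends from [pair_ends()].
#' @param rmap Primary (RE1) [digest()] map.
#' @param size_range Length-2 numeric, accepted molecule size in bp
#'   (inclusive); default `c(50, 5000)`.
#' @param rmap2 Optional secondary (RE2) map for size inference.
#' @return `pairs` with added columns `frag1`, `frag2`, `inferred_size`,
#'   `category`.
#' @export
classify_pairs <- function(pairs, rmap, size_range = c(50, 5000), rmap2 = NULL) {
  stopifnot(size_range[1] < size_range[2])
  n <- nrow(pairs)
  cat_ <- rep(NA_character_, n)
  cat_[pairs$status1 == "ambiguous" | pairs$status2 == "ambiguous"] <- "ambiguous"
  cat_[pairs$status1 == "unmapped" | pairs$status2 == "unmapped"] <- "unmapped"
  ok <- is.na(cat_)
  frag1 <- frag2 <- rep(NA_integer_, n)
  size <- rep(NA_real_, n)
  if (any(ok)) {
    frag1[ok] <- frag_lookup(rmap, pairs$chrom1[ok], pairs$pos1[ok])
    frag2[ok] <- frag_lookup(rmap, pairs$chrom2[ok], pairs$pos2[ok])
    sz_map <- rmap2 %||% rmap
    size[ok] <- dist_to_cut_3p(sz_map, pairs$chrom1[ok], pairs$pos1[ok],
                               pairs$strand1[ok]) +
      dist_to_cut_3p(sz_map, pairs$chrom2[ok], pairs$pos2[ok], pairs$strand2[ok])
    same_frag <- ok & pairs$chrom1 == pairs$chrom2 & frag1 == frag2
    # orient by position: outward means the leftmost end reads leftward
    # and the rightmost reads rightward (self-circularisation geometry)
    swap <- pairs$pos2 < pairs$pos1
    s_lo <- ifelse(swap, pairs$strand2, pairs$strand1)
    s_hi <- ifelse(swap, pairs$strand1, pairs$strand2)
    outward <- s_lo == "-" & s_hi == "+" & pairs$pos1 != pairs$pos2
    cat_[same_frag] <- ifelse(outward[same_frag], "circular", "internal")
    rest <- ok & is.na(cat_)
    adj <- rest & pairs$chrom1 == pairs$chrom2 & abs(frag1 - frag2) == 1L
    cat_[adj] <- "adjacent"
    rest <- ok & is.na(cat_)
    cat_[rest & size < size_range[1]] <- "too_small"
    cat_[rest & size > size_range[2]] <- "too_large"
    cat_[ok & is.na(cat_)] <- "accepted"
  }
  dplyr::mutate(pairs, frag1 = frag1, frag2 = frag2,
                inferred_size = size, category = cat_)
}

chrom_rank <- function(rmap, chrom) {
  match(chrom, rmap$chrom_order)
}

#' Collapse supported ligation events into non-redundant contacts
#'
#' Read pairs are grouped by the unordered pair of restriction-fragment
#' ends they connect, where a fragment end is (chromosome, fragment
#' index, side): side `R` for a `+` strand end (ligated at the fragment's
#' 3' cut) and `L` for a `-` strand end. Ligation events supported by a
#' single read pair are discarded; groups of two or more collapse to one
#' contact with `support` equal to the group size. The representative
#' positions are those of the group's first pair in coordinate order.
#'
#' @param pairs Classified pairs (only `category == "accepted"` rows are
#'   used).
#' @param rmap The primary [digest()] map (for fragment bounds and
#'   chromosome order).
#' @param cell_id Cell identifier stored on each contact.
#' @return A contacts tibble: `chromA`, `fragA`, `sideA`, `fragStartA`,
#'   `fragEndA`, `posA`, `strandA`, the `B` equivalents, `support`,
#'   `cell_id`; rows canonically ordered with end A before end B.
#' @export
dedup_and_support <- function(pairs, rmap, cell_id = "cell") {
  acc <- dplyr::filter(pairs, .data$category == "accepted")
  if (!nrow(acc)) return(empty_contacts(cell_id))
  ends <- function(i) {
    tibble::tibble(chrom = acc[[paste0("chrom", i)]],
                   frag = acc[[paste0("frag", i)]],
                   pos = acc[[paste0("pos", i)]],
                   strand = acc[[paste0("strand", i)]],
                   side = ifelse(acc[[paste0("strand", i)]] == "+", "R", "L"))
  }
  e1 <- ends(1); e2 <- ends(2)
  r1 <- chrom_rank(rmap, e1$chrom); r2 <- chrom_rank(rmap, e2$chrom)
  k1 <- paste(e1$chrom, e1$frag, e1$side)
  k2 <- paste(e2$chrom, e2$frag, e2$side)
  swap <- (r2 < r1) | (r1 == r2 & e2$frag < e1$frag) |
    (r1 == r2 & e1$frag == e2$frag & k2 < k1)
  eA <- e1; eA[swap, ] <- e2[swap, ]
  eB <- e2; eB[swap, ] <- e1[swap, ]
  fr <- rmap$fragments
  fb <- function(e) {
    i <- match(paste(e$chrom, e$frag), paste(fr$chrom, fr$frag))
    list(start = fr$start[i], end = fr$end[i])
  }
  bA <- fb(eA); bB <- fb(eB)
  tab <- tibble::tibble(
    chromA = eA$chrom, fragA = eA$frag, sideA = eA$side,
    fragStartA = bA$start, fragEndA = bA$end, posA = eA$pos, strandA = eA$strand,
    chromB = eB$chrom, fragB = eB$frag, sideB = eB$side,
    fragStartB = bB$start, fragEndB = bB$end, posB = eB$pos, strandB = eB$strand)
  tab |>
    dplyr::mutate(.key = paste(.data$chromA, .data$fragA, .data$sideA, "|",
                               .data$chromB, .data$fragB, .data$sideB)) |>
    dplyr::arrange(.data$posA, .data$posB) |>
    dplyr::group_by(.data$.key) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), dplyr::first),
                     support = dplyr::n(), .groups = "drop") |>
    dplyr::select(-".key") |>
    dplyr::mutate(cell_id = cell_id) |>
    dplyr::arrange(chrom_rank(rmap, .data$chromA), .data$posA,
                   chrom_rank(rmap, .data$chromB), .data$posB)
}

empty_contacts <- function(cell_id = character(0)) {
  tibble::tibble(chromA = character(0), fragA = integer(0), sideA = character(0),
                 fragStartA = numeric(0), fragEndA = numeric(0),
                 posA = numeric(0), strandA = character(0),
                 chromB = character(0), fragB = integer(0), sideB = character(0),
                 fragStartB = numeric(0), fragEndB = numeric(0),
                 posB = numeric(0), strandB = character(0),
                 support = integer(0),
                 cell_id = if (length(cell_id)) character(0) else cell_id)
}

#' Exclude promiscuous contacts
#'
#' A fragment end participating in more distinct contacts than the
#' cell's ploidy allows is evidence of spurious ligation; all contacts
#' involving such an end are excluded (none is treated as more credible
#' than another).
#'
#' @param contacts Contacts tibble from [dedup_and_support()].
#' @param ploidy Maximum number of distinct contacts one fragment end may
#'   legitimately join (1 for a haploid cell).
#' @return List with `contacts` (kept), `removed` and `n_promiscuous`
#'   (the number of removed contacts).
#' @export
remove_promiscuous <- function(contacts, ploidy = 1) {
  stopifnot(ploidy >= 1)
  if (!nrow(contacts)) {
    return(list(contacts = contacts, removed = contacts, n_promiscuous = 0L))
  }
  kA <- paste(contacts$chromA, contacts$fragA, contacts$sideA)
  kB <- paste(contacts$chromB, contacts$fragB, contacts$sideB)
  counts <- table(c(kA, kB))
  bad <- names(counts)[counts > ploidy]
  hit <- kA %in% bad | kB %in% bad
  list(contacts = contacts[!hit, , drop = FALSE],
       removed = contacts[hit, , drop = FALSE],
       n_promiscuous = sum(hit))
}
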