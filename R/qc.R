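PAIR_FATES <- c("unmapped", "ambiguous", "internal", "circular", "adjacent",
                "too_small", "too_large", "accepted")

#' Build a per-cell quality-control report
#'
#' Summarises the fate of every input read pair and the properties of the
#' final contacts, with the quality flags used to judge whether a cell's
#' data can support structure calculation: more than 50% of read pairs
#' uniquely mapped, at least 50% of unique pairs accepted by the filters,
#' and (for structure readiness) more than 60,000 contacts of which more
#' than 5% are trans.
#'
#' Percentage conventions: `pct_unique` is unique-mapped pairs over input
#' pairs; `pct_accepted` and `pct_promiscuous` are relative to the
#' unique-mapped ("filtered unique") pairs; the cis/trans split is over
#' the final kept contacts, with cis contacts divided at 10 kb
#' separation of the representative positions.
#'
#' @param ledger Tibble with one row per input read pair and a `category`
#'   column covering every pair exactly once (as returned by
#'   [classify_pairs()]).
#' @param contacts Final kept contacts tibble.
#' @param n_promiscuous Number of contacts removed as promiscuous.
#' @param cell_id Cell identifier.
#' @return A one-row tibble of class `qc_report`.
#' @export
build_qc_report <- function(ledger, contacts, n_promiscuous = 0,
                            cell_id = "cell") {
  if (!"category" %in% names(ledger)) rlang::abort("ledger needs a 'category' column")
  bad <- !ledger$category %in% PAIR_FATES
  if (any(bad) || anyNA(ledger$category)) {
    rlang::abort("ledger does not partition input pairs into known categories")
  }
  n_input <- nrow(ledger)
  tab <- table(factor(ledger$category, levels = PAIR_FATES))
  if (sum(tab) != n_input) rlang::abort("pair-fate counts do not sum to input pairs")
  n_unique <- n_input - tab[["unmapped"]] - tab[["ambiguous"]]
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  n_contacts <- nrow(contacts)
  trans <- contacts$chromA != contacts$chromB
  sep <- abs(contacts$posB - contacts$posA)
  cis_lt <- !trans & sep < 1e4
  cis_ge <- !trans & sep >= 1e4
  out <- tibble::tibble(
    cell_id = cell_id,
    input_pairs = n_input,
    n_unique = n_unique,
    pct_unique = pct(n_unique, n_input),
    n_accepted = tab[["accepted"]],
    pct_accepted = pct(tab[["accepted"]], n_unique),
    n_promiscuous = n_promiscuous,
    pct_promiscuous = pct(n_promiscuous, n_unique),
    n_internal = tab[["internal"]],
    n_circular = tab[["circular"]],
    n_adjacent = tab[["adjacent"]],
    n_too_small = tab[["too_small"]],
    n_too_large = tab[["too_large"]],
    n_contacts = n_contacts,
    pct_cis_lt10kb = pct(sum(cis_lt), n_contacts),
    pct_cis_ge10kb = pct(sum(cis_ge), n_contacts),
    pct_trans = pct(sum(trans), n_contacts),
    unique_ok = pct(n_unique, n_input) > 50,
    accepted_ok = pct(tab[["accepted"]], n_unique) >= 50,
    structure_ready = n_contacts > 60000 & pct(sum(trans), n_contacts) > 5)
  class(out) <- c("qc_report", class(out))
  out
}

#' Process one cell's paired reads into filtered contacts
#'
#' Runs the full per-cell cascade: ligation-junction clipping, separate
#' mapping of both ends, pairing, fragment allocation and molecular-event
#' classification, support-based deduplication, promiscuity exclusion and
#' QC reporting.
#'
#' @param r1,r2 FASTQ paths or read tibbles (`id`, `seq`, `qual`).
#' @param genome A [genome_assembly()] with sequences.
#' @param re1 Primary restriction [enzyme()].
#' @param re2 Optional secondary enzyme used for molecule-size inference.
#' @param size_range Accepted molecule size range in bp.
#' @param ploidy Cell ploidy for the promiscuity filter.
#' @param cell_id Cell identifier.
#' @param rmap,rmap2 Optional precomputed [digest()] maps (avoids
#'   re-digesting the genome for every cell).
#' @param backend Mapping backend, see [map_reads()].
#' @return List of class `cell_processing`: `contacts`, `ledger`
#'   (classified pairs), `qc`, `n_promiscuous`, `n_singleton_discarded`,
#'   `rmap`.
#' @export
process_cell <- function(r1, r2, genome, re1, re2 = NULL,
                         size_range = c(50, 5000), ploidy = 1,
                         cell_id = "cell", rmap = NULL, rmap2 = NULL,
                         backend = "builtin") {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  rmap <- rmap %||% digest(genome, re1)
  if (!is.null(re2) && is.null(rmap2)) rmap2 <- digest(genome, re2)
  junction <- junction_sequence(re1)
  r1$seq <- clip_at_junction(r1$seq, junction)
  r2$seq <- clip_at_junction(r2$seq, junction)
  m1 <- map_reads(r1, genome, backend = backend)
  m2 <- map_reads(r2, genome, backend = backend)
  pairs <- classify_pairs(pair_ends(m1, m2), rmap, size_range, rmap2)
  contacts_all <- dedup_and_support(pairs, rmap, cell_id)
  n_acc_pairs <- sum(pairs$category == "accepted")
  n_singleton <- n_acc_pairs - sum(contacts_all$support)
  prom <- remove_promiscuous(contacts_all, ploidy)
  qc <- build_qc_report(pairs, prom$contacts, prom$n_promiscuous, cell_id)
  structure(list(contacts = prom$contacts, ledger = pairs, qc = qc,
                 n_promiscuous = prom$n_promiscuous,
                 removed_promiscuous = prom$removed,
                 n_singleton_discarded = n_singleton,
                 rmap = rmap),
            class = "cell_processing")
}

#' @export
print.cell_processing <- function(x, ...) {
  cat("<cell_processing> ", x$qc$cell_id, ": ",
      x$qc$input_pairs, " read pairs -> ", x$qc$n_contacts, " contacts (",
      sprintf("%.1f%% unique, %.1f%% accepted, %.1f%% trans",
              x$qc$pct_unique, x$qc$pct_accepted, x$qc$pct_trans), ")\n",
      sep = "")
  invisible(x)
}
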