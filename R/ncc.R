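NCC_HEADER <- paste("#NCC/1 schic3d dialect: chromA fragStartA fragEndA posA strandA",
                    "chromB fragStartB fragEndB posB strandB support cell_id",
                    "(coordinates 1-based inclusive)")

#' Write contacts to an NCC text file
#'
#' The NCC dialect is whitespace-separated, one contact per line:
#' `chromA fragStartA fragEndA posA strandA chromB fragStartB fragEndB
#' posB strandB support cell_id`. Coordinates are written 1-based
#' inclusive; the dialect and version are recorded in a leading `#`
#' comment line. Internally the package is 0-based half-open, so the
#' conversion happens here.
#'
#' @param contacts Contacts tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ncc <- function(contacts, path) {
  df <- data.frame(
    chromA = contacts$chromA,
    fragStartA = format(contacts$fragStartA + 1, scientific = FALSE, trim = TRUE),
    fragEndA = format(contacts$fragEndA, scientific = FALSE, trim = TRUE),
    posA = format(contacts$posA + 1, scientific = FALSE, trim = TRUE),
    strandA = contacts$strandA,
    chromB = contacts$chromB,
    fragStartB = format(contacts$fragStartB + 1, scientific = FALSE, trim = TRUE),
    fragEndB = format(contacts$fragEndB, scientific = FALSE, trim = TRUE),
    posB = format(contacts$posB + 1, scientific = FALSE, trim = TRUE),
    strandB = contacts$strandB,
    support = contacts$support,
    cell_id = contacts$cell_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(NCC_HEADER, con)
  utils::write.table(df, con, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read contacts from an NCC text file
#'
#' Inverse of [write_ncc()]; coordinates are converted back to the
#' package's 0-based half-open convention. Fragment indices and sides are
#' reconstructed where possible (side from strand; index left `NA`
#' unless a restriction map is supplied).
#'
#' @param path NCC file path.
#' @param rmap Optional [digest()] map used to recover fragment indices.
#' @return Contacts tibble.
#' @export
read_ncc <- function(path, rmap = NULL) {
  cols <- c("chromA", "fragStartA", "fragEndA", "posA", "strandA",
            "chromB", "fragStartB", "fragEndB", "posB", "strandB",
            "support", "cell_id")
  df <- utils::read.table(path, comment.char = "#", col.names = cols,
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric", "character",
                                         "character", "numeric", "numeric",
                                         "numeric", "character",
                                         "integer", "character"))
  out <- tibble::tibble(
    chromA = df$chromA,
    fragA = NA_integer_,
    sideA = ifelse(df$strandA == "+", "R", "L"),
    fragStartA = df$fragStartA - 1, fragEndA = df$fragEndA,
    posA = df$posA - 1, strandA = df$strandA,
    chromB = df$chromB,
    fragB = NA_integer_,
    sideB = ifelse(df$strandB == "+", "R", "L"),
    fragStartB = df$fragStartB - 1, fragEndB = df$fragEndB,
    posB = df$posB - 1, strandB = df$strandB,
    support = df$support, cell_id = df$cell_id)
  if (!is.null(rmap)) {
    out$fragA <- frag_lookup(rmap, out$chromA, out$posA)
    out$fragB <- frag_lookup(rmap, out$chromB, out$posB)
  }
  out
}
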