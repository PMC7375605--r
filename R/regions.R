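# Antibody variable-region framework/CDR boundaries.
#
# The region map comes from a single-record FASTA whose sequence is the
# IMGT-gapped UCA V(D)J and whose header lists the 1-based inclusive
# nucleotide END position of each region, in canonical order, separated by
# spaces — exactly what IMGT/V-QUEST reports for a germline sequence.

REGION_NAMES6 <- c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3")
REGION_NAMES7 <- c(REGION_NAMES6, "FW4")

#' Parse a region FASTA
#'
#' @param path Single-record FASTA; header is a name followed by 6 or 7
#'   whitespace-separated integers (region end positions for FW1, CDR1, FW2,
#'   CDR2, FW3, CDR3 and optionally FW4, in alignment coordinates).
#' @return A `region_map` list with elements `name`, `boundaries` (data
#'   frame: `region`, `start`, `end`) and `uca_gapped` (the gapped UCA
#'   sequence).
#' @export
parse_region_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L)
    fatal("region FASTA must contain exactly one record, found %d", length(set))
  header <- names(set)[[1L]]
  seqs <- toupper(as.character(set[[1L]]))
  tok <- strsplit(trimws(header), "\\s+")[[1L]]
  if (length(tok) < 2L)
    fatal("region FASTA header '%s' carries no region end positions", header)
  ends <- suppressWarnings(as.integer(tok[-1L]))
  if (anyNA(ends))
    fatal("region FASTA header '%s': non-integer region end position", header)
  region_map(ends, uca_gapped = seqs, name = tok[[1L]])
}

#' Build a region map from end positions
#'
#' @param ends Integer vector of 6 or 7 strictly increasing 1-based inclusive
#'   nucleotide end positions.
#' @param uca_gapped The gapped UCA sequence the positions refer to.
#' @param name Display name for the UCA record.
#' @return A `region_map`.
#' @export
region_map <- function(ends, uca_gapped, name = "UCA") {
  if (!(length(ends) %in% c(6L, 7L)))
    fatal("expected 6 or 7 region end positions, got %d", length(ends))
  if (any(diff(ends) <= 0L) || ends[[1L]] < 1L)
    fatal("region end positions must be strictly increasing and positive: %s",
          paste(ends, collapse = ", "))
  if (ends[[length(ends)]] > nchar(uca_gapped))
    fatal("last region end position (%d) exceeds the sequence length (%d)",
          ends[[length(ends)]], nchar(uca_gapped))
  regions <- if (length(ends) == 6L) REGION_NAMES6 else REGION_NAMES7
  boundaries <- data.frame(region = regions,
                           start = c(1L, head_int(ends) + 1L),
                           end = as.integer(ends),
                           stringsAsFactors = FALSE)
  structure(list(name = name, boundaries = boundaries, uca_gapped = uca_gapped),
            class = "region_map")
}

#' @noRd
head_int <- function(x) x[-length(x)]

#' Region of an alignment position
#'
#' @param nt_position 1-based nucleotide position(s) in alignment
#'   coordinates.
#' @param map A `region_map`.
#' @return The name of the first region whose (inclusive) end is at or past
#'   the position, or `"UNASSIGNED"` beyond the last boundary.
#' @export
region_of_position <- function(nt_position, map) {
  n_max <- nchar(map$uca_gapped)
  if (any(nt_position < 1L | nt_position > n_max))
    fatal("position out of range 1..%d", n_max)
  vapply(nt_position, function(p) {
    hit <- which(map$boundaries$end >= p)
    if (length(hit) == 0L) "UNASSIGNED" else map$boundaries$region[[hit[[1L]]]]
  }, character(1))
}
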