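# Per-edge mutation annotation: nucleotide substitutions, codon context,
# replacement/silent classification, region assignment, position labels.

#' Classify a codon change as replacement or silent
#'
#' @param from_codon,to_codon Three-base strings over A/C/G/T.
#' @return `"S"` when the standard-genetic-code translations are equal,
#'   `"R"` otherwise (changes to or from a stop codon count as replacement).
#' @export
classify_rs <- function(from_codon, to_codon) {
  from_codon <- toupper(from_codon); to_codon <- toupper(to_codon)
  ok <- function(x) nchar(x) == 3L && grepl("^[ACGT]{3}$", x)
  if (!ok(from_codon) || !ok(to_codon))
    fatal("classify_rs expects 3-base A/C/G/T codons, got '%s' and '%s'",
          from_codon, to_codon)
  if (unname(Biostrings::GENETIC_CODE[from_codon]) ==
      unname(Biostrings::GENETIC_CODE[to_codon])) "S" else "R"
}

#' Label an amino-acid position
#'
#' By default the label is the absolute (1-based) codon index. When a
#' numbering map is supplied — for example a Kabat mapping with insertion
#' codes such as `"52a"` — the mapped label is used; indices absent from the
#' map fall back to the absolute index with a warning.
#'
#' @param codon_index 1-based codon index (scalar or vector).
#' @param numbering_map Optional named character vector mapping absolute
#'   indices (as names) to display labels.
#' @return Character label(s).
#' @export
aa_position_label <- function(codon_index, numbering_map = NULL) {
  abs_lab <- as.character(codon_index)
  if (is.null(numbering_map)) return(abs_lab)
  out <- unname(numbering_map[abs_lab])
  miss <- is.na(out)
  if (any(miss)) {
    warning(sprintf("no numbering-map entry for position(s) %s; using absolute index",
                    paste(unique(abs_lab[miss]), collapse = ", ")), call. = FALSE)
    out[miss] <- abs_lab[miss]
  }
  out
}

#' Read a numbering map TSV
#'
#' @param path Two-column tab-separated file (absolute codon index, display
#'   label), with or without a header row.
#' @return Named character vector usable as `numbering_map`.
#' @export
read_numbering_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          header = FALSE, quote = "", comment.char = "#")
  if (ncol(df) < 2L) fatal("numbering map must have two tab-separated columns")
  if (!grepl("^[0-9]+$", df[1L, 1L])) df <- df[-1L, , drop = FALSE]
  stats::setNames(df[[2L]], df[[1L]])
}

#' Diff two aligned sequences on one tree edge
#'
#' Compares equal-length aligned parent and child sequences and returns one
#' mutation event per position where both hold a concrete base (A/C/G/T) and
#' the bases differ. Positions where either side holds a gap or `N` are not
#' substitution events; they are tallied in `untallied`. Codons are read
#' in-frame on each gap-stripped sequence starting at alignment position 1;
#' the reported codon index is the parent's. Events whose codon context is
#' not a clean A/C/G/T triplet on both sides cannot be classified and are
#' counted in `untranslatable` instead of the event list.
#'
#' @param parent_seq,child_seq Aligned nucleotide strings of equal length.
#' @param map Optional `region_map`; adds a region to every event.
#' @param numbering_map Optional numbering map (see [aa_position_label()]).
#' @return An `edge_annotation` list: `nt_count`, `aa_count` (number of
#'   codons whose translation changed), `r_count`, `s_count`, `events`
#'   (data frame with columns `nt_position`, `from_nt`, `to_nt`,
#'   `codon_index`, `from_codon`, `to_codon`, `from_aa`, `to_aa`,
#'   `rs_class`, `region`, `aa_label`), `region_tally` (data frame
#'   `region`, `R`, `S`), `untallied`, `untranslatable`.
#' @export
diff_edge <- function(parent_seq, child_seq, map = NULL, numbering_map = NULL) {
  if (nchar(parent_seq) != nchar(child_seq))
    fatal("diff_edge: sequence lengths differ (%d vs %d)",
          nchar(parent_seq), nchar(child_seq))
  p <- seq_chars(toupper(parent_seq))
  c_ <- seq_chars(toupper(child_seq))
  gap <- function(x) x %in% GAP_CHARS
  conc <- function(x) x %in% CONCRETE_BASES

  differing <- which(p != c_ & !(gap(p) & gap(c_)))
  eventable <- differing[conc(p[differing]) & conc(c_[differing])]
  untallied <- length(differing) - length(eventable)

  # gap-stripped coordinate of each alignment position, per sequence
  p_idx <- cumsum(!gap(p))
  c_idx <- cumsum(!gap(c_))
  p_strip <- p[!gap(p)]
  c_strip <- c_[!gap(c_)]
  codon_at <- function(strip, ci) {
    if (3L * ci > length(strip)) return("")
    paste(strip[(3L * ci - 2L):(3L * ci)], collapse = "")
  }

  rows <- lapply(eventable, function(pos) {
    ci_p <- as.integer(ceiling(p_idx[pos] / 3))
    ci_c <- as.integer(ceiling(c_idx[pos] / 3))
    from_codon <- codon_at(p_strip, ci_p)
    to_codon <- codon_at(c_strip, ci_c)
    if (!grepl("^[ACGT]{3}$", from_codon) || !grepl("^[ACGT]{3}$", to_codon))
      return(NULL)  # untranslatable codon context
    list(nt_position = pos, from_nt = p[pos], to_nt = c_[pos],
         codon_index = ci_p, from_codon = from_codon, to_codon = to_codon,
         from_aa = aa_of_codon(from_codon), to_aa = aa_of_codon(to_codon),
         rs_class = classify_rs(from_codon, to_codon))
  })
  untranslatable <- sum(vapply(rows, is.null, logical(1)))
  rows <- Filter(Negate(is.null), rows)

  events <- if (length(rows) == 0L) {
    data.frame(nt_position = integer(0), from_nt = character(0),
               to_nt = character(0), codon_index = integer(0),
               from_codon = character(0), to_codon = character(0),
               from_aa = character(0), to_aa = character(0),
               rs_class = character(0), region = character(0),
               aa_label = character(0), stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    df$region <- if (is.null(map)) NA_character_
                 else region_of_position(df$nt_position, map)
    df$aa_label <- aa_position_label(df$codon_index, numbering_map)
    df
  }

  r_count <- sum(events$rs_class == "R")
  s_count <- sum(events$rs_class == "S")
  # one amino-acid mutation per codon whose translation changed (two
  # substitutions hitting the same codon count once)
  aa_count <- length(unique(events$codon_index[events$rs_class == "R"]))

  tally_regions <- if (is.null(map)) unique(events$region[!is.na(events$region)])
                   else c(map$boundaries$region,
                          if (any(events$region == "UNASSIGNED")) "UNASSIGNED")
  region_tally <- data.frame(
    region = tally_regions,
    R = vapply(tally_regions, function(rg)
      sum(events$rs_class == "R" & events$region == rg, na.rm = TRUE), integer(1)),
    S = vapply(tally_regions, function(rg)
      sum(events$rs_class == "S" & events$region == rg, na.rm = TRUE), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(nt_count = nrow(events), aa_count = aa_count,
                 r_count = r_count, s_count = s_count,
                 events = events, region_tally = region_tally,
                 untallied = untallied, untranslatable = untranslatable),
            class = "edge_annotation")
}

#' Annotate every edge of a lineage tree
#'
#' Runs [diff_edge()] on each parent-to-child pair and stores the result on
#' the tree, keyed by child node id.
#'
#' @param tree A processed `lineage_tree`.
#' @param map Optional `region_map`; defaults to the tree's own.
#' @param numbering_map Optional numbering map.
#' @return The tree with `annotations[[child_id]]` set for every edge.
#' @export
annotate_tree <- function(tree, map = tree$region_map, numbering_map = NULL) {
  tree$region_map <- map
  tree$annotations <- list()
  for (k in seq_len(nrow(tree$edges))) {
    pid <- tree$edges$parent[[k]]
    cid <- tree$edges$child[[k]]
    tree$annotations[[cid]] <- diff_edge(tree$nodes[[pid]]$sequence,
                                         tree$nodes[[cid]]$sequence,
                                         map, numbering_map)
  }
  tree
}
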