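# Tabular and FASTA exports of an annotated lineage tree.

#' Export the tree alignment as TSV with a region ruler
#'
#' Writes one row per node (UCA first, then pre-order), preceded by a ruler
#' row that maps every column to its FW/CDR region. In nucleotide mode there
#' is one column per alignment position; in protein mode one column per
#' codon of the gap-stripped in-frame translation, with the ruler placed by
#' the alignment position of each codon's first UCA base. A trailing partial
#' codon translates to `X` with a warning.
#'
#' @param tree An annotated `lineage_tree`.
#' @param path Output file path.
#' @param mode `"nucleotide"` or `"protein"`.
#' @param map Optional `region_map`; defaults to the tree's own. Without a
#'   map the ruler row is filled with `UNASSIGNED`.
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(tree, path, mode = c("nucleotide", "protein"),
                                map = tree$region_map) {
  mode <- match.arg(mode)
  ord <- preorder_ids(tree)
  ruler_for <- function(positions) {
    if (is.null(map)) rep("UNASSIGNED", length(positions))
    else region_of_position(positions, map)
  }

  if (mode == "nucleotide") {
    n_col <- tree$alignment_length
    ruler <- ruler_for(seq_len(n_col))
    row_of <- function(n) seq_chars(n$sequence)
  } else {
    ref <- tree$nodes[[root_id(tree)]]$sequence
    ref_ch <- seq_chars(ref)
    nongap <- which(!(ref_ch %in% GAP_CHARS))
    n_codon <- ceiling(length(nongap) / 3)
    if (length(nongap) %% 3L != 0L)
      warning("gap-stripped alignment length is not a multiple of 3; trailing partial codon translated as X",
              call. = FALSE)
    first_base_pos <- nongap[3L * seq_len(n_codon) - 2L]
    ruler <- ruler_for(first_base_pos)
    n_col <- n_codon
    row_of <- function(n) {
      aa <- translate_inframe(strip_gaps(n$sequence))
      length(aa) <- n_col                    # pad short translations
      aa[is.na(aa)] <- "X"
      aa
    }
  }

  lines <- character(0)
  header <- c("label", "members", if (n_col > 0L) paste0("p", seq_len(n_col)))
  lines <- c(lines, paste(header, collapse = "\t"))
  lines <- c(lines, paste(c("REGION", "", ruler), collapse = "\t"))
  for (id in ord) {
    n <- tree$nodes[[id]]
    lines <- c(lines, paste(c(n$label, paste(n$members, collapse = ","),
                              row_of(n)), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the FASTA input for selection-pressure analysis
#'
#' Emits the grouped FASTA layout consumed by the BASELINe web service: the
#' germline (UCA) record first, its header marked with the germline prefix,
#' followed by one record per *observed* member label — clusters of
#' identical sequences are expanded so every sequenced antibody appears.
#' All records are IMGT-gapped and of equal length. Requires the region
#' FASTA (gapped UCA) to have been provided.
#'
#' @param tree A processed `lineage_tree` with a `region_map`.
#' @param path Output file path.
#' @param germline_prefix Header prefix marking the germline record
#'   (BASELINe's grouped-FASTA convention; the default `">>"` against `">"`
#'   for clone members).
#' @return `path`, invisibly.
#' @export
write_baseline_fasta <- function(tree, path, germline_prefix = ">>") {
  if (is.null(tree$region_map))
    fatal(paste("selection-analysis FASTA requires the optional region FASTA",
                "(IMGT-gapped UCA V(D)J sequence) to have been provided"))
  root <- tree$nodes[[root_id(tree)]]
  lines <- c(paste0(germline_prefix, tree$region_map$name),
             root$sequence)
  for (id in preorder_ids(tree)) {
    n <- tree$nodes[[id]]
    if (nchar(n$sequence) != tree$alignment_length)
      fatal("node '%s' sequence length differs from the alignment length", n$label)
    obs <- which(n$member_kinds == "OBSERVED")
    for (k in obs)
      lines <- c(lines, paste0(">", n$members[[k]]), n$sequence)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load a selection-analysis (BASELINe) results file
#'
#' Reads the tab-separated summary downloaded from the BASELINe service:
#' one row per region class (CDR, FW) with the selection-strength estimate.
#' Columns are matched case-insensitively; a `region` column and a `sigma`
#' column are required, confidence-interval and p-value columns are kept
#' when present, and any extra columns are ignored.
#'
#' @param path Path to the results file.
#' @return A data frame with columns `region`, `sigma` and, when present,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
load_baseline_output <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", check.names = FALSE, quote = ""),
    error = function(e) fatal("cannot read selection results '%s': %s",
                              path, conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) == 0L)
    fatal("selection results file '%s' is empty", path)
  low <- tolower(names(df))
  pick <- function(cands) {
    hit <- which(low %in% cands)
    if (length(hit) == 0L) NA_integer_ else hit[[1L]]
  }
  i_region <- pick(c("region", "regions"))
  i_sigma <- pick(c("sigma", "selection_strength", "baseline_sigma"))
  if (is.na(i_region) || is.na(i_sigma))
    fatal("unrecognized selection results layout; header found: %s",
          paste(names(df), collapse = ", "))
  out <- data.frame(region = as.character(df[[i_region]]),
                    sigma = as.numeric(df[[i_sigma]]),
                    stringsAsFactors = FALSE)
  extras <- list(ci_lower = c("ci_lower", "cilower", "ci.low"),
                 ci_upper = c("ci_upper", "ciupper", "ci.high"),
                 p_value = c("p_value", "p", "pvalue"))
  for (nm in names(extras)) {
    i <- pick(extras[[nm]])
    if (!is.na(i)) out[[nm]] <- as.numeric(df[[i]])
  }
  out
}

#' Attach a selection summary to a tree
#'
#' @param tree A `lineage_tree`.
#' @param summary Data frame from [load_baseline_output()].
#' @return The tree with the summary stored in its provenance (it is then
#'   carried through XML and JSON exports).
#' @export
attach_baseline_summary <- function(tree, summary) {
  tree$provenance$baseline <- summary
  tree
}

#' Dump the annotated tree as JSON
#'
#' A machine-readable dump of nodes, edges and per-edge annotations for
#' downstream viewers.
#'
#' @param tree A `lineage_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_json <- function(tree, path) {
  ord <- preorder_ids(tree)
  obj <- list(
    alignment_length = tree$alignment_length,
    provenance = tree$provenance,
    region_map = if (is.null(tree$region_map)) NULL else
      list(name = tree$region_map$name,
           boundaries = tree$region_map$boundaries,
           uca_gapped = tree$region_map$uca_gapped),
    nodes = lapply(tree$nodes[ord], function(n)
      list(id = n$node_id, label = n$label, kind = n$kind,
           sequence = n$sequence, members = as.list(n$members),
           member_kinds = as.list(n$member_kinds),
           ec50 = if (is.na(n$ec50)) NULL else n$ec50,
           comment = if (is.na(n$comment)) NULL else n$comment)),
    edges = lapply(seq_len(nrow(tree$edges)), function(k) {
      cid <- tree$edges$child[[k]]
      ann <- tree$annotations[[cid]]
      c(list(parent = tree$edges$parent[[k]], child = cid),
        if (!is.null(ann))
          list(annotation = list(nt_count = ann$nt_count,
                                 aa_count = ann$aa_count,
                                 r_count = ann$r_count, s_count = ann$s_count,
                                 untallied = ann$untallied,
                                 untranslatable = ann$untranslatable,
                                 events = ann$events,
                                 region_tally = ann$region_tally)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Apply user annotations (EC50, comments) from a TSV file
#'
#' @param tree A `lineage_tree`.
#' @param path Tab-separated file with columns `label`, `ec50`, `comment`
#'   (header row required); labels may name any node or member label.
#' @return The tree with EC50/comment fields set on the matching nodes.
#' @export
apply_node_annotations <- function(tree, path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "")
  if (!("label" %in% names(df)))
    fatal("annotation file must have a 'label' column; header found: %s",
          paste(names(df), collapse = ", "))
  for (k in seq_len(nrow(df))) {
    lab <- df$label[[k]]
    hit <- NULL
    for (id in names(tree$nodes))
      if (lab %in% tree$nodes[[id]]$members) { hit <- id; break }
    if (is.null(hit)) {
      warning(sprintf("annotation label '%s' matches no node; skipped", lab),
              call. = FALSE)
      next
    }
    if ("ec50" %in% names(df) && nzchar(df$ec50[[k]]))
      tree$nodes[[hit]]$ec50 <- df$ec50[[k]]
    if ("comment" %in% names(df) && nzchar(df$comment[[k]]))
      tree$nodes[[hit]]$comment <- df$comment[[k]]
  }
  tree
}
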