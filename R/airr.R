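# Immcantation-side input: AIRR rearrangement TSV, IgPhyML clone/tree table,
# and the ancestral-sequence FASTA written by IgPhyML's ancestral state
# reconstruction (--asr).

#' Parse an AIRR rearrangement TSV
#'
#' Reads a tab-separated AIRR rearrangement file and keeps the columns the
#' lineage assembly needs. `germline_alignment_d_mask` is accepted as an
#' alias for `germline_alignment`. Rows with an empty required field are
#' skipped with a message.
#'
#' @param path Path to the AIRR TSV file.
#' @return A data frame with character columns `sequence_id`, `clone_id`,
#'   `sequence_alignment`, `germline_alignment` (plus `v_call`/`j_call` when
#'   present), one row per retained rearrangement record.
#' @export
parse_airr <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  germ_col <- intersect(c("germline_alignment", "germline_alignment_d_mask"),
                        names(df))
  required <- c("sequence_id", "clone_id", "sequence_alignment")
  missing <- setdiff(required, names(df))
  if (length(germ_col) == 0L) missing <- c(missing, "germline_alignment")
  if (length(missing) > 0L)
    fatal("AIRR file is missing required column(s) %s; header found: %s",
          paste(missing, collapse = ", "), paste(names(df), collapse = ", "))
  germ_col <- germ_col[[1L]]

  out <- data.frame(sequence_id = df$sequence_id,
                    clone_id = df$clone_id,
                    sequence_alignment = toupper(df$sequence_alignment),
                    germline_alignment = toupper(df[[germ_col]]),
                    stringsAsFactors = FALSE)
  for (opt in c("v_call", "j_call"))
    if (opt %in% names(df)) out[[opt]] <- df[[opt]]

  ok <- !is.na(out$sequence_id) & nzchar(out$sequence_id) &
    !is.na(out$clone_id) & nzchar(out$clone_id) &
    nzchar(out$sequence_alignment) & nzchar(out$germline_alignment)
  if (any(!ok))
    message(sprintf("parse_airr: skipped %d row(s) with empty required fields",
                    sum(!ok)))
  if (all(!ok) && nrow(out) == 0L)
    message("parse_airr: no data rows found")
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse an IgPhyML clone/tree table
#'
#' Reads the IgPhyML tab file mapping clone ids to newick trees. Column
#' names default to the upper-case `CLONE` / `TREE` pair and are matched
#' case-insensitively; both can be overridden.
#'
#' @param path Path to the IgPhyML tab-separated file.
#' @param clone_col,tree_col Column names holding the clone id and the
#'   newick string.
#' @return A named character vector: clone id -> newick string.
#' @export
parse_igphyml_tab <- function(path, clone_col = "CLONE", tree_col = "TREE") {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "")
  find_col <- function(want) {
    hit <- which(tolower(names(df)) == tolower(want))
    if (length(hit) == 0L)
      fatal("IgPhyML tab file is missing column '%s'; header found: %s",
            want, paste(names(df), collapse = ", "))
    hit[[1L]]
  }
  clones <- df[[find_col(clone_col)]]
  trees <- df[[find_col(tree_col)]]
  if (anyDuplicated(clones))
    fatal("IgPhyML tab file: duplicate clone id(s) %s",
          paste(unique(clones[duplicated(clones)]), collapse = ", "))
  for (k in seq_along(trees)) {
    nw <- trimws(trees[[k]])
    n_open <- lengths(regmatches(nw, gregexpr("(", nw, fixed = TRUE)))
    n_close <- lengths(regmatches(nw, gregexpr(")", nw, fixed = TRUE)))
    if (n_open != n_close || !endsWith(nw, ";"))
      fatal("malformed newick for clone '%s' (unbalanced parentheses or missing ';')",
            clones[[k]])
    trees[[k]] <- nw
  }
  stats::setNames(trees, clones)
}

#' List clones present in both AIRR and IgPhyML inputs
#'
#' @param records AIRR records from [parse_airr()].
#' @param igphyml_trees Named newick vector from [parse_igphyml_tab()].
#' @return A data frame with columns `clone_id` and `n_sequences`, sorted by
#'   descending sequence count then clone id. Empty (with a warning) when the
#'   clone sets are disjoint.
#' @export
list_clones <- function(records, igphyml_trees) {
  common <- intersect(unique(records$clone_id), names(igphyml_trees))
  if (length(common) == 0L) {
    warning("no clone id occurs in both the AIRR file and the IgPhyML tab file",
            call. = FALSE)
    return(data.frame(clone_id = character(0), n_sequences = integer(0)))
  }
  counts <- vapply(common, function(cl) sum(records$clone_id == cl), integer(1))
  ord <- order(-counts, common)
  data.frame(clone_id = common[ord], n_sequences = unname(counts[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read an ancestral-sequence FASTA
#'
#' @param path FASTA file of reconstructed sequences; record ids are taken as
#'   the first whitespace-delimited header token.
#' @return Named character vector of upper-case sequences.
#' @export
read_asr_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Assemble the lineage tree of one clone
#'
#' Combines the newick topology, the observed sequences from the AIRR
#' records and the reconstructed internal sequences into a rooted
#' `lineage_tree`. The germline leaf (identified by `germline_pattern`,
#' default: a label containing "GERM", case-insensitive) becomes the UCA
#' root; the tree is re-oriented away from it and any unlabeled internal
#' node left with a single child by that re-rooting is spliced out. Because
#' IgPhyML's reconstruction already resolves ambiguous states,
#' [resolve_ambiguities()] is run only if ambiguity codes are detected.
#'
#' @param records AIRR records (all clones; filtered by `clone_id`).
#' @param igphyml_trees Named newick vector from [parse_igphyml_tab()].
#' @param asr_sequences Named sequences from [read_asr_fasta()].
#' @param clone_id Clone to assemble.
#' @param germline_pattern Regular expression identifying the germline leaf
#'   label (case-insensitive).
#' @return A raw `lineage_tree`; [validate_tree()] on it is empty.
#' @export
assemble_clone_tree <- function(records, igphyml_trees, asr_sequences,
                                clone_id, germline_pattern = "GERM") {
  if (!(clone_id %in% names(igphyml_trees)))
    fatal("clone '%s' not in the IgPhyML tab file; available: %s",
          clone_id, paste(names(igphyml_trees), collapse = ", "))
  rec <- records[records$clone_id == clone_id, , drop = FALSE]
  phy <- ape::read.tree(text = igphyml_trees[[clone_id]])
  if (is.null(phy)) fatal("could not parse newick for clone '%s'", clone_id)

  ntip <- length(phy$tip.label)
  lab_of <- function(i) {
    if (i <= ntip) phy$tip.label[[i]]
    else {
      l <- phy$node.label[[i - ntip]] %||% ""
      if (is.na(l)) "" else l
    }
  }
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)

  germ_tip <- grep(germline_pattern, phy$tip.label, ignore.case = TRUE)
  if (length(germ_tip) == 0L)
    fatal(paste("no germline leaf matching '%s' in the tree of clone '%s';",
                "IgPhyML roots each clone tree on the reconstructed germline",
                "(run the Immcantation pipeline with germline reconstruction",
                "and --asr)"), germline_pattern, clone_id)
  germ_tip <- germ_tip[[1L]]

  # orient the edges away from the germline tip
  edge <- phy$edge
  adj <- list()
  for (k in seq_len(nrow(edge))) {
    a <- as.character(edge[k, 1L]); b <- as.character(edge[k, 2L])
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- character(0); child <- character(0)
  start <- as.character(germ_tip)
  visited <- start; queue <- start
  while (length(queue) > 0L) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (v %in% visited) next
      parent <- c(parent, u); child <- c(child, v)
      visited <- c(visited, v)
      queue <- c(queue, v)
    }
  }

  # splice out unlabeled internals left with a single child by the
  # re-rooting (typically the old newick root)
  repeat {
    idx <- NULL
    for (u in unique(parent)) {
      iu <- as.integer(u)
      if (iu <= ntip) next
      if (nzchar(lab_of(iu))) next
      kids <- which(parent == u)
      if (length(kids) == 1L) { idx <- u; break }
    }
    if (is.null(idx)) break
    kid_row <- which(parent == idx)
    up_row <- which(child == idx)
    if (length(up_row) == 1L) {
      child[up_row] <- child[kid_row]
      parent <- parent[-kid_row]; child <- child[-kid_row]
    } else break
  }

  used <- unique(c(parent, child))
  bad_internal <- used[vapply(used, function(u) {
    iu <- as.integer(u)
    iu > ntip && !nzchar(lab_of(iu)) && any(parent == u)
  }, logical(1))]
  if (length(bad_internal) > 0L)
    fatal(paste("clone '%s': the newick tree contains unlabeled internal",
                "node(s); internal sequences cannot be matched — rerun",
                "IgPhyML with the --asr option so every internal node is",
                "labeled"), clone_id)

  mk_node <- function(u) {
    iu <- as.integer(u)
    lab <- lab_of(iu)
    if (iu == germ_tip) {
      seqs <- if (lab %in% names(asr_sequences)) asr_sequences[[lab]]
              else rec$germline_alignment[[1L]]
      lineage_node(node_id = paste0("n", u), label = lab, kind = "UCA",
                   sequence = seqs)
    } else if (iu <= ntip) {
      hit <- which(rec$sequence_id == lab)
      if (length(hit) == 0L)
        fatal("leaf '%s' of clone '%s' has no matching AIRR record", lab, clone_id)
      lineage_node(node_id = paste0("n", u), label = lab, kind = "OBSERVED",
                   sequence = rec$sequence_alignment[[hit[[1L]]]])
    } else {
      if (!(lab %in% names(asr_sequences)))
        fatal("internal node '%s' of clone '%s' has no ancestral sequence in the FASTA",
              lab, clone_id)
      lineage_node(node_id = paste0("n", u), label = lab, kind = "BP",
                   sequence = asr_sequences[[lab]])
    }
  }
  if (nrow(rec) == 0L)
    fatal("no AIRR records with clone_id '%s'", clone_id)

  in_tree <- vapply(rec$sequence_id, function(s) s %in% phy$tip.label, logical(1))
  if (any(!in_tree))
    warning(sprintf("clone '%s': %d AIRR record(s) absent from the newick tree: %s",
                    clone_id, sum(!in_tree),
                    paste(rec$sequence_id[!in_tree], collapse = ", ")),
            call. = FALSE)

  nodes <- lapply(used[order(match(used, visited))], mk_node)
  lens <- vapply(nodes, function(n) nchar(n$sequence), integer(1))
  if (length(unique(lens)) != 1L)
    fatal("clone '%s': sequence lengths differ across germline/observed/ancestral sequences (%s)",
          clone_id, paste(unique(lens), collapse = ", "))

  tree <- lineage_tree(nodes,
                       data.frame(parent = paste0("n", parent),
                                  child = paste0("n", child),
                                  stringsAsFactors = FALSE),
                       alignment_length = lens[[1L]],
                       provenance = list(source = "IGPHYML", clone_id = clone_id))
  v <- validate_tree(tree)
  if (length(v) > 0L)
    fatal("clone tree assembly produced an invalid tree: %s",
          paste(v, collapse = "; "))
  has_amb <- any(vapply(tree$nodes, function(n)
    grepl("[RYSWKMBDHV]", n$sequence), logical(1)))
  if (has_amb) tree <- resolve_ambiguities(tree)
  tree
}

#' Read and process an Immcantation clone in one call
#'
#' @param airr_path AIRR rearrangement TSV path.
#' @param tab_path IgPhyML clone/tree table path.
#' @param asr_path Ancestral-sequence FASTA path.
#' @param clone_id Clone id to assemble.
#' @param process If `TRUE` (default), run [process_lineage()].
#' @inheritParams assemble_clone_tree
#' @return A `lineage_tree`.
#' @export
read_immcantation_lineage <- function(airr_path, tab_path, asr_path, clone_id,
                                      germline_pattern = "GERM",
                                      process = TRUE) {
  records <- parse_airr(airr_path)
  trees <- parse_igphyml_tab(tab_path)
  asr <- read_asr_fasta(asr_path)
  tree <- assemble_clone_tree(records, trees, asr, clone_id, germline_pattern)
  tree$provenance$files <- basename(c(airr_path, tab_path, asr_path))
  if (process) process_lineage(tree) else tree
}
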