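# Reading PHYLIP dnaml "outfile" text output.
#
# The target dialect is the PHYLIP 3.69-family dnaml output: an ASCII tree
# drawing (skipped), a "Between / And / Length" branch table, and, when the
# program was run with hypothetical-sequence reconstruction (menu option 5),
# a "Probable sequences at interior nodes" section of interleaved 60-column
# blocks. Interior nodes are numbers; tips are names. Only the branch table
# and the sequence section are used — never the whitespace-fragile drawing.

#' Parse a dnaml outfile
#'
#' Reads the branch table and the reconstructed-sequence section of a dnaml
#' output text file. Lowercase bases (dnaml's marker for reconstruction
#' confidence at or below 0.95) are normalized to uppercase; the positions
#' that were lowercase are recorded per node in `low_confidence`.
#'
#' @param path Path to the dnaml outfile (alternatively a character vector of
#'   lines via `lines`).
#' @param lines Optional character vector of file lines, used instead of
#'   `path`.
#' @return A `dnaml_document` list with elements `taxon_names`,
#'   `branch_records` (data frame: `from`, `to`, `length`),
#'   `interior_sequences` (named by interior node number),
#'   `tip_sequences` (named by tip name), `low_confidence` (named list of
#'   integer positions) and `log_likelihood`.
#' @export
parse_dnaml_outfile <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) {
    if (is.null(path)) fatal("either 'path' or 'lines' must be given")
    lines <- readLines(path, warn = FALSE)
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    fatal("empty dnaml outfile: nothing to parse")

  ll <- NA_real_
  ll_line <- grep("Ln Likelihood", lines, value = TRUE)
  if (length(ll_line) > 0L)
    ll <- suppressWarnings(as.numeric(sub(".*=\\s*", "", ll_line[[1L]])))

  # ---- branch table ----
  hdr <- grep("Between\\s+And\\s+Length", lines)
  if (length(hdr) == 0L)
    fatal("dnaml outfile: branch table header ('Between  And  Length') not found")
  i <- hdr[[1L]] + 1L
  # skip the dashes underline and blank lines
  while (i <= length(lines) &&
         (grepl("^[-\\s]*$", lines[[i]], perl = TRUE) || !nzchar(trimws(lines[[i]]))))
    i <- i + 1L
  from <- character(0); to <- character(0); len <- numeric(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) { if (length(from) > 0L) break else { i <- i + 1L; next } }
    tok <- strsplit(ln, "\\s+")[[1L]]
    if (length(tok) < 3L || !grepl("^[0-9]+$", tok[[1L]]) ||
        is.na(suppressWarnings(as.numeric(tok[[3L]])))) {
      if (length(from) > 0L) break
      fatal("dnaml outfile: unreadable branch table at line %d: '%s'", i, ln)
    }
    from <- c(from, tok[[1L]])
    to <- c(to, tok[[2L]])
    len <- c(len, as.numeric(tok[[3L]]))
    i <- i + 1L
  }
  if (length(from) == 0L)
    fatal("dnaml outfile: branch table is empty")
  branch_records <- data.frame(from = from, to = to, length = len,
                               stringsAsFactors = FALSE)

  # ---- reconstructed sequences ----
  seq_hdr <- grep("Probable sequences at interior nodes", lines)
  if (length(seq_hdr) == 0L)
    fatal(paste("dnaml outfile has no 'Probable sequences at interior nodes'",
                "section; rerun dnaml with menu option 5 (reconstruct",
                "hypothetical sequences)"))
  i <- seq_hdr[[1L]] + 1L
  seqs <- list()
  order_seen <- character(0)
  while (i <= length(lines)) {
    ln <- lines[[i]]
    lnt <- trimws(ln)
    if (!nzchar(lnt) || grepl("Reconstructed sequence", ln)) { i <- i + 1L; next }
    tok <- strsplit(lnt, "\\s+")[[1L]]
    if (length(tok) < 2L) break
    id <- tok[[1L]]
    chunk <- paste(tok[-1L], collapse = "")
    if (!grepl("^[A-Za-z.?*-]+$", chunk)) break
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- chunk
      order_seen <- c(order_seen, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], chunk)
    }
    i <- i + 1L
  }
  if (length(seqs) == 0L)
    fatal("dnaml outfile: reconstructed-sequence section is empty")

  lens <- vapply(seqs, nchar, integer(1))
  if (length(unique(lens)) != 1L) {
    bad <- names(lens)[lens != stats::median(lens)]
    fatal("dnaml outfile: assembled sequence length mismatch for node(s) %s",
          paste(bad, collapse = ", "))
  }

  low_confidence <- lapply(seqs, function(s)
    which(seq_chars(s) %in% letters))
  seqs <- lapply(seqs, toupper)

  is_interior <- grepl("^[0-9]+$", order_seen)
  tip_names <- order_seen[!is_interior]

  endpoints <- unique(c(branch_records$from, branch_records$to))
  missing <- setdiff(endpoints, names(seqs))
  if (length(missing) > 0L)
    fatal("dnaml outfile: branch endpoint(s) %s have no sequence record",
          paste(missing, collapse = ", "))

  structure(
    list(taxon_names = tip_names,
         branch_records = branch_records,
         interior_sequences = seqs[order_seen[is_interior]],
         tip_sequences = seqs[tip_names],
         low_confidence = low_confidence,
         log_likelihood = ll),
    class = "dnaml_document"
  )
}

#' Build a lineage tree from a parsed dnaml document
#'
#' Orients every branch of the (unrooted) dnaml tree away from the UCA tip,
#' which becomes the root. Interior node numbers become branch points;
#' all other tips become observed sequences. The convention of listing the
#' UCA first in the PHYLIP input (it is the declared outgroup) makes the
#' first taxon the default UCA.
#'
#' @param doc A `dnaml_document` from [parse_dnaml_outfile()].
#' @param uca_name Tip name of the unmutated common ancestor; defaults to the
#'   first taxon.
#' @return A raw `lineage_tree` (not yet processed); [validate_tree()] on the
#'   result is empty.
#' @export
dnaml_to_lineage <- function(doc, uca_name = doc$taxon_names[[1L]]) {
  if (!(uca_name %in% doc$taxon_names))
    fatal("UCA tip '%s' not found; available taxa: %s",
          uca_name, paste(doc$taxon_names, collapse = ", "))

  br <- doc$branch_records
  nbr <- nrow(br)
  # undirected adjacency, preserving branch-table order
  adj <- list()
  for (k in seq_len(nbr)) {
    adj[[br$from[k]]] <- c(adj[[br$from[k]]], br$to[k])
    adj[[br$to[k]]] <- c(adj[[br$to[k]]], br$from[k])
  }

  # orient away from the UCA tip (breadth-first, stable order)
  parent <- character(0); child <- character(0)
  visited <- uca_name
  queue <- uca_name
  while (length(queue) > 0L) {
    u <- queue[[1L]]; queue <- queue[-1L]
    for (v in adj[[u]]) {
      if (v %in% visited) next
      parent <- c(parent, u); child <- c(child, v)
      visited <- c(visited, v)
      queue <- c(queue, v)
    }
  }
  if (length(visited) != length(unique(c(br$from, br$to))))
    fatal("dnaml branch records do not form one connected tree")

  mk_node <- function(token) {
    if (grepl("^[0-9]+$", token)) {
      lineage_node(node_id = paste0("bp", token),
                   label = paste0("BP", token), kind = "BP",
                   sequence = doc$interior_sequences[[token]])
    } else if (token == uca_name) {
      lineage_node(node_id = token, label = token, kind = "UCA",
                   sequence = doc$tip_sequences[[token]])
    } else {
      lineage_node(node_id = token, label = token, kind = "OBSERVED",
                   sequence = doc$tip_sequences[[token]])
    }
  }
  node_id_of <- function(token)
    if (grepl("^[0-9]+$", token)) paste0("bp", token) else token

  nodes <- lapply(visited, mk_node)
  edges <- data.frame(parent = vapply(parent, node_id_of, character(1)),
                      child = vapply(child, node_id_of, character(1)),
                      stringsAsFactors = FALSE)
  tree <- lineage_tree(nodes, edges,
                       alignment_length = nchar(nodes[[1L]]$sequence),
                       provenance = list(source = "DNAML",
                                         uca_name = uca_name,
                                         log_likelihood = doc$log_likelihood))
  v <- validate_tree(tree)
  if (length(v) > 0L)
    fatal("dnaml tree assembly produced an invalid tree: %s",
          paste(v, collapse = "; "))
  tree
}

#' Read and process a dnaml outfile in one call
#'
#' @inheritParams parse_dnaml_outfile
#' @inheritParams dnaml_to_lineage
#' @param process If `TRUE` (default), run [process_lineage()] on the raw
#'   tree.
#' @return A `lineage_tree`.
#' @export
read_dnaml_lineage <- function(path, uca_name = NULL, process = TRUE) {
  doc <- parse_dnaml_outfile(path)
  tree <- dnaml_to_lineage(doc, uca_name %||% doc$taxon_names[[1L]])
  tree$provenance$files <- basename(path)
  if (process) process_lineage(tree) else tree
}
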