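# Seeded simulation of somatic-hypermutation lineages with ground truth,
# plus emitters for every input dialect the parsers read. The simulator
# tests plumbing, not SHM realism: substitutions are uniform over the three
# alternative bases, with a configurable rate bias toward CDR positions and
# no hot-spot motif model.

TWO_BASE_CODE <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a clonal lineage with ground truth
#'
#' Draws a random bifurcating tree over `n_leaves` observed sequences below
#' a UCA root, an in-frame stop-free random UCA sequence, and the configured
#' number of substitutions on every edge at positions biased toward the
#' CDRs. Every event is recorded in the returned ground truth. Optionally,
#' some leaves are duplicated verbatim as siblings (exercising identical-
#' sequence clustering) and some branch-point positions are rewritten as
#' two-base IUPAC codes whose true base holds a strict majority among the
#' observed descendants (exercising ambiguity resolution).
#'
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical results.
#' @param n_leaves Number of observed leaves (>= 1).
#' @param uca_length UCA sequence length in nucleotides (multiple of 3).
#' @param mutations_per_edge Integer range `c(min, max)` of substitutions
#'   per edge.
#' @param region_ends 6 strictly increasing region end positions
#'   (FW1..CDR3); defaults scale the canonical V(D)J layout to
#'   `uca_length`.
#' @param cdr_rate_multiplier Relative substitution rate of CDR positions
#'   (>= 1).
#' @param allow_reversions If `FALSE` (default), a site mutated anywhere on
#'   the path from the root is never mutated again on that path, so edge
#'   events are exactly recoverable from the leaf sequences.
#' @param ambiguity_rate Fraction of branch-point positions rewritten as
#'   IUPAC ambiguity codes.
#' @param duplicate_leaf_rate Fraction of leaves duplicated verbatim.
#' @return A `lineage_simulation` list: `tree` (raw `lineage_tree`),
#'   `truth` (list with `events` keyed by child label, `sequences` keyed by
#'   label (pre-ambiguity), `edges` as parent/child label pairs,
#'   `ambiguities` data frame), `region_ends`, `config`.
#' @export
simulate_lineage <- function(seed = 1, n_leaves = 8, uca_length = 360,
                             mutations_per_edge = c(1, 4),
                             region_ends = NULL,
                             cdr_rate_multiplier = 5,
                             allow_reversions = FALSE,
                             ambiguity_rate = 0,
                             duplicate_leaf_rate = 0) {
  if (n_leaves < 1L) fatal("n_leaves must be >= 1")
  if (uca_length %% 3L != 0L) fatal("uca_length must be a multiple of 3")
  if (is.null(region_ends))
    region_ends <- pmax(seq_len(6),
                        round(c(78, 114, 165, 195, 312, 360) / 360 * uca_length))
  region_ends[6] <- uca_length
  if (any(diff(region_ends) <= 0))
    fatal("region_ends must be strictly increasing")
  if (length(mutations_per_edge) == 1L)
    mutations_per_edge <- rep(mutations_per_edge, 2L)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  # in-frame, stop-free UCA
  codons <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  uca_seq <- paste(sample(codons, uca_length / 3L, replace = TRUE),
                   collapse = "")

  # ---- topology: random sequential edge splitting -----------------------
  label_width <- max(2L, nchar(as.character(2L * n_leaves)))
  leaf_label <- function(i) sprintf("Ig%0*d", label_width, i)
  edges <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  n_bp <- 0L
  new_bp <- function() { n_bp <<- n_bp + 1L; sprintf("b%d", n_bp) }
  if (n_leaves == 1L) {
    edges <- data.frame(parent = "uca", child = "L1", stringsAsFactors = FALSE)
  } else {
    r <- new_bp()
    edges <- data.frame(parent = c("uca", r, r), child = c(r, "L1", "L2"),
                        stringsAsFactors = FALSE)
    for (i in seq(3L, length.out = n_leaves - 2L)) {
      k <- sample.int(nrow(edges), 1L)
      u <- edges$parent[[k]]; v <- edges$child[[k]]
      w <- new_bp()
      edges$child[[k]] <- w
      edges <- rbind(edges,
                     data.frame(parent = c(w, w), child = c(v, sprintf("L%d", i)),
                                stringsAsFactors = FALSE))
    }
  }

  # ---- sequences and ground-truth events --------------------------------
  cdr_pos <- unlist(lapply(c(2L, 4L, 6L), function(j)
    seq.int(region_ends[j - 1L] + 1L, region_ends[j])))
  weights <- rep(1, uca_length)
  weights[cdr_pos] <- cdr_rate_multiplier

  sequences <- list(uca = seq_chars(uca_seq))
  mutated_on_path <- list(uca = integer(0))
  events <- list()
  ids_pre <- local({
    out <- character(0); stack <- "uca"
    while (length(stack) > 0L) {
      id <- stack[[1L]]; stack <- stack[-1L]
      out <- c(out, id)
      stack <- c(edges$child[edges$parent == id], stack)
    }
    out
  })
  for (id in ids_pre) {
    if (id == "uca") next
    par <- edges$parent[[match(id, edges$child)]]
    seqc <- sequences[[par]]
    used <- mutated_on_path[[par]]
    k <- sample(seq.int(mutations_per_edge[1L], mutations_per_edge[2L]), 1L)
    cand <- if (allow_reversions) seq_len(uca_length)
            else setdiff(seq_len(uca_length), used)
    k <- min(k, length(cand))
    pos <- sort(sample(cand, k, prob = weights[cand]))
    ev <- data.frame(nt_position = integer(0), from_nt = character(0),
                     to_nt = character(0), stringsAsFactors = FALSE)
    for (p in pos) {
      from <- seqc[[p]]
      to <- sample(setdiff(CONCRETE_BASES, from), 1L)
      seqc[[p]] <- to
      ev <- rbind(ev, data.frame(nt_position = p, from_nt = from, to_nt = to,
                                 stringsAsFactors = FALSE))
    }
    sequences[[id]] <- seqc
    mutated_on_path[[id]] <- c(used, pos)
    events[[id]] <- ev
  }

  # ---- duplicate leaves -------------------------------------------------
  leaf_ids0 <- setdiff(edges$child, edges$parent)
  n_extra <- 0L
  if (duplicate_leaf_rate > 0) {
    for (lf in leaf_ids0) {
      if (stats::runif(1) >= duplicate_leaf_rate) next
      n_extra <- n_extra + 1L
      dup <- sprintf("L%d", n_leaves + n_extra)
      par <- edges$parent[[match(lf, edges$child)]]
      edges <- rbind(edges, data.frame(parent = par, child = dup,
                                       stringsAsFactors = FALSE))
      sequences[[dup]] <- sequences[[lf]]
      # a verbatim duplicate differs from its parent exactly as the
      # original leaf does
      events[[dup]] <- events[[lf]]
    }
  }

  # ---- display labels ---------------------------------------------------
  label_of <- stats::setNames(character(0), character(0))
  label_of[["uca"]] <- "UCA"
  bp_counter <- 0L
  leaf_counter <- 0L
  for (id in preorder_ids_raw(edges, "uca")) {
    if (id == "uca") next
    if (startsWith(id, "b")) {
      bp_counter <- bp_counter + 1L
      label_of[[id]] <- sprintf("BP%d", bp_counter)
    } else {
      leaf_counter <- leaf_counter + 1L
      label_of[[id]] <- leaf_label(leaf_counter)
    }
  }

  truth_events <- stats::setNames(events[names(events)],
                                  label_of[names(events)])
  truth_edges <- data.frame(parent = unname(label_of[edges$parent]),
                            child = unname(label_of[edges$child]),
                            stringsAsFactors = FALSE)
  truth_sequences <- stats::setNames(
    lapply(sequences, paste, collapse = ""), label_of[names(sequences)])

  # ---- branch-point ambiguity perturbation ------------------------------
  display_seq <- lapply(sequences, identity)
  amb <- data.frame(node = character(0), nt_position = integer(0),
                    true_base = character(0), code = character(0),
                    stringsAsFactors = FALSE)
  if (ambiguity_rate > 0) {
    obs_below <- function(id) {
      below <- setdiff(preorder_ids_raw(edges, id), id)
      below[!startsWith(below, "b")]
    }
    for (id in ids_pre) {
      if (!startsWith(id, "b")) next
      desc <- obs_below(id)
      votes <- do.call(rbind, lapply(sequences[desc], identity))
      hit <- which(stats::runif(uca_length) < ambiguity_rate)
      for (p in hit) {
        b <- sequences[[id]][[p]]
        if (!(b %in% CONCRETE_BASES)) next
        counts <- vapply(CONCRETE_BASES, function(x) sum(votes[, p] == x),
                         integer(1))
        others <- setdiff(CONCRETE_BASES, b)
        o <- others[[which.min(counts[others])]]
        if (counts[[b]] <= counts[[o]]) next  # needs a strict majority
        code <- TWO_BASE_CODE[[paste(sort(c(b, o)), collapse = "")]]
        display_seq[[id]][[p]] <- code
        amb <- rbind(amb, data.frame(node = label_of[[id]], nt_position = p,
                                     true_base = b, code = code,
                                     stringsAsFactors = FALSE))
      }
    }
  }

  # ---- assemble the lineage_tree ---------------------------------------
  all_ids <- preorder_ids_raw(edges, "uca")
  nodes <- lapply(all_ids, function(id) {
    lineage_node(node_id = id, label = label_of[[id]],
                 kind = if (id == "uca") "UCA"
                        else if (startsWith(id, "b")) "BP" else "OBSERVED",
                 sequence = paste(display_seq[[id]], collapse = ""))
  })
  tree <- lineage_tree(nodes, edges, alignment_length = uca_length,
                       provenance = list(source = "SIMULATION",
                                         seed = seed))
  structure(
    list(tree = tree,
         truth = list(events = truth_events,
                      sequences = truth_sequences,
                      edges = truth_edges,
                      ambiguities = amb),
         region_ends = region_ends,
         config = list(seed = seed, n_leaves = n_leaves,
                       uca_length = uca_length,
                       mutations_per_edge = mutations_per_edge,
                       cdr_rate_multiplier = cdr_rate_multiplier,
                       allow_reversions = allow_reversions,
                       ambiguity_rate = ambiguity_rate,
                       duplicate_leaf_rate = duplicate_leaf_rate)),
    class = "lineage_simulation")
}

# pre-order over a raw edge table
#' @noRd
preorder_ids_raw <- function(edges, root) {
  out <- character(0); stack <- root
  while (length(stack) > 0L) {
    id <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, id)
    stack <- c(edges$child[edges$parent == id], stack)
  }
  out
}

#' Emit a dnaml outfile for a simulated lineage
#'
#' Writes the exact PHYLIP dnaml dialect [parse_dnaml_outfile()] reads: a
#' header, a placeholder ASCII tree, the `Between / And / Length` branch
#' table and the interleaved `Probable sequences at interior nodes` section.
#' Branch points become interior node numbers in pre-order; the UCA is the
#' first taxon (the declared outgroup). Parsing the result reproduces the
#' simulated topology and sequences.
#'
#' @param sim A `lineage_simulation` (or a raw `lineage_tree` whose root is
#'   the UCA).
#' @return Character vector of file lines.
#' @export
emit_dnaml_outfile <- function(sim) {
  tree <- if (inherits(sim, "lineage_simulation")) sim$tree else sim
  ord <- preorder_ids(tree)
  kinds <- vapply(tree$nodes[ord], `[[`, character(1), "kind")
  bp_ids <- ord[kinds == "BP"]
  number_of <- stats::setNames(as.character(seq_along(bp_ids)), bp_ids)
  repr <- function(id) {
    if (id %in% bp_ids) number_of[[id]]
    else tree$nodes[[id]]$label
  }
  root <- root_id(tree)
  root_label <- tree$nodes[[root]]$label

  n_taxa <- sum(kinds != "BP")
  lines <- c("Nucleic acid sequence Maximum Likelihood method, version 3.696",
             "",
             sprintf(" %d sequences, %d sites", n_taxa, tree$alignment_length),
             "",
             "  +--(ASCII tree drawing omitted by the emitter)",
             "",
             "remember: this is an unrooted tree!",
             "",
             sprintf("Ln Likelihood = %12.5f", -1000.0),
             "",
             " Between        And            Length      Approx. Confidence Limits",
             " -------        ---            ------      ------- ---------- -------",
             "")
  # branch records: root tip attaches to interior 1 (or directly to the
  # single leaf when the tree has no branch points)
  brec <- character(0)
  fmt <- function(a, b) sprintf("  %6s     %-12s    %8.5f     (     zero,     %7.5f)",
                                a, b, 0.1, 0.3)
  if (length(bp_ids) == 0L) {
    # degenerate lineage: introduce interior node 1 carrying the UCA state
    kid <- children_of(tree, root)[[1L]]
    brec <- c(fmt("1", root_label), fmt("1", tree$nodes[[kid]]$label))
  } else {
    brec <- fmt("1", root_label)
    for (bp in bp_ids) {
      for (kid in children_of(tree, bp))
        brec <- c(brec, fmt(number_of[[bp]], repr(kid)))
    }
  }
  lines <- c(lines, brec, "")

  lines <- c(lines, "Probable sequences at interior nodes:", "",
             "  node            Reconstructed sequence (caps if > 0.95)", "")
  row_ids <- c(root, setdiff(ord, root))
  row_names <- vapply(row_ids, repr, character(1))
  row_seqs <- vapply(row_ids, function(id) tree$nodes[[id]]$sequence,
                     character(1))
  if (length(bp_ids) == 0L) {
    row_ids <- c(row_ids, "synthetic-interior")
    row_names <- c(row_names, "1")
    row_seqs <- c(row_seqs, tree$nodes[[root]]$sequence)
  }
  L <- tree$alignment_length
  for (block_start in seq(1L, L, by = 60L)) {
    for (r in seq_along(row_ids)) {
      chunk <- substr(row_seqs[[r]], block_start, min(block_start + 59L, L))
      tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
      lines <- c(lines, sprintf("%6s    %s", row_names[[r]],
                                paste(tens, collapse = " ")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Emit the Immcantation input triple for a simulated lineage
#'
#' Produces the AIRR rearrangement TSV, the IgPhyML clone/tree tab file, the
#' ancestral-sequence FASTA, and the region FASTA, in the dialects the
#' corresponding parsers read. The germline leaf is labelled
#' `"<clone_id>_GERM"` and appears in the newick tree alongside the root
#' branch point's children.
#'
#' @param sim A `lineage_simulation`.
#' @param clone_id Clone identifier used throughout the files.
#' @return Named list of character vectors: `airr`, `tab`, `asr_fasta`,
#'   `region_fasta`, each one file's lines.
#' @export
emit_immcantation <- function(sim, clone_id = "1") {
  tree <- if (inherits(sim, "lineage_simulation")) sim$tree else sim
  region_ends <- if (inherits(sim, "lineage_simulation")) sim$region_ends
                 else c(78, 114, 165, 195, 312, 360)
  root <- root_id(tree)
  germ_label <- paste0(clone_id, "_GERM")
  uca_seq <- tree$nodes[[root]]$sequence

  leaves <- leaf_ids(tree)
  obs <- intersect(preorder_ids(tree), leaves)
  obs <- obs[vapply(tree$nodes[obs], function(n) n$kind == "OBSERVED", logical(1))]

  airr <- c(paste(c("sequence_id", "clone_id", "sequence_alignment",
                    "germline_alignment", "v_call", "j_call"), collapse = "\t"),
            vapply(obs, function(id)
              paste(c(tree$nodes[[id]]$label, clone_id,
                      tree$nodes[[id]]$sequence, uca_seq,
                      "IGHV1-18*01", "IGHJ4*02"), collapse = "\t"),
              character(1)))

  nw_of <- function(id) {
    kids <- children_of(tree, id)
    if (length(kids) == 0L) sprintf("%s:0.1", tree$nodes[[id]]$label)
    else sprintf("(%s)%s:0.1",
                 paste(vapply(kids, nw_of, character(1)), collapse = ","),
                 tree$nodes[[id]]$label)
  }
  root_kids <- children_of(tree, root)
  if (length(root_kids) == 1L && tree$nodes[[root_kids]]$kind == "BP") {
    top <- root_kids[[1L]]
    newick <- sprintf("(%s:0.0,%s)%s;", germ_label,
                      paste(vapply(children_of(tree, top), nw_of, character(1)),
                            collapse = ","),
                      tree$nodes[[top]]$label)
  } else {
    newick <- sprintf("(%s:0.0,%s);", germ_label,
                      paste(vapply(root_kids, nw_of, character(1)),
                            collapse = ","))
  }
  tab <- c("CLONE\tTREE", paste(clone_id, newick, sep = "\t"))

  bps <- preorder_ids(tree)
  bps <- bps[vapply(tree$nodes[bps], function(n) n$kind == "BP", logical(1))]
  asr <- c(paste0(">", germ_label), uca_seq)
  for (id in bps)
    asr <- c(asr, paste0(">", tree$nodes[[id]]$label), tree$nodes[[id]]$sequence)

  region_fasta <- c(paste(c(">UCA", region_ends), collapse = " "), uca_seq)

  list(airr = airr, tab = tab, asr_fasta = asr, region_fasta = region_fasta)
}

#' Write a complete simulated fixture bundle to disk
#'
#' @param sim A `lineage_simulation`.
#' @param dir Output directory (created if needed).
#' @param clone_id Clone id used in the Immcantation files.
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir, clone_id = "1") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(dnaml = file.path(dir, "dnaml_outfile.txt"),
             airr = file.path(dir, "airr.tsv"),
             tab = file.path(dir, "igphyml_clones.tab"),
             asr = file.path(dir, "igphyml_asr.fasta"),
             region = file.path(dir, "region_uca.fasta"),
             truth = file.path(dir, "ground_truth.json"))
  writeLines(emit_dnaml_outfile(sim), files[["dnaml"]])
  imm <- emit_immcantation(sim, clone_id)
  writeLines(imm$airr, files[["airr"]])
  writeLines(imm$tab, files[["tab"]])
  writeLines(imm$asr_fasta, files[["asr"]])
  writeLines(imm$region_fasta, files[["region"]])
  jsonlite::write_json(
    list(config = sim$config,
         sequences = sim$truth$sequences,
         edges = sim$truth$edges,
         events = sim$truth$events,
         ambiguities = sim$truth$ambiguities),
    files[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
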