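# Tree post-processing: ambiguity resolution at branch points, collapsing of
# redundant branch points, clustering of identical observed sequences.

#' Resolve IUPAC ambiguity codes at branch points
#'
#' Maximum-likelihood ancestral reconstruction (dnaml in particular) can emit
#' IUPAC ambiguity codes at inferred branch-point positions. For every
#' ambiguous position of every branch point, the code is replaced by the
#' single base, among those the code denotes, that is most frequent at that
#' position across the sequences of all *observed* leaves below that branch
#' point. Ties are broken by the fixed base order A < C < G < T; if no
#' descendant carries any base the code denotes, the position becomes `N` and
#' a warning is issued. Observed and UCA sequences are never modified.
#'
#' @param tree A `lineage_tree`.
#' @return The tree with ambiguity-free branch-point sequences (alphabet
#'   restricted to A/C/G/T/N and gaps); topology unchanged.
#' @export
resolve_ambiguities <- function(tree) {
  amb_codes <- names(IUPAC_AMBIGUITY)
  for (id in names(tree$nodes)) {
    node <- tree$nodes[[id]]
    if (node$kind != "BP") next
    ch <- seq_chars(node$sequence)
    pos <- which(ch %in% amb_codes)
    if (length(pos) == 0L) next
    obs <- observed_descendants(tree, id)
    obs_chars <- lapply(tree$nodes[obs], function(n) seq_chars(n$sequence))
    for (p in pos) {
      allowed <- IUPAC_AMBIGUITY[[ch[p]]]
      votes <- vapply(obs_chars, `[[`, character(1), p)
      counts <- vapply(allowed, function(b) sum(votes == b), integer(1))
      if (all(counts == 0L)) {
        warning(sprintf(
          "no observed descendant of '%s' carries a base denoted by '%s' at position %d; writing N",
          node$label, ch[p], p), call. = FALSE)
        ch[p] <- "N"
      } else {
        # `allowed` is already in A < C < G < T order, so which.max breaks
        # ties toward the earlier base.
        ch[p] <- allowed[which.max(counts)]
      }
    }
    tree$nodes[[id]]$sequence <- paste(ch, collapse = "")
  }
  tree
}

#' Collapse branch points identical to one of their children
#'
#' An inferred branch point whose reconstructed sequence is identical to an
#' existing child's sequence is redundant: it corresponds to a sequence that
#' actually exists in the tree. Each such branch point is merged with that
#' child (the first identical child in input order when there are several):
#' the merged node keeps the child's kind, label and id, the branch point's
#' member labels are appended to the child's, and the branch point's
#' remaining children are re-parented to the merged node. Applied bottom-up
#' until a fixed point. Identity is case-insensitive and treats `.` and `-`
#' as the same gap character; `N` matches only `N`.
#'
#' @param tree A `lineage_tree` (ambiguities already resolved).
#' @return The collapsed tree. The multiset of observed leaf sequences and
#'   the set of member labels are preserved.
#' @export
collapse_redundant_bps <- function(tree) {
  repeat {
    merged <- FALSE
    # Post-order so deeper branch points collapse first.
    for (id in rev(preorder_ids(tree))) {
      node <- tree$nodes[[id]]
      if (is.null(node) || node$kind != "BP") next
      kids <- children_of(tree, id)
      if (length(kids) == 0L) next
      norm_bp <- normalize_seq(node$sequence)
      hit <- kids[vapply(kids, function(k)
        normalize_seq(tree$nodes[[k]]$sequence) == norm_bp, logical(1))]
      if (length(hit) == 0L) next
      tree <- merge_bp_into_child(tree, id, hit[[1L]])
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  tree
}

# Merge branch point `bp` into its child `child`: the child takes the branch
# point's place in the tree and absorbs its members and remaining children.
#' @noRd
merge_bp_into_child <- function(tree, bp, child) {
  bp_node <- tree$nodes[[bp]]
  tree$nodes[[child]]$members <-
    c(tree$nodes[[child]]$members, bp_node$members)
  tree$nodes[[child]]$member_kinds <-
    c(tree$nodes[[child]]$member_kinds, bp_node$member_kinds)

  own_kids <- setdiff(children_of(tree, child), NULL)
  other_kids <- setdiff(children_of(tree, bp), child)

  e <- tree$edges
  # child takes the BP's slot under the BP's parent (root BPs cannot occur:
  # the root is always the UCA).
  e$child[e$child == bp] <- child
  e <- e[!(e$parent == bp & e$child == child), , drop = FALSE]
  e$parent[e$parent == bp] <- child
  # deterministic child order on the merged node: the child's own children
  # first, then the BP's remaining children, each group in original order.
  under <- e$parent == child
  reordered <- e[under, , drop = FALSE]
  reordered <- reordered[order(match(reordered$child, c(own_kids, other_kids))), ,
                         drop = FALSE]
  e <- rbind(e[!under, , drop = FALSE], reordered)
  rownames(e) <- NULL

  tree$nodes[[bp]] <- NULL
  tree$edges <- e
  tree
}

#' Cluster identical observed sibling sequences
#'
#' Observed leaves that are siblings and carry identical sequences (under the
#' same normalization as [collapse_redundant_bps()]) are merged into one node
#' whose member list concatenates all merged labels in child order. The union
#' of member labels across the tree is unchanged.
#'
#' @param tree A `lineage_tree` (collapsing already applied).
#' @return The clustered tree.
#' @export
cluster_identical_observed <- function(tree) {
  leaves <- leaf_ids(tree)
  for (id in preorder_ids(tree)) {
    if (!(id %in% names(tree$nodes))) next
    kids <- children_of(tree, id)
    obs_leaf_kids <- kids[kids %in% leaves &
      vapply(kids, function(k) tree$nodes[[k]]$kind == "OBSERVED", logical(1))]
    if (length(obs_leaf_kids) < 2L) next
    seqs <- vapply(tree$nodes[obs_leaf_kids], function(n)
      normalize_seq(n$sequence), character(1))
    for (s in unique(seqs)) {
      grp <- obs_leaf_kids[seqs == s]
      if (length(grp) < 2L) next
      keep <- grp[[1L]]
      for (dup in grp[-1L]) {
        tree$nodes[[keep]]$members <-
          c(tree$nodes[[keep]]$members, tree$nodes[[dup]]$members)
        tree$nodes[[keep]]$member_kinds <-
          c(tree$nodes[[keep]]$member_kinds, tree$nodes[[dup]]$member_kinds)
        tree$edges <- tree$edges[tree$edges$child != dup, , drop = FALSE]
        tree$nodes[[dup]] <- NULL
      }
    }
  }
  tree
}

#' Relabel branch points in pre-order
#'
#' Assigns labels `BP1`, `BP2`, ... to the surviving branch points in a
#' deterministic pre-order traversal so that repeated runs on the same input
#' are bit-stable. Historical member labels of branch points that were
#' collapsed away are kept; should such a stale label collide with a freshly
#' assigned one, the stale entry is marked with a trailing `*`.
#'
#' @param tree A `lineage_tree`.
#' @return The relabelled tree.
#' @export
relabel_branch_points <- function(tree) {
  ord <- preorder_ids(tree)
  bp_ids <- ord[vapply(tree$nodes[ord], function(n) n$kind == "BP", logical(1))]
  new_labels <- paste0("BP", seq_along(bp_ids))
  old_labels <- vapply(tree$nodes[bp_ids], `[[`, character(1), "label")

  for (i in seq_along(bp_ids)) {
    id <- bp_ids[[i]]
    tree$nodes[[id]]$label <- new_labels[[i]]
    tree$nodes[[id]]$members[[1L]] <- new_labels[[i]]
  }
  # disambiguate stale member labels (from merged-away branch points) that
  # now collide with a freshly assigned label
  for (id in names(tree$nodes)) {
    m <- tree$nodes[[id]]$members
    stale <- which(m %in% new_labels)
    stale <- stale[!(id %in% bp_ids & stale == 1L)]
    if (id %in% bp_ids) stale <- setdiff(stale, 1L)
    if (length(stale) > 0L)
      tree$nodes[[id]]$members[stale] <- paste0(m[stale], "*")
  }
  tree
}

#' Run the full post-processing pipeline
#'
#' Applies, in order: [resolve_ambiguities()], [collapse_redundant_bps()],
#' [cluster_identical_observed()] and [relabel_branch_points()].
#'
#' @param tree A raw `lineage_tree` as returned by [dnaml_to_lineage()] or
#'   [assemble_clone_tree()].
#' @return The processed tree, ready for [annotate_tree()].
#' @export
process_lineage <- function(tree) {
  tree <- resolve_ambiguities(tree)
  tree <- collapse_redundant_bps(tree)
  tree <- cluster_identical_observed(tree)
  relabel_branch_points(tree)
}
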