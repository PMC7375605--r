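#' Construct a lineage-tree node
#'
#' A node of a clonal lineage tree holds one aligned nucleotide sequence and
#' the labels of every sequence that has been merged into it (by branch-point
#' collapsing or identical-sequence clustering). Exactly one node per tree has
#' kind `"UCA"` (the unmutated common ancestor) and it is always the root;
#' `"OBSERVED"` nodes are sequenced antibodies and `"BP"` nodes are inferred
#' branch points carrying reconstructed intermediate sequences.
#'
#' @param node_id Unique opaque identifier within the tree.
#' @param label Display name: an observed Ig name, `"UCA"`, or `"BP<k>"`.
#' @param kind One of `"UCA"`, `"OBSERVED"`, `"BP"`.
#' @param sequence Aligned nucleotide string (A/C/G/T/N, IUPAC ambiguity
#'   codes, and the gap characters `-` and `.`).
#' @param members Labels of all sequences merged into this node; the first
#'   entry is always `label`.
#' @param member_kinds Node kind of each member, parallel to `members`.
#' @param ec50 Optional neutralization titer, kept verbatim as text
#'   (e.g. `"3.2 ng/ml"`).
#' @param comment Optional free-text comment.
#' @return A `lineage_node` list.
#' @export
lineage_node <- function(node_id, label, kind, sequence,
                         members = label, member_kinds = kind,
                         ec50 = NA_character_, comment = NA_character_) {
  kind <- match.arg(kind, c("UCA", "OBSERVED", "BP"))
  check_seq_alphabet(sequence, where = sprintf("sequence of node '%s'", label))
  stopifnot(length(members) >= 1L, length(member_kinds) == length(members))
  structure(
    list(node_id = as.character(node_id), label = as.character(label),
         kind = kind, sequence = toupper(sequence),
         members = as.character(members),
         member_kinds = as.character(member_kinds),
         ec50 = as.character(ec50), comment = as.character(comment)),
    class = "lineage_node"
  )
}

#' Construct a lineage tree
#'
#' @param nodes A list of [lineage_node()] objects.
#' @param edges A data frame with character columns `parent` and `child`
#'   holding node ids; row order fixes the (deterministic) child order.
#' @param alignment_length Common length of all node sequences.
#' @param region_map Optional region map from [parse_region_fasta()].
#' @param provenance Named list describing where the tree came from
#'   (elements such as `source` = `"DNAML"` or `"IGPHYML"`, `files`,
#'   `clone_id`).
#' @return A `lineage_tree` object.
#' @export
lineage_tree <- function(nodes, edges, alignment_length,
                         region_map = NULL, provenance = list()) {
  names(nodes) <- vapply(nodes, `[[`, character(1), "node_id")
  edges <- data.frame(parent = as.character(edges$parent),
                      child = as.character(edges$child),
                      stringsAsFactors = FALSE)
  structure(
    list(nodes = nodes, edges = edges,
         alignment_length = as.integer(alignment_length),
         region_map = region_map, provenance = provenance,
         annotations = list()),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat(sprintf("<lineage_tree> %d nodes (%d observed, %d branch points), alignment length %d\n",
              length(x$nodes), sum(kinds == "OBSERVED"), sum(kinds == "BP"),
              x$alignment_length))
  if (!is.null(x$provenance$source))
    cat(sprintf("  source: %s\n", x$provenance$source))
  if (length(x$annotations) > 0L)
    cat(sprintf("  %d annotated edges\n", length(x$annotations)))
  invisible(x)
}

# ---- structural accessors ----------------------------------------------

#' @noRd
tree_root_id <- function(tree) {
  ids <- names(tree$nodes)
  ids[!(ids %in% tree$edges$child)]
}

#' Root node id of a lineage tree
#' @param tree A `lineage_tree`.
#' @return The node id of the root.
#' @export
root_id <- function(tree) {
  r <- tree_root_id(tree)
  if (length(r) != 1L) fatal("tree has %d parentless nodes, expected 1", length(r))
  r
}

#' @noRd
children_of <- function(tree, id) tree$edges$child[tree$edges$parent == id]

#' @noRd
parent_of <- function(tree, id) {
  p <- tree$edges$parent[tree$edges$child == id]
  if (length(p) == 0L) NA_character_ else p
}

# Pre-order node ids (parent before children, children in edge-row order).
#' @noRd
preorder_ids <- function(tree, from = root_id(tree)) {
  out <- character(0)
  stack <- from
  while (length(stack) > 0L) {
    id <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, id)
    stack <- c(children_of(tree, id), stack)
  }
  out
}

#' @noRd
leaf_ids <- function(tree) {
  ids <- names(tree$nodes)
  ids[!(ids %in% tree$edges$parent)]
}

# Observed leaf descendants strictly below `id` (the empirical evidence a
# branch point's ambiguity vote is based on).
#' @noRd
observed_descendants <- function(tree, id) {
  below <- setdiff(preorder_ids(tree, from = id), id)
  below[vapply(tree$nodes[below], function(n) n$kind == "OBSERVED", logical(1))]
}

#' Validate lineage-tree invariants
#'
#' Checks that the edges form a single rooted tree, that the root (and only
#' the root) has kind `"UCA"`, that every node sequence has the tree's
#' alignment length, and that member labels are unique tree-wide.
#'
#' @param tree A `lineage_tree`.
#' @return A character vector of violation descriptions; empty when the tree
#'   is well-formed.
#' @export
validate_tree <- function(tree) {
  v <- character(0)
  ids <- names(tree$nodes)
  if (length(ids) == 0L) return("tree has no nodes")
  if (anyDuplicated(ids)) v <- c(v, "duplicate node ids")

  unknown <- setdiff(unique(c(tree$edges$parent, tree$edges$child)), ids)
  if (length(unknown) > 0L)
    v <- c(v, sprintf("edge references unknown node id '%s'", unknown))

  roots <- tree_root_id(tree)
  if (length(roots) == 0L) {
    v <- c(v, "no parentless node (cycle)")
  } else if (length(roots) > 1L) {
    v <- c(v, sprintf("multiple parentless nodes: %s",
                      paste(vapply(tree$nodes[roots], `[[`, character(1), "label"),
                            collapse = ", ")))
  }

  multi_parent <- unique(tree$edges$child[duplicated(tree$edges$child)])
  for (id in multi_parent)
    v <- c(v, sprintf("node '%s' has more than one parent", tree$nodes[[id]]$label))

  if (length(roots) == 1L && length(multi_parent) == 0L &&
      length(unknown) == 0L) {
    reached <- preorder_ids(tree, from = roots)
    if (length(setdiff(ids, reached)) > 0L)
      v <- c(v, sprintf("node '%s' unreachable from the root",
                        vapply(tree$nodes[setdiff(ids, reached)], `[[`,
                               character(1), "label")))
    if (tree$nodes[[roots]]$kind != "UCA")
      v <- c(v, sprintf("root node '%s' has kind %s, expected UCA",
                        tree$nodes[[roots]]$label, tree$nodes[[roots]]$kind))
  }

  kinds <- vapply(tree$nodes, `[[`, character(1), "kind")
  if (sum(kinds == "UCA") != 1L)
    v <- c(v, sprintf("tree has %d UCA nodes, expected exactly 1",
                      sum(kinds == "UCA")))

  for (n in tree$nodes) {
    if (nchar(n$sequence) != tree$alignment_length)
      v <- c(v, sprintf("node '%s' sequence length %d differs from alignment length %d",
                        n$label, nchar(n$sequence), tree$alignment_length))
    if (length(n$members) == 0L)
      v <- c(v, sprintf("node '%s' has an empty member list", n$label))
  }
  all_members <- unlist(lapply(tree$nodes, `[[`, "members"), use.names = FALSE)
  dup <- unique(all_members[duplicated(all_members)])
  for (m in dup)
    v <- c(v, sprintf("member label '%s' appears in more than one node", m))
  v
}

# Canonical string form of a (sub)tree, used by tests and by isomorphism
# comparisons: children are sorted by their own canonical form so the result
# is independent of child order.
#' @noRd
tree_canonical <- function(tree, id = root_id(tree)) {
  n <- tree$nodes[[id]]
  kids <- children_of(tree, id)
  kid_str <- sort(vapply(kids, function(k) tree_canonical(tree, k), character(1)))
  sprintf("(%s|%s|%s|[%s])",
          n$kind, normalize_seq(n$sequence),
          paste(sort(n$members), collapse = ","),
          paste(kid_str, collapse = ","))
}
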