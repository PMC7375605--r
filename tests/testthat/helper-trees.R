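# Shared fixtures and independent oracles for the test suite.

# Compact constructor for hand-built trees: `spec` is a list of
# list(id, label, kind, seq), `edges` a list of c(parent, child).
make_tree <- function(spec, edges, alignment_length = NULL) {
  nodes <- lapply(spec, function(s)
    lineage_node(node_id = s[[1]], label = s[[2]], kind = s[[3]],
                 sequence = s[[4]]))
  e <- data.frame(parent = vapply(edges, `[[`, character(1), 1L),
                  child = vapply(edges, `[[`, character(1), 2L),
                  stringsAsFactors = FALSE)
  lineage_tree(nodes, e,
               alignment_length %||% nchar(spec[[1]][[4]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Multiset of observed-node sequences (collapse/cluster must preserve it,
# counting member multiplicity for clustered nodes).
observed_seq_multiset <- function(tree) {
  out <- character(0)
  for (n in tree$nodes) {
    k <- sum(n$member_kinds == "OBSERVED")
    if (k > 0L) out <- c(out, rep(toupper(chartr(".", "-", n$sequence)), k))
  }
  sort(out)
}

all_member_labels <- function(tree) {
  sort(unlist(lapply(tree$nodes, `[[`, "members"), use.names = FALSE))
}

# ---- independent O(n^2) oracle for collapsing + clustering --------------
# Works on parent maps and plain vectors; shares no code with the package
# implementation.
oracle_collapse_cluster <- function(tree) {
  ids <- names(tree$nodes)
  par <- setNames(rep(NA_character_, length(ids)), ids)
  for (k in seq_len(nrow(tree$edges)))
    par[[tree$edges$child[[k]]]] <- tree$edges$parent[[k]]
  kind <- vapply(tree$nodes, `[[`, character(1), "kind")
  seqn <- vapply(tree$nodes, function(n)
    toupper(chartr(".", "-", n$sequence)), character(1))
  members <- lapply(tree$nodes, `[[`, "members")
  mkinds <- lapply(tree$nodes, `[[`, "member_kinds")
  alive <- setNames(rep(TRUE, length(ids)), ids)

  child_order <- function(p) tree$edges$child[tree$edges$parent == p]
  kids_of <- function(p) {
    k <- names(par)[!is.na(par) & par == p & alive[names(par)]]
    k[order(match(k, names(par)))]
  }

  # collapse: any live BP with a live child of identical sequence
  repeat {
    done <- TRUE
    for (b in ids) {
      if (!alive[[b]] || kind[[b]] != "BP") next
      kids <- kids_of(b)
      kids <- kids[order(match(kids, child_order(b)))]
      hit <- kids[seqn[kids] == seqn[[b]]]
      if (length(hit) == 0L) next
      ch <- hit[[1L]]
      members[[ch]] <- c(members[[ch]], members[[b]])
      mkinds[[ch]] <- c(mkinds[[ch]], mkinds[[b]])
      for (k2 in setdiff(kids, ch)) par[[k2]] <- ch
      par[[ch]] <- par[[b]]
      alive[[b]] <- FALSE
      done <- FALSE
      break
    }
    if (done) break
  }
  # cluster: identical observed leaf siblings
  repeat {
    done <- TRUE
    live <- ids[alive]
    for (a in live) {
      if (kind[[a]] != "OBSERVED" || length(kids_of(a)) > 0L) next
      sibs <- setdiff(kids_of(par[[a]]), a)
      twin <- sibs[vapply(sibs, function(s)
        kind[[s]] == "OBSERVED" && length(kids_of(s)) == 0L &&
          seqn[[s]] == seqn[[a]], logical(1))]
      if (length(twin) == 0L) next
      first <- c(a, twin)[order(match(c(a, twin), child_order(par[[a]])))][1L]
      rest <- setdiff(c(a, twin), first)
      for (r in rest) {
        members[[first]] <- c(members[[first]], members[[r]])
        mkinds[[first]] <- c(mkinds[[first]], mkinds[[r]])
        alive[[r]] <- FALSE
      }
      done <- FALSE
      break
    }
    if (done) break
  }

  live <- ids[alive]
  nodes <- lapply(live, function(id)
    lineage_node(node_id = id, label = tree$nodes[[id]]$label,
                 kind = kind[[id]], sequence = tree$nodes[[id]]$sequence,
                 members = members[[id]], member_kinds = mkinds[[id]]))
  e <- data.frame(parent = unname(par[live][!is.na(par[live])]),
                  child = live[!is.na(par[live])], stringsAsFactors = FALSE)
  lineage_tree(nodes, e, tree$alignment_length)
}

# Canonical form ignoring labels/members order (topology + sequences +
# member sets), for isomorphism checks.
canonical_form <- function(tree, id = root_id(tree)) {
  n <- tree$nodes[[id]]
  kids <- tree$edges$child[tree$edges$parent == id]
  ks <- sort(vapply(kids, function(k) canonical_form(tree, k), character(1)))
  sprintf("(%s|%s|[%s]|{%s})", n$kind,
          toupper(chartr(".", "-", n$sequence)),
          paste(sort(n$members), collapse = ","),
          paste(ks, collapse = ","))
}

# Ground-truth events accumulated along the simulated path from ancestor
# label `from` down to descendant label `to` (exclusive of `from`).
truth_path_events <- function(truth, from, to) {
  par <- setNames(truth$edges$parent, truth$edges$child)
  out <- list()
  cur <- to
  while (cur != from) {
    ev <- truth$events[[cur]]
    if (!is.null(ev) && nrow(ev) > 0L) out[[length(out) + 1L]] <- ev
    if (!(cur %in% names(par)))
      stop(sprintf("no truth path from %s to %s", from, to))
    cur <- par[[cur]]
  }
  if (length(out) == 0L)
    return(data.frame(nt_position = integer(0), from_nt = character(0),
                      to_nt = character(0), stringsAsFactors = FALSE))
  ev <- do.call(rbind, rev(out))
  ev[order(ev$nt_position), , drop = FALSE]
}

# Events of an edge annotation reduced to the simulator's ground-truth
# columns, sorted by position.
events_core <- function(events) {
  ev <- events[order(events$nt_position),
               c("nt_position", "from_nt", "to_nt"), drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# The processed node corresponding to a truth label is the node listing
# that label among its members.
node_label_in_truth <- function(tree, id, truth_root = "UCA") {
  n <- tree$nodes[[id]]
  if (n$kind == "UCA") truth_root else n$label
}

# Verify every annotated edge of a processed tree against simulator truth.
check_edges_against_truth <- function(tree, truth, truth_root = "UCA") {
  for (k in seq_len(nrow(tree$edges))) {
    pid <- tree$edges$parent[[k]]
    cid <- tree$edges$child[[k]]
    from <- node_label_in_truth(tree, pid, truth_root)
    to <- node_label_in_truth(tree, cid, truth_root)
    want <- truth_path_events(truth, from, to)
    rownames(want) <- NULL
    got <- events_core(tree$annotations[[cid]]$events)
    expect_equal(got, want,
                 info = sprintf("edge %s -> %s", from, to))
  }
  invisible(TRUE)
}
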