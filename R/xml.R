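# Lossless XML serialization of annotated lineage trees.
#
# The schema is this package's own (version "1.0"): a <lineage_tree> root
# carrying the alignment length, a provenance block (stored as JSON text to
# round-trip arbitrary fields), an optional <region_map>, a <nodes> list in
# pre-order and an <edges> list in deterministic edge order, each edge
# optionally carrying its <annotation> with every mutation event.

XML_SCHEMA_VERSION <- "1.0"

#' Write a lineage tree to XML
#'
#' The output is byte-stable: identical trees serialize to identical files,
#' and [read_lineage_xml()] reproduces the tree — topology, sequences,
#' members, annotations, EC50 and comments — exactly.
#'
#' @param tree A `lineage_tree` (annotated or not).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_xml <- function(tree, path) {
  doc <- xml2::xml_new_root("lineage_tree",
                            schema_version = XML_SCHEMA_VERSION,
                            alignment_length = as.character(tree$alignment_length))
  prov <- xml2::xml_add_child(doc, "provenance")
  xml2::xml_text(prov) <- as.character(
    jsonlite::toJSON(tree$provenance, auto_unbox = TRUE, digits = NA,
                     null = "null", na = "null"))

  if (!is.null(tree$region_map)) {
    rm_node <- xml2::xml_add_child(doc, "region_map", name = tree$region_map$name)
    for (k in seq_len(nrow(tree$region_map$boundaries))) {
      xml2::xml_add_child(rm_node, "region",
                          name = tree$region_map$boundaries$region[[k]],
                          start = as.character(tree$region_map$boundaries$start[[k]]),
                          end = as.character(tree$region_map$boundaries$end[[k]]))
    }
    seq_node <- xml2::xml_add_child(rm_node, "uca_gapped")
    xml2::xml_text(seq_node) <- tree$region_map$uca_gapped
  }

  nodes_el <- xml2::xml_add_child(doc, "nodes")
  for (id in preorder_ids(tree)) {
    n <- tree$nodes[[id]]
    n_el <- xml2::xml_add_child(nodes_el, "node", id = n$node_id,
                                label = n$label, kind = n$kind)
    s_el <- xml2::xml_add_child(n_el, "sequence")
    xml2::xml_text(s_el) <- n$sequence
    for (k in seq_along(n$members))
      xml2::xml_add_child(n_el, "member", label = n$members[[k]],
                          kind = n$member_kinds[[k]])
    if (!is.na(n$ec50)) {
      e_el <- xml2::xml_add_child(n_el, "ec50")
      xml2::xml_text(e_el) <- n$ec50
    }
    if (!is.na(n$comment)) {
      c_el <- xml2::xml_add_child(n_el, "comment")
      xml2::xml_text(c_el) <- n$comment
    }
  }

  edges_el <- xml2::xml_add_child(doc, "edges")
  for (k in seq_len(nrow(tree$edges))) {
    cid <- tree$edges$child[[k]]
    e_el <- xml2::xml_add_child(edges_el, "edge",
                                parent = tree$edges$parent[[k]], child = cid)
    ann <- tree$annotations[[cid]]
    if (!is.null(ann)) {
      a_el <- xml2::xml_add_child(e_el, "annotation",
                                  nt_count = as.character(ann$nt_count),
                                  aa_count = as.character(ann$aa_count),
                                  r_count = as.character(ann$r_count),
                                  s_count = as.character(ann$s_count),
                                  untallied = as.character(ann$untallied),
                                  untranslatable = as.character(ann$untranslatable))
      ev <- ann$events
      for (j in seq_len(nrow(ev))) {
        xml2::xml_add_child(a_el, "event",
                            nt_position = as.character(ev$nt_position[[j]]),
                            from_nt = ev$from_nt[[j]], to_nt = ev$to_nt[[j]],
                            codon_index = as.character(ev$codon_index[[j]]),
                            from_codon = ev$from_codon[[j]],
                            to_codon = ev$to_codon[[j]],
                            from_aa = ev$from_aa[[j]], to_aa = ev$to_aa[[j]],
                            rs_class = ev$rs_class[[j]],
                            region = if (is.na(ev$region[[j]])) "NA" else ev$region[[j]],
                            aa_label = ev$aa_label[[j]])
      }
      for (j in seq_len(nrow(ann$region_tally))) {
        xml2::xml_add_child(a_el, "region_tally",
                            region = ann$region_tally$region[[j]],
                            R = as.character(ann$region_tally$R[[j]]),
                            S = as.character(ann$region_tally$S[[j]]))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a lineage tree from XML
#'
#' @param path Path to a file written by [write_lineage_xml()].
#' @return The reconstructed `lineage_tree`.
#' @export
read_lineage_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    fatal("malformed XML in '%s': %s", path, conditionMessage(e)))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "lineage_tree")
    fatal("'%s' is not a lineage-tree XML document", path)
  ver <- xml2::xml_attr(root, "schema_version")
  if (!identical(ver, XML_SCHEMA_VERSION))
    fatal("XML schema version mismatch: file has '%s', this build reads '%s'",
          ver, XML_SCHEMA_VERSION)

  provenance <- jsonlite::fromJSON(
    xml2::xml_text(xml2::xml_find_first(root, "./provenance")),
    simplifyDataFrame = TRUE)

  map <- NULL
  rm_el <- xml2::xml_find_first(root, "./region_map")
  if (!inherits(rm_el, "xml_missing")) {
    ends <- as.integer(xml2::xml_attr(xml2::xml_find_all(rm_el, "./region"), "end"))
    map <- region_map(ends,
                      uca_gapped = xml2::xml_text(xml2::xml_find_first(rm_el, "./uca_gapped")),
                      name = xml2::xml_attr(rm_el, "name"))
  }

  node_els <- xml2::xml_find_all(root, "./nodes/node")
  nodes <- lapply(node_els, function(n_el) {
    mem_els <- xml2::xml_find_all(n_el, "./member")
    ec_el <- xml2::xml_find_first(n_el, "./ec50")
    co_el <- xml2::xml_find_first(n_el, "./comment")
    lineage_node(
      node_id = xml2::xml_attr(n_el, "id"),
      label = xml2::xml_attr(n_el, "label"),
      kind = xml2::xml_attr(n_el, "kind"),
      sequence = xml2::xml_text(xml2::xml_find_first(n_el, "./sequence")),
      members = xml2::xml_attr(mem_els, "label"),
      member_kinds = xml2::xml_attr(mem_els, "kind"),
      ec50 = if (inherits(ec_el, "xml_missing")) NA_character_ else xml2::xml_text(ec_el),
      comment = if (inherits(co_el, "xml_missing")) NA_character_ else xml2::xml_text(co_el))
  })

  edge_els <- xml2::xml_find_all(root, "./edges/edge")
  edges <- data.frame(parent = xml2::xml_attr(edge_els, "parent"),
                      child = xml2::xml_attr(edge_els, "child"),
                      stringsAsFactors = FALSE)

  al <- as.integer(xml2::xml_attr(root, "alignment_length"))
  tree <- lineage_tree(nodes, edges, alignment_length = al,
                       region_map = map, provenance = provenance)

  for (e_el in edge_els) {
    a_el <- xml2::xml_find_first(e_el, "./annotation")
    if (inherits(a_el, "xml_missing")) next
    ev_els <- xml2::xml_find_all(a_el, "./event")
    events <- data.frame(
      nt_position = as.integer(xml2::xml_attr(ev_els, "nt_position")),
      from_nt = xml2::xml_attr(ev_els, "from_nt"),
      to_nt = xml2::xml_attr(ev_els, "to_nt"),
      codon_index = as.integer(xml2::xml_attr(ev_els, "codon_index")),
      from_codon = xml2::xml_attr(ev_els, "from_codon"),
      to_codon = xml2::xml_attr(ev_els, "to_codon"),
      from_aa = xml2::xml_attr(ev_els, "from_aa"),
      to_aa = xml2::xml_attr(ev_els, "to_aa"),
      rs_class = xml2::xml_attr(ev_els, "rs_class"),
      region = xml2::xml_attr(ev_els, "region"),
      aa_label = xml2::xml_attr(ev_els, "aa_label"),
      stringsAsFactors = FALSE)
    events$region[events$region == "NA"] <- NA_character_
    rt_els <- xml2::xml_find_all(a_el, "./region_tally")
    region_tally <- data.frame(region = xml2::xml_attr(rt_els, "region"),
                               R = as.integer(xml2::xml_attr(rt_els, "R")),
                               S = as.integer(xml2::xml_attr(rt_els, "S")),
                               stringsAsFactors = FALSE)
    iattr <- function(a) as.integer(xml2::xml_attr(a_el, a))
    tree$annotations[[xml2::xml_attr(e_el, "child")]] <-
      structure(list(nt_count = iattr("nt_count"), aa_count = iattr("aa_count"),
                     r_count = iattr("r_count"), s_count = iattr("s_count"),
                     events = events, region_tally = region_tally,
                     untallied = iattr("untallied"),
                     untranslatable = iattr("untranslatable")),
                class = "edge_annotation")
  }
  tree
}
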