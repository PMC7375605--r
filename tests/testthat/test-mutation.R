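# Region maps, R/S classification, edge diffs, position labels.

fixture_region_map <- function(len = 360) {
  ends <- c(78, 114, 165, 195, 312, 360)
  region_map(ends, uca_gapped = strrep("A", len))
}

# Two in-frame 360 nt sequences differing only at alignment position 92:
# codon 31 AGT (Ser) in the parent, AAT (Asn) in the child.
worked_example_pair <- function() {
  base <- strrep("GCT", 120)                     # Ala codons, no gaps
  parent <- paste0(substr(base, 1, 90), "AGT", substr(base, 94, 360))
  child <- paste0(substr(base, 1, 90), "AAT", substr(base, 94, 360))
  list(parent = parent, child = child)
}

test_that("the region FASTA header defines inclusive 1-based region ends", {
  p <- file.path(withr::local_tempdir(), "uca.fasta")
  writeLines(c(">UCA 78 114 165 195 312 360", strrep("ACGTAC", 60)), p)
  map <- parse_region_fasta(p)
  expect_equal(map$boundaries$region,
               c("FW1", "CDR1", "FW2", "CDR2", "FW3", "CDR3"))
  expect_equal(map$boundaries$start[2], 79)
  expect_equal(map$boundaries$end[2], 114)
  expect_equal(region_of_position(92, map), "CDR1")
  expect_equal(region_of_position(1, map), "FW1")
  expect_equal(region_of_position(78, map), "FW1")   # inclusive end
  expect_equal(region_of_position(79, map), "CDR1")
  expect_error(region_of_position(0, map), "range")
  expect_error(region_of_position(361, map), "range")
})

test_that("malformed region headers are rejected", {
  d <- withr::local_tempdir()
  w <- function(lines) { p <- file.path(d, "r.fasta"); writeLines(lines, p); p }
  expect_error(parse_region_fasta(w(c(">U 10 9 20 30 40 50", strrep("A", 60)))),
               "increasing")
  expect_error(parse_region_fasta(w(c(">U 10 20 30", strrep("A", 60)))),
               "6 or 7")
  expect_error(parse_region_fasta(w(c(">U 10 20 30 40 50 70", strrep("A", 60)))),
               "exceeds")
  expect_error(parse_region_fasta(w(c(">U1 10 20 30 40 50 60", "AAA",
                                      ">U2 10 20 30 40 50 60", "AAA"))),
               "exactly one record")
})

test_that("a 7-region header adds FW4", {
  map <- region_map(c(10, 20, 30, 40, 50, 55, 60), strrep("A", 60))
  expect_equal(map$boundaries$region[7], "FW4")
  expect_equal(region_of_position(58, map), "FW4")
})

test_that("replacement/silent classification follows the genetic code", {
  expect_equal(classify_rs("AGT", "AAT"), "R")   # Ser -> Asn
  expect_equal(classify_rs("GCT", "GCC"), "S")   # Ala -> Ala
  expect_equal(classify_rs("TGG", "TGA"), "R")   # Trp -> stop
  expect_error(classify_rs("AG-", "AAT"), "codon")
  expect_error(classify_rs("AGN", "AAT"), "codon")
})

test_that("a substitution at position 92 maps to amino-acid position 31", {
  pr <- worked_example_pair()
  ann <- diff_edge(pr$parent, pr$child, map = fixture_region_map())
  expect_equal(ann$nt_count, 1L)
  ev <- ann$events
  expect_equal(ev$nt_position, 92L)
  expect_equal(ev$from_nt, "G")
  expect_equal(ev$to_nt, "A")
  expect_equal(ev$codon_index, 31L)
  expect_equal(ev$from_aa, "S")
  expect_equal(ev$to_aa, "N")
  expect_equal(ev$rs_class, "R")
  expect_equal(ev$region, "CDR1")
  expect_equal(ev$aa_label, "31")
})

test_that("identical sequences produce an empty annotation", {
  pr <- worked_example_pair()
  ann <- diff_edge(pr$parent, pr$parent)
  expect_equal(ann$nt_count, 0L)
  expect_equal(ann$aa_count, 0L)
  expect_equal(nrow(ann$events), 0)
  expect_equal(ann$untallied, 0L)
})

test_that("gap and N positions are excluded from events but counted", {
  # codon-sized deletion (IMGT-style) plus one substitution
  ann <- diff_edge("AAAACGTTT", "---ACGTTA")
  expect_equal(ann$nt_count, 1L)       # only T->A at position 9
  expect_equal(ann$untallied, 3L)      # A vs gap at positions 1-3
  expect_equal(ann$events$from_codon, "TTT")
  expect_equal(ann$events$to_codon, "TTA")
  ann2 <- diff_edge("ACGTTT", "NCGTTT")
  expect_equal(ann2$nt_count, 0L)
  expect_equal(ann2$untallied, 1L)
})

test_that("substitutions whose codon context is untranslatable are tallied apart", {
  # position 3 differs, but the shared codon holds an N
  ann <- diff_edge("ANGTTT", "ANATTT")
  expect_equal(ann$nt_count, 0L)
  expect_equal(ann$untranslatable, 1L)
})

test_that("length mismatch is fatal", {
  expect_error(diff_edge("ACGT", "ACG"), "length")
})

test_that("inserting a shared gap column shifts positions but not codon effects", {
  pr <- worked_example_pair()
  gapped <- function(s) paste0(substr(s, 1, 30), "---", substr(s, 31, 360))
  a1 <- diff_edge(pr$parent, pr$child)
  a2 <- diff_edge(gapped(pr$parent), gapped(pr$child))
  expect_equal(a2$events$nt_position, a1$events$nt_position + 3L)
  cols <- c("codon_index", "from_aa", "to_aa", "rs_class")
  expect_equal(a2$events[cols], a1$events[cols])
})

test_that("amino-acid labels default to absolute and honor a numbering map", {
  expect_equal(aa_position_label(31), "31")
  expect_equal(aa_position_label(31, c("31" = "31")), "31")
  expect_equal(aa_position_label(53, c("52" = "52", "53" = "52a")), "52a")
  expect_warning(out <- aa_position_label(7, c("1" = "1")), "absolute")
  expect_equal(out, "7")
})

test_that("a numbering map TSV round-trips through the labeller", {
  p <- file.path(withr::local_tempdir(), "map.tsv")
  writeLines(c("index\tlabel", "52\t52", "53\t52a"), p)
  nm <- read_numbering_map(p)
  expect_equal(aa_position_label(53, nm), "52a")
})

test_that("annotate_tree covers every edge and reconciles its tallies", {
  sim <- simulate_lineage(seed = 12, n_leaves = 6, uca_length = 90)
  tr <- annotate_tree(process_lineage(sim$tree),
                      map = region_map(c(18, 30, 42, 51, 78, 90),
                                       strrep("A", 90)))
  expect_length(tr$annotations, nrow(tr$edges))
  for (ann in tr$annotations) {
    expect_equal(ann$nt_count, nrow(ann$events))
    expect_equal(ann$r_count + ann$s_count, ann$nt_count)
    expect_equal(sum(ann$region_tally$R), ann$r_count)
    expect_equal(sum(ann$region_tally$S), ann$s_count)
    expect_lte(ann$aa_count, ann$r_count)
  }
})

test_that("a star tree gets one annotation per leaf independent of order", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAATTT"),
         list("a", "IgA", "OBSERVED", "AAGTTT"),
         list("b", "IgB", "OBSERVED", "AACTTT"),
         list("c", "IgC", "OBSERVED", "AAATTA")),
    list(c("u", "a"), c("u", "b"), c("u", "c")))
  ann <- annotate_tree(tr)
  expect_length(ann$annotations, 3)
  rev_tr <- make_tree(
    list(list("u", "UCA", "UCA", "AAATTT"),
         list("c", "IgC", "OBSERVED", "AAATTA"),
         list("b", "IgB", "OBSERVED", "AACTTT"),
         list("a", "IgA", "OBSERVED", "AAGTTT")),
    list(c("u", "c"), c("u", "b"), c("u", "a")))
  ann2 <- annotate_tree(rev_tr)
  for (id in c("a", "b", "c"))
    expect_equal(ann2$annotations[[id]], ann$annotations[[id]])
})

test_that("path events union equals the direct UCA-to-leaf diff", {
  for (seed in c(3, 13)) {
    sim <- simulate_lineage(seed = seed, n_leaves = 8, uca_length = 90)
    tr <- annotate_tree(process_lineage(sim$tree))
    r <- root_id(tr)
    for (lf in iglineage:::leaf_ids(tr)) {
      path_ev <- list()
      cur <- lf
      while (cur != r) {
        path_ev[[length(path_ev) + 1L]] <- tr$annotations[[cur]]$events
        cur <- iglineage:::parent_of(tr, cur)
      }
      path_ev <- do.call(rbind, rev(path_ev))
      direct <- diff_edge(tr$nodes[[r]]$sequence, tr$nodes[[lf]]$sequence)
      expect_equal(events_core(path_ev), events_core(direct$events))
    }
  }
})
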