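# Serialization: XML round trip, alignment TSV, selection FASTA, JSON, SVG.

annotated_fixture <- function(seed = 7, n_leaves = 5, len = 90) {
  sim <- simulate_lineage(seed = seed, n_leaves = n_leaves, uca_length = len,
                          duplicate_leaf_rate = 0.2)
  tr <- process_lineage(sim$tree)
  tr$region_map <- region_map(round(c(78, 114, 165, 195, 312, 360) / 360 * len),
                              uca_gapped = tr$nodes[[root_id(tr)]]$sequence)
  annotate_tree(tr)
}

test_that("XML write/read is the identity and byte-stable", {
  d <- withr::local_tempdir()
  for (seed in c(1, 7, 21)) {
    tr <- annotated_fixture(seed)
    tr$nodes[[iglineage:::leaf_ids(tr)[1]]]$ec50 <- "12.5 ng/ml"
    tr$nodes[[iglineage:::leaf_ids(tr)[1]]]$comment <- "potent neutralizer"
    p1 <- file.path(d, sprintf("t%d.xml", seed))
    p2 <- file.path(d, sprintf("t%d_again.xml", seed))
    write_lineage_xml(tr, p1)
    back <- read_lineage_xml(p1)
    expect_equal(canonical_form(back), canonical_form(tr))
    expect_equal(back$annotations[names(tr$annotations)], tr$annotations)
    expect_equal(back$alignment_length, tr$alignment_length)
    expect_equal(back$region_map$boundaries, tr$region_map$boundaries)
    n1 <- back$nodes[[iglineage:::leaf_ids(back)[1]]]
    expect_equal(n1$ec50, "12.5 ng/ml")
    expect_equal(n1$comment, "potent neutralizer")
    write_lineage_xml(tr, p2)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("truncated or version-mismatched XML is fatal", {
  d <- withr::local_tempdir()
  tr <- annotated_fixture()
  p <- file.path(d, "t.xml")
  write_lineage_xml(tr, p)
  full <- readLines(p)
  writeLines(full[1:(length(full) %/% 2)], file.path(d, "trunc.xml"))
  expect_error(read_lineage_xml(file.path(d, "trunc.xml")), "malformed|XML")
  bad <- sub('schema_version="1.0"', 'schema_version="9.9"', full)
  writeLines(bad, file.path(d, "vers.xml"))
  expect_error(read_lineage_xml(file.path(d, "vers.xml")), "version")
})

test_that("the nucleotide alignment TSV has the UCA first and a full ruler", {
  d <- withr::local_tempdir()
  tr <- annotated_fixture()
  p <- file.path(d, "a.tsv")
  write_alignment_tsv(tr, p)
  rows <- strsplit(readLines(p), "\t", fixed = TRUE)
  expect_equal(length(unique(lengths(rows))), 1)     # constant column count
  expect_equal(rows[[2]][1], "REGION")
  ruler <- rows[[2]][-(1:2)]
  expect_length(ruler, tr$alignment_length)          # spans sum to length
  expect_equal(rows[[3]][1], tr$nodes[[root_id(tr)]]$label)  # UCA first
  expect_equal(length(rows), 2 + length(tr$nodes))
})

test_that("the protein alignment TSV shows the worked-example substitution", {
  base <- strrep("GCT", 120)
  parent <- paste0(substr(base, 1, 90), "AGT", substr(base, 94, 360))
  child <- paste0(substr(base, 1, 90), "AAT", substr(base, 94, 360))
  tr <- make_tree(
    list(list("u", "UCA", "UCA", parent),
         list("a", "IgA", "OBSERVED", child),
         list("b", "IgB", "OBSERVED", child)),
    list(c("u", "a"), c("u", "b")))
  tr$region_map <- region_map(c(78, 114, 165, 195, 312, 360), parent)
  tr <- annotate_tree(tr)
  p <- file.path(withr::local_tempdir(), "p.tsv")
  write_alignment_tsv(tr, p, mode = "protein")
  rows <- strsplit(readLines(p), "\t", fixed = TRUE)
  col31 <- 2 + 31
  expect_equal(rows[[3]][col31], "S")          # UCA lane
  expect_equal(rows[[4]][col31], "N")          # descendants
  expect_equal(rows[[5]][col31], "N")
  expect_equal(rows[[2]][col31], "CDR1")
})

test_that("an out-of-frame translation warns and marks the partial codon X", {
  tr <- make_tree(
    list(list("u", "UCA", "UCA", "GCTGC"),
         list("a", "IgA", "OBSERVED", "GCCGC")),
    list(c("u", "a")))
  p <- file.path(withr::local_tempdir(), "p.tsv")
  expect_warning(write_alignment_tsv(tr, p, mode = "protein"), "multiple of 3")
  rows <- strsplit(readLines(p), "\t", fixed = TRUE)
  expect_equal(rows[[3]][length(rows[[3]])], "X")
})

test_that("the selection FASTA lists the germline first and expands clusters", {
  tr <- annotated_fixture(seed = 9)
  p <- file.path(withr::local_tempdir(), "b.fasta")
  write_baseline_fasta(tr, p)
  lines <- readLines(p)
  expect_true(startsWith(lines[1], ">>"))
  headers <- grep("^>", lines, value = TRUE)
  n_obs_members <- sum(unlist(lapply(tr$nodes, function(n)
    n$member_kinds == "OBSERVED")))
  expect_length(headers, 1 + n_obs_members)
  seqs <- lines[!startsWith(lines, ">")]
  expect_equal(unique(nchar(seqs)), tr$alignment_length)

  no_map <- tr
  no_map$region_map <- NULL
  expect_error(write_baseline_fasta(no_map, p), "region FASTA")
})

test_that("selection results load from the documented layout", {
  sample <- system.file("extdata", "baseline_output_synthetic.tsv",
                        package = "iglineage")
  out <- load_baseline_output(sample)
  expect_equal(out$region, c("CDR", "FW"))
  expect_equal(out$sigma, c(1.42, -0.38))
  expect_equal(out$ci_lower, c(0.55, -0.91))

  d <- withr::local_tempdir()
  writeLines(character(0), file.path(d, "empty.tsv"))
  expect_error(load_baseline_output(file.path(d, "empty.tsv")), "empty|read")
  writeLines(c("foo\tbar", "1\t2"), file.path(d, "odd.tsv"))
  expect_error(load_baseline_output(file.path(d, "odd.tsv")), "unrecognized")

  tr <- annotated_fixture()
  tr <- attach_baseline_summary(tr, out)
  p <- file.path(d, "t.xml")
  write_lineage_xml(tr, p)
  back <- read_lineage_xml(p)
  expect_equal(back$provenance$baseline$sigma, out$sigma)
})

test_that("the JSON dump is valid and complete", {
  d <- withr::local_tempdir()
  tr <- annotated_fixture()
  p <- file.path(d, "t.json")
  write_lineage_json(tr, p)
  obj <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_equal(length(obj$nodes), length(tr$nodes))
  expect_equal(length(obj$edges), nrow(tr$edges))
  expect_equal(obj$alignment_length, tr$alignment_length)
})

test_that("SVG rendering labels every edge with the nt (aa) pattern", {
  d <- withr::local_tempdir()
  tr <- annotated_fixture()
  p <- file.path(d, "t.svg")
  render_tree(tr, p)
  svg <- readLines(p)
  hits <- grep(">[0-9]+ \\([0-9]+\\)<", svg)
  expect_length(hits, nrow(tr$edges))

  single <- make_tree(list(list("u", "UCA", "UCA", "AAA")), list())
  render_tree(single, file.path(d, "s.svg"))
  expect_true(any(grepl("circle", readLines(file.path(d, "s.svg")))))

  tr$nodes[[iglineage:::leaf_ids(tr)[1]]]$ec50 <- "7.7 ng/ml"
  render_tree(tr, file.path(d, "e.svg"))
  expect_true(any(grepl("EC50 7.7 ng/ml", readLines(file.path(d, "e.svg")),
                        fixed = TRUE)))

  expect_error(render_tree(tr, file.path(d, "t.bmp")), "svg, png, eps")
})

test_that("EPS rendering produces a PostScript file", {
  d <- withr::local_tempdir()
  tr <- annotated_fixture()
  p <- file.path(d, "t.eps")
  render_tree(tr, p)
  expect_true(file.exists(p))
  expect_match(readLines(p, n = 1), "%!PS")
})
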