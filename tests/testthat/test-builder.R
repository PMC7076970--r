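simple_gene_info <- function(symbols, taxon = 9606L) {
  data.frame(taxon = taxon, gene_id = seq_along(symbols), symbol = symbols,
             synonyms = "", stringsAsFactors = FALSE)
}

simple_ann <- function(genes, terms, taxon = 9606L) {
  data.frame(gene_key = genes, term_id = terms, qualifier = "",
             evidence_code = "IEA", taxon = taxon, excluded = FALSE,
             stringsAsFactors = FALSE)
}

test_that("GO annotations propagate up chains and union at shared roots", {
  ont <- parse_obo(obo_chain())
  lib <- build_go_library(ont, simple_ann("g1", "C"),
                          simple_gene_info(c("g1", "g2")), 9606)
  expect_equal(lib$term_genes, list(A = "g1", B = "g1", C = "g1"))
  expect_equal(unname(lib$term_category["C"]), "biological_process")

  # two genes on sibling terms: the shared root gets their union
  sib <- parse_obo(c("[Term]", "id: R",
                     "[Term]", "id: S1", "is_a: R",
                     "[Term]", "id: S2", "is_a: R"))
  lib2 <- build_go_library(sib, simple_ann(c("g1", "g2"), c("S1", "S2")),
                           simple_gene_info(c("g1", "g2")), 9606)
  expect_equal(lib2$term_genes$R, c("g1", "g2"))
})

test_that("builder drops NOT-qualified, evidence-excluded and off-universe annotations", {
  ont <- parse_obo(obo_chain())
  ann <- simple_ann(c("g1", "g2", "g3", "gX"), c("C", "C", "B", "B"))
  ann$excluded[2] <- TRUE
  ann$evidence_code[3] <- "IEA"
  gi <- simple_gene_info(c("g1", "g2", "g3"))
  lib <- suppressMessages(
    build_go_library(ont, ann, gi, 9606, evidence_exclude = "ND"))
  expect_setequal(lib$term_genes$C, c("g1"))
  expect_setequal(lib$term_genes$B, c("g1", "g3"))
  st <- attr(lib, "build_stats")
  expect_equal(st$not_excluded, 1L)
  expect_equal(st$off_universe, 1L)

  # excluding the only evidence code present leaves nothing to build
  expect_error(build_go_library(ont, simple_ann("g1", "C"), gi, 9606,
                                evidence_exclude = "IEA"),
               "no annotations survive")
})

test_that("unknown and obsolete annotation terms are counted, not fatal", {
  ont <- parse_obo(c(obo_chain(), "[Term]", "id: OBS", "is_obsolete: true"))
  ann <- simple_ann(c("g1", "g1", "g1"), c("C", "GHOST:1", "OBS"))
  lib <- suppressMessages(
    build_go_library(ont, ann, simple_gene_info("g1"), 9606))
  st <- attr(lib, "build_stats")
  expect_equal(st$unknown_term, 1L)
  expect_equal(st$obsolete_term, 1L)
  expect_setequal(names(lib$term_genes), c("A", "B", "C"))
})

test_that("numeric gene ids and synonyms resolve to official symbols", {
  ont <- parse_obo(obo_chain())
  gi <- data.frame(taxon = 9606L, gene_id = c(10L, 20L),
                   symbol = c("ALPHA", "BETA"),
                   synonyms = c("A0", ""), stringsAsFactors = FALSE)
  ann <- simple_ann(c("10", "A0", "BETA"), c("C", "B", "B"))
  lib <- build_go_library(ont, ann, gi, 9606)
  expect_equal(lib$term_genes$C, "ALPHA")
  expect_setequal(lib$term_genes$B, c("ALPHA", "BETA"))
})

test_that("build_go_library matches the per-gene naive-DFS oracle on random fixtures", {
  for (seed in 1:25) {
    inp <- random_build_inputs(seed, n_genes = sample(10:50, 1),
                               n_terms = sample(5:15, 1))
    lib <- build_go_library(inp$ontology, inp$annotations, inp$gene_info, 9606)
    oracle <- naive_go_build(inp$ontology, inp$annotations)
    expect_identical(lib$term_genes, oracle)
    # parent-superset monotonicity on every propagation edge
    for (id in names(lib$term_genes)) {
      t <- inp$ontology$terms[[id]]
      for (p in c(t$is_a, t$part_of)) {
        expect_true(all(lib$term_genes[[id]] %in% lib$term_genes[[p]]))
      }
    }
  }
})

test_that("building twice from identical inputs yields equal libraries", {
  inp <- random_build_inputs(99)
  l1 <- build_go_library(inp$ontology, inp$annotations, inp$gene_info, 9606)
  l2 <- build_go_library(inp$ontology, inp$annotations, inp$gene_info, 9606)
  attr(l1, "build_stats") <- attr(l2, "build_stats") <- NULL
  expect_identical(l1, l2)
})

test_that("flat libraries de-duplicate, filter off-universe genes and prune empty terms", {
  gi <- simple_gene_info(c("G1", "G2", "G3"))
  pairs <- data.frame(term_id = c("P1", "P1", "P1", "P2"),
                      gene_key = c("G1", "G1", "G2", "G3"),
                      stringsAsFactors = FALSE)
  lib <- build_flat_library(pairs, c(P1 = "one", P2 = "two"), "KEGG", gi, 9606)
  expect_equal(sum(lengths(lib$term_genes)), 3)  # one duplicate removed

  pairs2 <- data.frame(term_id = c("P1", "P2"), gene_key = c("G1", "GHOST"),
                       stringsAsFactors = FALSE)
  lib2 <- suppressMessages(
    build_flat_library(pairs2, c(P1 = "one", P2 = "two"), "KEGG", gi, 9606))
  expect_equal(attr(lib2, "build_stats")$off_universe, 1L)
  expect_false("P2" %in% names(lib2$term_genes))  # emptied, pruned

  expect_error(build_flat_library(pairs, c(P1 = "one"), "KEGG", gi, 9606),
               "no name: P2")
})

test_that("flat-library totals match a hand construction on a seeded fixture", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:20)
  gi <- simple_gene_info(genes[1:15])  # 5 genes off-universe
  pairs <- data.frame(term_id = sprintf("P%02d", sample.int(10, 50, TRUE)),
                      gene_key = genes[sample.int(20, 50, TRUE)],
                      stringsAsFactors = FALSE)
  nm <- stats::setNames(paste("pathway", 1:10), sprintf("P%02d", 1:10))
  lib <- suppressMessages(build_flat_library(pairs, nm, "Reactome", gi, 9606))
  # hand construction
  uniq <- unique(pairs)
  uniq <- uniq[uniq$gene_key %in% gi$symbol, ]
  expected <- lapply(split(uniq$gene_key, uniq$term_id), function(g) sort(g))
  expected <- expected[lengths(expected) > 0]
  expect_identical(lib$term_genes, expected)
})

test_that("disease channels merge to non-redundant pairs with provenance", {
  ch <- function(terms, genes) data.frame(term_id = terms, gene_key = genes,
                                          stringsAsFactors = FALSE)
  # same pair in two channels: one pair, two labels
  m <- merge_disease_channels(list(tm = ch("D1", "G1"), kn = ch("D1", "G1")))
  expect_equal(nrow(m), 1)
  expect_equal(m$channels, "kn|tm")

  # disjoint channels of sizes 2, 3, 4: 9 pairs
  m2 <- merge_disease_channels(list(
    a = ch(rep("D1", 2), c("G1", "G2")),
    b = ch(rep("D2", 3), c("G1", "G2", "G3")),
    c = ch(rep("D3", 4), c("G1", "G2", "G3", "G4"))))
  expect_equal(nrow(m2), 9)

  # overlapping fixture: inclusion-exclusion 4 + 4 - 2 = 6
  m3 <- merge_disease_channels(list(
    a = ch(rep("D1", 4), c("G1", "G2", "G3", "G4")),
    b = ch(rep("D1", 4), c("G3", "G4", "G5", "G6"))))
  expect_equal(nrow(m3), 6)
  expect_equal(sum(m3$channels == "a|b"), 2)

  expect_equal(nrow(merge_disease_channels(list())), 0)
})

test_that("make_species_db validates inputs up front and writes per-database files", {
  fx <- generate_fixture(fixture_spec(seed = 5), withr::local_tempdir())
  out <- withr::local_tempdir()
  written <- suppressMessages(make_species_db(fx$paths$config, out))
  expect_setequal(names(written), c("GO", "KEGG", "DISEASES", "DisGeNET"))
  expect_true(all(file.exists(unlist(written))))
  expect_true(file.exists(file.path(out, "build_report.txt")))
  report <- readLines(file.path(out, "build_report.txt"))
  expect_length(report, 4)

  # GO-only manifest: exactly one library file
  out2 <- withr::local_tempdir()
  w2 <- suppressMessages(make_species_db(
    list(taxon = 9606, gene_info = fx$paths$gene_info,
         go.obo = fx$paths$obo, go.gaf = fx$paths$gaf), out2))
  expect_equal(names(w2), "GO")

  # missing input: error before anything is written
  out3 <- withr::local_tempdir()
  expect_error(make_species_db(
    list(taxon = 9606, gene_info = fx$paths$gene_info,
         go.obo = "no/such/file.obo", go.gaf = fx$paths$gaf), out3),
    "missing input")
  expect_length(list.files(out3), 0)
})

test_that("rebuilding with identical inputs gives identical libraries (timestamp aside)", {
  fx <- generate_fixture(fixture_spec(seed = 6), withr::local_tempdir())
  cfg <- list(taxon = 9606, gene_info = fx$paths$gene_info,
              go.obo = fx$paths$obo, go.gaf = fx$paths$gaf)
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  suppressMessages(make_species_db(cfg, o1))
  suppressMessages(make_species_db(cfg, o2))
  l1 <- readLines(file.path(o1, "GO.library.tsv"))
  l2 <- readLines(file.path(o2, "GO.library.tsv"))
  expect_identical(l1[!startsWith(l1, "# built:")],
                   l2[!startsWith(l2, "# built:")])
})
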