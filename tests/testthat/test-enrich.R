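# a small hand-built library used across these tests
toy_library <- function() {
  species_library(
    database = "custom", taxon = 9606,
    term_genes = list(TA = sprintf("G%02d", 1:6),
                      TB = sprintf("G%02d", 5:14),
                      TC = sprintf("G%02d", 11:30),
                      TD = sprintf("G%02d", 1:2)),   # below min size
    term_names = c(TA = "term A", TB = "term B", TC = "term C", TD = "term D"),
    term_category = c(TA = "custom", TB = "custom", TC = "custom",
                      TD = "custom"),
    universe = sprintf("G%02d", 1:50))
}

test_that("background resolution: default universe, subset, unknown symbols", {
  lib <- toy_library()
  bg <- resolve_background(lib)
  expect_length(bg, 50)
  expect_equal(attr(bg, "dropped"), 0L)

  bg2 <- resolve_background(lib, sprintf("G%02d", 1:30))
  expect_length(bg2, 30)

  user <- c(sprintf("G%02d", 1:47), "NOPE1", "NOPE2", "NOPE3")
  bg3 <- suppressMessages(resolve_background(lib, user))
  expect_length(bg3, 47)
  expect_equal(attr(bg3, "dropped"), 3L)

  expect_error(resolve_background(lib, c("NOPE1", "NOPE2")),
               "no user background gene")
  expect_error(resolve_background(lib, c(" ", "")), "empty")
})

test_that("enrich counts, filters by size, sorts by (p, term_id) and flags q", {
  lib <- toy_library()
  tab <- enrich(sprintf("G%02d", 1:6), lib, min_term_size = 3)
  expect_s3_class(tab, "enrich_table")
  expect_false("TD" %in% tab$term_id)            # below min_term_size
  expect_equal(attr(tab, "background_size"), 50)
  expect_equal(attr(tab, "query_used"), 6)
  expect_equal(tab$term_id[1], "TA")             # query == TA exactly
  ra <- tab[tab$term_id == "TA", ]
  expect_equal(ra$k, 6); expect_equal(ra$K, 6)
  expect_equal(ra$p_value, hypergeom_upper_tail(6, 6, 6, 50),
               tolerance = 1e-12)
  expect_equal(ra$genes, paste(sprintf("G%02d", 1:6), collapse = ";"))
  expect_true(!is.unsorted(tab$p_value))
})

test_that("a query equal to a small specific term attains the minimum p", {
  lib <- toy_library()
  tab <- enrich(sprintf("G%02d", 1:6), lib)
  expect_equal(which(tab$term_id == "TA"), 1L)
  expect_true(all(tab$p_value >= tab$p_value[1]))
})

test_that("fold enrichment is exactly 1 when the query hits a term at the background rate", {
  lib <- species_library(
    "custom", 9606, list(T1 = sprintf("G%02d", 1:10)), c(T1 = "t"),
    c(T1 = "custom"), sprintf("G%02d", 1:50))
  # n = 5, k = 1: k/n = 1/5 = K/N = 10/50
  tab <- enrich(c("G01", sprintf("G%02d", 30:33)), lib)
  expect_equal(tab$fold_enrichment, 1)
})

test_that("query and term sets are restricted to a user background consistently", {
  lib <- toy_library()
  bg <- sprintf("G%02d", 1:20)
  tab <- suppressMessages(
    enrich(c("G01", "G05", "G12", "G40"), lib, background = bg))
  expect_equal(attr(tab, "background_size"), 20)
  expect_equal(attr(tab, "query_used"), 3)            # G40 outside bg
  expect_equal(attr(tab, "query_dropped"), "G40")
  # TC has 20 genes but only 10 inside the background
  expect_equal(tab$K[tab$term_id == "TC"], 10)
  expect_true(all(tab$N == 20))
})

test_that("empty query-background overlap and empty tested family are errors", {
  lib <- toy_library()
  expect_error(suppressMessages(enrich("NOPE", lib)), "query")
  expect_error(enrich("G01", lib, min_term_size = 40),
               "size window \\[40, 5000\\]")
})

test_that("duplicate query entries collapse with a reported count", {
  lib <- toy_library()
  expect_message(tab <- enrich(c("G01", "G01", " G02", "G03"), lib),
                 "1 duplicate")
  expect_equal(attr(tab, "query_used"), 3)
})

test_that("term order permutation changes no p or q value", {
  lib <- toy_library()
  perm <- lib
  idx <- c(3, 1, 4, 2)
  perm$term_genes <- perm$term_genes[idx]
  perm$term_names <- perm$term_names[idx]
  perm$term_category <- perm$term_category[idx]
  class(perm) <- "species_library"
  t1 <- enrich(sprintf("G%02d", c(1:4, 12, 13)), lib)
  t2 <- enrich(sprintf("G%02d", c(1:4, 12, 13)), perm)
  expect_identical(t1$term_id, t2$term_id)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$q_value, t2$q_value)
})

test_that("size filters change the correction family exactly as recomputing BH", {
  lib <- toy_library()
  q <- sprintf("G%02d", c(1:4, 12, 13))
  full <- enrich(q, lib, min_term_size = 3)
  reduced <- enrich(q, lib, min_term_size = 7)   # drops TA (6 genes)
  expect_false("TA" %in% reduced$term_id)
  keep <- full$term_id %in% reduced$term_id
  manual_q <- adjust_pvalues(full$p_value[keep], "BH")
  expect_equal(reduced$q_value[match(full$term_id[keep], reduced$term_id)],
               manual_q, tolerance = 1e-12)
})

test_that("fisher and hypergeometric methods give identical tables", {
  lib <- toy_library()
  q <- sprintf("G%02d", c(1:5, 20))
  tf <- enrich(q, lib, method = "fisher")
  th <- enrich(q, lib, method = "hypergeometric")
  expect_equal(tf$p_value, th$p_value, tolerance = 1e-12)
  expect_identical(tf$term_id, th$term_id)
})

test_that("null queries reject at close to the exact attainable level", {
  # single fixed term; queries drawn uniformly from the background
  lib <- toy_library()
  N <- 50; n <- 8; K <- 10          # term TB
  support <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  tails <- rev(cumsum(rev(pmf)))
  alpha_att <- sum(pmf[tails <= 0.05])
  R <- 400
  set.seed(321)
  rej <- 0L
  for (r in 1:R) {
    q <- sample(lib$universe, n)
    tab <- enrich(q, lib)
    if (tab$p_value[tab$term_id == "TB"] <= 0.05) rej <- rej + 1L
  }
  bounds <- stats::qbinom(c(0.005, 0.995), R, alpha_att)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})

test_that("results TSV round-trips the table and is byte-stable", {
  lib <- toy_library()
  tab <- enrich(sprintf("G%02d", 1:6), lib)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_enrich_table(tab, p1)
  write_enrich_table(tab, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- utils::read.delim(p1, comment.char = "#")
  expect_equal(back$term_id, tab$term_id)
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-12)
})
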