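#' Parameters of the synthetic annotation mini-universe
#'
#' The fixture generator emulates, at miniature scale, the files an
#' annotation-library build consumes: an ontology DAG (single root), a
#' species gene table with synonyms, GO-style annotations rendered
#' consistently as both GAF and gene2go, flat pathway and disease
#' tables, and a query gene list in which a known set of planted terms
#' is over-represented. Defaults are the study conditions used
#' throughout the test-suite and acceptance checks.
#'
#' @param seed integer RNG seed; the fixture is fully determined by it.
#' @param n_genes size of the gene universe (default 200).
#' @param n_terms ontology terms including the root (default 30).
#' @param dag_depth maximum depth of the DAG (default 4).
#' @param planted_terms number of leaf terms given elevated query
#'   membership (default 1).
#' @param effect fraction of the query drawn from each planted term
#'   (default 0.5); each planted term contributes
#'   `ceiling(effect * query_size)` query genes.
#' @param query_size query gene-list length (default 25).
#' @param taxon taxon id stamped on all generated files (default 9606).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_genes = 200L, n_terms = 30L, dag_depth = 4L,
                         planted_terms = 1L, effect = 0.5, query_size = 25L,
                         taxon = 9606L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_terms = as.integer(n_terms), dag_depth = as.integer(dag_depth),
               planted_terms = as.integer(planted_terms),
               effect = as.numeric(effect),
               query_size = as.integer(query_size), taxon = as.integer(taxon))
  if (spec$planted_terms > spec$n_terms) {
    stop("planted_terms must not exceed n_terms", call. = FALSE)
  }
  if (spec$effect <= 0 || spec$effect > 1) {
    stop("effect must lie in (0, 1]", call. = FALSE)
  }
  if (spec$query_size > spec$n_genes) {
    stop("query_size must not exceed n_genes", call. = FALSE)
  }
  if (spec$n_terms < 2L || spec$n_genes < 10L || spec$dag_depth < 1L) {
    stop("fixture too small: need n_terms >= 2, n_genes >= 10, dag_depth >= 1",
         call. = FALSE)
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a deterministic synthetic annotation fixture
#'
#' Writes a mini OBO ontology, a GAF and a gene2go rendering of the
#' same annotation truth, a gene_info table, flat pathway / disease /
#' disgenet tables, a query list with planted over-representation, a
#' full-universe background list, a machine-readable `truth.json`
#' naming the planted terms, and a `config.txt` manifest ready for
#' [make_species_db()]. Re-running with the same spec yields
#' byte-identical files.
#'
#' @param spec a `fixture_spec`.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with `paths` (named file paths) and
#'   `truth` (the planted-term ground truth, also written as JSON).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  # ---- gene universe ----
  symbols <- sprintf("GN%04d", seq_len(spec$n_genes))
  gene_ids <- 1000L + seq_len(spec$n_genes)
  has_syn <- stats::runif(spec$n_genes) < 0.2
  synonyms <- ifelse(has_syn, sprintf("SY%04d", seq_len(spec$n_genes)), "-")

  # ---- ontology DAG: ids FT:0000001 (root) ... ----
  term_ids <- sprintf("FT:%07d", seq_len(spec$n_terms))
  root <- term_ids[1]
  depth <- c(0L, sort(sample(seq_len(spec$dag_depth), spec$n_terms - 1L,
                             replace = TRUE)))
  parents <- vector("list", spec$n_terms)
  rel_is_a <- vector("list", spec$n_terms)
  rel_part_of <- vector("list", spec$n_terms)
  for (i in seq.int(2L, spec$n_terms)) {
    cand <- which(depth < depth[i])
    np <- min(length(cand), sample(1:2, 1))
    ps <- term_ids[sample_safe(cand, np)]
    parents[[i]] <- ps
    # most edges is_a; occasionally part_of
    is_po <- stats::runif(length(ps)) < 0.15
    rel_is_a[[i]] <- ps[!is_po]
    rel_part_of[[i]] <- ps[is_po]
    if (!length(rel_is_a[[i]])) {  # keep at least one is_a path to the root
      rel_is_a[[i]] <- ps[1]
      rel_part_of[[i]] <- setdiff(ps, ps[1])
    }
  }
  has_child <- term_ids %in% unlist(parents)
  leaves <- which(!has_child & depth > 0L)
  planted_idx <- sample_safe(leaves[order(-depth[leaves])][
    seq_len(min(length(leaves), max(spec$planted_terms * 3L, 5L)))],
    spec$planted_terms)
  planted <- term_ids[planted_idx]

  obo <- character(0)
  for (i in seq_len(spec$n_terms)) {
    obo <- c(obo, "[Term]",
             paste0("id: ", term_ids[i]),
             paste0("name: synthetic term ", i),
             "namespace: biological_process",
             if (length(rel_is_a[[i]])) paste0("is_a: ", sort(rel_is_a[[i]])),
             if (length(rel_part_of[[i]]))
               paste0("relationship: part_of ", sort(rel_part_of[[i]])),
             "")
  }

  # ---- direct annotations: each gene to 1-3 non-root terms ----
  ann_gene <- integer(0); ann_term <- integer(0)
  for (g in seq_len(spec$n_genes)) {
    ts <- sample_safe(seq.int(2L, spec$n_terms), sample(1:3, 1))
    ann_gene <- c(ann_gene, rep(g, length(ts)))
    ann_term <- c(ann_term, ts)
  }
  # top up each planted term so the planted signal has a defined size
  contribution <- as.integer(ceiling(spec$effect * spec$query_size))
  target_size <- max(20L, contribution + 5L)
  for (pi in planted_idx) {
    members <- unique(ann_gene[ann_term == pi])
    need <- target_size - length(members)
    if (need > 0L) {
      extra <- sample_safe(setdiff(seq_len(spec$n_genes), members), need)
      ann_gene <- c(ann_gene, extra)
      ann_term <- c(ann_term, rep(pi, need))
    }
  }
  dup <- duplicated(paste(ann_gene, ann_term))
  ann_gene <- ann_gene[!dup]; ann_term <- ann_term[!dup]
  ord <- order(ann_gene, ann_term)
  ann_gene <- ann_gene[ord]; ann_term <- ann_term[ord]

  gaf <- c("!gaf-version: 2.2",
           "!generated-by: enrichkit fixture generator",
           paste("EK", sprintf("EK:%s", symbols[ann_gene]), symbols[ann_gene],
                 "", term_ids[ann_term], "EK_REF:0000001", "IEA", "", "P",
                 paste0("synthetic gene ", ann_gene), "", "gene",
                 paste0("taxon:", spec$taxon), "20260101", "enrichkit", "", "",
                 sep = "\t"))
  g2g <- c("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tPubMed\tCategory",
           paste(spec$taxon, gene_ids[ann_gene], term_ids[ann_term], "IEA", "-",
                 paste0("synthetic term ", ann_term), "-", "Process",
                 sep = "\t"))
  gi <- c("#tax_id\tGeneID\tSymbol\tLocusTag\tSynonyms",
          paste(spec$taxon, gene_ids, symbols, "-", synonyms, sep = "\t"))

  # ---- flat tables ----
  pw_lines <- "#term_id\tterm_name\tgene"
  for (p in 1:8) {
    genes <- sort(sample_safe(seq_len(spec$n_genes), sample(10:25, 1)))
    pw_lines <- c(pw_lines, paste(sprintf("PW%04d", p),
                                  paste0("synthetic pathway ", p),
                                  symbols[genes], sep = "\t"))
  }
  # mirror each planted term as a pathway so the flat path carries truth
  planted_pw <- sprintf("PWPL%02d", seq_along(planted_idx))
  for (j in seq_along(planted_idx)) {
    members <- sort(unique(ann_gene[ann_term == planted_idx[j]]))
    pw_lines <- c(pw_lines, paste(planted_pw[j],
                                  paste0("planted pathway ", j),
                                  symbols[members], sep = "\t"))
  }
  disease_channel <- function(channel, n_dis) {
    lines <- "#term_id\tterm_name\tgene"
    for (d in seq_len(n_dis)) {
      genes <- sort(sample_safe(seq_len(spec$n_genes), sample(8:20, 1)))
      lines <- c(lines, paste(sprintf("DZ%04d", d),
                              paste0("synthetic disease ", d),
                              symbols[genes], sep = "\t"))
    }
    lines
  }
  dz_tm <- disease_channel("text_mining", 6)
  dz_kn <- disease_channel("knowledge", 4)
  dz_ex <- disease_channel("experiments", 3)
  dg_lines <- "#term_id\tterm_name\tgene"
  for (d in 1:5) {
    genes <- sort(sample_safe(seq_len(spec$n_genes), sample(8:20, 1)))
    dg_lines <- c(dg_lines, paste(sprintf("DG%04d", d),
                                  paste0("synthetic disgenet disease ", d),
                                  symbols[genes], sep = "\t"))
  }

  # ---- query with planted over-representation ----
  query <- integer(0)
  for (pi in planted_idx) {
    members <- unique(ann_gene[ann_term == pi])
    query <- c(query, sample_safe(setdiff(members, query), contribution))
  }
  rest <- spec$query_size - length(query)
  if (rest > 0L) {
    query <- c(query, sample_safe(setdiff(seq_len(spec$n_genes), query), rest))
  }
  query <- query[seq_len(spec$query_size)]

  paths <- list(
    obo = file.path(out_dir, "ontology.obo"),
    gaf = file.path(out_dir, "annotations.gaf"),
    gene2go = file.path(out_dir, "gene2go.tsv"),
    gene_info = file.path(out_dir, "gene_info.tsv"),
    pathways = file.path(out_dir, "pathways.tsv"),
    do_text_mining = file.path(out_dir, "diseases_textmining.tsv"),
    do_knowledge = file.path(out_dir, "diseases_knowledge.tsv"),
    do_experiments = file.path(out_dir, "diseases_experiments.tsv"),
    disgenet = file.path(out_dir, "disgenet.tsv"),
    query = file.path(out_dir, "query.txt"),
    background = file.path(out_dir, "background.txt"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "config.txt")
  )
  writeLines(obo, paths$obo)
  writeLines(gaf, paths$gaf)
  writeLines(g2g, paths$gene2go)
  writeLines(gi, paths$gene_info)
  writeLines(pw_lines, paths$pathways)
  writeLines(dz_tm, paths$do_text_mining)
  writeLines(dz_kn, paths$do_knowledge)
  writeLines(dz_ex, paths$do_experiments)
  writeLines(dg_lines, paths$disgenet)
  writeLines(symbols[query], paths$query)
  writeLines(symbols, paths$background)

  truth <- list(planted_go_terms = planted,
                planted_pathways = planted_pw,
                planted_contribution = contribution,
                planted_term_size = target_size,
                spec = unclass(spec))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE)
  # input paths are written relative to the manifest so fixtures are
  # byte-identical wherever they are generated
  writeLines(c(
    paste0("taxon = ", spec$taxon),
    paste0("gene_info = ", basename(paths$gene_info)),
    paste0("go.obo = ", basename(paths$obo)),
    paste0("go.gaf = ", basename(paths$gaf)),
    paste0("kegg.table = ", basename(paths$pathways)),
    paste0("do.text_mining = ", basename(paths$do_text_mining)),
    paste0("do.knowledge = ", basename(paths$do_knowledge)),
    paste0("do.experiments = ", basename(paths$do_experiments)),
    paste0("disgenet.table = ", basename(paths$disgenet))
  ), paths$config)

  invisible(list(paths = paths, truth = truth))
}

# sample() without the length-1 surprise
sample_safe <- function(x, size) {
  if (length(x) == 1L) return(rep(x, min(size, 1L)))
  sample(x, size)
}
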