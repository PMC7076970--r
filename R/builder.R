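#' Build a propagated GO library for one species
#'
#' Each surviving annotation assigns its gene to the annotated term and
#' to every ancestor of that term under `relations` (the true-path
#' rule). NOT-qualified annotations and annotations with an excluded
#' evidence code are dropped. Gene keys are normalised to official
#' symbols via the gene_info table: numeric gene ids translate
#' directly, known symbols pass through, synonyms resolve when
#' unambiguous, and anything unresolved is counted and then dropped at
#' assembly because it lies outside the species universe. Annotations
#' naming terms absent from the ontology, or obsolete terms, are
#' counted and skipped (GO releases drift); they are never fatal.
#'
#' @param ontology an `ontology` from [parse_obo()].
#' @param annotations a data.frame from [parse_gaf()] or
#'   [parse_gene2go()].
#' @param gene_info a data.frame from [parse_gene_info()].
#' @param taxon numeric taxon id; annotations and gene_info rows are
#'   restricted to it (annotations with `NA` taxon are kept).
#' @param relations propagation relations, subset of
#'   `c("is_a", "part_of")`.
#' @param evidence_exclude character vector of evidence codes to drop
#'   (e.g. `"IEA"`); empty by default — the builder is inclusive.
#' @return A `species_library` with `database = "GO"` and
#'   `term_category` set to each term's namespace. Build statistics
#'   (dropped counts by reason) are attached as attribute
#'   `build_stats`.
#' @export
build_go_library <- function(ontology, annotations, gene_info, taxon,
                             relations = c("is_a", "part_of"),
                             evidence_exclude = character(0)) {
  stopifnot(inherits(ontology, "ontology"))
  taxon <- as.integer(taxon)
  gi <- gene_info[gene_info$taxon == taxon, , drop = FALSE]
  if (!nrow(gi)) stop("no gene_info rows for taxon ", taxon, call. = FALSE)
  universe <- sort(unique(gi$symbol))

  ann <- annotations
  ann <- ann[is.na(ann$taxon) | ann$taxon == taxon, , drop = FALSE]
  stats <- list(parsed = nrow(ann))
  ann <- ann[!ann$excluded, , drop = FALSE]
  stats$not_excluded <- stats$parsed - nrow(ann)
  if (length(evidence_exclude)) {
    drop <- ann$evidence_code %in% evidence_exclude
    stats$evidence_excluded <- sum(drop)
    ann <- ann[!drop, , drop = FALSE]
  } else stats$evidence_excluded <- 0L

  res <- normalize_gene_keys(ann$gene_key, gi)
  stats$unresolved_symbols <- sum(!res$resolved)
  ann$gene <- res$symbol

  # resolve term ids (alt ids transparently); count unknown / obsolete
  known <- names(ontology$terms)
  resolved_term <- character(nrow(ann))
  status <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    tid <- ann$term_id[i]
    primary <- if (tid %in% known) tid else unname(ontology$alt_index[tid])
    if (is.na(primary) || is.null(primary)) {
      status[i] <- "unknown"
    } else if (isTRUE(ontology$terms[[primary]]$obsolete)) {
      status[i] <- "obsolete"
    } else {
      status[i] <- "ok"
      resolved_term[i] <- primary
    }
  }
  stats$unknown_term <- sum(status == "unknown")
  stats$obsolete_term <- sum(status == "obsolete")
  ann <- ann[status == "ok", , drop = FALSE]
  ann$term_id <- resolved_term[status == "ok"]

  off <- !(ann$gene %in% universe)
  stats$off_universe <- sum(off)
  ann <- ann[!off, , drop = FALSE]
  if (!nrow(ann)) stop("no annotations survive filtering", call. = FALSE)

  # propagate over the DAG
  pairs_term <- character(0)
  pairs_gene <- character(0)
  for (i in seq_len(nrow(ann))) {
    terms_i <- c(ann$term_id[i], ancestors(ontology, ann$term_id[i], relations))
    pairs_term <- c(pairs_term, terms_i)
    pairs_gene <- c(pairs_gene, rep(ann$gene[i], length(terms_i)))
  }
  term_genes <- lapply(split(pairs_gene, pairs_term), unique)

  ids <- names(term_genes)
  term_names <- stats::setNames(
    vapply(ids, function(id) {
      nm <- ontology$terms[[id]]$name
      if (is.na(nm)) id else nm
    }, character(1)), ids)
  term_category <- stats::setNames(
    vapply(ids, function(id) {
      ns <- ontology$terms[[id]]$namespace
      if (is.na(ns)) "ontology" else ns
    }, character(1)), ids)

  if (stats$unknown_term + stats$obsolete_term + stats$off_universe +
      stats$unresolved_symbols > 0) {
    message(sprintf(
      "build_go_library: dropped %d unknown-term, %d obsolete-term, %d off-universe annotation(s); %d unresolved gene key(s)",
      stats$unknown_term, stats$obsolete_term, stats$off_universe,
      stats$unresolved_symbols))
  }

  lib <- species_library("GO", taxon, term_genes, term_names, term_category,
                         universe,
                         version_info = sprintf("GO build, taxon %d", taxon))
  attr(lib, "build_stats") <- stats
  lib
}

#' Build a flat (pathway/disease) library for one species
#'
#' De-duplicates (term, gene) pairs, maps gene keys to official symbols
#' via gene_info, removes genes absent from the species universe
#' (reporting the drop count) and prunes terms left empty.
#'
#' @param pairs data.frame with columns `term_id`, `gene_key` (e.g.
#'   from [parse_term_gene_table()]).
#' @param term_names named character vector covering every term in
#'   `pairs`.
#' @param database library label (`"KEGG"`, `"Reactome"`, `"DISEASES"`,
#'   `"DisGeNET"`, `"custom"`).
#' @param gene_info a data.frame from [parse_gene_info()].
#' @param taxon numeric taxon id.
#' @return A `species_library`; drop counts in attribute `build_stats`.
#' @export
build_flat_library <- function(pairs, term_names, database, gene_info, taxon) {
  taxon <- as.integer(taxon)
  gi <- gene_info[gene_info$taxon == taxon, , drop = FALSE]
  if (!nrow(gi)) stop("no gene_info rows for taxon ", taxon, call. = FALSE)
  universe <- sort(unique(gi$symbol))

  unnamed <- setdiff(unique(pairs$term_id), names(term_names))
  if (length(unnamed)) {
    stop("term(s) with no name: ", paste(sort(unnamed), collapse = ", "),
         call. = FALSE)
  }
  res <- normalize_gene_keys(pairs$gene_key, gi)
  gene <- res$symbol
  key <- paste(pairs$term_id, gene, sep = "\r")
  dup <- duplicated(key)
  pairs2 <- data.frame(term_id = pairs$term_id[!dup], gene = gene[!dup],
                       stringsAsFactors = FALSE)
  off <- !(pairs2$gene %in% universe)
  n_drop <- sum(off)
  pairs2 <- pairs2[!off, , drop = FALSE]
  if (n_drop > 0) {
    message(sprintf("build_flat_library(%s): dropped %d off-universe gene membership(s)",
                    database, n_drop))
  }
  if (!nrow(pairs2)) stop("no annotations survive filtering", call. = FALSE)
  term_genes <- split(pairs2$gene, pairs2$term_id)
  ids <- names(term_genes)
  lib <- species_library(database, taxon, term_genes, term_names[ids],
                         stats::setNames(rep(database, length(ids)), ids),
                         universe,
                         version_info = sprintf("%s build, taxon %d",
                                                database, taxon))
  attr(lib, "build_stats") <- list(pairs_in = nrow(pairs),
                                   duplicates = sum(dup),
                                   off_universe = n_drop,
                                   unresolved_symbols = sum(!res$resolved))
  lib
}

#' Merge gene-disease annotation channels into one non-redundant set
#'
#' Takes several channels (e.g. text mining, knowledge, experiments) of
#' term-gene associations and returns the union of (term, gene) pairs,
#' each pair once, with its supporting channel labels preserved.
#'
#' @param channels a named list; each element a data.frame with columns
#'   `term_id`, `gene_key`.
#' @return A data.frame with columns `term_id`, `gene_key`, `channels`
#'   (`|`-joined supporting channel labels).
#' @export
merge_disease_channels <- function(channels) {
  if (!length(channels)) {
    return(data.frame(term_id = character(0), gene_key = character(0),
                      channels = character(0), stringsAsFactors = FALSE))
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- paste0("channel", seq_along(channels))
  }
  all <- do.call(rbind, lapply(names(channels), function(lab) {
    ch <- channels[[lab]]
    if (!nrow(ch)) return(NULL)
    data.frame(term_id = ch$term_id, gene_key = ch$gene_key, lab = lab,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all)) {
    return(data.frame(term_id = character(0), gene_key = character(0),
                      channels = character(0), stringsAsFactors = FALSE))
  }
  key <- paste(all$term_id, all$gene_key, sep = "\r")
  labs <- lapply(split(all$lab, key), function(l) sort(unique(l)))
  first <- !duplicated(key)
  out <- data.frame(term_id = all$term_id[first],
                    gene_key = all$gene_key[first],
                    channels = vapply(labs[unique(key)], paste,
                                      character(1), collapse = "|"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$term_id, out$gene_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build all requested species libraries from a manifest
#'
#' The manifest is a plain `key = value` file (or an equivalent named
#' list) naming input files per database plus the taxon. Recognised
#' keys: `taxon`, `gene_info`, `relations` (comma-separated subset of
#' `is_a,part_of`), `evidence_exclude` (comma-separated codes),
#' `go.obo`, `go.gaf`, `go.gene2go`, `kegg.table`, `reactome.table`,
#' `disgenet.table`, and DISEASES channels `do.text_mining`,
#' `do.knowledge`, `do.experiments` (any subset). All referenced input
#' files are checked before any library is written (all-or-nothing).
#'
#' @param config path to a manifest file, or a named list/character of
#'   manifest values.
#' @param out_dir output directory; one `<database>.library.tsv` per
#'   requested database plus a `build_report.txt`.
#' @return Invisibly, a named list of written library paths.
#' @export
make_species_db <- function(config, out_dir) {
  cfg <- if (is.character(config) && length(config) == 1L && file.exists(config)) {
    m <- read_manifest(config)
    # relative input paths resolve against the manifest's directory
    path_keys <- setdiff(names(m), c("taxon", "relations", "evidence_exclude"))
    for (k in path_keys) {
      if (!grepl("^(/|[A-Za-z]:)", m[[k]])) {
        m[[k]] <- file.path(dirname(config), m[[k]])
      }
    }
    m
  } else {
    as.list(config)
  }
  if (is.null(cfg$taxon)) stop("manifest must set 'taxon'", call. = FALSE)
  if (is.null(cfg$gene_info)) stop("manifest must set 'gene_info'", call. = FALSE)
  taxon <- as.integer(cfg$taxon)

  want_go <- !is.null(cfg$go.obo)
  do_channels <- intersect(c("do.text_mining", "do.knowledge", "do.experiments"),
                           names(cfg))
  flat_keys <- c(kegg.table = "KEGG", reactome.table = "Reactome",
                 disgenet.table = "DisGeNET")
  want_flat <- intersect(names(flat_keys), names(cfg))
  if (!want_go && !length(want_flat) && !length(do_channels)) {
    stop("manifest names no database inputs", call. = FALSE)
  }
  inputs <- unlist(cfg[intersect(names(cfg),
                                 c("gene_info", "go.obo", "go.gaf", "go.gene2go",
                                   names(flat_keys), do_channels))])
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (want_go && is.null(cfg$go.gaf) && is.null(cfg$go.gene2go)) {
    stop("GO build needs 'go.gaf' or 'go.gene2go'", call. = FALSE)
  }

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gene_info <- parse_gene_info(cfg$gene_info, taxon = taxon)
  written <- list()
  report <- character(0)
  add_report <- function(lib, label) {
    st <- attr(lib, "build_stats")
    report <<- c(report, sprintf(
      "[%s] terms=%d genes=%d universe=%d dropped=%s", label,
      length(lib$term_genes),
      length(unique(unlist(lib$term_genes, use.names = FALSE))),
      length(lib$universe),
      paste(names(st), unlist(st), sep = "=", collapse = ",")))
  }

  if (want_go) {
    ont <- parse_obo(cfg$go.obo)
    ann <- if (!is.null(cfg$go.gaf)) parse_gaf(cfg$go.gaf)
           else parse_gene2go(cfg$go.gene2go, taxon = taxon)
    relations <- if (!is.null(cfg$relations)) {
      strsplit(cfg$relations, ",", fixed = TRUE)[[1]]
    } else c("is_a", "part_of")
    ev_ex <- if (!is.null(cfg$evidence_exclude)) {
      strsplit(cfg$evidence_exclude, ",", fixed = TRUE)[[1]]
    } else character(0)
    lib <- build_go_library(ont, ann, gene_info, taxon,
                            relations = relations, evidence_exclude = ev_ex)
    p <- file.path(out_dir, "GO.library.tsv")
    write_library(lib, p)
    written$GO <- p
    add_report(lib, "GO")
  }
  for (k in want_flat) {
    db <- flat_keys[[k]]
    tab <- parse_term_gene_table(cfg[[k]])
    lib <- build_flat_library(tab$annotations, tab$term_names, db,
                              gene_info, taxon)
    p <- file.path(out_dir, paste0(db, ".library.tsv"))
    write_library(lib, p)
    written[[db]] <- p
    add_report(lib, db)
  }
  if (length(do_channels)) {
    chans <- lapply(cfg[do_channels], function(f) parse_term_gene_table(f))
    merged <- merge_disease_channels(
      stats::setNames(lapply(chans, `[[`, "annotations"),
                      sub("^do\\.", "", do_channels)))
    nm <- do.call(c, unname(lapply(rev(chans), `[[`, "term_names")))
    nm <- nm[!duplicated(names(nm))]
    lib <- build_flat_library(merged, nm, "DISEASES", gene_info, taxon)
    p <- file.path(out_dir, "DISEASES.library.tsv")
    write_library(lib, p)
    written$DISEASES <- p
    add_report(lib, "DISEASES")
  }
  writeLines(report, file.path(out_dir, "build_report.txt"))
  invisible(written)
}

read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) < 3L)
  if (length(bad)) {
    stop("malformed manifest line: ", lines[bad[1]], call. = FALSE)
  }
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, `[[`, character(1), 2))
}

# Map raw gene keys (numeric gene ids, official symbols, or synonyms)
# to official symbols for one taxon. Synonyms resolve only when they
# name exactly one official symbol; ambiguous or unknown keys are kept
# verbatim and flagged unresolved.
normalize_gene_keys <- function(keys, gene_info) {
  id_map <- stats::setNames(gene_info$symbol, as.character(gene_info$gene_id))
  symbols <- unique(gene_info$symbol)
  syn_pairs <- do.call(rbind, lapply(seq_len(nrow(gene_info)), function(i) {
    syns <- split_synonyms(gene_info$synonyms[i])
    if (!length(syns)) return(NULL)
    data.frame(syn = syns, symbol = gene_info$symbol[i],
               stringsAsFactors = FALSE)
  }))
  syn_map <- character(0)
  if (!is.null(syn_pairs)) {
    per_syn <- lapply(split(syn_pairs$symbol, syn_pairs$syn), unique)
    unambiguous <- lengths(per_syn) == 1L
    syn_map <- stats::setNames(unlist(per_syn[unambiguous]),
                               names(per_syn)[unambiguous])
    syn_map <- syn_map[!(names(syn_map) %in% symbols)]  # symbols win
  }
  out <- as.character(keys)
  resolved <- logical(length(out))
  is_id <- out %in% names(id_map)
  out[is_id] <- id_map[out[is_id]]
  resolved[is_id] <- TRUE
  is_sym <- !resolved & out %in% symbols
  resolved[is_sym] <- TRUE
  is_syn <- !resolved & out %in% names(syn_map)
  out[is_syn] <- syn_map[out[is_syn]]
  resolved[is_syn] <- TRUE
  list(symbol = out, resolved = resolved)
}
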