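LIBRARY_MARKER <- "# enrichkit-library-v1"

#' Construct a species-specific function library
#'
#' A `species_library` maps term ids to gene-symbol sets for one
#' species and one database, together with term names, per-term
#' category labels (the GO namespace, or the database label for flat
#' sources), the species gene universe (the default enrichment
#' background) and free-text provenance.
#'
#' @param database one of `"GO"`, `"KEGG"`, `"Reactome"`, `"DISEASES"`,
#'   `"DisGeNET"`, `"custom"`.
#' @param taxon numeric NCBI taxon id.
#' @param term_genes named list: term id -> character vector of gene
#'   symbols (non-empty; every gene must belong to `universe`).
#' @param term_names named character vector covering every term.
#' @param term_category named character vector covering every term.
#' @param universe character vector of all gene symbols known for the
#'   species.
#' @param version_info free-text provenance lines.
#' @return An object of class `species_library`.
#' @export
species_library <- function(database, taxon, term_genes, term_names,
                            term_category, universe,
                            version_info = character(0)) {
  database <- match.arg(database,
                        c("GO", "KEGG", "Reactome", "DISEASES", "DisGeNET",
                          "custom"))
  taxon <- as.integer(taxon)
  universe <- sort(unique(as.character(universe)))
  term_genes <- lapply(term_genes, function(g) sort(unique(as.character(g))))
  term_genes <- term_genes[order(names(term_genes))]
  if (any(lengths(term_genes) == 0L)) {
    stop("term(s) with empty gene sets: ",
         paste(names(term_genes)[lengths(term_genes) == 0L], collapse = ", "),
         call. = FALSE)
  }
  all_genes <- unique(unlist(term_genes, use.names = FALSE))
  off <- setdiff(all_genes, universe)
  if (length(off)) {
    stop("annotated gene(s) outside the species universe: ",
         paste(utils::head(sort(off), 5), collapse = ", "), call. = FALSE)
  }
  ids <- names(term_genes)
  miss_nm <- setdiff(ids, names(term_names))
  if (length(miss_nm)) {
    stop("term(s) without a name: ", paste(miss_nm, collapse = ", "),
         call. = FALSE)
  }
  miss_ct <- setdiff(ids, names(term_category))
  if (length(miss_ct)) {
    stop("term(s) without a category: ", paste(miss_ct, collapse = ", "),
         call. = FALSE)
  }
  structure(list(database = database,
                 taxon = taxon,
                 term_genes = term_genes,
                 term_names = term_names[ids],
                 term_category = term_category[ids],
                 universe = universe,
                 version_info = as.character(version_info)),
            class = "species_library")
}

#' @export
print.species_library <- function(x, ...) {
  cat(sprintf("<species_library> %s, taxon %d\n", x$database, x$taxon))
  cat(sprintf("  %d terms, %d annotated genes, universe of %d genes\n",
              length(x$term_genes),
              length(unique(unlist(x$term_genes, use.names = FALSE))),
              length(x$universe)))
  invisible(x)
}

#' Write a species library to its on-disk TSV format
#'
#' Deterministic, sorted, tab-separated: one gene per row with columns
#' category, term_id, term_name, gene_symbol, preceded by `#`-header
#' metadata (version marker, database, taxon, build timestamp,
#' provenance). Universe genes carrying no annotation are written as
#' rows with `-` in the first three columns so the full background
#' round-trips. Two writes of one library are byte-identical apart from
#' the timestamp line.
#'
#' @param library a `species_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "species_library"))
  header <- c(
    LIBRARY_MARKER,
    paste0("# database: ", library$database),
    paste0("# taxon: ", library$taxon),
    paste0("# built: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("# source: ", library$version_info),
    "# fields: category\tterm_id\tterm_name\tgene_symbol"
  )
  rows <- character(0)
  for (id in names(library$term_genes)) {
    rows <- c(rows, paste(library$term_category[[id]], id,
                          library$term_names[[id]],
                          library$term_genes[[id]], sep = "\t"))
  }
  unannotated <- setdiff(library$universe,
                         unlist(library$term_genes, use.names = FALSE))
  if (length(unannotated)) {
    rows <- c(rows, paste("-", "-", "-", sort(unannotated), sep = "\t"))
  }
  writeLines(c(header, sort(rows)), path)
  invisible(path)
}

#' Read a species library written by [write_library()]
#'
#' Refuses files whose first line is not the expected version marker.
#'
#' @param path path to a library TSV.
#' @return A `species_library`.
#' @export
read_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != LIBRARY_MARKER) {
    stop(sprintf("not an enrichkit library file (expected marker '%s')",
                 LIBRARY_MARKER), call. = FALSE)
  }
  hdr <- lines[startsWith(lines, "#")]
  grab <- function(key) {
    hit <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(hit)) return(character(0))
    trimws(sub(paste0("^# ", key, ":"), "", hit))
  }
  database <- grab("database")
  taxon <- as.integer(grab("taxon"))
  version_info <- grab("source")
  data_lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop("malformed library data line (4 columns expected)", call. = FALSE)
  }
  category <- vapply(fields, `[[`, character(1), 1)
  term_id <- vapply(fields, `[[`, character(1), 2)
  term_name <- vapply(fields, `[[`, character(1), 3)
  gene <- vapply(fields, `[[`, character(1), 4)
  is_universe_row <- term_id == "-"
  ann <- data.frame(category = category[!is_universe_row],
                    term_id = term_id[!is_universe_row],
                    term_name = term_name[!is_universe_row],
                    gene = gene[!is_universe_row],
                    stringsAsFactors = FALSE)
  term_genes <- split(ann$gene, ann$term_id)
  first <- !duplicated(ann$term_id)
  term_names <- stats::setNames(ann$term_name[first], ann$term_id[first])
  term_category <- stats::setNames(ann$category[first], ann$term_id[first])
  species_library(database = database, taxon = taxon,
                  term_genes = term_genes, term_names = term_names,
                  term_category = term_category,
                  universe = c(ann$gene, gene[is_universe_row]),
                  version_info = version_info)
}
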