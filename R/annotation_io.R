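#' Read a GAF 2.x gene association file
#'
#' Header lines start with `!`. Data lines are tab-separated with at
#' least 15 columns; column 3 is the object symbol, column 4 the
#' qualifier, column 5 the term id, column 7 the evidence code and
#' column 13 the `taxon:<id>` field (first token used when several are
#' listed). The reader is lossless: NOT-qualified rows are parsed and
#' flagged (`excluded == TRUE`), not dropped — exclusion is the library
#' builder's decision.
#'
#' @param x path to a GAF file, or a character vector of lines.
#' @return A data.frame of annotations with columns `gene_key`,
#'   `term_id`, `qualifier`, `evidence_code`, `taxon`, `excluded`.
#' @export
parse_gaf <- function(x) {
  lines <- read_input_lines(x)
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_annotations())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 15L)
  if (length(bad)) {
    stop(sprintf("GAF data line %d has %d columns (>= 15 required)",
                 idx[bad[1]], ncols[bad[1]]), call. = FALSE)
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  term_id <- getf(5)
  if (any(!nzchar(term_id))) {
    stop(sprintf("GAF data line %d has an empty term id",
                 idx[which(!nzchar(term_id))[1]]), call. = FALSE)
  }
  qualifier <- getf(4)
  taxon_raw <- getf(13)
  taxon <- suppressWarnings(as.integer(
    sub("^taxon:", "", vapply(strsplit(taxon_raw, "|", fixed = TRUE),
                              `[[`, character(1), 1))))
  data.frame(gene_key = getf(3),
             term_id = term_id,
             qualifier = qualifier,
             evidence_code = getf(7),
             taxon = taxon,
             excluded = grepl("NOT", qualifier, fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Read an NCBI gene2go-style annotation table
#'
#' Tab-separated with a `#`-prefixed header; columns are tax_id,
#' GeneID, GO_ID, Evidence, Qualifier, and any further columns are
#' ignored. Rows are keyed by the numeric gene id; translation to
#' symbols happens at library-build time via the gene_info table.
#'
#' @param x path or character vector of lines.
#' @param taxon optional numeric taxon id to filter on; `NULL` keeps all
#'   rows. Filtering on an absent taxon yields an empty result, not an
#'   error.
#' @return A data.frame with the same columns as [parse_gaf()].
#' @export
parse_gene2go <- function(x, taxon = NULL) {
  lines <- read_input_lines(x)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(empty_annotations())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 5L)
  if (length(bad)) {
    stop(sprintf("gene2go line %d has %d columns (>= 5 required)",
                 idx[bad[1]], ncols[bad[1]]), call. = FALSE)
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  tax <- suppressWarnings(as.integer(getf(1)))
  gid <- suppressWarnings(as.integer(getf(2)))
  if (anyNA(tax)) {
    stop(sprintf("gene2go line %d: non-numeric tax_id", idx[which(is.na(tax))[1]]),
         call. = FALSE)
  }
  if (anyNA(gid)) {
    stop(sprintf("gene2go line %d: non-numeric GeneID", idx[which(is.na(gid))[1]]),
         call. = FALSE)
  }
  qualifier <- getf(5)
  qualifier[qualifier == "-"] <- ""
  out <- data.frame(gene_key = as.character(gid),
                    term_id = getf(3),
                    qualifier = qualifier,
                    evidence_code = getf(4),
                    taxon = tax,
                    excluded = grepl("NOT", qualifier, fixed = TRUE),
                    stringsAsFactors = FALSE)
  if (!is.null(taxon)) out <- out[out$taxon == as.integer(taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an NCBI gene_info-style gene table
#'
#' Tab-separated with a `#`-prefixed header; columns are tax_id,
#' GeneID, Symbol, LocusTag, Synonyms (`|`-separated, `-` meaning
#' none). Further columns are ignored.
#'
#' @param x path or character vector of lines.
#' @param taxon optional taxon filter.
#' @return A data.frame with columns `taxon`, `gene_id`, `symbol`,
#'   `synonyms` (a `|`-joined string, `""` when none).
#' @export
parse_gene_info <- function(x, taxon = NULL) {
  lines <- read_input_lines(x)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(data.frame(taxon = integer(0), gene_id = integer(0),
                      symbol = character(0), synonyms = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 5L)
  if (length(bad)) {
    stop(sprintf("gene_info line %d has %d columns (>= 5 required)",
                 idx[bad[1]], ncols[bad[1]]), call. = FALSE)
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  tax <- suppressWarnings(as.integer(getf(1)))
  gid <- suppressWarnings(as.integer(getf(2)))
  if (anyNA(tax) || anyNA(gid)) {
    j <- which(is.na(tax) | is.na(gid))[1]
    stop(sprintf("gene_info line %d: non-numeric tax_id/GeneID", idx[j]),
         call. = FALSE)
  }
  symbol <- getf(3)
  if (any(!nzchar(symbol))) {
    stop(sprintf("gene_info line %d: empty Symbol",
                 idx[which(!nzchar(symbol))[1]]), call. = FALSE)
  }
  syn <- getf(5)
  syn[syn == "-"] <- ""
  out <- data.frame(taxon = tax, gene_id = gid, symbol = symbol,
                    synonyms = syn, stringsAsFactors = FALSE)
  dup <- duplicated(out[c("taxon", "gene_id")])
  if (any(dup)) {
    stop("duplicate (taxon, gene_id) in gene_info: gene id ",
         out$gene_id[which(dup)[1]], call. = FALSE)
  }
  if (!is.null(taxon)) out <- out[out$taxon == as.integer(taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split a gene_info synonyms string into a character vector
#' @param synonyms a `|`-joined synonyms string (as stored by
#'   [parse_gene_info()]).
#' @return Character vector of synonyms (empty when none).
#' @export
split_synonyms <- function(synonyms) {
  if (!nzchar(synonyms)) return(character(0))
  strsplit(synonyms, "|", fixed = TRUE)[[1]]
}

#' Read a flat three-column term-gene association table
#'
#' Tab-separated columns term_id, term_name, gene_key; `#` header lines
#' allowed; duplicates permitted (de-duplication is the library
#' builder's job). Later duplicate names for one term overwrite earlier
#' ones.
#'
#' @param x path or character vector of lines.
#' @return A list with `annotations` (data.frame `term_id`, `gene_key`)
#'   and `term_names` (named character vector).
#' @export
parse_term_gene_table <- function(x) {
  lines <- read_input_lines(x)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(list(annotations = data.frame(term_id = character(0),
                                         gene_key = character(0),
                                         stringsAsFactors = FALSE),
                term_names = stats::setNames(character(0), character(0))))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols < 3L)
  if (length(bad)) {
    stop(sprintf("term-gene table line %d has %d columns (3 required)",
                 idx[bad[1]], ncols[bad[1]]), call. = FALSE)
  }
  getf <- function(i) vapply(fields, `[[`, character(1), i)
  term_id <- getf(1); term_name <- getf(2); gene_key <- getf(3)
  if (any(!nzchar(term_id)) || any(!nzchar(gene_key))) {
    j <- which(!nzchar(term_id) | !nzchar(gene_key))[1]
    stop(sprintf("term-gene table line %d has an empty field", idx[j]),
         call. = FALSE)
  }
  nm <- stats::setNames(term_name, term_id)
  nm <- nm[!duplicated(names(nm), fromLast = TRUE)]  # later names win
  list(annotations = data.frame(term_id = term_id, gene_key = gene_key,
                                stringsAsFactors = FALSE),
       term_names = nm[sort(names(nm))])
}

# ---- shared helpers ----

read_input_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
}

empty_annotations <- function() {
  data.frame(gene_key = character(0), term_id = character(0),
             qualifier = character(0), evidence_code = character(0),
             taxon = integer(0), excluded = logical(0),
             stringsAsFactors = FALSE)
}
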