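#' Resolve the background gene set for an enrichment run
#'
#' With no user background the full species universe of the library is
#' used (the default genomic background). A user-supplied list is
#' trimmed, de-duplicated and intersected with the universe; genes the
#' library does not know are dropped with a reported count (attribute
#' `dropped`).
#'
#' @param library a `species_library`.
#' @param user_background optional character vector of gene symbols.
#' @return Sorted character vector of background genes, with attributes
#'   `dropped` (count of unrecognised user genes) and `duplicates`
#'   (count of duplicate user entries collapsed).
#' @export
resolve_background <- function(library, user_background = NULL) {
  stopifnot(inherits(library, "species_library"))
  if (is.null(user_background)) {
    bg <- library$universe
    attr(bg, "dropped") <- 0L
    attr(bg, "duplicates") <- 0L
    return(bg)
  }
  ub <- trimws(as.character(user_background))
  ub <- ub[nzchar(ub)]
  n_dup <- sum(duplicated(ub))
  ub <- unique(ub)
  if (!length(ub)) stop("user background is empty", call. = FALSE)
  bg <- sort(intersect(ub, library$universe))
  if (!length(bg)) {
    stop("no user background gene is present in the species universe",
         call. = FALSE)
  }
  dropped <- length(ub) - length(bg)
  if (dropped > 0) {
    message(sprintf("resolve_background: %d background gene(s) not in the species universe, dropped",
                    dropped))
  }
  attr(bg, "dropped") <- dropped
  attr(bg, "duplicates") <- n_dup
  bg
}

#' Over-representation analysis of a gene set against a library
#'
#' For every term of the library whose background-restricted gene set
#' falls inside the size window, tests whether the query hits the term
#' more often than expected under random sampling from the background,
#' with an exact one-sided tail test. Term gene sets and the query are
#' both intersected with the background first, so K and N are
#' background-consistent. Multiple-testing correction runs across
#' exactly the tested family. All tested terms are returned; the
#' `significant` column flags q <= `q_cutoff`. Rows are sorted by
#' (p-value, term id) for deterministic output.
#'
#' @param query character vector of gene symbols (whitespace-trimmed,
#'   case-sensitively matched; duplicates collapsed with a reported
#'   count).
#' @param library a `species_library`.
#' @param background optional: a character vector of background genes
#'   (a user list, resolved against the library), or `NULL` for the
#'   full species universe.
#' @param method `"fisher"` (default) or `"hypergeometric"`; the two
#'   one-sided tests are numerically identical.
#' @param adjust multiple-testing method for [adjust_pvalues()]
#'   (default `"BH"`; `"fdr"` is an alias).
#' @param min_term_size,max_term_size size window applied to term sizes
#'   measured after background restriction; terms outside it are
#'   excluded from testing and from the correction family.
#' @param q_cutoff significance flag threshold (default 0.05).
#' @return A data.frame of class `enrich_table` with columns
#'   `category`, `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`, `q_value`, `significant`, `genes`
#'   (semicolon-joined, sorted). Attributes: `background_size`,
#'   `query_used`, `query_dropped` (genes absent from the background),
#'   `settings`.
#' @export
enrich <- function(query, library, background = NULL,
                   method = c("fisher", "hypergeometric"),
                   adjust = "BH", min_term_size = 3L, max_term_size = 5000L,
                   q_cutoff = 0.05) {
  stopifnot(inherits(library, "species_library"))
  method <- match.arg(method)
  bg <- if (is.null(background)) resolve_background(library)
        else resolve_background(library, background)
  q <- trimws(as.character(query))
  q <- q[nzchar(q)]
  n_dup <- sum(duplicated(q))
  q <- unique(q)
  if (!length(q)) stop("query is empty", call. = FALSE)
  if (n_dup > 0) {
    message(sprintf("enrich: %d duplicate query entr(ies) collapsed", n_dup))
  }
  q_in <- sort(intersect(q, bg))
  q_out <- sort(setdiff(q, bg))
  if (!length(q_in)) {
    stop("no query gene is present in the background", call. = FALSE)
  }
  if (length(q_out)) {
    message(sprintf("enrich: %d query gene(s) not in the background, dropped",
                    length(q_out)))
  }
  N <- length(bg)
  n <- length(q_in)

  term_bg <- lapply(library$term_genes, function(g) intersect(g, bg))
  sizes <- lengths(term_bg)
  tested <- names(term_bg)[sizes >= min_term_size & sizes <= max_term_size]
  if (!length(tested)) {
    stop(sprintf("no term passes the size window [%d, %d] after background restriction",
                 min_term_size, max_term_size), call. = FALSE)
  }
  K <- sizes[tested]
  hits <- lapply(term_bg[tested], function(g) sort(intersect(g, q_in)))
  k <- lengths(hits)
  p <- if (method == "fisher") fisher_exact_greater(k, n, K, N)
       else hypergeom_upper_tail(k, n, K, N)
  qv <- adjust_pvalues(p, adjust)
  fold <- fold_enrichment(k, n, K, N)

  out <- data.frame(
    category = unname(library$term_category[tested]),
    term_id = tested,
    term_name = unname(library$term_names[tested]),
    k = unname(k), n = n, K = unname(K), N = N,
    fold_enrichment = unname(fold),
    p_value = unname(p),
    q_value = unname(qv),
    significant = unname(qv) <= q_cutoff,
    genes = vapply(hits, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "background_size") <- N
  attr(out, "query_used") <- n
  attr(out, "query_dropped") <- q_out
  attr(out, "settings") <- list(method = method, adjust = adjust,
                                min_term_size = as.integer(min_term_size),
                                max_term_size = as.integer(max_term_size),
                                q_cutoff = q_cutoff,
                                database = library$database,
                                taxon = library$taxon)
  class(out) <- c("enrich_table", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' One row per tested term; a `#` header echoes all settings and the
#' background/query accounting, so identical runs produce byte-identical
#' files.
#'
#' @param table an `enrich_table` from [enrich()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrich_table <- function(table, path) {
  stopifnot(inherits(table, "enrich_table"))
  s <- attr(table, "settings")
  header <- c(
    "# enrichkit-results-v1",
    sprintf("# database: %s", s$database),
    sprintf("# taxon: %d", s$taxon),
    sprintf("# method: %s", s$method),
    sprintf("# adjust: %s", s$adjust),
    sprintf("# min_term_size: %d", s$min_term_size),
    sprintf("# max_term_size: %d", s$max_term_size),
    sprintf("# q_cutoff: %g", s$q_cutoff),
    sprintf("# background_size: %d", attr(table, "background_size")),
    sprintf("# query_used: %d", attr(table, "query_used")),
    sprintf("# query_dropped: %d", length(attr(table, "query_dropped")))
  )
  cols <- c("category", "term_id", "term_name", "k", "n", "K", "N",
            "fold_enrichment", "p_value", "q_value", "significant", "genes")
  body <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(table$category[i], table$term_id[i], table$term_name[i],
            table$k[i], table$n[i], table$K[i], table$N[i],
            format_num(table$fold_enrichment[i]),
            format_num(table$p_value[i]),
            format_num(table$q_value[i]),
            tolower(as.character(table$significant[i])),
            table$genes[i]), collapse = "\t")
  }, character(1))
  writeLines(c(header, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

format_num <- function(x) trimws(formatC(x, digits = 15, format = "g"))

#' @export
print.enrich_table <- function(x, ...) {
  cat(sprintf("<enrich_table> %d tested terms; n=%d query genes, N=%d background\n",
              nrow(x), attr(x, "query_used"), attr(x, "background_size")))
  cat(sprintf("  %d significant at q <= %g\n", sum(x$significant),
              attr(x, "settings")$q_cutoff))
  print.data.frame(utils::head(as.data.frame(
    x[, c("term_id", "term_name", "k", "K", "fold_enrichment",
          "p_value", "q_value")]), 10))
  invisible(x)
}
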