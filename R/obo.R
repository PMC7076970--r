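#' Parse an OBO 1.2 flat-file ontology
#'
#' Reads `[Term]` stanzas from an OBO-format stream and assembles an
#' `ontology` object: a directed acyclic graph of terms connected by
#' `is_a` and `part_of` edges, with alternative-id resolution and
#' obsolete-term flagging. Non-`[Term]` stanzas (e.g. `[Typedef]`) are
#' ignored. Trailing comments introduced by an unescaped `!` are
#' stripped.
#'
#' Obsolete terms are retained and flagged but carry no parents:
#' annotation propagation through an obsolete term would silently
#' truncate, so they never receive annotations downstream.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @return An object of class `ontology`: a list with elements
#'   `terms` (named list of term records with fields `term_id`, `name`,
#'   `namespace`, `is_a`, `part_of`, `alt_ids`, `obsolete`) and
#'   `alt_index` (named character vector mapping alternative ids to
#'   primary ids). Ancestor queries are memoised per object.
#' @examples
#' obo <- c("[Term]", "id: A", "name: root",
#'          "[Term]", "id: B", "name: child", "is_a: A ! root")
#' ont <- parse_obo(obo)
#' ancestors(ont, "B")
#' @export
parse_obo <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    x
  }
  lines_clean <- vapply(lines, strip_obo_comment, character(1), USE.NAMES = FALSE)

  terms <- list()
  alt_index <- character(0)
  cur <- NULL
  cur_start <- NA_integer_
  in_term <- FALSE

  finish <- function() {
    if (!in_term || is.null(cur)) return(invisible())
    if (is.null(cur$term_id)) {
      stop(sprintf("malformed [Term] stanza starting at line %d: missing 'id:'",
                   cur_start), call. = FALSE)
    }
    if (isTRUE(cur$obsolete)) {
      # obsolete terms must not carry parents
      cur$is_a <- character(0)
      cur$part_of <- character(0)
    }
    terms[[cur$term_id]] <<- cur
    if (length(cur$alt_ids)) {
      ai <- rep(cur$term_id, length(cur$alt_ids))
      names(ai) <- cur$alt_ids
      alt_index <<- c(alt_index, ai)
    }
    invisible()
  }

  for (i in seq_along(lines_clean)) {
    line <- trimws(lines_clean[i])
    if (!nzchar(line)) next
    if (grepl("^\\[", line)) {
      finish()
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(term_id = NULL, name = NA_character_,
                    namespace = NA_character_,
                    is_a = character(0), part_of = character(0),
                    alt_ids = character(0), obsolete = FALSE)
        cur_start <- i
      } else {
        cur <- NULL
      }
      next
    }
    if (!in_term) next
    kv <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(kv) < 3L) next
    key <- kv[2]; val <- trimws(kv[3])
    if (key == "id") cur$term_id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- union(cur$is_a, strsplit(val, "\\s+")[[1]][1])
    else if (key == "alt_id") cur$alt_ids <- union(cur$alt_ids, val)
    else if (key == "is_obsolete") cur$obsolete <- tolower(val) %in% c("true", "1")
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) >= 2L && parts[1] == "part_of") {
        cur$part_of <- union(cur$part_of, parts[2])
      }
      # other relationship types (regulates, has_part, ...) are ignored
    }
  }
  finish()

  # referential integrity: every parent must exist
  all_ids <- names(terms)
  parents <- unique(unlist(lapply(terms, function(t) c(t$is_a, t$part_of)),
                           use.names = FALSE))
  missing <- setdiff(parents, all_ids)
  if (length(missing)) {
    stop("dangling parent reference(s): ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  }

  ont <- structure(list(terms = terms,
                        alt_index = alt_index,
                        cache = new.env(parent = emptyenv())),
                   class = "ontology")
  cyc <- find_cycle(ont)
  if (!is.null(cyc)) {
    stop("cycle detected among ontology terms: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  ont
}

# strip an unescaped "!" comment; "\!" stays literal
strip_obo_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (ch == "!") return(substr(line, 1L, i - 1L))
  }
  line
}

# DFS cycle detection over is_a + part_of; returns one cycle or NULL
find_cycle <- function(ont) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  result <- NULL
  visit <- function(id, stack) {
    if (!is.null(result)) return()
    s <- get0(id, envir = state)
    if (identical(s, 2L)) return()
    if (identical(s, 1L)) {
      pos <- match(id, stack)
      result <<- c(stack[pos:length(stack)], id)
      return()
    }
    assign(id, 1L, envir = state)
    t <- ont$terms[[id]]
    for (p in c(t$is_a, t$part_of)) visit(p, c(stack, id))
    assign(id, 2L, envir = state)
  }
  for (id in names(ont$terms)) {
    visit(id, character(0))
    if (!is.null(result)) return(result)
  }
  NULL
}

#' Resolve a possibly-alternative term id to its primary id
#'
#' @param ontology an `ontology` object.
#' @param term_id a term accession, possibly an `alt_id` of a merged term.
#' @return The primary term id.
#' @export
resolve_term_id <- function(ontology, term_id) {
  stopifnot(inherits(ontology, "ontology"))
  if (term_id %in% names(ontology$terms)) return(term_id)
  hit <- ontology$alt_index[term_id]
  if (!is.na(hit)) return(unname(hit))
  stop(sprintf("unknown term id '%s'", term_id), call. = FALSE)
}

#' Ancestors of a term under selected relations
#'
#' Transitive closure of the parent relation over the selected edge
#' types, excluding the term itself. Results are memoised on the
#' ontology object, so repeated queries cost no more than one full
#' traversal overall. Alternative ids resolve transparently.
#'
#' @param ontology an `ontology` object from [parse_obo()].
#' @param term_id term accession (primary or alternative id).
#' @param relations subset of `c("is_a", "part_of")` to follow.
#' @return Sorted character vector of ancestor term ids (possibly empty).
#' @export
ancestors <- function(ontology, term_id, relations = c("is_a", "part_of")) {
  stopifnot(inherits(ontology, "ontology"))
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  id <- resolve_term_id(ontology, term_id)
  t <- ontology$terms[[id]]
  if (isTRUE(t$obsolete)) {
    stop(sprintf("term '%s' is obsolete and has no ancestry", id), call. = FALSE)
  }
  key_suffix <- paste(sort(relations), collapse = "+")
  anc_rec <- function(id) {
    key <- paste0(id, "|", key_suffix)
    hit <- get0(key, envir = ontology$cache)
    if (!is.null(hit)) return(hit)
    t <- ontology$terms[[id]]
    parents <- character(0)
    if ("is_a" %in% relations) parents <- c(parents, t$is_a)
    if ("part_of" %in% relations) parents <- c(parents, t$part_of)
    out <- parents
    for (p in parents) out <- c(out, anc_rec(p))
    out <- sort(unique(out))
    assign(key, out, envir = ontology$cache)
    out
  }
  anc_rec(id)
}

#' @export
print.ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, function(t) isTRUE(t$obsolete), logical(1)))
  cat(sprintf("<ontology> %d terms (%d obsolete), %d alt ids\n",
              length(x$terms), n_obs, length(x$alt_index)))
  ns <- table(vapply(x$terms, function(t) t$namespace, character(1)),
              useNA = "ifany")
  for (nm in names(ns)) cat(sprintf("  %s: %d\n", nm, ns[[nm]]))
  invisible(x)
}

#' Serialise an ontology to minimal OBO text
#'
#' Writes id/name/namespace/is_a/relationship/alt_id/is_obsolete lines
#' only, in sorted term order; [parse_obo()] of the output reproduces
#' the same term and edge sets.
#'
#' @param ontology an `ontology` object.
#' @return Character vector of OBO lines.
#' @export
write_obo_lines <- function(ontology) {
  stopifnot(inherits(ontology, "ontology"))
  out <- character(0)
  for (id in sort(names(ontology$terms))) {
    t <- ontology$terms[[id]]
    out <- c(out, "[Term]", paste0("id: ", id))
    if (!is.na(t$name)) out <- c(out, paste0("name: ", t$name))
    if (!is.na(t$namespace)) out <- c(out, paste0("namespace: ", t$namespace))
    for (a in sort(t$alt_ids)) out <- c(out, paste0("alt_id: ", a))
    for (p in sort(t$is_a)) out <- c(out, paste0("is_a: ", p))
    for (p in sort(t$part_of)) out <- c(out, paste0("relationship: part_of ", p))
    if (isTRUE(t$obsolete)) out <- c(out, "is_obsolete: true")
    out <- c(out, "")
  }
  out
}
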