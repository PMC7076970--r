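# Shared in-code fixtures and independent oracles.

# minimal OBO text: chain C is_a B is_a A, with an alt id on A
obo_chain <- function() c(
  "[Term]", "id: A", "name: root", "namespace: biological_process",
  "alt_id: X",
  "[Term]", "id: B", "name: mid", "namespace: biological_process",
  "is_a: A ! root",
  "[Term]", "id: C", "name: leaf", "namespace: biological_process",
  "is_a: B"
)

# diamond: D is_a B, D is_a C, B is_a A, C is_a A
obo_diamond <- function() c(
  "[Term]", "id: A", "name: top",
  "[Term]", "id: B", "name: left", "is_a: A",
  "[Term]", "id: C", "name: right", "is_a: A",
  "[Term]", "id: D", "name: bottom", "is_a: B", "is_a: C"
)

# random DAG ontology, built independently of the package's fixture
# generator: term i may have parents among terms 1..i-1 only
random_dag_obo <- function(n_terms, seed, p_part_of = 0.2) {
  set.seed(seed)
  ids <- sprintf("RT:%04d", seq_len(n_terms))
  lines <- c("[Term]", paste0("id: ", ids[1]), "name: root")
  for (i in seq.int(2L, n_terms)) {
    np <- sample(1:min(2L, i - 1L), 1)
    ps <- ids[sample.int(i - 1L, np)]
    po <- runif(length(ps)) < p_part_of
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: term ", i),
               if (any(!po)) paste0("is_a: ", ps[!po]),
               if (any(po)) paste0("relationship: part_of ", ps[po]))
  }
  parse_obo(lines)
}

# naive per-call DFS ancestor closure — the oracle the memoised
# implementation is checked against
naive_ancestors <- function(ont, id, relations = c("is_a", "part_of")) {
  out <- character(0)
  stack <- id
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    t <- ont$terms[[cur]]
    ps <- c(if ("is_a" %in% relations) t$is_a,
            if ("part_of" %in% relations) t$part_of)
    new <- setdiff(ps, out)
    out <- c(out, new)
    stack <- c(stack, new)
  }
  sort(setdiff(out, id))
}

# random annotation universe for builder oracle checks
random_build_inputs <- function(seed, n_genes = 30, n_terms = 10) {
  ont <- random_dag_obo(n_terms, seed)
  set.seed(seed + 1L)
  symbols <- sprintf("G%03d", seq_len(n_genes))
  gi <- data.frame(taxon = 9606L, gene_id = seq_len(n_genes),
                   symbol = symbols, synonyms = "",
                   stringsAsFactors = FALSE)
  n_ann <- n_genes + sample(5:25, 1)
  ann <- data.frame(
    gene_key = symbols[sample.int(n_genes, n_ann, replace = TRUE)],
    term_id = names(ont$terms)[sample.int(n_terms, n_ann, replace = TRUE)],
    qualifier = "", evidence_code = "IEA", taxon = 9606L,
    excluded = FALSE, stringsAsFactors = FALSE)
  list(ontology = ont, annotations = ann, gene_info = gi)
}

# brute-force per-gene construction: each gene unions every directly
# annotated term with its naive-DFS ancestors
naive_go_build <- function(ont, ann) {
  pairs <- list()
  for (i in seq_len(nrow(ann))) {
    terms_i <- c(ann$term_id[i], naive_ancestors(ont, ann$term_id[i]))
    for (t in terms_i) pairs[[t]] <- union(pairs[[t]], ann$gene_key[i])
  }
  lapply(pairs[order(names(pairs))], sort)
}

# textbook double-loop BH/BY/bonferroni oracle (no vector tricks)
naive_adjust <- function(p, method) {
  m <- length(p)
  if (method == "bonferroni") return(pmin(1, m * p))
  scale <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {                 # rank r in the sorted order
    cand <- Inf
    for (s in r:m) cand <- min(cand, scale * m * p[o[s]] / s)
    adj[o[r]] <- min(1, cand)
  }
  adj
}

# hypergeometric upper tail by direct enumeration with choose()
brute_tail <- function(k, n, K, N) {
  lo <- max(0, n + K - N); hi <- min(n, K)
  a <- lo:hi
  probs <- choose(K, a) * choose(N - K, n - a) / choose(N, n)
  sum(probs[a >= k])
}

strip_pdf_metadata <- function(path) {
  lines <- suppressWarnings(readLines(path, warn = FALSE, skipNul = TRUE))
  lines[!grepl("CreationDate|ModDate|/Producer", lines, useBytes = TRUE)]
}
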