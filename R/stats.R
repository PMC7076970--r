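#' Upper tail of the hypergeometric distribution
#'
#' For a term annotated to `K` of `N` background genes and a query of
#' `n` background genes overlapping the term in `k` genes, returns
#' P(X >= k) where X ~ Hypergeometric(N, K, n): the exact
#' over-representation p-value. The tail is accumulated in log space
#' over the support of X, so extreme counts do not underflow.
#'
#' @param k query genes annotated to the term. Vectorised; `n`, `K`,
#'   `N` recycle against it.
#' @param n query genes present in the background.
#' @param K background genes annotated to the term.
#' @param N background size.
#' @return Numeric vector of tail probabilities; exactly 1 when
#'   `k == 0`.
#' @seealso [fisher_exact_greater()], which must agree to within 1e-12
#'   relative on every valid input.
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  cc <- validate_counts(k, n, K, N)
  out <- numeric(length(cc$k))
  grp <- paste(cc$n, cc$K, cc$N, sep = "/")
  for (g in unique(grp)) {
    i <- which(grp == g)
    n_ <- cc$n[i[1]]; K_ <- cc$K[i[1]]; N_ <- cc$N[i[1]]
    lo <- max(0L, n_ + K_ - N_)
    hi <- min(n_, K_)
    a <- lo:hi
    # log pmf conditioning on drawing n from K successes / N-K failures
    lp <- lchoose(K_, a) + lchoose(N_ - K_, n_ - a) - lchoose(N_, n_)
    lt <- log_tail_from_top(lp)         # lt[j] = log P(X >= a[j])
    kk <- cc$k[i]
    p <- ifelse(kk <= lo, 0,            # log 1
                ifelse(kk > hi, -Inf, lt[pmax(kk, lo) - lo + 1L]))
    out[i] <- exp(p)
  }
  out[cc$k == 0L] <- 1  # P(X >= 0) is exactly 1
  out
}

#' One-sided (greater) Fisher exact test on the enrichment 2x2 table
#'
#' Tests the table `[[k, n-k], [K-k, N-K-n+k]]` against the alternative
#' of over-representation. Computed by enumerating the conditional
#' distribution of the table's top-left cell at odds ratio 1 — a route
#' algebraically identical to, but computed differently from,
#' [hypergeom_upper_tail()] (it conditions on the other margin); the
#' two must agree to within 1e-12 relative.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Numeric vector of one-sided p-values.
#' @export
fisher_exact_greater <- function(k, n, K, N) {
  cc <- validate_counts(k, n, K, N)
  out <- numeric(length(cc$k))
  grp <- paste(cc$n, cc$K, cc$N, sep = "/")
  for (g in unique(grp)) {
    i <- which(grp == g)
    n_ <- cc$n[i[1]]; K_ <- cc$K[i[1]]; N_ <- cc$N[i[1]]
    lo <- max(0L, n_ + K_ - N_)
    hi <- min(n_, K_)
    a <- lo:hi
    # log pmf conditioning on distributing K successes over n / N-n slots
    lp <- lchoose(n_, a) + lchoose(N_ - n_, K_ - a) - lchoose(N_, K_)
    lt <- log_tail_from_top(lp)
    kk <- cc$k[i]
    p <- ifelse(kk <= lo, 0,
                ifelse(kk > hi, -Inf, lt[pmax(kk, lo) - lo + 1L]))
    out[i] <- exp(p)
  }
  out[cc$k == 0L] <- 1
  out
}

# cumulative logsumexp from the top of the support:
# returns t with t[j] = log sum_{m >= j} exp(lp[m])
log_tail_from_top <- function(lp) {
  m <- length(lp)
  t <- numeric(m)
  t[m] <- lp[m]
  if (m > 1L) {
    for (j in (m - 1L):1L) {
      hi <- max(lp[j], t[j + 1L])
      t[j] <- if (is.infinite(hi) && hi < 0) -Inf
              else hi + log1p(exp(min(lp[j], t[j + 1L]) - hi))
    }
  }
  t
}

validate_counts <- function(k, n, K, N) {
  len <- max(length(k), length(n), length(K), length(N))
  k <- as.integer(rep_len(k, len)); n <- as.integer(rep_len(n, len))
  K <- as.integer(rep_len(K, len)); N <- as.integer(rep_len(N, len))
  if (any(N < 1L)) stop("invalid counts: N >= 1 violated", call. = FALSE)
  if (any(n > N)) stop("invalid counts: n <= N violated", call. = FALSE)
  if (any(K > N)) stop("invalid counts: K <= N violated", call. = FALSE)
  if (any(k < 0L)) stop("invalid counts: k >= 0 violated", call. = FALSE)
  if (any(k > pmin(n, K))) {
    stop("invalid counts: k <= min(n, K) violated", call. = FALSE)
  }
  if (any(n < 0L) || any(K < 0L)) {
    stop("invalid counts: n >= 0 and K >= 0 violated", call. = FALSE)
  }
  list(k = k, n = n, K = K, N = N)
}

#' Multiple-testing adjustment of p-values
#'
#' Hand-implemented step procedures, returned in the original order:
#' `BH` — Benjamini-Hochberg step-up, p(i) * m / i with a cumulative
#' minimum from the largest p down and a cap at 1; `BY` —
#' Benjamini-Yekutieli, BH scaled by the harmonic sum
#' 1 + 1/2 + ... + 1/m; `bonferroni` — min(1, m * p). `"fdr"`/`"FDR"`
#' are accepted as aliases of BH.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method one of `"BH"`, `"BY"`, `"bonferroni"` (or the alias
#'   `"fdr"`).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY", "bonferroni", "fdr", "FDR")) {
  method <- match.arg(method)
  if (method %in% c("fdr", "FDR")) method <- "BH"
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (method == "bonferroni") return(pmin(1, m * p))
  # BH / BY step-up: walk from the largest p down, carrying the min
  o <- order(p, decreasing = TRUE)
  scale <- if (method == "BY") sum(1 / seq_len(m)) else 1
  adj_desc <- pmin(1, cummin(scale * m / (m:1) * p[o]))
  out <- numeric(m)
  out[o] <- adj_desc
  out
}

#' Fold enrichment of a term in a query
#'
#' The observed query proportion divided by the background proportion:
#' (k/n) / (K/N). Equals 1 when the query hits the term exactly at its
#' background rate, and 0 when `k == 0`.
#'
#' @inheritParams hypergeom_upper_tail
#' @return Numeric vector of fold-enrichment ratios.
#' @export
fold_enrichment <- function(k, n, K, N) {
  cc <- validate_counts(k, n, K, N)
  if (any(cc$n < 1L)) stop("fold enrichment needs n >= 1", call. = FALSE)
  if (any(cc$K < 1L)) stop("fold enrichment needs K >= 1", call. = FALSE)
  (cc$k / cc$n) / (cc$K / cc$N)
}
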