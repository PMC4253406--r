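#' Fisher's exact overlap p-value (hypergeometric upper tail)
#'
#' Probability of observing at least `k` genes of a `K`-gene term in a
#' random query of size `n` drawn from an `N`-gene universe; computed in
#' log space by the hypergeometric distribution function.
#'
#' @param k Observed overlap.
#' @param query_size Query list size `n`.
#' @param term_size Term size `K`.
#' @param universe_size Universe size `N`.
#' @return Upper-tail p-value `P(X >= k)` in (0, 1].
#' @export
fisher_p <- function(k, query_size, term_size, universe_size) {
  if (any(k > pmin(query_size, term_size)) ||
      any(query_size > universe_size) || any(term_size > universe_size) ||
      any(k < 0))
    stopf("inconsistent contingency sizes")
  p <- phyper(k - 1, term_size, universe_size - term_size, query_size,
              lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

## Rank all terms by ascending Fisher p. Tied p-values share their
## average rank: deterministic, and unbiased for exchangeable terms
## (breaking ties by term identifier would systematically favor
## lexicographically early terms when many terms tie at p = 1).
rank_terms <- function(pvals, term_ids) {
  rank(pvals, ties.method = "average")
}

## Overlaps of one query with every term in the library.
term_overlaps <- function(query, library) {
  vapply(library$sets, function(s) length(intersect(query, s)),
         integer(1))
}

#' Monte-Carlo expected-rank calibration
#'
#' Draws `B` uniform random gene lists of the query's size from the
#' universe; for each draw, all terms are ranked by ascending Fisher
#' p-value (tied p-values share their average rank) and each term's rank is
#' recorded. The per-term mean and sample SD of these ranks calibrate the
#' rank z-score of the combined enrichment score.
#'
#' @param library A [gene_set_library].
#' @param query_size Size of the random queries.
#' @param B Number of Monte-Carlo draws (>= 2).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param term Optional single term name; if given, a list
#'   `(mu, sigma)` for that term is returned instead of the full table.
#' @return data.frame with columns `term`, `mu`, `sigma` (or the single
#'   term's list). Terms whose rank never varies get `sigma = 0` and are
#'   flagged downstream (z forced to 0).
#' @export
rank_calibration <- function(library, query_size, B = 1000L, seed,
                             term = NULL) {
  if (B < 2L) stopf("B must be >= 2")
  if (length(library$sets) < 2L) stopf("library needs >= 2 terms")
  if (missing(seed)) stopf("seed is mandatory")
  terms <- names(library$sets)
  N <- length(library$universe)
  K <- lengths(library$sets)
  ## term x gene membership for fast overlap counting
  memb <- vapply(library$sets, function(s) library$universe %in% s,
                 logical(N))
  set.seed(seed)
  ranks <- matrix(0L, B, length(terms))
  for (b in seq_len(B)) {
    idx <- sample.int(N, query_size)
    k <- colSums(memb[idx, , drop = FALSE])
    p <- fisher_p(k, query_size, K, N)
    ranks[b, ] <- rank_terms(p, terms)
  }
  out <- data.frame(term = terms,
                    mu = colMeans(ranks),
                    sigma = apply(ranks, 2, sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(term)) {
    i <- match(term, terms)
    if (is.na(i)) stopf("unknown term %s", term)
    return(list(mu = out$mu[i], sigma = out$sigma[i]))
  }
  out
}

#' Combined enrichment score
#'
#' `c = ln(fisher_p) * z` with `z = (rank - mu) / sigma`; a term ranking
#' better than expected (`z < 0`) with a small Fisher p (`ln p < 0`)
#' scores positively. Degenerate calibration (`sigma = 0`) forces
#' `z = 0`, hence `c = 0`.
#'
#' @param fisher_p Fisher exact p-value in (0, 1].
#' @param rank Observed rank of the term (ascending p).
#' @param mu,sigma Expected rank and rank SD from [rank_calibration()].
#' @return The combined score (>= 0 is not enforced; enriched terms are
#'   positive).
#' @export
combined_score <- function(fisher_p, rank, mu, sigma) {
  if (any(fisher_p <= 0)) stopf("fisher_p must be > 0")
  z <- ifelse(sigma > 0, (rank - mu) / sigma, 0)
  log(fisher_p) * z
}

#' Gene-set enrichment with the combined Fisher/rank-z score
#'
#' Scores every library term against a query gene list: Fisher exact
#' overlap p, observed rank among terms, Monte-Carlo expected rank, rank
#' z-score and combined score `ln(p) * z`. Scores from down-regulated
#' query lists are negated for reporting (the magnitude is direction
#' invariant). BH q-values over the Fisher p-values are reported as
#' additional information.
#'
#' @param query Character vector of query genes; genes outside the
#'   library universe are dropped (their count is recorded in the
#'   `n_dropped` attribute, with a warning).
#' @param direction `"up"` or `"down"`; down negates reported scores.
#' @param library A [gene_set_library].
#' @param B Monte-Carlo draws for rank calibration.
#' @param seed Integer seed for the calibration.
#' @return data.frame sorted by decreasing `|combined_score|` with
#'   columns `term`, `overlap`, `term_size`, `fisher_p`, `q`, `rank`,
#'   `expected_rank`, `rank_sd`, `z`, `combined_score`, `direction`.
#' @export
enrich <- function(query, direction = c("up", "down"), library,
                   B = 1000L, seed = 17L) {
  direction <- match.arg(direction)
  q0 <- unique(query)
  query <- intersect(q0, library$universe)
  n_dropped <- length(q0) - length(query)
  if (n_dropped > 0L)
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    n_dropped))
  if (length(query) == 0L)
    stopf("empty query after universe intersection")
  terms <- names(library$sets)
  N <- length(library$universe)
  K <- lengths(library$sets)
  k <- term_overlaps(query, library)
  p <- fisher_p(k, length(query), K, N)
  rk <- rank_terms(p, terms)
  cal <- rank_calibration(library, length(query), B = B, seed = seed)
  z <- ifelse(cal$sigma > 0, (rk - cal$mu) / cal$sigma, 0)
  cs <- log(p) * z
  sign_mult <- if (direction == "down") -1 else 1
  out <- data.frame(term = terms, overlap = unname(k),
                    term_size = unname(K), fisher_p = p, q = bh_fdr(p),
                    rank = rk, expected_rank = cal$mu,
                    rank_sd = cal$sigma, z = z,
                    combined_score = sign_mult * cs,
                    direction = direction, stringsAsFactors = FALSE)
  out <- out[order(-abs(out$combined_score), out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  attr(out, "log_base") <- "natural"
  out
}
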