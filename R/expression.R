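#' Differential-expression thresholds
#'
#' @param fc_min Fold-change lower bound (> 1); applied as
#'   `|log2FC| >= log2(fc_min)`.
#' @param fdr_max BH-FDR bound for the negative-binomial stage.
#' @param p_max Raw-p bound for the moderated-t stage.
#' @return List of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_min = 2, fdr_max = 0.01, p_max = 0.05) {
  if (!(fc_min > 1)) stopf("fc_min must be > 1")
  if (!(fdr_max > 0 && fdr_max < 1 && p_max > 0 && p_max < 1))
    stopf("fdr_max and p_max must lie in (0, 1)")
  structure(list(fc_min = fc_min, fdr_max = fdr_max, p_max = p_max),
            class = "de_thresholds")
}

counts_of <- function(x) if (inherits(x, "panel_counts")) x$counts else
  as.matrix(x)

#' Counts per million and log-CPM
#'
#' `cpm()` scales each sample to one million mapped reads; `log_cpm()`
#' applies the prior-damped log2 transform
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)`.
#'
#' @param counts A [panel_counts] object or a counts matrix.
#' @param prior Prior count added before the log (default 0.5).
#' @return Numeric matrix of the same dimensions.
#' @export
cpm <- function(counts) {
  m <- counts_of(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stopf("zero library size")
  sweep(m, 2, lib / 1e6, `/`)
}

#' @rdname cpm
#' @export
log_cpm <- function(counts, prior = 0.5) {
  m <- counts_of(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stopf("zero library size")
  log2(sweep(m + prior, 2, (lib + 2 * prior) / 1e6, `/`))
}

#' Equalize library sizes for the exact test
#'
#' Scales every sample's counts linearly to the geometric mean of the
#' library sizes and rounds to integers, so group sums are comparable
#' under the conditional negative-binomial model. The per-sample scale
#' factors applied are recorded in the `scale_factors` attribute.
#'
#' @param counts A [panel_counts] object or counts matrix.
#' @return Integer matrix of pseudo-counts with attribute `scale_factors`.
#' @export
equalize_libsizes <- function(counts) {
  m <- counts_of(counts)
  lib <- colSums(m)
  if (any(lib == 0)) stopf("zero library size")
  target <- exp(mean(log(lib)))
  f <- target / lib
  out <- round(sweep(m, 2, f, `*`))
  storage.mode(out) <- "integer"
  attr(out, "scale_factors") <- f
  out
}

## Conditional NB log-likelihood of the whole matrix at dispersion phi,
## summed over genes and over groups with >= 2 samples.
cond_loglik <- function(m, groups, phi) {
  r <- 1 / phi
  total <- 0
  for (g in levels(groups)) {
    y <- m[, groups == g, drop = FALSE]
    n <- ncol(y)
    if (n < 2L) next
    z <- rowSums(y)
    total <- total +
      sum(lgamma(y + r)) - length(y) * lgamma(r) - sum(lgamma(y + 1)) -
      sum(lgamma(z + n * r)) + nrow(y) * lgamma(n * r) +
      sum(lgamma(z + 1))
  }
  total
}

#' Estimate a common negative-binomial dispersion
#'
#' Maximizes the summed per-gene conditional NB log-likelihood (counts
#' conditional on each gene's group total, which removes the mean
#' parameter) over a log-spaced dispersion grid, after library-size
#' equalization. For Poisson data the estimate collapses to the grid
#' minimum.
#'
#' @param counts A [panel_counts] object or counts matrix.
#' @param groups Factor of group labels (ignored if `counts` is a
#'   [panel_counts]).
#' @param grid_range Dispersion grid limits (default `c(1e-6, 5)`).
#' @param grid_length Number of log-spaced grid points (default 200).
#' @return The dispersion `phi` maximizing the conditional likelihood.
#' @export
estimate_common_dispersion <- function(counts, groups = NULL,
                                       grid_range = c(1e-6, 5),
                                       grid_length = 200L) {
  if (inherits(counts, "panel_counts")) {
    groups <- counts$groups
  }
  groups <- droplevels(as.factor(groups))
  if (all(counts_of(counts) == 0)) stopf("all-zero count matrix")
  m <- equalize_libsizes(counts)
  if (max(table(groups)) < 2L)
    stopf("need >= 2 samples in at least one group")
  ## drop genes that cannot inform the conditional likelihood
  m <- m[rowSums(m) > 0, , drop = FALSE]
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_length))
  ll <- vapply(grid, function(phi) cond_loglik(m, groups, phi),
               numeric(1))
  grid[which.max(ll)]
}

## Log-probabilities of all splits (t, z - t) of a gene total z between
## two groups of sizes n1, n2 under NB with common dispersion phi.
split_logprob <- function(z, n1, n2, phi) {
  t <- 0:z
  if (phi == 0) {
    lp <- dbinom(t, z, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- 1 / phi
    m <- z / (n1 + n2)
    lp <- dnbinom(t, size = n1 * r, mu = n1 * m, log = TRUE) +
      dnbinom(z - t, size = n2 * r, mu = n2 * m, log = TRUE)
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  lp
}

#' Negative-binomial exact test for one gene
#'
#' Two-sided exact test of equal group means, conditional on the gene's
#' total count across samples (library sizes assumed equalized). The
#' p-value sums the probabilities of all group-sum splits no more
#' probable than the observed one (ties counted once); at `phi = 0` this
#' reduces to the exact binomial split test for Poisson counts.
#'
#' @param gene_counts Integer vector of equalized counts for one gene.
#' @param groups Factor with exactly two levels, one label per count.
#' @param phi Common dispersion (>= 0).
#' @return p-value in (0, 1].
#' @export
nb_exact_test <- function(gene_counts, groups, phi) {
  if (phi < 0) stopf("phi must be >= 0")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stopf("exactly two groups required")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  z1 <- sum(gene_counts[g1])
  z <- sum(gene_counts)
  if (z == 0L) return(1)
  lp <- split_logprob(z, n1, n2, phi)
  obs <- lp[z1 + 1L]
  p <- sum(exp(lp[lp <= obs + 1e-12]))
  min(max(p, exp(obs)), 1)
}

## Vectorized over genes; used by de_test.
nb_exact_test_all <- function(m, groups, phi) {
  vapply(seq_len(nrow(m)), function(i) nb_exact_test(m[i, ], groups, phi),
         numeric(1))
}

## Newton inversion of the trigamma function (for the log-F moment fit).
trigamma_inverse <- function(y) {
  if (y <= 1e-8) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    delta <- (trigamma(x) - y) / psigamma(x, deriv = 2)
    x <- x - delta
    if (x <= 0) x <- 1e-8
    if (abs(delta) < 1e-10 * x) break
  }
  x
}

#' Empirical-Bayes moderated t-test
#'
#' Gene-wise pooled residual variances (d residual degrees of freedom)
#' are shrunk toward a prior variance `s0^2` with `d0` prior degrees of
#' freedom: `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)`. The prior is
#' estimated by matching the observed mean and variance of `log s^2` to
#' the scaled log-F distribution implied by the hierarchical model; the
#' moderated statistic is referred to a t distribution on `d0 + d`
#' degrees of freedom.
#'
#' @param log_expr Gene x sample matrix of log2-scale expression
#'   (e.g. from [log_cpm()]).
#' @param groups Factor with exactly two levels.
#' @param prior.df Optional forced prior degrees of freedom `d0`; `0`
#'   gives the ordinary two-sample t-test, `Inf` complete pooling to
#'   `s0^2`. Default `NULL` estimates `d0` from the data.
#' @return data.frame with columns `gene`, `log2fc` (group 2 minus
#'   group 1 mean), `t`, `p`, `df_total`; attributes `df_prior` and
#'   `s2_prior`.
#' @export
moderated_t <- function(log_expr, groups, prior.df = NULL) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stopf("exactly two groups required")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  d <- n1 + n2 - 2L
  if (n1 < 2L || n2 < 2L || d < 1L)
    stopf(paste("no residual degrees of freedom for variance estimation;",
                "use the count-based exact test for unreplicated designs"))
  m1 <- rowMeans(log_expr[, g1, drop = FALSE])
  m2 <- rowMeans(log_expr[, !g1, drop = FALSE])
  ss <- rowSums((log_expr[, g1, drop = FALSE] - m1)^2) +
    rowSums((log_expr[, !g1, drop = FALSE] - m2)^2)
  s2 <- ss / d

  e <- log(s2[s2 > 0 & is.finite(s2)])
  if (length(e) < 2L) stopf("too few genes with positive variance")
  emean <- mean(e)
  evar <- var(e)
  if (is.null(prior.df)) {
    excess <- evar - trigamma(d / 2)
    d0 <- if (excess > 0) 2 * trigamma_inverse(excess) else Inf
  } else {
    d0 <- prior.df
  }
  log_s02 <- emean - digamma(d / 2) + log(d / 2) +
    (if (is.finite(d0) && d0 > 0) digamma(d0 / 2) - log(d0 / 2) else 0)
  s02 <- exp(log_s02)

  s2_tilde <- if (d0 == 0) s2 else if (is.infinite(d0))
    rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  df_total <- d + d0
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- data.frame(gene = rownames(log_expr) %||%
                      as.character(seq_len(nrow(log_expr))),
                    log2fc = m2 - m1, t = tstat, p = p,
                    df_total = df_total, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "df_prior") <- d0
  attr(out, "s2_prior") <- s02
  out
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p Numeric vector of p-values in [0, 1]; `NaN` is an error.
#' @return Vector of monotone BH q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p))) stopf("NaN/NA p-values")
  if (any(p < 0 | p > 1)) stopf("p-values outside [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}

#' Gate differential-expression results by fold change and significance
#'
#' @param results data.frame with columns `gene`, `log2fc`, `p`, `q`.
#' @param thresholds A [de_thresholds] object.
#' @param mode `"nb_fdr"` gates on `q < fdr_max`; `"modt_p"` gates on
#'   `p < p_max`. Both additionally require `|log2fc| >= log2(fc_min)`.
#' @return List with `up` and `down` gene vectors, `counts`
#'   (`total`, `n_up`, `n_down`) and `results` carrying a `direction`
#'   column (`up`/`down`/`ns`).
#' @export
call_de <- function(results, thresholds = de_thresholds(),
                    mode = c("nb_fdr", "modt_p")) {
  mode <- match.arg(mode)
  lfc <- log2(thresholds$fc_min)
  sig <- if (mode == "nb_fdr") results$q < thresholds$fdr_max else
    results$p < thresholds$p_max
  up <- sig & results$log2fc >= lfc
  down <- sig & results$log2fc <= -lfc
  results$direction <- ifelse(up, "up", ifelse(down, "down", "ns"))
  list(up = results$gene[up], down = results$gene[down],
       counts = c(total = sum(up) + sum(down), n_up = sum(up),
                  n_down = sum(down)),
       results = results)
}

#' Two-class differential expression, end to end
#'
#' Runs either the negative-binomial exact-test stage (common dispersion,
#' BH-FDR gate) or the moderated-t stage (log-CPM, raw-p gate) and
#' applies the fold-change/significance calls. Fold changes are group-2
#' over group-1 differences of mean log-CPM.
#'
#' @param counts A [panel_counts] object.
#' @param mode `"nb_fdr"` or `"modt_p"`.
#' @param thresholds A [de_thresholds] object.
#' @param prior Prior count for the log-CPM transform.
#' @return The [call_de()] list, with `phi` (NB mode) or `df_prior`
#'   (moderated-t mode) attached.
#' @export
de_test <- function(counts, mode = c("nb_fdr", "modt_p"),
                    thresholds = de_thresholds(), prior = 0.5) {
  mode <- match.arg(mode)
  groups <- counts$groups
  if (nlevels(groups) != 2L) stopf("exactly two groups required")
  lc <- log_cpm(counts, prior = prior)
  g1 <- groups == levels(groups)[1]
  lfc <- rowMeans(lc[, !g1, drop = FALSE]) -
    rowMeans(lc[, g1, drop = FALSE])
  if (mode == "nb_fdr") {
    phi <- estimate_common_dispersion(counts)
    m <- equalize_libsizes(counts)
    p <- nb_exact_test_all(m, groups, phi)
    res <- data.frame(gene = rownames(counts$counts) %||%
                        as.character(seq_len(nrow(counts$counts))),
                      log2fc = lfc, p = p, q = bh_fdr(p),
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    out <- call_de(res, thresholds, mode)
    out$phi <- phi
  } else {
    mt <- moderated_t(lc, groups)
    res <- data.frame(gene = mt$gene, log2fc = mt$log2fc, t = mt$t,
                      p = mt$p, q = bh_fdr(mt$p),
                      stringsAsFactors = FALSE)
    out <- call_de(res, thresholds, mode)
    out$df_prior <- attr(mt, "df_prior")
  }
  out
}
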