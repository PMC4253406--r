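test_that("cpm and log-cpm match their defining formulas", {
  m <- matrix(c(1, 1, 2), ncol = 1, dimnames = list(paste0("g", 1:3), "S"))
  expect_equal(unname(cpm(m))[, 1], c(250000, 250000, 500000))
  ## per-sample scale invariance
  m2 <- cbind(S1 = c(3, 5, 9), S2 = 2 * c(3, 5, 9))
  expect_equal(unname(cpm(m2)[, 1]), unname(cpm(m2)[, 2]))
  expect_equal(unname(colSums(cpm(m2))), c(1e6, 1e6))

  set.seed(5)
  r <- matrix(rpois(60, 40), 10)
  lib <- colSums(r)
  direct <- log2(sweep(r + 0.5, 2, (lib + 1) / 1e6, `/`))
  expect_equal(log_cpm(r, prior = 0.5), direct, tolerance = 1e-12)
  expect_error(cpm(matrix(0, 2, 1)), "library size")
})

test_that("library equalization targets the geometric mean", {
  m <- cbind(A = c(10L, 90L), B = c(40L, 360L))
  eq <- equalize_libsizes(m)
  expect_equal(unname(colSums(eq)), c(200, 200))
  expect_equal(unname(attr(eq, "scale_factors")), c(2, 0.5))
})

test_that("common dispersion recovery: Poisson, NB and degenerate data", {
  ## Poisson data collapses to the grid minimum
  cfg <- tiny_sim(31, de = list(phi = 0, n_up = 0L, n_down = 0L,
                                n_genes = 500L))
  sc <- simulate_counts(cfg)
  expect_lte(estimate_common_dispersion(sc$counts), 0.01)

  ## phi = 0.2 recovered
  cfg2 <- tiny_sim(32, de = list(phi = 0.2, n_up = 0L, n_down = 0L,
                                 n_genes = 500L))
  phi_hat <- estimate_common_dispersion(simulate_counts(cfg2)$counts)
  expect_gte(phi_hat, 0.15)
  expect_lte(phi_hat, 0.25)

  ## duplicated identical samples have no excess variance
  base <- matrix(rpois(200, 50), 100, 2)
  dup <- cbind(base[, 1], base[, 1], base[, 2], base[, 2])
  expect_equal(estimate_common_dispersion(
    dup, factor(c("a", "a", "b", "b"))), 1e-6)
  expect_error(estimate_common_dispersion(
    matrix(0L, 3, 4), factor(c("a", "a", "b", "b"))), "all-zero")
})

test_that("NB exact test: most-probable split, Poisson limit, symmetry", {
  g <- factor(rep(c("a", "b"), each = 3))
  ## equal group sums with equal sample counts -> p = 1
  expect_equal(nb_exact_test(c(5L, 5L, 5L, 5L, 5L, 5L), g, 0.1), 1)

  ## phi = 0 equals the conditional Poisson split test by enumeration
  set.seed(71)
  for (i in 1:20) {
    y <- rpois(6, sample(5:60, 1))
    z <- sum(y); z1 <- sum(y[1:3])
    lp <- dpois(0:z, 7, log = TRUE) + dpois(z:0, 7, log = TRUE)
    lp <- lp - max(lp) - log(sum(exp(lp - max(lp))))
    oracle <- sum(exp(lp)[lp <= lp[z1 + 1] + 1e-12])
    expect_equal(nb_exact_test(y, g, 0), oracle, tolerance = 1e-10)
  }

  ## relabeling the groups leaves p unchanged
  y <- c(3L, 9L, 4L, 30L, 22L, 41L)
  g_rev <- factor(rep(c("b", "a"), each = 3), levels = c("b", "a"))
  expect_equal(nb_exact_test(y, g, 0.15), nb_exact_test(y, g_rev, 0.15))

  expect_error(nb_exact_test(y, g, -1), "phi")
  p <- nb_exact_test(c(0L, 0L, 0L, 12L, 9L, 14L), g, 0.05)
  expect_gt(p, 0); expect_lte(p, 1)
})

test_that("NB exact test agrees with an independent exact-test implementation", {
  skip_if_not_installed("edgeR")
  set.seed(81)
  m <- matrix(rnbinom(400 * 6, size = 10, mu = 60), 400, 6,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:6)))
  g <- factor(rep(c("a", "b"), each = 3))
  phi <- 0.1
  p_mine <- vapply(seq_len(nrow(m)),
                   function(i) nb_exact_test(m[i, ], g, phi), numeric(1))
  dge <- edgeR::DGEList(counts = m, group = g)
  dge$samples$norm.factors <- 1
  dge$common.dispersion <- phi
  p_edger <- edgeR::exactTest(dge, dispersion = phi)$table$PValue
  expect_gt(cor(log(p_mine), log(p_edger)), 0.99)
  expect_lt(median(abs(log10(p_mine) - log10(p_edger))), 0.05)
})

test_that("moderated t: shrinkage limits and agreement with limma", {
  set.seed(13)
  x <- matrix(rnorm(500 * 8, sd = rep(sqrt(rchisq(500, 4) / 4), 8)),
              500, 8, dimnames = list(paste0("g", 1:500), NULL))
  g <- factor(rep(c("a", "b"), each = 4))

  ## d0 = 0 reduces to the ordinary two-sample t
  mt0 <- moderated_t(x, g, prior.df = 0)
  ord <- apply(x, 1, function(r)
    t.test(r[5:8], r[1:4], var.equal = TRUE)$statistic)
  expect_equal(mt0$t, unname(ord), tolerance = 1e-12)
  expect_equal(unique(mt0$df_total), 6)

  ## d0 = Inf pools every gene to the common variance
  mtI <- moderated_t(x, g, prior.df = Inf)
  s2 <- attr(mtI, "s2_prior")
  manual <- (rowMeans(x[, 5:8]) - rowMeans(x[, 1:4])) / sqrt(s2 / 2)
  expect_equal(mtI$t, unname(manual), tolerance = 1e-12)

  ## estimated prior matches limma's moment fit
  skip_if_not_installed("limma")
  fit <- limma::eBayes(limma::lmFit(x, cbind(1, as.integer(g) - 1)))
  mt <- moderated_t(x, g)
  expect_equal(attr(mt, "df_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mt, "s2_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$p, fit$p.value[, 2], ignore_attr = TRUE,
               tolerance = 1e-10)

  expect_error(moderated_t(x[, c(1, 5)], factor(c("a", "b"))),
               "degrees of freedom")
})

test_that("BH q-values match the brute-force step-up definition", {
  set.seed(17)
  for (i in 1:10) {
    p <- runif(sample(5:200, 1))^2
    q <- bh_fdr(p)
    m <- length(p)
    ## brute force: q_i = min over j with p_(j) >= p_i of p_(j) m / j
    o <- order(p)
    brute <- numeric(m)
    for (idx in seq_len(m)) {
      i_rank <- which(o == idx)
      brute[idx] <- min(pmin(p[o] * m / seq_len(m), 1)[i_rank:m])
    }
    expect_equal(q, brute, tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    ## monotone in sorted-p order
    expect_true(all(diff(q[o]) >= 0))
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")
})

test_that("DE calls gate on fold change and significance, totals add up", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(1.5, 0.9, -2.1, -1.2),
                    p = c(0.001, 0.001, 0.2, 0.01),
                    q = c(0.001, 0.001, 0.3, 0.004))
  out <- call_de(res, de_thresholds(), mode = "nb_fdr")
  expect_equal(out$up, "a")       # passes both gates
  expect_equal(out$down, "d")     # b fails FC, c fails FDR
  expect_equal(unname(out$counts), c(2L, 1L, 1L))
  out2 <- call_de(res, de_thresholds(), mode = "modt_p")
  expect_equal(out2$down, "d")
  expect_equal(sum(out2$counts[2:3]), unname(out2$counts[1]))
  expect_error(call_de(res, de_thresholds(), mode = "bogus"))
})

test_that("planted differential expression is recovered by both stages", {
  ## moderately expressed genes so recovery probes the tests, not the
  ## detection floor of near-zero-count genes
  cfg <- tiny_sim(55, de = list(n_genes = 1500L, n_group1 = 4L,
                                n_group2 = 4L, phi = 0.1,
                                meanlog = 5, sdlog = 1,
                                n_up = 30L, n_down = 50L, lfc = 2))
  sc <- simulate_counts(cfg)
  nb <- de_test(sc$counts, mode = "nb_fdr")
  expect_gte(nb$counts["n_up"], 27); expect_lte(nb$counts["n_up"], 33)
  expect_gte(nb$counts["n_down"], 45); expect_lte(nb$counts["n_down"], 55)
  ## direction matches the planted sign; few false calls among nulls
  tr <- merge(nb$results, sc$truth, by = "gene")
  expect_lte(sum(tr$status == "null" & tr$direction != "ns"), 5)
  expect_gt(mean(tr$direction[tr$status == "up"] == "up"), 0.85)

  mo <- de_test(sc$counts, mode = "modt_p")
  expect_gte(unname(mo$counts["total"]), 72)
})
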