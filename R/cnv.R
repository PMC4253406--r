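#' Copy-number thresholds
#'
#' Log2-ratio cutpoints for categorical copy-number calls and the
#' pseudocount used when forming ratios. Defaults are the conventional
#' exome-panel cutoffs: ratios at or below -1.3 are homozygous deletions,
#' (-1.3, -0.4] single-copy losses, [0.4, 1.0) gains, and >= 1.0
#' amplifications.
#'
#' @param t_homdel,t_loss,t_gain,t_amp Log2-ratio thresholds; must
#'   satisfy `t_homdel < t_loss < 0 < t_gain < t_amp`.
#' @param epsilon Pseudocount added to depth and baseline before the log
#'   ratio (guards zero depths).
#' @return List of class `cnv_thresholds`.
#' @export
cnv_thresholds <- function(t_homdel = -1.3, t_loss = -0.4,
                           t_gain = 0.4, t_amp = 1.0, epsilon = 1.0) {
  if (!(t_homdel < t_loss && t_loss < 0 && 0 < t_gain && t_gain < t_amp))
    stopf("thresholds must satisfy t_homdel < t_loss < 0 < t_gain < t_amp")
  structure(list(t_homdel = t_homdel, t_loss = t_loss, t_gain = t_gain,
                 t_amp = t_amp, epsilon = epsilon),
            class = "cnv_thresholds")
}

#' Median-scale a depth matrix across lines
#'
#' Each line (column) is rescaled so all per-line median depths equal the
#' grand median of the original per-line medians. Without this step,
#' library-size differences between lines masquerade as copy-number
#' change.
#'
#' @param matrix Gene x line matrix of mean capture depths (>= 0).
#' @return Scaled matrix with attribute `scale_factors`.
#' @export
scale_depths <- function(matrix) {
  zero <- colSums(matrix > 0) == 0L
  if (any(zero))
    stopf("line(s) with all-zero depths: %s",
          paste(colnames(matrix)[zero], collapse = ", "))
  med <- apply(matrix, 2, stats::median)
  if (any(med == 0))
    stopf("line(s) with zero median depth: %s",
          paste(colnames(matrix)[med == 0], collapse = ", "))
  target <- stats::median(med)
  f <- target / med
  out <- sweep(matrix, 2, f, `*`)
  attr(out, "scale_factors") <- f
  out
}

#' Pseudonormal baseline from panel average depths
#'
#' The copy-number baseline for each gene is the arithmetic mean of its
#' (scaled) depth across all panel lines, including the line later
#' compared against it; on a 22-line panel this self-inclusion attenuates
#' ratios by at most 1/22.
#'
#' @param matrix Scaled gene x line depth matrix.
#' @return Named numeric vector, one baseline per gene.
#' @export
pseudonormal <- function(matrix) {
  rowMeans(matrix)
}

#' Log2 depth ratios against the pseudonormal baseline
#'
#' @param matrix Scaled gene x line depth matrix.
#' @param baseline Per-gene baseline from [pseudonormal()].
#' @param epsilon Pseudocount; must be > 0 if any depth or baseline is 0.
#' @return Matrix of `log2((depth + epsilon) / (baseline + epsilon))`
#'   clamped to [-8, 8], with attribute `clamped` (logical matrix).
#' @export
log2_ratio <- function(matrix, baseline, epsilon = 1.0) {
  if (epsilon < 0) stopf("epsilon must be >= 0")
  if (epsilon == 0 && (any(matrix == 0) || any(baseline == 0)))
    stopf("epsilon = 0 with zero depth or baseline")
  r <- log2((matrix + epsilon) / (baseline + epsilon))
  clamped <- r < -8 | r > 8
  r[r < -8] <- -8
  r[r > 8] <- 8
  attr(r, "clamped") <- clamped
  r
}

#' Categorical copy-number calls from log2 ratios
#'
#' @param ratios Gene x line matrix of log2 ratios (or a numeric vector).
#' @param thresholds A [cnv_thresholds] object.
#' @return data.frame with columns `gene`, `line`, `log2_ratio`,
#'   `category` (factor: homozygous_deletion, loss, neutral, gain,
#'   amplification). For a bare vector, `gene`/`line` fall back to
#'   indices.
#' @export
call_cnv <- function(ratios, thresholds = cnv_thresholds()) {
  t <- thresholds
  m <- as.matrix(ratios)
  cat <- matrix("neutral", nrow(m), ncol(m))
  cat[m <= t$t_loss] <- "loss"
  cat[m <= t$t_homdel] <- "homozygous_deletion"
  cat[m >= t$t_gain] <- "gain"
  cat[m >= t$t_amp] <- "amplification"
  data.frame(
    gene = rep(rownames(m) %||% as.character(seq_len(nrow(m))),
               times = ncol(m)),
    line = rep(colnames(m) %||% as.character(seq_len(ncol(m))),
               each = nrow(m)),
    log2_ratio = as.numeric(m),
    category = factor(as.character(cat),
                      levels = c("homozygous_deletion", "loss", "neutral",
                                 "gain", "amplification")),
    stringsAsFactors = FALSE)
}

#' Full pseudonormal copy-number pipeline
#'
#' Convenience wrapper: median scaling, pseudonormal baseline, log2
#' ratios, categorical calls.
#'
#' @param depths Raw gene x line depth matrix.
#' @param thresholds A [cnv_thresholds] object.
#' @param sex_chrom_prefixes Chromosome-style gene-name prefixes (or an
#'   explicit character vector of genes via `sex_genes`) flagged as
#'   sex-linked in the output; no ploidy correction is applied.
#' @param sex_genes Optional character vector of sex-chromosome genes.
#' @return The [call_cnv()] data.frame with an extra logical column
#'   `sex_linked`.
#' @export
cnv_pipeline <- function(depths, thresholds = cnv_thresholds(),
                         sex_genes = character(0),
                         sex_chrom_prefixes = character(0)) {
  scaled <- scale_depths(depths)
  base <- pseudonormal(scaled)
  r <- log2_ratio(scaled, base, thresholds$epsilon)
  calls <- call_cnv(r, thresholds)
  flagged <- calls$gene %in% sex_genes
  for (p in sex_chrom_prefixes)
    flagged <- flagged | startsWith(calls$gene, p)
  calls$sex_linked <- flagged
  calls
}
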