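## Shared fixture builders; everything is generated in code at test time.

## A small panel configuration that keeps unit tests fast.
tiny_sim <- function(seed, ...) {
  base <- list(seed = seed,
               germline = list(count = 60L),
               artifact = list(count = 8L),
               somatic_private = list(count_per_line = 1L),
               somatic_hotspot = list(count = 4L, lines_carrying = 6L),
               cnv = list(n_genes = 200L),
               de = list(n_genes = 300L, n_group1 = 3L, n_group2 = 3L,
                         n_up = 10L, n_down = 10L),
               enrichment = list(n_terms = 10L, term_size = 20L))
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (nm %in% names(base) && is.list(base[[nm]]) &&
                        is.list(over[[nm]]))
      utils::modifyList(base[[nm]], over[[nm]]) else over[[nm]]
  }
  do.call(sim_config, base)
}

## Hand-built three-variant table on four lines.
toy_table <- function() {
  variants <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("T", "G", "A"),
    gene = c("TP53", "TP53", "FAT1"),
    effect = c("missense", "synonymous", "nonsense"),
    protein_change = c("R175H", NA, NA),
    score = c(-4.2, NA, NA),
    stringsAsFactors = FALSE)
  presence <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                    c(TRUE, FALSE, FALSE, FALSE),
                    c(FALSE, FALSE, TRUE, FALSE))
  panel_variants(variants, presence, c("L1", "L2", "L3", "L4"))
}

## Independent brute-force evaluation of the filter's set expression
## V \ ((P | R) \ C), record by record.
brute_force_kept <- function(table, db, catalog, config) {
  v <- table$variants
  n <- length(table$lines)
  kept <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    key <- v[i, c("chrom", "pos", "ref", "alt")]
    in_P <- pop_frequency(db, key) != 0
    in_R <- sum(table$presence[i, ]) / n > config$recurrence_fraction
    in_C <- hotspot_contains(catalog, key, gene = v$gene[i],
                             protein_change = v$protein_change[i])
    kept[i] <- !((in_P || in_R) && !(in_C && config$rescue_enabled))
  }
  sort(variant_id(v)[kept])
}

## Log-space hypergeometric enumeration, independent of phyper.
enum_hyper_upper <- function(k, n, K, N) {
  kk <- max(0, k):min(n, K)
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  sum(exp(lp))
}
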