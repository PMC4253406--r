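mini_db <- function(...) {
  rows <- list(...)
  if (!length(rows)) return(population_db())
  population_db(do.call(rbind, rows))
}
db_row <- function(chrom, pos, ref, alt, f)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             allele_frequency = f, stringsAsFactors = FALSE)

test_that("classification follows the population/recurrence/rescue rules", {
  db <- mini_db(db_row("chr1", 100, "A", "T", 0.004),
                db_row("chr1", 300, "G", "C", 0.02))
  cat <- hotspot_catalog(data.frame(
    chrom = "chr1", pos = 300, ref = "G", alt = "C",
    gene = NA, protein_change = NA, stringsAsFactors = FALSE))
  cfg <- filter_config()

  ## population-database rejection (any nonzero frequency)
  d <- classify_variant(variant_key("chr1", 100, "A", "T"), NULL,
                        1L, 22L, db, cat, cfg)
  expect_equal(d$status, "rejected")
  expect_equal(d$reason, "population_db")

  ## recurrence rejection above 15% of 22 lines
  d <- classify_variant(variant_key("chr2", 50, "C", "A"), NULL,
                        4L, 22L, db, cat, cfg)
  expect_equal(d$reason, "recurrent_panel")

  ## catalog rescue overrides a population hit
  d <- classify_variant(variant_key("chr1", 300, "G", "C"), NULL,
                        1L, 22L, db, cat, cfg)
  expect_equal(d$status, "kept")
  expect_true(d$rescued)

  ## no rule fires at the 3-line boundary
  d <- classify_variant(variant_key("chr2", 50, "C", "A"), NULL,
                        3L, 22L, db, cat, cfg)
  expect_equal(d$status, "kept")
  expect_equal(d$reason, "none")
  expect_false(d$rescued)

  ## both rules firing records the population reason (first in order)
  d <- classify_variant(variant_key("chr1", 100, "A", "T"), NULL,
                        10L, 22L, db, cat, cfg)
  expect_equal(d$reason, "population_db")

  ## rescue disabled
  d <- classify_variant(variant_key("chr1", 300, "G", "C"), NULL, 1L,
                        22L, db, cat, filter_config(rescue_enabled = FALSE))
  expect_equal(d$status, "rejected")

  expect_error(classify_variant(variant_key("chr1", 1, "A", "T"), NULL,
                                5L, 4L, db, cat, cfg), "presence_count")
  expect_error(classify_variant(variant_key("chr1", 1, "A", "T"), NULL,
                                0L, 0L, db, cat, cfg), "n_lines")
})

test_that("recurrence boundary on 22 lines: fires at 4, not at 3", {
  db <- population_db()
  cat <- hotspot_catalog()
  cfg <- filter_config(recurrence_fraction = 0.15)
  for (count in 0:22) {
    d <- classify_variant(variant_key("chr1", 1, "A", "T"), NULL,
                          count, 22L, db, cat, cfg)
    expect_equal(d$status, if (count >= 4) "rejected" else "kept",
                 label = sprintf("presence %d", count))
  }
})

test_that("apply_filter equals the brute-force set expression on seeded panels", {
  for (seed in 1:5) {
    sp <- simulate_panel(tiny_sim(seed))
    res <- apply_filter(sp$table, sp$popdb, sp$catalog, filter_config())
    expect_equal(sort(variant_id(res$filtered$variants)),
                 brute_force_kept(sp$table, sp$popdb, sp$catalog,
                                  filter_config()))
    ## one decision per record; totals consistent
    expect_equal(nrow(res$decisions), nrow(sp$table$variants))
    expect_equal(unname(res$summary["kept"]), nrow(res$filtered$variants))
  }
})

test_that("filter is order invariant and byte-deterministic", {
  sp <- simulate_panel(tiny_sim(3))
  res1 <- apply_filter(sp$table, sp$popdb, sp$catalog)
  set.seed(42)
  perm <- sample(nrow(sp$table$variants))
  shuffled <- panel_variants(sp$table$variants[perm, ],
                             sp$table$presence[perm, , drop = FALSE],
                             sp$table$lines)
  res2 <- apply_filter(shuffled, sp$popdb, sp$catalog)
  expect_setequal(variant_id(res2$filtered$variants),
                  variant_id(res1$filtered$variants))
  ## identical inputs -> identical decision report bytes
  f1 <- tempfile(); f2 <- tempfile()
  write_tsv_prov(res1$decisions, f1)
  write_tsv_prov(apply_filter(sp$table, sp$popdb, sp$catalog)$decisions,
                 f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("catalog growth never shrinks and DB growth never grows the kept set", {
  sp <- simulate_panel(tiny_sim(7))
  base <- apply_filter(sp$table, sp$popdb, sp$catalog)
  kept0 <- variant_id(base$filtered$variants)

  ## enlarge the catalog with some currently-rejected keys
  rej <- base$decisions[base$decisions$status == "rejected", ][1:5, ]
  bigger_cat <- hotspot_catalog(rbind(
    sp$catalog_df,
    data.frame(rej[, c("chrom", "pos", "ref", "alt")], gene = NA,
               protein_change = NA, stringsAsFactors = FALSE)))
  kept1 <- variant_id(apply_filter(sp$table, sp$popdb,
                                   bigger_cat)$filtered$variants)
  expect_true(all(kept0 %in% kept1))

  ## enlarge the population DB with some currently-kept keys
  kp <- base$filtered$variants[1:5, ]
  bigger_db <- population_db(rbind(
    sp$popdb_df,
    data.frame(kp[, c("chrom", "pos", "ref", "alt")],
               allele_frequency = 0.01, stringsAsFactors = FALSE)))
  kept2 <- variant_id(apply_filter(sp$table, bigger_db,
                                   sp$catalog)$filtered$variants)
  expect_true(all(kept2 %in% kept0))
})

test_that("empty tables and all-catalog tables behave as stated", {
  sp <- simulate_panel(tiny_sim(2))
  empty <- panel_variants(sp$table$variants[0, ],
                          sp$table$presence[0, , drop = FALSE],
                          sp$table$lines)
  res <- apply_filter(empty, sp$popdb, sp$catalog)
  expect_equal(nrow(res$decisions), 0L)
  expect_equal(nrow(res$filtered$variants), 0L)

  ## every variant in the catalog -> everything kept (rescue dominates)
  v <- sp$table$variants
  allcat <- hotspot_catalog(data.frame(
    v[, c("chrom", "pos", "ref", "alt")], gene = NA, protein_change = NA,
    stringsAsFactors = FALSE))
  res2 <- apply_filter(sp$table, sp$popdb, allcat)
  expect_equal(nrow(res2$filtered$variants), nrow(v))
})

test_that("per-gene mutation frequency counts lines once per gene", {
  tab <- toy_table()
  freq <- gene_mutation_frequency(tab)
  ## TP53: synonymous variant excluded, missense in L1+L2 -> 2/4
  expect_equal(freq$n_lines_mutated[freq$gene == "TP53"], 2L)
  expect_equal(freq$fraction[freq$gene == "TP53"], 0.5)
  expect_equal(freq$n_lines_mutated[freq$gene == "FAT1"], 1L)
  ## absent gene reported as no row (fraction 0 by convention)
  expect_false("PTEN" %in% freq$gene)
  expect_error(gene_mutation_frequency(tab, effect_filter = "weird"),
               "unknown effect")

  ## brute-force counting oracle on a synthetic panel
  sp <- simulate_panel(tiny_sim(9))
  kept <- apply_filter(sp$table, sp$popdb, sp$catalog)$filtered
  freq2 <- gene_mutation_frequency(kept)
  v <- kept$variants
  altering <- v$effect != "synonymous"
  for (g in freq2$gene[1:10]) {
    rows <- which(v$gene == g & altering)
    manual <- sum(apply(kept$presence[rows, , drop = FALSE], 2, any))
    expect_equal(freq2$n_lines_mutated[freq2$gene == g], manual)
  }
  ## ordering: descending fraction then gene symbol
  expect_true(all(diff(freq2$fraction) <= 0))
})

test_that("panel membership restriction drops non-member lines and counts", {
  sp <- simulate_panel(tiny_sim(5))
  members <- sp$table$lines[1:20]
  res <- apply_filter(sp$table, sp$popdb, sp$catalog,
                      panel_members = members)
  expect_equal(res$filtered$lines, members)
  expect_true(all(res$decisions$presence_count <= 20))
  expect_error(apply_filter(sp$table, sp$popdb, sp$catalog,
                            panel_members = c("L01", "NOPE")), "NOPE")
})
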