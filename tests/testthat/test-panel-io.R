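vcf_text <- function(records, samples = c("S1", "S2")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("multi-sample VCF reading: genotypes, multi-allelic split", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_text(c(
    "chr1\t100\t.\tA\tT\t.\tPASS\tGENE=TP53;EFFECT=missense\tGT\t0/1\t0/0",
    "chr2\t200\t.\tG\tA,T\t.\tPASS\tGENE=FAT1;EFFECT=missense\tGT\t1/2\t0/2"
  )), f)
  tab <- read_multisample_vcf(f)
  expect_equal(tab$lines, c("S1", "S2"))
  expect_equal(nrow(tab$variants), 3L)  # biallelic + 2 from the split
  ## biallelic: presence follows GT
  i <- which(tab$variants$pos == 100)
  expect_equal(unname(tab$presence[i, ]), c(TRUE, FALSE))
  ## split shares chrom/pos/ref; allele-specific presence
  alt_a <- which(tab$variants$pos == 200 & tab$variants$alt == "A")
  alt_t <- which(tab$variants$pos == 200 & tab$variants$alt == "T")
  expect_equal(unname(tab$presence[alt_a, ]), c(TRUE, FALSE))
  expect_equal(unname(tab$presence[alt_t, ]), c(TRUE, TRUE))
})

test_that("unparseable genotypes are counted and treated as absent", {
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf_text(
    "chr1\t100\t.\tA\tT\t.\tPASS\tGENE=X;EFFECT=other\tGT\tbad\t0/1"), f)
  expect_warning(tab <- read_multisample_vcf(f), "unparseable")
  expect_equal(attr(tab, "parse_report")$n_bad_genotypes, 1L)
  expect_equal(unname(tab$presence[1, ]), c(FALSE, TRUE))
})

test_that("VCF write/read round trip preserves keys and presence flags", {
  sp <- simulate_panel(tiny_sim(11))
  f <- tempfile(fileext = ".vcf")
  write_filtered_vcf(sp$table, f)
  back <- read_multisample_vcf(f)
  expect_equal(back$lines, sp$table$lines)
  ids0 <- variant_id(sp$table$variants)
  ids1 <- variant_id(back$variants)
  expect_setequal(ids1, ids0)
  o <- match(ids0, ids1)
  expect_equal(unname(back$presence[o, ]), unname(sp$table$presence))
  expect_equal(back$variants$gene[o], sp$table$variants$gene)
})

test_that("population DB: lookup, empty DB, duplicate collapse, validation", {
  f <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tallele_frequency",
               "chr1\t100\tA\tT\t0.004",
               "chr1\t100\tA\tT\t0.02",
               "chr2\t5\tG\tC\t0"), f)
  db <- read_population_db(f)
  expect_equal(pop_frequency(db, variant_key("chr1", 100, "A", "T")),
               0.02)  # duplicates collapse to the max
  expect_equal(pop_frequency(db, variant_key("chr9", 1, "A", "T")), 0)

  empty <- tempfile()
  writeLines("chrom\tpos\tref\talt\tallele_frequency", empty)
  dbe <- read_population_db(empty)
  expect_equal(pop_frequency(dbe, variant_key("chr1", 100, "A", "T")), 0)

  bad <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tallele_frequency",
               "chr1\t100\tA\tT\t1.5"), bad)
  expect_error(read_population_db(bad), "row 1")
})

test_that("hotspot catalog: genomic key, secondary index, validation", {
  f <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tgene\tprotein_change",
               "chr17\t7577\tC\tT\tTP53\tR175H",
               ".\t.\t.\t.\tPIK3CA\tE545K"), f)
  cat <- read_hotspot_catalog(f)
  expect_true(hotspot_contains(cat, variant_key("chr17", 7577, "C", "T")))
  expect_false(hotspot_contains(cat, variant_key("chr17", 7578, "C", "T")))
  ## secondary index fires only with matching gene + protein change
  k <- variant_key("chr3", 1789, "G", "A")
  expect_true(hotspot_contains(cat, k, gene = "PIK3CA",
                               protein_change = "E545K"))
  expect_false(hotspot_contains(cat, k, gene = "PIK3CA",
                                protein_change = "H1047R"))

  bad <- tempfile()
  writeLines(c("chrom\tpos\tref\talt\tgene\tprotein_change",
               ".\t.\t.\t.\t.\t."), bad)
  expect_error(read_hotspot_catalog(bad), "neither")
})

test_that("count matrix reader validates shapes, labels and integer counts", {
  cf <- tempfile(); gf <- tempfile()
  writeLines(c("gene\tS1\tS2", "g1\t1\t4", "g2\t1\t0", "g3\t2\t6"), cf)
  writeLines(c("sample\tgroup", "S1\ta", "S2\tb"), gf)
  pc <- read_count_matrix(cf, gf)
  expect_equal(dim(pc$counts), c(3L, 2L))
  expect_equal(unname(pc$lib.size), c(4, 10))
  expect_equal(as.character(pc$groups), c("a", "b"))

  gf2 <- tempfile()
  writeLines(c("sample\tgroup", "S1\ta"), gf2)
  expect_error(read_count_matrix(cf, gf2), "S2")
  expect_error(panel_counts(matrix(c(1, -1), 1), factor(c("a", "b"))),
               "nonnegative")
  expect_error(panel_counts(matrix(c(1, 1.5), 1), factor(c("a", "b"))),
               "nonnegative")
})

test_that("GMT parsing and universe handling", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("TERM1\tdesc\tA\tB\tC", "TERM2\tdesc\tB\tD"), f)
  lib <- read_gene_sets(f)
  expect_equal(sort(lib$sets$TERM1), c("A", "B", "C"))
  expect_equal(length(lib$sets$TERM2), 2L)
  expect_setequal(lib$universe, c("A", "B", "C", "D"))
  ## explicit universe drops outside genes
  lib2 <- read_gene_sets(f, universe = c("A", "B", "C", "D", "E"))
  expect_equal(length(lib2$universe), 5L)
  expect_error(read_gene_sets(f, universe = c("A", "C", "X")), "TERM2")
})

test_that("table write/read round trip is exact for integer tables", {
  df <- data.frame(gene = c("g1", "g2"), n = c(10L, 2147480000L),
                   frac = c(1L, 0L))
  dir <- tempfile()
  paths <- write_tables(list(tab = df), dir, config = list(a = 1))
  expect_true(file.exists(paths))
  hdr <- readLines(paths, n = 2)
  expect_match(hdr[1], "^# oncopanel")
  expect_match(hdr[2], "^# config_hash [0-9a-f]{8}$")
  back <- read_tsv_prov(paths)
  expect_identical(back$n, df$n)
  expect_identical(back$gene, df$gene)
})
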