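## Readers and writers for the external formats the pipeline consumes:
## multi-sample VCF, population allele-frequency TSV, hotspot catalog TSV,
## count/depth matrices, GMT gene-set libraries, and result tables.

VALID_EFFECTS <- c("synonymous", "missense", "nonsense", "frameshift",
                   "splice", "other")

#' Panel variant table
#'
#' Container for the normalized variants of a multi-sample panel: one row
#' per (site, alt allele) with per-line presence flags and functional
#' annotation. Duplicate keys arising after normalization are collapsed by
#' OR-ing their presence vectors (first annotation wins).
#'
#' @param variants data.frame with columns `chrom, pos, ref, alt, gene,
#'   effect, protein_change, score`. `effect` must be one of
#'   `r paste(VALID_EFFECTS, collapse = ", ")`; `protein_change` and
#'   `score` may be `NA`.
#' @param presence Logical matrix, one row per variant, one column per line.
#' @param lines Character vector of unique line identifiers (column names
#'   of `presence`).
#' @return An object of class `panel_variants`.
#' @export
panel_variants <- function(variants, presence, lines = colnames(presence)) {
  presence <- as.matrix(presence)
  if (anyDuplicated(lines)) stopf("line identifiers must be unique")
  if (ncol(presence) != length(lines))
    stopf("presence has %d columns for %d lines", ncol(presence),
          length(lines))
  if (nrow(presence) != nrow(variants))
    stopf("presence rows (%d) != variant rows (%d)", nrow(presence),
          nrow(variants))
  if (!all(variants$effect %in% VALID_EFFECTS))
    stopf("unknown effect class: %s",
          paste(setdiff(unique(variants$effect), VALID_EFFECTS),
                collapse = ", "))
  colnames(presence) <- lines
  key <- normalize_variant(variants[, c("chrom", "pos", "ref", "alt")])
  variants$pos <- key$pos
  variants$ref <- key$ref
  variants$alt <- key$alt
  ids <- variant_id(variants)
  if (anyDuplicated(ids)) {
    keep <- !duplicated(ids)
    for (d in which(duplicated(ids))) {
      i <- match(ids[d], ids)
      presence[i, ] <- presence[i, ] | presence[d, ]
    }
    variants <- variants[keep, , drop = FALSE]
    presence <- presence[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  rownames(variants) <- NULL
  rownames(presence) <- NULL
  structure(list(lines = lines, variants = variants,
                 presence = presence),
            class = "panel_variants")
}

#' @export
print.panel_variants <- function(x, ...) {
  cat(sprintf("panel_variants: %d variants x %d lines\n",
              nrow(x$variants), length(x$lines)))
  invisible(x)
}

#' Read a multi-sample VCF into a panel variant table
#'
#' Multi-allelic sites are split into one record per alternate allele; a
#' line is flagged as carrying the variant iff its genotype contains at
#' least one copy of that allele (no depth or VAF threshold is applied).
#' Unparseable genotypes are treated as absent, with a warning, and
#' counted in the `parse_report` attribute of the result.
#'
#' @param path Path to a VCF v4.x file with at least one sample column.
#' @param annotation_fields Named character vector mapping the annotation
#'   slots `gene`, `effect`, `protein_change`, `score` to INFO keys.
#' @return A [panel_variants] object with attribute `parse_report`
#'   (list with `n_bad_genotypes`).
#' @export
read_multisample_vcf <- function(path,
                                 annotation_fields = c(
                                   gene = "GENE", effect = "EFFECT",
                                   protein_change = "PCHANGE",
                                   score = "SCORE")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(vcf@gt) < 2L)
    stopf("VCF %s has no sample columns", path)
  lines <- colnames(vcf@gt)[-1]
  fix <- vcf@fix
  gt <- vcfR::extract.gt(vcf, element = "GT")
  info_get <- function(slot) {
    key <- annotation_fields[[slot]]
    if (is.null(key) || is.na(key)) return(rep(NA_character_, nrow(fix)))
    vcfR::extract.info(vcf, element = key)
  }
  gene <- info_get("gene")
  effect <- info_get("effect")
  pchange <- info_get("protein_change")
  score <- suppressWarnings(as.numeric(info_get("score")))

  n_bad <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt[i, ]
    toks <- lapply(strsplit(gts, "[/|]"), function(t) t[t != "."])
    ok <- vapply(toks, function(t) all(grepl("^[0-9]+$", t)) ,
                 logical(1)) & !is.na(gts)
    n_bad <- n_bad + sum(!ok & !is.na(gts) & gts != ".")
    pres <- matrix(FALSE, length(alts), length(lines))
    for (a in seq_along(alts)) {
      pres[a, ] <- vapply(seq_along(toks), function(s) {
        if (!ok[s]) return(FALSE)
        as.character(a) %in% toks[[s]]
      }, logical(1))
    }
    rows[[i]] <- list(
      variants = data.frame(
        chrom = unname(fix[i, "CHROM"]),
        pos = as.integer(unname(fix[i, "POS"])),
        ref = unname(fix[i, "REF"]), alt = alts,
        gene = gene[i], effect = effect[i] %||% "other",
        protein_change = pchange[i], score = score[i],
        stringsAsFactors = FALSE),
      presence = pres)
  }
  variants <- do.call(rbind, lapply(rows, `[[`, "variants"))
  presence <- do.call(rbind, lapply(rows, `[[`, "presence"))
  variants$effect[is.na(variants$effect)] <- "other"
  if (n_bad > 0L)
    warning(sprintf("%d unparseable genotype(s) treated as absent", n_bad))
  out <- panel_variants(variants, presence, lines)
  attr(out, "parse_report") <- list(n_bad_genotypes = n_bad)
  out
}

#' Write a panel variant table as VCF v4.2
#'
#' One record per normalized (site, alt) pair; genotypes are emitted as
#' `0/1` for lines carrying the allele and `0/0` otherwise. Annotations
#' travel in INFO (`GENE`, `EFFECT`, `PCHANGE`, `SCORE`).
#'
#' @param table A [panel_variants] object.
#' @param path Output path.
#' @param config Optional configuration object; its hash is recorded in
#'   the header.
#' @return `path`, invisibly.
#' @export
write_filtered_vcf <- function(table, path, config = NULL) {
  v <- table$variants
  info <- sprintf("GENE=%s;EFFECT=%s", v$gene, v$effect)
  has_pc <- !is.na(v$protein_change)
  info[has_pc] <- paste0(info[has_pc], ";PCHANGE=",
                         v$protein_change[has_pc])
  has_sc <- !is.na(v$score)
  info[has_sc] <- paste0(info[has_sc], ";SCORE=",
                         format(v$score[has_sc], trim = TRUE))
  gts <- ifelse(table$presence, "0/1", "0/0")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=oncopanel_%s",
            utils::packageVersion("oncopanel")),
    if (!is.null(config))
      sprintf("##oncopanel_config_hash=%s", config_hash(config)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect class\">",
    "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Deleteriousness score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", table$lines), collapse = "\t"))
  ## deterministic record order: chrom, pos, ref, alt
  ord <- order(v$chrom, v$pos, v$ref, v$alt)
  body <- vapply(ord, function(i) {
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            info[i], "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a population allele-frequency database
#'
#' TSV with columns `chrom, pos, ref, alt, allele_frequency`. Keys are
#' normalized; duplicate keys collapse to the maximum frequency. A lookup
#' of an absent key returns 0.
#'
#' @param path Path to the TSV file.
#' @return An object of class `population_db`.
#' @export
read_population_db <- function(path) {
  df <- read_tsv_prov(path)
  req <- c("chrom", "pos", "ref", "alt", "allele_frequency")
  if (!all(req %in% names(df)))
    stopf("population DB %s lacks columns: %s", path,
          paste(setdiff(req, names(df)), collapse = ", "))
  bad <- which(df$allele_frequency < 0 | df$allele_frequency > 1 |
                 is.na(df$allele_frequency))
  if (length(bad))
    stopf("allele_frequency outside [0,1] at row %d of %s", bad[1], path)
  population_db(df)
}

#' @rdname read_population_db
#' @param df data.frame with columns `chrom, pos, ref, alt,
#'   allele_frequency` (may have zero rows).
#' @export
population_db <- function(df = NULL) {
  freq <- numeric(0)
  if (!is.null(df) && nrow(df)) {
    key <- normalize_variant(variant_key(df$chrom, df$pos, df$ref, df$alt))
    ids <- variant_id(key)
    freq <- tapply(df$allele_frequency, ids, max)
    freq <- setNames(as.numeric(freq), names(freq))
  }
  structure(list(freq = freq), class = "population_db")
}

#' Look up population allele frequencies
#'
#' @param db A `population_db`.
#' @param key A data.frame of (already normalized) variant keys.
#' @return Numeric vector of frequencies; 0 for absent keys.
#' @export
pop_frequency <- function(db, key) {
  out <- db$freq[variant_id(key)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Read a somatic hotspot catalog
#'
#' TSV with columns `chrom, pos, ref, alt` and optional `gene,
#' protein_change`. Rows may carry a genomic key, a (gene, protein_change)
#' pair, or both; rows with neither are a validation error. Membership is
#' tested on the normalized genomic key first, then on the
#' (gene, protein_change) secondary index.
#'
#' @param path Path to the TSV file.
#' @return An object of class `hotspot_catalog`.
#' @export
read_hotspot_catalog <- function(path) {
  df <- read_tsv_prov(path, colClasses = "character")
  for (col in c("chrom", "pos", "ref", "alt", "gene", "protein_change"))
    if (is.null(df[[col]])) df[[col]] <- NA_character_
  df[df == "." | df == ""] <- NA
  hotspot_catalog(df)
}

#' @rdname read_hotspot_catalog
#' @param df data.frame with the catalog columns (may have zero rows).
#' @export
hotspot_catalog <- function(df = NULL) {
  keys <- character(0)
  aa <- character(0)
  if (!is.null(df) && nrow(df)) {
    has_gen <- !is.na(df$chrom) & !is.na(df$pos) & !is.na(df$ref) &
      !is.na(df$alt)
    has_aa <- !is.na(df$gene) & !is.na(df$protein_change)
    if (any(!has_gen & !has_aa))
      stopf("catalog row %d has neither genomic key nor gene+protein_change",
            which(!has_gen & !has_aa)[1])
    if (any(has_gen)) {
      g <- df[has_gen, ]
      keys <- unique(variant_id(normalize_variant(
        variant_key(g$chrom, g$pos, g$ref, g$alt))))
    }
    if (any(has_aa))
      aa <- unique(paste0(df$gene[has_aa], "|", df$protein_change[has_aa]))
  }
  structure(list(keys = keys, aa = aa), class = "hotspot_catalog")
}

#' Test hotspot catalog membership
#'
#' @param catalog A `hotspot_catalog`.
#' @param key data.frame of normalized variant keys.
#' @param gene,protein_change Optional annotation vectors for the
#'   secondary (gene, protein change) index.
#' @return Logical vector.
#' @export
hotspot_contains <- function(catalog, key, gene = NULL,
                             protein_change = NULL) {
  hit <- variant_id(key) %in% catalog$keys
  if (!is.null(gene) && !is.null(protein_change) && length(catalog$aa)) {
    aa_ok <- !is.na(gene) & !is.na(protein_change)
    hit[aa_ok] <- hit[aa_ok] |
      (paste0(gene[aa_ok], "|", protein_change[aa_ok]) %in% catalog$aa)
  }
  hit
}

#' Read a gene x sample count matrix with group labels
#'
#' @param path TSV whose first column is the gene identifier and remaining
#'   columns are per-sample nonnegative integer counts.
#' @param groups_path TSV with columns `sample, group` covering every
#'   sample column.
#' @return A [panel_counts] object.
#' @export
read_count_matrix <- function(path, groups_path) {
  df <- read_tsv_prov(path)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  g <- read_tsv_prov(groups_path)
  if (!all(c("sample", "group") %in% names(g)))
    stopf("groups file %s needs columns sample, group", groups_path)
  missing <- setdiff(colnames(m), g$sample)
  if (length(missing))
    stopf("samples present in counts but absent from groups: %s",
          paste(missing, collapse = ", "))
  groups <- setNames(as.character(g$group), g$sample)[colnames(m)]
  panel_counts(m, factor(groups))
}

#' Count matrix container
#'
#' @param counts Gene x sample matrix of nonnegative integer counts.
#' @param groups Factor of group labels, one per sample (two groups for
#'   the differential-expression tests).
#' @return An object of class `panel_counts` with elements `counts`,
#'   `groups` and `lib.size` (column sums).
#' @export
panel_counts <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stopf("counts must be nonnegative integers")
  if (length(groups) != ncol(counts))
    stopf("%d group labels for %d samples", length(groups), ncol(counts))
  if (any(is.na(groups))) stopf("every sample must carry a group label")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 1L || min(table(groups)) < 1L)
    stopf("each group needs at least one sample")
  structure(list(counts = counts, groups = groups,
                 lib.size = colSums(counts)),
            class = "panel_counts")
}

#' Read a gene x line mean capture-depth matrix
#'
#' @param path TSV whose first column is the gene identifier and remaining
#'   columns are per-line mean depths (nonnegative reals).
#' @return Numeric matrix (genes x lines).
#' @export
read_depth_matrix <- function(path) {
  df <- read_tsv_prov(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (any(m < 0)) stopf("depth matrix %s has negative entries", path)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stopf("depth matrix identifiers must be unique")
  m
}

#' Read a GMT gene-set library
#'
#' GMT lines are `term<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @param universe Optional explicit background gene universe; defaults to
#'   the union of all term genes.
#' @return A [gene_set_library] object.
#' @export
read_gene_sets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) stopf("GMT line %d has no genes", which(short)[1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_library(sets, universe)
}

#' Gene-set library container
#'
#' @param sets Named list of character vectors (term -> genes).
#' @param universe Background gene universe; defaults to the union of all
#'   term genes. Term genes outside the universe are dropped.
#' @return An object of class `gene_set_library`.
#' @export
gene_set_library <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stopf("gene sets must have unique term names")
  universe <- unique(universe %||% unlist(sets, use.names = FALSE))
  sets <- lapply(sets, intersect, y = universe)
  if (any(lengths(sets) == 0L))
    stopf("term(s) empty after universe intersection: %s",
          paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_library")
}

#' Write result tables with provenance headers
#'
#' Each element of `results` is written as `<name>.tsv` in `out_dir`, with
#' a header comment recording the package version and configuration hash.
#'
#' @param results Named list of data.frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional configuration object for the header hash.
#' @return Character vector of file paths written.
#' @export
write_tables <- function(results, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(results), ".tsv"))
  for (i in seq_along(results))
    write_tsv_prov(results[[i]], paths[i], config = config)
  paths
}
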