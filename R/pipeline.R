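#' Pipeline run configuration
#'
#' Bundles the stage configurations and either a synthetic-data
#' configuration (`sim`) or a list of input `paths` (`vcf`, `popdb`,
#' `hotspots`, `depths`, `counts`, `groups`, `gmt`).
#'
#' @param sim A [sim_config] used to generate inputs when `paths` is
#'   NULL.
#' @param paths Named list of existing input files (alternative to
#'   `sim`).
#' @param filter A [filter_config].
#' @param cnv A [cnv_thresholds].
#' @param de A [de_thresholds].
#' @param enrich_B,enrich_seed Monte-Carlo settings for enrichment.
#' @param top_n Number of genes (by descending mutation frequency) in the
#'   oncoprint table.
#' @param panel_members Optional explicit panel membership (line ids).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = NULL, paths = NULL,
                       filter = filter_config(),
                       cnv = cnv_thresholds(),
                       de = de_thresholds(),
                       enrich_B = 1000L, enrich_seed = 17L,
                       top_n = 30L, panel_members = NULL) {
  if (is.null(sim) && is.null(paths))
    stopf("provide either a sim config or input paths")
  structure(list(sim = sim, paths = paths, filter = filter, cnv = cnv,
                 de = de, enrich_B = enrich_B,
                 enrich_seed = enrich_seed, top_n = top_n,
                 panel_members = panel_members),
            class = "run_config")
}

#' Read a pipeline run configuration from YAML
#'
#' Recognized top-level keys: `seed` (mandatory, feeds [sim_config()]),
#' `sim` (overrides for the generator), `filter`, `cnv`, `de`,
#' `enrichment` (`B`, `seed`), `top_n`, `panel_members`, `paths`.
#'
#' @param path YAML file path.
#' @return A [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (is.null(y$paths)) {
    if (is.null(y$seed)) stopf("config %s needs a seed", path)
    sim <- do.call(sim_config, c(list(seed = y$seed), y$sim))
  }
  run_config(
    sim = sim, paths = y$paths,
    filter = do.call(filter_config, y$filter %||% list()),
    cnv = do.call(cnv_thresholds, y$cnv %||% list()),
    de = do.call(de_thresholds, y$de %||% list()),
    enrich_B = y$enrichment$B %||% 1000L,
    enrich_seed = y$enrichment$seed %||% 17L,
    top_n = y$top_n %||% 30L,
    panel_members = y$panel_members)
}

log_stage <- function(log_lines, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  c(log_lines, line)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full panel pipeline
#'
#' Executes simulate (optional) -> variant filtering -> copy number ->
#' differential expression -> enrichment, and writes the report bundle:
#' `filtered.vcf`, `decisions.tsv`, `gene_frequency.tsv`,
#' `cnv_calls.tsv`, `de_genes.tsv`, `enrichment_up.tsv`,
#' `enrichment_down.tsv`, `oncoprint.tsv` (plus `summary.json` and
#' `run.log`). Each stage reads its own inputs, so a missing input fails
#' at that stage with earlier outputs intact; identical configurations
#' produce byte-identical outputs.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage results and `artifact`
#'   paths.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logl <- character(0)
  paths <- config$paths

  if (is.null(paths)) {
    sim_dir <- file.path(out_dir, "inputs")
    logl <- log_stage(logl, "simulate", "generating synthetic inputs")
    paths <- run_stage("simulate", {
      p1 <- simulate_panel(config$sim, sim_dir)$paths
      p2 <- simulate_depths(config$sim, sim_dir)$paths
      cm <- simulate_counts(config$sim, out_dir = sim_dir)
      lib <- simulate_gene_sets(config$sim,
                                universe = rownames(cm$counts$counts),
                                sources = list(),
                                out_dir = sim_dir)
      list(vcf = unname(p1["vcf"]), popdb = unname(p1["popdb"]),
           hotspots = unname(p1["hotspots"]),
           depths = unname(p2["depths"]),
           counts = unname(cm$paths["counts"]),
           groups = unname(cm$paths["groups"]),
           gmt = unname(lib$paths["gmt"]))
    })
  }

  artifacts <- c(filtered_vcf = file.path(out_dir, "filtered.vcf"),
                 decisions = file.path(out_dir, "decisions.tsv"),
                 gene_frequency = file.path(out_dir,
                                            "gene_frequency.tsv"),
                 cnv_calls = file.path(out_dir, "cnv_calls.tsv"),
                 de_genes = file.path(out_dir, "de_genes.tsv"),
                 enrichment_up = file.path(out_dir, "enrichment_up.tsv"),
                 enrichment_down = file.path(out_dir,
                                             "enrichment_down.tsv"),
                 oncoprint = file.path(out_dir, "oncoprint.tsv"))

  ## --- somatic filter ------------------------------------------------
  filt <- run_stage("filter", {
    table <- read_multisample_vcf(paths$vcf)
    db <- read_population_db(paths$popdb)
    catalog <- read_hotspot_catalog(paths$hotspots)
    res <- apply_filter(table, db, catalog, config$filter,
                        panel_members = config$panel_members)
    write_filtered_vcf(res$filtered, artifacts["filtered_vcf"], config)
    write_tsv_prov(res$decisions, artifacts["decisions"], config)
    res$catalog <- catalog
    res
  })
  freq <- run_stage("filter", {
    f <- gene_mutation_frequency(filt$filtered)
    write_tsv_prov(f, artifacts["gene_frequency"], config)
    f
  })
  logl <- log_stage(logl, "filter",
                    sprintf("%d records: %d kept, %d rescued",
                            nrow(filt$decisions), filt$summary["kept"],
                            filt$summary["rescued"]))

  ## --- copy number ---------------------------------------------------
  cnv_calls <- run_stage("cnv", {
    depths <- read_depth_matrix(paths$depths)
    calls <- cnv_pipeline(depths, config$cnv)
    write_tsv_prov(calls, artifacts["cnv_calls"], config)
    calls
  })
  logl <- log_stage(logl, "cnv",
                    sprintf("%d calls (%d non-neutral)", nrow(cnv_calls),
                            sum(cnv_calls$category != "neutral")))

  ## --- differential expression --------------------------------------
  de <- run_stage("de", {
    counts <- read_count_matrix(paths$counts, paths$groups)
    res <- de_test(counts, mode = "nb_fdr", thresholds = config$de)
    write_tsv_prov(res$results, artifacts["de_genes"], config)
    res$counts_obj <- counts
    res
  })
  logl <- log_stage(logl, "de",
                    sprintf("total %d DE (%d up, %d down)",
                            de$counts["total"], de$counts["n_up"],
                            de$counts["n_down"]))

  ## --- enrichment ----------------------------------------------------
  enr <- run_stage("enrich", {
    lib <- read_gene_sets(paths$gmt,
                          universe = rownames(de$counts_obj$counts))
    out <- list()
    for (dir in c("up", "down")) {
      genes <- de[[dir]]
      out[[dir]] <- if (length(genes)) {
        e <- enrich(genes, direction = dir, library = lib,
                    B = config$enrich_B, seed = config$enrich_seed)
        write_tsv_prov(e, artifacts[paste0("enrichment_", dir)], config)
        e
      } else {
        empty <- data.frame(term = character(0))
        write_tsv_prov(empty, artifacts[paste0("enrichment_", dir)],
                       config)
        empty
      }
    }
    out
  })
  logl <- log_stage(logl, "enrich",
                    sprintf("up: %d terms, down: %d terms",
                            nrow(enr$up), nrow(enr$down)))

  ## --- oncoprint -----------------------------------------------------
  onco <- run_stage("oncoprint", {
    top_genes <- head(freq$gene, config$top_n)
    expr <- cpm(de$counts_obj)
    panel_lines <- filt$filtered$lines
    expr_panel <- expr[, intersect(colnames(expr), panel_lines),
                       drop = FALSE]
    o <- make_oncoprint_table(filt$filtered, cnv_calls, expr_panel,
                              catalog = filt$catalog, genes = top_genes)
    write_tsv_prov(o, artifacts["oncoprint"], config)
    o
  })
  logl <- log_stage(logl, "oncoprint",
                    sprintf("%d genes x %d lines", length(unique(onco$gene)),
                            length(unique(onco$line))))

  ## --- summary -------------------------------------------------------
  summary <- list(
    filter = as.list(filt$summary),
    cnv = as.list(table(cnv_calls$category)),
    de = as.list(de$counts),
    enrichment = list(up_terms = nrow(enr$up),
                      down_terms = nrow(enr$down)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(logl, file.path(out_dir, "run.log"))

  invisible(list(filter = filt, gene_frequency = freq,
                 cnv_calls = cnv_calls, de = de, enrichment = enr,
                 oncoprint = onco, artifacts = artifacts,
                 inputs = paths))
}

#' Gene x line oncoprint-style summary table
#'
#' Combines mutation presence (with hotspot vs novel distinction),
#' copy-number category and an expression tier per cell. Expression is
#' log2 of the line's value over the panel median for that gene; tiers
#' are cut at `+-tier_break` into -1/0/+1 (a line exactly at the panel
#' median gets tier 0).
#'
#' @param filtered A [panel_variants] of kept (somatic) variants.
#' @param cnv_calls data.frame from [call_cnv()]/[cnv_pipeline()].
#' @param expression Gene x line matrix of expression values (e.g. CPM)
#'   for the panel lines; genes missing from it get `NA` tiers.
#' @param catalog A [hotspot_catalog] for the hotspot/novel distinction.
#' @param genes Character vector of genes (rows) to report.
#' @param tier_break Log2 breakpoint for the expression tiers.
#' @param prior Pseudocount guarding zero expression values.
#' @return data.frame with columns `gene`, `line`, `mutation`
#'   (none/novel/hotspot), `cnv`, `expr_tier`.
#' @export
make_oncoprint_table <- function(filtered, cnv_calls, expression,
                                 catalog = hotspot_catalog(),
                                 genes = NULL, tier_break = 1,
                                 prior = 0.5) {
  lines <- filtered$lines
  cnv_lines <- unique(cnv_calls$line)
  missing <- setdiff(lines, cnv_lines)
  if (length(missing))
    stopf("lines missing from CNV calls: %s",
          paste(missing, collapse = ", "))
  if (is.null(genes))
    genes <- unique(c(filtered$variants$gene, cnv_calls$gene))
  v <- filtered$variants
  is_hot <- hotspot_contains(catalog, v, gene = v$gene,
                             protein_change = v$protein_change)

  grid <- expand.grid(gene = genes, line = lines,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mut <- rep("none", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows <- which(v$gene == grid$gene[i] &
                    filtered$presence[, grid$line[i]])
    if (length(rows))
      mut[i] <- if (any(is_hot[rows])) "hotspot" else "novel"
  }
  cnv_key <- paste(cnv_calls$gene, cnv_calls$line, sep = "\r")
  cnv_cat <- as.character(cnv_calls$category)[
    match(paste(grid$gene, grid$line, sep = "\r"), cnv_key)]

  tier <- rep(NA_integer_, nrow(grid))
  have <- grid$gene %in% rownames(expression) &
    grid$line %in% colnames(expression)
  if (any(have)) {
    med <- apply(expression, 1, stats::median)
    val <- expression[cbind(match(grid$gene[have], rownames(expression)),
                            match(grid$line[have], colnames(expression)))]
    lf <- log2((val + prior) / (med[match(grid$gene[have],
                                          rownames(expression))] + prior))
    tier[have] <- ifelse(lf >= tier_break, 1L,
                         ifelse(lf <= -tier_break, -1L, 0L))
  }
  data.frame(gene = grid$gene, line = grid$line, mutation = mut,
             cnv = cnv_cat, expr_tier = tier, stringsAsFactors = FALSE)
}
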