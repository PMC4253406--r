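## Synthetic-data generators. These emulate the statistical structure of a
## 22-line tumor-only sequencing panel with known ground truth: germline
## variants shared at population frequencies, recurrent artifacts, private
## and hotspot somatic mutations, per-gene capture depths with planted
## copy-number states, and negative-binomial count matrices with planted
## differential expression.

#' Default per-gene somatic mutation profile
#'
#' Number of panel lines carrying protein-altering mutations in each of
#' the recurrently mutated genes the panel emulates; on 22 lines the top
#' gene (TP53, 15 lines) has mutation frequency 15/22 = 68.2%.
#'
#' @return data.frame with columns `gene`, `n_lines`.
#' @export
default_gene_profile <- function() {
  data.frame(
    gene = c("TP53", "NOTCH1", "FAT1", "PIK3CA", "CASP8", "HRAS",
             "SMAD4"),
    n_lines = c(15L, 6L, 5L, 5L, 4L, 3L, 3L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All generators are pure functions of this configuration; the seed is
#' mandatory and each artifact derives its own stream from it so
#' artifacts are independently reproducible.
#'
#' @param seed Integer seed (mandatory).
#' @param n_lines Number of panel lines (default 22).
#' @param germline List: `count`, Beta shape parameters `beta_a`,
#'   `beta_b` for population allele frequencies.
#' @param artifact List: `count`, `min_lines` (forced above the
#'   recurrence boundary).
#' @param somatic_private List: `count_per_line`.
#' @param somatic_hotspot List: `count`, `lines_carrying`.
#' @param gene_profile data.frame(gene, n_lines) of planted per-gene
#'   mutation recurrences (see [default_gene_profile()]).
#' @param cnv List: `n_genes`, `base_depth`, `cv` (multiplicative noise
#'   CV), `weights` (named mixture weights over copy states
#'   0/1/2/3/5), `background` (residual depth fraction for copy 0),
#'   `line_depth_range` (per-line global depth multipliers).
#' @param de List: `n_genes`, `n_group1`, `n_group2`, `meanlog`,
#'   `sdlog` (baseline log-mean distribution), `phi`, `n_up`, `n_down`,
#'   `lfc` (planted |log2 fold change|), `labels` (group1/group2 names;
#'   group1 must sort first).
#' @param enrichment List: `n_terms`, `term_size`, `planted_overlap`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_lines = 22L,
                       germline = list(),
                       artifact = list(),
                       somatic_private = list(),
                       somatic_hotspot = list(),
                       gene_profile = default_gene_profile(),
                       cnv = list(),
                       de = list(),
                       enrichment = list()) {
  if (missing(seed)) stopf("seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    n_lines = as.integer(n_lines),
    germline = utils::modifyList(
      list(count = 300L, beta_a = 0.3, beta_b = 3), germline),
    artifact = utils::modifyList(
      list(count = 20L, min_lines = 5L), artifact),
    somatic_private = utils::modifyList(
      list(count_per_line = 3L), somatic_private),
    somatic_hotspot = utils::modifyList(
      list(count = 10L, lines_carrying = 6L), somatic_hotspot),
    gene_profile = gene_profile,
    cnv = utils::modifyList(
      list(n_genes = 1000L, base_depth = 100, cv = 0.1,
           weights = c("0" = 0.01, "1" = 0.02, "2" = 0.94,
                       "3" = 0.02, "5" = 0.01),
           background = 0.02, line_depth_range = c(0.5, 2)), cnv),
    de = utils::modifyList(
      list(n_genes = 5000L, n_group1 = 3L, n_group2 = 21L,
           meanlog = 4, sdlog = 1.5, phi = 0.1,
           n_up = 90L, n_down = 140L, lfc = 2,
           labels = c("normal", "tumor")), de),
    enrichment = utils::modifyList(
      list(n_terms = 50L, term_size = 50L, planted_overlap = 0.8),
      enrichment))
  if (any(unlist(cfg$cnv$weights) < 0) ||
      abs(sum(unlist(cfg$cnv$weights)) - 1) > 1e-8)
    stopf("cnv weights must be nonnegative and sum to 1")
  structure(cfg, class = "sim_config")
}

line_ids <- function(n) sprintf("L%02d", seq_len(n))

gene_universe <- function(config, n) {
  prof <- config$gene_profile$gene
  c(prof, sprintf("GENE%04d", seq_len(max(0L, n - length(prof)))))[1:n]
}

## Random distinct ref/alt single bases at globally unique positions.
random_snvs <- function(n, pos_pool) {
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, n, replace = TRUE)
  alt_i <- ((ref_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  data.frame(chrom = paste0("chr", sample.int(22L, n, replace = TRUE)),
             pos = pos_pool[seq_len(n)],
             ref = bases[ref_i], alt = bases[alt_i],
             stringsAsFactors = FALSE)
}

random_protein_change <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "L", "K", "P",
          "S", "T", "W", "Y", "V")
  sprintf("%s%d%s", sample(aa, n, replace = TRUE),
          sample(30:700, n, replace = TRUE),
          sample(aa, n, replace = TRUE))
}

#' Simulate a tumor-only variant panel with known truth
#'
#' Generates a multi-sample panel with four variant classes:
#' \describe{
#'   \item{germline}{population frequency drawn from a Beta distribution
#'     (truncated > 0); per-line presence is Bernoulli with the diploid
#'     carrier probability `1 - (1 - f)^2`; listed in the population DB,
#'     never in the catalog.}
#'   \item{artifact}{forced into more than `ceil(0.15 n)` lines, DB
#'     frequency 0 (recurrence-filter fodder).}
#'   \item{somatic_private}{present in exactly one line, DB frequency 0;
#'     includes the planted per-gene mutation profile.}
#'   \item{somatic_hotspot}{listed in the hotspot catalog and planted in
#'     several lines, so the recurrence rule fires but rescue keeps
#'     them.}
#' }
#'
#' @param config A [sim_config].
#' @param out_dir Optional directory; if given, writes `panel.vcf`,
#'   `popdb.tsv`, `hotspots.tsv`, `truth_variants.tsv`.
#' @return List with `table` ([panel_variants]), `popdb`
#'   ([population_db]), `popdb_df`, `catalog` ([hotspot_catalog]),
#'   `catalog_df`, `truth` (data.frame: key columns, `gene`, `class`)
#'   and, when written, `paths`.
#' @export
simulate_panel <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  n <- config$n_lines
  lines <- line_ids(n)
  prof <- config$gene_profile
  n_prof <- sum(prof$n_lines)
  n_priv <- config$somatic_private$count_per_line * n
  n_total <- config$germline$count + config$artifact$count + n_priv +
    n_prof + config$somatic_hotspot$count
  pos_pool <- sample.int(10000000L, n_total)
  if (config$germline$count > length(pos_pool))
    stopf("germline count exceeds available positions")
  snv <- random_snvs(n_total, pos_pool)
  idx <- 0L
  take <- function(k) {
    out <- snv[idx + seq_len(k), , drop = FALSE]
    idx <<- idx + k
    out
  }
  universe <- gene_universe(config, 10000L)
  other_genes <- setdiff(universe, prof$gene)

  rows <- list()
  pres <- list()
  popdb_rows <- list()
  cat_rows <- list()
  truth <- list()
  add <- function(key, gene, effect, pchange, presence, class) {
    rows[[length(rows) + 1L]] <<- data.frame(
      key, gene = gene, effect = effect, protein_change = pchange,
      score = NA_real_, stringsAsFactors = FALSE)
    pres[[length(pres) + 1L]] <<- presence
    truth[[length(truth) + 1L]] <<- data.frame(
      key, gene = gene, class = class, stringsAsFactors = FALSE)
  }

  ## germline: population-frequency carriers, HWE diploid presence
  g <- config$germline
  if (g$count > 0L) {
    key <- take(g$count)
    f <- rbeta(g$count, g$beta_a, g$beta_b)
    f <- pmax(f, 1e-4)  # truncate away from 0: present in the population
    popdb_rows[[1L]] <- data.frame(key, allele_frequency = round(f, 6),
                                   stringsAsFactors = FALSE)
    carrier_p <- 1 - (1 - f)^2
    presence <- matrix(rbinom(g$count * n, 1L, rep(carrier_p, n)) == 1L,
                       nrow = g$count)
    effect <- sample(VALID_EFFECTS, g$count, replace = TRUE,
                     prob = c(0.5, 0.35, 0.03, 0.03, 0.04, 0.05))
    seen <- rowSums(presence) > 0L
    if (any(seen))
      add(key[seen, ], sample(other_genes, sum(seen)), effect[seen],
          NA_character_, presence[seen, , drop = FALSE], "germline")
  }

  ## recurrent artifacts: > ceil(0.15 n) lines, DB frequency 0
  a <- config$artifact
  if (a$count > 0L) {
    key <- take(a$count)
    presence <- matrix(FALSE, a$count, n)
    for (i in seq_len(a$count)) {
      m <- sample(a$min_lines:n, 1L)
      presence[i, sample.int(n, m)] <- TRUE
    }
    add(key, sample(other_genes, a$count),
        sample(VALID_EFFECTS, a$count, replace = TRUE),
        NA_character_, presence, "artifact")
  }

  ## private somatics: exactly one line each
  pv <- config$somatic_private
  if (pv$count_per_line > 0L) {
    key <- take(n_priv)
    presence <- matrix(FALSE, n_priv, n)
    presence[cbind(seq_len(n_priv),
                   rep(seq_len(n), each = pv$count_per_line))] <- TRUE
    add(key, sample(other_genes, n_priv, replace = TRUE),
        sample(c("missense", "nonsense", "frameshift", "splice"),
               n_priv, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1)),
        NA_character_, presence, "somatic_private")
  }

  ## planted per-gene profile: one private variant per (gene, line)
  if (n_prof > 0L) {
    key <- take(n_prof)
    gene <- rep(prof$gene, prof$n_lines)
    carriers <- unlist(lapply(prof$n_lines, function(k)
      sample.int(n, k)))
    presence <- matrix(FALSE, n_prof, n)
    presence[cbind(seq_len(n_prof), carriers)] <- TRUE
    pchange <- random_protein_change(n_prof)
    in_cat <- runif(n_prof) < 0.5
    if (any(in_cat))
      cat_rows[[length(cat_rows) + 1L]] <-
        data.frame(key[in_cat, ], gene = gene[in_cat],
                   protein_change = pchange[in_cat],
                   stringsAsFactors = FALSE)
    add(key, gene,
        sample(c("missense", "nonsense", "frameshift"), n_prof,
               replace = TRUE, prob = c(0.7, 0.15, 0.15)),
        pchange, presence, "somatic_private")
  }

  ## hotspot somatics: recurrent but catalogued
  h <- config$somatic_hotspot
  if (h$count > 0L) {
    key <- take(h$count)
    gene <- sample(other_genes, h$count)
    pchange <- random_protein_change(h$count)
    presence <- matrix(FALSE, h$count, n)
    for (i in seq_len(h$count))
      presence[i, sample.int(n, h$lines_carrying)] <- TRUE
    cat_rows[[length(cat_rows) + 1L]] <-
      data.frame(key, gene = gene, protein_change = pchange,
                 stringsAsFactors = FALSE)
    add(key, gene, rep("missense", h$count), pchange, presence,
        "somatic_hotspot")
  }

  variants <- do.call(rbind, rows)
  presence <- do.call(rbind, pres)
  truth <- do.call(rbind, truth)
  table <- panel_variants(variants, presence, lines)
  popdb_df <- if (length(popdb_rows)) popdb_rows[[1L]] else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               allele_frequency = numeric(0))
  catalog_df <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               gene = character(0), protein_change = character(0))
  out <- list(table = table, popdb = population_db(popdb_df),
              popdb_df = popdb_df, catalog = hotspot_catalog(catalog_df),
              catalog_df = catalog_df, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(vcf = file.path(out_dir, "panel.vcf"),
               popdb = file.path(out_dir, "popdb.tsv"),
               hotspots = file.path(out_dir, "hotspots.tsv"),
               truth = file.path(out_dir, "truth_variants.tsv"))
    write_filtered_vcf(table, paths["vcf"], config = config)
    write_tsv_prov(popdb_df, paths["popdb"], config = config)
    write_tsv_prov(catalog_df, paths["hotspots"], config = config)
    write_tsv_prov(truth, paths["truth"], config = config)
    out$paths <- paths
  }
  out
}

#' Simulate a capture-depth matrix with planted copy numbers
#'
#' Depth for copy state `c` is `base_depth * (c/2)` times multiplicative
#' log-normal noise with the configured CV; copy 0 emits residual
#' background (`background * base_depth`). Each line additionally gets a
#' global depth multiplier drawn from `line_depth_range` to exercise the
#' median scaling step.
#'
#' @param config A [sim_config].
#' @param out_dir Optional directory; writes `depths.tsv`,
#'   `truth_cnv.tsv`.
#' @return List with `depths` (gene x line matrix), `truth`
#'   (data.frame gene, line, copy_number) and, when written, `paths`.
#' @export
simulate_depths <- function(config, out_dir = NULL) {
  set.seed(config$seed + 1L)
  cc <- config$cnv
  n_g <- cc$n_genes
  n_l <- config$n_lines
  genes <- gene_universe(config, n_g)
  lines <- line_ids(n_l)
  states <- as.integer(names(cc$weights))
  cn <- matrix(sample(states, n_g * n_l, replace = TRUE,
                      prob = unlist(cc$weights)), n_g, n_l)
  sdlog <- sqrt(log(1 + cc$cv^2))
  noise <- matrix(rlnorm(n_g * n_l, -sdlog^2 / 2, sdlog), n_g, n_l)
  mult <- runif(n_l, cc$line_depth_range[1], cc$line_depth_range[2])
  dose <- ifelse(cn == 0L, cc$background, cn / 2)
  depths <- pmax(cc$base_depth * dose * noise, 0)
  depths <- sweep(depths, 2, mult, `*`)
  dimnames(depths) <- list(genes, lines)
  truth <- data.frame(gene = rep(genes, times = n_l),
                      line = rep(lines, each = n_g),
                      copy_number = as.integer(cn),
                      stringsAsFactors = FALSE)
  out <- list(depths = depths, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(depths = file.path(out_dir, "depths.tsv"),
               truth = file.path(out_dir, "truth_cnv.tsv"))
    write_tsv_prov(data.frame(gene = genes, as.data.frame(depths),
                              check.names = FALSE),
                   paths["depths"], config = config)
    write_tsv_prov(truth, paths["truth"], config = config)
    out$paths <- paths
  }
  out
}

#' Simulate a count matrix with planted differential expression
#'
#' Baseline gene means are log-normal; planted genes have their group-2
#' mean multiplied by `2^(+-lfc)`; counts are negative-binomial with
#' common dispersion `phi` (`phi = 0` gives Poisson). Mild per-sample
#' depth factors (0.8-1.25) exercise the normalization steps.
#'
#' @param config A [sim_config]; the `de` element may be overridden via
#'   `de_override` for a second comparison (e.g. the HPV contrast).
#' @param de_override Named list merged over `config$de`.
#' @param out_dir Optional directory; writes `counts.tsv`, `groups.tsv`,
#'   `truth_de.tsv`.
#' @param seed_offset Stream offset so different comparisons draw
#'   independent data (default 2).
#' @return List with `counts` ([panel_counts]), `truth`
#'   (gene, status, true_lfc) and, when written, `paths`.
#' @export
simulate_counts <- function(config, de_override = list(),
                            out_dir = NULL, seed_offset = 2L) {
  set.seed(config$seed + seed_offset)
  de <- utils::modifyList(config$de, de_override)
  if (sort(de$labels)[1] != de$labels[1])
    stopf("group labels must sort with group1 first (got %s)",
          paste(de$labels, collapse = ", "))
  n_g <- de$n_genes
  genes <- gene_universe(config, n_g)
  n1 <- de$n_group1
  n2 <- de$n_group2
  ## group-2 samples reuse panel line identifiers when they fit, so
  ## expression joins against the mutation/CNV panels downstream
  g2_names <- if (n2 <= config$n_lines)
    line_ids(config$n_lines)[seq_len(n2)] else
      sprintf("%s_%02d", de$labels[2], seq_len(n2))
  samples <- c(sprintf("%s_%02d", de$labels[1], seq_len(n1)), g2_names)
  groups <- factor(rep(de$labels, c(n1, n2)), levels = de$labels)
  mu <- rlnorm(n_g, de$meanlog, de$sdlog)
  status <- rep("null", n_g)
  planted <- sample.int(n_g, de$n_up + de$n_down)
  status[planted[seq_len(de$n_up)]] <- "up"
  status[planted[de$n_up + seq_len(de$n_down)]] <- "down"
  true_lfc <- ifelse(status == "up", de$lfc,
                     ifelse(status == "down", -de$lfc, 0))
  sf <- runif(n1 + n2, 0.8, 1.25)
  mu_mat <- outer(mu, sf)
  g2 <- as.integer(groups) == 2L
  mu_mat[, g2] <- mu_mat[, g2] * 2^true_lfc
  counts <- matrix(
    if (de$phi == 0) rpois(length(mu_mat), mu_mat) else
      rnbinom(length(mu_mat), size = 1 / de$phi, mu = mu_mat),
    nrow = n_g, dimnames = list(genes, samples))
  pc <- panel_counts(counts, groups)
  truth <- data.frame(gene = genes, status = status,
                      true_lfc = true_lfc, stringsAsFactors = FALSE)
  out <- list(counts = pc, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(counts = file.path(out_dir, "counts.tsv"),
               groups = file.path(out_dir, "groups.tsv"),
               truth = file.path(out_dir, "truth_de.tsv"))
    write_tsv_prov(data.frame(gene = genes, as.data.frame(counts),
                              check.names = FALSE),
                   paths["counts"], config = config)
    write_tsv_prov(data.frame(sample = samples,
                              group = as.character(groups)),
                   paths["groups"], config = config)
    write_tsv_prov(truth, paths["truth"], config = config)
    out$paths <- paths
  }
  out
}

#' Simulate a gene-set library with planted enrichment
#'
#' Random same-size terms drawn from the universe, plus one planted term
#' per provided source list containing `planted_overlap * term_size`
#' source genes (the remainder drawn from non-source genes).
#'
#' @param config A [sim_config].
#' @param universe Character vector of background genes.
#' @param sources Named list of source gene lists to plant (e.g.
#'   `list(PLANTED_UP = up_genes)`); may be empty.
#' @param out_dir Optional directory; writes `sets.gmt`,
#'   `truth_sets.tsv`.
#' @return List with `library` ([gene_set_library]), `truth`
#'   (term, planted, source) and, when written, `paths`.
#' @export
simulate_gene_sets <- function(config, universe, sources = list(),
                               out_dir = NULL) {
  set.seed(config$seed + 3L)
  en <- config$enrichment
  size <- min(en$term_size, length(universe))
  sets <- lapply(seq_len(en$n_terms), function(i)
    sample(universe, size))
  names(sets) <- sprintf("TERM%03d", seq_len(en$n_terms))
  planted <- character(0)
  for (nm in names(sources)) {
    src <- intersect(sources[[nm]], universe)
    k <- min(round(en$planted_overlap * size), length(src))
    fill <- sample(setdiff(universe, src), size - k)
    sets[[nm]] <- c(sample(src, k), fill)
    planted <- c(planted, nm)
  }
  lib <- gene_set_library(sets, universe)
  truth <- data.frame(term = names(sets),
                      planted = names(sets) %in% planted,
                      stringsAsFactors = FALSE)
  out <- list(library = lib, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(gmt = file.path(out_dir, "sets.gmt"),
               truth = file.path(out_dir, "truth_sets.tsv"))
    gmt <- vapply(names(sets), function(nm)
      paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"),
      character(1))
    writeLines(gmt, paths["gmt"])
    write_tsv_prov(truth, paths["truth"], config = config)
    out$paths <- paths
  }
  out
}
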