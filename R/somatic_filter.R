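#' Somatic-approximation filter for tumor-only panels
#'
#' Cell-line panels lack matched normal DNA, so somatic mutation calling
#' is approximated by filtering: any non-reference allele with nonzero
#' frequency in a population database is rejected as germline, and any
#' allele left that recurs in more than a fraction `recurrence_fraction`
#' of the panel lines is rejected as a putative uncatalogued SNP or
#' pipeline artifact. Either rejection is overridden ("rescued") when the
#' allele is present in a somatic hotspot catalog, which preserves truly
#' frequent driver mutations.
#'
#' With the default fraction 0.15 on a 22-line panel the recurrence rule
#' fires at presence in 4 or more lines (0.15 * 22 = 3.3), i.e. variants
#' in more than 3 lines are discarded.
#'
#' @param recurrence_fraction Fraction of panel lines above which a
#'   variant is rejected as recurrent (strictly greater-than). Default 0.15.
#' @param rescue_enabled Whether hotspot-catalog rescue is applied.
#' @return `filter_config()` returns a list of class `filter_config`.
#' @export
filter_config <- function(recurrence_fraction = 0.15,
                          rescue_enabled = TRUE) {
  if (!(recurrence_fraction > 0 && recurrence_fraction < 1))
    stopf("recurrence_fraction must lie in (0, 1)")
  structure(list(recurrence_fraction = recurrence_fraction,
                 rescue_enabled = isTRUE(rescue_enabled)),
            class = "filter_config")
}

#' Classify a single variant under the somatic-approximation rules
#'
#' @param key One-row data.frame variant key (normalized).
#' @param annotation List or one-row data.frame with `gene` and
#'   `protein_change` (used for secondary hotspot matching); may be NULL.
#' @param presence_count Number of panel lines carrying the variant.
#' @param n_lines Number of lines in the panel.
#' @param db A [population_db].
#' @param catalog A [hotspot_catalog].
#' @param config A [filter_config].
#' @return data.frame with columns `status` ("kept"/"rejected"), `reason`
#'   ("none"/"population_db"/"recurrent_panel") and `rescued` (logical).
#'   When both rejection rules fire the recorded reason is
#'   `population_db` (the rule applied first).
#' @export
classify_variant <- function(key, annotation, presence_count, n_lines,
                             db, catalog, config = filter_config()) {
  if (n_lines < 1L) stopf("n_lines must be >= 1")
  if (presence_count < 0L || presence_count > n_lines)
    stopf("presence_count %d outside [0, %d]", presence_count, n_lines)
  freq <- pop_frequency(db, key)
  pop_hit <- freq != 0
  rec_hit <- presence_count / n_lines > config$recurrence_fraction
  fired <- pop_hit | rec_hit
  in_cat <- hotspot_contains(catalog, key,
                             gene = annotation$gene %||% NA,
                             protein_change =
                               annotation$protein_change %||% NA)
  rescued <- fired & in_cat & config$rescue_enabled
  kept <- !fired | rescued
  reason <- if (kept) "none" else if (pop_hit) "population_db" else
    "recurrent_panel"
  data.frame(status = if (kept) "kept" else "rejected",
             reason = reason, rescued = rescued,
             stringsAsFactors = FALSE)
}

#' Apply the somatic-approximation filter to a panel variant table
#'
#' The kept set equals the set expression `V \ ((P | R) \ C)` where P is
#' the population-database hit set, R the panel-recurrence hit set and C
#' the hotspot-catalog hit set; the result is independent of record order.
#'
#' @param table A [panel_variants] object (normalized).
#' @param db A [population_db].
#' @param catalog A [hotspot_catalog].
#' @param config A [filter_config].
#' @param panel_members Optional character vector restricting which lines
#'   constitute the panel for recurrence counting and output (e.g. to
#'   exclude a normal line present in the VCF). Default: all lines.
#' @return List with `filtered` (a [panel_variants] of kept records) and
#'   `decisions` (a data.frame with one row per input record: key columns,
#'   `presence_count`, `status`, `reason`, `rescued`), plus `summary`
#'   (rejection counts by reason).
#' @export
apply_filter <- function(table, db, catalog, config = filter_config(),
                         panel_members = NULL) {
  lines <- table$lines
  if (!is.null(panel_members)) {
    missing <- setdiff(panel_members, lines)
    if (length(missing))
      stopf("panel_members not in table: %s",
            paste(missing, collapse = ", "))
    keep_l <- lines %in% panel_members
    table <- panel_variants(table$variants,
                            table$presence[, keep_l, drop = FALSE],
                            lines[keep_l])
    ## drop records no longer seen in any panel member
    seen <- rowSums(table$presence) > 0L
    table$variants <- table$variants[seen, , drop = FALSE]
    table$presence <- table$presence[seen, , drop = FALSE]
  }
  v <- table$variants
  n_lines <- length(table$lines)
  n_rec <- nrow(v)
  presence_count <- if (n_rec) as.integer(rowSums(table$presence)) else
    integer(0)
  freq <- if (n_rec) pop_frequency(db, v) else numeric(0)
  pop_hit <- freq != 0
  rec_hit <- presence_count / n_lines > config$recurrence_fraction
  in_cat <- if (n_rec)
    hotspot_contains(catalog, v, gene = v$gene,
                     protein_change = v$protein_change) else logical(0)
  fired <- pop_hit | rec_hit
  rescued <- fired & in_cat & config$rescue_enabled
  kept <- !fired | rescued
  reason <- rep("none", n_rec)
  reason[!kept & pop_hit] <- "population_db"
  reason[!kept & !pop_hit & rec_hit] <- "recurrent_panel"
  decisions <- cbind(
    v[, c("chrom", "pos", "ref", "alt", "gene"), drop = FALSE],
    data.frame(presence_count = presence_count,
               pop_frequency = freq,
               status = ifelse(kept, "kept", "rejected"),
               reason = reason, rescued = rescued,
               stringsAsFactors = FALSE))
  filtered <- table
  filtered$variants <- v[kept, , drop = FALSE]
  filtered$presence <- table$presence[kept, , drop = FALSE]
  rownames(filtered$variants) <- NULL
  rownames(filtered$presence) <- NULL
  list(filtered = filtered, decisions = decisions,
       summary = c(kept = sum(kept),
                   rejected_population_db = sum(reason == "population_db"),
                   rejected_recurrent_panel =
                     sum(reason == "recurrent_panel"),
                   rescued = sum(rescued)))
}

#' Per-gene mutation frequency across the panel
#'
#' A line counts once per gene regardless of how many qualifying variants
#' it carries. By default only protein-altering effect classes count
#' (synonymous variants are excluded).
#'
#' @param filtered A [panel_variants] object (normally the kept set from
#'   [apply_filter()]).
#' @param effect_filter Character vector of effect classes that qualify.
#' @return data.frame with columns `gene`, `n_lines_mutated`, `fraction`,
#'   ordered by descending fraction then gene symbol.
#' @export
gene_mutation_frequency <- function(filtered,
                                    effect_filter = c(
                                      "missense", "nonsense", "frameshift",
                                      "splice", "other")) {
  unknown <- setdiff(effect_filter, VALID_EFFECTS)
  if (length(unknown))
    stopf("unknown effect class in filter: %s",
          paste(unknown, collapse = ", "))
  v <- filtered$variants
  n_total <- length(filtered$lines)
  sel <- v$effect %in% effect_filter & !is.na(v$gene)
  if (!any(sel))
    return(data.frame(gene = character(0), n_lines_mutated = integer(0),
                      fraction = numeric(0)))
  genes <- sort(unique(v$gene[sel]))
  n_mut <- vapply(genes, function(g) {
    rows <- which(sel & v$gene == g)
    sum(colSums(filtered$presence[rows, , drop = FALSE]) > 0L)
  }, integer(1))
  out <- data.frame(gene = genes, n_lines_mutated = unname(n_mut),
                    fraction = unname(n_mut) / n_total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fraction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
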