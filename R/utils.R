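## Internal helpers shared across modules.

#' FNV-1a hash of a configuration object
#'
#' Stable 32-bit hash of a (possibly nested) list, used to stamp output
#' file headers so results can be traced to the exact configuration that
#' produced them.
#'
#' @param x Any R object; deparsed canonically before hashing.
#' @return An 8-character lowercase hex string.
#' @keywords internal
config_hash <- function(x) {
  s <- paste(deparse(x, control = c("keepNA", "keepInteger")), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    ## xor with a byte only touches the low 8 bits
    h <- h - (h %% 256) + bitwXor(h %% 256, b %% 256)
    ## 32-bit multiply by the FNV prime, split to stay exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Header comment lines stamped on every TSV the package writes.
provenance_header <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("oncopanel"))
  lines <- sprintf("# oncopanel %s", ver)
  if (!is.null(config)) {
    lines <- c(lines, sprintf("# config_hash %s", config_hash(config)))
  }
  lines
}

## Write a data.frame as TSV with provenance header; deterministic formatting.
write_tsv_prov <- function(df, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Read a TSV written by write_tsv_prov (skips leading '#' comments).
read_tsv_prov <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
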