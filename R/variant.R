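#' Variant keys and allele normalization
#'
#' A variant key identifies a substitution or indel by chromosome,
#' 1-based position, reference allele and alternate allele. Keys are kept
#' in minimal, left-aligned-within-record representation so that joins
#' against population databases and hotspot catalogs are deterministic:
#' the shared allele suffix is trimmed first, then the shared prefix
#' (always keeping at least one base on each side), and the position is
#' advanced past the trimmed prefix.
#'
#' @param chrom Chromosome name(s).
#' @param pos 1-based position(s).
#' @param ref,alt Allele strings over A,C,G,T.
#' @return `variant_key()` returns a data.frame with columns
#'   `chrom, pos, ref, alt`; `normalize_variant()` returns the same shape
#'   with normalized alleles and adjusted positions.
#' @examples
#' normalize_variant(variant_key("chr1", 1000, "AT", "AC"))
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  k <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)),
                  stringsAsFactors = FALSE)
  bad <- !grepl("^[ACGT]+$", k$ref) | !grepl("^[ACGT]+$", k$alt)
  if (any(bad))
    stopf("invalid allele string in %d record(s), e.g. %s>%s",
          sum(bad), k$ref[which(bad)[1]], k$alt[which(bad)[1]])
  if (any(k$pos < 1)) stopf("variant position must be >= 1")
  k
}

#' @rdname variant_key
#' @param key A data.frame of variant keys as returned by [variant_key()].
#' @export
normalize_variant <- function(key) {
  ref <- key$ref
  alt <- key$alt
  pos <- as.integer(key$pos)
  if (any(ref == alt))
    stopf("ref equals alt for %s:%d", key$chrom[ref == alt][1],
          pos[ref == alt][1])
  for (i in seq_along(ref)) {
    r <- strsplit(ref[i], "")[[1]]
    a <- strsplit(alt[i], "")[[1]]
    ## trim shared suffix, keep >= 1 base each
    while (length(r) > 1L && length(a) > 1L &&
           r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    ## trim shared prefix, keep >= 1 base each; position advances
    while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  if (any(ref == alt))
    stopf("variant reduces to ref == alt after trimming at %s:%d",
          key$chrom[ref == alt][1], pos[ref == alt][1])
  out <- key
  out$pos <- pos
  out$ref <- ref
  out$alt <- alt
  out
}

## Canonical string form used for joins: "chrom:pos:ref>alt".
variant_id <- function(key) {
  paste0(key$chrom, ":", key$pos, ":", key$ref, ">", key$alt)
}
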