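#' Normalize variant identities
#'
#' Reduces each `(chrom, pos, ref, alt)` record to the canonical
#' representation used throughout the package so that the same variant
#' matches across caller output dialects. Alleles are uppercased, any
#' shared redundant suffix is trimmed, then any shared prefix is trimmed
#' with `pos` advanced accordingly. When a reference sequence is supplied,
#' insertions and deletions are additionally left-aligned against it
#' (shifted to their leftmost equivalent position), the canonical VCF
#' convention for indels in repeat tracts.
#'
#' Without a reference only prefix/suffix trimming is performed, so two
#' representations of the same indel inside a repeat that entered at
#' different anchor positions will not be unified; this is a documented
#' limitation of reference-free normalization.
#'
#' @param variants A data frame with columns `chrom`, `pos` (1-based),
#'   `ref` and `alt`. Other columns are carried through unchanged.
#' @param reference Optional named character vector of chromosome
#'   sequences (names matching `chrom`, sequence starting at position 1),
#'   used to left-align indels.
#' @return A tibble with the same rows, normalized `pos`/`ref`/`alt`, and
#'   a `key` column (`"chrom:pos:ref:alt"`).
#' @examples
#' normalize_variants(tibble::tibble(
#'   chrom = "chr1", pos = 100, ref = "AT", alt = "AG"))
#' @export
normalize_variants <- function(variants, reference = NULL) {
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("`variants` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(variants)
  if (nrow(out) == 0) {
    out$key <- character(0)
    return(out)
  }
  out$pos <- as.integer(out$pos)
  out$ref <- toupper(out$ref)
  out$alt <- toupper(out$alt)
  bad <- !grepl("^[ACGT]+$", out$ref) | !grepl("^[ACGT]+$", out$alt)
  if (any(bad)) {
    abort(paste0("non-nucleotide ref/alt at row(s): ",
                 paste(head(which(bad), 5), collapse = ", ")))
  }
  if (any(out$pos < 1L)) abort("`pos` must be >= 1")
  if (any(out$ref == out$alt)) abort("`ref` must differ from `alt`")

  # fast path: single-base substitutions are already canonical
  todo <- which(str_length(out$ref) > 1L | str_length(out$alt) > 1L)
  for (i in todo) {
    ctx <- if (!is.null(reference)) reference[[out$chrom[i]]] else NULL
    norm <- normalize_one(out$pos[i], out$ref[i], out$alt[i], ctx)
    out$pos[i] <- norm$pos
    out$ref[i] <- norm$ref
    out$alt[i] <- norm$alt
  }
  out$key <- variant_id(out$chrom, out$pos, out$ref, out$alt)
  out
}

#' Normalize a single variant
#'
#' Scalar convenience wrapper around [normalize_variants()].
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate alleles (nucleotide strings).
#' @param reference Optional named character vector of chromosome
#'   sequences for indel left-alignment.
#' @return A one-row tibble with `chrom`, `pos`, `ref`, `alt`, `key`.
#' @examples
#' normalize_key("chr4", 152326214, "C", "T")
#' @export
normalize_key <- function(chrom, pos, ref, alt, reference = NULL) {
  normalize_variants(
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    reference = reference)
}

variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Suffix/prefix trimming plus (if ctx given) leftmost shifting of indels.
# Alleles are kept non-empty throughout: when suffix trimming empties one
# allele the representation is extended one reference base to the left.
normalize_one <- function(pos, ref, alt, ctx = NULL) {
  if (!is.null(ctx) && str_length(ref) != str_length(alt)) {
    repeat {
      lr <- str_length(ref); la <- str_length(alt)
      if (lr > 0 && la > 0 &&
          str_sub(ref, lr, lr) == str_sub(alt, la, la)) {
        ref <- str_sub(ref, 1, lr - 1)
        alt <- str_sub(alt, 1, la - 1)
        if (str_length(ref) == 0 || str_length(alt) == 0) {
          if (pos <= 1L) {
            abort("cannot left-align past the start of the reference")
          }
          pos <- pos - 1L
          prev <- str_sub(ctx, pos, pos)
          ref <- paste0(prev, ref)
          alt <- paste0(prev, alt)
        }
      } else break
    }
  } else {
    # shared redundant suffix (keep at least one base per allele)
    while (str_length(ref) > 1 && str_length(alt) > 1 &&
           str_sub(ref, -1) == str_sub(alt, -1)) {
      ref <- str_sub(ref, 1, str_length(ref) - 1)
      alt <- str_sub(alt, 1, str_length(alt) - 1)
    }
  }
  # shared prefix, advancing pos
  while (str_length(ref) > 1 && str_length(alt) > 1 &&
         str_sub(ref, 1, 1) == str_sub(alt, 1, 1)) {
    ref <- str_sub(ref, 2)
    alt <- str_sub(alt, 2)
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}
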