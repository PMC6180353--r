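#' Binary SNP codec
#'
#' Each SNP data line compresses into an 80-bit (10-byte) word with fields,
#' most significant first: CHROM (5 bits), POS (32 bits), numeric part of the
#' rsID (37 bits), REF&ALT pair code (5 bits), TYPE (1 bit, 0 = heterozygous,
#' 1 = homozygous). Bytes are big-endian, so comparing packed records as
#' unsigned byte strings sorts them by (chrom, pos).
#'
#' @name snp-codec
NULL

# ordered non-equal base pairs in alphabet order (A, C, G, T, N):
# (A,C)=0, (A,G)=1, (A,T)=2, (A,N)=3, (C,A)=4, ..., (N,T)=19
refalt_pairs <- local({
  g <- expand.grid(alt = BASES, ref = BASES, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)[, c("ref", "alt")]
  g <- g[order(match(g$ref, BASES), match(g$alt, BASES)), ]
  g[g$ref != g$alt, , drop = FALSE]
})

#' Encode a REF/ALT base pair as a 5-bit code
#'
#' The 20 ordered non-equal pairs over `{A, C, G, T, N}` map bijectively onto
#' codes 0..19 in alphabet-lexicographic order: `(A,C) = 0`, `(A,G) = 1`,
#' `(A,T) = 2`, `(A,N) = 3`, `(C,A) = 4`, ..., `(N,T) = 19`.
#'
#' @param ref,alt Base symbols; vectors recycle to a common length.
#' @param code Integer codes in 0..19.
#' @return `encode_refalt()` returns integer codes; `decode_refalt()` a
#'   tibble with columns `ref` and `alt`.
#' @examples
#' encode_refalt("G", "A")
#' decode_refalt(8L)
#' @export
encode_refalt <- function(ref, alt) {
  n <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    abort("REF/ALT symbols must come from {A, C, G, T, N}",
          class = "cryptsnp_codec_error")
  }
  if (any(ref == alt)) {
    abort("REF and ALT must differ", class = "cryptsnp_codec_error")
  }
  idx <- match(paste(ref, alt), paste(refalt_pairs$ref, refalt_pairs$alt))
  as.integer(idx - 1L)
}

#' @rdname encode_refalt
#' @export
decode_refalt <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 0L | code > 19L)) {
    abort("REF&ALT codes must lie in 0..19", class = "cryptsnp_codec_error")
  }
  tibble::tibble(ref = refalt_pairs$ref[code + 1L],
                 alt = refalt_pairs$alt[code + 1L])
}

rsid_numeric <- function(id) {
  ok <- grepl("^rs[0-9]+$", id)
  if (!all(ok)) {
    abort(sprintf("SNP ID '%s' is not of the form rs<digits>; only numeric rsIDs can be packed",
                  id[!ok][1]),
          class = "cryptsnp_codec_error")
  }
  num <- as.numeric(substring(id, 3))
  if (any(num > 2^37 - 1)) {
    abort("numeric rsID exceeds 37 bits", class = "cryptsnp_codec_error")
  }
  num
}

#' Pack SNP records into the 10-byte binary format
#'
#' @param records A tibble of SNP records (see [vcf-dialect]); IDs must be
#'   numeric rsIDs (`rs<digits>`, value below 2^37).
#' @return A raw vector of `10 * nrow(records)` bytes.
#' @examples
#' r <- snp_records("1", 13110, "rs540538026", "G", "A", "heterozygous")
#' pack_snps(r)
#' @export
pack_snps <- function(records) {
  validate_snp_records(records, check_sorted = FALSE)
  if (nrow(records) == 0) return(raw(0))
  cpp_pack_snps(records$chrom, records$pos, rsid_numeric(records$id),
                encode_refalt(records$ref, records$alt),
                as.integer(records$zygosity == "homozygous"))
}

#' Unpack 10-byte binary SNPs into records
#'
#' Inverse of [pack_snps()]. Corrupt payloads (chromosome code 0 or above 25,
#' REF&ALT code above 19, length not a multiple of 10) raise an error.
#'
#' @param bytes Raw vector whose length is a multiple of 10.
#' @return A tibble of SNP records.
#' @export
unpack_snps <- function(bytes) {
  f <- cpp_unpack_snps(bytes)
  ra <- decode_refalt(f$refalt)
  new_snp_records(f$chrom, f$pos, paste0("rs", format(f$id_num,
                                                      scientific = FALSE,
                                                      trim = TRUE)),
                  ra$ref, ra$alt,
                  ZYGOSITY_LEVELS[f$homozygous + 1L])
}

#' 42-bit SNP variation keys
#'
#' The counter tables and the search engine identify a SNP variation by
#' chromosome, position and REF/ALT pair only (zygosity and rsID are
#' excluded). The key packs CHROM (5 bits), POS (32 bits) and the REF&ALT
#' code (5 bits) into a 42-bit integer, stored exactly in a double.
#'
#' @param chrom Integer chromosome codes 1..25.
#' @param pos Positions below 2^32.
#' @param refalt REF&ALT codes 0..19.
#' @return `snp_key()` returns numeric keys; `snp_key_fields()` a tibble with
#'   columns `chrom`, `pos`, `refalt`.
#' @export
snp_key <- function(chrom, pos, refalt) {
  as.numeric(chrom) * 2^37 + as.numeric(pos) * 2^5 + as.numeric(refalt)
}

#' @param key Numeric 42-bit keys.
#' @rdname snp_key
#' @export
snp_key_fields <- function(key) {
  key <- as.numeric(key)
  chrom <- key %/% 2^37
  rest <- key - chrom * 2^37
  pos <- rest %/% 2^5
  tibble::tibble(chrom = as.integer(chrom), pos = pos,
                 refalt = as.integer(rest - pos * 2^5))
}

#' @param records A tibble of SNP records.
#' @rdname snp_key
#' @export
record_keys <- function(records) {
  snp_key(records$chrom, records$pos,
          encode_refalt(records$ref, records$alt))
}
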