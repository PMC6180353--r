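#' The simplified VCF dialect
#'
#' The cohort files handled by this package are a restricted 8-column VCF:
#' zero or more `##` meta lines, one `#CHROM POS ID REF ALT QUAL FILTER TYPE`
#' header, then one whitespace-separated data line per SNP. REF and ALT are
#' distinct symbols from `{A, C, G, T, N}`, TYPE is `heterozygous` or
#' `homozygous`, and data lines are sorted by chromosome then position.
#' Records are represented as a tibble with columns `chrom` (integer code,
#' 1-25), `pos`, `id`, `ref`, `alt`, `zygosity`.
#'
#' @name vcf-dialect
NULL

#' Convert chromosome symbols to integer codes and back
#'
#' Chromosomes `"1"`..`"22"` map to codes 1..22, `"X"` to 23, `"Y"` to 24 and
#' `"MT"` to 25, so every contig fits the 5-bit CHROM field of the packed
#' binary format.
#'
#' @param symbol Character vector of chromosome symbols.
#' @param code Integer vector of chromosome codes in 1..25.
#' @return `chrom_code()` returns integer codes; `chrom_symbol()` returns
#'   symbols.
#' @examples
#' chrom_code(c("1", "X", "MT"))
#' chrom_symbol(c(1L, 23L, 25L))
#' @export
chrom_code <- function(symbol) {
  idx <- match(as.character(symbol), chrom_symbols)
  if (anyNA(idx)) {
    bad <- unique(symbol[is.na(idx)])
    abort(sprintf("unknown chromosome symbol(s): %s",
                  paste(bad, collapse = ", ")),
          class = "cryptsnp_field_error")
  }
  as.integer(idx)
}

#' @rdname chrom_code
#' @export
chrom_symbol <- function(code) {
  code <- as.integer(code)
  if (anyNA(code) || any(code < 1L | code > 25L)) {
    abort("chromosome codes must lie in 1..25", class = "cryptsnp_field_error")
  }
  chrom_symbols[code]
}

new_snp_records <- function(chrom, pos, id, ref, alt, zygosity) {
  tibble::tibble(
    chrom = as.integer(chrom), pos = as.numeric(pos), id = as.character(id),
    ref = as.character(ref), alt = as.character(alt),
    zygosity = as.character(zygosity)
  )
}

#' Construct a SNP record tibble
#'
#' Builds and validates the tabular record representation used throughout the
#' package (see [vcf-dialect]). Chromosomes may be given as symbols or codes.
#'
#' @param chrom Chromosome symbols (`"1"`..`"22"`, `"X"`, `"Y"`, `"MT"`) or
#'   integer codes 1..25.
#' @param pos 1-based positions (must fit in 32 bits).
#' @param id SNP identifiers of the form `"rs<digits>"`.
#' @param ref,alt Distinct bases from `{A, C, G, T, N}`.
#' @param zygosity `"heterozygous"` or `"homozygous"`.
#' @return A validated tibble of SNP records.
#' @examples
#' snp_records("1", 13110, "rs540538026", "G", "A", "heterozygous")
#' @export
snp_records <- function(chrom, pos, id, ref, alt, zygosity) {
  if (is.character(chrom) || is.factor(chrom)) chrom <- chrom_code(chrom)
  validate_snp_records(new_snp_records(chrom, pos, id, ref, alt, zygosity))
}

#' Validate a tibble of SNP records
#'
#' Checks every dialect invariant: chromosome codes in 1..25, 32-bit
#' positions, distinct REF/ALT from the 5-letter alphabet, a known zygosity
#' token, and (optionally) non-decreasing (chrom, pos) order.
#'
#' @param records A tibble as returned by [snp_records()] or [read_snp_vcf()].
#' @param check_sorted Verify the (chrom, pos) sort order.
#' @return `records`, invisibly unchanged, or an error.
#' @export
validate_snp_records <- function(records, check_sorted = TRUE) {
  need <- c("chrom", "pos", "id", "ref", "alt", "zygosity")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("records are missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cryptsnp_field_error")
  }
  if (nrow(records) == 0) return(records)
  if (anyNA(records[need])) {
    abort("records contain missing values", class = "cryptsnp_field_error")
  }
  if (any(records$chrom < 1L | records$chrom > 25L)) {
    abort("chromosome codes must lie in 1..25", class = "cryptsnp_field_error")
  }
  if (any(records$pos < 0 | records$pos != floor(records$pos) |
          records$pos > 2^32 - 1)) {
    abort("positions must be non-negative integers below 2^32",
          class = "cryptsnp_field_error")
  }
  bad_base <- !(records$ref %in% BASES) | !(records$alt %in% BASES)
  if (any(bad_base)) {
    abort(sprintf("invalid REF/ALT base at record %d", which(bad_base)[1]),
          class = "cryptsnp_field_error")
  }
  if (any(records$ref == records$alt)) {
    abort(sprintf("REF equals ALT at record %d",
                  which(records$ref == records$alt)[1]),
          class = "cryptsnp_field_error")
  }
  if (!all(records$zygosity %in% ZYGOSITY_LEVELS)) {
    abort("zygosity must be 'heterozygous' or 'homozygous'",
          class = "cryptsnp_field_error")
  }
  if (check_sorted) {
    key <- records$chrom * 2^32 + records$pos
    if (is.unsorted(key)) {
      i <- which(diff(key) < 0)[1] + 1L
      abort(sprintf(
        "records are not sorted by (chrom, pos): violation at record %d", i),
        class = "cryptsnp_order_error")
    }
  }
  records
}

#' Parse simplified-VCF text into SNP records
#'
#' `parse_snp_vcf()` parses a character vector of dialect lines;
#' `read_snp_vcf()` reads a file. QUAL and FILTER are read and discarded.
#' Fields may be separated by any run of spaces or tabs. Malformed lines are
#' reported with their 1-based line number in the input.
#'
#' @param lines Character vector of VCF lines.
#' @param file Path to a dialect VCF file.
#' @return A tibble of SNP records in file order (see [vcf-dialect]).
#' @examples
#' parse_snp_vcf(c(
#'   "##example",
#'   "#CHROM POS ID REF ALT QUAL FILTER TYPE",
#'   "1 13110 rs540538026 G A 100 PASS heterozygous"
#' ))
#' @export
parse_snp_vcf <- function(lines) {
  is_meta <- startsWith(lines, "##")
  body <- lines[!is_meta]
  body_lineno <- which(!is_meta)
  if (length(body) == 0 || !startsWith(body[1], "#")) {
    abort("missing '#CHROM ...' header line", class = "cryptsnp_parse_error")
  }
  data_lines <- body[-1]
  data_lineno <- body_lineno[-1]
  keep <- nzchar(trimws(data_lines))
  data_lines <- data_lines[keep]
  data_lineno <- data_lineno[keep]
  if (length(data_lines) == 0) {
    return(new_snp_records(integer(), numeric(), character(), character(),
                           character(), character()))
  }
  fields <- strsplit(trimws(data_lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    i <- which(nf != 8L)[1]
    abort(sprintf("line %d: expected 8 fields, found %d",
                  data_lineno[i], nf[i]),
          class = "cryptsnp_parse_error")
  }
  mat <- matrix(unlist(fields), ncol = 8, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(mat[, 2]))
  if (anyNA(pos)) {
    i <- which(is.na(pos))[1]
    abort(sprintf("line %d: POS '%s' is not an integer",
                  data_lineno[i], mat[i, 2]),
          class = "cryptsnp_field_error")
  }
  records <- withCallingHandlers(
    new_snp_records(chrom_code(mat[, 1]), pos, mat[, 3], mat[, 4], mat[, 5],
                    mat[, 8]),
    error = function(e) e
  )
  validate_snp_records(records)
}

#' @rdname parse_snp_vcf
#' @export
read_snp_vcf <- function(file) {
  parse_snp_vcf(readLines(file, warn = FALSE))
}

#' Write SNP records as simplified-VCF text
#'
#' Emits the dialect header followed by one tab-separated data line per
#' record with `QUAL = 100` and `FILTER = PASS`. Round trips with
#' [parse_snp_vcf()] exactly.
#'
#' @param records A sorted tibble of SNP records.
#' @param file Path to write, or `NULL` to return the lines.
#' @param meta Optional character vector of `##` meta lines to prepend.
#' @return The lines, invisibly when written to a file.
#' @export
write_snp_vcf <- function(records, file = NULL, meta = character()) {
  validate_snp_records(records)
  header <- paste(VCF_HEADER, collapse = "\t")
  data <- if (nrow(records) == 0) character() else {
    paste(chrom_symbol(records$chrom), format(records$pos, scientific = FALSE,
                                              trim = TRUE),
          records$id, records$ref, records$alt, "100", "PASS",
          records$zygosity, sep = "\t")
  }
  lines <- c(meta, header, data)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
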