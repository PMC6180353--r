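#' Encrypted SNP block format
#'
#' Packed SNPs are grouped into blocks and sealed with AES-128-GCM. A
#' serialized block is `count || IV || MAC || ciphertext`:
#' a 4-byte little-endian unsigned SNP count `n`, a fresh 12-byte random IV,
#' the 16-byte GCM tag, then `10 * n` bytes of ciphertext — `32 + 10n` bytes
#' in total. The count field is bound as associated data, so truncating or
#' altering it fails authentication exactly like a ciphertext flip.
#'
#' @name block-format
NULL

#' Handle 128-bit AES keys
#'
#' `key_from_hex()` decodes a 32-hex-character string into the 16 raw bytes
#' used by the block cipher; `random_key()` draws a fresh key from the OS
#' random source.
#'
#' @param hex A 32-character hexadecimal string.
#' @return A raw vector of 16 bytes.
#' @examples
#' key_from_hex("000102030405060708090a0b0c0d0e0f")
#' @export
key_from_hex <- function(hex) {
  hex <- gsub("[[:space:]]", "", hex)
  if (!grepl("^[0-9a-fA-F]{32}$", hex)) {
    abort("key must be exactly 32 hexadecimal characters (128 bits)",
          class = "cryptsnp_key_error")
  }
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

#' @rdname key_from_hex
#' @export
random_key <- function() crypto_random_bytes(16L)

# OS CSPRNG (urandom); independent of R's RNG stream on purpose, so
# simulation seeds never make IVs or keys predictable.
crypto_random_bytes <- function(n) {
  con <- file("/dev/urandom", "rb", raw = TRUE)
  on.exit(close(con))
  readBin(con, what = "raw", n = n)
}

check_key <- function(key) {
  if (!is.raw(key) || length(key) != 16L) {
    abort("key must be a raw vector of exactly 16 bytes",
          class = "cryptsnp_key_error")
  }
  key
}

encode_count <- function(n) {
  if (n > 2^31 - 1) abort("block SNP count exceeds supported range")
  writeBin(as.integer(n), raw(), size = 4L, endian = "little")
}

decode_count <- function(bytes4) {
  sum(as.numeric(bytes4) * 256^(0:3))
}

#' Encrypt packed SNPs into a serialized block
#'
#' @param payload Raw vector of packed SNPs (length a positive multiple
#'   of 10).
#' @param key 16-byte raw AES key.
#' @param iv Optional 12-byte IV; drawn from the OS random source when
#'   omitted (the safe default — IVs must never repeat under one key).
#' @return Raw vector of `32 + length(payload)` bytes (see [block-format]).
#' @export
encrypt_block <- function(payload, key, iv = NULL) {
  check_key(key)
  if (!is.raw(payload) || length(payload) == 0 || length(payload) %% 10 != 0) {
    abort("payload must be a non-empty raw vector of 10-byte packed SNPs",
          class = "cryptsnp_crypto_error")
  }
  if (is.null(iv)) iv <- crypto_random_bytes(12L)
  count <- encode_count(length(payload) / 10)
  enc <- cpp_aes_gcm_encrypt(key, iv, count, payload)
  c(count, iv, enc$tag, enc$ciphertext)
}

#' Decrypt and authenticate a serialized block
#'
#' Any modification of the count, IV, tag or ciphertext fails the GCM tag
#' check and raises a `cryptsnp_auth_error`; corrupted data is never
#' returned.
#'
#' @param block Raw vector holding one serialized block.
#' @param key 16-byte raw AES key.
#' @return The decrypted packed-SNP payload (raw, `10 * n` bytes).
#' @export
decrypt_block <- function(block, key) {
  check_key(key)
  if (length(block) < BLOCK_HEADER_BYTES) {
    abort("truncated block: shorter than the 32-byte header",
          class = "cryptsnp_framing_error")
  }
  count <- block[1:4]
  n <- decode_count(count)
  if (length(block) != BLOCK_HEADER_BYTES + 10 * n) {
    abort(sprintf("framing error: block advertises %d SNPs but holds %d payload bytes",
                  n, length(block) - BLOCK_HEADER_BYTES),
          class = "cryptsnp_framing_error")
  }
  iv <- block[5:16]
  tag <- block[17:32]
  ct <- block[-(1:32)]
  res <- cpp_aes_gcm_decrypt(key, iv, count, ct, tag)
  if (!isTRUE(res$ok)) {
    abort("block authentication failed: data was modified or the key is wrong",
          class = "cryptsnp_auth_error")
  }
  res$plaintext
}

#' Compress and encrypt a VCF file
#'
#' Parses a dialect VCF, packs each SNP into 10 bytes, groups `block_size`
#' consecutive SNPs per block (all blocks full except possibly the last) and
#' encrypts each block. A file of `m` SNPs serializes to exactly
#' `32 * ceiling(m / block_size) + 10 * m` bytes.
#'
#' @param input Path to a dialect VCF file, or a tibble of SNP records.
#' @param output Path for the encrypted file.
#' @param key 16-byte raw AES key.
#' @param block_size SNPs per full block; the default 2080 is a common
#'   multiple of the 10-byte SNP size and the 16-byte AES block size.
#' @return Invisibly, a tibble with `n_snps`, `n_blocks` and `bytes` written.
#' @export
compress_encrypt_file <- function(input, output, key,
                                  block_size = BLOCK_SNPS_DEFAULT) {
  check_key(key)
  if (block_size < 1) abort("block_size must be at least 1")
  records <- if (is.data.frame(input)) validate_snp_records(input)
             else read_snp_vcf(input)
  payload <- pack_snps(records)
  m <- nrow(records)
  con <- file(output, "wb")
  on.exit(close(con))
  n_blocks <- 0L
  if (m > 0) {
    starts <- seq(1, m, by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1, m)
      chunk <- payload[(10 * (s - 1) + 1):(10 * e)]
      writeBin(encrypt_block(chunk, key), con)
      n_blocks <- n_blocks + 1L
    }
  }
  invisible(tibble::tibble(n_snps = m, n_blocks = n_blocks,
                           bytes = BLOCK_HEADER_BYTES * n_blocks + 10 * m))
}

#' Index the blocks of an encrypted VCF file
#'
#' Scans the framing (without decrypting) and returns one row per block:
#' `index` (0-based), `offset` (bytes from file start), `n_snps` and `size`.
#' This is the cursor table the search engine resumes from; reading a
#' truncated file or trailing garbage raises a framing error naming the block.
#'
#' @param file Path to an encrypted VCF file.
#' @return A tibble with one row per block.
#' @export
scan_blocks <- function(file) {
  size <- file.size(file)
  if (is.na(size)) {
    abort(sprintf("cannot read '%s'", file), class = "cryptsnp_io_error")
  }
  con <- file(file, "rb")
  on.exit(close(con))
  offset <- 0
  idx <- integer()
  offs <- numeric()
  ns <- numeric()
  sizes <- numeric()
  while (offset < size) {
    if (size - offset < BLOCK_HEADER_BYTES) {
      abort(sprintf("framing error in '%s': block %d truncated in header",
                    file, length(idx)),
            class = "cryptsnp_framing_error")
    }
    count <- readBin(con, "raw", n = 4L)
    n <- decode_count(count)
    blk_size <- BLOCK_HEADER_BYTES + 10 * n
    if (offset + blk_size > size) {
      abort(sprintf("framing error in '%s': block %d truncated (needs %d bytes)",
                    file, length(idx), blk_size),
            class = "cryptsnp_framing_error")
    }
    idx <- c(idx, length(idx))
    offs <- c(offs, offset)
    ns <- c(ns, n)
    sizes <- c(sizes, blk_size)
    offset <- offset + blk_size
    seek(con, offset)
  }
  tibble::tibble(index = idx, offset = offs, n_snps = ns, size = sizes)
}

#' Read serialized blocks from an encrypted VCF file
#'
#' `read_blocks()` returns the serialized blocks (still encrypted) starting
#' from a 0-based block index, supporting the engine's resume-from-cursor
#' access pattern.
#'
#' @param file Path to an encrypted VCF file.
#' @param from 0-based index of the first block to yield.
#' @param n_blocks Maximum number of blocks to yield (default: all).
#' @param index Optional pre-computed [scan_blocks()] tibble.
#' @return A list of raw vectors, one serialized block each.
#' @export
read_blocks <- function(file, from = 0, n_blocks = Inf, index = NULL) {
  if (is.null(index)) index <- scan_blocks(file)
  take <- index[index$index >= from, , drop = FALSE]
  if (nrow(take) > n_blocks) take <- take[seq_len(n_blocks), , drop = FALSE]
  con <- file(file, "rb")
  on.exit(close(con))
  lapply(seq_len(nrow(take)), function(i) {
    seek(con, take$offset[i])
    readBin(con, "raw", n = take$size[i])
  })
}

#' Decrypt an encrypted VCF file back to SNP records
#'
#' Debug/inspection inverse of [compress_encrypt_file()]: decrypts every
#' block, unpacks the payload and returns the record tibble.
#'
#' @param file Path to an encrypted VCF file.
#' @param key 16-byte raw AES key.
#' @return A tibble of SNP records.
#' @export
decrypt_vcf_file <- function(file, key) {
  blocks <- read_blocks(file)
  payload <- do.call(c, c(list(raw(0)), lapply(blocks, decrypt_block, key = key)))
  unpack_snps(payload)
}
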