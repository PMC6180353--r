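#' Mask-randomized Fibonacci-hashed counter table
#'
#' The presence maps CTRL_CNT and CASE_CNT are bounded open-addressing hash
#' tables over 42-bit SNP keys (see [snp_key()]). A slot is found by
#' Fibonacci hashing: the key is XOR-ed with a random 64-bit mask drawn once
#' per table, multiplied by the golden-ratio constant `0x9E3779B97F4A7C15`,
#' and the top 22 bits of the 64-bit product are reduced modulo the capacity;
#' collisions probe linearly. The mask randomizes slot placement between
#' runs — memory access patterns differ run to run while the (key -> count)
#' mapping is mask-invariant. The default capacity of 282914 slots keeps the
#' table within a typical 8 MB L3 cache at a moderate fill ratio. If every
#' slot is occupied the table rehashes into twice the capacity with a
#' warning.
#'
#' @param capacity Number of slots.
#' @param mask Optional 8-byte raw mask; drawn from R's RNG when omitted so
#'   seeded runs are reproducible.
#' @return An object of class `snp_count_table`.
#' @examples
#' tab <- count_table(capacity = 64)
#' increment_counts(tab, snp_key(1, 100, 0), 2L)
#' count_entries(tab)
#' @export
count_table <- function(capacity = 282914, mask = NULL) {
  if (is.null(mask)) {
    mask <- as.raw(sample.int(256L, 8L, replace = TRUE) - 1L)
  }
  if (!is.raw(mask) || length(mask) != 8L) {
    abort("mask must be a raw vector of 8 bytes")
  }
  structure(list(ptr = cpp_ct_new(capacity, mask), mask = mask),
            class = "snp_count_table")
}

#' Add presence counts for SNP keys
#'
#' Heterozygous observations contribute 1, homozygous observations 2. The
#' final contents depend only on the multiset of `(key, amount)` pairs, never
#' on their order.
#'
#' @param table A [count_table()].
#' @param keys Numeric 42-bit SNP keys.
#' @param amounts Integer vector of 1s and 2s (recycled).
#' @return Integer vector of the new count for each key, invisibly.
#' @export
increment_counts <- function(table, keys, amounts = 1L) {
  amounts <- rep_len(as.integer(amounts), length(keys))
  invisible(cpp_ct_increment(table$ptr, as.numeric(keys), amounts))
}

#' @describeIn count_table Empty all slots, keeping capacity and mask.
#' @param table A [count_table()].
#' @export
clear_counts <- function(table) {
  cpp_ct_clear(table$ptr)
  invisible(table)
}

#' Extract occupied entries of a counter table
#'
#' @param table A [count_table()].
#' @return A tibble with columns `key` and `count`, one row per occupied
#'   slot, in slot order. Slot placement depends on the mask and, under
#'   collisions, on insertion history; the key -> count mapping never does.
#' @export
count_entries <- function(table) {
  e <- cpp_ct_entries(table$ptr)
  tibble::tibble(key = e$key, count = e$count)
}

#' @describeIn count_table Home slot index (0-based) for keys, before probing.
#' @param keys Numeric 42-bit SNP keys.
#' @export
slot_index <- function(table, keys) {
  cpp_ct_slot_index(table$ptr, as.numeric(keys))
}

#' @describeIn count_table Capacity and number of occupied slots.
#' @export
table_stats <- function(table) {
  tibble::tibble(capacity = cpp_ct_capacity(table$ptr),
                 occupied = cpp_ct_occupied(table$ptr))
}

#' @export
print.snp_count_table <- function(x, ...) {
  s <- table_stats(x)
  cat(sprintf("<snp_count_table> %d/%d slots occupied, mask %s\n",
              s$occupied, s$capacity,
              paste(format(x$mask), collapse = "")))
  invisible(x)
}
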