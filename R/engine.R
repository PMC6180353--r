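#' Cohort manifests
#'
#' A manifest labels encrypted VCF files `control` or `case`, one
#' tab-separated `path<TAB>label` pair per line. Relative paths resolve
#' against the manifest's directory.
#'
#' @param path Path of the manifest file.
#' @param manifest A tibble with columns `path` and `label`.
#' @return `read_manifest()` returns the manifest tibble;
#'   `write_manifest()` the path, invisibly.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    abort(sprintf("manifest '%s': every line must be 'path<TAB>label'", path),
          class = "cryptsnp_manifest_error")
  }
  m <- tibble::tibble(path = vapply(parts, `[[`, "", 1),
                      label = vapply(parts, `[[`, "", 2))
  rel <- !grepl("^(/|~)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  writeLines(paste(manifest$path, manifest$label, sep = "\t"), path)
  invisible(path)
}

check_manifest <- function(manifest) {
  if (!all(c("path", "label") %in% names(manifest))) {
    abort("manifest needs columns 'path' and 'label'",
          class = "cryptsnp_manifest_error")
  }
  if (!all(manifest$label %in% c("control", "case"))) {
    abort("manifest labels must be 'control' or 'case'",
          class = "cryptsnp_manifest_error")
  }
  if (!any(manifest$label == "control") || !any(manifest$label == "case")) {
    abort("manifest must contain at least one control and one case file",
          class = "cryptsnp_manifest_error")
  }
  manifest
}

#' Create a top-K SNP search engine
#'
#' The engine exposes a minimal five-call interface, shaped so that the
#' search loop could sit behind a trusted-execution boundary: create ([snp_engine()]), register a labeled cohort
#' ([register_cohort()]), then iterate SNP ranges ([next_range()],
#' [consume_range()], [end_range()]) until done — or let [run_search()]
#' drive the loop. Two counter tables (CTRL_CNT and CASE_CNT) are created
#' with fresh random masks; the result is invariant to block size, range
#' width, table capacity and mask, which only shape the access pattern.
#'
#' @param key 16-byte raw AES key shared by all cohort files.
#' @param top_k Number of most significant SNPs to report.
#' @param range_blocks Blocks of the first registered file spanning one SNP
#'   range (default 4).
#' @param table_capacity Slots per counter table (default 282914).
#' @param seed Optional integer seed making the table masks (and nothing
#'   else) reproducible.
#' @param ranking `"largest_stat"` (default) ranks by largest statistic =
#'   smallest p-value, the standard significance direction;
#'   `"smallest_stat"` flips it.
#' @return An engine object (environment) of class `snp_search_engine`.
#' @export
snp_engine <- function(key, top_k = 10, range_blocks = 4,
                       table_capacity = 282914, seed = NULL,
                       ranking = c("largest_stat", "smallest_stat")) {
  check_key(key)
  ranking <- match.arg(ranking)
  if (top_k < 1) abort("top_k must be at least 1", class = "cryptsnp_config_error")
  if (range_blocks < 1) abort("range_blocks must be at least 1",
                              class = "cryptsnp_config_error")
  draw <- function() {
    count_table(capacity = table_capacity)
  }
  tables <- if (is.null(seed)) list(draw(), draw()) else
    withr::with_seed(seed, list(draw(), draw()))
  e <- new.env(parent = emptyenv())
  e$key <- key
  e$top_k <- as.integer(top_k)
  e$range_blocks <- as.integer(range_blocks)
  e$ranking <- ranking
  e$ctrl_tab <- tables[[1]]
  e$case_tab <- tables[[2]]
  e$files <- NULL
  e$N_ctrl <- NULL
  e$N_case <- NULL
  e$topk <- tibble::tibble(key = numeric(), n_ctrl = numeric(),
                           n_case = numeric(), statistic = numeric())
  e$range_masses <- numeric()
  e$n_ranges <- 0L
  class(e) <- "snp_search_engine"
  e
}

#' @export
print.snp_search_engine <- function(x, ...) {
  cat(sprintf("<snp_search_engine> top_k=%d, range_blocks=%d, %s\n",
              x$top_k, x$range_blocks,
              if (is.null(x$files)) "no cohort registered"
              else sprintf("%d files registered (N_ctrl=%d, N_case=%d)",
                           length(x$files), x$N_ctrl, x$N_case)))
  invisible(x)
}

#' Register a labeled cohort of encrypted VCF files
#'
#' Memorizes file paths and their control/case flags, indexes each file's
#' block framing, initializes all cursors to block 0 and fixes the cohort
#' totals `N_ctrl` and `N_case` (twice the file counts).
#'
#' @param engine A [snp_engine()].
#' @param manifest A tibble with columns `path` and `label`, or the path of
#'   a manifest file (see [read_manifest()]).
#' @return The engine, invisibly.
#' @export
register_cohort <- function(engine, manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  check_manifest(manifest)
  engine$files <- lapply(seq_len(nrow(manifest)), function(i) {
    idx <- tryCatch(scan_blocks(manifest$path[i]), error = function(e) {
      abort(sprintf("cannot register '%s': %s", manifest$path[i],
                    conditionMessage(e)),
            class = "cryptsnp_manifest_error")
    })
    list(path = manifest$path[i], label = manifest$label[i], index = idx,
         cur_block = 0L, cur_offset = 0L, last_pk = -Inf,
         cache_idx = NA_integer_, cache = NULL)
  })
  engine$N_ctrl <- 2L * sum(manifest$label == "control")
  engine$N_case <- 2L * sum(manifest$label == "case")
  invisible(engine)
}

# decrypt + unpack block `bidx` (0-based) of file slot `fi`, with a one-block
# cache per file so next_range and consume_range share work
engine_block_fields <- function(engine, fi, bidx) {
  f <- engine$files[[fi]]
  if (!is.na(f$cache_idx) && f$cache_idx == bidx) return(f$cache)
  blk <- read_blocks(f$path, from = bidx, n_blocks = 1, index = f$index)[[1]]
  payload <- tryCatch(decrypt_block(blk, engine$key), error = function(e) {
    abort(sprintf("file '%s', block %d: %s", f$path, bidx,
                  conditionMessage(e)),
          class = class(e)[1])
  })
  fl <- cpp_unpack_snps(payload)
  key42 <- snp_key(fl$chrom, fl$pos, fl$refalt)
  flds <- list(key42 = key42, posk = key42 %/% 32, amount = fl$homozygous + 1L)
  f$cache_idx <- bidx
  f$cache <- flds
  engine$files[[fi]] <- f
  flds
}

file_exhausted <- function(f) f$cur_block >= nrow(f$index)

#' Draw the next SNP range from the reference file
#'
#' Ranges are defined by the first registered file: each range spans up to
#' `range_blocks` of its blocks, starting at the first not-yet-consumed SNP
#' and ending (inclusively) at the last SNP of the last such block. When the
#' reference file is exhausted but other files still hold SNPs beyond its
#' final position, one last open-ended range sweeps up the remainder.
#'
#' @param engine A registered [snp_engine()].
#' @return A list of class `snp_range` with fields `start_pk`, `end_pk`
#'   (`Inf` for the final sweep) and `open`, or `NULL` when every file is
#'   exhausted.
#' @export
next_range <- function(engine) {
  if (is.null(engine$files)) {
    abort("no cohort registered", class = "cryptsnp_config_error")
  }
  f1 <- engine$files[[1]]
  if (!file_exhausted(f1)) {
    b0 <- f1$cur_block
    b1 <- min(b0 + engine$range_blocks - 1L, nrow(f1$index) - 1L)
    first <- engine_block_fields(engine, 1L, b0)
    last <- engine_block_fields(engine, 1L, b1)
    return(structure(list(start_pk = first$posk[f1$cur_offset + 1L],
                          end_pk = last$posk[length(last$posk)],
                          open = FALSE, blocks = c(b0, b1)),
                     class = "snp_range"))
  }
  if (any(vapply(engine$files, Negate(file_exhausted), logical(1)))) {
    return(structure(list(start_pk = -Inf, end_pk = Inf, open = TRUE,
                          blocks = NULL),
                     class = "snp_range"))
  }
  NULL
}

#' Count the SNPs of one range across every cohort file
#'
#' For each registered file, starting at its cursor, decrypts successive
#' blocks and adds every SNP at or before the range end to its cohort's
#' counter table (1 for heterozygous, 2 for homozygous). Cursors store a
#' block index plus an intra-block offset, so a block straddling the range
#' boundary is split logically and its remainder survives to the next range:
#' every SNP is counted exactly once over the whole run.
#'
#' @param engine A registered [snp_engine()].
#' @param range A range from [next_range()].
#' @return The engine, invisibly.
#' @export
consume_range <- function(engine, range) {
  stopifnot(inherits(range, "snp_range"))
  mass <- 0
  for (fi in seq_along(engine$files)) {
    tab <- if (engine$files[[fi]]$label == "control") engine$ctrl_tab
           else engine$case_tab
    repeat {
      f <- engine$files[[fi]]
      if (file_exhausted(f)) break
      flds <- engine_block_fields(engine, fi, f$cur_block)
      rem <- seq.int(f$cur_offset + 1L, length(flds$posk))
      pk <- flds$posk[rem]
      if (is.unsorted(c(f$last_pk, pk))) {
        abort(sprintf("file '%s', block %d: SNPs out of (chrom, pos) order",
                      f$path, f$cur_block),
              class = "cryptsnp_order_error")
      }
      ntake <- sum(pk <= range$end_pk)
      if (ntake > 0) {
        take <- rem[seq_len(ntake)]
        increment_counts(tab, flds$key42[take], flds$amount[take])
        mass <- mass + sum(flds$amount[take])
        f$last_pk <- pk[ntake]
      }
      if (ntake == length(rem)) {
        f$cur_block <- f$cur_block + 1L
        f$cur_offset <- 0L
        engine$files[[fi]] <- f
      } else {
        f$cur_offset <- f$cur_offset + ntake
        engine$files[[fi]] <- f
        break
      }
    }
  }
  engine$pending_mass <- mass
  invisible(engine)
}

#' Close a range: score its SNPs and fold them into the global top-K
#'
#' Computes the chi-squared statistic for every key present in either
#' counter table (a key missing from one cohort counts 0 there), merges the
#' scored SNPs into the global top-K list — ties broken by ascending
#' (chrom, pos, refalt) — and clears both tables for the next range.
#'
#' @param engine A registered [snp_engine()].
#' @return The engine, invisibly.
#' @export
end_range <- function(engine) {
  ec <- count_entries(engine$ctrl_tab)
  ek <- count_entries(engine$case_tab)
  keys <- union(ec$key, ek$key)
  if (length(keys) > 0) {
    n_ctrl <- ec$count[match(keys, ec$key)]
    n_ctrl[is.na(n_ctrl)] <- 0
    n_case <- ek$count[match(keys, ek$key)]
    n_case[is.na(n_case)] <- 0
    cand <- tibble::tibble(
      key = keys, n_ctrl = as.numeric(n_ctrl), n_case = as.numeric(n_case),
      statistic = chi2_statistic(n_ctrl, n_case, engine$N_ctrl, engine$N_case))
    pool <- dplyr::bind_rows(engine$topk, cand)
    ord <- if (engine$ranking == "largest_stat") {
      order(-pool$statistic, pool$key)
    } else {
      order(pool$statistic, pool$key)
    }
    engine$topk <- pool[head(ord, engine$top_k), , drop = FALSE]
  }
  engine$range_masses <- c(engine$range_masses,
                           if (is.null(engine$pending_mass)) 0
                           else engine$pending_mass)
  engine$pending_mass <- NULL
  engine$n_ranges <- engine$n_ranges + 1L
  clear_counts(engine$ctrl_tab)
  clear_counts(engine$case_tab)
  invisible(engine)
}

#' Run the full top-K search
#'
#' Drives the range loop ([next_range()] / [consume_range()] /
#' [end_range()]) until every file is exhausted, then computes p-values —
#' for the final K SNPs only — from the precomputed survival table.
#'
#' @param engine A registered [snp_engine()].
#' @param surv A [survival_table()] for the final p-values.
#' @return An object of class `snp_topk_result`; see [tidy.snp_topk_result()].
#' @export
run_search <- function(engine, surv = survival_table()) {
  repeat {
    rng <- next_range(engine)
    if (is.null(rng)) break
    consume_range(engine, rng)
    end_range(engine)
  }
  tk <- engine$topk
  fields <- snp_key_fields(tk$key)
  ra <- decode_refalt(fields$refalt)
  results <- tibble::tibble(
    rank = seq_len(nrow(tk)),
    chrom = chrom_symbol(fields$chrom),
    pos = fields$pos,
    ref = ra$ref,
    alt = ra$alt,
    n_ctrl = tk$n_ctrl,
    n_case = tk$n_case,
    statistic = tk$statistic,
    p_value = if (nrow(tk) > 0) chi2_survival(surv, tk$statistic) else numeric(),
    key = tk$key
  )
  structure(list(
    results = results,
    params = list(top_k = engine$top_k, range_blocks = engine$range_blocks,
                  ranking = engine$ranking, N_ctrl = engine$N_ctrl,
                  N_case = engine$N_case, n_files = length(engine$files),
                  n_ranges = engine$n_ranges),
    range_masses = engine$range_masses
  ), class = "snp_topk_result")
}

#' Tidy and summarize top-K search results
#'
#' `tidy()` returns one row per reported SNP (rank, locus, counts,
#' statistic, p-value); `glance()` a one-row summary of the run.
#'
#' @param x A `snp_topk_result` from [run_search()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.snp_topk_result <- function(x, ...) x$results

#' @rdname tidy.snp_topk_result
#' @export
glance.snp_topk_result <- function(x, ...) {
  tibble::tibble(
    n_reported = nrow(x$results),
    top_statistic = if (nrow(x$results) > 0) x$results$statistic[1] else NA_real_,
    top_p_value = if (nrow(x$results) > 0) x$results$p_value[1] else NA_real_,
    n_files = x$params$n_files,
    N_ctrl = x$params$N_ctrl,
    N_case = x$params$N_case,
    n_ranges = x$params$n_ranges,
    ranking = x$params$ranking
  )
}

#' @export
print.snp_topk_result <- function(x, ...) {
  cat(sprintf("<snp_topk_result> top %d SNPs (%s first) from %d files\n",
              nrow(x$results),
              if (x$params$ranking == "largest_stat") "most significant"
              else "least significant",
              x$params$n_files))
  print(x$results)
  invisible(x)
}

#' Plot top-K search results
#'
#' Dot plot of the reported SNPs' chi-squared statistics by genomic locus,
#' colored by chromosome.
#'
#' @param object A `snp_topk_result` from [run_search()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snp_topk_result <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$statistic,
                                  color = .data$chrom)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "position", y = expression(chi^2 ~ statistic),
                  color = "chromosome",
                  title = sprintf("Top %d SNPs by Pearson chi-squared",
                                  nrow(d))) +
    ggplot2::theme_minimal()
}
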