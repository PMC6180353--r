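# independent reference implementations used as test oracles; each avoids the
# code path it checks

# bit-assembly packing oracle: builds the 80-bit word bit by bit with plain
# division arithmetic, never touching the compiled codec
oracle_pack_record <- function(chrom, pos, id_num, refalt, homozygous) {
  field_bits <- function(value, width) {
    bits <- integer(width)
    for (b in seq_len(width)) {        # LSB first
      bits[b] <- value %% 2
      value <- value %/% 2
    }
    rev(bits)                          # MSB first
  }
  bits <- c(field_bits(chrom, 5), field_bits(pos, 32), field_bits(id_num, 37),
            field_bits(refalt, 5), field_bits(homozygous, 1))
  bytes <- vapply(seq(1, 80, by = 8), function(s)
    sum(bits[s:(s + 7)] * 2^(7:0)), numeric(1))
  as.raw(bytes)
}

# plain-R REF&ALT pair enumeration, written out explicitly
oracle_refalt_code <- function(ref, alt) {
  ab <- c("A", "C", "G", "T", "N")
  k <- 0L
  for (r in ab) for (a in ab) {
    if (r == a) next
    if (r == ref && a == alt) return(k)
    k <- k + 1L
  }
  stop("invalid pair")
}

# closed-form 2x2 Pearson statistic N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d));
# NA where a margin is zero (degenerate table)
oracle_chi2 <- function(n_ctrl, n_case, N_ctrl, N_case) {
  a <- n_ctrl; b <- N_ctrl - n_ctrl
  c_ <- n_case; d <- N_case - n_case
  N <- N_ctrl + N_case
  N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# naive counter map over (key, amount) pairs
oracle_count_map <- function(keys, amounts) {
  agg <- tapply(amounts, as.character(keys), sum)
  tibble::tibble(key = as.numeric(names(agg)), count = as.numeric(agg))
}

# naive full-decrypt top-K reference: decrypt every file up front, build one
# global pair of count maps, score, sort by (-statistic, key)
oracle_topk <- function(manifest, key, top_k) {
  per_file <- lapply(seq_len(nrow(manifest)), function(i) {
    recs <- decrypt_vcf_file(manifest$path[i], key)
    tibble::tibble(key = record_keys(recs),
                   amount = ifelse(recs$zygosity == "homozygous", 2, 1),
                   label = manifest$label[i])
  })
  all <- dplyr::bind_rows(per_file)
  counts <- all |>
    dplyr::group_by(key, label) |>
    dplyr::summarise(n = sum(amount), .groups = "drop") |>
    tidyr::pivot_wider(names_from = label, values_from = n, values_fill = 0)
  if (!"control" %in% names(counts)) counts$control <- 0
  if (!"case" %in% names(counts)) counts$case <- 0
  N_ctrl <- 2 * sum(manifest$label == "control")
  N_case <- 2 * sum(manifest$label == "case")
  counts$statistic <- chi2_statistic(counts$control, counts$case,
                                     N_ctrl, N_case)
  counts$closed_form <- oracle_chi2(counts$control, counts$case,
                                    N_ctrl, N_case)
  out <- counts[order(-counts$statistic, counts$key), ]
  utils::head(out, top_k)
}

# total counted mass a file contributes: 2 per homozygous line, 1 otherwise
oracle_file_mass <- function(vcf_path) {
  recs <- read_snp_vcf(vcf_path)
  sum(ifelse(recs$zygosity == "homozygous", 2, 1))
}
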