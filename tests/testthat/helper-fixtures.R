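# shared fixtures: fixed key, dialect sample, random record generator

test_key <- function() key_from_hex("000102030405060708090a0b0c0d0e0f")

# reference 8-column dialect sample (header + six data lines)
sample_vcf_lines <- function() {
  c("##real id in 1000genome project: HG00253",
    "#CHROM POS ID REF ALT QUAL FILTER TYPE",
    "1 13110 rs540538026 G A 100 PASS heterozygous",
    "1 13116 rs62635286 T G 100 PASS heterozygous",
    "1 13118 rs200579949 A G 100 PASS heterozygous",
    "1 14930 rs75454623 A G 100 PASS heterozygous",
    "1 15211 rs78601809 T G 100 PASS homozygous",
    "1 18849 rs533090414 C G 100 PASS homozygous")
}

# random dialect-valid record tibbles, sorted by (chrom, pos)
random_records <- function(n, max_chrom = 25, max_pos = 2^32 - 1) {
  if (n == 0) {
    return(snp_records(integer(), numeric(), character(), character(),
                       character(), character()))
  }
  chrom <- sort(sample.int(max_chrom, n, replace = TRUE))
  pos <- numeric(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(floor(runif(length(i)) * max_pos))
  }
  ra <- decode_refalt(sample(0:19, n, replace = TRUE))
  snp_records(chrom, pos,
              paste0("rs", floor(runif(n) * (2^37 - 1))),
              ra$ref, ra$alt,
              sample(c("heterozygous", "homozygous"), n, replace = TRUE))
}

# small synthetic cohort, generated + encrypted, returns manifest and truth
make_encrypted_cohort <- function(key, n_ctrl = 4, n_case = 4, n_snps = 60,
                                  block_size = 16, seed = 1, ...) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  cfg <- synth_config(n_control_files = n_ctrl, n_case_files = n_case,
                      n_snps = n_snps, seed = seed, ...)
  g <- generate_cohort(cfg, dir)
  list(manifest = encrypt_cohort(g$manifest, key, block_size = block_size),
       truth = g$truth, plain = g$manifest, dir = dir)
}
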