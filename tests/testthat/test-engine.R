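# builds an encrypted file directly from a record tibble
enc_file <- function(records, key, block_size, dir, name) {
  path <- file.path(dir, name)
  compress_encrypt_file(records, path, key, block_size = block_size)
  path
}

test_that("engine construction and registration enforce their contracts", {
  key <- test_key()
  expect_error(snp_engine(as.raw(1:5)), class = "cryptsnp_key_error")
  expect_error(snp_engine(key, top_k = 0), class = "cryptsnp_config_error")
  eng <- snp_engine(key)
  expect_equal(eng$range_blocks, 4L)
  e1 <- snp_engine(key, seed = 5)
  e2 <- snp_engine(key, seed = 5)
  expect_identical(e1$ctrl_tab$mask, e2$ctrl_tab$mask)
  expect_identical(e1$case_tab$mask, e2$case_tab$mask)

  dir <- withr::local_tempdir()
  f <- enc_file(random_records(10), key, 16, dir, "a.evcf")
  expect_error(register_cohort(snp_engine(key),
                               tibble::tibble(path = f, label = "control")),
               class = "cryptsnp_manifest_error")
  expect_error(register_cohort(snp_engine(key),
                               tibble::tibble(path = "missing.evcf",
                                              label = c("control", "case"))),
               class = "cryptsnp_manifest_error")
  g <- enc_file(random_records(10), key, 16, dir, "b.evcf")
  eng <- snp_engine(key)
  register_cohort(eng, tibble::tibble(path = c(f, g),
                                      label = c("control", "case")))
  expect_equal(eng$N_ctrl, 2L)
  expect_equal(eng$N_case, 2L)
})

test_that("cohort totals double the file counts", {
  withr::local_seed(2)
  key <- test_key()
  dir <- withr::local_tempdir()
  paths <- vapply(1:6, function(i)
    enc_file(random_records(5), key, 16, dir, sprintf("f%d.evcf", i)), "")
  eng <- snp_engine(key)
  register_cohort(eng, tibble::tibble(path = paths,
                                      label = rep(c("control", "case"),
                                                  c(4, 2))))
  expect_equal(eng$N_ctrl, 8L)
  expect_equal(eng$N_case, 4L)
})

test_that("ranges walk the reference file four blocks at a time", {
  withr::local_seed(41)
  key <- test_key()
  dir <- withr::local_tempdir()
  recs <- random_records(100)
  f1 <- enc_file(recs, key, 10, dir, "ref.evcf")      # 10 blocks
  f2 <- enc_file(recs[1:5, ], key, 10, dir, "other.evcf")
  eng <- snp_engine(key, range_blocks = 4)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("control", "case")))
  seen <- list()
  repeat {
    r <- next_range(eng)
    if (is.null(r)) break
    seen <- c(seen, list(r$blocks))
    consume_range(eng, r)
    end_range(eng)
  }
  expect_equal(seen, list(c(0L, 3L), c(4L, 7L), c(8L, 9L)))
})

test_that("a short reference file yields a single remainder range", {
  withr::local_seed(43)
  key <- test_key()
  dir <- withr::local_tempdir()
  f1 <- enc_file(random_records(15), key, 10, dir, "ref.evcf")  # 2 blocks
  f2 <- enc_file(random_records(3), key, 10, dir, "o.evcf")
  eng <- snp_engine(key)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("case", "control")))
  r <- next_range(eng)
  expect_equal(r$blocks, c(0L, 1L))
  consume_range(eng, r)
  end_range(eng)
  expect_null(next_range(eng))
})

test_that("presence counting follows the het=1 / hom=2 rule exactly", {
  key <- test_key()
  dir <- withr::local_tempdir()
  site <- function(zyg) snp_records("7", 1234, "rs77", "C", "T", zyg)
  # planted SNP homozygous in all 5 case files, absent from 5 controls
  ctrl <- snp_records("7", 99, "rs1", "A", "G", "heterozygous")
  paths <- character()
  labels <- character()
  for (i in 1:5) {
    paths <- c(paths, enc_file(ctrl, key, 4, dir, sprintf("c%d.evcf", i)))
    labels <- c(labels, "control")
  }
  for (i in 1:5) {
    paths <- c(paths, enc_file(site("homozygous"), key, 4, dir,
                               sprintf("k%d.evcf", i)))
    labels <- c(labels, "case")
  }
  eng <- snp_engine(key, top_k = 5)
  register_cohort(eng, tibble::tibble(path = paths, label = labels))
  res <- tidy(run_search(eng))
  planted <- res[res$pos == 1234, ]
  expect_equal(planted$n_case, 10)
  expect_equal(planted$n_ctrl, 0)
  expect_equal(planted$rank, 1L)

  # heterozygous in 3 of 5 control files
  dir2 <- withr::local_tempdir()
  p2 <- character(); l2 <- character()
  for (i in 1:5) {
    r <- if (i <= 3) site("heterozygous") else ctrl
    p2 <- c(p2, enc_file(r, key, 4, dir2, sprintf("c%d.evcf", i)))
    l2 <- c(l2, "control")
  }
  p2 <- c(p2, enc_file(ctrl, key, 4, dir2, "k.evcf"))
  l2 <- c(l2, "case")
  eng2 <- snp_engine(key, top_k = 5)
  register_cohort(eng2, tibble::tibble(path = p2, label = l2))
  res2 <- tidy(run_search(eng2))
  expect_equal(res2$n_ctrl[res2$pos == 1234], 3)
})

test_that("multi-allelic sites at the range boundary are all included", {
  key <- test_key()
  dir <- withr::local_tempdir()
  # reference file: 4 SNPs, one block => range ends at (1, 400)
  ref <- snp_records(rep("1", 4), c(100, 200, 300, 400),
                     paste0("rs", 1:4), rep("A", 4), rep("G", 4),
                     rep("heterozygous", 4))
  # case file holds two alleles at the boundary position (1, 400)
  kc <- snp_records(rep("1", 2), c(400, 400), c("rs4", "rs5"),
                    c("A", "A"), c("G", "T"), rep("heterozygous", 2))
  f1 <- enc_file(ref, key, 4, dir, "ref.evcf")
  f2 <- enc_file(kc, key, 4, dir, "case.evcf")
  eng <- snp_engine(key, top_k = 10, range_blocks = 1)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("control", "case")))
  r <- next_range(eng)
  consume_range(eng, r)
  end_range(eng)
  # both case alleles at pos 400 were consumed in the first (only) range
  expect_null(next_range(eng))
  res <- eng$topk
  expect_equal(nrow(res), 5)    # 4 control sites + the extra (A,T) allele
})

test_that("SNPs beyond the reference file's span are swept up at the end", {
  key <- test_key()
  dir <- withr::local_tempdir()
  ref <- snp_records("1", 100, "rs1", "A", "G", "heterozygous")
  far <- snp_records(c("2", "2"), c(50, 60), c("rs2", "rs3"),
                     c("C", "C"), c("T", "G"), rep("homozygous", 2))
  f1 <- enc_file(ref, key, 4, dir, "ref.evcf")
  f2 <- enc_file(far, key, 4, dir, "far.evcf")
  eng <- snp_engine(key, top_k = 10)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("control", "case")))
  res <- tidy(run_search(eng))
  expect_setequal(res$pos, c(100, 50, 60))
  expect_equal(sort(res$n_case), c(0, 2, 2))
})

test_that("results equal the naive full-decrypt oracle on random cohorts", {
  withr::local_seed(47)
  key <- test_key()
  for (i in 1:8) {
    co <- make_encrypted_cohort(key, n_ctrl = sample(2:6, 1),
                                n_case = sample(2:6, 1),
                                n_snps = sample(50:250, 1),
                                block_size = sample(c(7, 16, 64), 1),
                                seed = 1000 + i)
    eng <- snp_engine(key, top_k = 10)
    register_cohort(eng, co$manifest)
    got <- tidy(run_search(eng))
    want <- oracle_topk(co$manifest, key, 10)
    expect_equal(got$key, want$key)
    expect_equal(got$n_ctrl, want$control)
    expect_equal(got$n_case, want$case)
    expect_equal(got$statistic, want$closed_form, tolerance = 1e-9)
  }
})

test_that("output is invariant to block size, range width, capacity and mask", {
  withr::local_seed(53)
  key <- test_key()
  co <- make_encrypted_cohort(key, n_ctrl = 3, n_case = 3, n_snps = 120,
                              block_size = 16, seed = 77)
  run_with <- function(block_size, range_blocks, capacity, seed) {
    m <- encrypt_cohort(co$plain, key, dir = withr::local_tempdir(),
                        block_size = block_size)
    eng <- snp_engine(key, top_k = 8, range_blocks = range_blocks,
                      table_capacity = capacity, seed = seed)
    register_cohort(eng, m)
    r <- tidy(run_search(eng))
    r$p_value <- NULL
    r
  }
  baseline <- run_with(16, 4, 282914, 1)
  for (B in c(5, 40)) {
    for (rb in c(1, 7)) {
      expect_identical(run_with(B, rb, 4099, B * 100 + rb), baseline)
    }
  }
})

test_that("counted mass is conserved across ranges", {
  withr::local_seed(59)
  key <- test_key()
  co <- make_encrypted_cohort(key, n_ctrl = 3, n_case = 2, n_snps = 80,
                              block_size = 9, seed = 5)
  eng <- snp_engine(key, top_k = 5)
  register_cohort(eng, co$manifest)
  res <- run_search(eng)
  total <- sum(vapply(co$plain$path, oracle_file_mass, numeric(1)))
  expect_equal(sum(res$range_masses), total)
  expect_gt(res$params$n_ranges, 1)   # the partition actually partitioned
})

test_that("K beyond the number of distinct SNPs returns everything", {
  withr::local_seed(61)
  key <- test_key()
  dir <- withr::local_tempdir()
  recs <- random_records(7)
  f1 <- enc_file(recs, key, 4, dir, "a.evcf")
  f2 <- enc_file(recs[2:3, ], key, 4, dir, "b.evcf")
  eng <- snp_engine(key, top_k = 100)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("control", "case")))
  res <- tidy(run_search(eng))
  expect_equal(nrow(res), length(unique(record_keys(recs))))
})

test_that("equal statistics break ties by ascending genomic key", {
  key <- test_key()
  dir <- withr::local_tempdir()
  # rank 1 is forced (homozygous control-only site, statistic 4); the two
  # heterozygous case-only sites tie at 4/3 and compete for the last slot
  kc <- snp_records(c("3", "5"), c(10, 20), c("rs1", "rs2"),
                    c("A", "C"), c("G", "T"), rep("heterozygous", 2))
  ctrl <- snp_records("1", 5, "rs9", "A", "G", "homozygous")
  f1 <- enc_file(ctrl, key, 4, dir, "c.evcf")
  f2 <- enc_file(kc, key, 4, dir, "k.evcf")
  eng <- snp_engine(key, top_k = 2)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("control", "case")))
  res <- tidy(run_search(eng))
  expect_equal(res$chrom, c("1", "3"))    # ascending key wins the tie
  expect_equal(res$statistic[1], 4)
})

test_that("ranking can be flipped to report smallest statistics first", {
  withr::local_seed(67)
  key <- test_key()
  co <- make_encrypted_cohort(key, n_ctrl = 3, n_case = 3, n_snps = 60,
                              seed = 9)
  run_dir <- function(ranking) {
    eng <- snp_engine(key, top_k = 5, ranking = ranking)
    register_cohort(eng, co$manifest)
    tidy(run_search(eng))
  }
  hi <- run_dir("largest_stat")
  lo <- run_dir("smallest_stat")
  expect_true(all(diff(hi$statistic) <= 0))
  expect_true(all(diff(lo$statistic) >= 0))
  expect_gte(min(hi$statistic), max(lo$statistic) - 1e-12)
})

test_that("tampered cohort files abort the search naming file and block", {
  withr::local_seed(71)
  key <- test_key()
  dir <- withr::local_tempdir()
  f1 <- enc_file(random_records(30), key, 8, dir, "good.evcf")
  f2 <- enc_file(random_records(30), key, 8, dir, "bad.evcf")
  bytes <- readBin(f2, "raw", file.size(f2))
  bytes[100] <- xor(bytes[100], as.raw(1))
  writeBin(bytes, f2)
  eng <- snp_engine(key, top_k = 3)
  register_cohort(eng, tibble::tibble(path = c(f1, f2),
                                      label = c("control", "case")))
  expect_error(run_search(eng), "bad\\.evcf.*block 0",
               class = "cryptsnp_auth_error")
})

test_that("p-values are attached only to the final top-K entries", {
  withr::local_seed(73)
  key <- test_key()
  co <- make_encrypted_cohort(key, n_ctrl = 3, n_case = 3, n_snps = 50,
                              seed = 3)
  eng <- snp_engine(key, top_k = 4)
  register_cohort(eng, co$manifest)
  res <- tidy(run_search(eng))
  expect_equal(nrow(res), 4)
  surv <- survival_table()
  expect_equal(res$p_value, chi2_survival(surv, res$statistic))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})
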