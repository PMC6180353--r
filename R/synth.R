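#' Configure a synthetic case/control cohort
#'
#' The generator emulates the shape of a real screening dataset: a shared
#' template of
#' sorted, rs-numbered SNP sites on chromosomes 1-22, from which each file
#' includes site `i` independently with its cohort's carrier probability.
#' `n_planted` sites get cohort-specific carrier probabilities
#' (`carrier_prob_control` vs `carrier_prob_case`); all others use the
#' shared background probability. Carried sites are homozygous with
#' probability `hom_fraction`, independently per file. The seed fully
#' determines the output.
#'
#' @param n_control_files,n_case_files Cohort sizes in files.
#' @param n_snps Sites in the shared template.
#' @param n_planted Number of associated (planted) sites.
#' @param carrier_prob_control,carrier_prob_case Carrier probability of each
#'   planted site in the two cohorts.
#' @param background_prob Carrier probability of non-planted sites in both
#'   cohorts.
#' @param hom_fraction Probability that a carried site is homozygous.
#' @param seed Integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_control_files = 50, n_case_files = 50,
                         n_snps = 1000, n_planted = 5,
                         carrier_prob_control = 0.1,
                         carrier_prob_case = 0.9,
                         background_prob = 0.3, hom_fraction = 0.3,
                         seed = 1) {
  probs <- c(carrier_prob_control, carrier_prob_case, background_prob,
             hom_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]", class = "cryptsnp_config_error")
  }
  if (n_planted > n_snps) {
    abort("n_planted cannot exceed n_snps", class = "cryptsnp_config_error")
  }
  if (n_control_files < 1 || n_case_files < 1 || n_snps < 1) {
    abort("cohort sizes and n_snps must be positive",
          class = "cryptsnp_config_error")
  }
  structure(as.list(environment())[c(
    "n_control_files", "n_case_files", "n_snps", "n_planted",
    "carrier_prob_control", "carrier_prob_case", "background_prob",
    "hom_fraction", "seed")], class = "synth_config")
}

#' Expected chi-squared statistic of a site at its expected counts
#'
#' A site carried with probability `p` contributes an expected presence
#' count of `files * p * (1 + hom_fraction)` in its cohort (each carrier
#' adds 1 if heterozygous, 2 if homozygous). The truth statistic is
#' [chi2_statistic()] evaluated at those expectations, and predicts the
#' ranking of planted against background sites.
#'
#' @param p_ctrl,p_case Carrier probabilities in the two cohorts.
#' @param n_control_files,n_case_files Cohort sizes in files.
#' @param hom_fraction Probability a carried site is homozygous.
#' @return Numeric vector of expected statistics.
#' @examples
#' truth_statistic(0.1, 0.9, 50, 50, hom_fraction = 0)
#' @export
truth_statistic <- function(p_ctrl, p_case, n_control_files, n_case_files,
                            hom_fraction) {
  w <- 1 + hom_fraction
  chi2_statistic(n_control_files * p_ctrl * w, n_case_files * p_case * w,
                 2 * n_control_files, 2 * n_case_files)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one dialect VCF per file, a `manifest.tsv` (`path<TAB>label`) and
#' a `truth.tsv` holding, per template site, the carrier probabilities, the
#' exact expected presence counts and the expected chi-squared statistic at
#' those expectations.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with `manifest` (tibble), `truth` (tibble),
#'   `manifest_path`, `truth_path` and `dir`.
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(config$seed, {
    n <- config$n_snps
    chrom <- sort(sample.int(22L, n, replace = TRUE))
    pos <- numeric(n)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      pos[i] <- sort(sample.int(2e8, length(i)))
    }
    ids <- paste0("rs", sample.int(2^30, n))
    ra <- decode_refalt(sample(0:19, n, replace = TRUE))
    template <- new_snp_records(chrom, pos, ids, ra$ref, ra$alt,
                                rep("heterozygous", n))
    planted <- sort(sample.int(n, config$n_planted))
    p_ctrl <- rep(config$background_prob, n)
    p_case <- rep(config$background_prob, n)
    p_ctrl[planted] <- config$carrier_prob_control
    p_case[planted] <- config$carrier_prob_case

    emit <- function(label, i, p) {
      carried <- runif(n) < p
      zyg <- ifelse(runif(n) < config$hom_fraction, "homozygous",
                    "heterozygous")
      recs <- template[carried, , drop = FALSE]
      recs$zygosity <- zyg[carried]
      fname <- sprintf("%s_%04d.vcf", label, i)
      write_snp_vcf(recs, file.path(dir, fname),
                    meta = sprintf("##synthetic cohort file %s (seed %d)",
                                   fname, config$seed))
      fname
    }
    files <- c(
      vapply(seq_len(config$n_control_files), function(i)
        emit("control", i, p_ctrl), ""),
      vapply(seq_len(config$n_case_files), function(i)
        emit("case", i, p_case), "")
    )
    labels <- rep(c("control", "case"),
                  c(config$n_control_files, config$n_case_files))
  })
  manifest <- tibble::tibble(path = file.path(dir, files), label = labels)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(tibble::tibble(path = files, label = labels), manifest_path)

  w <- 1 + config$hom_fraction
  truth <- tibble::tibble(
    chrom = template$chrom, pos = template$pos, id = template$id,
    ref = template$ref, alt = template$alt,
    planted = seq_len(config$n_snps) %in% planted,
    p_ctrl = p_ctrl, p_case = p_case,
    e_n_ctrl = config$n_control_files * p_ctrl * w,
    e_n_case = config$n_case_files * p_case * w,
    truth_stat = truth_statistic(p_ctrl, p_case, config$n_control_files,
                                 config$n_case_files, config$hom_fraction)
  )
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = manifest, truth = truth,
                 manifest_path = manifest_path, truth_path = truth_path,
                 dir = dir))
}

#' Compress and encrypt every file of a cohort
#'
#' Convenience wrapper running [compress_encrypt_file()] over a manifest and
#' returning a new manifest pointing at the encrypted files.
#'
#' @param manifest A tibble with columns `path` and `label`.
#' @param key 16-byte raw AES key.
#' @param dir Output directory (default: alongside the inputs).
#' @param block_size SNPs per full block.
#' @return A manifest tibble for the encrypted files.
#' @export
encrypt_cohort <- function(manifest, key, dir = NULL,
                           block_size = BLOCK_SNPS_DEFAULT) {
  out <- vapply(manifest$path, function(p) {
    d <- if (is.null(dir)) dirname(p) else dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    o <- file.path(d, paste0(sub("\\.vcf$", "", basename(p)), ".evcf"))
    compress_encrypt_file(p, o, key, block_size = block_size)
    o
  }, "")
  tibble::tibble(path = unname(out), label = manifest$label)
}
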