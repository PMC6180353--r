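# Shared dialect constants. The base alphabet order fixes the REF&ALT pair
# enumeration, so it is part of the on-disk binary format.
BASES <- c("A", "C", "G", "T", "N")
ZYGOSITY_LEVELS <- c("heterozygous", "homozygous")
VCF_HEADER <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "TYPE")
chrom_symbols <- c(as.character(1:22), "X", "Y", "MT")

BLOCK_SNPS_DEFAULT <- 2080L
BLOCK_HEADER_BYTES <- 32L
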