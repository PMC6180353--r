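#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 80-bit SNP record layout, most-significant field first:
//   CHROM(5) | POS(32) | ID(37) | REF&ALT(5) | TYPE(1)
// serialized big-endian into 10 bytes. The top 37 bits are CHROM|POS, so
// unsigned byte-wise comparison of packed records sorts by (chrom, pos).

typedef unsigned __int128 u128;

// [[Rcpp::export]]
RawVector cpp_pack_snps(IntegerVector chrom, NumericVector pos,
                        NumericVector id_num, IntegerVector refalt,
                        IntegerVector homozygous) {
  R_xlen_t m = chrom.size();
  RawVector out(10 * m);
  for (R_xlen_t i = 0; i < m; ++i) {
    int64_t c = chrom[i];
    if (c < 1 || c > 25)
      stop("record %ld: chromosome code %ld outside 1..25", (long)(i + 1), (long)c);
    double pd = pos[i], idd = id_num[i];
    if (!(pd >= 0) || pd != std::floor(pd) || pd > 4294967295.0)
      stop("record %ld: position does not fit in 32 bits", (long)(i + 1));
    if (!(idd >= 0) || idd != std::floor(idd) || idd > 137438953471.0) // 2^37-1
      stop("record %ld: numeric rsID does not fit in 37 bits", (long)(i + 1));
    int ra = refalt[i];
    if (ra < 0 || ra > 19)
      stop("record %ld: REF&ALT code %d outside 0..19", (long)(i + 1), ra);
    int ty = homozygous[i];
    if (ty != 0 && ty != 1)
      stop("record %ld: TYPE bit must be 0 or 1", (long)(i + 1));
    u128 v = ((u128)c << 75) | ((u128)(uint64_t)pd << 43) |
             ((u128)(uint64_t)idd << 6) | ((u128)ra << 1) | (u128)ty;
    for (int b = 0; b < 10; ++b)
      out[10 * i + b] = (Rbyte)(uint8_t)(v >> (8 * (9 - b)));
  }
  return out;
}

// [[Rcpp::export]]
List cpp_unpack_snps(RawVector bytes) {
  if (bytes.size() % 10 != 0)
    stop("packed payload length %ld is not a multiple of 10 bytes", (long)bytes.size());
  R_xlen_t m = bytes.size() / 10;
  IntegerVector chrom(m), refalt(m), homozygous(m);
  NumericVector pos(m), id_num(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    u128 v = 0;
    for (int b = 0; b < 10; ++b)
      v = (v << 8) | (u128)(uint8_t)bytes[10 * i + b];
    int c = (int)((v >> 75) & 0x1F);
    uint64_t p = (uint64_t)((v >> 43) & 0xFFFFFFFFULL);
    uint64_t idn = (uint64_t)((v >> 6) & 0x1FFFFFFFFFULL);
    int ra = (int)((v >> 1) & 0x1F);
    int ty = (int)(v & 1);
    if (c < 1 || c > 25)
      stop("corrupt record %ld: chromosome code %d outside 1..25", (long)(i + 1), c);
    if (ra > 19)
      stop("corrupt record %ld: REF&ALT code %d outside 0..19", (long)(i + 1), ra);
    chrom[i] = c;
    pos[i] = (double)p;
    id_num[i] = (double)idn;
    refalt[i] = ra;
    homozygous[i] = ty;
  }
  return List::create(_["chrom"] = chrom, _["pos"] = pos, _["id_num"] = id_num,
                      _["refalt"] = refalt, _["homozygous"] = homozygous);
}
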