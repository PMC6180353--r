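#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Bounded counter table for 42-bit SNP keys (CHROM(5)|POS(32)|REF&ALT(5)).
// Placement: Fibonacci hashing — the key is XOR-ed with a per-run random
// 64-bit mask, multiplied by the 64-bit golden-ratio constant, and the top
// 22 bits of the product are reduced modulo the capacity. Collisions resolve
// by linear probing. Each slot carries the element state machine
// (0 = empty, 1 = update, 2 = wait); sequential execution passes through
// update on every write, so the transitions mirror the element-level
// synchronization contract even without threads.

static const uint64_t FIB_MULT = 0x9E3779B97F4A7C15ULL;

struct CountTable {
  uint64_t mask;
  size_t capacity;
  size_t occupied;
  std::vector<uint8_t> state;
  std::vector<uint64_t> key;
  std::vector<int> count;
  CountTable(size_t n, uint64_t m)
      : mask(m), capacity(n), occupied(0), state(n, 0), key(n, 0), count(n, 0) {}
  size_t home(uint64_t k) const {
    uint64_t h = (k ^ mask) * FIB_MULT;
    return (size_t)((h >> 42) % (uint64_t)capacity);
  }
};

static uint64_t mask_from_raw(RawVector mask8) {
  if (mask8.size() != 8) stop("mask must be exactly 8 bytes");
  uint64_t m = 0;
  for (int i = 0; i < 8; ++i) m = (m << 8) | (uint64_t)(uint8_t)mask8[i];
  return m;
}

// [[Rcpp::export]]
SEXP cpp_ct_new(double capacity, RawVector mask8) {
  if (!(capacity >= 1) || capacity != std::floor(capacity))
    stop("capacity must be a positive integer");
  XPtr<CountTable> p(new CountTable((size_t)capacity, mask_from_raw(mask8)), true);
  return p;
}

static void grow(CountTable &t) {
  Rf_warning("counter table capacity %lu exhausted; rehashing into %lu slots",
             (unsigned long)t.capacity, (unsigned long)(2 * t.capacity));
  CountTable bigger(2 * t.capacity, t.mask);
  for (size_t i = 0; i < t.capacity; ++i) {
    if (t.state[i] == 0) continue;
    size_t j = bigger.home(t.key[i]);
    while (bigger.state[j] != 0) j = (j + 1) % bigger.capacity;
    bigger.state[j] = 2;
    bigger.key[j] = t.key[i];
    bigger.count[j] = t.count[i];
    ++bigger.occupied;
  }
  t = std::move(bigger);
}

// [[Rcpp::export]]
IntegerVector cpp_ct_increment(SEXP ptr, NumericVector keys, IntegerVector amounts) {
  XPtr<CountTable> p(ptr);
  CountTable &t = *p;
  R_xlen_t m = keys.size();
  if (amounts.size() != m) stop("keys and amounts differ in length");
  IntegerVector out(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    int a = amounts[i];
    if (a != 1 && a != 2) stop("increment amount must be 1 or 2");
    uint64_t k = (uint64_t)keys[i];
    for (;;) {
      size_t j = t.home(k);
      size_t probed = 0;
      bool placed = false;
      while (probed < t.capacity) {
        if (t.state[j] == 0) {
          t.state[j] = 1;                 // empty -> update
          t.key[j] = k;
          t.count[j] = a;
          t.state[j] = 2;                 // update -> wait
          ++t.occupied;
          out[i] = a;
          placed = true;
          break;
        }
        if (t.key[j] == k) {
          t.state[j] = 1;                 // wait -> update
          t.count[j] += a;
          t.state[j] = 2;                 // update -> wait
          out[i] = t.count[j];
          placed = true;
          break;
        }
        j = (j + 1) % t.capacity;
        ++probed;
      }
      if (placed) break;
      grow(t);                            // full probe cycle: reallocate 2N
    }
  }
  return out;
}

// [[Rcpp::export]]
void cpp_ct_clear(SEXP ptr) {
  XPtr<CountTable> p(ptr);
  std::fill(p->state.begin(), p->state.end(), 0);
  std::fill(p->count.begin(), p->count.end(), 0);
  p->occupied = 0;
}

// [[Rcpp::export]]
List cpp_ct_entries(SEXP ptr) {
  XPtr<CountTable> p(ptr);
  size_t n = p->occupied;
  NumericVector keys(n);
  IntegerVector counts(n);
  size_t k = 0;
  for (size_t i = 0; i < p->capacity; ++i) {
    if (p->state[i] == 0) continue;
    keys[k] = (double)p->key[i];
    counts[k] = p->count[i];
    ++k;
  }
  return List::create(_["key"] = keys, _["count"] = counts);
}

// [[Rcpp::export]]
double cpp_ct_capacity(SEXP ptr) { return (double)XPtr<CountTable>(ptr)->capacity; }

// [[Rcpp::export]]
double cpp_ct_occupied(SEXP ptr) { return (double)XPtr<CountTable>(ptr)->occupied; }

// [[Rcpp::export]]
NumericVector cpp_ct_slot_index(SEXP ptr, NumericVector keys) {
  XPtr<CountTable> p(ptr);
  NumericVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i)
    out[i] = (double)p->home((uint64_t)keys[i]);
  return out;
}
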