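// Lossless bitstream codecs for quantized skip-connection feature maps.
//
// All four schemes operate on unsigned q-bit integer codes in scan order
// (channel-major, row-major within a channel).  Sizes returned are payload
// bits only; container metadata (shape, q, codec id) lives in the R-level
// header and is excluded from size comparisons.
//
// BPC dialect: per block of 8/16 codes, the first value is the base (q raw
// bits); the block-1 successive deltas (q+1-bit two's complement) are
// transposed into q+1 bit-planes, adjacent planes are XORed (top plane kept
// as-is) and each resulting plane is coded with a prefix-free symbol table:
//   run of 2-33 all-zero planes : 01 + 5-bit (run-2)
//   single all-zero plane       : 001
//   all-ones plane              : 00000
//   nonzero plane, zero DBP     : 00001            (plane equals DBP above)
//   two consecutive ones        : 00010 + position
//   single one                  : 00011 + position
//   uncompressed                : 1 + (block-1) raw bits
// The full table is documented in the package vignette.

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct BitWriter {
  std::vector<uint8_t> buf;
  size_t nbits = 0;
  void put_bit(int b) {
    if (nbits % 8 == 0) buf.push_back(0);
    if (b) buf.back() |= (uint8_t)(1u << (7 - (nbits % 8)));
    ++nbits;
  }
  void put(uint32_t v, int nb) {
    for (int i = nb - 1; i >= 0; --i) put_bit((v >> i) & 1u);
  }
  List as_list() const {
    RawVector r(buf.size());
    std::copy(buf.begin(), buf.end(), r.begin());
    return List::create(_["bytes"] = r, _["nbits"] = (double)nbits);
  }
};

struct BitReader {
  const uint8_t* p;
  size_t nbits, pos = 0;
  BitReader(const RawVector& r, double nb) : p(RAW(r)), nbits((size_t)nb) {}
  int get_bit() {
    if (pos >= nbits) stop("corrupt stream: read past end");
    int b = (p[pos / 8] >> (7 - (pos % 8))) & 1;
    ++pos;
    return b;
  }
  uint32_t get(int nb) {
    uint32_t v = 0;
    for (int i = 0; i < nb; ++i) v = (v << 1) | (uint32_t)get_bit();
    return v;
  }
};

void check_codes(const IntegerVector& codes, int q) {
  const int maxv = (1 << q) - 1;
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    if (codes[i] == NA_INTEGER || codes[i] < 0 || codes[i] > maxv)
      stop("codes must be unsigned %d-bit integers", q);
  }
}

int pos_bits(int m) {  // width of the position field for an m-bit plane
  int b = 0;
  while ((1 << b) < m) ++b;
  return b;
}

// ---- BPC block primitives --------------------------------------------------

void bpc_encode_block(BitWriter& bw, const int* v, int block, int q) {
  const int m = block - 1;            // number of deltas
  const int planes = q + 1;           // delta bitwidth
  const uint32_t mmask = (m == 32) ? 0xffffffffu : ((1u << m) - 1u);
  const uint32_t dmask = (1u << planes) - 1u;
  bw.put((uint32_t)v[0], q);          // base value, raw

  uint32_t ud[32];
  for (int j = 0; j < m; ++j) ud[j] = (uint32_t)(v[j + 1] - v[j]) & dmask;

  uint32_t dbp[8], dbx[8];            // indexed by plane b = 0..q
  for (int b = 0; b < planes; ++b) {
    uint32_t w = 0;
    for (int j = 0; j < m; ++j) w |= ((ud[j] >> b) & 1u) << j;
    dbp[b] = w;
  }
  dbx[q] = dbp[q];
  for (int b = 0; b < q; ++b) dbx[b] = dbp[b] ^ dbp[b + 1];

  const int pb = pos_bits(m);
  int b = q;
  while (b >= 0) {
    if (dbx[b] == 0) {
      int run = 1;
      while (b - run >= 0 && dbx[b - run] == 0) ++run;
      if (run >= 2) {                 // run length is at most q+1 <= 33
        bw.put(1u, 2);                // 01
        bw.put((uint32_t)(run - 2), 5);
      } else {
        bw.put(1u, 3);                // 001
      }
      b -= run;
      continue;
    }
    if (dbp[b] == 0) {
      bw.put(1u, 5);                  // 00001: plane equals DBP of plane above
    } else if (dbx[b] == mmask) {
      bw.put(0u, 5);                  // 00000: all ones
    } else {
      // locate set bits
      int first = -1, count = 0;
      for (int j = 0; j < m; ++j)
        if ((dbx[b] >> j) & 1u) { if (first < 0) first = j; ++count; }
      bool two_consec = (count == 2) && (((dbx[b] >> first) & 3u) == 3u);
      if (two_consec) {
        bw.put(2u, 5);                // 00010
        bw.put((uint32_t)first, pb);
      } else if (count == 1) {
        bw.put(3u, 5);                // 00011
        bw.put((uint32_t)first, pb);
      } else {
        bw.put_bit(1);                // uncompressed
        for (int j = 0; j < m; ++j) bw.put_bit((dbx[b] >> j) & 1u);
      }
    }
    --b;
  }
}

void bpc_decode_block(BitReader& br, int* v, int block, int q) {
  const int m = block - 1;
  const int planes = q + 1;
  const uint32_t mmask = (m == 32) ? 0xffffffffu : ((1u << m) - 1u);
  const int pb = pos_bits(m);
  uint32_t base = br.get(q);

  uint32_t dbx[8];
  bool dbp_zero[8];
  int b = q;
  while (b >= 0) {
    if (br.get_bit()) {               // 1: uncompressed plane
      uint32_t w = 0;
      for (int j = 0; j < m; ++j) w |= (uint32_t)br.get_bit() << j;
      dbx[b] = w; dbp_zero[b] = false; --b;
    } else if (br.get_bit()) {        // 01: zero run
      int run = (int)br.get(5) + 2;
      if (run > b + 1) stop("corrupt stream: zero run too long");
      for (int k = 0; k < run; ++k) { dbx[b] = 0; dbp_zero[b] = false; --b; }
    } else if (br.get_bit()) {        // 001: single zero plane
      dbx[b] = 0; dbp_zero[b] = false; --b;
    } else {
      uint32_t sym = br.get(2);       // 000xx
      if (sym == 0u) { dbx[b] = mmask; dbp_zero[b] = false; }
      else if (sym == 1u) { dbx[b] = 0; dbp_zero[b] = true; }   // resolved below
      else if (sym == 2u) {
        uint32_t p = br.get(pb);
        if ((int)p > m - 2) stop("corrupt stream: bad position");
        dbx[b] = 3u << p; dbp_zero[b] = false;
      } else {
        uint32_t p = br.get(pb);
        if ((int)p > m - 1) stop("corrupt stream: bad position");
        dbx[b] = 1u << p; dbp_zero[b] = false;
      }
      --b;
    }
  }

  uint32_t dbp[8];
  for (int bb = q; bb >= 0; --bb) {
    uint32_t above = (bb == q) ? 0u : dbp[bb + 1];
    if (dbp_zero[bb]) { dbp[bb] = 0u; }
    else dbp[bb] = (bb == q) ? dbx[bb] : (dbx[bb] ^ above);
  }

  const uint32_t dmask = (1u << planes) - 1u;
  v[0] = (int)base;
  for (int j = 0; j < m; ++j) {
    uint32_t ud = 0;
    for (int bb = 0; bb < planes; ++bb) ud |= ((dbp[bb] >> j) & 1u) << bb;
    int d = (int)ud;
    if (ud & (1u << q)) d -= (int)(dmask + 1u);  // sign-extend
    v[j + 1] = v[j] + d;
  }
}

void bpc_encode_all(BitWriter& bw, const IntegerVector& codes, int q, int block) {
  const R_xlen_t n = codes.size();
  int v[32];
  for (R_xlen_t start = 0; start < n; start += block) {
    for (int j = 0; j < block; ++j)
      v[j] = (start + j < n) ? codes[start + j] : 0;  // zero-pad tail block
    bpc_encode_block(bw, v, block, q);
  }
}

IntegerVector bpc_decode_all(BitReader& br, int n, int q, int block) {
  IntegerVector out(n);
  int v[32];
  const int nblocks = (n + block - 1) / block;
  for (int bl = 0; bl < nblocks; ++bl) {
    bpc_decode_block(br, v, block, q);
    for (int j = 0; j < block; ++j) {
      R_xlen_t idx = (R_xlen_t)bl * block + j;
      if (idx < n) out[idx] = v[j];
    }
  }
  return out;
}

}  // namespace

// ---- ZVC -------------------------------------------------------------------

// [[Rcpp::export(name = ".cx_zvc_encode")]]
List cx_zvc_encode(IntegerVector codes, int q) {
  check_codes(codes, q);
  BitWriter bw;
  for (R_xlen_t i = 0; i < codes.size(); ++i) bw.put_bit(codes[i] != 0);
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    if (codes[i] != 0) bw.put((uint32_t)codes[i], q);
  return bw.as_list();
}

// [[Rcpp::export(name = ".cx_zvc_decode")]]
IntegerVector cx_zvc_decode(RawVector bytes, double nbits, int n, int q) {
  BitReader br(bytes, nbits);
  std::vector<int> flags(n);
  for (int i = 0; i < n; ++i) flags[i] = br.get_bit();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = flags[i] ? (int)br.get(q) : 0;
  if (br.pos != br.nbits) stop("corrupt stream: trailing bits");
  return out;
}

// ---- DZVC ------------------------------------------------------------------

// [[Rcpp::export(name = ".cx_dzvc_encode")]]
List cx_dzvc_encode(IntegerVector codes, int q, IntegerVector chan_sizes) {
  check_codes(codes, q);
  BitWriter bw;
  std::vector<int> payload;
  R_xlen_t off = 0;
  for (R_xlen_t c = 0; c < chan_sizes.size(); ++c) {
    for (int i = 0; i < chan_sizes[c]; ++i) {
      bool fresh = (i == 0) || (codes[off + i] != codes[off + i - 1]);
      bw.put_bit(fresh);
      if (fresh) payload.push_back(codes[off + i]);
    }
    off += chan_sizes[c];
  }
  if (off != codes.size()) stop("chan_sizes must sum to length(codes)");
  for (int v : payload) bw.put((uint32_t)v, q);
  return bw.as_list();
}

// [[Rcpp::export(name = ".cx_dzvc_decode")]]
IntegerVector cx_dzvc_decode(RawVector bytes, double nbits, int q,
                             IntegerVector chan_sizes) {
  R_xlen_t n = 0;
  for (R_xlen_t c = 0; c < chan_sizes.size(); ++c) n += chan_sizes[c];
  BitReader br(bytes, nbits);
  std::vector<int> flags(n);
  for (R_xlen_t i = 0; i < n; ++i) flags[i] = br.get_bit();
  IntegerVector out(n);
  R_xlen_t off = 0;
  for (R_xlen_t c = 0; c < chan_sizes.size(); ++c) {
    for (int i = 0; i < chan_sizes[c]; ++i) {
      if (flags[off + i]) out[off + i] = (int)br.get(q);
      else {
        if (i == 0) stop("corrupt stream: channel-initial value missing");
        out[off + i] = out[off + i - 1];
      }
    }
    off += chan_sizes[c];
  }
  if (br.pos != br.nbits) stop("corrupt stream: trailing bits");
  return out;
}

// ---- BPC / EBPC ------------------------------------------------------------

// [[Rcpp::export(name = ".cx_bpc_encode")]]
List cx_bpc_encode(IntegerVector codes, int q, int block) {
  if (block != 8 && block != 16) stop("block must be 8 or 16");
  check_codes(codes, q);
  BitWriter bw;
  bpc_encode_all(bw, codes, q, block);
  return bw.as_list();
}

// [[Rcpp::export(name = ".cx_bpc_decode")]]
IntegerVector cx_bpc_decode(RawVector bytes, double nbits, int n, int q, int block) {
  BitReader br(bytes, nbits);
  IntegerVector out = bpc_decode_all(br, n, q, block);
  if (br.pos != br.nbits) stop("corrupt stream: trailing bits");
  return out;
}

// [[Rcpp::export(name = ".cx_ebpc_encode")]]
List cx_ebpc_encode(IntegerVector codes, int q, int block) {
  if (block != 8 && block != 16) stop("block must be 8 or 16");
  check_codes(codes, q);
  BitWriter bw;
  IntegerVector nz(std::count_if(codes.begin(), codes.end(),
                                 [](int v) { return v != 0; }));
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    bw.put_bit(codes[i] != 0);
    if (codes[i] != 0) nz[k++] = codes[i];
  }
  bpc_encode_all(bw, nz, q, block);
  return bw.as_list();
}

// [[Rcpp::export(name = ".cx_ebpc_decode")]]
IntegerVector cx_ebpc_decode(RawVector bytes, double nbits, int n, int q, int block) {
  BitReader br(bytes, nbits);
  std::vector<int> flags(n);
  int nnz = 0;
  for (int i = 0; i < n; ++i) { flags[i] = br.get_bit(); nnz += flags[i]; }
  IntegerVector nz = bpc_decode_all(br, nnz, q, block);
  if (br.pos != br.nbits) stop("corrupt stream: trailing bits");
  IntegerVector out(n);
  int k = 0;
  for (int i = 0; i < n; ++i) out[i] = flags[i] ? nz[k++] : 0;
  return out;
}
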