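#include <Rcpp.h>
#include <openssl/evp.h>
using namespace Rcpp;

// Thin EVP wrappers for AES-128-GCM with associated data. The tag is the
// standard 16-byte GCM tag; decryption returns ok = FALSE on any
// authentication failure instead of plaintext.

static void evp_fail(EVP_CIPHER_CTX *ctx, const char *what) {
  if (ctx) EVP_CIPHER_CTX_free(ctx);
  stop("OpenSSL failure in %s", what);
}

// [[Rcpp::export]]
List cpp_aes_gcm_encrypt(RawVector key, RawVector iv, RawVector aad,
                         RawVector plaintext) {
  if (key.size() != 16) stop("key must be exactly 16 bytes");
  if (iv.size() != 12) stop("IV must be exactly 12 bytes");
  EVP_CIPHER_CTX *ctx = EVP_CIPHER_CTX_new();
  if (!ctx) evp_fail(nullptr, "ctx_new");
  if (EVP_EncryptInit_ex(ctx, EVP_aes_128_gcm(), nullptr,
                         (const unsigned char *)RAW(key),
                         (const unsigned char *)RAW(iv)) != 1)
    evp_fail(ctx, "EncryptInit");
  int len = 0;
  if (aad.size() > 0 &&
      EVP_EncryptUpdate(ctx, nullptr, &len, (const unsigned char *)RAW(aad),
                        (int)aad.size()) != 1)
    evp_fail(ctx, "aad");
  RawVector ct(plaintext.size());
  if (plaintext.size() > 0 &&
      EVP_EncryptUpdate(ctx, (unsigned char *)RAW(ct), &len,
                        (const unsigned char *)RAW(plaintext),
                        (int)plaintext.size()) != 1)
    evp_fail(ctx, "EncryptUpdate");
  unsigned char dummy[16];
  if (EVP_EncryptFinal_ex(ctx, dummy, &len) != 1) evp_fail(ctx, "EncryptFinal");
  RawVector tag(16);
  if (EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_GET_TAG, 16,
                          (unsigned char *)RAW(tag)) != 1)
    evp_fail(ctx, "get_tag");
  EVP_CIPHER_CTX_free(ctx);
  return List::create(_["ciphertext"] = ct, _["tag"] = tag);
}

// [[Rcpp::export]]
List cpp_aes_gcm_decrypt(RawVector key, RawVector iv, RawVector aad,
                         RawVector ciphertext, RawVector tag) {
  if (key.size() != 16) stop("key must be exactly 16 bytes");
  if (iv.size() != 12) stop("IV must be exactly 12 bytes");
  if (tag.size() != 16) stop("tag must be exactly 16 bytes");
  EVP_CIPHER_CTX *ctx = EVP_CIPHER_CTX_new();
  if (!ctx) evp_fail(nullptr, "ctx_new");
  if (EVP_DecryptInit_ex(ctx, EVP_aes_128_gcm(), nullptr,
                         (const unsigned char *)RAW(key),
                         (const unsigned char *)RAW(iv)) != 1)
    evp_fail(ctx, "DecryptInit");
  int len = 0;
  if (aad.size() > 0 &&
      EVP_DecryptUpdate(ctx, nullptr, &len, (const unsigned char *)RAW(aad),
                        (int)aad.size()) != 1)
    evp_fail(ctx, "aad");
  RawVector pt(ciphertext.size());
  if (ciphertext.size() > 0 &&
      EVP_DecryptUpdate(ctx, (unsigned char *)RAW(pt), &len,
                        (const unsigned char *)RAW(ciphertext),
                        (int)ciphertext.size()) != 1) {
    EVP_CIPHER_CTX_free(ctx);
    return List::create(_["ok"] = false, _["plaintext"] = R_NilValue);
  }
  if (EVP_CIPHER_CTX_ctrl(ctx, EVP_CTRL_GCM_SET_TAG, 16,
                          (unsigned char *)RAW(tag)) != 1)
    evp_fail(ctx, "set_tag");
  unsigned char dummy[16];
  int ok = EVP_DecryptFinal_ex(ctx, dummy, &len);
  EVP_CIPHER_CTX_free(ctx);
  if (ok != 1) return List::create(_["ok"] = false, _["plaintext"] = R_NilValue);
  return List::create(_["ok"] = true, _["plaintext"] = pt);
}
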