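# 32-bit FNV-1a hash of a character string; used for parameter fingerprints
# and for deriving per-compound sub-seeds. Returns a non-negative integer
# below 2^31 (double-backed to avoid 32-bit overflow in R integers).
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(paste(x, collapse = "\x1f")))) {
    h <- bitwXor(as.integer(h %% 2^31), b) +
      (if (h >= 2^31) 2^31 else 0)  # keep the xor on the low 31 bits
    h <- (h * 16777619) %% 2^32
  }
  as.integer(h %% 2^31)
}

# short hex fingerprint of a list of parameters/ids
fingerprint <- function(...) {
  sprintf("%08x", fnv1a32(paste(
    vapply(list(...), function(x) paste(format(x, digits = 15),
                                        collapse = ","), ""),
    collapse = "|")))
}
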