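# Derive a reproducible sub-seed from a master seed and a purpose tag, so the
# mask, dropout and initialization streams are independent but all pinned by
# one recorded integer. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, salt) {
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((as.numeric(seed) * 48271 + h * 9349 + 1) %% (2^31 - 2)) + 1L
}

# add a bias row-vector to every row of a matrix (column-major recycling)
add_bias <- function(X, b) X + rep(b, each = nrow(X))

`%||%` <- function(a, b) if (is.null(a)) b else a
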