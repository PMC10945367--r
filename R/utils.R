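# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so results are a pure
# function of their `seed` argument.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed (< 2^31) from a master seed and a tag,
# so independent stages never share an RNG stream.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1009 + h * 97 + 1) %% 2147483629)
}

# i.i.d. random protein of length `len` from residue frequencies `freqs`
# (named over the 20 standard residues).
random_protein <- function(len, freqs = NULL) {
  aa <- aa_standard()
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(aa, len, replace = TRUE, prob = freqs), collapse = "")
}

# Replace anything outside the 20 standard residues with X.
sanitize_seq <- function(x) {
  toupper(gsub(sprintf("[^%s]", paste(aa_standard(), collapse = "")),
               "X", toupper(x)))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
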