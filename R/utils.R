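`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Locale-independent lexicographic sort (radix works on the underlying bytes).
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(x) order(x, method = "radix")

# Canonical unordered-pair key: lexicographically smaller label first.
pair_key <- function(a, b) {
  swap <- mapply(function(x, y) {
    order(c(x, y), method = "radix")[1L] == 2L
  }, a, b, USE.NAMES = FALSE)
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  list(a = lo, b = hi, key = paste(lo, hi, sep = "\t"))
}

stop_value <- function(...) stop(..., call. = FALSE)
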