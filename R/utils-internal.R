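# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats setNames
.BASE_LOOKUP <- local({
  x <- rep(NA_integer_, 128)
  x[utf8ToInt("A")] <- 0L
  x[utf8ToInt("C")] <- 1L
  x[utf8ToInt("G")] <- 2L
  x[utf8ToInt("T")] <- 3L
  x
})

# DNA string -> integer codes (A=0, C=1, G=2, T=3, N/other = NA)
.base_codes <- function(seq_chr) {
  .BASE_LOOKUP[utf8ToInt(seq_chr)]
}

.CODE_TO_BASE <- c("A", "C", "G", "T")

# Code of the k-mer starting at each position (bases left to right,
# first base most significant).  NA where the window leaves the sequence
# or contains an ambiguous base.
.window_codes <- function(codes, k = 6L) {
  n <- length(codes)
  if (n < k) return(integer(0))
  out <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    out <- out + codes[j:(n - k + j)] * 4^(k - j)
  }
  as.integer(out)
}

# Reverse-complement of a k-mer code, vectorised.
.rc_codes <- function(code, k = 6L) {
  out <- numeric(length(code))
  rem <- code
  for (j in seq_len(k)) {
    digit <- rem %% 4            # base at position k - j + 1 (least significant first)
    rem <- rem %/% 4
    out <- out + (3 - digit) * 4^(k - j)
  }
  as.integer(out)
}

# All k-mer strings in code order.
.kmer_strings <- function(k = 6L) {
  g <- expand.grid(rep(list(.CODE_TO_BASE), k))[, k:1, drop = FALSE]
  do.call(paste0, g)
}

# Deterministic per-component sub-seed derived from the scenario seed.
component_seed <- function(seed, component) {
  idx <- utf8ToInt(component)
  h <- sum(idx * seq_along(idx)) %% 10007L
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h) %% 2147483647L
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
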