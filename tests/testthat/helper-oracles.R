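# Independent oracles and small fixture builders shared across tests.

# Single-chromosome CutProfile from bare vectors.
make_profile <- function(fwd, rev = fwd, chrom = "chr1", time = 0,
                         treatment = "nuclei") {
  cut_profile(setNames(list(as.integer(fwd)), chrom),
              setNames(list(as.integer(rev)), chrom),
              time = time, treatment = treatment)
}

# Direct-summation binomial upper tail P(X >= k) in log10 space,
# via log terms and log-sum-exp (independent of pbinom).
oracle_log10_binom_tail <- function(k, n, p) {
  if (k <= 0) return(0)
  if (k > n) return(-Inf)
  j <- k:n
  lt <- lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  m <- max(lt)
  (m + log(sum(exp(lt - m)))) / log(10)
}

# Vectorised variant: tail for every k = 0..n via a reverse log-sum-exp
# sweep over the individual log binomial terms.
oracle_log10_binom_tail_all <- function(n, p) {
  if (n == 0) return(0)
  j <- 0:n
  lt <- lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)
  out <- numeric(n + 1)
  acc <- -Inf
  for (k in n:0) {
    m <- max(acc, lt[k + 1])
    acc <- m + log(exp(acc - m) + exp(lt[k + 1] - m))
    out[k + 1] <- acc
  }
  out <- out / log(10)
  out[1] <- 0  # P(X >= 0) = 1 exactly
  out
}

# Per-base boolean oracle for DHS set classification on one chromosome.
oracle_dhs_sets <- function(collections, chrom_len) {
  cov <- vapply(collections, function(gr) {
    v <- logical(chrom_len)
    for (i in seq_along(gr)) {
      v[IRanges::start(gr)[i]:IRanges::end(gr)[i]] <- TRUE
    }
    v
  }, logical(chrom_len))
  times <- as.numeric(colnames(cov))
  dark <- cov[, which.min(times)]
  all5 <- rowSums(cov) == ncol(cov)
  light4 <- rowSums(cov[, -which.min(times), drop = FALSE]) == ncol(cov) - 1
  bool_to_gr <- function(v) {
    r <- rle(v)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    n_runs <- sum(r$values)
    GenomicRanges::GRanges(rep("chr1", n_runs),
                           IRanges::IRanges(s[r$values], e[r$values]))
  }
  list(hyperconserved = bool_to_gr(all5),
       light_specific = bool_to_gr(light4 & !dark))
}

# Exhaustive enumeration oracle for PWM hit p-values: scores every
# width-w sequence with the same score matrix and sums background
# probabilities of sequences scoring at least the hit score (1e-9
# tolerance absorbs float tie splitting).
oracle_pwm_pvalues <- function(pwm) {
  w <- pwm$width
  grid <- expand.grid(rep(list(0:3), w))
  scores <- numeric(nrow(grid))
  probs <- rep(1, nrow(grid))
  for (j in seq_len(w)) {
    scores <- scores + pwm$scores[grid[[j]] + 1L, j]
    probs <- probs * pwm$background[grid[[j]] + 1L]
  }
  function(s) sum(probs[scores >= s - 1e-9])
}

random_granges <- function(n, chrom_len, max_width = 400L) {
  s <- sample.int(chrom_len - max_width, n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  GenomicRanges::reduce(GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + w - 1L)))
}

# Small shared scenario bundle (lazy, built once per test run).
.small_env <- new.env(parent = emptyenv())
small_scenario_data <- function() {
  if (is.null(.small_env$data)) {
    sc <- synthetic_scenario(seed = 101, genome_length = 6e5, n_genes = 40,
                             n_footprints = 60, n_decoys = 30)
    .small_env$data <- generate_scenario_data(sc)
  }
  .small_env$data
}
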