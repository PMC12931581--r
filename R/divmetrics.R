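#' Abundance vector with singleton/doubleton bookkeeping
#'
#' Wraps a named vector of non-negative integer OTU read counts, recomputing
#' total reads `n` and the singleton and doubleton counts `f1`, `f2` (never
#' cached stale).
#'
#' @param counts Non-negative integer vector (zeros are dropped).
#' @return An object of class `abundance_vector`: list with `counts`, `n`,
#'   `f1`, `f2`.
#' @export
abundance_vector <- function(counts) {
  if (inherits(counts, "abundance_vector")) return(counts)
  counts <- counts[counts > 0]
  if (any(counts != floor(counts))) stop("counts must be integers")
  structure(list(counts = counts, n = sum(counts),
                 f1 = sum(counts == 1), f2 = sum(counts == 2)),
            class = "abundance_vector")
}

#' Good's coverage estimate of sample completeness
#'
#' `1 - f1 / n`: the estimated probability that the next read belongs to an
#' already-seen OTU.
#'
#' @param v Abundance vector (or raw counts).
#' @return Coverage in `[0, 1]`.
#' @examples
#' goods_coverage(c(A = 5, B = 3, C = 1, D = 1)) # 0.8
#' @export
goods_coverage <- function(v) {
  v <- abundance_vector(v)
  if (v$n < 1) stop("empty abundance vector")
  1 - v$f1 / v$n
}

#' Hill diversity of order 0 (richness) or 1 (effective OTU number)
#'
#' Order 0 is observed richness; order 1 is the exponential of the Shannon
#' entropy (nats), the number of equally abundant OTUs with the observed
#' diversity.
#'
#' @param v Abundance vector (or raw counts).
#' @param q Order, 0 or 1.
#' @return Diversity value.
#' @export
hill_diversity <- function(v, q = 0) {
  v <- abundance_vector(v)
  if (v$n < 1) stop("empty abundance vector")
  if (q == 0) return(length(v$counts))
  if (q == 1) {
    p <- v$counts / v$n
    return(exp(-sum(p * log(p))))
  }
  stop("unsupported Hill order q = ", q)
}

#' Full diversity summary of one abundance vector
#'
#' @param v Abundance vector (or raw counts).
#' @return List with `S_obs`, `H` (Shannon, nats), `hill1`, `coverage`.
#' @export
diversity_result <- function(v) {
  v <- abundance_vector(v)
  p <- v$counts / v$n
  H <- -sum(p * log(p))
  list(S_obs = length(v$counts), H = H, hill1 = exp(H),
       coverage = 1 - v$f1 / v$n)
}

#' Expected rarefied richness (hypergeometric closed form)
#'
#' The expected number of OTUs in a without-replacement subsample of `d`
#' reads: `sum_s [1 - C(n - n_s, d) / C(n, d)]`, evaluated in log space via
#' log-gamma so it is stable for read depths up to 1e5 and beyond.
#'
#' @param v Abundance vector (or raw counts).
#' @param d Rarefaction depth, `0 <= d <= n`.
#' @return Expected richness.
#' @examples
#' rarefy_expect(c(A = 4, B = 4, C = 2), 5) # about 2.7302
#' @export
rarefy_expect <- function(v, d) {
  v <- abundance_vector(v)
  if (d > v$n) stop("depth d exceeds total reads n")
  if (d < 0) stop("negative depth")
  d <- floor(d)
  if (d == 0) return(0)
  ns <- v$counts
  # log C(n - ns, d) - log C(n, d); term is 0 when n - ns < d
  lp <- ifelse(v$n - ns >= d,
               lchoose(v$n - ns, d) - lchoose(v$n, d),
               -Inf)
  sum(1 - exp(lp))
}

# one without-replacement subsample of d reads from integer counts,
# memory-light: draw read indices and map them onto OTU bins
subsample_counts <- function(counts, d) {
  n <- sum(counts)
  if (d >= n) return(counts)
  cuts <- cumsum(counts)
  idx <- sample.int(n, d)
  tabulate(findInterval(idx - 1L, c(0L, cuts), rightmost.closed = FALSE),
           nbins = length(counts))
}

#' Monte-Carlo rarefaction averaged over iterations
#'
#' Subsamples `d` reads without replacement per iteration and averages the
#' resulting richness, Shannon index, Hill-1 and coverage across iterations
#' (the "multiple rarefactions, averaged" estimator; 1000 iterations by
#' default). `d = n` returns the exact full-vector summary regardless of
#' `iterations`.
#'
#' @param v Abundance vector (or raw counts).
#' @param d Depth (fractional depths are floored).
#' @param iterations Number of subsamples to average (>= 1).
#' @param seed Integer seed; means are deterministic given the seed.
#' @return List with means `S_obs`, `H`, `hill1`, `coverage`, plus
#'   `S_obs_sd` (between-iteration sd), `depth`, `iterations`.
#' @export
rarefy_mc <- function(v, d, iterations = 1000, seed = NULL) {
  v <- abundance_vector(v)
  d <- floor(d)
  if (d > v$n) stop("depth d exceeds total reads n")
  stopifnot(iterations >= 1)
  if (d == v$n) {
    r <- diversity_result(v)
    return(c(r, list(S_obs_sd = 0, depth = d, iterations = iterations)))
  }
  with_seed(seed, {
    S <- H <- Cov <- numeric(iterations)
    for (i in seq_len(iterations)) {
      cc <- subsample_counts(v$counts, d)
      cc <- cc[cc > 0]
      p <- cc / d
      S[i] <- length(cc)
      H[i] <- -sum(p * log(p))
      Cov[i] <- 1 - sum(cc == 1) / d
    }
    list(S_obs = mean(S), H = mean(H), hill1 = mean(exp(H)),
         coverage = mean(Cov), S_obs_sd = stats::sd(S), depth = d,
         iterations = iterations)
  })
}

#' Chao1 asymptotic richness estimate
#'
#' Bias-corrected by default: `S_obs + f1 (f1 - 1) / (2 (f2 + 1))`, which is
#' defined for `f2 = 0` and equals `S_obs` when `f1 <= 1`. The classical
#' form `S_obs + f1^2 / (2 f2)` is available by flag (falling back to the
#' corrected form when `f2 = 0`).
#'
#' @param v Abundance vector (or raw counts).
#' @param bias_corrected Use the bias-corrected form (default TRUE).
#' @return Estimated asymptotic richness.
#' @examples
#' chao1(c(A = 1, B = 1, C = 2, D = 3)) # 4.5
#' @export
chao1 <- function(v, bias_corrected = TRUE) {
  v <- abundance_vector(v)
  if (v$n < 1) stop("empty abundance vector")
  S <- length(v$counts)
  if (!bias_corrected && v$f2 > 0) return(S + v$f1^2 / (2 * v$f2))
  S + v$f1 * (v$f1 - 1) / (2 * (v$f2 + 1))
}

#' Sample-based OTU accumulation curve
#'
#' Expected richness after `k = 1..K` samples. Exact mode uses the
#' hypergeometric identity `E[S_k] = sum_sp [1 - C(K - m_sp, k) / C(K, k)]`
#' where `m_sp` is the number of samples containing the OTU; permuted mode
#' averages over random sample orderings.
#'
#' @param rows Samples x OTU count matrix (or list of abundance vectors over
#'   a shared OTU set).
#' @param mode `"exact"` or `"permuted"`.
#' @param permutations Orderings to average in permuted mode.
#' @param seed Seed for permuted mode.
#' @return Numeric vector of expected richness at `k = 1..K` (non-decreasing).
#' @export
accumulation_curve <- function(rows, mode = c("exact", "permuted"),
                               permutations = 100, seed = NULL) {
  mode <- match.arg(mode)
  rows <- as.matrix(rows)
  K <- nrow(rows)
  if (K < 1) stop("empty input")
  pres <- rows > 0
  m <- colSums(pres)
  m <- m[m > 0]
  if (mode == "exact") {
    vapply(seq_len(K), function(k)
      sum(1 - exp(lchoose(K - m, k) - lchoose(K, k))), numeric(1))
  } else {
    with_seed(seed, {
      acc <- numeric(K)
      for (b in seq_len(permutations)) {
        ord <- sample.int(K)
        seen <- rep(FALSE, ncol(pres))
        for (k in seq_len(K)) {
          seen <- seen | pres[ord[k], ]
          acc[k] <- acc[k] + sum(seen)
        }
      }
      acc / permutations
    })
  }
}

#' Size-based richness extrapolation beyond the observed depth
#'
#' Expected richness at `n + m` reads:
#' `S_obs + f0 * [1 - (1 - f1 / (n f0 + f1))^m]` with
#' `f0 = chao1 - S_obs`. Equals `S_obs` at `m = 0`, is non-decreasing in `m`
#' and approaches the Chao1 asymptote.
#'
#' @param v Abundance vector (or raw counts).
#' @param m Additional reads (>= 0).
#' @return Expected richness at depth `n + m`.
#' @export
extrapolate_richness <- function(v, m) {
  if (m < 0) stop("negative m")
  v <- abundance_vector(v)
  S <- length(v$counts)
  f0 <- chao1(v) - S
  if (f0 <= 0 || v$f1 == 0) return(S)
  S + f0 * (1 - (1 - v$f1 / (v$n * f0 + v$f1))^m)
}

#' Cumulative abundance curve by OTU rank
#'
#' OTUs sorted by descending read count; the curve gives the cumulative
#' proportion of reads captured by the top-ranked OTUs, ending at exactly 1.
#'
#' @param v Abundance vector (or raw counts).
#' @return Numeric vector of cumulative read shares.
#' @export
cumulative_abundance_curve <- function(v) {
  v <- abundance_vector(v)
  if (v$n < 1) stop("empty abundance vector")
  cs <- cumsum(sort(v$counts, decreasing = TRUE)) / v$n
  cs[length(cs)] <- 1
  unname(cs)
}
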