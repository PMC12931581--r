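#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` on non-negative count (or
#' abundance) rows. A pair of all-zero rows has no defined dissimilarity;
#' such cells are set to `NA` with a warning.
#'
#' @param rows Samples x OTU matrix with >= 2 rows.
#' @return A `dist`-like symmetric matrix with zero diagonal, labelled by
#'   row names, attribute `metric = "bray"`.
#' @examples
#' bray_curtis(rbind(a = c(1, 1), b = c(1, 3)))["a", "b"] # 1/3
#' @export
bray_curtis <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2) stop("need at least two rows")
  if (any(rows < 0)) stop("negative counts")
  n <- nrow(rows)
  D <- matrix(0, n, n, dimnames = list(rownames(rows), rownames(rows)))
  for (i in seq_len(n - 1)) {
    xi <- rows[i, ]
    for (j in (i + 1):n) {
      tot <- sum(xi + rows[j, ])
      D[i, j] <- D[j, i] <-
        if (tot == 0) NA_real_ else sum(abs(xi - rows[j, ])) / tot
    }
  }
  if (anyNA(D)) warning("pair(s) of all-zero rows: dissimilarity undefined")
  attr(D, "metric") <- "bray"
  D
}

# sum of squared distances partition of Anderson's PERMANOVA for a given
# integer group coding; D2 is the squared distance matrix
permanova_ss <- function(D2, g) {
  N <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  c(total = ss_total, within = ss_within)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Anderson's distance-based pseudo-F:
#' `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`,
#' `R^2 = SS_between / SS_total`. The p-value permutes group labels
#' (restricted within `strata` when given) with the `(b + 1) / (m + 1)`
#' convention, `b` = permuted statistics >= observed. Permutations are drawn
#' on indices after sorting samples by label, so the p-value is invariant to
#' input row order given the same seed.
#'
#' @param D Symmetric distance matrix (e.g. from [bray_curtis()]).
#' @param groups Factor of group labels, one per sample.
#' @param strata Optional factor restricting permutations within its levels.
#' @param n_permutations Number of label permutations (default 999); if it
#'   meets or exceeds the number of distinct relabellings for small designs,
#'   all distinct permutations are enumerated instead (exact test).
#' @param seed Integer seed.
#' @return List with `pseudo_F`, `R2`, `p`, `n_permutations`, `df`
#'   (c(between, within)), `exact` (logical).
#' @export
permanova <- function(D, groups, strata = NULL, n_permutations = 999,
                      seed = NULL) {
  D <- as.matrix(D)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  N <- nrow(D)
  stopifnot(length(groups) == N)
  # canonical order so permutations do not depend on row order
  ord <- order(as.integer(groups),
               if (is.null(strata)) rep(0L, N)
               else as.integer(as.factor(strata)),
               rownames(D) %||% as.character(seq_len(N)))
  D <- D[ord, ord]
  groups <- groups[ord]
  if (!is.null(strata)) strata <- as.factor(strata)[ord]
  D2 <- D^2
  a <- nlevels(droplevels(groups))
  g <- as.integer(groups)
  ss <- permanova_ss(D2, g)
  ss_between <- ss["total"] - ss["within"]
  df1 <- a - 1; df2 <- N - a
  Fobs <- if (ss["within"] <= 0) Inf
          else (ss_between / df1) / (ss["within"] / df2)
  R2 <- unname(ss_between / ss["total"])

  # distinct relabellings: enumerate when feasible and requested budget covers
  perms <- NULL
  exact <- FALSE
  if (is.null(strata) && N <= 8) {
    all_p <- all_permutations(N)
    if (nrow(all_p) - 1 <= n_permutations) {
      perms <- all_p[-1, , drop = FALSE] # drop identity
      exact <- TRUE
    }
  }
  stat_perm <- with_seed(seed, {
    m <- if (exact) nrow(perms) else n_permutations
    out <- numeric(m)
    for (b in seq_len(m)) {
      idx <- if (exact) perms[b, ] else permute_labels(N, strata)
      ssb <- permanova_ss(D2, g[idx])
      wb <- ssb["within"]
      out[b] <- if (wb <= 0) Inf
                else ((ssb["total"] - wb) / df1) / (wb / df2)
    }
    out
  })
  p <- (sum(stat_perm >= Fobs - 1e-12) + 1) / (length(stat_perm) + 1)
  list(pseudo_F = unname(Fobs), R2 = R2, p = p,
       n_permutations = length(stat_perm), df = c(df1, df2), exact = exact)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all N! permutations of 1..N as rows (N small): insert N at every
# position of each permutation of 1..N-1
all_permutations <- function(N) {
  if (N == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(N - 1L)
  out <- matrix(0L, N * nrow(sub), N)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(N)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], N, after = pos - 1L)
    }
  }
  out
}

# one random permutation of 1..N, restricted within strata levels
permute_labels <- function(N, strata = NULL) {
  if (is.null(strata)) return(sample.int(N))
  idx <- seq_len(N)
  for (lev in levels(strata)) {
    at <- which(strata == lev)
    idx[at] <- at[sample.int(length(at))]
  }
  idx
}

#' Homogeneity of multivariate dispersion
#'
#' Embeds the distance matrix by principal coordinates analysis, keeping
#' negative-eigenvalue axes on an imaginary subspace, and measures each
#' sample's generalised distance to its group centre (squared real-part
#' distance minus squared imaginary-part distance, floored at zero before
#' the square root). Group centres are spatial medians by default (centroid
#' optional). Homogeneity is tested by the one-way ANOVA F on the
#' distances-to-centre with a label-permutation p-value.
#'
#' @param D Symmetric distance matrix.
#' @param groups Factor of group labels.
#' @param n_permutations Label permutations (default 999).
#' @param seed Integer seed.
#' @param type `"median"` (spatial median, default) or `"centroid"`.
#' @return List with `distances` (per sample), `group_dispersion` (mean
#'   distance per group), `F`, `p`. Groups of size 1 contribute dispersion 0
#'   and are flagged in `singleton_groups`.
#' @export
dispersion_homogeneity <- function(D, groups, n_permutations = 999,
                                   seed = NULL, type = c("median",
                                                         "centroid")) {
  type <- match.arg(type)
  D <- as.matrix(D)
  groups <- droplevels(as.factor(groups))
  N <- nrow(D)
  stopifnot(length(groups) == N)
  # PCoA: double-centred Gower matrix
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-9
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]
  axes <- sweep(vecs, 2, sqrt(abs(vals)), `*`)
  pos <- vals > 0

  dist_to <- function(centre) {
    d2 <- colSums((t(axes[, pos, drop = FALSE]) - centre[pos])^2) -
      colSums((t(axes[, !pos, drop = FALSE]) - centre[!pos])^2)
    sqrt(pmax(d2, 0))
  }
  centres <- lapply(levels(groups), function(lev) {
    rows <- axes[groups == lev, , drop = FALSE]
    if (nrow(rows) == 1L) return(rows[1, ])
    if (type == "centroid") return(colMeans(rows))
    # spatial median on the real axes; imaginary coordinates stay at the
    # group centroid (optimising them too is degenerate: the generalised
    # distance can be driven to zero along imaginary directions)
    cen <- colMeans(rows)
    imag_d2 <- colSums((t(rows[, !pos, drop = FALSE]) - cen[!pos])^2)
    obj <- function(re) {
      d2 <- colSums((t(rows[, pos, drop = FALSE]) - re)^2) - imag_d2
      sum(sqrt(pmax(d2, 0)))
    }
    fit <- stats::optim(cen[pos], obj, method = "BFGS",
                        control = list(maxit = 200))
    cen[pos] <- fit$par
    cen
  })
  names(centres) <- levels(groups)
  distances <- numeric(N)
  for (lev in levels(groups))
    distances[groups == lev] <-
      dist_to(centres[[lev]])[groups == lev]

  sizes <- table(groups)
  singleton <- names(sizes)[sizes == 1]
  Fstat <- function(d, g) {
    gm <- tapply(d, g, mean)
    ssb <- sum(table(g) * (gm - mean(d))^2)
    ssw <- sum((d - gm[g])^2)
    df1 <- nlevels(g) - 1; df2 <- length(d) - nlevels(g)
    if (ssw <= 0) Inf else (ssb / df1) / (ssw / df2)
  }
  Fobs <- Fstat(distances, groups)
  perm <- with_seed(seed, vapply(seq_len(n_permutations), function(b)
    Fstat(distances[sample.int(N)], groups), numeric(1)))
  p <- (sum(perm >= Fobs - 1e-12) + 1) / (n_permutations + 1)
  list(distances = stats::setNames(distances, rownames(D)),
       group_dispersion = tapply(distances, groups, mean),
       F = Fobs, p = p, singleton_groups = singleton)
}

#' Mantel correlogram of community distance against geographic distance
#'
#' For each geographic distance class `[lo, hi)`, computes the Mantel
#' correlation between the community distance matrix and the class
#' membership indicator over sample pairs, sign-flipped so that positive
#' values mean samples in that class are more similar than average (the
#' usual reading of positive spatial autocorrelation at short range).
#' P-values permute sample identities and are Holm-corrected across classes.
#'
#' @param D_community Symmetric community distance matrix.
#' @param coordinates Two-column matrix/data.frame of sample x, y (m).
#' @param distance_classes Breaks (m) defining half-open classes.
#' @param n_permutations Permutations per class (default 199).
#' @param seed Integer seed.
#' @return data.frame with class bounds, n pairs, Mantel `r`, raw `p`,
#'   Holm-adjusted `p_adj`; empty classes are skipped.
#' @export
mantel_correlogram <- function(D_community, coordinates,
                               distance_classes, n_permutations = 199,
                               seed = NULL) {
  D <- as.matrix(D_community)
  xy <- as.matrix(coordinates)
  N <- nrow(D)
  stopifnot(nrow(xy) == N, length(distance_classes) >= 3)
  geo <- as.matrix(stats::dist(xy))
  lt <- lower.tri(D)
  dc <- D[lt]
  res <- list()
  perm_idx <- with_seed(seed, replicate(n_permutations, sample.int(N),
                                        simplify = FALSE))
  for (k in seq_len(length(distance_classes) - 1)) {
    lo <- distance_classes[k]; hi <- distance_classes[k + 1]
    Ik <- (geo >= lo & geo < hi) * 1
    n_pairs <- sum(Ik[lt])
    if (n_pairs == 0 || n_pairs == sum(lt)) next # empty/degenerate class
    r_obs <- -stats::cor(dc, Ik[lt])
    r_perm <- vapply(perm_idx, function(idx)
      -stats::cor(D[idx, idx][lt], Ik[lt]), numeric(1))
    # one-sided toward the observed sign, as customary for correlograms
    p <- if (r_obs >= 0) (sum(r_perm >= r_obs - 1e-12) + 1) /
           (n_permutations + 1)
         else (sum(r_perm <= r_obs + 1e-12) + 1) / (n_permutations + 1)
    res[[length(res) + 1]] <- data.frame(class_lo = lo, class_hi = hi,
                                         n_pairs = n_pairs, r = r_obs, p = p)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no non-empty distance classes")
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}
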