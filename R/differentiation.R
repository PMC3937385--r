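#' Symmetric pairwise-population matrix
#'
#' Container for pairwise differentiation results: an ordered population list,
#' a symmetric value matrix with an undefined diagonal, and optional matrices
#' of p-values and bootstrap confidence bounds.
#'
#' @param populations ordered character labels.
#' @param values symmetric numeric matrix (diagonal `NA`).
#' @param p_values,ci_low,ci_high optional symmetric matrices.
#' @return an object of class `msat_pairwise`.
#' @export
pairwise_matrix <- function(populations, values, p_values = NULL,
                            ci_low = NULL, ci_high = NULL) {
  k <- length(populations)
  chk <- function(m, what) {
    if (is.null(m)) return(NULL)
    if (!all(dim(m) == c(k, k))) stop(what, " dimensions must match populations")
    od <- row(m) != col(m) & !is.na(m) & !is.na(t(m))
    if (any(abs(m[od] - t(m)[od]) > 0)) stop(what, " must be symmetric")
    dimnames(m) <- list(populations, populations)
    m
  }
  structure(list(populations = populations,
                 values = chk(values, "values"),
                 p_values = chk(p_values, "p_values"),
                 ci_low = chk(ci_low, "ci_low"),
                 ci_high = chk(ci_high, "ci_high")),
            class = "msat_pairwise")
}

#' @export
print.msat_pairwise <- function(x, ...) {
  cat(sprintf("msat_pairwise: %d populations\n", length(x$populations)))
  print(round(x$values, 4))
  invisible(x)
}

# Weir-Cockerham variance components (a, b, c) for one locus across a set of
# populations, summed over alleles. `glist` = list per population of 2-column
# matrices of diploid genotypes. Populations with no typed diploids at the
# locus are dropped; returns zeros when fewer than two remain or nbar <= 1.
wc_components_locus <- function(glist) {
  glist <- glist[vapply(glist, nrow, 0L) > 0]
  r <- length(glist)
  zero <- c(a = 0, b = 0, c = 0)
  if (r < 2) return(zero)
  ni <- vapply(glist, nrow, 0L)
  nbar <- mean(ni)
  if (nbar <= 1) return(zero)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(zero)
  alleles <- unique(unlist(glist))
  a <- b <- cc <- 0
  for (A in alleles) {
    pi <- vapply(glist, function(g) mean(g == A), 0)
    hi <- vapply(glist, function(g) mean((g[, 1] == A) != (g[, 2] == A)), 0)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- a + (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- b + (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = a, b = b, c = cc)
}

# diploid genotype matrix (2 columns) for one population at one locus;
# Z-linked loci contribute male genotypes only
genotypes_cell <- function(d, l, rows) {
  dr <- diploid_rows(d, l, rows)
  cbind(d$a1[dr, l], d$a2[dr, l])
}

# multi-locus theta for a set of row-index vectors (one per population)
theta_multilocus <- function(d, rowsets, loci = seq_len(nrow(d$loci))) {
  A <- D <- 0
  for (l in loci) {
    comp <- wc_components_locus(lapply(rowsets, function(r) genotypes_cell(d, l, r)))
    A <- A + comp["a"]; D <- D + sum(comp)
  }
  if (D == 0) return(NA_real_)
  unname(A / D)
}

#' Pairwise F_ST (Weir-Cockerham theta)
#'
#' Multi-locus theta for every population pair: the ratio of summed
#' among-population variance components to summed total components
#' (`sum a / sum (a+b+c)`) over loci and alleles, using the Weir & Cockerham
#' (1984) estimator. Loci monomorphic across a pair contribute nothing. At
#' Z-linked loci only male diploid genotypes enter (hemizygous females carry
#' no within-individual component). Small negative estimates are admissible.
#'
#' @param dataset an `msat_dataset` with at least two populations.
#' @return an `msat_pairwise`; pairs sharing no typed locus are `NA` and
#'   listed in the `"undefined"` attribute of `values`.
#' @export
pairwise_fst <- function(dataset) {
  d <- dataset
  pops <- populations(d)
  if (length(pops) < 2) stop("need at least two populations")
  k <- length(pops)
  v <- matrix(NA_real_, k, k)
  undef <- character(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    th <- theta_multilocus(d, list(pop_rows(d, pops[i]), pop_rows(d, pops[j])))
    if (is.na(th)) undef <- c(undef, paste(pops[i], pops[j], sep = ":"))
    v[i, j] <- v[j, i] <- th
  }
  m <- pairwise_matrix(pops, v)
  attr(m$values, "undefined") <- undef
  m
}

#' Permutation test of pairwise F_ST
#'
#' For each pair, whole multi-locus genotypes (individuals) are permuted
#' between the two populations -- not alleles, so no Hardy-Weinberg assumption
#' is made -- and `p = (1 + #{theta_perm >= theta_obs}) / (permutations + 1)`.
#'
#' @param dataset an `msat_dataset`.
#' @param permutations permutations per pair (default 10000).
#' @param alpha nominal significance level (default 0.001).
#' @param seed RNG seed.
#' @return an `msat_pairwise` with `values` = observed theta, `p_values`, and
#'   a logical `"significant"` attribute on `p_values` at `alpha`.
#' @export
fst_significance <- function(dataset, permutations = 10000, alpha = 0.001,
                             seed = 1) {
  stopifnot(permutations >= 1)
  d <- dataset
  pops <- populations(d)
  k <- length(pops)
  v <- pm <- matrix(NA_real_, k, k)
  set.seed(seed)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r1 <- pop_rows(d, pops[i]); r2 <- pop_rows(d, pops[j])
    obs <- theta_multilocus(d, list(r1, r2))
    v[i, j] <- v[j, i] <- obs
    if (is.na(obs)) next
    all_rows <- c(r1, r2); n1 <- length(r1)
    hits <- 0L
    for (b in seq_len(permutations)) {
      s <- sample(all_rows)
      th <- theta_multilocus(d, list(s[1:n1], s[-(1:n1)]))
      if (!is.na(th) && th >= obs) hits <- hits + 1L
    }
    pm[i, j] <- pm[j, i] <- (1 + hits) / (permutations + 1)
  }
  m <- pairwise_matrix(pops, v, p_values = pm)
  attr(m$p_values, "significant") <- !is.na(pm) & pm <= alpha
  m
}

# Nei-Chesser bias-corrected Jost's D for one locus between two populations
# given copy vectors; returns NA when the locus carries no information
dest_locus <- function(cp1, cp2) {
  n1 <- length(cp1) / 2; n2 <- length(cp2) / 2  # diploid-equivalent sizes
  if (n1 <= 0.5 || n2 <= 0.5) return(NA_real_)
  alleles <- unique(c(cp1, cp2))
  if (length(alleles) < 2) return(NA_real_)  # monomorphic across the pair
  p1 <- vapply(alleles, function(A) mean(cp1 == A), 0)
  p2 <- vapply(alleles, function(A) mean(cp2 == A), 0)
  s <- 2
  ntilde <- s / (1 / n1 + 1 / n2)
  hs <- 1 - mean(c(sum(p1^2), sum(p2^2)))
  ht <- 1 - sum(((p1 + p2) / 2)^2)
  Hs <- (2 * ntilde / (2 * ntilde - 1)) * hs
  Ht <- ht + Hs / (2 * ntilde * s)
  if (1 - Hs <= 0) return(NA_real_)  # H_S = 1: estimator undefined, skip
  (Ht - Hs) / (1 - Hs) * s / (s - 1)
}

# harmonic mean across loci. The default is the variance-corrected
# approximation HM ~ 1/(1/A + V/A^3) (A = arithmetic mean, V = variance),
# which stays defined when some per-locus estimates are <= 0 -- the near-zero
# and negative values that drift-heavy pairs routinely produce would otherwise
# dominate a plain harmonic mean. "epsilon" is the plain harmonic mean with
# non-positive values replaced by eps.
harmonic_mean_loci <- function(x, method = c("chao", "epsilon"), eps = 1e-4) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  if (method == "epsilon") {
    x[x <= 0] <- eps
    return(length(x) / sum(1 / x))
  }
  A <- mean(x)
  if (length(x) == 1) return(A)
  V <- stats::var(x)
  if (A == 0) return(0)
  1 / (1 / A + V / A^3)
}

#' Pairwise Jost's D_est with bootstrap confidence intervals
#'
#' Per locus, the Nei-Chesser bias-corrected estimator
#' `D = (Ht - Hs)/(1 - Hs) * s/(s - 1)` with `s = 2` subpopulations. Across
#' loci the harmonic mean is taken; by default the variance-corrected
#' approximation `1/(1/A + V/A^3)` is used, which remains defined when some
#' per-locus estimates are zero or negative (`method = "epsilon"` gives the
#' plain harmonic mean with non-positive values replaced by `eps`; pairs with
#' such values are flagged either way). Confidence intervals are percentile
#' intervals over bootstrap resamples of individuals with replacement within
#' each population.
#'
#' @param dataset an `msat_dataset`.
#' @param bootstrap number of bootstrap replicates (default 1000; 0 disables).
#' @param seed RNG seed.
#' @param method `"chao"` (variance-corrected, default) or `"epsilon"`.
#' @param eps replacement value for non-positive per-locus estimates under
#'   `method = "epsilon"`.
#' @return an `msat_pairwise` with `values`, `ci_low`, `ci_high`; pairs where
#'   any per-locus value was non-positive are listed in the `"clamped"`
#'   attribute of `values`.
#' @export
pairwise_dest <- function(dataset, bootstrap = 1000, seed = 1,
                          method = c("chao", "epsilon"), eps = 1e-4) {
  method <- match.arg(method)
  d <- dataset
  pops <- populations(d)
  if (length(pops) < 2) stop("need at least two populations")
  k <- length(pops)
  L <- nrow(d$loci)
  v <- lo <- hi <- matrix(NA_real_, k, k)
  clamped <- character(0)
  set.seed(seed)
  dest_pair <- function(r1, r2) {
    dl <- vapply(seq_len(L), function(l)
      dest_locus(gene_copies(d, l, r1), gene_copies(d, l, r2)), 0)
    dl
  }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r1 <- pop_rows(d, pops[i]); r2 <- pop_rows(d, pops[j])
    dl <- dest_pair(r1, r2)
    if (any(!is.na(dl) & dl <= 0))
      clamped <- c(clamped, paste(pops[i], pops[j], sep = ":"))
    v[i, j] <- v[j, i] <- harmonic_mean_loci(dl, method, eps)
    if (bootstrap > 0) {
      bs <- numeric(bootstrap)
      for (b in seq_len(bootstrap)) {
        b1 <- sample(r1, replace = TRUE); b2 <- sample(r2, replace = TRUE)
        bs[b] <- harmonic_mean_loci(dest_pair(b1, b2), method, eps)
      }
      q <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo[i, j] <- lo[j, i] <- q[1]
      hi[i, j] <- hi[j, i] <- q[2]
    }
  }
  m <- pairwise_matrix(pops, v, ci_low = if (bootstrap > 0) lo else NULL,
                       ci_high = if (bootstrap > 0) hi else NULL)
  attr(m$values, "clamped") <- clamped
  m
}

#' Pearson correlation between two pairwise matrices
#'
#' Correlation over the `n(n-1)/2` lower-triangle off-diagonal entries of two
#' matrices sharing the same population labels and order (e.g. F_ST vs
#' D_est across the same pairs).
#'
#' @param m1,m2 `msat_pairwise` objects.
#' @return Pearson's r.
#' @export
matrix_correlation <- function(m1, m2) {
  if (!identical(m1$populations, m2$populations))
    stop("matrices must share population labels and order")
  lt <- lower.tri(m1$values)
  x <- m1$values[lt]; y <- m2$values[lt]
  if (anyNA(x) || anyNA(y)) {
    cells <- which(lt & (is.na(m1$values) | is.na(m2$values)), arr.ind = TRUE)
    stop("undefined cells: ",
         paste(m1$populations[cells[, 1]], m1$populations[cells[, 2]],
               sep = ":", collapse = ", "))
  }
  stats::cor(x, y)
}
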