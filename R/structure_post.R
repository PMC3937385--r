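#' Evanno's delta-K from clustering log-likelihoods
#'
#' Given replicate-run log probabilities of the data for a contiguous range
#' of cluster numbers K, computes
#' `deltaK(K) = |mean lnP(K+1) - 2 mean lnP(K) + mean lnP(K-1)| / sd(lnP(K))`
#' for interior K (endpoints are undefined by construction); `sd` uses the
#' n-1 denominator. The K with the largest delta-K is the usual choice of
#' cluster number.
#'
#' @param table data.frame with columns `K`, `run`, `lnP` (>= 2 runs per
#'   interior K; K values contiguous).
#' @return named numeric vector of delta-K values for interior K; `NA` (with
#'   a warning) where the within-K sd is zero.
#' @export
delta_k <- function(table) {
  if (!all(c("K", "run", "lnP") %in% names(table)))
    stop("table must have columns K, run, lnP")
  ks <- sort(unique(table$K))
  if (length(ks) < 3) stop("need at least three K values")
  if (!all(diff(ks) == 1)) stop("K values must be contiguous")
  m <- vapply(ks, function(k) mean(table$lnP[table$K == k]), 0)
  s <- vapply(ks, function(k) stats::sd(table$lnP[table$K == k]), 0)
  nruns <- vapply(ks, function(k) sum(table$K == k), 0L)
  interior <- 2:(length(ks) - 1)
  if (any(nruns[interior] < 2))
    stop("interior K values need at least 2 runs: K = ",
         paste(ks[interior][nruns[interior] < 2], collapse = ", "))
  dk <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1]) / s[interior]
  names(dk) <- ks[interior]
  if (any(!is.finite(dk))) {
    warning("delta-K undefined (sd = 0) at K = ",
            paste(names(dk)[!is.finite(dk)], collapse = ", "))
    dk[!is.finite(dk)] <- NA_real_
  }
  dk
}

# all permutations of 1..k as a matrix (k! rows)
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- setdiff(seq_len(k), i)
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Align cluster labels across clustering runs
#'
#' Cluster labels are arbitrary per run; for each run after the first, the
#' column permutation maximizing the summed per-individual dot product with
#' the first run's membership matrix is found by exhaustive search over the
#' K! permutations and applied. Row proportions are untouched.
#'
#' @param runs list of individuals x K membership matrices sharing K and
#'   individual order (rows summing to 1; K <= 8).
#' @return list of matrices with columns permuted into the first run's frame.
#' @export
align_runs <- function(runs) {
  if (!length(runs)) return(runs)
  K <- ncol(runs[[1]])
  if (K > 8)
    stop("K > 8: exhaustive alignment over K! permutations is impractical; ",
         "use a greedy matcher")
  for (r in runs) {
    if (ncol(r) != K || nrow(r) != nrow(runs[[1]]))
      stop("all runs must share K and individual order")
    if (any(abs(rowSums(r) - 1) > 1e-6))
      stop("membership rows must sum to 1")
  }
  ref <- runs[[1]]
  perms <- all_permutations(K)
  out <- vector("list", length(runs))
  out[[1]] <- ref
  for (i in seq_along(runs)[-1]) {
    r <- runs[[i]]
    score <- apply(perms, 1, function(pp) sum(r[, pp] * ref))
    out[[i]] <- r[, perms[which.max(score), ], drop = FALSE]
  }
  out
}
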