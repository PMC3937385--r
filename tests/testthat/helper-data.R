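# Fixture builders used across the test files. Everything is generated in
# code from fixed seeds; no data files.

# dataset from a list of per-population genotype matrices (2 columns = the
# two alleles; NA rows = missing); all loci autosomal unless stated
quick_dataset <- function(pop_genos, n_loci = NULL, loci = NULL) {
  pops <- names(pop_genos)
  rows <- list(); ids <- character(0); popv <- character(0)
  for (p in pops) {
    g <- pop_genos[[p]]
    ids <- c(ids, sprintf("%s_%d", p, seq_len(nrow(g[[1]]))))
    popv <- c(popv, rep(p, nrow(g[[1]])))
  }
  L <- length(pop_genos[[1]])
  if (is.null(loci))
    loci <- data.frame(name = paste0("L", seq_len(L)), inheritance = "autosomal")
  a1 <- do.call(rbind, lapply(pops, function(p)
    sapply(pop_genos[[p]], function(g) g[, 1])))
  a2 <- do.call(rbind, lapply(pops, function(p)
    sapply(pop_genos[[p]], function(g) g[, 2])))
  a1 <- matrix(as.integer(a1), length(ids), L)
  a2 <- matrix(as.integer(a2), length(ids), L)
  msat_dataset(loci,
               data.frame(id = ids, population = popv, sex = "male",
                          stringsAsFactors = FALSE),
               a1, a2)
}

# random small multi-population dataset (all diploid, autosomal)
random_dataset <- function(n_pops = 2, n_ind = 6, n_loci = 3, n_alleles = 4,
                          seed = 1) {
  set.seed(seed)
  pops <- LETTERS[seq_len(n_pops)]
  gl <- lapply(pops, function(p) {
    lapply(seq_len(n_loci), function(l) {
      fr <- rgamma(n_alleles, 1); fr <- fr / sum(fr)
      matrix(sample(100 + seq_len(n_alleles), 2 * n_ind, TRUE, fr),
             n_ind, 2)
    })
  })
  names(gl) <- pops
  quick_dataset(gl)
}

# panmictic Hardy-Weinberg sample: genotypes drawn allele-by-allele
hwe_dataset <- function(freqs, n, n_loci = 5, seed = 1) {
  set.seed(seed)
  alleles <- 100 + seq_along(freqs)
  gl <- list(P = lapply(seq_len(n_loci), function(l)
    matrix(sample(alleles, 2 * n, TRUE, freqs), n, 2)))
  quick_dataset(gl)
}

# island-model sample: population allele frequencies drawn around a common
# ancestral frequency with drift parameter F = 1/(1 + 4Nm) (Dirichlet via
# gamma draws), then HWE genotypes within populations
island_dataset <- function(F, n_pops = 2, n_ind = 20, n_loci = 10,
                           n_alleles = 5, seed = 1) {
  set.seed(seed)
  alleles <- 100 + seq_len(n_alleles)
  anc <- rep(1 / n_alleles, n_alleles)
  conc <- anc * (1 - F) / F
  gl <- lapply(seq_len(n_pops), function(p) {
    lapply(seq_len(n_loci), function(l) {
      fr <- rgamma(n_alleles, conc); fr <- fr / sum(fr)
      matrix(sample(alleles, 2 * n_ind, TRUE, fr), n_ind, 2)
    })
  })
  names(gl) <- LETTERS[seq_len(n_pops)]
  quick_dataset(gl)
}

# Literal transcription of the Weir & Cockerham (1984) variance components,
# written as plain sums over populations and alleles: the brute-force oracle
# for theta, independent of the package implementation.
oracle_theta <- function(d) {
  pops <- unique(d$individuals$population)
  A_sum <- ABC_sum <- 0
  for (l in seq_len(nrow(d$loci))) {
    glist <- list()
    for (p in pops) {
      rows <- which(d$individuals$population == p &
                      !is.na(d$a1[, l]) & !is.na(d$a2[, l]))
      glist[[p]] <- cbind(d$a1[rows, l], d$a2[rows, l])
    }
    glist <- glist[sapply(glist, nrow) > 0]
    r <- length(glist)
    if (r < 2) next
    ni <- sapply(glist, nrow)
    nbar <- sum(ni) / r
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    for (A in unique(unlist(glist))) {
      pi <- hi <- numeric(r)
      for (i in seq_len(r)) {
        g <- glist[[i]]
        pi[i] <- sum(g == A) / (2 * ni[i])
        hi[i] <- sum((g[, 1] == A & g[, 2] != A) |
                       (g[, 2] == A & g[, 1] != A)) / ni[i]
      }
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                            (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                    ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      A_sum <- A_sum + a
      ABC_sum <- ABC_sum + a + b + cc
    }
  }
  A_sum / ABC_sum
}

# Literal transcription of the Nei-Chesser estimators and Jost's D for one
# locus between two populations, from allele-frequency and size inputs: the
# hand-formula oracle for D_est.
oracle_dest_locus <- function(counts1, counts2) {
  n1 <- sum(counts1) / 2; n2 <- sum(counts2) / 2
  p1 <- counts1 / sum(counts1); p2 <- counts2 / sum(counts2)
  s <- 2
  ntilde <- s / (1 / n1 + 1 / n2)
  hs <- 1 - (sum(p1^2) + sum(p2^2)) / 2
  ht <- 1 - sum(((p1 + p2) / 2)^2)
  Hs <- (2 * ntilde / (2 * ntilde - 1)) * hs
  Ht <- ht + Hs / (2 * ntilde * s)
  (Ht - Hs) / (1 - Hs) * s / (s - 1)
}

# shared small locus panel for simulation tests
sim_loci <- function(n, z = 0) {
  data.frame(name = paste0("L", seq_len(n)),
             inheritance = c(rep("z_linked", z), rep("autosomal", n - z)))
}
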