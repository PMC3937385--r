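#' Per-population diversity statistics
#'
#' Computes, for each population, the descriptive statistics customarily
#' reported for microsatellite surveys: sample size, mean number of alleles
#' per locus, number of monomorphic loci, number of private alleles (alleles
#' observed in that population and no other, summed over loci), allelic
#' richness by rarefaction, observed heterozygosity (Ho), Nei's unbiased
#' expected heterozygosity (He), and Weir & Cockerham's F_IS.
#'
#' Z-linked loci are handled as follows: allele frequencies, He and richness
#' use all typed gene copies (hemizygous females contribute one copy); Ho,
#' F_IS and the Hardy-Weinberg test use male diploid genotypes only, since a
#' hemizygote carries no information about departures from random mating.
#'
#' @param dataset an `msat_dataset`.
#' @param rarefaction_g gene-copy count for rarefaction, or `"auto"` (the
#'   minimum typed copy count over all population-by-locus cells with data).
#' @param hwe_permutations if > 0, run [hwe_test()] with this many
#'   permutations and report, per population, the smallest per-locus p-value
#'   (unadjusted) in column `hwe_p`.
#' @param seed RNG seed for the permutation test.
#' @return a data.frame with one row per population (input order) and columns
#'   `population`, `sample_size`, `mean_alleles`, `monomorphic_loci`,
#'   `private_alleles`, `allelic_richness`, `Ho`, `He`, `Fis`, `hwe_p`.
#' @export
population_diversity <- function(dataset, rarefaction_g = "auto",
                                 hwe_permutations = 0, seed = 1) {
  d <- dataset
  pops <- populations(d)
  L <- nrow(d$loci)

  # allele presence per (pop, locus) for private-allele counts
  seen <- vector("list", length(pops))
  names(seen) <- pops
  for (p in pops) {
    rows <- pop_rows(d, p)
    seen[[p]] <- lapply(seq_len(L), function(l) unique(gene_copies(d, l, rows)))
  }

  rich <- allelic_richness(d, rarefaction_g)
  hwe <- if (hwe_permutations > 0)
    hwe_test(d, permutations = hwe_permutations, seed = seed) else NULL

  out <- lapply(pops, function(p) {
    rows <- pop_rows(d, p)
    nall <- ho <- he <- rep(NA_real_, L)
    mono <- 0L
    for (l in seq_len(L)) {
      cp <- gene_copies(d, l, rows)
      if (length(cp) == 0) next  # locus untyped in this population: skipped
      tab <- table(cp)
      nall[l] <- length(tab)
      if (length(tab) == 1) mono <- mono + 1L
      C <- length(cp)
      he[l] <- if (C > 1) (C / (C - 1)) * (1 - sum((tab / C)^2)) else 0
      dr <- diploid_rows(d, l, rows)
      if (length(dr)) {
        ho[l] <- mean(d$a1[dr, l] != d$a2[dr, l])
      }
    }
    priv <- 0L
    for (l in seq_len(L)) {
      mine <- seen[[p]][[l]]
      others <- unique(unlist(lapply(setdiff(pops, p), function(q) seen[[q]][[l]])))
      priv <- priv + sum(!(mine %in% others))
    }
    fis <- fis_population(d, rows)
    data.frame(population = p,
               sample_size = length(rows),
               mean_alleles = mean(nall, na.rm = TRUE),
               monomorphic_loci = mono,
               private_alleles = priv,
               allelic_richness = rich$mean[p],
               Ho = mean(ho, na.rm = TRUE),
               He = mean(he, na.rm = TRUE),
               Fis = fis,
               hwe_p = if (is.null(hwe)) NA_real_ else
                 suppressWarnings(min(hwe[p, ], na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# rows (within `rows`) holding typed diploid genotypes at locus l;
# at Z-linked loci only males carry two copies, so hemizygotes never qualify
diploid_rows <- function(d, l, rows) {
  rows[!is.na(d$a1[rows, l]) & !is.na(d$a2[rows, l])]
}

# Weir & Cockerham within-population components b (among individuals) and
# c (within individuals) for one population at one locus, summed over alleles
fis_components_cell <- function(g1, g2) {
  n <- length(g1)
  if (n < 2) return(c(b = 0, c = 0))
  alleles <- unique(c(g1, g2))
  b <- cc <- 0
  for (A in alleles) {
    p <- (sum(g1 == A) + sum(g2 == A)) / (2 * n)
    h <- mean((g1 == A) != (g2 == A))
    b <- b + (n / (n - 1)) * (p * (1 - p) - h * (2 * n - 1) / (4 * n))
    cc <- cc + h / 2
  }
  c(b = b, c = cc)
}

# multi-locus F_IS = sum(b) / sum(b + c) for one population
fis_population <- function(d, rows) {
  B <- CC <- 0
  for (l in seq_len(nrow(d$loci))) {
    dr <- diploid_rows(d, l, rows)
    if (length(dr) < 2) next
    bc <- fis_components_cell(d$a1[dr, l], d$a2[dr, l])
    B <- B + bc["b"]; CC <- CC + bc["c"]
  }
  if (B + CC == 0) return(NA_real_)
  unname(B / (B + CC))
}

#' Allelic richness by rarefaction
#'
#' Expected number of distinct alleles in a standardized sample of `g` gene
#' copies drawn without replacement from each population-by-locus cell:
#' `sum_i [1 - choose(C - N_i, g) / choose(C, g)]` where `C` is the cell's
#' typed copy count and `N_i` the count of allele `i`.
#'
#' @param dataset an `msat_dataset`.
#' @param g gene-copy count, or `"auto"` for the minimum typed copy count
#'   over all cells with at least one typed copy.
#' @return a list with `per_cell` (populations x loci matrix, `NA` for
#'   untyped cells), `mean` (named per-population means across typed loci)
#'   and `g` (the copy count used).
#' @export
allelic_richness <- function(dataset, g = "auto") {
  d <- dataset
  pops <- populations(d)
  L <- nrow(d$loci)
  copies <- lapply(pops, function(p) {
    rows <- pop_rows(d, p)
    lapply(seq_len(L), function(l) gene_copies(d, l, rows))
  })
  names(copies) <- pops
  counts <- vapply(pops, function(p) vapply(copies[[p]], length, 0L), integer(L))
  if (identical(g, "auto")) {
    typed <- counts[counts > 0]
    if (!length(typed)) stop("no typed cells")
    g <- min(typed)
  }
  g <- as.integer(g)
  if (g < 1) stop("g must be >= 1")
  per_cell <- matrix(NA_real_, length(pops), L,
                     dimnames = list(pops, d$loci$name))
  for (p in pops) for (l in seq_len(L)) {
    cp <- copies[[p]][[l]]
    C <- length(cp)
    if (C == 0) next
    if (g > C)
      stop(sprintf("g = %d exceeds the %d typed copies of population '%s' at locus '%s'",
                   g, C, p, d$loci$name[l]))
    Ni <- table(cp)
    per_cell[p, l] <- sum(1 - exp(lchoose(C - Ni, g) - lchoose(C, g)))
  }
  list(per_cell = per_cell,
       mean = apply(per_cell, 1, mean, na.rm = TRUE),
       g = g)
}

#' Permutation test of Hardy-Weinberg equilibrium
#'
#' For each population-by-locus cell, the null distribution of |F_IS| is
#' built by re-pairing the cell's typed alleles into random diploid genotypes
#' (shuffling alleles among individuals within the population); the p-value is
#' `(1 + #{perm >= observed}) / (permutations + 1)`. Monomorphic cells (and
#' cells with fewer than two diploid genotypes) report p = 1 and are flagged
#' in the `"flagged"` attribute.
#'
#' @param dataset an `msat_dataset`.
#' @param permutations number of allele shuffles per cell (>= 1).
#' @param seed RNG seed; the same seed reproduces the same p-values.
#' @return populations x loci matrix of p-values with attribute `flagged`,
#'   a logical matrix marking monomorphic/undersized cells.
#' @export
hwe_test <- function(dataset, permutations = 1000, seed = 1) {
  stopifnot(permutations >= 1)
  d <- dataset
  pops <- populations(d)
  L <- nrow(d$loci)
  pmat <- matrix(NA_real_, length(pops), L,
                 dimnames = list(pops, d$loci$name))
  flag <- matrix(FALSE, length(pops), L,
                 dimnames = list(pops, d$loci$name))
  set.seed(seed)
  fis_of <- function(g1, g2) {
    bc <- fis_components_cell(g1, g2)
    if (sum(bc) == 0) NA_real_ else bc[["b"]] / sum(bc)
  }
  for (p in pops) for (l in seq_len(L)) {
    dr <- diploid_rows(d, l, pop_rows(d, p))
    if (length(dr) < 2) { pmat[p, l] <- 1; flag[p, l] <- TRUE; next }
    g1 <- d$a1[dr, l]; g2 <- d$a2[dr, l]
    obs <- fis_of(g1, g2)
    if (is.na(obs)) { pmat[p, l] <- 1; flag[p, l] <- TRUE; next }
    pool <- c(g1, g2); n <- length(dr)
    hits <- 0L
    for (k in seq_len(permutations)) {
      s <- sample(pool)
      f <- fis_of(s[1:n], s[(n + 1):(2 * n)])
      if (!is.na(f) && abs(f) >= abs(obs)) hits <- hits + 1L
    }
    pmat[p, l] <- (1 + hits) / (permutations + 1)
  }
  attr(pmat, "flagged") <- flag
  pmat
}
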