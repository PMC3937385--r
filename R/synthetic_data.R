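#' Locus panel with the study-like linkage map
#'
#' 21 microsatellite loci: three multi-locus linkage groups (LG1b, LG2 and the
#' Z chromosome with four Z-linked loci) plus loci on unique chromosomes. Map
#' positions are chosen so that after removing the two amplification-failure
#' loci (`Tgu9`, `Pca8`), thinning at 10 cM ([select_spaced_loci()]) retains
#' 14 loci.
#'
#' @return a 21-row locus definition data.frame.
#' @export
fixture_loci <- function() {
  data.frame(
    name = c("CcaTgu19", "PK12", "CcaTgu21", "Ase18",
             "Pdo5", "Mcy4", "ApCo46-ZEST", "LS2", "PK11",
             "Ase46-ZFM", "CcaTgu31", "TGZ-040", "Phtr3",
             "Cdi31-ZFM", "POCC6", "PmaTGAn42", "TG02-088", "Pca3",
             "Titgata02", "Tgu9", "Pca8"),
    inheritance = c(rep("autosomal", 9), rep("z_linked", 4),
                    rep("autosomal", 8)),
    linkage_group = c(rep("LG1b", 4), rep("LG2", 5), rep("LGZ", 4),
                      "LG4", "LG4", "LG5", "LG7", "LG7", "LG9", "LG8", "LG12"),
    map_position = c(0, 4, 15, 30,
                     0, 5, 12, 25, 30,
                     0, 14, 26, 40,
                     0, 6, 0, 0, 7, 0, 0, 0),
    motif_step = 1L,
    stringsAsFactors = FALSE)
}

# Invented drift-heavy island history behind the bundled fixtures: a large
# ancestral source, two recently-separated European mainland populations, a
# North African population, and seven island populations with small sizes and
# staggered splits, giving strong drift (fixed loci, private alleles) and
# pairwise differentiation spanning roughly 0.02-0.6.
fixture_scenario <- function() {
  pops <- c(Sweden = 3000, Spain = 3000, ElHierro = 250, LaPalma = 400,
            LaGomera = 350, Tenerife = 1500, GranCanaria = 1200,
            Fuerteventura = 500, Lanzarote = 200, NorthAfrica = 3000)
  events <- list(
    event_merge(200, "Sweden", "Spain"),
    event_merge(300, "Lanzarote", "Fuerteventura"),
    event_merge(500, "Fuerteventura", "NorthAfrica"),
    event_merge(600, "LaGomera", "Tenerife"),
    event_merge(700, "GranCanaria", "Tenerife"),
    event_merge(800, "ElHierro", "LaPalma"),
    event_merge(1000, "LaPalma", "Tenerife"),
    event_merge(1500, "Tenerife", "NorthAfrica"),
    event_merge(20000, "Spain", "NorthAfrica"),
    event_size_change(20000, "NorthAfrica", 5000))
  scenario("fixture-islands", pops, events,
           note = "synthetic drift-heavy island history (invented)")
}

#' The 14-locus linkage-thinned panel of [fixture_loci()]: the loci surviving
#' removal of the two amplification-failure loci followed by 10 cM thinning
#' (10 autosomal, 4 Z-linked). This is the panel the coalescent analyses use.
#'
#' @return a 14-row locus definition data.frame.
#' @export
fixture_abc_loci <- function() {
  keep <- c("CcaTgu19", "CcaTgu21", "Ase18", "Pdo5", "ApCo46-ZEST", "LS2",
            "Ase46-ZFM", "CcaTgu31", "TGZ-040", "Phtr3", "Cdi31-ZFM",
            "PmaTGAn42", "TG02-088", "Titgata02")
  fl <- fixture_loci()
  fl[fl$name %in% keep, , drop = FALSE]
}

#' Synthetic dataset with the study's shape
#'
#' Ten populations (two European mainland, seven Canary Islands, North
#' Africa) with sample sizes (20, 22, 13, 24, 21, 25, 22, 20, 17, 22) - 206
#' individuals in all - typed at the 21 loci of [fixture_loci()] (4
#' Z-linked). Genotypes are simulated under an invented drift-heavy island
#' scenario (the truth is returned, so parameter-recovery tests can use it),
#' then locus `Tgu9` is masked in the eight Afrocanarian populations and
#' `Pca8` in La Palma, emulating total amplification failure; after
#' [drop_failed_loci()] 19 loci remain.
#'
#' @param seed single integer seed driving all randomness.
#' @return a list with `dataset` (an `msat_dataset`) and `spec` (sample
#'   sizes, the scenario and parameter truth, the failure plan, the seed).
#' @export
paper_shape_fixture <- function(seed = 1) {
  sizes <- c(Sweden = 20L, Spain = 22L, ElHierro = 13L, LaPalma = 24L,
             LaGomera = 21L, Tenerife = 25L, GranCanaria = 22L,
             Fuerteventura = 20L, Lanzarote = 17L, NorthAfrica = 22L)
  cfg <- sample_config(names(sizes),
                       n_males = ceiling(sizes / 2),
                       n_females = floor(sizes / 2))
  sc <- fixture_scenario()
  mut <- mutation_model(2e-4)
  d <- simulate_dataset(sc, list(), cfg, fixture_loci(), mut, seed = seed)
  plan <- list(
    Tgu9 = c("ElHierro", "LaPalma", "LaGomera", "Tenerife", "GranCanaria",
             "Fuerteventura", "Lanzarote", "NorthAfrica"),
    Pca8 = "LaPalma")
  d <- inject_amplification_failure(d, plan)
  list(dataset = d,
       spec = list(sample_sizes = sizes, scenario = sc, draw = list(),
                   mutation = mut, failure_plan = plan, seed = seed))
}

#' Simulate a dataset with its ground truth attached
#'
#' Thin wrapper over [simulate_dataset()] that returns the generating
#' scenario, parameter draw and seed alongside the data, for recovery tests.
#'
#' @param scenario a valid `msat_scenario`.
#' @param draw named parameter values.
#' @param config an [sample_config()].
#' @param loci locus definition data.frame (default: [fixture_loci()]).
#' @param mut an [mutation_model()] (default SMM at 5e-4).
#' @param seed RNG seed.
#' @return a list with `dataset` and `truth` (scenario id, draw, seed).
#' @export
known_truth_dataset <- function(scenario, draw, config,
                                loci = fixture_loci(),
                                mut = mutation_model(5e-4), seed = 1) {
  d <- simulate_dataset(scenario, draw, config, loci, mut, seed = seed)
  list(dataset = d,
       truth = list(scenario = scenario$id, draw = as.list(draw), seed = seed))
}

#' Mask calls to emulate amplification failure
#'
#' Sets every call at the named loci to missing within the named populations;
#' all other cells are untouched.
#'
#' @param d an `msat_dataset`.
#' @param plan named list: locus name -> character vector of populations.
#' @return the masked `msat_dataset`.
#' @export
inject_amplification_failure <- function(d, plan) {
  for (locus in names(plan)) {
    l <- match(locus, d$loci$name)
    if (is.na(l)) stop("unknown locus '", locus, "' in failure plan")
    pops <- plan[[locus]]
    bad <- setdiff(pops, populations(d))
    if (length(bad)) stop("unknown population(s) in failure plan: ",
                          paste(bad, collapse = ", "))
    rows <- which(d$individuals$population %in% pops)
    d$a1[rows, l] <- NA_integer_
    d$a2[rows, l] <- NA_integer_
  }
  d
}
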