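#' Per-population sample configuration
#'
#' @param populations character labels (must match the scenario's).
#' @param n_males,n_females sampled males/females per population.
#' @return a data.frame of class `msat_sample_config`.
#' @export
sample_config <- function(populations, n_males, n_females) {
  stopifnot(length(n_males) == length(populations),
            length(n_females) == length(populations),
            all(n_males >= 0), all(n_females >= 0))
  if (sum(2 * n_males + n_females) < 2)
    stop("need at least 2 sampled gene copies in total")
  structure(data.frame(population = populations,
                       n_males = as.integer(n_males),
                       n_females = as.integer(n_females),
                       stringsAsFactors = FALSE),
            class = c("msat_sample_config", "data.frame"))
}

#' Microsatellite mutation model
#'
#' Stepwise mutation: each mutation moves the allele by one repeat unit
#' (`model = "smm"`) or by a geometric number of units
#' (`model = "gsm"`, step magnitude `k` with probability
#' `(1 - gsm_p) * gsm_p^(k-1)`), direction equiprobable. Allele states are
#' repeat counts and reflect at 1; an optional contiguous range of width
#' `range_width` above 0 adds an upper reflecting boundary at
#' `ancestral_state + range_width/2` and a lower one implied by positivity.
#'
#' @param mean_rate mutations per locus per generation.
#' @param model `"smm"` or `"gsm"`.
#' @param gsm_p geometric parameter in \[0,1); 0 reduces the GSM to the SMM.
#' @param ancestral_state repeat count at the root (default 20).
#' @param range_width optional allele-range width (e.g. 40); `NULL` = no
#'   upper bound.
#' @return a list of class `msat_mutation_model`.
#' @export
mutation_model <- function(mean_rate, model = c("smm", "gsm"), gsm_p = 0,
                           ancestral_state = 20L, range_width = NULL) {
  model <- match.arg(model)
  stopifnot(mean_rate > 0, gsm_p >= 0, gsm_p < 1)
  if (model == "smm") gsm_p <- 0
  structure(list(mean_rate = mean_rate, model = model, gsm_p = gsm_p,
                 ancestral_state = as.integer(ancestral_state),
                 range_width = range_width),
            class = "msat_mutation_model")
}

# upper reflecting bound for the C++ code; 0 = unbounded above
range_high_of <- function(mut) {
  if (is.null(mut$range_width)) 0L
  else as.integer(mut$ancestral_state + ceiling(mut$range_width / 2))
}

# Compile a scenario into the numeric encoding the C++ simulator takes:
# population index map, size symbols/literals, event template. `draw` is a
# one-row data.frame (or named vector) of parameter values.
resolve_scenario <- function(s, draw, config) {
  draw <- as.list(draw)
  val <- function(x) {
    if (is.numeric(x)) return(x)
    if (!is_symbol(x)) return(as.numeric(x))
    v <- draw[[x]]
    if (is.null(v)) stop("parameter '", x, "' missing from draw")
    v
  }
  pops <- names(s$populations)
  if (!identical(sort(pops), sort(config$population)))
    stop("sample config populations must match the scenario's")
  sizes <- vapply(s$populations, val, 0)
  pid <- function(p) match(p, pops) - 1L
  ev <- do.call(rbind, lapply(s$events, function(e) {
    switch(e$kind,
           merge = c(val(e$time), 0, pid(e$from), pid(e$to), 0, 0),
           admixture = c(val(e$time), 1, pid(e$target), pid(e$source1),
                         pid(e$source2), val(e$rate)),
           size_change = c(val(e$time), 2, pid(e$pop), 0, 0, val(e$new_size)))
  }))
  if (is.null(ev)) ev <- matrix(0, 0, 6)
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  nm <- config$n_males[match(pops, config$population)]
  nf <- config$n_females[match(pops, config$population)]
  list(pops = pops, sizes = unname(sizes), events = ev,
       n_males = nm, n_females = nf)
}

# tip layout at one locus: population blocks; within a block, male copies
# (2 per male, adjacent) then female copies (2 per female, or 1 at Z loci)
tip_populations <- function(rs, z) {
  unlist(lapply(seq_along(rs$pops), function(p)
    rep(p - 1L, 2L * rs$n_males[p] + (if (z) 1L else 2L) * rs$n_females[p])))
}

#' Simulate one locus genealogy under a scenario
#'
#' Continuous-time coalescent backward from the sample: within each
#' population, pairs coalesce at rate `k(k-1)/2` per `2N` generations (`N` in
#' diploids); Z-linked loci use `0.75 * 2N` (three Z copies per two diploids).
#' Merge events transfer lineage sets; admixture events reassign each lineage
#' to the first source with the event's probability. Runs to the single root.
#'
#' @param scenario a valid `msat_scenario`.
#' @param draw named parameter values (one row of [sample_parameters()], or a
#'   named list/vector).
#' @param config an [sample_config()].
#' @param locus a one-row data.frame with at least `name` and `inheritance`.
#' @param seed RNG seed.
#' @return a list of class `msat_genealogy`: `edges` (data.frame `parent`,
#'   `child`, `length`), `node_time`, `tips` (data.frame `population`, `sex`),
#'   `tmrca`.
#' @export
simulate_locus <- function(scenario, draw, config, locus, seed = 1) {
  rs <- resolve_scenario(scenario, draw, config)
  z <- locus$inheritance == "z_linked"
  tp <- tip_populations(rs, z)
  set.seed(seed)
  g <- sim_genealogy_cpp(rs$sizes, rs$events, tp, if (z) 0.75 else 1.0)
  parent <- g$parent + 1L
  has_par <- g$parent >= 0
  edges <- data.frame(parent = parent[has_par],
                      child = which(has_par),
                      length = g$node_time[parent[has_par]] -
                        g$node_time[which(has_par)])
  sexes <- unlist(lapply(seq_along(rs$pops), function(p)
    c(rep("male", 2L * rs$n_males[p]),
      rep("female", (if (z) 1L else 2L) * rs$n_females[p]))))
  structure(list(edges = edges, node_time = g$node_time,
                 tips = data.frame(population = rs$pops[tp + 1L], sex = sexes,
                                   stringsAsFactors = FALSE),
                 tmrca = max(g$node_time)),
            class = "msat_genealogy")
}

#' Simulate a full microsatellite dataset under a scenario
#'
#' Independent loci: for each locus a genealogy is simulated (see
#' [simulate_locus()]), mutations are placed as a Poisson process with the
#' model's rate on branch lengths, and tip allele states are assembled into
#' diploid (males, and females at autosomal loci) or hemizygous (females at
#' Z-linked loci) calls. Fully reproducible per seed.
#'
#' @param scenario a valid `msat_scenario`.
#' @param draw named parameter values.
#' @param config an [sample_config()].
#' @param loci data.frame of locus definitions (`name`, `inheritance`, and
#'   optionally `linkage_group`, `map_position`).
#' @param mut an [mutation_model()].
#' @param seed RNG seed.
#' @return an `msat_dataset`; individuals are labelled
#'   `<population>_M<i>` / `<population>_F<i>`.
#' @export
simulate_dataset <- function(scenario, draw, config, loci, mut, seed = 1) {
  rs <- resolve_scenario(scenario, draw, config)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  set.seed(seed)
  P <- length(rs$pops)
  n_ind <- sum(rs$n_males + rs$n_females)
  a1 <- a2 <- matrix(NA_integer_, n_ind, nrow(loci))
  ind_pop <- unlist(lapply(seq_len(P), function(p)
    rep(rs$pops[p], rs$n_males[p] + rs$n_females[p])))
  ind_sex <- unlist(lapply(seq_len(P), function(p)
    c(rep("male", rs$n_males[p]), rep("female", rs$n_females[p]))))
  ids <- unlist(lapply(seq_len(P), function(p)
    c(sprintf("%s_M%d", rs$pops[p], seq_len(rs$n_males[p]))[seq_len(rs$n_males[p])],
      sprintf("%s_F%d", rs$pops[p], seq_len(rs$n_females[p]))[seq_len(rs$n_females[p])])))
  rh <- range_high_of(mut)
  for (l in seq_len(nrow(loci))) {
    z <- loci$inheritance[l] == "z_linked"
    tp <- tip_populations(rs, z)
    st <- sim_locus_states_cpp(rs$sizes, rs$events, tp, if (z) 0.75 else 1.0,
                               mut$mean_rate, mut$gsm_p, mut$ancestral_state,
                               rh)
    # walk population blocks and assign genotypes
    off <- 0L; row <- 0L
    for (p in seq_len(P)) {
      for (m in seq_len(rs$n_males[p])) {
        row <- row + 1L
        a1[row, l] <- st[off + 1L]; a2[row, l] <- st[off + 2L]
        off <- off + 2L
      }
      for (f in seq_len(rs$n_females[p])) {
        row <- row + 1L
        if (z) {
          a1[row, l] <- st[off + 1L]; off <- off + 1L
        } else {
          a1[row, l] <- st[off + 1L]; a2[row, l] <- st[off + 2L]
          off <- off + 2L
        }
      }
    }
  }
  msat_dataset(loci,
               data.frame(id = ids, population = ind_pop, sex = ind_sex,
                          stringsAsFactors = FALSE),
               a1, a2)
}
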