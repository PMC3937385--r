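#' Uniform or log-uniform prior for a demographic parameter
#'
#' @param name parameter symbol (e.g. `"t1"`, `"NEU"`).
#' @param low,high support bounds in parameter units (generations for times,
#'   diploid individuals for sizes, a proportion for admixture rates).
#' @param distribution `"uniform"` (default) or `"log_uniform"`.
#' @param greater_than optional symbol of another parameter this one must
#'   exceed (e.g. an older split time).
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(name, low, high, distribution = c("uniform", "log_uniform"),
                       greater_than = NULL) {
  distribution <- match.arg(distribution)
  if (!(low < high)) stop("prior requires low < high")
  if (distribution == "log_uniform" && low <= 0)
    stop("log-uniform prior requires low > 0")
  structure(list(name = name, distribution = distribution,
                 low = low, high = high, greater_than = greater_than),
            class = "prior_spec")
}

#' Demographic events (backward in time, 0 = present)
#'
#' `event_merge`: at `time`, all lineages of `from` move into `to` (forward in
#' time: `from` split off from `to`). `event_admixture`: each lineage of
#' `target` moves to `source1` with probability `rate`, else to `source2`
#' (forward in time: `target` was founded as a mixture). `event_size_change`:
#' population `pop` takes size `new_size` further into the past.
#'
#' Times, rates and sizes may be numeric literals or parameter symbols priced
#' by a [prior_spec()].
#'
#' @param time generations before present (or symbol).
#' @param from,to,target,source1,source2,pop population labels.
#' @param rate admixture proportion from `source1` (or symbol).
#' @param new_size diploid size (or symbol).
#' @return an event list with a `kind` field.
#' @export
event_merge <- function(time, from, to)
  list(kind = "merge", time = time, from = from, to = to)

#' @rdname event_merge
#' @export
event_admixture <- function(time, target, source1, source2, rate)
  list(kind = "admixture", time = time, target = target,
       source1 = source1, source2 = source2, rate = rate)

#' @rdname event_merge
#' @export
event_size_change <- function(time, pop, new_size)
  list(kind = "size_change", time = time, pop = pop, new_size = new_size)

#' Declarative demographic scenario
#'
#' A scenario names its populations (each with an effective-size symbol or
#' literal), a time-ordered list of backward-time events, and the priors for
#' every free parameter. After all merges a single root population must
#' remain.
#'
#' @param id scenario label.
#' @param populations named character/numeric vector: population label ->
#'   size symbol or literal diploid size.
#' @param events list of [event_merge()]/[event_admixture()]/
#'   [event_size_change()], ordered by increasing time into the past.
#' @param priors list of [prior_spec()].
#' @param note free-text provenance.
#' @return an object of class `msat_scenario`.
#' @export
scenario <- function(id, populations, events = list(), priors = list(),
                     note = "") {
  s <- structure(list(id = id, populations = populations, events = events,
                      priors = priors, note = note),
                 class = "msat_scenario")
  v <- validate_scenario(s)
  if (length(v)) stop("invalid scenario '", id, "': ", paste(v, collapse = "; "))
  s
}

#' @export
print.msat_scenario <- function(x, ...) {
  cat(sprintf("msat_scenario '%s': %d populations, %d events, %d priors\n",
              x$id, length(x$populations), length(x$events), length(x$priors)))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# a character value is a parameter symbol unless it parses as a number
# (mixed named vectors like c(A = "N1", B = 500) coerce literals to text)
is_symbol <- function(x)
  is.character(x) && is.na(suppressWarnings(as.numeric(x)))

# all parameter symbols referenced by a scenario
scenario_symbols <- function(s) {
  syms <- character(0)
  take <- function(x) if (is_symbol(x)) syms <<- c(syms, x)
  for (x in s$populations) take(x)
  for (e in s$events) {
    take(e$time)
    if (e$kind == "admixture") take(e$rate)
    if (e$kind == "size_change") take(e$new_size)
  }
  unique(syms)
}

#' Check a scenario's invariants
#'
#' Returns a character vector of violations (empty when valid): unpriced or
#' multiply-priced parameter symbols, events naming unknown or already-merged
#' populations, merge sequences leaving more than one root, admixture rates
#' outside \[0,1\], out-of-order literal event times, and cyclic ordering
#' constraints among priors.
#'
#' @param s an `msat_scenario` (or the underlying list).
#' @return character vector of violation messages.
#' @export
validate_scenario <- function(s) {
  v <- character(0)
  pops <- names(s$populations)
  if (is.null(pops) || any(!nzchar(pops))) return("populations must be named")
  if (anyDuplicated(pops)) v <- c(v, "duplicate population labels")
  pnames <- vapply(s$priors, function(p) p$name, "")
  if (anyDuplicated(pnames)) v <- c(v, "parameter priced by more than one prior")
  syms <- scenario_symbols(s)
  unpriced <- setdiff(syms, pnames)
  if (length(unpriced))
    v <- c(v, paste0("unpriced parameter: ", paste(unpriced, collapse = ", ")))
  # constraint cycle check
  edges <- do.call(rbind, lapply(s$priors, function(p)
    if (!is.null(p$greater_than)) c(p$name, p$greater_than)))
  if (!is.null(edges)) {
    g <- stats::setNames(vector("list", length(unique(c(edges)))), unique(c(edges)))
    for (i in seq_len(nrow(edges))) g[[edges[i, 1]]] <- c(g[[edges[i, 1]]], edges[i, 2])
    seen <- character(0)
    visit <- function(node, path) {
      if (node %in% path) return(TRUE)
      any(vapply(g[[node]], visit, TRUE, path = c(path, node)), na.rm = TRUE)
    }
    if (any(vapply(names(g), function(n) isTRUE(visit(n, character(0))), TRUE)))
      v <- c(v, "ordering constraints form a cycle")
  }
  # structural connectivity: apply events in order
  alive <- pops
  times <- vapply(s$events, function(e)
    if (is.numeric(e$time)) e$time else NA_real_, 0)
  if (any(diff(times[!is.na(times)]) < 0))
    v <- c(v, "literal event times not weakly increasing backward")
  for (e in s$events) {
    actors <- switch(e$kind,
                     merge = c(e$from, e$to),
                     admixture = c(e$target, e$source1, e$source2),
                     size_change = e$pop)
    missing_pop <- setdiff(actors, pops)
    if (length(missing_pop)) {
      v <- c(v, paste0("unknown population: ", paste(missing_pop, collapse = ", ")))
      next
    }
    dead <- setdiff(actors, alive)
    if (length(dead)) {
      v <- c(v, paste0("event references merged-away population: ",
                       paste(dead, collapse = ", ")))
      next
    }
    if (e$kind == "merge") alive <- setdiff(alive, e$from)
    if (e$kind == "admixture") alive <- setdiff(alive, e$target)
    if (e$kind == "admixture" && is.numeric(e$rate) &&
        (e$rate < 0 || e$rate > 1))
      v <- c(v, "admixture rate outside [0,1]")
  }
  if (length(alive) > 1)
    v <- c(v, paste0("disconnected: ", length(alive), " roots remain (",
                     paste(alive, collapse = ", "), ")"))
  v
}

#' Draw parameter sets from a scenario's priors
#'
#' Independent draws from each prior; draws violating the ordering
#' constraints are rejected and redrawn. Reproducible for a given seed.
#'
#' @param s a valid `msat_scenario`.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return a data.frame (one column per parameter symbol) with attributes
#'   `scenario` (the id) and `seed`.
#' @export
sample_parameters <- function(s, n, seed = 1) {
  set.seed(seed)
  priors <- s$priors
  if (!length(priors)) {
    out <- as.data.frame(matrix(numeric(0), nrow = n, ncol = 0))
    attr(out, "scenario") <- s$id; attr(out, "seed") <- seed
    return(out)
  }
  draw1 <- function(m) {
    cols <- lapply(priors, function(p) {
      if (p$distribution == "uniform") stats::runif(m, p$low, p$high)
      else exp(stats::runif(m, log(p$low), log(p$high)))
    })
    out <- as.data.frame(cols)
    names(out) <- vapply(priors, function(p) p$name, "")
    out
  }
  ok_rows <- function(df) {
    ok <- rep(TRUE, nrow(df))
    for (p in priors) if (!is.null(p$greater_than))
      ok <- ok & df[[p$name]] > df[[p$greater_than]]
    ok
  }
  out <- draw1(n)
  keep <- ok_rows(out)
  tried <- n; accepted <- sum(keep)
  while (any(!keep)) {
    if (tried >= 1e4 && accepted / tried < 1e-4)
      stop("constraint acceptance rate below 1e-4: degenerate constraint system")
    redo <- draw1(sum(!keep))
    out[!keep, ] <- redo
    tried <- tried + nrow(redo)
    keep2 <- ok_rows(out)
    accepted <- accepted + sum(!keep & keep2)
    keep <- keep2
  }
  attr(out, "scenario") <- s$id; attr(out, "seed") <- seed
  out
}

#' Convert generations to years
#'
#' @param g generations (>= 0).
#' @param generation_time years per generation (default 2, a typical small
#'   passerine value).
#' @return years.
#' @export
generations_to_years <- function(g, generation_time = 2) {
  if (any(g < 0)) stop("generations must be >= 0")
  g * generation_time
}

#' Scenario sets for the Canary Islands blue tit study design
#'
#' Returns ready-made scenario sets for a three-way mainland/archipelago
#' split analysis and its island-group refinements:
#' \describe{
#'   \item{fig4}{three rooted topologies over Europe, the combined Canary
#'     Islands, and North Africa; sizes U(100, 1e6), split times U(100, 1e5)
#'     generations with `t1 > t2`. Scenario 3 places Europe as the outgroup
#'     to a Canaries + North Africa clade.}
#'   \item{figS1_western}{five scenarios over Europe, La Palma, El Hierro and
#'     the combined central islands; scenario 4 is the simultaneous island
#'     split with no admixture.}
#'   \item{figS2_central}{six scenarios over Tenerife, Gran Canaria and La
#'     Gomera (including admixture variants); scenario 5 is the simultaneous
#'     split with no admixture.}
#'   \item{figS2_eastern}{six scenarios over Fuerteventura, Lanzarote and
#'     North Africa, analogous to the central set.}
#'   \item{fig5_final}{six nine-population scenarios combining the
#'     within-group simultaneous splits with different branching orders;
#'     scenario 2 has the most recent eastern + Morocco split with the
#'     central trio on a branch sister to La Palma + El Hierro, and scenario
#'     6 splits all nine regions simultaneously.}
#' }
#' Island-group sets use size priors U(100, 1e4) and time priors
#' U(100, 1e6) generations. Branch orderings that the study design leaves
#' open are shipped as best-effort reconstructions and carry
#' `note = "topology partially inferred"`.
#'
#' @param set_id one of `"fig4"`, `"figS1_western"`, `"figS2_central"`,
#'   `"figS2_eastern"`, `"fig5_final"`.
#' @return list of `msat_scenario` objects.
#' @export
paper_scenarios <- function(set_id = c("fig4", "figS1_western", "figS2_central",
                                       "figS2_eastern", "fig5_final")) {
  set_id <- match.arg(set_id)
  inferred <- "topology partially inferred"
  if (set_id == "fig4") {
    pops <- c(Europe = "NEU", Canaries = "NCA", NorthAfrica = "NAF")
    pri <- list(prior_spec("NEU", 100, 1e6), prior_spec("NCA", 100, 1e6),
                prior_spec("NAF", 100, 1e6),
                prior_spec("t2", 100, 1e5),
                prior_spec("t1", 100, 1e5, greater_than = "t2"))
    return(list(
      scenario("fig4-1", pops,
               list(event_merge("t2", "Canaries", "Europe"),
                    event_merge("t1", "NorthAfrica", "Europe")),
               pri, note = inferred),
      scenario("fig4-2", pops,
               list(event_merge("t2", "NorthAfrica", "Europe"),
                    event_merge("t1", "Canaries", "Europe")),
               pri, note = inferred),
      scenario("fig4-3", pops,
               list(event_merge("t2", "Canaries", "NorthAfrica"),
                    event_merge("t1", "NorthAfrica", "Europe")),
               pri, note = "Europe outgroup to Canaries + North Africa")))
  }
  if (set_id == "figS1_western") {
    pops <- c(Europe = "NEU", LaPalma = "NLP", ElHierro = "NEH",
              Central = "NCE")
    pri <- list(prior_spec("NEU", 100, 1e4), prior_spec("NLP", 100, 1e4),
                prior_spec("NEH", 100, 1e4), prior_spec("NCE", 100, 1e4),
                prior_spec("t1", 100, 1e6),
                prior_spec("t2", 100, 1e6, greater_than = "t1"),
                prior_spec("t0", 100, 1e6, greater_than = "t2"))
    seq_sc <- function(id, e1, e2) scenario(id, pops, list(
      e1, e2, event_merge("t0", "Central", "Europe")), pri, note = inferred)
    return(list(
      seq_sc("figS1-1", event_merge("t1", "ElHierro", "LaPalma"),
             event_merge("t2", "LaPalma", "Central")),
      seq_sc("figS1-2", event_merge("t1", "LaPalma", "ElHierro"),
             event_merge("t2", "ElHierro", "Central")),
      seq_sc("figS1-3", event_merge("t1", "ElHierro", "Central"),
             event_merge("t2", "LaPalma", "Central")),
      scenario("figS1-4", pops,
               list(event_merge("t1", "LaPalma", "Central"),
                    event_merge("t1", "ElHierro", "Central"),
                    event_merge("t0", "Central", "Europe")),
               c(pri[1:5], list(prior_spec("t0", 100, 1e6, greater_than = "t1"))),
               note = "simultaneous island splits, no admixture"),
      seq_sc("figS1-5", event_merge("t1", "LaPalma", "Central"),
             event_merge("t2", "ElHierro", "Central"))))
  }
  if (set_id %in% c("figS2_central", "figS2_eastern")) {
    if (set_id == "figS2_central") {
      nm <- c("Tenerife", "GranCanaria", "LaGomera")
    } else nm <- c("Fuerteventura", "Lanzarote", "NorthAfrica")
    pops <- stats::setNames(c("N1", "N2", "N3"), nm)
    pri <- list(prior_spec("N1", 100, 1e4), prior_spec("N2", 100, 1e4),
                prior_spec("N3", 100, 1e4),
                prior_spec("t1", 100, 1e6),
                prior_spec("t2", 100, 1e6, greater_than = "t1"))
    pri_r <- c(pri, list(prior_spec("ra", 0, 1)))
    return(list(
      scenario(paste0(set_id, "-1"), pops,
               list(event_merge("t1", nm[2], nm[1]),
                    event_merge("t2", nm[3], nm[1])), pri, note = inferred),
      scenario(paste0(set_id, "-2"), pops,
               list(event_merge("t1", nm[3], nm[2]),
                    event_merge("t2", nm[2], nm[1])), pri, note = inferred),
      scenario(paste0(set_id, "-3"), pops,
               list(event_merge("t1", nm[2], nm[3]),
                    event_merge("t2", nm[3], nm[1])), pri, note = inferred),
      scenario(paste0(set_id, "-4"), pops,
               list(event_admixture("t1", nm[2], nm[1], nm[3], "ra"),
                    event_merge("t2", nm[3], nm[1])), pri_r,
               note = paste0(inferred, "; admixture variant")),
      scenario(paste0(set_id, "-5"), pops,
               list(event_merge("t1", nm[2], nm[1]),
                    event_merge("t1", nm[3], nm[1])), pri,
               note = "simultaneous splits, no admixture"),
      scenario(paste0(set_id, "-6"), pops,
               list(event_admixture("t1", nm[3], nm[1], nm[2], "ra"),
                    event_merge("t2", nm[2], nm[1])), pri_r,
               note = paste0(inferred, "; admixture variant"))))
  }
  # fig5_final: nine populations, six scenarios built from the within-group
  # simultaneous splits (western pair, central trio, eastern pair + Morocco)
  pops <- c(Europe = "NEU", ElHierro = "NEH", LaPalma = "NLP",
            LaGomera = "NLG", Tenerife = "NTE", GranCanaria = "NGC",
            Lanzarote = "NLA", Fuerteventura = "NFU", NorthAfrica = "NAF")
  sizes <- list(prior_spec("NEU", 100, 1e4), prior_spec("NEH", 100, 1e4),
                prior_spec("NLP", 100, 1e4), prior_spec("NLG", 100, 1e4),
                prior_spec("NTE", 100, 1e4), prior_spec("NGC", 100, 1e4),
                prior_spec("NLA", 100, 1e4), prior_spec("NFU", 100, 1e4),
                prior_spec("NAF", 100, 1e4))
  west <- function(t) list(event_merge(t, "LaPalma", "ElHierro"))
  central <- function(t) list(event_merge(t, "LaGomera", "Tenerife"),
                              event_merge(t, "GranCanaria", "Tenerife"))
  east <- function(t) list(event_merge(t, "Lanzarote", "NorthAfrica"),
                           event_merge(t, "Fuerteventura", "NorthAfrica"))
  tp <- function(name, gt = NULL) prior_spec(name, 100, 1e6, greater_than = gt)
  chain <- function(...) {
    nms <- c(...)
    lapply(seq_along(nms), function(i)
      tp(nms[i], if (i > 1) nms[i - 1] else NULL))
  }
  sc <- list()
  # scenario 1: serial colonisation outward from North Africa
  sc[[1]] <- scenario("fig5-1", pops, c(
    east("te"), central("tc"), west("tw"),
    list(event_merge("t3", "ElHierro", "Tenerife"),
         event_merge("t4", "Tenerife", "NorthAfrica"),
         event_merge("t5", "NorthAfrica", "Europe"))),
    c(sizes, chain("te", "tc", "tw", "t3", "t4", "t5")), note = inferred)
  # scenario 2: most recent eastern+Morocco split; central trio from a branch
  # sister to the La Palma + El Hierro pair; eastern/central share an ancestor
  sc[[2]] <- scenario("fig5-2", pops, c(
    east("te"), list(event_merge("tw", "LaPalma", "ElHierro")),
    central("tc"),
    list(event_merge("t3", "NorthAfrica", "Tenerife"),
         event_merge("t4", "Tenerife", "ElHierro"),
         event_merge("t5", "ElHierro", "Europe"))),
    c(sizes, chain("te", "tw", "tc", "t3", "t4", "t5")),
    note = "eastern split most recent; central trio sister to western pair")
  # scenario 3: western pair as outgroup to everything else
  sc[[3]] <- scenario("fig5-3", pops, c(
    east("te"), central("tc"), west("tw"),
    list(event_merge("t3", "Tenerife", "NorthAfrica"),
         event_merge("t4", "NorthAfrica", "ElHierro"),
         event_merge("t5", "ElHierro", "Europe"))),
    c(sizes, chain("te", "tc", "tw", "t3", "t4", "t5")), note = inferred)
  # scenario 4: eastern branch originating from the central ancestor
  sc[[4]] <- scenario("fig5-4", pops, c(
    east("te"), central("tc"), west("tw"),
    list(event_merge("t3", "NorthAfrica", "Tenerife"),
         event_merge("t4", "Tenerife", "ElHierro"),
         event_merge("t5", "ElHierro", "Europe"))),
    c(sizes, chain("te", "tc", "tw", "t3", "t4", "t5")), note = inferred)
  # scenario 5: central trio splitting directly from North Africa
  sc[[5]] <- scenario("fig5-5", pops, c(
    east("te"), central("tc"), west("tw"),
    list(event_merge("t3", "ElHierro", "NorthAfrica"),
         event_merge("t4", "Tenerife", "NorthAfrica"),
         event_merge("t5", "NorthAfrica", "Europe"))),
    c(sizes, chain("te", "tc", "tw", "t3", "t4", "t5")), note = inferred)
  # scenario 6: all nine-region splits simultaneous, Europe outgroup
  sc[[6]] <- scenario("fig5-6", pops, c(
    east("t1"), central("t1"), list(event_merge("t1", "LaPalma", "NorthAfrica"),
                                    event_merge("t1", "ElHierro", "NorthAfrica"),
                                    event_merge("t1", "Tenerife", "NorthAfrica"),
                                    event_merge("t0", "NorthAfrica", "Europe"))),
    c(sizes, chain("t1", "t0")),
    note = "all island/Morocco splits simultaneous")
  sc
}

#' Serialize scenarios to and from YAML
#'
#' @param s an `msat_scenario`.
#' @param text YAML produced by `scenario_to_yaml`.
#' @return `scenario_to_yaml`: a YAML string; `scenario_from_yaml`: an
#'   `msat_scenario`.
#' @export
scenario_to_yaml <- function(s) {
  pops <- as.list(s$populations)
  pri <- lapply(s$priors, function(p)
    Filter(Negate(is.null), list(name = p$name, distribution = p$distribution,
                                 low = p$low, high = p$high,
                                 greater_than = p$greater_than)))
  yaml::as.yaml(list(id = s$id, populations = pops, events = s$events,
                     priors = pri, note = s$note))
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(text) {
  x <- yaml::yaml.load(text)
  pops <- unlist(x$populations)
  events <- lapply(x$events, function(e) e)
  priors <- lapply(x$priors, function(p)
    prior_spec(p$name, p$low, p$high, p$distribution,
               greater_than = p$greater_than))
  scenario(x$id, pops, events, priors, note = if (is.null(x$note)) "" else x$note)
}
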