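#' Summary-statistic vector of a dataset
#'
#' The statistic set used for approximate Bayesian computation: per population
#' the mean number of alleles per locus, mean unbiased expected
#' heterozygosity, and mean allele-size variance; per population pair the
#' multi-locus Weir-Cockerham theta (0 when undefined because every locus is
#' monomorphic across the pair) and the mean squared difference in mean allele
#' size, (delta-mu)^2. The order is fixed given the population list:
#' `(A, He, V)` per population, then `(theta, dmu2)` per pair `(i < j)`;
#' length `3P + 2*choose(P,2)`.
#'
#' @param d an `msat_dataset`.
#' @return named numeric vector.
#' @export
summarize_dataset <- function(d) {
  pops <- populations(d)
  P <- length(pops)
  L <- nrow(d$loci)
  out <- numeric(0)
  msize <- matrix(NA_real_, P, L)
  for (p in seq_len(P)) {
    rows <- pop_rows(d, pops[p])
    nall <- he <- va <- rep(NA_real_, L)
    any_typed <- FALSE
    for (l in seq_len(L)) {
      cp <- gene_copies(d, l, rows)
      C <- length(cp)
      if (C == 0) next
      any_typed <- TRUE
      nall[l] <- length(unique(cp))
      msize[p, l] <- mean(cp)
      if (C > 1) {
        f <- table(cp) / C
        he[l] <- (C / (C - 1)) * (1 - sum(f^2))
        va[l] <- stats::var(cp)
      } else {
        he[l] <- 0; va[l] <- 0
      }
    }
    if (!any_typed)
      stop("population '", pops[p], "' has zero typed copies at all loci")
    v <- c(mean(nall, na.rm = TRUE), mean(he, na.rm = TRUE),
           mean(va, na.rm = TRUE))
    names(v) <- paste0(c("A_", "He_", "V_"), pops[p])
    out <- c(out, v)
  }
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    th <- theta_multilocus(d, list(pop_rows(d, pops[i]), pop_rows(d, pops[j])))
    if (is.na(th)) th <- 0
    dm <- mean((msize[i, ] - msize[j, ])^2, na.rm = TRUE)
    v <- c(th, dm)
    names(v) <- paste0(c("theta_", "dmu2_"), pops[i], ".", pops[j])
    out <- c(out, v)
  }
  out
}

# summary layout names for a population list (must match summarize_dataset
# and the C++ fast path)
summary_names <- function(pops) {
  P <- length(pops)
  nm <- unlist(lapply(pops, function(p) paste0(c("A_", "He_", "V_"), p)))
  for (i in seq_len(P - 1)) for (j in (i + 1):P)
    nm <- c(nm, paste0(c("theta_", "dmu2_"), pops[i], ".", pops[j]))
  nm
}

#' Build an ABC reference table
#'
#' For each scenario, draws parameter sets from the priors, simulates a
#' dataset per draw with the coalescent engine, and records its
#' summary-statistic vector. All scenarios must share the population set and
#' sample configuration. The per-statistic robust scale (MAD with sd
#' fallback) over all records is stored for distance standardization.
#' Generation is chunked internally (`chunk_size`) without affecting results.
#'
#' @param scenarios list of valid `msat_scenario` objects.
#' @param n_per_scenario simulations per scenario.
#' @param config an [sample_config()].
#' @param loci locus definition data.frame.
#' @param mut an [mutation_model()].
#' @param seed RNG seed (one stream drives the whole table).
#' @param chunk_size draws per internal chunk.
#' @return an object of class `msat_reftable`: `scenario` (id per record),
#'   `params` (data.frame, union of symbols, `NA` where not in a scenario's
#'   model), `summaries` (records x statistics matrix), `scaling`,
#'   `scenarios` (the input list), `config`, `loci`, `mut`, `seed`.
#' @export
build_reference_table <- function(scenarios, n_per_scenario, config, loci,
                                  mut, seed = 1, chunk_size = 1000) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  zv <- loci$inheritance == "z_linked"
  rh <- range_high_of(mut)
  ids <- vapply(scenarios, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("scenario ids must be unique")
  set.seed(seed)
  all_params <- list(); all_sum <- list(); all_id <- character(0)
  for (s in scenarios) {
    # per-scenario parameter draws from the common stream
    pr <- sample_parameters(s, n_per_scenario,
                            seed = sample.int(.Machine$integer.max, 1))
    sm <- matrix(NA_real_, n_per_scenario, 3 * nrow(config) +
                   nrow(config) * (nrow(config) - 1))
    done <- 0L
    while (done < n_per_scenario) {
      take <- min(chunk_size, n_per_scenario - done)
      for (k in seq_len(take)) {
        rs <- resolve_scenario(s, pr[done + k, , drop = FALSE], config)
        sm[done + k, ] <- sim_summary_cpp(rs$sizes, rs$events, rs$n_males,
                                          rs$n_females, zv, mut$mean_rate,
                                          mut$gsm_p, mut$ancestral_state, rh)
      }
      done <- done + take
    }
    all_params[[s$id]] <- pr
    all_sum[[s$id]] <- sm
    all_id <- c(all_id, rep(s$id, n_per_scenario))
  }
  syms <- unique(unlist(lapply(all_params, names)))
  params <- do.call(rbind, lapply(all_params, function(pr) {
    miss <- setdiff(syms, names(pr))
    for (m in miss) pr[[m]] <- NA_real_
    pr[, syms, drop = FALSE]
  }))
  rownames(params) <- NULL
  summaries <- do.call(rbind, all_sum)
  pops <- names(scenarios[[1]]$populations)
  colnames(summaries) <- summary_names(pops)
  scaling <- apply(summaries, 2, function(x) {
    s <- stats::mad(x)
    if (s == 0) s <- stats::sd(x)
    if (is.na(s) || s == 0) s <- 1
    s
  })
  structure(list(scenario = all_id, params = params, summaries = summaries,
                 scaling = scaling, scenarios = scenarios, config = config,
                 loci = loci, mut = mut, seed = seed),
            class = "msat_reftable")
}

#' @export
print.msat_reftable <- function(x, ...) {
  cat(sprintf("msat_reftable: %d records, %d scenarios, %d statistics\n",
              length(x$scenario), length(unique(x$scenario)),
              ncol(x$summaries)))
  invisible(x)
}

#' Write/read a reference table as TSV with a YAML manifest header
#'
#' The table is persisted as plain text: `#`-prefixed YAML manifest lines
#' (statistic order, scaling, seed) followed by a tab-separated body.
#'
#' @param table an `msat_reftable`.
#' @param path output file.
#' @return `write_reference_table`: `path` invisibly;
#'   `read_reference_table`: a list with `scenario`, `params`, `summaries`,
#'   `scaling`, `seed` (scenario objects are not round-tripped).
#' @export
write_reference_table <- function(table, path) {
  man <- yaml::as.yaml(list(statistics = colnames(table$summaries),
                            parameters = names(table$params),
                            scaling = as.list(table$scaling),
                            seed = table$seed))
  hdr <- paste0("#", strsplit(man, "\n")[[1]])
  body <- cbind(data.frame(scenario = table$scenario), table$params,
                as.data.frame(table$summaries))
  con <- file(path, "w")
  writeLines(hdr, con)
  suppressWarnings(utils::write.table(body, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
  close(con)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  man <- yaml::yaml.load(paste(sub("^#", "", lines[which(hdr)]), collapse = "\n"))
  body <- utils::read.delim(text = lines[!hdr], stringsAsFactors = FALSE)
  structure(list(scenario = body$scenario,
                 params = body[, man$parameters, drop = FALSE],
                 summaries = as.matrix(body[, man$statistics, drop = FALSE]),
                 scaling = unlist(man$scaling)[man$statistics],
                 seed = man$seed),
            class = "msat_reftable")
}

# standardized Euclidean distances from every record to the observed vector
reftable_distances <- function(table, observed) {
  z <- sweep(sweep(table$summaries, 2, observed, "-"), 2, table$scaling, "/")
  sqrt(rowSums(z^2))
}

#' Scenario choice by the direct ABC estimate
#'
#' Posterior scenario probabilities estimated as the relative proportion of
#' each scenario among the `n_closest` records nearest to the observed
#' summary vector (Euclidean distance on scale-standardized statistics; ties
#' at the cutoff broken by record index).
#'
#' @param table an `msat_reftable`.
#' @param observed summary vector from [summarize_dataset()].
#' @param n_closest retained records (default 500).
#' @return a data.frame (class `msat_model_choice`) with `scenario` and
#'   `probability`, plus attributes `method` and `n_used`.
#' @export
model_choice_direct <- function(table, observed, n_closest = 500) {
  n <- length(table$scenario)
  if (n_closest > n) stop("n_closest exceeds table size")
  d <- reftable_distances(table, observed)
  sel <- order(d, seq_len(n))[seq_len(n_closest)]
  ids <- vapply(table$scenarios, function(s) s$id, "")
  prob <- vapply(ids, function(i) mean(table$scenario[sel] == i), 0)
  structure(data.frame(scenario = ids, probability = unname(prob),
                       stringsAsFactors = FALSE),
            class = c("msat_model_choice", "data.frame"),
            method = "direct", n_used = n_closest)
}

#' Scenario choice by weighted multinomial logistic regression
#'
#' Retains the `n_regression` records closest to the observed vector and
#' regresses scenario identity on the standardized differences between
#' simulated and observed statistics, weighting records by an Epanechnikov
#' kernel of relative distance. The predicted probabilities at zero
#' difference (the regression intercept) are the point estimates. A small
#' ridge penalty keeps the fit defined under complete separation.
#'
#' @param table an `msat_reftable`.
#' @param observed summary vector.
#' @param n_regression retained records.
#' @param ridge ridge penalty passed to the regression (default 1e-6).
#' @return a data.frame as in [model_choice_direct()]; scenarios absent from
#'   the retained set get probability 0 with a warning.
#' @export
model_choice_logistic <- function(table, observed, n_regression,
                                  ridge = 1e-6) {
  n <- length(table$scenario)
  if (n_regression > n) stop("n_regression exceeds table size")
  d <- reftable_distances(table, observed)
  sel <- order(d, seq_len(n))[seq_len(n_regression)]
  ids <- vapply(table$scenarios, function(s) s$id, "")
  y <- factor(table$scenario[sel], levels = ids)
  present <- levels(droplevels(y))
  if (length(present) < 2)
    stop("need at least two scenarios among the retained records")
  if (length(present) < length(ids))
    warning("scenario(s) absent from retained records reported with probability 0: ",
            paste(setdiff(ids, present), collapse = ", "))
  X <- sweep(sweep(table$summaries[sel, , drop = FALSE], 2, observed, "-"),
             2, table$scaling, "/")
  dmax <- max(d[sel])
  w <- if (dmax > 0) pmax(1 - (d[sel] / dmax)^2, 1e-8) else rep(1, length(sel))
  fit <- glmnet::glmnet(X, droplevels(y), family = "multinomial",
                        weights = w, alpha = 0, lambda = ridge,
                        standardize = FALSE)
  pr <- drop(stats::predict(fit, newx = matrix(0, 1, ncol(X)),
                            type = "response", s = ridge))
  prob <- stats::setNames(rep(0, length(ids)), ids)
  prob[names(pr)] <- pr
  prob <- prob / sum(prob)
  structure(data.frame(scenario = ids, probability = unname(prob),
                       stringsAsFactors = FALSE),
            class = c("msat_model_choice", "data.frame"),
            method = "logistic", n_used = n_regression)
}

#' Regression-adjusted parameter posterior with mode and 95% HPD
#'
#' Among one scenario's records, accepts the `n_accept` closest to the
#' observed vector, applies the local-linear regression adjustment
#' `theta* = theta - t(beta) (S - s_obs)` with Epanechnikov weights
#' (bandwidth = the largest retained distance) on log-transformed parameters
#' whose priors are strictly positive, and summarizes each adjusted weighted
#' sample by a kernel-density mode (Silverman's bandwidth) and the smallest
#' 95% highest-density region on a grid, clamped to the prior support.
#'
#' @param table an `msat_reftable`.
#' @param observed summary vector.
#' @param scenario scenario id present in the table.
#' @param n_accept accepted records (default 500).
#' @param adjust set `FALSE` to skip the regression adjustment (weighted
#'   rejection sample only).
#' @param grid_n density grid size (default 512).
#' @return a list of class `msat_posterior`, one element per parameter:
#'   `values` (adjusted sample), `weights`, `mode`, `hpd95`.
#' @export
parameter_posterior <- function(table, observed, scenario, n_accept = 500,
                                adjust = TRUE, grid_n = 512) {
  rows <- which(table$scenario == scenario)
  if (!length(rows)) stop("scenario '", scenario, "' not in table")
  if (n_accept > length(rows))
    stop("n_accept exceeds the scenario's record count")
  sobj <- table$scenarios[[match(scenario,
                                 vapply(table$scenarios, function(s) s$id, ""))]]
  d <- reftable_distances(table, observed)[rows]
  sel <- rows[order(d, seq_along(rows))[seq_len(n_accept)]]
  dsel <- reftable_distances(table, observed)[sel]
  dmax <- max(dsel)
  w <- if (dmax > 0) pmax(1 - (dsel / dmax)^2, 1e-8) else rep(1, n_accept)
  X <- sweep(sweep(table$summaries[sel, , drop = FALSE], 2, observed, "-"),
             2, table$scaling, "/")
  prior_of <- function(nm) {
    for (p in sobj$priors) if (p$name == nm) return(p)
    NULL
  }
  syms <- names(table$params)[!vapply(names(table$params), function(nm)
    anyNA(table$params[sel, nm]), TRUE)]
  out <- list()
  for (nm in syms) {
    pr <- prior_of(nm)
    if (is.null(pr)) next
    theta <- table$params[sel, nm]
    uselog <- pr$low > 0
    th <- if (uselog) log(theta) else theta
    if (adjust && stats::var(th) > 0) {
      # weighted local-linear adjustment; drop constant predictors
      keep <- apply(X, 2, function(x) stats::var(x) > 0)
      if (any(keep)) {
        fit <- stats::lm.wfit(cbind(1, X[, keep, drop = FALSE]), th, w)
        beta <- fit$coefficients[-1]
        beta[is.na(beta)] <- 0
        th <- th - drop(X[, keep, drop = FALSE] %*% beta)
      }
    }
    val <- if (uselog) exp(th) else th
    val <- pmin(pmax(val, pr$low), pr$high)
    if (max(val) - min(val) < .Machine$double.eps * max(abs(val), 1)) {
      out[[nm]] <- list(values = val, weights = w, mode = val[1],
                        hpd95 = c(val[1], val[1]))
      next
    }
    de <- stats::density(val, weights = w / sum(w), bw = stats::bw.nrd0(val),
                         n = grid_n,
                         from = max(min(val), pr$low),
                         to = min(max(val), pr$high))
    mode <- de$x[which.max(de$y)]
    ord <- order(de$y, decreasing = TRUE)
    mass <- cumsum(de$y[ord]) / sum(de$y)
    k <- which(mass >= 0.95)[1]
    hsel <- ord[seq_len(k)]
    hpd <- c(max(min(de$x[hsel]), pr$low), min(max(de$x[hsel]), pr$high))
    out[[nm]] <- list(values = val, weights = w, mode = mode, hpd95 = hpd)
  }
  structure(out, class = "msat_posterior", scenario = scenario,
            n_accept = n_accept)
}

#' @export
print.msat_posterior <- function(x, ...) {
  cat(sprintf("msat_posterior for scenario '%s' (%d accepted)\n",
              attr(x, "scenario"), attr(x, "n_accept")))
  for (nm in names(x))
    cat(sprintf("  %-8s mode %.4g  95%% HPD [%.4g, %.4g]\n", nm,
                x[[nm]]$mode, x[[nm]]$hpd95[1], x[[nm]]$hpd95[2]))
  invisible(x)
}
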