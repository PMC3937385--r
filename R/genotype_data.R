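#' Microsatellite dataset with population, sex and linkage metadata
#'
#' An `msat_dataset` bundles an individuals-by-loci matrix of integer allele
#' calls with the metadata needed to interpret them: which population and sex
#' each individual belongs to, and for each locus whether it is autosomal or
#' Z-linked, plus (optionally) its linkage group and map position.
#'
#' Allele calls are stored as two integer matrices `a1`, `a2` (one column per
#' locus). A call is diploid when both entries are present, hemizygous when
#' only `a1` is present (legal only for females at Z-linked loci: female birds
#' are ZW and carry a single Z copy), and missing when both are `NA`.
#'
#' @param loci data.frame with columns `name`, `inheritance`
#'   (`"autosomal"`/`"z_linked"`), and optionally `linkage_group`,
#'   `map_position` (cM), `motif_step` (repeat-unit size, default 1).
#' @param individuals data.frame with columns `id`, `population`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`).
#' @param a1,a2 integer matrices, `nrow(individuals)` x `nrow(loci)`, of
#'   positive allele states (repeat counts or fragment sizes); `NA` = absent.
#' @return an object of class `msat_dataset`.
#' @export
msat_dataset <- function(loci, individuals, a1, a2) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (is.null(loci$linkage_group)) loci$linkage_group <- NA_character_
  if (is.null(loci$map_position)) loci$map_position <- NA_real_
  if (is.null(loci$motif_step)) loci$motif_step <- 1L
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(individuals$id, loci$name)
  d <- structure(list(loci = loci, individuals = individuals,
                      a1 = a1, a2 = a2),
                 class = "msat_dataset")
  validate_dataset(d)
  d
}

#' Validate an msat_dataset's structural invariants
#'
#' Checks matrix dimensions, uniqueness of ids and locus names, legal
#' inheritance/sex codes, positivity of allele states, and the ploidy rules:
#' hemizygous calls only for females at Z-linked loci; males and autosomal
#' loci are diploid or missing.
#'
#' @param d an `msat_dataset`.
#' @return `d`, invisibly; errors on the first violated invariant.
#' @export
validate_dataset <- function(d) {
  stopifnot(inherits(d, "msat_dataset"))
  n <- nrow(d$individuals); L <- nrow(d$loci)
  if (!all(dim(d$a1) == c(n, L)) || !all(dim(d$a2) == c(n, L)))
    stop("call matrices must be individuals x loci")
  if (anyDuplicated(d$loci$name)) stop("locus names must be unique")
  if (anyDuplicated(d$individuals$id)) stop("individual ids must be unique")
  if (!all(d$loci$inheritance %in% c("autosomal", "z_linked")))
    stop("inheritance must be 'autosomal' or 'z_linked'")
  if (!all(d$individuals$sex %in% c("male", "female", "unknown")))
    stop("sex must be 'male', 'female' or 'unknown'")
  mp <- d$loci$map_position
  if (any(!is.na(mp) & mp < 0)) stop("map positions must be >= 0")
  if (any(d$a1 <= 0, na.rm = TRUE) || any(d$a2 <= 0, na.rm = TRUE))
    stop("allele states must be positive integers")
  hemi <- !is.na(d$a1) & is.na(d$a2)
  half <- is.na(d$a1) & !is.na(d$a2)
  if (any(half)) stop("calls with only the second allele present are invalid")
  if (any(hemi)) {
    okrow <- d$individuals$sex == "female"
    okcol <- d$loci$inheritance == "z_linked"
    bad <- hemi & !(outer(okrow, okcol, "&"))
    if (any(bad)) {
      ij <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("hemizygous call at %s x %s: only females at Z-linked loci may be hemizygous",
                   d$individuals$id[ij[1]], d$loci$name[ij[2]]))
    }
  }
  # females must not carry diploid Z calls
  zf <- outer(d$individuals$sex == "female", d$loci$inheritance == "z_linked", "&")
  if (any(zf & !is.na(d$a2))) {
    ij <- which(zf & !is.na(d$a2), arr.ind = TRUE)[1, ]
    stop(sprintf("female %s has a diploid call at Z-linked locus %s",
                 d$individuals$id[ij[1]], d$loci$name[ij[2]]))
  }
  invisible(d)
}

#' @export
print.msat_dataset <- function(x, ...) {
  cat(sprintf("msat_dataset: %d individuals x %d loci (%d Z-linked), %d populations\n",
              nrow(x$individuals), nrow(x$loci),
              sum(x$loci$inheritance == "z_linked"),
              length(unique(x$individuals$population))))
  invisible(x)
}

#' Population labels in input order
#' @param d an `msat_dataset`.
#' @return character vector of unique population labels.
#' @export
populations <- function(d) unique(d$individuals$population)

# status matrix: "diploid", "hemizygous" or "missing" per cell
call_status <- function(d) {
  s <- matrix("missing", nrow(d$a1), ncol(d$a1))
  s[!is.na(d$a1) & !is.na(d$a2)] <- "diploid"
  s[!is.na(d$a1) & is.na(d$a2)] <- "hemizygous"
  s
}

# typed gene copies at locus `l` for the individuals in rows `rows`:
# integer vector of allele states (diploids contribute 2, hemizygotes 1)
gene_copies <- function(d, l, rows) {
  c(d$a1[rows, l], d$a2[rows, l])[!is.na(c(d$a1[rows, l], d$a2[rows, l]))]
}

pop_rows <- function(d, pop) which(d$individuals$population == pop)

# subset individuals (rows) and/or loci (columns), preserving order
subset_dataset <- function(d, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(d$individuals))
  if (is.null(cols)) cols <- seq_len(nrow(d$loci))
  msat_dataset(d$loci[cols, , drop = FALSE],
               d$individuals[rows, , drop = FALSE],
               d$a1[rows, cols, drop = FALSE],
               d$a2[rows, cols, drop = FALSE])
}

#' Read genotypes from a GenePop file with a metadata table
#'
#' Reads the GenePop dialect with 3-digit allele codes, `Pop` separators and
#' `000` for missing. For females at Z-linked loci the code `xxx000` denotes a
#' hemizygous call with allele `xxx` (single Z copy), not a half-missing
#' genotype. Individual ids are matched against a tab-separated metadata table
#' with header `id  population  sex`; the population assignment comes from the
#' metadata and population order follows the genotype file.
#'
#' @param path GenePop file.
#' @param metadata tab-separated file with columns `id`, `population`, `sex`.
#' @param locus_table optional tab-separated file (or data.frame) with columns
#'   `locus`, `linkage_group`, `position_cM`, `inheritance`; absent loci
#'   default to autosomal with no map position.
#' @return an `msat_dataset`.
#' @export
read_genepop <- function(path, metadata, locus_table = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GenePop file too short")
  meta <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  if (!all(c("id", "population", "sex") %in% names(meta)))
    stop("metadata must have columns id, population, sex")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no 'Pop' separator found")
  # line 1 = title; lines 2..first_pop-1 = locus names (possibly comma-joined)
  locus_names <- trimws(unlist(strsplit(lines[2:(first_pop - 1)], ",")))
  locus_names <- locus_names[nzchar(locus_names)]

  ltab <- NULL
  if (!is.null(locus_table)) {
    ltab <- if (is.data.frame(locus_table)) locus_table else
      utils::read.delim(locus_table, stringsAsFactors = FALSE)
    if (!all(c("locus", "inheritance") %in% names(ltab)))
      stop("locus table must have columns locus, inheritance")
  }
  loci <- data.frame(name = locus_names,
                     inheritance = "autosomal",
                     linkage_group = NA_character_,
                     map_position = NA_real_,
                     motif_step = 1L,
                     stringsAsFactors = FALSE)
  if (!is.null(ltab)) {
    m <- match(loci$name, ltab$locus)
    hit <- !is.na(m)
    loci$inheritance[hit] <- ltab$inheritance[m[hit]]
    if ("linkage_group" %in% names(ltab))
      loci$linkage_group[hit] <- as.character(ltab$linkage_group[m[hit]])
    if ("position_cM" %in% names(ltab))
      loci$map_position[hit] <- as.numeric(ltab$position_cM[m[hit]])
  }

  L <- length(locus_names)
  ids <- character(0); a1 <- NULL; a2 <- NULL
  pop_block <- integer(0); block <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) { block <- block + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("line %d: expected 'id , genotypes'", i))
    id <- trimws(parts[1])
    genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(genos) != L)
      stop(sprintf("line %d: %d genotypes for %d loci", i, length(genos), L))
    if (!all(grepl("^[0-9]{6}$", genos)))
      stop(sprintf("line %d: malformed allele code '%s'", i,
                   genos[which(!grepl("^[0-9]{6}$", genos))[1]]))
    x1 <- as.integer(substr(genos, 1, 3))
    x2 <- as.integer(substr(genos, 4, 6))
    ids <- c(ids, id)
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
    pop_block <- c(pop_block, block)
  }
  mi <- match(ids, meta$id)
  if (anyNA(mi))
    stop(sprintf("individual '%s' in genotype file absent from metadata",
                 ids[which(is.na(mi))[1]]))
  ind <- data.frame(id = ids,
                    population = meta$population[mi],
                    sex = meta$sex[mi],
                    stringsAsFactors = FALSE)
  # decode: 000000 -> missing; xxx000 -> hemizygous for females at Z loci,
  # otherwise malformed; 000xxx -> malformed
  zcol <- loci$inheritance == "z_linked"
  fem <- ind$sex == "female"
  miss <- a1 == 0L & a2 == 0L
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  hemi <- !is.na(a1) & !is.na(a2) & a2 == 0L
  badhalf <- !is.na(a1) & !is.na(a2) & a1 == 0L & a2 != 0L
  if (any(badhalf)) {
    ij <- which(badhalf, arr.ind = TRUE)[1, ]
    stop(sprintf("half-missing code for %s at %s", ids[ij[1]], locus_names[ij[2]]))
  }
  if (any(hemi)) {
    ok <- outer(fem, zcol, "&")
    if (any(hemi & !ok)) {
      ij <- which(hemi & !ok, arr.ind = TRUE)[1, ]
      stop(sprintf("code 'xxx000' for %s at %s: hemizygous calls are only legal for females at Z-linked loci",
                   ids[ij[1]], locus_names[ij[2]]))
    }
    a2[hemi] <- NA_integer_
  }
  # females at Z loci with full diploid codes are inconsistent with ZW ploidy
  d <- msat_dataset(loci, ind, a1, a2)
  d
}

#' Write an msat_dataset to a GenePop file
#'
#' Emits the same dialect `read_genepop` consumes: 3-digit codes, one locus
#' name per line, one `Pop` block per population (input order), `000000` for
#' missing and `xxx000` for hemizygous female Z calls, so that
#' `read_genepop(write_genepop(d))` reproduces `d` exactly.
#'
#' @param dataset an `msat_dataset` (all allele states must be <= 999).
#' @param path output file.
#' @param title first (comment) line of the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(dataset, path, title = "msatdem export") {
  d <- dataset
  if (nrow(d$individuals) == 0) stop("cannot write a dataset with no individuals")
  if (any(d$a1 > 999, na.rm = TRUE) || any(d$a2 > 999, na.rm = TRUE))
    stop("allele states > 999 cannot be encoded with 3-digit GenePop codes")
  enc <- function(x) ifelse(is.na(x), "000", sprintf("%03d", x))
  lines <- c(title, d$loci$name)
  for (pop in populations(d)) {
    lines <- c(lines, "Pop")
    for (r in pop_rows(d, pop)) {
      g <- paste0(enc(d$a1[r, ]), enc(d$a2[r, ]))
      lines <- c(lines, paste0(d$individuals$id[r], " ,  ", paste(g, collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the metadata and locus tables for a dataset
#'
#' Companions to [write_genepop()]: a tab-separated individual table
#' (`id  population  sex`) and locus table
#' (`locus  linkage_group  position_cM  inheritance`).
#'
#' @param dataset an `msat_dataset`.
#' @param meta_path,locus_path output files (either may be `NULL` to skip).
#' @return invisibly, `NULL`.
#' @export
write_metadata <- function(dataset, meta_path = NULL, locus_path = NULL) {
  if (!is.null(meta_path))
    utils::write.table(dataset$individuals, meta_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(locus_path)) {
    lt <- data.frame(locus = dataset$loci$name,
                     linkage_group = dataset$loci$linkage_group,
                     position_cM = dataset$loci$map_position,
                     inheritance = dataset$loci$inheritance)
    utils::write.table(lt, locus_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}

#' Drop loci that completely failed to amplify in some population
#'
#' Removes every locus whose calls are 100% missing in at least one population
#' (or population group, when `groups` maps populations to groups). Primer-site
#' mutations in diverged populations typically produce exactly this pattern of
#' total amplification failure.
#'
#' @param dataset an `msat_dataset`.
#' @param groups optional named character vector mapping population label to
#'   group label; the missing-rate rule is then applied per group.
#' @return a list with `dataset` (loci filtered, order preserved) and `report`,
#'   a data.frame of removed loci and the populations/groups driving removal.
#' @export
drop_failed_loci <- function(dataset, groups = NULL) {
  d <- dataset
  pops <- populations(d)
  unit_of <- if (is.null(groups)) stats::setNames(pops, pops) else {
    if (!all(pops %in% names(groups)))
      stop("groups must cover every population")
    groups[pops]
  }
  units <- unique(unname(unit_of))
  miss <- is.na(d$a1)  # a call is missing iff a1 is NA
  removed <- character(0); driver <- character(0)
  for (l in seq_len(nrow(d$loci))) {
    bad <- character(0)
    for (u in units) {
      rows <- which(unit_of[d$individuals$population] == u)
      if (length(rows) && all(miss[rows, l])) bad <- c(bad, u)
    }
    if (length(bad)) {
      removed <- c(removed, d$loci$name[l])
      driver <- c(driver, paste(bad, collapse = ","))
    }
  }
  keep <- !(d$loci$name %in% removed)
  list(dataset = subset_dataset(d, cols = which(keep)),
       report = data.frame(locus = removed, failed_in = driver,
                           stringsAsFactors = FALSE))
}

#' Thin loci to a minimum map distance
#'
#' Greedy scan per linkage group in map order: a locus is kept only when it
#' lies at least `min_distance` centimorgans from the last kept locus on the
#' same group. Loci on unique linkage groups (or with no group assigned) are
#' always kept. Deterministic given input order; used to reduce linkage
#' between loci entering coalescent analyses, which assume independence.
#'
#' @param dataset an `msat_dataset`.
#' @param min_distance minimum separation in cM (default 10).
#' @return the thinned `msat_dataset`.
#' @export
select_spaced_loci <- function(dataset, min_distance = 10) {
  d <- dataset
  lg <- d$loci$linkage_group
  # NA groups are treated as singleton groups
  lg[is.na(lg)] <- paste0(".solo", seq_len(nrow(d$loci)))[is.na(lg)]
  keep <- rep(TRUE, nrow(d$loci))
  for (g in unique(lg)) {
    idx <- which(lg == g)
    if (length(idx) < 2) next
    pos <- d$loci$map_position[idx]
    if (anyNA(pos))
      stop(sprintf("locus '%s' on multi-locus group '%s' has no map position",
                   d$loci$name[idx[which(is.na(pos))[1]]], g))
    ord <- idx[order(pos)]
    last <- -Inf
    for (l in ord) {
      if (d$loci$map_position[l] - last >= min_distance) {
        last <- d$loci$map_position[l]
      } else keep[l] <- FALSE
    }
  }
  subset_dataset(d, cols = which(keep))
}
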