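test_that("GenePop round-trip reproduces a hand-written file and its dataset", {
  gp <- tempfile(fileext = ".gen")
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("toy file",
               "LocA",
               "Pop",
               "a1 ,  120130",
               "a2 ,  120120",
               "Pop",
               "b1 ,  140140",
               "b2 ,  000000"), gp)
  writeLines(c("id\tpopulation\tsex",
               "a1\tNorth\tmale", "a2\tNorth\tfemale",
               "b1\tSouth\tmale", "b2\tSouth\tmale"), meta)
  d <- read_genepop(gp, meta)
  expect_equal(nrow(d$individuals), 4)
  expect_equal(nrow(d$loci), 1)
  expect_equal(populations(d), c("North", "South"))
  expect_equal(d$a1[, 1], c(a1 = 120L, a2 = 120L, b1 = 140L, b2 = NA))
  expect_true(is.na(d$a1["b2", 1]) && is.na(d$a2["b2", 1]))

  out <- tempfile(fileext = ".gen")
  write_genepop(d, out, title = "toy file")
  # genotype block is byte-identical after a round trip through the writer
  reread <- read_genepop(out, meta)
  out2 <- tempfile(fileext = ".gen")
  write_genepop(reread, out2, title = "toy file")
  expect_identical(readLines(out), readLines(out2))
  expect_identical(reread$a1, d$a1)
  expect_identical(reread$a2, d$a2)
})

test_that("female 'xxx000' at a Z-linked locus reads as hemizygous", {
  gp <- tempfile(); meta <- tempfile(); lt <- tempfile()
  writeLines(c("z", "Zloc", "Pop", "f1 ,  120000", "m1 ,  120124"), gp)
  writeLines(c("id\tpopulation\tsex", "f1\tP\tfemale", "m1\tP\tmale"), meta)
  writeLines(c("locus\tlinkage_group\tposition_cM\tinheritance",
               "Zloc\tLGZ\t0\tz_linked"), lt)
  d <- read_genepop(gp, meta, lt)
  expect_equal(unname(d$a1["f1", 1]), 120L)
  expect_true(is.na(d$a2["f1", 1]))
  expect_equal(unname(msatdem:::call_status(d)["f1" == d$individuals$id, 1]),
               "hemizygous")
  # but the same code for a male is a ploidy violation
  writeLines(c("id\tpopulation\tsex", "f1\tP\tmale", "m1\tP\tmale"), meta)
  expect_error(read_genepop(gp, meta, lt), "hemizygous")
})

test_that("reader rejects malformed input and unknown individuals", {
  gp <- tempfile(); meta <- tempfile()
  writeLines(c("bad", "L1", "Pop", "x1 ,  12013"), gp)
  writeLines(c("id\tpopulation\tsex", "x1\tP\tmale"), meta)
  expect_error(read_genepop(gp, meta), "malformed allele code")
  writeLines(c("bad", "L1", "Pop", "x9 ,  120130"), gp)
  expect_error(read_genepop(gp, meta), "absent from metadata")
})

test_that("writer rejects empty datasets and >999 allele states", {
  fx <- paper_shape_fixture(seed = 3)
  d <- fx$dataset
  d$a1[1, 1] <- 1001L
  expect_error(write_genepop(d, tempfile()), "999")
  d2 <- fx$dataset
  d2$individuals <- d2$individuals[0, , drop = FALSE]
  d2$a1 <- d2$a1[0, , drop = FALSE]; d2$a2 <- d2$a2[0, , drop = FALSE]
  expect_error(write_genepop(d2, tempfile()), "no individuals")
})

test_that("GenePop round-trip is the identity on randomized datasets", {
  for (seed in 1:5) {
    d <- random_dataset(n_pops = 3, n_ind = 5, n_loci = 4, seed = seed)
    gp <- tempfile(); meta <- tempfile()
    write_genepop(d, gp)
    write_metadata(d, meta_path = meta)
    r <- read_genepop(gp, meta)
    expect_identical(unname(r$a1), unname(d$a1))
    expect_identical(unname(r$a2), unname(d$a2))
    expect_equal(r$individuals$population, d$individuals$population)
  }
})

test_that("dataset validation enforces the ploidy rules", {
  loci <- data.frame(name = c("A1", "Z1"),
                     inheritance = c("autosomal", "z_linked"))
  ind <- data.frame(id = c("m", "f"), population = "P",
                    sex = c("male", "female"))
  # legal: male diploid everywhere, female hemizygous at Z
  d <- msat_dataset(loci, ind, matrix(c(10L, 11L, 12L, 13L), 2),
                    matrix(c(10L, 11L, 12L, NA), 2))
  expect_s3_class(d, "msat_dataset")
  # female diploid at Z is illegal
  expect_error(msat_dataset(loci, ind, matrix(c(10L, 11L, 12L, 13L), 2),
                            matrix(c(10L, 11L, 12L, 13L), 2)),
               "diploid call at Z-linked")
  # male hemizygous anywhere is illegal
  expect_error(msat_dataset(loci, ind, matrix(c(10L, 11L, 12L, 13L), 2),
                            matrix(c(NA, 11L, 12L, NA), 2)),
               "hemizygous")
})

test_that("drop_failed_loci removes only fully-missing loci and is idempotent", {
  fx <- paper_shape_fixture(seed = 5)
  res <- drop_failed_loci(fx$dataset)
  expect_equal(nrow(res$dataset$loci), 19)
  expect_setequal(res$report$locus, c("Tgu9", "Pca8"))
  expect_match(res$report$failed_in[res$report$locus == "Pca8"], "LaPalma")
  # idempotent
  res2 <- drop_failed_loci(res$dataset)
  expect_equal(nrow(res2$dataset$loci), 19)
  expect_equal(nrow(res2$report), 0)

  # 95% missing is retained: the rule is 100% only
  d <- random_dataset(n_pops = 2, n_ind = 20, n_loci = 2, seed = 7)
  rows <- which(d$individuals$population == "A")[1:19]
  d$a1[rows, 1] <- NA_integer_; d$a2[rows, 1] <- NA_integer_
  expect_equal(nrow(drop_failed_loci(d)$dataset$loci), 2)

  # grouped mode: locus missing across a whole group is removed even though
  # no single population is at 100%... (here: both pops of group G1 fully missing)
  d2 <- random_dataset(n_pops = 3, n_ind = 4, n_loci = 2, seed = 8)
  rows <- which(d2$individuals$population %in% c("A", "B"))
  d2$a1[rows, 2] <- NA_integer_; d2$a2[rows, 2] <- NA_integer_
  res3 <- drop_failed_loci(d2, groups = c(A = "G1", B = "G1", C = "G2"))
  expect_equal(res3$report$locus, "L2")
})

test_that("select_spaced_loci applies the greedy map-distance rule", {
  loci <- data.frame(name = c("a", "b", "c"), inheritance = "autosomal",
                     linkage_group = "LG1", map_position = c(0, 5, 12))
  ind <- data.frame(id = "x", population = "P", sex = "male")
  d <- msat_dataset(loci, ind, matrix(c(10L, 10L, 10L), 1),
                    matrix(c(10L, 10L, 10L), 1))
  out <- select_spaced_loci(d, 10)
  expect_equal(out$loci$name, c("a", "c"))
  # all loci on distinct groups: everything kept
  loci2 <- transform(loci, linkage_group = c("LG1", "LG2", "LG3"))
  d2 <- msat_dataset(loci2, ind, matrix(rep(10L, 3), 1), matrix(rep(10L, 3), 1))
  expect_equal(nrow(select_spaced_loci(d2, 10)$loci), 3)
  # missing position on a shared group errors
  loci3 <- transform(loci, map_position = c(0, NA, 12))
  d3 <- msat_dataset(loci3, ind, matrix(rep(10L, 3), 1), matrix(rep(10L, 3), 1))
  expect_error(select_spaced_loci(d3, 10), "map position")
})

test_that("the fixture's 19-locus map thins to the 14-locus panel at 10 cM", {
  fx <- paper_shape_fixture(seed = 2)
  d19 <- drop_failed_loci(fx$dataset)$dataset
  d14 <- select_spaced_loci(d19, 10)
  expect_equal(nrow(d14$loci), 14)
  expect_setequal(d14$loci$name, fixture_abc_loci()$name)
  # invariant: within-group adjacent distances all >= 10
  for (g in unique(stats::na.omit(d14$loci$linkage_group))) {
    pos <- sort(d14$loci$map_position[d14$loci$linkage_group %in% g])
    if (length(pos) > 1) expect_true(all(diff(pos) >= 10))
  }
})
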