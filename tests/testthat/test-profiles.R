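test_that("marker presence needs both the 1% frequency and 4-read support", {
  sc <- tiny_scheme()
  mk <- derive_marker_snps(sc, tiny_profiles())
  fba2 <- list(locus = "fba", position = 2L, base = "T")

  # 0.9% at high depth: frequency rule fails despite 90 supporting reads
  pl <- tiny_pileup(sc, list(c(fba2, count = 90L,
                               other = list(list(base = "G", count = 9910L)))))
  calls <- call_marker_snps(pl, mk)
  cl <- calls[calls$locus == "fba" & calls$allele == 2L, ]
  expect_equal(cl$frequency, 90 / 10000)
  expect_false(cl$present)

  # 5% but only 3 reads: support rule fails
  pl <- tiny_pileup(sc, list(c(fba2, count = 3L,
                               other = list(list(base = "G", count = 57L)))))
  cl <- call_marker_snps(pl, mk)
  cl <- cl[cl$locus == "fba" & cl$allele == 2L, ]
  expect_equal(cl$frequency, 0.05)
  expect_false(cl$present)

  # fixed: frequency 1.0 at depth 100
  pl <- tiny_pileup(sc, list(c(fba2, count = 100L,
                               other = list(list(base = "G", count = 0L)))))
  cl <- call_marker_snps(pl, mk)
  cl <- cl[cl$locus == "fba" & cl$allele == 2L, ]
  expect_true(cl$present)
  expect_equal(cl$frequency, 1)

  # boundary: exactly 1% with exactly 4 reads is present
  pl <- tiny_pileup(sc, list(c(fba2, count = 4L,
                               other = list(list(base = "G", count = 396L)))))
  cl <- call_marker_snps(pl, mk)
  expect_true(cl[cl$locus == "fba" & cl$allele == 2L, "present"])
})

test_that("zero-depth marker positions yield frequency 0 and absent calls", {
  sc <- tiny_scheme()
  mk <- derive_marker_snps(sc, tiny_profiles())
  pl <- tiny_pileup(sc)
  pl[pl$locus == "fba" & pl$position == 2L, c("A", "C", "G", "T")] <- 0L
  pl$depth <- pl$A + pl$C + pl$G + pl$T
  cl <- call_marker_snps(pl, mk)
  row <- cl[cl$locus == "fba" & cl$allele == 2L, ]
  expect_equal(row$frequency, 0)
  expect_false(row$present)
})

test_that("raising filter thresholds never turns an absent SNP present", {
  sc <- tiny_scheme()
  mk <- derive_marker_snps(sc, tiny_profiles())
  set.seed(11)
  for (rep in 1:20) {
    count <- sample(0:50, 1)
    rest <- sample(0:500, 1)
    pl <- tiny_pileup(sc, list(list(locus = "fba", position = 2L, base = "T",
                                    count = count,
                                    other = list(base = "G", count = rest))))
    base_call <- call_marker_snps(pl, mk, min_freq = 0.01, min_reads = 4L)
    for (mf in c(0.02, 0.05, 0.2)) for (mr in c(4L, 8L, 20L)) {
      stricter <- call_marker_snps(pl, mk, min_freq = mf, min_reads = mr)
      expect_true(all(stricter$present <= base_call$present))
    }
  }
})

test_that("markers referencing unknown loci are an error", {
  sc <- tiny_scheme()
  mk <- derive_marker_snps(sc, tiny_profiles())
  mk$locus[1] <- "nope"
  expect_error(call_marker_snps(tiny_pileup(sc), mk), "absent from pileup")
})

test_that("allele abundance follows the all-markers-present and residual rules", {
  # one locus, alleles 1 (default), 2, 3, each non-default with one marker
  sc <- mlst_scheme(list(mlst_locus("fba", c(`1` = "ACGT", `2` = "ACTT",
                                             `3` = "GCGT"))),
                    default_allele = c(fba = 1L))
  pr <- data.frame(strain = paste0("s", 1:3), group = paste0("g", 1:3),
                   popflag = TRUE, fba = 1:3)
  mk <- derive_marker_snps(sc, pr)

  mk_calls <- function(f2, f3, depth = 1000L) {
    calls <- call_marker_snps(tiny_pileup(sc, list(
      list(locus = "fba", position = 2L, base = "T",
           count = as.integer(f2 * depth),
           other = list(base = "G", count = as.integer((1 - f2) * depth))),
      list(locus = "fba", position = 0L, base = "G",
           count = as.integer(f3 * depth),
           other = list(base = "A", count = as.integer((1 - f3) * depth))))),
      mk)
    calls
  }

  # worked example: A2 at 0.30, A3 at 0.20 -> default takes 0.50
  ab <- infer_allele_abundance(mk_calls(0.30, 0.20), sc)
  expect_equal(ab$fba, c(`1` = 0.5, `2` = 0.3, `3` = 0.2))
  expect_equal(sum(ab$fba), 1, tolerance = 1e-9)

  # no marker present -> default allele gets everything
  ab0 <- infer_allele_abundance(mk_calls(0, 0), sc)
  expect_equal(ab0$fba, c(`1` = 1))
})

test_that("an allele with any absent marker is absent and its mass defaults", {
  # allele 2 carries two markers; only one is present in the pileup
  sc <- mlst_scheme(list(mlst_locus("fba", c(`1` = "AAAA", `2` = "TTAA"))),
                    default_allele = c(fba = 1L))
  pr <- data.frame(strain = c("s1", "s2"), group = c("g1", "g2"),
                   popflag = TRUE, fba = c(1L, 2L))
  mk <- derive_marker_snps(sc, pr)
  expect_equal(nrow(mk[mk$allele == 2L, ]), 2L)
  pl <- tiny_pileup(sc, list(
    list(locus = "fba", position = 0L, base = "T", count = 30L,
         other = list(base = "A", count = 70L))))  # position 1 stays all-A
  ab <- infer_allele_abundance(call_marker_snps(pl, mk), sc)
  expect_equal(ab$fba, c(`1` = 1))
})

test_that("negative residuals clamp with a warning or error when gross", {
  sc <- mlst_scheme(list(mlst_locus("fba", c(`1` = "ACGT", `2` = "ACTT",
                                             `3` = "GCGT"))),
                    default_allele = c(fba = 1L))
  pr <- data.frame(strain = paste0("s", 1:3), group = paste0("g", 1:3),
                   popflag = TRUE, fba = 1:3)
  mk <- derive_marker_snps(sc, pr)
  over <- function(f2, f3) call_marker_snps(tiny_pileup(sc, list(
    list(locus = "fba", position = 2L, base = "T", count = round(f2 * 1000),
         other = list(base = "G", count = round((1 - f2) * 1000))),
    list(locus = "fba", position = 0L, base = "G", count = round(f3 * 1000),
         other = list(base = "A", count = round((1 - f3) * 1000))))), mk)
  expect_warning(ab <- infer_allele_abundance(over(0.55, 0.50), sc),
                 "clamped")
  expect_equal(sum(ab$fba), 1, tolerance = 1e-9)
  expect_equal(unname(ab$fba["1"]), 0)
  expect_error(infer_allele_abundance(over(0.70, 0.45), sc),
               "grossly inconsistent")
})

test_that("ploidy encoding rounds half away from zero with off-by-one repair", {
  # plain case: 10% + 90%
  v <- encode_ploidy(c(`5` = 0.10, `2` = 0.90))
  expect_equal(sum(v == 5L), 10L)
  expect_equal(sum(v == 2L), 90L)
  expect_equal(length(v), 100L)

  # 101-copy repair: raw rounding gives 34+34+33; the first of the tied
  # most-abundant alleles (lowest ID) loses one copy
  v <- encode_ploidy(c(`1` = 0.335, `2` = 0.335, `3` = 0.33))
  expect_equal(as.integer(table(v)), c(33L, 34L, 33L))
  expect_equal(length(v), 100L)

  # 99-copy repair: a missing copy fills the locus
  v <- encode_ploidy(c(`1` = 0.994, `2` = 0.003, `3` = 0.003))
  expect_equal(sum(v == 1L, na.rm = TRUE), 99L)
  expect_equal(sum(is.na(v)), 1L)
  expect_equal(length(v), 100L)

  # degenerate single allele
  v <- encode_ploidy(c(`7` = 1))
  expect_equal(v, rep(7L, 100L))

  expect_error(encode_ploidy(c(`1` = -0.1, `2` = 1.1)), "negative")
})

test_that("encoding always returns exactly ploidy entries on random simplexes", {
  set.seed(5)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    x <- stats::rgamma(n, 1)
    x <- x / sum(x)
    names(x) <- sample(1:99, n)
    v <- encode_ploidy(x)
    expect_equal(length(v), 100L)
    # rounding error (0.5) plus at most one repair copy per allele
    got <- table(factor(v, levels = sort(as.integer(names(x)))))
    expect_true(max(abs(got - x[order(as.integer(names(x)))] * 100)) <= 1.5)
  }
})

test_that("learning strains encode as constant copy vectors", {
  sc <- tiny_scheme()
  pr <- validate_profiles(tiny_profiles(), sc)
  pp <- learning_profile_to_ploidy(pr[2, ], sc)
  expect_equal(pp$copies$fba, rep(2L, 100L))
  expect_equal(pp$copies$lac, rep(2L, 100L))
  expect_error(learning_profile_to_ploidy(pr[2, c("strain", "group", "fba")],
                                          sc),
               "missing locus")
})

test_that("pileups from synthetic alignments match the generating alleles", {
  fix <- syn_fixture()
  one <- fix$profiles[fix$profiles$group == "RT3", ][1, ]
  comm <- simulate_set_a("RT3", one, fix$scheme, seed = 3)
  sam <- withr::local_tempfile(fileext = ".sam")
  community_to_sam(comm, fix$profiles, fix$scheme, sam, depth = 20, seed = 4)
  pl <- pileup_from_alignments(sam, scheme_regions(fix$scheme))
  # single-strain community, error 0: every covered position is
  # monomorphic for that strain's allele base
  for (ln in scheme_loci(fix$scheme)) {
    seqc <- strsplit(fix$scheme$loci[[ln]]$alleles[[as.character(one[[ln]])]],
                     "")[[1]]
    sub <- pl[pl$locus == ln, ]
    expect_true(all(sub$depth > 0))
    for (b in c("A", "C", "G", "T"))
      expect_true(all(sub[[b]][seqc != b] == 0))
    hit <- vapply(seq_along(seqc), function(p) sub[[seqc[p]]][p],
                  integer(1))
    expect_equal(hit, sub$depth)
  }
})

test_that("partially covering reads leave zero depth elsewhere", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "half.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:fba\tLN:8",
               paste("r1", 0, "fba", 1, 60, "4M", "*", 0, 0,
                     "ACGT", "IIII", sep = "\t"),
               paste("r2", 0, "fba", 1, 60, "4M", "*", 0, 0,
                     "ACGT", "IIII", sep = "\t")),
             sam)
  regions <- data.frame(locus = "fba", ref = "fba", start = 0L, end = 8L)
  pl <- pileup_from_alignments(sam, regions)
  expect_equal(pl$depth, c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L))
  expect_equal(pl$A[1], 2L)
})

test_that("empty alignments warn and give all-zero pileups; bad regions error", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "empty.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:fba\tLN:8"), sam)
  regions <- data.frame(locus = "fba", ref = "fba", start = 0L, end = 8L)
  expect_warning(pl <- pileup_from_alignments(sam, regions), "all-zero")
  expect_true(all(pl$depth == 0L))
  bad <- data.frame(locus = "fba", ref = "fba", start = 0L, end = 99L)
  expect_error(pileup_from_alignments(sam, bad), "exceeds reference bounds")
  missing_ref <- data.frame(locus = "x", ref = "x", start = 0L, end = 4L)
  expect_error(pileup_from_alignments(sam, missing_ref), "not present")
})

test_that("pileup tables round-trip through TSV", {
  fix <- syn_fixture()
  comm <- simulate_set_a("RT1", fix$profiles, fix$scheme, seed = 1)
  pl <- community_to_pileup(comm, fix$profiles, fix$scheme, depth = 30,
                            seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pileup(pl, path)
  expect_equal(read_pileup(path), pl, ignore_attr = TRUE)
})

test_that("known mixtures are recovered through the full coverage pipeline", {
  # expectation-level pileups at depth 400 and zero error must yield
  # inferred abundances within 0.02 (L-infinity) of the generating allele
  # fractions; the conservative min-of-markers estimator only loses mass
  # to rounding here (depth 400 keeps a 1% allele above the 4-read floor)
  fix <- syn_fixture()
  set.seed(21)
  comm <- simulate_set_b(fix$profiles, fix$scheme, seed = 31)
  pl <- community_to_pileup(comm, fix$profiles, fix$scheme, depth = 400,
                            error_rate = 0, seed = 32, exact = TRUE)
  calls <- call_marker_snps(pl, fix$markers)
  ab <- infer_allele_abundance(calls, fix$scheme)
  idx <- match(comm$members$strain, fix$profiles$strain)
  for (ln in scheme_loci(fix$scheme)) {
    truth <- table(fix$profiles[[ln]][idx]) / nrow(comm$members)
    est <- ab[[ln]][names(truth)]
    expect_true(max(abs(est - as.numeric(truth))) < 0.02)
  }
})

test_that("STRUCTURE export writes ploidy rows with pop codes and -9 missing", {
  sc <- tiny_scheme()
  pr <- validate_profiles(tiny_profiles(), sc)
  pps <- lapply(1:2, function(i)
    learning_profile_to_ploidy(pr[i, ], sc, ploidy = 3L))
  test_pp <- ploidy_profile("t1", list(fba = c(1L, NA, 2L),
                                       lac = c(1L, 1L, 1L)), ploidy = 3L)
  path <- withr::local_tempfile(fileext = ".str")
  code <- write_structure(c(pps, list(test_pp)),
                          stats::setNames(pr$group, pr$strain), path)
  lines <- readLines(path)
  expect_equal(lines[1], "fba\tlac")
  expect_length(lines, 1L + 3L * 3L)
  expect_equal(lines[2], paste("s1", code[["gA"]], 1, 1, 1, sep = "\t"))
  t1 <- strsplit(lines[9], "\t")[[1]]
  expect_equal(t1[1:3], c("t1", "0", "0"))
  expect_true("-9" %in% strsplit(paste(lines[8:10], collapse = "\t"),
                                 "\t")[[1]])
})
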