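# Hand-built two-locus scheme used across unit tests.
# fba: allele 1 = ACGT (default), 2 = ACTT, 3 = GCGT
#   -> marker for 2: (2, T); for 3: (0, G)
# lac: allele 1 = AACC (default), 2 = ATCC
#   -> marker for 2: (1, T)
tiny_scheme <- function() {
  mlst_scheme(
    list(mlst_locus("fba", c(`1` = "ACGT", `2` = "ACTT", `3` = "GCGT")),
         mlst_locus("lac", c(`1` = "AACC", `2` = "ATCC"))),
    default_allele = c(fba = 1L, lac = 1L))
}

tiny_profiles <- function() {
  data.frame(strain = c("s1", "s2", "s3"),
             group = c("gA", "gB", "gC"),
             popflag = TRUE,
             fba = c(1L, 2L, 3L),
             lac = c(1L, 2L, 1L),
             stringsAsFactors = FALSE)
}

# Pileup with a single marker position set to the given count/depth and
# everything else monomorphic for the allele-1 bases.
tiny_pileup <- function(scheme, overrides = list()) {
  pl <- do.call(rbind, lapply(scheme_loci(scheme), function(ln) {
    ref <- strsplit(scheme$loci[[ln]]$alleles[["1"]], "")[[1L]]
    n <- length(ref)
    df <- data.frame(locus = ln, position = seq_len(n) - 1L,
                     A = 0L, C = 0L, G = 0L, T = 0L,
                     stringsAsFactors = FALSE)
    for (p in seq_len(n)) df[p, ref[p]] <- 100L
    df
  }))
  for (ov in overrides) {
    i <- which(pl$locus == ov$locus & pl$position == ov$position)
    pl[i, ov$base] <- ov$count
    if (!is.null(ov$other)) pl[i, ov$other$base] <- ov$other$count
  }
  pl$depth <- pl$A + pl$C + pl$G + pl$T
  pl
}

# Synthetic six-group scheme shared by the slower tests; built once per
# test session.
syn_env <- new.env()
syn_fixture <- function() {
  if (is.null(syn_env$fix)) {
    syn <- generate_synthetic_scheme(K = 6, L = 4, strains_per_group = 10,
                                     seed = 42)
    cur <- curate_learning_set(syn$profiles, syn$scheme)
    syn_env$fix <- list(scheme = syn$scheme, profiles = cur$profiles,
                        markers = derive_marker_snps(syn$scheme,
                                                     cur$profiles))
  }
  syn_env$fix
}

# MCMC settings small enough for unit tests but large enough to be stable
test_cfg <- function(seed = 1L, ...) {
  mcmc_config(burn_in = 500L, iterations = 3000L, n_runs = 3L,
              class_burn_in = 200L, class_iterations = 500L,
              seed = seed, ...)
}

expect_simplex <- function(q, tol = 1e-9) {
  expect_true(all(q >= -tol))
  expect_equal(sum(q), 1, tolerance = 1e-9)
}
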