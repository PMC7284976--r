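#' Generate a synthetic MLST scheme and learning set
#'
#' Builds a random but fully resolvable scheme emulating the structure of
#' a curated *P. acnes*-style learning set: K population groups, L loci,
#' equal-length random allele sequences, each group carrying a
#' group-distinctive allele at every locus, plus optional within-group
#' variant alleles. Every allele used by the learning set carries at least
#' `snp_divergence` private (position, base) pairs, so marker-SNP
#' derivation succeeds for all non-default alleles and curation removes
#' nothing.
#'
#' @param K Number of population groups (default 6; group labels follow
#'   the six major ribotype groups when `K <= 6`).
#' @param L Number of loci (default 4; named after the informative
#'   housekeeping genes for `L <= 8`).
#' @param strains_per_group Learning strains per group.
#' @param within_group_allele_diversity Number of alternative alleles per
#'   group (each placed at one random locus and carried by a minority of
#'   the group's strains).
#' @param snp_divergence Private mutated positions per allele (>= 1).
#' @param allele_length Aligned allele length in bases.
#' @param seed RNG seed; identical seeds give identical schemes.
#' @return List with `scheme` ([mlst_scheme()]) and `profiles` (validated
#'   learning data.frame, all `popflag = TRUE`).
#' @export
generate_synthetic_scheme <- function(K = 6L, L = 4L, strains_per_group = 10L,
                                      within_group_allele_diversity = 1L,
                                      snp_divergence = 2L,
                                      allele_length = 120L, seed = 1L) {
  stopifnot(K >= 1, L >= 1, strains_per_group >= 1, snp_divergence >= 1,
            within_group_allele_diversity >= 0)
  rt6 <- c("RT1", "RT2/6", "RT3", "RT4/5", "RT8", "RT1/IB-3")
  groups <- if (K <= 6L) rt6[seq_len(K)] else
    c(rt6, paste0("G", seq_len(K - 6L)))
  gene8 <- c("fba", "lac", "recA", "zno", "aroE", "guaA", "tly", "camp2")
  loci_names <- if (L <= 8L) gene8[seq_len(L)] else
    c(gene8, paste0("locus", seq_len(L - 8L)))

  n_variants <- K * within_group_allele_diversity
  max_alleles <- K + n_variants
  if (max_alleles * snp_divergence > allele_length)
    stop("infeasible spec: ", max_alleles, " alleles x ", snp_divergence,
         " private positions exceed allele length ", allele_length)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")

  # variant allele v of group k lives at one random locus
  var_owner <- rep(seq_len(K), each = within_group_allele_diversity)
  var_locus <- if (n_variants) sample(L, n_variants, replace = TRUE) else
    integer()

  loci <- vector("list", L)
  for (l in seq_len(L)) {
    ref <- sample(bases, allele_length, replace = TRUE)
    n_all <- K + sum(var_locus == l)
    pos_pool <- sample(allele_length, n_all * snp_divergence)
    seqs <- matrix(ref, nrow = n_all, ncol = allele_length, byrow = TRUE)
    for (a in seq_len(n_all)) {
      pos <- pos_pool[((a - 1L) * snp_divergence + 1L):(a * snp_divergence)]
      for (p in pos)
        seqs[a, p] <- sample(setdiff(bases, ref[p]), 1L)
    }
    alleles <- apply(seqs, 1L, paste, collapse = "")
    names(alleles) <- seq_len(n_all)
    loci[[l]] <- mlst_locus(loci_names[l], alleles)
  }

  # allele IDs: group k's primary allele is k at every locus; variant
  # alleles take IDs K+1, ... in order at their locus
  var_id <- integer(n_variants)
  if (n_variants) {
    for (l in seq_len(L)) {
      vs <- which(var_locus == l)
      var_id[vs] <- K + seq_along(vs)
    }
  }

  profiles <- do.call(rbind, lapply(seq_len(K), function(k) {
    prof <- matrix(k, nrow = strains_per_group, ncol = L,
                   dimnames = list(NULL, loci_names))
    vs <- which(var_owner == k)
    for (v in vs) {
      # a minority of the group's strains carry the variant, so the
      # per-locus majority consensus stays at the primary allele
      n_carry <- max(1L, strains_per_group %/% 3L)
      if (n_carry >= (strains_per_group + 1L) %/% 2L)
        n_carry <- max(0L, (strains_per_group - 1L) %/% 2L)
      if (n_carry > 0L) {
        carriers <- sample(strains_per_group, n_carry)
        prof[carriers, var_locus[v]] <- var_id[v]
      }
    }
    df <- data.frame(
      strain = sprintf("%s_S%02d", gsub("[/-]", "", groups[k]),
                       seq_len(strains_per_group)),
      group = groups[k], popflag = TRUE, stringsAsFactors = FALSE)
    cbind(df, as.data.frame(prof))
  }))
  rownames(profiles) <- NULL

  scheme <- mlst_scheme(
    loci,
    stats::setNames(rep(1L, L), loci_names),  # group 1's allele plays the
    stats::setNames(groups, groups))          # default "RT1 allele" role
  list(scheme = scheme, profiles = validate_profiles(profiles, scheme))
}

strains_by_reporting_group <- function(learning, merge_map) {
  rep_of <- merge_map[learning$group]
  if (anyNA(rep_of))
    stop("merge map lacks group(s): ",
         paste(unique(learning$group[is.na(rep_of)]), collapse = ", "))
  split(learning$strain, unname(rep_of))
}

new_community <- function(members, missing, expected, targets, seed) {
  structure(list(members = members, missing = missing,
                 expected = expected, targets = targets, seed = seed),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat(sprintf("<sim_community> %d members + %d missing; expected: %s\n",
              nrow(x$members), x$missing,
              paste(sprintf("%s=%.2f", names(x$expected), x$expected),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate a community with fixed target composition
#'
#' Constructs a 100-member community whose reporting-group membership
#' counts follow `targets`: counts are the half-up-rounded target
#' fractions with the off-by-one repair (99 members gain one missing
#' member; 101 members lose one from the most abundant group), and
#' members are drawn uniformly with replacement from each reporting
#' group's learning strains. `expected` records the realized counts as
#' fractions.
#'
#' @param targets Named fraction vector over reporting groups, summing
#'   to 1.
#' @param learning Validated learning profile data.frame.
#' @param scheme An [mlst_scheme()] (its merge map defines reporting
#'   groups; identity where empty).
#' @param seed RNG seed.
#' @param size Community size (default 100).
#' @return A `sim_community`: `members` (data.frame `member`, `strain`,
#'   `group`), `missing` (0 or 1), `expected` (named fractions), `targets`,
#'   `seed`.
#' @export
simulate_community <- function(targets, learning, scheme, seed,
                               size = 100L) {
  stopifnot(abs(sum(targets) - 1) < 1e-6, all(targets >= 0))
  merge_map <- scheme$merge_map
  if (!length(merge_map)) {
    g <- sort(unique(learning$group))
    merge_map <- stats::setNames(g, g)
  }
  pool <- strains_by_reporting_group(learning, merge_map)
  unknown <- setdiff(names(targets), names(pool))
  if (length(unknown))
    stop("unknown reporting group(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  targets <- targets[order(names(targets))]
  ap <- apportion_counts(targets, size, tie_order = seq_along(targets))
  counts <- ap$counts
  members <- do.call(rbind, lapply(names(counts)[counts > 0L], function(g)
    data.frame(strain = sample(pool[[g]], counts[[g]], replace = TRUE),
               group = g, stringsAsFactors = FALSE)))
  members <- members[sample(nrow(members)), , drop = FALSE]
  members <- data.frame(member = seq_len(nrow(members)), members,
                        row.names = NULL, stringsAsFactors = FALSE)
  expected <- counts / sum(counts)
  new_community(members, ap$missing, expected[expected >= 0], targets, seed)
}

#' Simulate a Set A community: a single group (or close pair)
#'
#' Set A communities contain only one ribotype group, or a stated pair of
#' closely related groups in equal parts; the expected composition is
#' concentrated on the corresponding reporting group(s).
#'
#' @param groups One or two reporting group labels.
#' @param learning,scheme,seed,size As in [simulate_community()].
#' @return A `sim_community`.
#' @export
simulate_set_a <- function(groups, learning, scheme, seed, size = 100L) {
  stopifnot(length(groups) %in% 1:2)
  targets <- stats::setNames(rep(1 / length(groups), length(groups)), groups)
  simulate_community(targets, learning, scheme, seed, size)
}

#' Simulate a Set B community: random composition
#'
#' Target fractions are drawn from a flat Dirichlet over the reporting
#' groups (maximal-entropy reading of "randomly generated"), then realized
#' as in [simulate_community()].
#'
#' @param learning,scheme,seed,size As in [simulate_community()].
#' @return A `sim_community`.
#' @export
simulate_set_b <- function(learning, scheme, seed, size = 100L) {
  merge_map <- scheme$merge_map
  groups <- if (length(merge_map)) sort(unique(unname(merge_map))) else
    sort(unique(learning$group))
  if (length(groups) < 2L) stop("Set B needs at least two reporting groups")
  set.seed(seed)
  g <- stats::rgamma(length(groups), 1)
  targets <- stats::setNames(g / sum(g), groups)
  simulate_community(targets, learning, scheme, seed = seed + 1L, size)
}

#' Simulate Set C communities: clinically shaped compositions
#'
#' Set C mirrors compositions observed in skin-microbiome samples: one
#' dominant group with several minor groups. Targets are supplied
#' explicitly (e.g. from [setc_targets()]).
#'
#' @param target_list List of named fraction vectors, each summing to 1.
#' @param learning,scheme,seed,size As in [simulate_community()].
#' @return List of `sim_community` objects.
#' @export
simulate_set_c <- function(target_list, learning, scheme, seed, size = 100L) {
  stopifnot(is.list(target_list), length(target_list) >= 1L)
  lapply(seq_along(target_list), function(i)
    simulate_community(target_list[[i]], learning, scheme,
                       seed = seed + i, size))
}

#' Packaged synthetic Set C target compositions
#'
#' Representative clinically shaped target vectors (dominant group at
#' 0.5-0.9 relative abundance plus minor groups) over the default
#' six-group labels. These are synthetic stand-ins shipped with the
#' package, not measured clinical compositions.
#'
#' @return Named list of named fraction vectors.
#' @export
setc_targets <- function() {
  path <- system.file("extdata", "setc_synthetic_targets.tsv",
                      package = "mgmlst", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$community), function(d)
    stats::setNames(d$fraction, d$group))
  out[order(names(out))]
}

#' Ploidy profile of a simulated community
#'
#' Each of the community's members contributes one allele copy per locus
#' (its strain's allele); a missing member contributes a missing copy at
#' every locus. The result is the exact ploidy-`size` profile the
#' admixture model consumes.
#'
#' @param community A `sim_community`.
#' @param learning Learning profile data.frame (source of member alleles).
#' @param scheme An [mlst_scheme()].
#' @param sample Sample name for the profile.
#' @return A [ploidy_profile()].
#' @export
community_to_profile <- function(community, learning, scheme,
                                 sample = "community") {
  idx <- match(community$members$strain, learning$strain)
  if (anyNA(idx))
    stop("community references strain(s) absent from the learning set: ",
         paste(unique(community$members$strain[is.na(idx)]), collapse = ", "))
  copies <- lapply(scheme_loci(scheme), function(ln)
    c(learning[[ln]][idx], rep(NA_integer_, community$missing)))
  names(copies) <- scheme_loci(scheme)
  ploidy_profile(sample, copies,
                 ploidy = nrow(community$members) + community$missing)
}

community_base_freqs <- function(community, learning, scheme) {
  idx <- match(community$members$strain, learning$strain)
  lapply(scheme_loci(scheme), function(ln) {
    loc <- scheme$loci[[ln]]
    av <- learning[[ln]][idx]
    tab <- table(av) / length(av)
    mat <- matrix(0, nrow = 4L, ncol = loc$aligned_length,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (a in names(tab)) {
      s <- strsplit(loc$alleles[[a]], "")[[1L]]
      for (b in c("A", "C", "G", "T"))
        mat[b, ] <- mat[b, ] + as.numeric(tab[[a]]) * (s == b)
    }
    mat
  }) |> stats::setNames(scheme_loci(scheme))
}

#' Synthesize a pileup from a simulated community
#'
#' Per locus position, read depth is Poisson(`depth`) and each read base
#' is drawn from the member-weighted allele base distribution, perturbed
#' by a uniform substitution error: with probability `error_rate` the true
#' base is replaced by one of the three other bases. At `error_rate = 0`
#' and large depth, base frequencies converge to the member allele
#' fractions.
#'
#' @param community A `sim_community`.
#' @param learning Learning profile data.frame.
#' @param scheme An [mlst_scheme()].
#' @param depth Mean per-position coverage.
#' @param error_rate Per-base substitution error in `[0, 0.25)`.
#' @param seed RNG seed.
#' @param exact Emit expected counts (`round(freq * depth)`) instead of
#'   Poisson/multinomial sampling; useful for exactness checks.
#' @return A pileup data.frame (`locus position A C G T depth`).
#' @export
community_to_pileup <- function(community, learning, scheme, depth = 50,
                                error_rate = 0, seed = 1L, exact = FALSE) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.25)
  set.seed(seed)
  bf <- community_base_freqs(community, learning, scheme)
  out <- list()
  for (ln in names(bf)) {
    f <- bf[[ln]]
    # substitution error mixes each base's mass uniformly into the others
    ef <- (1 - error_rate) * f +
      (error_rate / 3) * (matrix(rep(colSums(f), each = 4L), nrow = 4L) - f)
    n <- ncol(f)
    d <- if (exact) rep(as.integer(depth), n) else stats::rpois(n, depth)
    cnt <- vapply(seq_len(n), function(p) {
      if (d[p] == 0L) return(c(A = 0L, C = 0L, G = 0L, T = 0L))
      v <- if (exact) as.integer(round(ef[, p] * d[p]))
           else as.integer(stats::rmultinom(1L, d[p], ef[, p]))
      stats::setNames(v, c("A", "C", "G", "T"))
    }, integer(4L))
    out[[ln]] <- data.frame(locus = ln, position = seq_len(n) - 1L,
                            A = cnt["A", ], C = cnt["C", ], G = cnt["G", ],
                            T = cnt["T", ], depth = colSums(cnt),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a synthetic SAM file for a simulated community
#'
#' Emits full-length reads (one locus-spanning read per draw) aligned to a
#' per-locus reference whose sequence is the locus's default allele. Each
#' read's sequence is a member's allele, optionally perturbed by a uniform
#' substitution error. This exercises the SAM/BAM pileup path end to end.
#'
#' @param community A `sim_community`.
#' @param learning Learning profile data.frame.
#' @param scheme An [mlst_scheme()].
#' @param path Output SAM path.
#' @param depth Reads per locus (Poisson mean).
#' @param error_rate Per-base substitution error.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
community_to_sam <- function(community, learning, scheme, path,
                             depth = 50, error_rate = 0, seed = 1L) {
  set.seed(seed)
  idx <- match(community$members$strain, learning$strain)
  bases <- c("A", "C", "G", "T")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ln in scheme_loci(scheme))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ln,
                       scheme$loci[[ln]]$aligned_length), con)
  rid <- 0L
  for (ln in scheme_loci(scheme)) {
    loc <- scheme$loci[[ln]]
    n_reads <- stats::rpois(1L, depth)
    if (n_reads == 0L) next
    av <- learning[[ln]][idx]
    picks <- sample(av, n_reads, replace = TRUE)
    for (a in picks) {
      s <- strsplit(loc$alleles[[as.character(a)]], "")[[1L]]
      if (error_rate > 0) {
        hit <- stats::runif(length(s)) < error_rate
        if (any(hit))
          s[hit] <- vapply(s[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
      }
      rid <- rid + 1L
      writeLines(paste(sprintf("read%06d", rid), 0L, ln, 1L, 60L,
                       paste0(length(s), "M"), "*", 0L, 0L,
                       paste(s, collapse = ""),
                       paste(rep("I", length(s)), collapse = ""),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write community manifest and ground truth tables
#'
#' Manifest dialect: `community member_index strain group`; ground truth:
#' `community group expected_fraction`.
#'
#' @param communities Named list of `sim_community` objects.
#' @param manifest_path,truth_path Output paths (either may be `NULL`).
#' @return Invisibly, list of written paths.
#' @export
write_communities <- function(communities, manifest_path = NULL,
                              truth_path = NULL) {
  nm <- names(communities) %||% as.character(seq_along(communities))
  if (!is.null(manifest_path)) {
    man <- do.call(rbind, lapply(seq_along(communities), function(i)
      data.frame(community = nm[i],
                 member_index = communities[[i]]$members$member,
                 strain = communities[[i]]$members$strain,
                 group = communities[[i]]$members$group,
                 stringsAsFactors = FALSE)))
    utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(truth_path)) {
    tr <- do.call(rbind, lapply(seq_along(communities), function(i)
      data.frame(community = nm[i],
                 group = names(communities[[i]]$expected),
                 expected_fraction = unname(communities[[i]]$expected),
                 stringsAsFactors = FALSE)))
    utils::write.table(tr, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(manifest = manifest_path, truth = truth_path))
}
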