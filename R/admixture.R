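#' MCMC configuration for supervised admixture inference
#'
#' Defaults mirror the production run configuration: 25,000 burn-in sweeps
#' followed by 125,000 retained sweeps, at least 20 accepted runs per
#' sample, run acceptance requiring at least 80% of learning strains to be
#' re-assigned to their labelled population.
#'
#' @param burn_in Discarded initial sweeps.
#' @param iterations Retained post-burn-in sweeps.
#' @param n_runs Accepted runs to collect per sample set.
#' @param max_attempts Cap on total runs attempted before erroring.
#' @param lambda Dirichlet pseudocount on population allele frequencies.
#' @param alpha Admixture Dirichlet concentration for q; `NULL` means
#'   `1/K`, resolved when the group count is known.
#' @param update_alpha Metropolis-update a common alpha under a
#'   Uniform(0, `alpha_max`] prior instead of fixing it.
#' @param alpha_max Upper bound of the alpha prior.
#' @param alpha_prop_sd Proposal s.d. of the alpha Metropolis step.
#' @param sample_freqs Sample population allele frequencies each sweep
#'   (default); `FALSE` fixes them at their posterior means given the
#'   learning counts (fast mode).
#' @param accept_threshold Minimum learning-set re-assignment accuracy for
#'   a run to be accepted (strict complement of "more than 20%
#'   misassigned").
#' @param class_burn_in,class_iterations Sweeps used when re-classifying
#'   each learning strain for run acceptance; `NULL` defaults to a tenth
#'   of the main settings (at least 200 / 500).
#' @param aggregate How accepted runs are combined: `"mean"` (default) or
#'   `"median"`.
#' @param seed Base RNG seed; run i uses `seed + i`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(burn_in = 25000L, iterations = 125000L,
                        n_runs = 20L, max_attempts = 100L,
                        lambda = 1, alpha = NULL,
                        update_alpha = FALSE, alpha_max = 10,
                        alpha_prop_sd = 0.05,
                        sample_freqs = TRUE,
                        accept_threshold = 0.8,
                        class_burn_in = NULL, class_iterations = NULL,
                        aggregate = c("mean", "median"),
                        seed = 1L) {
  stopifnot(burn_in >= 0, iterations > 0, n_runs >= 1, lambda >= 0,
            accept_threshold >= 0, accept_threshold <= 1)
  if (iterations < 100L)
    warning("fewer than 100 retained sweeps; diagnostics will be unreliable")
  structure(list(
    burn_in = as.integer(burn_in), iterations = as.integer(iterations),
    n_runs = as.integer(n_runs), max_attempts = as.integer(max_attempts),
    lambda = lambda, alpha = alpha,
    update_alpha = isTRUE(update_alpha), alpha_max = alpha_max,
    alpha_prop_sd = alpha_prop_sd,
    sample_freqs = isTRUE(sample_freqs),
    accept_threshold = accept_threshold,
    class_burn_in = as.integer(class_burn_in %||% max(200L, burn_in %/% 10L)),
    class_iterations = as.integer(class_iterations %||%
                                    max(500L, iterations %/% 10L)),
    aggregate = match.arg(aggregate),
    seed = as.integer(seed)), class = "mcmc_config")
}

resolve_alpha <- function(cfg, K) {
  a <- cfg$alpha %||% (1 / K)
  if (length(a) == 1L) a <- rep(a, K)
  stopifnot(length(a) == K, all(a > 0))
  a
}

#' Count learning allele copies per population group
#'
#' Tallies `n[k][l][j]`, the number of learning allele copies of allele j
#' at locus l contributed by group k. Each learning strain contributes
#' `ploidy` copies of its allele per locus; missing copies contribute
#' nothing. These counts are the sole source of population allele
#' frequencies: test samples never update them.
#'
#' @param learning Either a validated learning profile data.frame (each
#'   strain expanded to `ploidy` copies) or a list of [ploidy_profile()]
#'   objects with a parallel `groups` character vector.
#' @param scheme An [mlst_scheme()].
#' @param groups Group label per profile when `learning` is a list of
#'   ploidy profiles.
#' @param ploidy Copies per strain per locus for the data.frame form.
#' @return An object of class `pop_freqs`: list with `counts` (per locus,
#'   K x J matrices with group/allele dimnames), `groups`, `loci`,
#'   `alleles` (per-locus catalogue IDs).
#' @export
count_learning_alleles <- function(learning, scheme, groups = NULL,
                                   ploidy = 100L) {
  loci <- scheme_loci(scheme)
  alleles <- lapply(scheme$loci, allele_ids)
  if (is.data.frame(learning)) {
    learn <- learning[learning$popflag %||% TRUE, , drop = FALSE]
    if (!nrow(learn)) stop("empty learning set")
    glab <- learn$group
    copies_of <- function(ln) {
      v <- lapply(learn[[ln]], function(a) rep(a, ploidy))
      v
    }
    per_strain <- lapply(loci, copies_of)
    names(per_strain) <- loci
  } else {
    stopifnot(is.list(learning), length(learning) >= 1L,
              !is.null(groups), length(groups) == length(learning))
    glab <- as.character(groups)
    per_strain <- lapply(loci, function(ln)
      lapply(learning, function(pp) pp$copies[[ln]]))
    names(per_strain) <- loci
  }
  gl <- sort(unique(glab))
  if (any(!nzchar(gl))) stop("empty group label in learning set")
  counts <- lapply(loci, function(ln) {
    J <- length(alleles[[ln]])
    mat <- matrix(0, nrow = length(gl), ncol = J,
                  dimnames = list(gl, alleles[[ln]]))
    for (i in seq_along(per_strain[[ln]])) {
      v <- per_strain[[ln]][[i]]
      v <- v[!is.na(v)]
      if (!length(v)) next
      bad <- setdiff(unique(v), alleles[[ln]])
      if (length(bad))
        stop("learning copies use allele ", bad[1L],
             " absent from locus '", ln, "'")
      tab <- table(factor(v, levels = alleles[[ln]]))
      mat[glab[i], ] <- mat[glab[i], ] + as.numeric(tab)
    }
    mat
  })
  names(counts) <- loci
  if (any(vapply(counts, function(m) any(rowSums(m) == 0), logical(1))))
    stop("a group contributes no learning copies at some locus")
  structure(list(counts = counts, groups = gl, loci = loci,
                 alleles = alleles),
            class = "pop_freqs")
}

#' @export
print.pop_freqs <- function(x, ...) {
  cat(sprintf("<pop_freqs> %d groups x %d loci (%s copies/group median)\n",
              length(x$groups), length(x$loci),
              format(stats::median(vapply(x$counts, sum, numeric(1)) /
                                     length(x$groups)))))
  invisible(x)
}

sample_allele_counts <- function(sample, freqs) {
  lapply(freqs$loci, function(ln) {
    v <- sample$copies[[ln]]
    if (is.null(v)) stop("sample '", sample$sample,
                         "' has no copies at locus '", ln, "'")
    v <- v[!is.na(v)]
    bad <- setdiff(unique(v), freqs$alleles[[ln]])
    if (length(bad))
      stop("sample '", sample$sample, "' carries allele ", bad[1L],
           " absent from the catalogue at locus '", ln, "'")
    as.integer(table(factor(v, levels = freqs$alleles[[ln]])))
  })
}

#' Supervised admixture Gibbs inference for one sample
#'
#' Estimates the posterior-mean mixture proportions q of a ploidy-encoded
#' sample over the learning set's population groups. Population allele
#' frequencies are drawn from Dirichlet(lambda + learning counts) each
#' sweep (or fixed at their posterior means / at `fixed_freqs`), allele
#' copies are assigned to groups proportionally to `q_k * p_klj`, and q is
#' redrawn from Dirichlet(alpha + assignment counts).
#'
#' @param sample A [ploidy_profile()].
#' @param freqs Learning counts from [count_learning_alleles()].
#' @param cfg An [mcmc_config()].
#' @param fixed_freqs Optional per-locus K x J matrices of fixed
#'   population allele frequencies (rows in `freqs$groups` order); implies
#'   no frequency sampling.
#' @return List with `q` (named posterior mean), `mc_se` (batch-means
#'   Monte-Carlo s.e. per component), `alpha_mean`, `n_kept`.
#' @export
gibbs_infer <- function(sample, freqs, cfg = mcmc_config(),
                        fixed_freqs = NULL) {
  stopifnot(inherits(sample, "ploidy_profile"), inherits(freqs, "pop_freqs"))
  K <- length(freqs$groups)
  cs <- sample_allele_counts(sample, freqs)
  res <- .gibbs_admixture_cpp(
    cs, unname(freqs$counts), cfg$lambda, resolve_alpha(cfg, K),
    cfg$burn_in, cfg$iterations,
    if (is.null(fixed_freqs)) cfg$sample_freqs else FALSE,
    if (is.null(fixed_freqs)) NULL else lapply(fixed_freqs, unname),
    cfg$update_alpha, cfg$alpha_max, cfg$alpha_prop_sd,
    freqs$loci)
  list(q = stats::setNames(res$q_mean, freqs$groups),
       mc_se = stats::setNames(res$q_se, freqs$groups),
       alpha_mean = res$alpha_mean,
       n_kept = res$n_kept)
}

#' Re-classify the learning set and compute run acceptance accuracy
#'
#' Each learning strain is re-inferred as if it were a test sample, with
#' its own copies left out of the learning counts, and is correctly
#' assigned when the argmax of its posterior-mean q equals its label. A
#' run is accepted when the accuracy is at least `cfg$accept_threshold`
#' (i.e. NOT more than 20% misassigned at the default).
#'
#' @param freqs Learning counts from [count_learning_alleles()].
#' @param learning Validated learning profile data.frame.
#' @param scheme An [mlst_scheme()].
#' @param cfg An [mcmc_config()]; classification uses the (shorter)
#'   `class_burn_in` / `class_iterations` settings.
#' @param ploidy Copies per strain per locus.
#' @return List with `accuracy`, `accepted`, and `assignments`
#'   (data.frame `strain`, `group`, `assigned`, `correct`).
#' @export
classify_learning <- function(freqs, learning, scheme, cfg = mcmc_config(),
                              ploidy = 100L) {
  learn <- learning[learning$popflag %||% TRUE, , drop = FALSE]
  if (!nrow(learn)) stop("empty learning set")
  ccfg <- cfg
  ccfg$burn_in <- cfg$class_burn_in
  ccfg$iterations <- cfg$class_iterations
  assigned <- character(nrow(learn))
  for (i in seq_len(nrow(learn))) {
    pp <- learning_profile_to_ploidy(learn[i, , drop = FALSE], scheme, ploidy)
    loo <- freqs
    for (ln in freqs$loci) {
      v <- pp$copies[[ln]]
      v <- v[!is.na(v)]
      tab <- table(factor(v, levels = freqs$alleles[[ln]]))
      loo$counts[[ln]][learn$group[i], ] <-
        pmax(0, loo$counts[[ln]][learn$group[i], ] - as.numeric(tab))
    }
    q <- gibbs_infer(pp, loo, ccfg)$q
    assigned[i] <- names(q)[which.max(q)]
  }
  correct <- assigned == learn$group
  acc <- mean(correct)
  list(accuracy = acc,
       accepted = run_accepted(acc, cfg$accept_threshold),
       assignments = data.frame(strain = learn$strain, group = learn$group,
                                assigned = assigned, correct = correct,
                                stringsAsFactors = FALSE))
}

#' Run-acceptance rule
#'
#' A run is accepted when the learning set is properly predicted: the
#' fraction of learning strains assigned to their pre-defined population
#' is at least `threshold` (default 0.8, the strict complement of "more
#' than 20% misassigned").
#'
#' @param accuracy Fraction of learning strains correctly re-assigned.
#' @param threshold Acceptance threshold.
#' @return Logical.
#' @export
run_accepted <- function(accuracy, threshold = 0.8) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  accuracy >= threshold
}

#' Merge population groups to reporting groups
#'
#' Population groups derived from a single ribotype (e.g. the clade IA-1
#' and clade IB-3 groups of RT1) are combined for reporting by summing
#' their proportions; the simplex is preserved.
#'
#' @param q Named proportion vector over population groups.
#' @param merge_map Named character vector mapping each group to its
#'   reporting label.
#' @return Named proportion vector over reporting groups.
#' @export
merge_groups <- function(q, merge_map) {
  miss <- setdiff(names(q), names(merge_map))
  if (length(miss))
    stop("merge map lacks group(s): ", paste(miss, collapse = ", "))
  tgt <- merge_map[names(q)]
  out <- tapply(q, tgt, sum)
  stats::setNames(as.numeric(out), names(out))[unique(unname(tgt))]
}

#' Full admixture pipeline over samples: repeated runs, acceptance, merging
#'
#' Launches MCMC runs with seeds `cfg$seed + i` until `cfg$n_runs` runs
#' pass the learning-set acceptance rule (capped at `cfg$max_attempts`
#' attempts). Each accepted run infers q for every sample; per-sample
#' results are aggregated (arithmetic mean by default) and merged to
#' reporting groups via the scheme's merge map (identity where absent).
#'
#' @param samples List of [ploidy_profile()] objects (test samples).
#' @param learning Validated learning profile data.frame.
#' @param scheme An [mlst_scheme()].
#' @param cfg An [mcmc_config()].
#' @param ploidy Learning copies per strain per locus.
#' @return Object of class `mgmlst_result`: list with `q_mean` and
#'   `q_merged` (samples x groups matrices), `mc_se` (s.e. of the
#'   across-run mean), `n_runs_used`, `diagnostics` (per-attempt
#'   data.frame `run`, `seed`, `learning_accuracy`, `accepted`).
#' @export
run_mgmlst <- function(samples, learning, scheme, cfg = mcmc_config(),
                       ploidy = 100L) {
  stopifnot(length(samples) >= 1L)
  if (inherits(samples, "ploidy_profile")) samples <- list(samples)
  freqs <- count_learning_alleles(learning, scheme, ploidy = ploidy)
  K <- length(freqs$groups)
  snames <- vapply(samples, `[[`, character(1), "sample")
  merge_map <- scheme$merge_map
  if (!length(merge_map))
    merge_map <- stats::setNames(freqs$groups, freqs$groups)

  qs <- list()   # accepted runs: list of samples x K matrices
  diag <- data.frame(run = integer(), seed = integer(),
                     learning_accuracy = numeric(), accepted = logical())
  attempt <- 0L
  while (length(qs) < cfg$n_runs && attempt < cfg$max_attempts) {
    attempt <- attempt + 1L
    run_seed <- cfg$seed + attempt
    set.seed(run_seed)
    cl <- classify_learning(freqs, learning, scheme, cfg, ploidy)
    diag <- rbind(diag, data.frame(run = attempt, seed = run_seed,
                                   learning_accuracy = cl$accuracy,
                                   accepted = cl$accepted))
    if (!cl$accepted) next
    qmat <- matrix(NA_real_, nrow = length(samples), ncol = K,
                   dimnames = list(snames, freqs$groups))
    for (s in seq_along(samples))
      qmat[s, ] <- gibbs_infer(samples[[s]], freqs, cfg)$q
    qs[[length(qs) + 1L]] <- qmat
  }
  if (length(qs) < cfg$n_runs)
    stop("only ", length(qs), " of the required ", cfg$n_runs,
         " runs were accepted within ", cfg$max_attempts,
         " attempts; inspect diagnostics:\n",
         paste(utils::capture.output(print(diag)), collapse = "\n"))

  arr <- simplify2array(qs)  # samples x K x runs
  if (length(samples) == 1L && is.matrix(arr))
    arr <- array(arr, dim = c(1L, K, length(qs)),
                 dimnames = list(snames, freqs$groups, NULL))
  q_mean <- if (cfg$aggregate == "median") apply(arr, c(1, 2), stats::median)
            else apply(arr, c(1, 2), mean)
  q_mean <- q_mean / rowSums(q_mean)
  mc_se <- apply(arr, c(1, 2), stats::sd) / sqrt(length(qs))
  q_merged <- do.call(rbind, lapply(seq_len(nrow(q_mean)), function(i)
    merge_groups(q_mean[i, ], merge_map)))
  rownames(q_merged) <- rownames(q_mean)
  structure(list(q_mean = q_mean, q_merged = q_merged, mc_se = mc_se,
                 n_runs_used = length(qs), diagnostics = diag,
                 groups = freqs$groups,
                 reporting_groups = colnames(q_merged)),
            class = "mgmlst_result")
}

#' @export
print.mgmlst_result <- function(x, ...) {
  cat(sprintf("<mgmlst_result> %d sample(s), %d runs used\n",
              nrow(x$q_mean), x$n_runs_used))
  print(round(x$q_merged, 3))
  invisible(x)
}

#' Write admixture results as TSV
#'
#' Dialect: `sample group proportion mc_se n_runs` with header; reporting
#' (merged) groups by default.
#'
#' @param result An `mgmlst_result` from [run_mgmlst()].
#' @param path File path.
#' @param merged Write merged reporting groups (default) or raw groups.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, merged = TRUE) {
  q <- if (merged) result$q_merged else result$q_mean
  rows <- do.call(rbind, lapply(rownames(q), function(s) {
    se <- if (!merged) result$mc_se[s, colnames(q)] else NA_real_
    data.frame(sample = s, group = colnames(q), proportion = q[s, ],
               mc_se = se, n_runs = result$n_runs_used,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
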