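#' @useDynLib mgmlst, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct an MLST locus
#'
#' A locus holds the allele catalogue of one typing gene: a set of
#' pre-aligned, equal-length nucleotide sequences identified by integer
#' allele IDs (PubMLST convention).
#'
#' @param name Locus name (e.g. `"fba"`).
#' @param alleles Named character vector of nucleotide sequences over
#'   `A,C,G,T,N`; names are the integer allele IDs.
#' @return An object of class `mlst_locus`.
#' @export
mlst_locus <- function(name, alleles) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ids <- names(alleles)
  alleles <- stats::setNames(toupper(as.character(alleles)), ids)
  if (is.null(ids) || anyNA(suppressWarnings(as.integer(ids))))
    stop("allele IDs at locus '", name, "' must be integers (vector names)")
  ids <- as.integer(ids)
  if (anyDuplicated(ids))
    stop("duplicate allele IDs at locus '", name, "'")
  lens <- nchar(alleles)
  if (length(unique(lens)) != 1L)
    stop("alleles at locus '", name, "' have unequal lengths; ",
         "pre-aligned equal-length alleles are required")
  if (any(grepl("[^ACGTN]", alleles)))
    stop("alleles at locus '", name, "' contain characters outside A,C,G,T,N")
  o <- order(ids)
  structure(list(name = name,
                 alleles = stats::setNames(unname(alleles[o]), ids[o]),
                 aligned_length = unname(lens[1L])),
            class = "mlst_locus")
}

#' @export
print.mlst_locus <- function(x, ...) {
  cat(sprintf("<mlst_locus> %s: %d alleles, aligned length %d bp\n",
              x$name, length(x$alleles), x$aligned_length))
  invisible(x)
}

allele_ids <- function(locus) as.integer(names(locus$alleles))

#' Construct an MLST scheme
#'
#' @param loci List of [mlst_locus()] objects.
#' @param default_allele Named integer vector, one entry per locus: the
#'   allele to which coverage not explained by marker SNPs is attributed
#'   (the "RT1 allele" role in *P. acnes* schemes).
#' @param merge_map Named character vector mapping each population group
#'   label used by the learning set to a reporting group label (groups
#'   derived from a single ribotype are combined for reporting). May be
#'   extended lazily; must be total over groups when inference runs.
#' @return An object of class `mlst_scheme`.
#' @export
mlst_scheme <- function(loci, default_allele, merge_map = character()) {
  stopifnot(is.list(loci), length(loci) >= 1L)
  if (!all(vapply(loci, inherits, logical(1), "mlst_locus")))
    stop("loci must be a list of mlst_locus objects")
  names(loci) <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(names(loci))) stop("duplicate locus names")
  default_allele <- vapply(default_allele, as.integer, integer(1))
  if (!setequal(names(default_allele), names(loci)))
    stop("default_allele must name every locus exactly once")
  for (ln in names(loci)) {
    if (!default_allele[[ln]] %in% allele_ids(loci[[ln]]))
      stop("default allele ", default_allele[[ln]],
           " does not exist at locus '", ln, "'")
  }
  merge_map <- vapply(merge_map, as.character, character(1))
  structure(list(loci = loci,
                 default_allele = default_allele[names(loci)],
                 merge_map = merge_map),
            class = "mlst_scheme")
}

#' @export
print.mlst_scheme <- function(x, ...) {
  cat(sprintf("<mlst_scheme> %d loci: %s\n", length(x$loci),
              paste(names(x$loci), collapse = ", ")))
  cat(sprintf("  alleles per locus: %s\n",
              paste(vapply(x$loci, function(l) length(l$alleles), integer(1)),
                    collapse = ", ")))
  if (length(x$merge_map))
    cat(sprintf("  reporting groups: %s\n",
                paste(unique(x$merge_map), collapse = ", ")))
  invisible(x)
}

scheme_loci <- function(scheme) names(scheme$loci)

#' Validate a strain profile table against a scheme
#'
#' A profile table has one row per reference strain with columns `strain`,
#' `group`, optionally `popflag`, and one integer allele ID per scheme
#' locus. `popflag = TRUE` marks learning samples whose labels train the
#' admixture model.
#'
#' @param profiles A data.frame as described above.
#' @param scheme An [mlst_scheme()].
#' @return The validated (type-normalized) data.frame.
#' @export
validate_profiles <- function(profiles, scheme) {
  stopifnot(is.data.frame(profiles))
  need <- c("strain", "group", scheme_loci(scheme))
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("profile table is missing columns: ", paste(miss, collapse = ", "))
  if (!"popflag" %in% names(profiles)) profiles$popflag <- TRUE
  profiles$popflag <- as.logical(profiles$popflag)
  profiles$strain <- as.character(profiles$strain)
  profiles$group <- as.character(profiles$group)
  if (anyDuplicated(profiles$strain)) stop("duplicate strain names")
  if (any(profiles$popflag & !nzchar(profiles$group)))
    stop("learning samples (popflag = TRUE) must carry a non-empty group label")
  for (ln in scheme_loci(scheme)) {
    profiles[[ln]] <- as.integer(profiles[[ln]])
    if (anyNA(profiles[[ln]]))
      stop("missing allele ID at locus '", ln, "'")
    bad <- !profiles[[ln]] %in% allele_ids(scheme$loci[[ln]])
    if (any(bad))
      stop("strain '", profiles$strain[which(bad)[1L]],
           "' references allele ", profiles[[ln]][which(bad)[1L]],
           " at locus '", ln, "', absent from the allele catalogue")
  }
  profiles[, c("strain", "group", "popflag", scheme_loci(scheme))]
}

parse_fasta_headers <- function(headers, path) {
  m <- regmatches(headers, regexec("^(.*)[_-](\\d+)$", headers))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop("cannot parse allele ID from FASTA header '",
         headers[which(bad)[1L]], "' in ", path,
         " (expected 'locus_ID')")
  list(locus = vapply(m, `[[`, character(1), 2L),
       id = as.integer(vapply(m, `[[`, character(1), 3L)))
}

#' Load an MLST scheme and strain profiles from files
#'
#' Reads one allele FASTA per locus (headers in the PubMLST `locus_ID`
#' dialect), a tab-separated strain profile table
#' (`strain<TAB>group<TAB><locus1>...<locusN>`, optional `popflag` column),
#' and a YAML config naming the loci, the per-locus default allele, and
#' the group-to-reporting merge map.
#'
#' @param allele_fastas Character vector of per-locus FASTA paths.
#' @param profile_path Path to the profile TSV.
#' @param config_path Path to the YAML scheme config with keys `loci`
#'   (ordered list), `default_allele` (map locus -> allele ID) and
#'   optionally `merge_map` (map group -> reporting group).
#' @return A list with elements `scheme` ([mlst_scheme()]) and `profiles`
#'   (validated data.frame).
#' @export
load_scheme <- function(allele_fastas, profile_path, config_path) {
  cfg <- yaml::read_yaml(config_path)
  if (is.null(cfg$loci) || is.null(cfg$default_allele))
    stop("scheme config must define 'loci' and 'default_allele'")
  loci <- list()
  for (fa in allele_fastas) {
    seqs <- Biostrings::readDNAStringSet(fa)
    hd <- parse_fasta_headers(sub("\\s.*$", "", names(seqs)), fa)
    if (length(unique(hd$locus)) != 1L)
      stop("FASTA ", fa, " mixes loci: ",
           paste(unique(hd$locus), collapse = ", "))
    ln <- hd$locus[1L]
    if (ln %in% names(loci)) stop("locus '", ln, "' appears in two FASTAs")
    loci[[ln]] <- mlst_locus(ln, stats::setNames(as.character(seqs), hd$id))
  }
  want <- unlist(cfg$loci)
  miss <- setdiff(want, names(loci))
  if (length(miss))
    stop("config lists loci with no allele FASTA: ", paste(miss, collapse = ", "))
  loci <- loci[want]
  merge_map <- if (is.null(cfg$merge_map)) character() else
    unlist(cfg$merge_map)
  scheme <- mlst_scheme(loci,
                        unlist(cfg$default_allele)[want],
                        merge_map)
  profiles <- utils::read.delim(profile_path, sep = "\t",
                                stringsAsFactors = FALSE,
                                check.names = FALSE)
  profiles <- validate_profiles(profiles, scheme)
  list(scheme = scheme, profiles = profiles)
}

#' Write an MLST scheme and profiles to files
#'
#' Inverse of [load_scheme()]: writes one allele FASTA per locus, the
#' profile TSV and the YAML scheme config into `dir`. Loading the written
#' files reproduces the scheme and profiles exactly.
#'
#' @param scheme An [mlst_scheme()].
#' @param profiles A validated profile data.frame (or `NULL` to skip).
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of written paths (`fastas`, `profiles`,
#'   `config`).
#' @export
write_scheme <- function(scheme, profiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fastas <- character()
  for (ln in scheme_loci(scheme)) {
    loc <- scheme$loci[[ln]]
    ss <- Biostrings::DNAStringSet(loc$alleles)
    names(ss) <- paste0(ln, "_", names(loc$alleles))
    path <- file.path(dir, paste0(ln, ".fas"))
    Biostrings::writeXStringSet(ss, path, width = 80L)
    fastas <- c(fastas, path)
  }
  cfg_path <- file.path(dir, "scheme.yml")
  yaml::write_yaml(list(loci = as.list(scheme_loci(scheme)),
                        default_allele = as.list(scheme$default_allele),
                        merge_map = as.list(scheme$merge_map)),
                   cfg_path)
  prof_path <- NULL
  if (!is.null(profiles)) {
    prof_path <- file.path(dir, "profiles.tsv")
    utils::write.table(profiles, prof_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(fastas = fastas, profiles = prof_path, config = cfg_path))
}

group_consensus <- function(profiles, scheme) {
  groups <- sort(unique(profiles$group))
  cons <- matrix(NA_integer_, nrow = length(groups),
                 ncol = length(scheme_loci(scheme)),
                 dimnames = list(groups, scheme_loci(scheme)))
  for (g in groups) {
    sub <- profiles[profiles$group == g, , drop = FALSE]
    for (ln in scheme_loci(scheme)) {
      tab <- table(sub[[ln]])
      best <- names(tab)[tab == max(tab)]
      # tie at a locus -> smallest allele ID, deterministically
      cons[g, ln] <- min(as.integer(best))
    }
  }
  cons
}

#' Curate a learning set by consensus allelic profiles
#'
#' For each declared population group the per-locus majority allele forms
#' the group's consensus allelic profile. A strain is excluded when (a) it
#' carries an allele absent from the scheme's catalogue, or (b) its profile
#' is ambiguous: it matches the consensus of some other group at least as
#' well (per-locus exact-match count) as its own group's consensus.
#'
#' @param profiles Profile data.frame (see [validate_profiles()]); only
#'   rows with `popflag = TRUE` are curated, others pass through untouched.
#' @param scheme An [mlst_scheme()].
#' @return A list with `profiles` (curated data.frame), `excluded`
#'   (data.frame `strain`, `group`, `reason`) and `consensus` (group x
#'   locus matrix of consensus allele IDs).
#' @export
curate_learning_set <- function(profiles, scheme) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  learn <- profiles[profiles$popflag %||% TRUE, , drop = FALSE]
  if (!nrow(learn)) stop("no learning strains (popflag = TRUE) to curate")
  loci <- scheme_loci(scheme)
  all_groups <- sort(unique(learn$group))

  excluded <- data.frame(strain = character(), group = character(),
                         reason = character(), stringsAsFactors = FALSE)
  # catalogue check first: strains with unknown alleles cannot vote
  known <- rep(TRUE, nrow(learn))
  for (ln in loci) {
    bad <- !learn[[ln]] %in% allele_ids(scheme$loci[[ln]])
    if (any(bad)) {
      for (i in which(bad & known))
        excluded <- rbind(excluded, data.frame(
          strain = learn$strain[i], group = learn$group[i],
          reason = sprintf("allele %d at locus %s absent from catalogue",
                           learn[[ln]][i], ln),
          stringsAsFactors = FALSE))
      known <- known & !bad
    }
  }
  learn <- learn[known, , drop = FALSE]
  if (!nrow(learn)) stop("all learning strains carry unknown alleles")

  cons <- group_consensus(learn, scheme)
  groups <- rownames(cons)
  keep <- rep(TRUE, nrow(learn))
  for (i in seq_len(nrow(learn))) {
    matches <- vapply(groups, function(g)
      sum(vapply(loci, function(ln) learn[[ln]][i] == cons[g, ln],
                 logical(1))), integer(1))
    own <- matches[[learn$group[i]]]
    others <- matches[setdiff(groups, learn$group[i])]
    if (length(others) && any(others >= own)) {
      keep[i] <- FALSE
      rival <- names(others)[which.max(others)]
      excluded <- rbind(excluded, data.frame(
        strain = learn$strain[i], group = learn$group[i],
        reason = sprintf("ambiguous profile: matches group %s consensus (%d/%d) at least as well as own (%d/%d)",
                         rival, max(others), length(loci), own, length(loci)),
        stringsAsFactors = FALSE))
    }
  }
  curated <- learn[keep, , drop = FALSE]
  gone <- setdiff(all_groups, unique(curated$group))
  if (length(gone))
    stop("curation removed every strain of group(s): ",
         paste(gone, collapse = ", "))
  rest <- profiles[!(profiles$popflag %||% TRUE), , drop = FALSE]
  out <- rbind(curated, rest)
  rownames(out) <- NULL
  list(profiles = out, excluded = excluded, consensus = cons)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive allele-distinguishing marker SNPs
#'
#' Restricted to the alleles actually used by the learning set (plus each
#' locus's default allele), a marker SNP for allele `a` at a locus is a
#' `(position, base)` pair at which `a`'s base differs from the base of
#' every other considered allele. The default allele needs no markers:
#' coverage not claimed by any marker is attributed to it. A non-default
#' considered allele with no distinguishing position makes the scheme
#' unable to resolve it and is an error.
#'
#' @param scheme An [mlst_scheme()].
#' @param learning Curated learning profile data.frame.
#' @return A data.frame `locus`, `position` (0-based index into the
#'   aligned allele), `base`, `allele`.
#' @export
derive_marker_snps <- function(scheme, learning) {
  stopifnot(is.data.frame(learning))
  if (!nrow(learning)) stop("empty learning set")
  out <- list()
  for (ln in scheme_loci(scheme)) {
    loc <- scheme$loci[[ln]]
    used <- sort(unique(c(learning[[ln]], scheme$default_allele[[ln]])))
    unknown <- setdiff(used, allele_ids(loc))
    if (length(unknown))
      stop("learning set uses allele(s) ", paste(unknown, collapse = ","),
           " absent from locus '", ln, "'")
    seqs <- do.call(rbind, strsplit(loc$alleles[as.character(used)], ""))
    rownames(seqs) <- used
    if (length(used) >= 2L) {
      same <- outer(seq_along(used), seq_along(used), Vectorize(function(i, j)
        i < j && all(seqs[i, ] == seqs[j, ])))
      if (any(same)) {
        ij <- which(same, arr.ind = TRUE)[1L, ]
        stop("alleles ", used[ij[1L]], " and ", used[ij[2L]],
             " at locus '", ln, "' have identical sequences and cannot be resolved")
      }
    }
    for (a in setdiff(used, scheme$default_allele[[ln]])) {
      ai <- match(a, used)
      uniq <- vapply(seq_len(ncol(seqs)), function(p)
        all(seqs[-ai, p] != seqs[ai, p]), logical(1))
      if (!any(uniq))
        stop("allele ", a, " at locus '", ln,
             "' has no position distinguishing it from all other considered alleles")
      out[[length(out) + 1L]] <- data.frame(
        locus = ln, position = which(uniq) - 1L,
        base = seqs[ai, uniq], allele = a, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(locus = character(), position = integer(),
                      base = character(), allele = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a marker-SNP table
#'
#' TSV dialect: `locus<TAB>position<TAB>base<TAB>allele` with a header,
#' positions 0-based.
#'
#' @param markers Marker data.frame from [derive_marker_snps()].
#' @param path File path.
#' @return `write_markers` returns `path` invisibly; `read_markers`
#'   returns the marker data.frame.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers[, c("locus", "position", "base", "allele")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$position <- as.integer(m$position)
  m$allele <- as.integer(m$allele)
  m
}
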