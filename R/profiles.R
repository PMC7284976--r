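MISSING_CODE <- -9L

#' Construct a ploidy-100 allelic profile
#'
#' A sample's genotype is represented as exactly `ploidy` allele copies per
#' locus, so a community can be treated as a single highly polyploid
#' admixed individual. Missing copies are `NA` internally and exported as
#' `-9` (STRUCTURE convention).
#'
#' @param sample Sample name.
#' @param copies Named list (one entry per locus) of integer vectors of
#'   length `ploidy`, each entry an allele ID or `NA`.
#' @param ploidy Copies per locus (default 100).
#' @return An object of class `ploidy_profile`.
#' @export
ploidy_profile <- function(sample, copies, ploidy = 100L) {
  stopifnot(is.list(copies), !is.null(names(copies)))
  copies <- lapply(copies, as.integer)
  bad <- vapply(copies, length, integer(1)) != ploidy
  if (any(bad))
    stop("locus '", names(copies)[which(bad)[1L]], "' has ",
         length(copies[[which(bad)[1L]]]), " copies, expected ", ploidy)
  structure(list(sample = as.character(sample), copies = copies,
                 ploidy = as.integer(ploidy)),
            class = "ploidy_profile")
}

#' @export
print.ploidy_profile <- function(x, ...) {
  cat(sprintf("<ploidy_profile> sample '%s': %d loci x %d copies (%d missing)\n",
              x$sample, length(x$copies), x$ploidy,
              sum(vapply(x$copies, function(v) sum(is.na(v)), integer(1)))))
  invisible(x)
}

#' Per-locus reference regions of a scheme
#'
#' Builds the locus interval table used by [pileup_from_alignments()] for
#' the common case where each locus is its own reference sequence spanning
#' the full aligned allele length. Coordinates are 0-based, half-open.
#'
#' @param scheme An [mlst_scheme()].
#' @return data.frame `locus`, `ref`, `start`, `end`.
#' @export
scheme_regions <- function(scheme) {
  data.frame(locus = scheme_loci(scheme),
             ref = scheme_loci(scheme),
             start = 0L,
             end = vapply(scheme$loci, `[[`, integer(1), "aligned_length"),
             stringsAsFactors = FALSE)
}

empty_pileup <- function(regions) {
  do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    n <- regions$end[i] - regions$start[i]
    data.frame(locus = regions$locus[i], position = seq_len(n) - 1L,
               A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L,
               stringsAsFactors = FALSE)
  }))
}

#' Per-position base counts over marker-gene loci from alignments
#'
#' Tallies aligned read bases (deletions and clips skipped) over each locus
#' interval of a SAM or BAM file. Reads below the mapping-quality floor are
#' excluded. SAM input is converted to sorted/indexed BAM internally.
#'
#' @param path SAM or BAM file of reads aligned to the marker-gene
#'   reference.
#' @param regions data.frame `locus`, `ref`, `start`, `end` (0-based,
#'   half-open), e.g. from [scheme_regions()].
#' @param min_mapq Mapping-quality floor (default 0: all mapped reads).
#' @return A pileup data.frame `locus`, `position` (0-based within locus),
#'   `A`, `C`, `G`, `T`, `depth`.
#' @export
pileup_from_alignments <- function(path, regions, min_mapq = 0L) {
  stopifnot(all(c("locus", "ref", "start", "end") %in% names(regions)))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
    if (!file.exists(paste0(bam, ".bai"))) Rsamtools::indexBam(bam)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  for (i in seq_len(nrow(regions))) {
    rf <- regions$ref[i]
    if (!rf %in% names(hdr))
      stop("reference '", rf, "' not present in alignment header")
    if (regions$start[i] < 0L || regions$end[i] > hdr[[rf]])
      stop("locus '", regions$locus[i], "' interval [", regions$start[i],
           ",", regions$end[i], ") exceeds reference bounds (length ",
           hdr[[rf]], ")")
  }
  gr <- GenomicRanges::GRanges(
    regions$ref,
    IRanges::IRanges(start = regions$start + 1L, end = regions$end))
  pp <- Rsamtools::PileupParam(max_depth = 10000000L,
                               min_base_quality = 0L,
                               min_mapq = as.integer(min_mapq),
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  sbp <- Rsamtools::ScanBamParam(which = gr)
  res <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  out <- empty_pileup(regions)
  if (!nrow(res)) {
    warning("no aligned bases found in ", path, "; returning all-zero pileup")
    return(out)
  }
  res$seqnames <- as.character(res$seqnames)
  res$nucleotide <- as.character(res$nucleotide)
  res <- res[res$nucleotide %in% c("A", "C", "G", "T"), , drop = FALSE]
  for (i in seq_len(nrow(regions))) {
    sel <- res$seqnames == regions$ref[i] &
      res$pos >= regions$start[i] + 1L & res$pos <= regions$end[i]
    sub <- res[sel, , drop = FALSE]
    if (!nrow(sub)) next
    rows <- which(out$locus == regions$locus[i])
    idx <- rows[sub$pos - regions$start[i]]
    for (b in c("A", "C", "G", "T")) {
      bi <- sub$nucleotide == b
      if (any(bi)) {
        at <- idx[bi]
        out[[b]][at] <- out[[b]][at] + sub$count[bi]
      }
    }
  }
  out$depth <- out$A + out$C + out$G + out$T
  out
}

#' Read / write a pileup table
#'
#' TSV dialect: `locus position A C G T depth` with header, positions
#' 0-based within each locus.
#'
#' @param pileup Pileup data.frame.
#' @param path File path.
#' @return `write_pileup` returns `path` invisibly; `read_pileup` the
#'   pileup data.frame.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup[, c("locus", "position", "A", "C", "G", "T", "depth")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cn in c("position", "A", "C", "G", "T", "depth"))
    p[[cn]] <- as.integer(p[[cn]])
  p
}

#' Call marker SNPs from a pileup
#'
#' A marker SNP is considered present when (1) its relative abundance at
#' the marker position is at least `min_freq` (default 1%) and (2) it is
#' supported by at least `min_reads` reads (default 4). The frequency
#' denominator is the total depth at the marker position; zero-depth
#' positions yield frequency 0 and an absent call.
#'
#' @param pileup Pileup data.frame (see [read_pileup()]).
#' @param markers Marker data.frame from [derive_marker_snps()].
#' @param min_freq Minimum relative abundance for presence.
#' @param min_reads Minimum supporting reads for presence.
#' @return data.frame `locus`, `position`, `base`, `allele`, `count`,
#'   `depth`, `frequency`, `present`.
#' @export
call_marker_snps <- function(pileup, markers, min_freq = 0.01, min_reads = 4L) {
  stopifnot(min_freq >= 0, min_freq <= 1, min_reads >= 0)
  unknown <- setdiff(unique(markers$locus), unique(pileup$locus))
  if (length(unknown))
    stop("markers reference locus(es) absent from pileup: ",
         paste(unknown, collapse = ", "))
  key <- paste(pileup$locus, pileup$position)
  idx <- match(paste(markers$locus, markers$position), key)
  if (anyNA(idx))
    stop("marker position outside pileup range at locus '",
         markers$locus[which(is.na(idx))[1L]], "'")
  count <- vapply(seq_len(nrow(markers)), function(i)
    as.numeric(pileup[[markers$base[i]]][idx[i]]), numeric(1))
  depth <- pileup$depth[idx]
  frequency <- ifelse(depth > 0L, count / depth, 0)
  data.frame(locus = markers$locus, position = markers$position,
             base = markers$base, allele = markers$allele,
             count = count, depth = depth, frequency = frequency,
             present = depth > 0L & frequency >= min_freq & count >= min_reads,
             stringsAsFactors = FALSE)
}

#' Infer per-locus allele relative abundances from marker-SNP calls
#'
#' An allele is considered present only when all of its marker SNPs are
#' present; its abundance is then summarized from its marker frequencies
#' (`method = "min"`, the default conservative choice, or `"mean"`). All
#' coverage not claimed by present non-default alleles is attributed to
#' the locus's default allele as the residual `1 - sum(present)`, floored
#' at 0. Small negative residuals (down to -0.10) are clamped with a
#' warning and the vector renormalized; grossly inconsistent marker
#' frequencies (residual below -0.10) are an error.
#'
#' @param calls SNP calls from [call_marker_snps()].
#' @param scheme An [mlst_scheme()].
#' @param method Marker-to-allele summary: `"min"` or `"mean"`.
#' @return Named list per locus of named abundance vectors (names are
#'   allele IDs) summing to 1.
#' @export
infer_allele_abundance <- function(calls, scheme, method = c("min", "mean")) {
  method <- match.arg(method)
  out <- list()
  for (ln in scheme_loci(scheme)) {
    sub <- calls[calls$locus == ln, , drop = FALSE]
    default <- scheme$default_allele[[ln]]
    ab <- numeric()
    for (a in setdiff(unique(sub$allele), default)) {
      ms <- sub[sub$allele == a, , drop = FALSE]
      if (all(ms$present)) {
        v <- if (method == "min") min(ms$frequency) else mean(ms$frequency)
        ab[as.character(a)] <- v
      }
    }
    residual <- 1 - sum(ab)
    if (residual < -0.10)
      stop("marker frequencies at locus '", ln, "' sum to ", round(sum(ab), 3),
           "; residual below -0.10 is grossly inconsistent")
    if (residual < 0) {
      warning("negative default-allele residual (", round(residual, 4),
              ") at locus '", ln, "' clamped to 0")
      residual <- 0
    }
    ab[as.character(default)] <- residual
    ab <- ab / sum(ab)
    out[[ln]] <- ab[order(as.integer(names(ab)))]
  }
  out
}

# round-half-away-from-zero (base R round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# Apportion `total` integer units over fractions `fr` by half-up rounding
# with the off-by-one repair: 1 short -> one missing unit appended; 1 over
# -> decrement the most abundant category (ties -> first by `tie_order`);
# anything further off falls back to largest-remainder apportionment.
# Returns list(counts, missing).
apportion_counts <- function(fr, total, tie_order = order(as_num_ids(names(fr)))) {
  stopifnot(all(fr >= 0))
  if (abs(sum(fr) - 1) > 1e-6)
    stop("fractions must sum to 1 (got ", sum(fr), ")")
  counts <- as.integer(round_half_up(fr * total))
  names(counts) <- names(fr)
  diff <- sum(counts) - total
  missing <- 0L
  if (diff == -1L) {
    missing <- 1L
  } else if (diff == 1L) {
    ranked <- tie_order[order(-fr[tie_order])]
    # stable: among ties in fr, tie_order decides
    top <- ranked[1L]
    if (counts[top] < 1L) top <- ranked[which(counts[ranked] >= 1L)[1L]]
    counts[top] <- counts[top] - 1L
  } else if (diff != 0L) {
    base <- as.integer(floor(fr * total))
    rem <- fr * total - base
    short <- total - sum(base)
    ord <- order(-rem, seq_along(fr))
    add <- integer(length(fr))
    if (short > 0L) add[ord[seq_len(short)]] <- 1L
    counts <- base + add
    names(counts) <- names(fr)
  }
  list(counts = counts, missing = missing)
}

as_num_ids <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (anyNA(n)) seq_along(x) else n
}

#' Encode allele abundances as a ploidy-100 locus vector
#'
#' Each allele receives `round(abundance * ploidy)` copies
#' (half-away-from-zero). When rounding leaves the locus one copy short, a
#' missing copy fills it; one copy over, the most abundant allele (ties:
#' lowest allele ID) loses one copy; larger discrepancies fall back to
#' largest-remainder apportionment. The result always has exactly `ploidy`
#' entries.
#'
#' @param abundance Named non-negative numeric vector summing to 1 (names
#'   are allele IDs).
#' @param ploidy Copies per locus (default 100).
#' @return Integer vector of length `ploidy` of allele IDs, `NA` for the
#'   missing copy if inserted.
#' @export
encode_ploidy <- function(abundance, ploidy = 100L) {
  if (any(abundance < 0)) stop("negative abundances are not allowed")
  ids <- as.integer(names(abundance))
  if (anyNA(ids)) stop("abundance names must be integer allele IDs")
  o <- order(ids)
  abundance <- abundance[o]
  ids <- ids[o]
  ap <- apportion_counts(abundance, ploidy, tie_order = seq_along(abundance))
  v <- c(rep(ids, ap$counts), rep(NA_integer_, ap$missing))
  stopifnot(length(v) == ploidy)
  v
}

#' Ploidy profile from per-locus allele abundances
#'
#' @param sample Sample name.
#' @param abundances Named list per locus of abundance vectors, as
#'   returned by [infer_allele_abundance()].
#' @param ploidy Copies per locus.
#' @return A [ploidy_profile()].
#' @export
profile_from_abundance <- function(sample, abundances, ploidy = 100L) {
  ploidy_profile(sample, lapply(abundances, encode_ploidy, ploidy = ploidy),
                 ploidy = ploidy)
}

#' Ploidy profile of a single reference strain
#'
#' A learning strain's profile is `ploidy` identical copies of its allele
#' at every scheme locus.
#'
#' @param strain One row of a validated profile data.frame (or a
#'   data.frame from which the row named `strain` is taken).
#' @param scheme An [mlst_scheme()].
#' @param ploidy Copies per locus.
#' @return A [ploidy_profile()].
#' @export
learning_profile_to_ploidy <- function(strain, scheme, ploidy = 100L) {
  stopifnot(is.data.frame(strain), nrow(strain) == 1L)
  loci <- scheme_loci(scheme)
  miss <- loci[!loci %in% names(strain) |
                 vapply(loci, function(ln) is.na(strain[[ln]][1L] %||% NA),
                        logical(1))]
  if (length(miss))
    stop("strain '", strain$strain, "' profile is missing locus(es): ",
         paste(miss, collapse = ", "))
  copies <- lapply(loci, function(ln) rep(as.integer(strain[[ln]]), ploidy))
  names(copies) <- loci
  ploidy_profile(strain$strain, copies, ploidy)
}

#' Write ploidy profiles in STRUCTURE's genotype file format
#'
#' Multi-row-per-individual dialect: a header row of locus names, then
#' `ploidy` rows per individual with columns `ID POP POPFLAG` followed by
#' one allele ID per locus; missing copies are written as `-9`. Population
#' labels are mapped to integer codes 1..K in sorted label order (0 for
#' unlabelled test samples); the mapping is returned invisibly.
#'
#' @param profiles List of [ploidy_profile()] objects.
#' @param groups Named character vector mapping sample name to population
#'   label for learning samples; samples absent from it get `POP 0`,
#'   `POPFLAG 0`.
#' @param path Output path.
#' @return Invisibly, the named integer population code map.
#' @export
write_structure <- function(profiles, groups, path) {
  labs <- sort(unique(groups))
  code <- stats::setNames(seq_along(labs), labs)
  loci <- names(profiles[[1L]]$copies)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(loci, collapse = "\t"), con)
  for (pp in profiles) {
    g <- groups[pp$sample]
    pop <- if (is.na(g) || is.null(g)) 0L else code[[g]]
    flag <- if (pop > 0L) 1L else 0L
    mat <- vapply(loci, function(ln) {
      v <- pp$copies[[ln]]
      v[is.na(v)] <- MISSING_CODE
      v
    }, integer(pp$ploidy))
    for (r in seq_len(pp$ploidy))
      writeLines(paste(c(pp$sample, pop, flag, mat[r, ]), collapse = "\t"),
                 con)
  }
  invisible(code)
}

#' Write per-locus allele abundances as TSV
#'
#' Dialect: `sample locus allele abundance` with header.
#'
#' @param sample Sample name.
#' @param abundances Output of [infer_allele_abundance()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(sample, abundances, path) {
  rows <- do.call(rbind, lapply(names(abundances), function(ln)
    data.frame(sample = sample, locus = ln,
               allele = as.integer(names(abundances[[ln]])),
               abundance = unname(abundances[[ln]]),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
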