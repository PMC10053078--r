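#' Extract qualifying spliced alignments over a locus
#'
#' Reads a SAM or BAM file and returns the alignment records that can serve as
#' splice-junction evidence: records that overlap the locus with at least one
#' aligned block, contain at least one skip (`N`) gap, and satisfy every
#' enabled flag of the filter policy. With `require_strand_match`, records
#' whose spliced-strand attribute (`XS` tag) differs from the locus strand are
#' excluded and records lacking the attribute are skipped and tallied (see
#' Details), never an error.
#'
#' SAM input is converted on the fly with [Rsamtools::asBam()]; BAM input is
#' indexed in a temporary location if no index is present.
#'
#' @details The number of spliced in-locus records skipped because their
#'   strand could not be resolved is available as
#'   `S4Vectors::metadata(result)$n_strand_unresolved`.
#'
#' @param file Path to a SAM (`.sam`) or BAM file.
#' @param locus An [locus()] object; only records overlapping it are returned.
#' @param policy An [alignment_filter_policy()].
#' @return A [GenomicAlignments::GAlignments] object with an `XS` metadata
#'   column (spliced strand, `NA` when absent).
#' @export
extract_spliced_alignments <- function(file, locus = ar_locus_grch37(),
                                       policy = alignment_filter_policy()) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- as_indexed_bam(file)
  flag <- Rsamtools::scanBamFlag(
    isSecondaryAlignment = if (policy$require_primary) FALSE else NA,
    isSupplementaryAlignment = if (policy$require_primary) FALSE else NA,
    isDuplicate = if (policy$exclude_duplicates) FALSE else NA,
    isProperPair = if (policy$require_properly_paired) TRUE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, tag = "XS",
                                   which = locus_as_granges(locus))
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  gal <- gal[GenomicAlignments::njunc(gal) >= 1L]
  # a record overlaps the locus iff one of its aligned blocks does (a read
  # whose skip gap merely spans the window does not count)
  blk <- GenomicAlignments::grglist(gal)
  gal <- gal[IRanges::overlapsAny(blk, locus_as_granges(locus),
                                  ignore.strand = TRUE)]
  xs <- S4Vectors::mcols(gal)$XS
  if (is.null(xs)) xs <- rep(NA_character_, length(gal))
  xs <- as.character(xs)
  n_unresolved <- 0L
  if (policy$require_strand_match) {
    n_unresolved <- sum(is.na(xs))
    keep <- !is.na(xs) & xs == locus$strand
    gal <- gal[keep]
    xs <- xs[keep]
  }
  S4Vectors::mcols(gal)$XS <- xs
  S4Vectors::metadata(gal) <- list(n_strand_unresolved = n_unresolved,
                                   locus = locus, policy = policy)
  gal
}

as_indexed_bam <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(Rsamtools::asBam(file, dest, overwrite = TRUE),
                    error = function(e)
                      stop("unreadable or truncated SAM file '", file, "': ",
                           conditionMessage(e)))
    return(bam)
  }
  idx <- paste0(file, ".bai")
  if (!file.exists(idx)) {
    tmp <- tempfile(fileext = ".bam")
    file.copy(file, tmp)
    Rsamtools::sortBam(tmp, sub("\\.bam$", "", tmp))
    Rsamtools::indexBam(tmp)
    return(tmp)
  }
  file
}

#' Enumerate splice junctions from alignment records
#'
#' One junction per skip (`N`) gap: the donor is the first intronic base (the
#' reference position immediately after the preceding aligned block) and the
#' acceptor the last intronic base, both 1-based. Junction strand is the
#' record's `XS` attribute when present, `"*"` otherwise.
#'
#' @param gal A [GenomicAlignments::GAlignments] object, e.g. from
#'   [extract_spliced_alignments()].
#' @return A data frame with columns `chrom`, `donor`, `acceptor`, `strand`
#'   and `read` (index of the supporting record in `gal`), ordered along each
#'   read.
#' @export
junctions_from_alignments <- function(gal) {
  if (length(gal) == 0L) {
    return(data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), strand = character(),
                      read = integer()))
  }
  jl <- GenomicAlignments::junctions(gal)
  n <- S4Vectors::elementNROWS(jl)
  j <- unlist(jl, use.names = FALSE)
  xs <- S4Vectors::mcols(gal)$XS
  if (is.null(xs)) xs <- rep(NA_character_, length(gal))
  strand <- rep(ifelse(is.na(xs), "*", as.character(xs)), n)
  data.frame(chrom = as.character(GenomicRanges::seqnames(j)),
             donor = GenomicRanges::start(j),
             acceptor = GenomicRanges::end(j),
             strand = strand,
             read = rep(seq_along(gal), n))
}

junction_key <- function(df) {
  sprintf("%s:%d-%d:%s", df$chrom, df$donor, df$acceptor, df$strand)
}

parse_junction_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+)-([0-9]+):([+*-])$", keys))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed junction key: ", keys[bad][1])
  data.frame(chrom = vapply(m, `[`, "", 2),
             donor = as.integer(vapply(m, `[`, "", 3)),
             acceptor = as.integer(vapply(m, `[`, "", 4)),
             strand = vapply(m, `[`, "", 5))
}

#' Tally junction read support per sample
#'
#' Counts, for every sample, the number of qualifying spliced alignments
#' supporting each junction. A read spanning k junctions contributes one count
#' to each of the k.
#'
#' @param records Named list mapping sample identifiers to
#'   [GenomicAlignments::GAlignments] objects (from
#'   [extract_spliced_alignments()]).
#' @return A `"junction_counts"` object: an integer matrix with one row per
#'   junction (rownames are `chrom:donor-acceptor:strand` keys) and one column
#'   per sample, plus a `junctions` attribute holding the parsed key table.
#' @export
count_junctions <- function(records) {
  if (length(records) > 0 &&
      (is.null(names(records)) || anyDuplicated(names(records))))
    stop("sample identifiers must be unique and non-empty")
  per_sample <- lapply(records, function(gal) {
    jdf <- junctions_from_alignments(gal)
    if (nrow(jdf) == 0L) return(integer(0))
    tab <- table(junction_key(jdf))
    setNames(as.integer(tab), names(tab))
  })
  all_keys <- sort(unique(unlist(lapply(per_sample, names))))
  mat <- matrix(0L, nrow = length(all_keys), ncol = length(records),
                dimnames = list(all_keys, names(records)))
  for (s in names(per_sample)) {
    v <- per_sample[[s]]
    mat[names(v), s] <- v
  }
  junction_counts(mat)
}

#' Construct a junction count matrix
#'
#' @param mat Integer matrix, junctions in rows (rownames are junction keys
#'   `chrom:donor-acceptor:strand`), samples in columns.
#' @return A `"junction_counts"` object.
#' @export
junction_counts <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (any(mat < 0, na.rm = TRUE)) stop("junction counts must be non-negative")
  if (nrow(mat) > 0 && is.null(rownames(mat)))
    stop("junction count matrix needs junction-key rownames")
  structure(mat, junctions = parse_junction_key(rownames(mat)),
            class = c("junction_counts", "matrix", "array"))
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("<junction_counts> %d junction(s) x %d sample(s)\n",
              nrow(x), ncol(x)))
  if (nrow(x) > 0) {
    show <- head(unclass(x), 8L)
    print(show)
    if (nrow(x) > 8L) cat(sprintf("... and %d more junction(s)\n", nrow(x) - 8L))
  }
  invisible(x)
}

#' Write / read a junction count table as TSV
#'
#' The table has columns `chrom`, `donor`, `acceptor`, `strand` followed by
#' one integer count column per sample.
#'
#' @param x A `"junction_counts"` object.
#' @param path Output (input) TSV path.
#' @return `write_junction_counts()` returns `path` invisibly;
#'   `read_junction_counts()` returns a `"junction_counts"` object.
#' @export
write_junction_counts <- function(x, path) {
  j <- attr(x, "junctions")
  df <- cbind(j, as.data.frame(unclass(x), check.names = FALSE,
                               row.names = NULL))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_counts
#' @export
read_junction_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = NA)
  fixed <- c("chrom", "donor", "acceptor", "strand")
  if (!all(fixed %in% names(df)))
    stop("junction table must have columns chrom, donor, acceptor, strand")
  mat <- as.matrix(df[setdiff(names(df), fixed)])
  rownames(mat) <- junction_key(df)
  junction_counts(mat)
}

#' One-call junction extraction for a cohort
#'
#' Runs [extract_spliced_alignments()] and [count_junctions()] over a set of
#' per-sample alignment files.
#'
#' @param files Named character vector of SAM/BAM paths; names are sample ids.
#' @inheritParams extract_spliced_alignments
#' @return A `"junction_counts"` object.
#' @export
extract_cohort_junctions <- function(files, locus = ar_locus_grch37(),
                                     policy = alignment_filter_policy()) {
  if (is.null(names(files)) || anyDuplicated(names(files)))
    stop("'files' must be a uniquely named vector of alignment paths")
  recs <- lapply(files, extract_spliced_alignments, locus = locus,
                 policy = policy)
  count_junctions(recs)
}
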