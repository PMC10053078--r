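#' Define a genomic target locus
#'
#' A locus restricts junction extraction to one genomic window on one strand.
#' Coordinates are 1-based and inclusive.
#'
#' @param chrom Chromosome name (e.g. `"chrX"`).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @param genome_build Free-text build label (e.g. `"GRCh37"`).
#' @return An object of class `"arv_locus"`.
#' @seealso [ar_locus_grch37()] for the default AR locus, [parse_locus()] for
#'   the `"chrom:start-end:strand"` string form.
#' @export
#' @examples
#' locus("chrT", 1, 8000, "+", "toy1")
locus <- function(chrom, start, end, strand = "+", genome_build = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(is.character(chrom), length(chrom) == 1L, !is.na(start), !is.na(end))
  if (start > end) stop("locus start must be <= end")
  if (!strand %in% c("+", "-")) stop("locus strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand,
                 genome_build = genome_build),
            class = "arv_locus")
}

#' Parse a locus string
#'
#' @param x String `"chrom:start-end:strand"`, e.g.
#'   `"chrX:66763863-66951462:+"`.
#' @param genome_build Optional build label attached to the result.
#' @return An `"arv_locus"` object.
#' @export
parse_locus <- function(x, genome_build = NA_character_) {
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+):([+-])$", x))[[1]]
  if (length(m) != 5L) stop("cannot parse locus string: ", x)
  locus(m[2], as.integer(m[3]), as.integer(m[4]), m[5], genome_build)
}

#' The AR gene locus on GRCh37
#'
#' The androgen receptor locus used by default when analysing human data:
#' chrX:66763863-66951462 on the plus strand of GRCh37.
#'
#' @return An `"arv_locus"` object.
#' @export
ar_locus_grch37 <- function() {
  locus("chrX", 66763863L, 66951462L, "+", "GRCh37")
}

#' @export
print.arv_locus <- function(x, ...) {
  cat(sprintf("<arv_locus> %s:%d-%d:%s (%s)\n", x$chrom, x$start, x$end,
              x$strand, ifelse(is.na(x$genome_build), "build unspecified",
                               x$genome_build)))
  invisible(x)
}

#' Format a locus as a string
#' @param x An `"arv_locus"` object.
#' @param ... Unused.
#' @method format arv_locus
#' @export
format.arv_locus <- function(x, ...) {
  sprintf("%s:%d-%d:%s", x$chrom, x$start, x$end, x$strand)
}

locus_as_granges <- function(loc) {
  GenomicRanges::GRanges(loc$chrom, IRanges::IRanges(loc$start, loc$end),
                         strand = loc$strand)
}

#' Alignment filter policy
#'
#' Which alignment records qualify as junction evidence. The defaults require
#' primary, properly paired, non-duplicate spliced alignments whose spliced
#' strand matches the locus strand; each flag can be relaxed independently.
#'
#' @param require_primary Drop secondary and supplementary/chimeric records.
#' @param require_properly_paired Keep only properly paired records.
#' @param exclude_duplicates Drop records flagged as PCR/optical duplicates.
#' @param require_strand_match Keep only junctions whose strand attribute
#'   (`XS` tag) matches the locus strand; records lacking the attribute are
#'   skipped and tallied as strand-unresolved rather than failing.
#' @return An object of class `"alignment_filter_policy"`.
#' @export
alignment_filter_policy <- function(require_primary = TRUE,
                                    require_properly_paired = TRUE,
                                    exclude_duplicates = TRUE,
                                    require_strand_match = TRUE) {
  structure(list(require_primary = isTRUE(require_primary),
                 require_properly_paired = isTRUE(require_properly_paired),
                 exclude_duplicates = isTRUE(exclude_duplicates),
                 require_strand_match = isTRUE(require_strand_match)),
            class = "alignment_filter_policy")
}

#' @export
print.alignment_filter_policy <- function(x, ...) {
  cat("<alignment_filter_policy>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, x[[nm]]))
  invisible(x)
}
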