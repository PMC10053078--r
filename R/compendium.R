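#' Cohort recurrence filter for splice junctions
#'
#' A junction is recurrent when at least `min_samples` samples each support it
#' with at least `min_reads` strand-correct spliced reads (defaults 10 and 5).
#' With `per_sample = FALSE` the alternative reading is used instead: a
#' junction is retained when it is observed (count >= 1) in `min_samples`
#' samples and its summed cohort-wide support reaches `min_reads`.
#'
#' @param counts A `"junction_counts"` object.
#' @param min_reads Minimum per-sample read support (>= 1).
#' @param min_samples Minimum number of supporting samples (>= 1).
#' @param per_sample Use per-sample support (default) or cohort-sum support.
#' @return Data frame of retained junctions (`chrom`, `donor`, `acceptor`,
#'   `strand`, `key`, `n_supporting_samples`), ordered by key.
#' @export
recurrent_junctions <- function(counts, min_reads = 5L, min_samples = 10L,
                                per_sample = TRUE) {
  stopifnot(inherits(counts, "junction_counts"))
  min_reads <- as.integer(min_reads); min_samples <- as.integer(min_samples)
  if (min_reads < 1L || min_samples < 1L)
    stop("min_reads and min_samples must both be >= 1")
  m <- unclass(counts)
  if (nrow(m) == 0L) {
    keep <- logical(0); nsup <- integer(0)
  } else if (per_sample) {
    nsup <- rowSums(m >= min_reads)
    keep <- nsup >= min_samples
  } else {
    nsup <- rowSums(m >= 1L)
    keep <- nsup >= min_samples & rowSums(m) >= min_reads
  }
  j <- attr(counts, "junctions")[keep, , drop = FALSE]
  keys <- if (is.null(rownames(m))) character(0) else rownames(m)
  j$key <- keys[keep]
  j$n_supporting_samples <- as.integer(nsup[keep])
  ord <- order(j$key)
  `rownames<-`(j[ord, , drop = FALSE], NULL)
}

#' Read a variant-definition table
#'
#' The TSV schema is: `name`, `chrom`, `donor`, `acceptor`, `strand`,
#' `genome_build`, `role` with role one of `defining-primary`,
#' `defining-alternate` or `none`. A variant whose rows all have role `none`
#' (or missing coordinates) has no distinctive junction and is treated as
#' non-quantifiable. Lines starting with `#` are comments.
#'
#' @param path TSV path.
#' @return Data frame of definitions.
#' @export
read_variant_definitions <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "chrom", "donor", "acceptor", "strand", "genome_build",
            "role")
  if (!all(need %in% names(df)))
    stop("variant definition table must have columns: ",
         paste(need, collapse = ", "))
  ok_role <- df$role %in% c("defining-primary", "defining-alternate", "none")
  if (!all(ok_role))
    stop("unknown role value(s): ", paste(unique(df$role[!ok_role]),
                                          collapse = ", "))
  df
}

#' Build the AR-V compendium
#'
#' Merges the cohort's recurrent junctions with literature-supplied variant
#' definitions. Every definition is kept regardless of recurrence; each
#' defining junction is annotated with whether it passed the recurrence
#' filter. A variant with no defining junction (no row with coordinates and a
#' `defining-*` role) is retained but marked non-quantifiable, mirroring
#' AR-V11, for which no distinctive junction exists.
#'
#' @param recurrent Data frame from [recurrent_junctions()] (may be empty).
#' @param definitions Data frame from [read_variant_definitions()], or a path
#'   to the TSV.
#' @param reference_junction The canonical exon 1-exon 2 junction, as a
#'   one-row data frame with `chrom`, `donor`, `acceptor`, `strand`.
#' @param thresholds Optional list recording the `min_reads`/`min_samples`
#'   used, stored as metadata.
#' @return An object of class `"arv_compendium"`: a list with elements
#'   `reference_junction`, `variants` (one row per variant: `name`,
#'   `quantifiable`, `primary_key`, `recurrent`, `source`), `junctions` (all
#'   defining junction rows with keys and recurrence flags),
#'   `recurrent_junctions` and `meta`.
#' @export
build_compendium <- function(recurrent, definitions,
                             reference_junction,
                             thresholds = list(min_reads = 5L,
                                               min_samples = 10L)) {
  if (is.character(definitions)) definitions <- read_variant_definitions(definitions)
  ref_key <- junction_key(reference_junction[1, , drop = FALSE])
  defs <- definitions[definitions$name != "reference", , drop = FALSE]
  has_coord <- !(is.na(defs$donor) | is.na(defs$acceptor) | is.na(defs$chrom))
  defining <- defs$role %in% c("defining-primary", "defining-alternate") & has_coord

  jn <- defs[defining, , drop = FALSE]
  if (nrow(jn) > 0) {
    jn$key <- junction_key(jn)
    if (any(jn$key == ref_key))
      stop("a defining junction equals the reference junction: ", ref_key)
    rec_keys <- if (nrow(recurrent)) recurrent$key else character(0)
    jn$recurrent <- jn$key %in% rec_keys
  } else {
    jn$key <- character(0); jn$recurrent <- logical(0)
  }

  vnames <- unique(defs$name)
  # one primary junction per variant: the first defining-primary row wins
  variants <- do.call(rbind, lapply(vnames, function(v) {
    rows <- jn[jn$name == v, , drop = FALSE]
    prim <- rows[rows$role == "defining-primary", , drop = FALSE]
    if (nrow(prim) > 1L)
      stop("variant '", v, "' has more than one defining-primary junction")
    quant <- nrow(prim) == 1L
    data.frame(name = v,
               quantifiable = quant,
               primary_key = if (quant) prim$key[1] else NA_character_,
               recurrent = if (quant) prim$recurrent[1] else NA,
               n_defining_junctions = nrow(rows),
               source = "literature",
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(variants$name))
    stop("duplicate variant names in definitions")
  structure(list(reference_junction = reference_junction,
                 reference_key = ref_key,
                 variants = variants,
                 junctions = jn,
                 recurrent_junctions = recurrent,
                 meta = list(thresholds = thresholds,
                             genome_build = unique(defs$genome_build))),
            class = "arv_compendium")
}

#' @export
print.arv_compendium <- function(x, ...) {
  cat("<arv_compendium>\n")
  cat("  reference junction:", x$reference_key, "\n")
  cat(sprintf("  %d variant(s), %d quantifiable; %d recurrent junction(s) in cohort\n",
              nrow(x$variants), sum(x$variants$quantifiable),
              nrow(x$recurrent_junctions)))
  print(x$variants, row.names = FALSE)
  invisible(x)
}

#' Serialize / load a compendium
#'
#' Writes `<path>.tsv` (the per-variant table) and `<path>.json` (reference
#' junction, recurrent junctions and metadata).
#'
#' @param x An `"arv_compendium"`.
#' @param path Output stem (no extension).
#' @export
write_compendium <- function(x, path) {
  write.table(x$variants, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(reference_junction = x$reference_junction,
         junctions = x$junctions,
         recurrent_junctions = x$recurrent_junctions,
         meta = x$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Bundled variant-definition tables
#'
#' `ar_variant_definitions_grch37()` returns the bundled GRCh37 template: the
#' canonical reference junction coordinates are filled in (RefSeq NM_000044
#' exon bounds) while the cryptic-exon rows of the named AR-Vs are left as
#' editable placeholders (`NA` coordinates) to be completed from the user's
#' compendium of choice; with placeholders every variant is non-quantifiable,
#' so real analyses require an edited copy.
#'
#' @return Path to the TSV inside the installed package.
#' @export
ar_variant_definitions_grch37 <- function() {
  system.file("extdata", "ar_variants_grch37.tsv", package = "arvquant",
              mustWork = TRUE)
}

#' Reference junction from a definitions table
#'
#' Convenience: the row with `name == "reference"` and role `defining-primary`
#' in a definitions TSV is taken as the canonical exon 1-exon 2 junction.
#'
#' @param definitions Data frame or TSV path.
#' @return One-row data frame (`chrom`, `donor`, `acceptor`, `strand`).
#' @export
reference_junction_from_definitions <- function(definitions) {
  if (is.character(definitions)) definitions <- read_variant_definitions(definitions)
  row <- definitions[definitions$name == "reference" &
                       definitions$role == "defining-primary", , drop = FALSE]
  if (nrow(row) != 1L || is.na(row$donor))
    stop("definitions table has no usable 'reference' junction row")
  row[, c("chrom", "donor", "acceptor", "strand")]
}
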