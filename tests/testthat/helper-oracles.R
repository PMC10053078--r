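# Independent oracles and fixture builders. Everything here is deliberately
# naive (double loops, full enumeration, regex-level SAM parsing) so it stays
# independent of the package's own code paths.

toy_chrom <- "chrT"
toy_len <- 8000L

# write a SAM file from a record table: qname, flag, pos, cigar, xs (NA = no
# XS tag)
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           chrom = toy_chrom, len = toy_len) {
  seqlen <- function(cigar) {
    ops <- regmatches(cigar, gregexpr("[0-9]+[MIS=X]", cigar))[[1]]
    sum(as.integer(sub("[MIS=X]", "", ops)))
  }
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
  ord <- order(records$pos)
  records <- records[ord, , drop = FALSE]
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    n <- seqlen(r$cigar)
    tag <- if (is.na(r$xs)) "" else sprintf("\tXS:A:%s", r$xs)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t0\t%s\t%s%s",
                              r$qname, r$flag, chrom, r$pos, r$cigar, r$pos,
                              strrep("A", n), strrep("I", n), tag))
  }
  writeLines(lines, path)
  path
}

qualifying_flag <- 99L  # paired, proper pair, mate reverse, first in pair

# junctions of one CIGAR by direct arithmetic over the reference-consuming
# operations
cigar_junctions_oracle <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[A-Z=]", "", ops))
  type <- sub("[0-9]+", "", ops)
  ref <- pos
  out <- NULL
  for (k in seq_along(ops)) {
    if (type[k] == "N")
      out <- rbind(out, c(donor = ref, acceptor = ref + lens[k] - 1L))
    if (type[k] %in% c("M", "D", "N", "=", "X")) ref <- ref + lens[k]
  }
  out
}

# naive re-scan of a SAM text file: tally junctions of qualifying spliced
# plus-strand reads
sam_junction_tally_oracle <- function(path, strand = "+") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  tally <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 256L) > 0 || bitwAnd(flag, 1024L) > 0 ||
        bitwAnd(flag, 2048L) > 0 || bitwAnd(flag, 2L) == 0) next
    if (!grepl("N", f[6])) next
    xs <- regmatches(ln, regexpr("XS:A:[+-]", ln))
    if (length(xs) == 0) next
    xs <- substr(xs, 6, 6)
    if (xs != strand) next
    j <- cigar_junctions_oracle(as.integer(f[4]), f[6])
    for (r in seq_len(nrow(j))) {
      key <- sprintf("%s:%d-%d:%s", f[3], j[r, 1], j[r, 2], xs)
      tally[[key]] <- (tally[[key]] %||% 0L) + 1L
    }
  }
  unlist(tally)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# double-loop recurrence filter
brute_recurrent <- function(mat, min_reads, min_samples) {
  keep <- character(0)
  for (j in rownames(mat)) {
    nsup <- 0L
    for (s in colnames(mat)) if (mat[j, s] >= min_reads) nsup <- nsup + 1L
    if (nsup >= min_samples) keep <- c(keep, j)
  }
  sort(keep)
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# BH step-up computed literally from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# random junction count matrix with junction-key rownames
random_count_matrix <- function(n_junc, n_samp, lambda = 4) {
  m <- matrix(rpois(n_junc * n_samp, lambda), n_junc, n_samp)
  rownames(m) <- sprintf("chrT:%d-%d:+", 1000 + 100 * seq_len(n_junc),
                         1050 + 100 * seq_len(n_junc))
  colnames(m) <- sprintf("S%02d", seq_len(n_samp))
  m
}

# minimal count matrix + compendium pair for quantifier tests
toy_quant_fixture <- function(sj_ref, sj_var,
                              variant = "AR-V7",
                              ref_key = "chrT:1201-1700:+",
                              var_key = "chrT:2601-2800:+") {
  stopifnot(length(sj_ref) == length(sj_var))
  n <- length(sj_ref)
  m <- rbind(sj_ref, sj_var)
  rownames(m) <- c(ref_key, var_key)
  colnames(m) <- sprintf("S%02d", seq_len(n))
  counts <- junction_counts(m)
  defs <- data.frame(
    name = c("reference", variant),
    chrom = "chrT", donor = c(1201L, 2601L), acceptor = c(1700L, 2800L),
    strand = "+", genome_build = "toy1", role = "defining-primary",
    stringsAsFactors = FALSE)
  comp <- build_compendium(
    recurrent_junctions(counts, 1, 1), defs,
    reference_junction_from_definitions(defs))
  list(counts = counts, compendium = comp)
}

# clinical table with explicit per-treatment counts among evaluable records
make_clinical <- function(n_total, n_missing, treated_counts,
                          age = NULL, n_lines = NULL) {
  n_eval <- n_total - n_missing
  ids <- sprintf("P%03d", seq_len(n_total))
  ind <- sapply(names(treated_counts), function(tr)
    c(rep(1L, treated_counts[[tr]]), rep(0L, n_eval - treated_counts[[tr]]),
      rep(NA_integer_, n_missing)))
  df <- data.frame(patient_id = ids,
                   age_at_biopsy = age %||% rep(65, n_total),
                   n_treatment_lines = n_lines %||%
                     c(rep(2L, n_eval), rep(NA_integer_, n_missing)),
                   ind, check.names = FALSE, stringsAsFactors = FALSE)
  df
}

# rbind two clinical frames with different treatment columns (missing -> 0)
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (cn in setdiff(cols, names(a))) a[[cn]] <- 0L
  for (cn in setdiff(cols, names(b))) b[[cn]] <- 0L
  b$patient_id <- paste0("X", b$patient_id)
  rbind(a[cols], b[cols])
}
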