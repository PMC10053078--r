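#' Relative expression of AR-Vs per sample
#'
#' For every quantifiable variant v and sample s the relative expression is
#'
#'   value(s, v) = 100 * SJ_x(s, v) / SJ_E1E2(s)
#'
#' where SJ_x is the read support for v's primary defining junction and
#' SJ_E1E2 the support for the canonical exon 1-exon 2 reference junction. A
#' sample with zero reference support has *undefined* relative expression for
#' every variant (distinct from 0%); a variant with zero support in a sample
#' with positive reference support is 0%. Variants without a distinctive
#' junction (e.g. AR-V11) are carried with status `"exempt"`, never silently
#' as 0. A junction absent from the count matrix has support 0.
#'
#' @param counts A `"junction_counts"` object.
#' @param compendium An `"arv_compendium"` from [build_compendium()].
#' @param threshold_pct Positivity threshold in percent (default 1):
#'   a sample is positive for a variant when its relative expression is >=
#'   this value.
#' @return An object of class `"arv_relexpr"`: list with `values` (samples x
#'   variants numeric matrix, percent, `NA` where undefined or exempt),
#'   `status` (character matrix `"ok"`/`"undefined"`/`"exempt"`),
#'   `sj_variant`, `sj_reference`, `positive` (logical matrix; undefined and
#'   exempt cells are `FALSE`) and `threshold_pct`.
#' @export
relative_expression <- function(counts, compendium, threshold_pct = 1) {
  stopifnot(inherits(counts, "junction_counts"),
            inherits(compendium, "arv_compendium"))
  m <- unclass(counts)
  samples <- colnames(m)
  variants <- compendium$variants$name
  key_count <- function(key) {
    if (!is.na(key) && key %in% rownames(m)) m[key, ] else
      setNames(rep(0L, length(samples)), samples)
  }
  sj_ref <- key_count(compendium$reference_key)
  values <- matrix(NA_real_, length(samples), length(variants),
                   dimnames = list(samples, variants))
  status <- matrix("ok", length(samples), length(variants),
                   dimnames = list(samples, variants))
  sj_var <- matrix(0L, length(samples), length(variants),
                   dimnames = list(samples, variants))
  for (i in seq_along(variants)) {
    vr <- compendium$variants[i, ]
    if (!vr$quantifiable) {
      status[, i] <- "exempt"
      next
    }
    sv <- key_count(vr$primary_key)
    sj_var[, i] <- sv
    und <- sj_ref == 0L
    status[und, i] <- "undefined"
    values[!und, i] <- 100 * sv[!und] / sj_ref[!und]
  }
  positive <- !is.na(values) & values >= threshold_pct
  structure(list(values = values, status = status, sj_variant = sj_var,
                 sj_reference = sj_ref, positive = positive,
                 threshold_pct = threshold_pct),
            class = "arv_relexpr")
}

#' Positivity calls and per-variant prevalence
#'
#' A sample is positive for a variant when its defined relative expression
#' reaches `threshold_pct`. Prevalence is the number of positive samples per
#' variant; the percentage is reported over all samples (rounded to the
#' nearest integer) unless `strict = TRUE`, which restricts the denominator
#' to samples with defined relative expression.
#'
#' @param x An `"arv_relexpr"` object.
#' @param threshold_pct Threshold in percent; defaults to the threshold the
#'   matrix was built with.
#' @param strict Drop undefined samples from the denominator.
#' @return List with `positive` (samples x variants logical matrix) and
#'   `prevalence` (data frame: `variant`, `n_positive`, `n_total`,
#'   `prevalence_pct`).
#' @export
call_positive <- function(x, threshold_pct = x$threshold_pct, strict = FALSE) {
  stopifnot(inherits(x, "arv_relexpr"))
  positive <- !is.na(x$values) & x$values >= threshold_pct
  defined <- x$status == "ok"
  n_total <- if (strict) colSums(defined) else
    rep(nrow(x$values), ncol(x$values))
  n_pos <- colSums(positive)
  exempt <- apply(x$status == "exempt", 2, all)
  prev <- data.frame(variant = colnames(x$values),
                     n_positive = ifelse(exempt, NA_integer_,
                                         as.integer(n_pos)),
                     n_total = as.integer(n_total),
                     prevalence_pct = ifelse(!exempt & n_total > 0,
                                             round(100 * n_pos / n_total),
                                             NA_real_),
                     status = ifelse(exempt, "exempt", "ok"),
                     stringsAsFactors = FALSE)
  rownames(prev) <- NULL
  list(positive = positive, prevalence = prev)
}

#' @export
print.arv_relexpr <- function(x, ...) {
  cat(sprintf("<arv_relexpr> %d sample(s) x %d variant(s); positivity threshold %g%%\n",
              nrow(x$values), ncol(x$values), x$threshold_pct))
  exempt <- colnames(x$status)[apply(x$status == "exempt", 2, all)]
  if (length(exempt))
    cat("  exempt (no distinctive junction):", paste(exempt, collapse = ", "),
        "\n")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Per-variant summary of a relative-expression matrix
#'
#' Median and quartiles of defined relative expression (2 decimals, matching
#' the field's reporting convention) plus prevalence at the object's
#' positivity threshold.
#'
#' @param object An `"arv_relexpr"` object.
#' @param ... Unused.
#' @return Data frame, one row per variant.
#' @method summary arv_relexpr
#' @export
summary.arv_relexpr <- function(object, ...) {
  prev <- call_positive(object)$prevalence
  qs <- t(vapply(seq_len(ncol(object$values)), function(i) {
    v <- object$values[object$status[, i] == "ok", i]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_))
    unname(stats::quantile(v, c(.5, .25, .75)))
  }, numeric(3)))
  data.frame(variant = colnames(object$values),
             median_pct = round(qs[, 1], 2),
             q1_pct = round(qs[, 2], 2),
             q3_pct = round(qs[, 3], 2),
             n_positive = prev$n_positive,
             prevalence_pct = prev$prevalence_pct,
             stringsAsFactors = FALSE)
}

#' Long-format export of relative expression
#'
#' @param x An `"arv_relexpr"` object.
#' @param ... Unused.
#' @return Data frame with columns `sample`, `variant`, `sj_variant`,
#'   `sj_reference`, `relative_expression_pct`, `positive`, `status`.
#' @method as.data.frame arv_relexpr
#' @export
as.data.frame.arv_relexpr <- function(x, ...) {
  samples <- rownames(x$values); variants <- colnames(x$values)
  df <- data.frame(
    sample = rep(samples, times = length(variants)),
    variant = rep(variants, each = length(samples)),
    sj_variant = as.vector(x$sj_variant),
    sj_reference = rep(as.vector(x$sj_reference), times = length(variants)),
    relative_expression_pct = as.vector(x$values),
    positive = as.vector(x$positive),
    status = as.vector(x$status),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Rebuild an `"arv_relexpr"` object from its long-format export
#'
#' @param df Data frame as produced by [as.data.frame.arv_relexpr()].
#' @param threshold_pct Positivity threshold in percent.
#' @return An `"arv_relexpr"` object.
#' @export
relexpr_from_long <- function(df, threshold_pct = 1) {
  samples <- unique(df$sample); variants <- unique(df$variant)
  shape <- function(col, mode) {
    m <- matrix(vector(mode, 1), length(samples), length(variants),
                dimnames = list(samples, variants))
    m[cbind(match(df$sample, samples), match(df$variant, variants))] <-
      as.vector(df[[col]], mode)
    m
  }
  values <- shape("relative_expression_pct", "double")
  status <- shape("status", "character")
  sj_var <- shape("sj_variant", "integer")
  sj_ref <- setNames(df$sj_reference[match(samples, df$sample)], samples)
  positive <- !is.na(values) & values >= threshold_pct
  structure(list(values = values, status = status, sj_variant = sj_var,
                 sj_reference = sj_ref, positive = positive,
                 threshold_pct = threshold_pct),
            class = "arv_relexpr")
}

#' Box plot of relative expression per variant
#'
#' @param x An `"arv_relexpr"` object.
#' @param ... Passed to [graphics::boxplot()].
#' @method plot arv_relexpr
#' @export
plot.arv_relexpr <- function(x, ...) {
  ok <- x$status == "ok"
  vals <- lapply(seq_len(ncol(x$values)),
                 function(i) x$values[ok[, i], i])
  names(vals) <- colnames(x$values)
  vals <- vals[vapply(vals, length, 1L) > 0]
  boxplot(vals, ylab = "relative expression vs AR (%)", las = 2, ...)
  invisible(x)
}
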