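#' Baseline cohort summary
#'
#' Summarises a clinical table the way cohort baseline tables are reported:
#' median and range of age at biopsy and of total prior treatment lines, and
#' per-treatment counts with percentages over the evaluable (non-missing)
#' records for that column, one decimal.
#'
#' @param clinical Data frame with columns `patient_id`, `age_at_biopsy`,
#'   `n_treatment_lines` and one 0/1 indicator column per treatment (any
#'   other numeric 0/1 columns are treated as treatments).
#' @param treatment_cols Character vector naming the indicator columns;
#'   defaults to every column other than the three fixed ones.
#' @return List with `age` (median, min, max, n_evaluable, n_missing),
#'   `treatment_lines` (same shape) and `treatments` (data frame: `treatment`,
#'   `n`, `n_evaluable`, `pct` at one decimal; `pct` is `NA` when no record is
#'   evaluable).
#' @export
cohort_summary <- function(clinical, treatment_cols = NULL) {
  fixed <- c("patient_id", "age_at_biopsy", "n_treatment_lines")
  if (is.null(treatment_cols))
    treatment_cols <- setdiff(names(clinical), fixed)
  num_summary <- function(v) {
    ok <- !is.na(v)
    list(median = if (any(ok)) median(v[ok]) else NA_real_,
         min = if (any(ok)) min(v[ok]) else NA_real_,
         max = if (any(ok)) max(v[ok]) else NA_real_,
         n_evaluable = sum(ok), n_missing = sum(!ok))
  }
  treatments <- do.call(rbind, lapply(treatment_cols, function(cn) {
    v <- clinical[[cn]]
    ok <- !is.na(v)
    n <- sum(v[ok] == 1)
    data.frame(treatment = cn, n = n, n_evaluable = sum(ok),
               pct = if (sum(ok) > 0) round(100 * n / sum(ok), 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(n = nrow(clinical),
       age = num_summary(clinical$age_at_biopsy),
       treatment_lines = num_summary(clinical$n_treatment_lines),
       treatments = treatments)
}

#' Single-treatment patient subset
#'
#' Patients with exactly one prior treatment line and exactly one recorded
#' treatment, grouped by that treatment. Only groups with at least
#' `min_group` patients are retained for analysis (the others are reported
#' but flagged).
#'
#' @inheritParams cohort_summary
#' @param min_group Minimum group size retained (default 10).
#' @return List with `groups` (data frame: `treatment`, `n`, `retained`),
#'   `n_single` (total single-treatment patients) and `patients` (the subset
#'   of `clinical` belonging to a retained group, with a `single_treatment`
#'   column).
#' @export
single_treatment_subset <- function(clinical, treatment_cols = NULL,
                                    min_group = 10L) {
  fixed <- c("patient_id", "age_at_biopsy", "n_treatment_lines")
  if (is.null(treatment_cols))
    treatment_cols <- setdiff(names(clinical), fixed)
  ind <- as.matrix(clinical[treatment_cols])
  single <- !is.na(clinical$n_treatment_lines) &
    clinical$n_treatment_lines == 1L &
    rowSums(ind == 1, na.rm = TRUE) == 1L &
    rowSums(is.na(ind)) == 0L
  which_tr <- rep(NA_character_, nrow(clinical))
  which_tr[single] <- treatment_cols[max.col(ind[single, , drop = FALSE])]
  tab <- table(factor(which_tr[single], levels = treatment_cols))
  groups <- data.frame(treatment = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  groups <- groups[groups$n > 0, , drop = FALSE]
  groups <- groups[order(-groups$n, groups$treatment), , drop = FALSE]
  rownames(groups) <- NULL
  groups$retained <- groups$n >= min_group
  keep <- single & which_tr %in% groups$treatment[groups$retained]
  pats <- clinical[keep, , drop = FALSE]
  pats$single_treatment <- which_tr[keep]
  list(groups = groups, n_single = sum(single), patients = pats)
}

#' Mann-Whitney comparison wrapper
#'
#' Two-sided rank-based comparison of two groups: the exact distribution is
#' used when both groups have at most 8 observations and no ties, the normal
#' approximation with midranks and tie correction otherwise.
#'
#' @param x,y Numeric vectors.
#' @return List with `U` (statistic for `x`), `p`, `method` and `degenerate`
#'   (`TRUE` with `p = NA` when a group is empty).
#' @keywords internal
mw_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    return(list(U = NA_real_, p = NA_real_, method = "degenerate",
                degenerate = TRUE))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 8L && length(y) <= 8L
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation (tie-corrected)",
       degenerate = FALSE)
}

#' AR expression by any-variant positivity
#'
#' Tests whether samples harbouring at least one positive AR-V show different
#' normalized AR expression than samples with none (two-sided Mann-Whitney).
#'
#' @param ar Data frame with columns `sample` and `ar_expression`
#'   (library-size-normalized AR gene expression, >= 0).
#' @param positive Samples x variants logical matrix (from [call_positive()])
#'   or a logical vector named by sample giving any-variant positivity.
#' @return List with `U`, `p`, `method`, `n_positive`, `n_negative` and
#'   `degenerate`.
#' @export
any_variant_vs_ar_expression <- function(ar, positive) {
  any_pos <- if (is.matrix(positive)) rowSums(positive) > 0 else positive
  idx <- match(ar$sample, names(any_pos))
  if (anyNA(idx)) stop("samples in 'ar' missing from positivity calls: ",
                       paste(head(ar$sample[is.na(idx)]), collapse = ", "))
  grp <- any_pos[idx]
  res <- mw_test(ar$ar_expression[grp], ar$ar_expression[!grp])
  c(res, list(n_positive = sum(grp), n_negative = sum(!grp)))
}

#' Pairwise AR-expression tests across variant-count groups
#'
#' Samples are grouped by their number of positive AR-Vs; all pairwise
#' two-sided Mann-Whitney comparisons are run and adjusted by
#' Benjamini-Hochberg over the pairwise family. Groups with fewer than 2
#' samples are skipped with a notice.
#'
#' @inheritParams any_variant_vs_ar_expression
#' @param n_positive Integer vector named by sample: number of positive
#'   variants per sample (e.g. `rowSums(call_positive(x)$positive)`).
#' @return List with `tests` (data frame: `group1`, `group2`, `n1`, `n2`,
#'   `U`, `p`, `q`) and `skipped_groups`.
#' @export
per_count_group_tests <- function(ar, n_positive) {
  idx <- match(ar$sample, names(n_positive))
  if (anyNA(idx)) stop("samples in 'ar' missing from 'n_positive'")
  grp <- n_positive[idx]
  sizes <- table(grp)
  usable <- as.integer(names(sizes)[sizes >= 2L])
  skipped <- as.integer(names(sizes)[sizes < 2L])
  if (length(usable) < 2L)
    return(list(tests = data.frame(), skipped_groups = skipped))
  pairs <- utils::combn(sort(usable), 2)
  tests <- do.call(rbind, apply(pairs, 2, function(pr) {
    a <- ar$ar_expression[grp == pr[1]]
    b <- ar$ar_expression[grp == pr[2]]
    res <- mw_test(a, b)
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(a), n2 = length(b),
               U = res$U, p = res$p)
  }))
  tests$q <- p.adjust(tests$p, method = "BH")
  rownames(tests) <- NULL
  list(tests = tests, skipped_groups = skipped)
}

#' Univariate screen of clinical covariates on relative AR-V expression
#'
#' For every (covariate, variant) pair, fits an ordinary least-squares
#' regression of the variant's relative expression on the single covariate
#' over complete cases. Samples with undefined relative expression are
#' dropped for that variant; non-quantifiable variants are skipped. No
#' multiplicity correction is applied across the screen.
#'
#' @param clinical Clinical data frame (see [cohort_summary()]); only
#'   complete-case records (no missing covariate) enter any model.
#' @param relexpr An `"arv_relexpr"` object; its row names must be the
#'   `patient_id`/sample identifiers of `clinical`.
#' @param covariates Character vector of covariate columns to screen.
#' @param alpha Significance threshold for flagging (default 0.05).
#' @return Data frame with columns `variant`, `covariate`, `n`, `slope`,
#'   `p`, `significant`, `note` (`"ok"`, `"inestimable"` for constant
#'   covariates or zero residual degrees of freedom).
#' @export
univariate_screen <- function(clinical, relexpr, covariates, alpha = 0.05) {
  stopifnot(inherits(relexpr, "arv_relexpr"))
  cc <- clinical[complete.cases(clinical[covariates]), , drop = FALSE]
  variants <- colnames(relexpr$values)[apply(relexpr$status != "exempt", 2, all)]
  out <- list()
  for (v in variants) {
    y_all <- relexpr$values[, v]
    ok <- relexpr$status[, v] == "ok"
    idx <- match(cc$patient_id, rownames(relexpr$values))
    use <- !is.na(idx) & ok[pmax(idx, 1L)] & !is.na(idx)
    dat <- cc[use, , drop = FALSE]
    y <- y_all[idx[use]]
    for (cv in covariates) {
      x <- dat[[cv]]
      if (length(unique(x)) < 2L || length(y) < 3L) {
        out[[length(out) + 1L]] <- data.frame(
          variant = v, covariate = cv, n = length(y), slope = NA_real_,
          p = NA_real_, significant = FALSE, note = "inestimable")
        next
      }
      fit <- lm(y ~ x)
      sm <- suppressWarnings(summary(fit)) # zero-residual fits warn here
      if (nrow(sm$coefficients) < 2L || fit$df.residual < 1L ||
          !is.finite(sm$coefficients[2, 4])) {
        out[[length(out) + 1L]] <- data.frame(
          variant = v, covariate = cv, n = length(y),
          slope = unname(coef(fit)[2]), p = NA_real_, significant = FALSE,
          note = "inestimable")
        next
      }
      p <- sm$coefficients[2, 4]
      out[[length(out) + 1L]] <- data.frame(
        variant = v, covariate = cv, n = length(y),
        slope = sm$coefficients[2, 1], p = p, significant = p < alpha,
        note = "ok")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multivariate regression per variant
#'
#' One multiple OLS regression per variant, including every feature selected
#' by the univariate screen (for any variant, following the study design of
#' pooling univariate hits into one model). Aliased (collinear) features are
#' dropped with a notice.
#'
#' @inheritParams univariate_screen
#' @param features Character vector of covariates to include (typically
#'   `unique(screen$covariate[screen$significant])`).
#' @param alpha Significance threshold for the `retained` flag.
#' @return Data frame with columns `variant`, `feature`, `n`, `estimate`,
#'   `p`, `retained`, `note`.
#' @export
multivariate_model <- function(clinical, relexpr, features, alpha = 0.05) {
  stopifnot(inherits(relexpr, "arv_relexpr"))
  if (length(features) < 1L) stop("at least one selected feature is required")
  cc <- clinical[complete.cases(clinical[features]), , drop = FALSE]
  variants <- colnames(relexpr$values)[apply(relexpr$status != "exempt", 2, all)]
  out <- list()
  for (v in variants) {
    ok <- relexpr$status[, v] == "ok"
    idx <- match(cc$patient_id, rownames(relexpr$values))
    use <- !is.na(idx) & ok[pmax(idx, 1L)]
    dat <- cc[use, features, drop = FALSE]
    y <- relexpr$values[idx[use], v]
    if (length(y) <= length(features) + 1L) next
    fit <- lm(y ~ ., data = dat)
    aliased <- names(which(is.na(coef(fit))))
    if (length(aliased)) {
      keep <- setdiff(features, sub("`?(.*?)`?$", "\\1", aliased))
      fit <- lm(y ~ ., data = dat[, keep, drop = FALSE])
    }
    sm <- suppressWarnings(summary(fit))$coefficients
    feat_rows <- rownames(sm)[-1]
    for (k in seq_along(feat_rows)) {
      out[[length(out) + 1L]] <- data.frame(
        variant = v, feature = feat_rows[k], n = length(y),
        estimate = sm[k + 1L, 1], p = sm[k + 1L, 4],
        retained = sm[k + 1L, 4] < alpha,
        note = if (length(aliased)) "collinear feature(s) dropped" else "ok")
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  rownames(res) <- NULL
  res
}

#' Oncoprint sample and variant ordering
#'
#' Deterministic layout for a co-occurrence (oncoprint) plot of binary
#' positivity calls: variants are sorted by descending prevalence (ties by
#' name) and samples by the standard memo-sort -- each sample's positivity
#' vector, read in variant order, is treated as a binary number and samples
#' are sorted on it in descending order, ties broken by sample identifier.
#'
#' @param positive Samples x variants logical matrix.
#' @return List with `samples` and `variants`: identifiers in plot order.
#' @export
oncoprint_order <- function(positive) {
  stopifnot(is.matrix(positive))
  prev <- colSums(positive)
  vord <- order(-prev, colnames(positive))
  variants <- colnames(positive)[vord]
  m <- positive[, vord, drop = FALSE]
  # lexicographic descending on the bit rows == descending binary number
  key <- apply(m, 1, function(r) paste(as.integer(r), collapse = ""))
  sord <- order(key, rownames(m), decreasing = c(TRUE, FALSE),
                method = "radix")
  list(samples = rownames(m)[sord], variants = variants)
}

#' Minimal oncoprint plot
#'
#' @param positive Samples x variants logical matrix.
#' @param ... Passed to [graphics::image()].
#' @return The ordering used, invisibly.
#' @export
plot_oncoprint <- function(positive, ...) {
  ord <- oncoprint_order(positive)
  m <- positive[ord$samples, ord$variants, drop = FALSE]
  image(seq_len(nrow(m)), seq_len(ncol(m)), m + 0,
        col = c("grey90", "firebrick"), xlab = "samples", ylab = "",
        yaxt = "n", ...)
  axis(2, at = seq_len(ncol(m)), labels = colnames(m), las = 2)
  invisible(ord)
}
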