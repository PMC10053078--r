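#' Toy AR-like isoform model for simulation
#'
#' A compact gene model on a declared toy build (`chrT`, 8000 bp, plus
#' strand) emulating the AR splice-variant landscape: eight canonical exons
#' E1..E8, an AR45-style alternative first exon inside intron 1, and cryptic
#' exons in introns 2-4 whose distinctive junctions define AR-V-like
#' isoforms (AR45, AR-V3, AR-V7, AR-V9, AR23, AR-V1). AR-V11 is carried
#' without a distinctive junction. The reference junction is canonical E1-E2.
#'
#' @return List of class `"arv_isoform_model"` with elements `chrom`,
#'   `chrom_len`, `strand`, `genome_build`, `exons`, `canonical_junctions`,
#'   `variant_junctions` and `reference_junction`.
#' @export
toy_isoform_model <- function() {
  exons <- data.frame(
    name  = c("E1", "E1b", "E2", "CEb", "E3", "CEa", "CEc", "E4", "CEe",
              "CEd", "E5", "E6", "E7", "E8"),
    start = c(1001, 1301, 1701, 2001, 2401, 2801, 2951, 3101, 3451,
              3601, 3801, 4501, 5201, 5901),
    end   = c(1200, 1400, 1900, 2100, 2600, 2900, 3050, 3300, 3550,
              3700, 4000, 4700, 5400, 6100))
  canon <- data.frame(
    name = paste0("E", 1:7, "-E", 2:8),
    donor = c(1201, 1901, 2601, 3301, 4001, 4701, 5401),
    acceptor = c(1700, 2400, 3100, 3800, 4500, 5200, 5900))
  varj <- data.frame(
    name = c("AR45", "AR-V3", "AR-V7", "AR-V9", "AR23", "AR-V1"),
    donor = c(1401, 1901, 2601, 2601, 3301, 3301),
    acceptor = c(1700, 2000, 2800, 2950, 3600, 3450))
  structure(list(chrom = "chrT", chrom_len = 8000L, strand = "+",
                 genome_build = "toy1", exons = exons,
                 canonical_junctions = canon, variant_junctions = varj,
                 reference_junction = canon[1, c("donor", "acceptor")]),
            class = "arv_isoform_model")
}

#' Variant-definition table for the toy model
#'
#' Builds the definitions data frame (see [read_variant_definitions()] for
#' the schema) matching [toy_isoform_model()]: a `reference` row for the
#' canonical E1-E2 junction, one defining-primary row per variant with a
#' distinctive junction, and an AR-V11 row without coordinates.
#'
#' @param model An `"arv_isoform_model"`.
#' @return Data frame usable by [build_compendium()].
#' @export
toy_variant_definitions <- function(model = toy_isoform_model()) {
  vj <- model$variant_junctions
  rbind(
    data.frame(name = "reference", chrom = model$chrom,
               donor = model$reference_junction$donor,
               acceptor = model$reference_junction$acceptor,
               strand = model$strand, genome_build = model$genome_build,
               role = "defining-primary", stringsAsFactors = FALSE),
    data.frame(name = vj$name, chrom = model$chrom, donor = vj$donor,
               acceptor = vj$acceptor, strand = model$strand,
               genome_build = model$genome_build, role = "defining-primary",
               stringsAsFactors = FALSE),
    data.frame(name = "AR-V11", chrom = NA_character_, donor = NA_integer_,
               acceptor = NA_integer_, strand = NA_character_,
               genome_build = model$genome_build, role = "none",
               stringsAsFactors = FALSE))
}

#' Write a variant-definition table as TSV
#' @param definitions Data frame (schema of [read_variant_definitions()]).
#' @param path Output path.
#' @export
write_variant_definitions <- function(definitions, path) {
  write.table(definitions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulation configuration
#'
#' Defines the synthetic-cohort conditions: cohort size, reference-junction
#' sequencing depth, per-variant expected relative fraction and cohort
#' prevalence, contamination rates and the clinical-covariate generator.
#' Defaults emulate a modest mCRPC-like cohort in which AR45 is the most
#' prevalent variant and positivity is called at 1% relative expression.
#'
#' @param n_samples Number of samples/patients.
#' @param depth Expected read support of the reference junction (Poisson
#'   mean); canonical junctions share this depth.
#' @param variants Data frame with columns `name`, `fraction_pct` (expected
#'   relative fraction, percent, when the variant is active in a sample) and
#'   `prevalence` (share of samples in which it is active). Names must match
#'   the model's variant junctions.
#' @param dup_rate,secondary_rate,wrong_strand_rate,xs_missing_rate Per-read
#'   probabilities that an emitted junction read is flagged duplicate,
#'   secondary, carries the opposite-strand attribute, or lacks the strand
#'   attribute entirely. Their sum must be at most 1; the remainder is the
#'   qualifying fraction.
#' @param unspliced_rate Expected unspliced (contiguous-CIGAR) reads per
#'   sample as a fraction of `depth`.
#' @param noise_junction_rate Expected sporadic noise-junction reads per
#'   sample as a fraction of `depth`; each noise read supports a random
#'   non-recurrent junction.
#' @param clinical List controlling the clinical generator: `age_mean`,
#'   `age_sd`, `age_range`, `n_lines_lambda`, `max_lines`,
#'   `treatment_weights` (named, marginal-probability-like weights),
#'   `missing_rate` (treatment-record masking), `age_missing_rate`.
#' @param effects List of effect descriptors, each
#'   `list(treatment=, variant=, factor=)`: in patients who received the
#'   treatment, the variant's active fraction is multiplied by `factor`
#'   (multiplicative injection, giving regressions a recoverable signal).
#' @param ar_expr_factor Multiplicative shift of normalized AR expression in
#'   samples with at least one active variant.
#' @param threshold_pct Positivity threshold used for the recorded truth.
#' @param seed Integer seed; fixed seed makes the cohort bit-reproducible.
#' @return List of class `"arv_sim_config"`.
#' @export
simulation_config <- function(
    n_samples = 20L,
    depth = 1000,
    variants = data.frame(
      name = c("AR45", "AR-V3", "AR-V7", "AR-V9", "AR23", "AR-V1"),
      fraction_pct = c(5, 2, 3, 2, 1.5, 1.5),
      prevalence = c(0.66, 0.41, 0.37, 0.12, 0.08, 0.06)),
    dup_rate = 0.10, secondary_rate = 0.05,
    wrong_strand_rate = 0.02, xs_missing_rate = 0.02,
    unspliced_rate = 0.20, noise_junction_rate = 0.02,
    clinical = list(age_mean = 67, age_sd = 8, age_range = c(46, 85),
                    n_lines_lambda = 1.3, max_lines = 8,
                    treatment_weights = c(docetaxel = 0.826,
                                          enzalutamide = 0.526,
                                          cabazitaxel = 0.258,
                                          abiraterone = 0.235,
                                          radium223 = 0.131,
                                          other = 0.05),
                    missing_rate = 0.23, age_missing_rate = 0.01),
    effects = list(list(treatment = "enzalutamide", variant = "AR-V7",
                        factor = 2)),
    ar_expr_factor = 1.5,
    threshold_pct = 1,
    seed = NULL) {
  if (any(variants$fraction_pct < 0)) stop("variant fractions must be >= 0")
  if (any(variants$fraction_pct > 100))
    stop("variant fraction > 100% is infeasible")
  rates <- c(dup_rate, secondary_rate, wrong_strand_rate, xs_missing_rate,
             unspliced_rate, noise_junction_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (dup_rate + secondary_rate + wrong_strand_rate + xs_missing_rate > 1)
    stop("per-read contamination rates must sum to <= 1")
  if (any(variants$prevalence < 0 | variants$prevalence > 1))
    stop("prevalence must lie in [0, 1]")
  structure(list(n_samples = as.integer(n_samples), depth = depth,
                 variants = variants, dup_rate = dup_rate,
                 secondary_rate = secondary_rate,
                 wrong_strand_rate = wrong_strand_rate,
                 xs_missing_rate = xs_missing_rate,
                 unspliced_rate = unspliced_rate,
                 noise_junction_rate = noise_junction_rate,
                 clinical = clinical, effects = effects,
                 ar_expr_factor = ar_expr_factor,
                 threshold_pct = threshold_pct, seed = seed),
            class = "arv_sim_config")
}

simulate_clinical <- function(config) {
  cl <- config$clinical
  n <- config$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  age <- round(rnorm(n, cl$age_mean, cl$age_sd))
  age <- pmin(pmax(age, cl$age_range[1]), cl$age_range[2])
  n_lines <- pmin(1L + rpois(n, cl$n_lines_lambda), cl$max_lines)
  agents <- names(cl$treatment_weights)
  ind <- matrix(0L, n, length(agents), dimnames = list(ids, agents))
  for (i in seq_len(n)) {
    k <- min(n_lines[i], length(agents))
    got <- sample(agents, k, prob = cl$treatment_weights)
    ind[i, got] <- 1L
  }
  truth <- data.frame(patient_id = ids, age_at_biopsy = age,
                      n_treatment_lines = n_lines, ind,
                      check.names = FALSE, stringsAsFactors = FALSE)
  observed <- truth
  mask <- runif(n) < cl$missing_rate
  observed[mask, c("n_treatment_lines", agents)] <- NA
  observed$age_at_biopsy[runif(n) < cl$age_missing_rate] <- NA
  list(truth = truth, observed = observed)
}

# split n generated reads into qualifying/duplicate/secondary/wrong-strand/
# missing-XS categories
split_contamination <- function(n, config) {
  probs <- c(dup = config$dup_rate, secondary = config$secondary_rate,
             wrong_strand = config$wrong_strand_rate,
             xs_missing = config$xs_missing_rate)
  probs <- c(ok = 1 - sum(probs), probs)
  if (n == 0L) return(setNames(rep(0L, 5L), names(probs)))
  drop(stats::rmultinom(1, n, probs))[names(probs)]
}

sam_header <- function(model) {
  c("@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", model$chrom, model$chrom_len))
}

# one SAM line per read; spliced reads are two 50M blocks around the intron.
# vectorized over qname/flag/xs
sam_junction_read <- function(qname, model, donor, acceptor, flag, xs) {
  pos <- donor - 50L
  gap <- acceptor - donor + 1L
  cigar <- sprintf("50M%dN50M", gap)
  tag <- ifelse(is.na(xs), "", sprintf("\tXS:A:%s", xs))
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t200\t%s\t%s%s",
          qname, flag, model$chrom, pos, cigar, pos,
          strrep("A", 100L), strrep("I", 100L), tag)
}

sam_unspliced_read <- function(qname, model, pos, flag) {
  sprintf("%s\t%d\t%s\t%d\t60\t100M\t=\t%d\t200\t%s\t%s",
          qname, flag, model$chrom, pos, pos,
          strrep("A", 100L), strrep("I", 100L))
}

#' Simulate a synthetic cohort
#'
#' Draws per-sample junction read counts from the configured conditions
#' (reference and canonical junctions ~ Poisson(depth); an active variant's
#' junction ~ Poisson(fraction/100 x depth), with clinical effects applied
#' multiplicatively to the fraction), emits every read as a properly flagged,
#' coordinate-sorted SAM record with a skip-gap CIGAR and an `XS` strand
#' attribute, adds the configured contamination (duplicate / secondary /
#' wrong-strand / missing-strand-attribute reads, unspliced reads, sporadic
#' noise junctions), and writes the AR-expression and clinical tables. All
#' draws are integer-count-level, so a fixed seed reproduces the cohort
#' bit-identically.
#'
#' The recorded truth uses the *qualifying* (post-contamination) read counts,
#' so it is consistent with the emitted reads by construction:
#' `true_relexpr = 100 * qualifying variant reads / qualifying reference
#' reads`.
#'
#' @param config An [simulation_config()] object.
#' @param dir Output directory (created if needed).
#' @param model An [toy_isoform_model()]-style model.
#' @return List of class `"arv_sim"` with `files` (named vector of per-sample
#'   SAM paths), `ar_file`, `clinical_file`, `truth` (list: `samples` data
#'   frame, `clinical_truth`, `cohort` list), `locus`, `model`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), dir = tempfile("simcohort"),
                            model = toy_isoform_model()) {
  stopifnot(inherits(config, "arv_sim_config"))
  vn <- config$variants$name
  unknown <- setdiff(vn, model$variant_junctions$name)
  if (length(unknown))
    stop("config variants not in model: ", paste(unknown, collapse = ", "))
  dir.create(file.path(dir, "sam"), recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  clin <- simulate_clinical(config)
  ids <- clin$truth$patient_id
  files <- setNames(file.path(dir, "sam", paste0(ids, ".sam")), ids)

  truth_rows <- list()
  ar_expr <- numeric(config$n_samples)
  vjmap <- model$variant_junctions

  for (i in seq_len(config$n_samples)) {
    chunks <- list()
    positions <- list()
    serial <- 0L
    emit_junction <- function(donor, acceptor, n, base_flag = 99L) {
      if (n == 0L) return(invisible(NULL))
      cat_n <- split_contamination(n, config)
      flag_add <- c(ok = 0L, dup = 1024L, secondary = 256L,
                    wrong_strand = 0L, xs_missing = 0L)
      xs_val <- c(ok = "+", dup = "+", secondary = "+",
                  wrong_strand = "-", xs_missing = NA)
      flags <- base_flag + rep(flag_add, cat_n)
      xs <- rep(xs_val, cat_n)
      qnames <- sprintf("%s_r%06d", ids[i], serial + seq_len(n))
      serial <<- serial + n
      k <- length(chunks) + 1L
      chunks[[k]] <<- sam_junction_read(qnames, model, donor, acceptor,
                                        flags, xs)
      positions[[k]] <<- rep(donor - 50L, n)
      invisible(cat_n)
    }

    # canonical chain, including the E1-E2 reference junction
    canon_counts <- rpois(nrow(model$canonical_junctions), config$depth)
    ref_qual <- 0L
    for (j in seq_len(nrow(model$canonical_junctions))) {
      cj <- model$canonical_junctions[j, ]
      qn <- emit_junction(cj$donor, cj$acceptor, canon_counts[j])
      if (j == 1L) ref_qual <- if (is.null(qn)) 0L else qn[["ok"]]
    }

    # variants
    any_active <- FALSE
    for (v in seq_len(nrow(config$variants))) {
      vr <- config$variants[v, ]
      active <- runif(1) < vr$prevalence
      frac <- vr$fraction_pct
      for (ef in config$effects) {
        if (ef$variant == vr$name &&
            clin$truth[[ef$treatment]][i] == 1L)
          frac <- frac * ef$factor
      }
      if (frac > 100) stop("effect-adjusted fraction exceeds 100%")
      nv <- if (active) rpois(1, frac / 100 * config$depth) else 0L
      any_active <- any_active || (active && nv > 0L)
      jr <- vjmap[vjmap$name == vr$name, ]
      qn <- emit_junction(jr$donor, jr$acceptor, nv)
      nq <- if (is.null(qn)) 0L else qn[["ok"]]
      true_rel <- if (ref_qual > 0L) 100 * nq / ref_qual else NA_real_
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample = ids[i], variant = vr$name, active = active,
        expected_fraction_pct = if (active) frac else 0,
        n_variant_reads = nq, n_reference_reads = ref_qual,
        true_relexpr_pct = true_rel,
        true_positive = !is.na(true_rel) &&
          true_rel >= config$threshold_pct,
        stringsAsFactors = FALSE)
    }

    # sporadic noise junctions (never recurrent by construction)
    n_noise <- rpois(1, config$noise_junction_rate * config$depth)
    for (r in seq_len(n_noise)) {
      donor <- sample(1101:5800, 1)
      acceptor <- donor + sample(50:500, 1)
      emit_junction(donor, acceptor, 1L)
    }

    # unspliced contamination (excluded by the spliced requirement)
    n_unspliced <- rpois(1, config$unspliced_rate * config$depth)
    if (n_unspliced > 0L) {
      pos <- sample(1001:(model$chrom_len - 100L), n_unspliced,
                    replace = TRUE)
      qnames <- sprintf("%s_r%06d", ids[i], serial + seq_len(n_unspliced))
      serial <- serial + n_unspliced
      k <- length(chunks) + 1L
      chunks[[k]] <- sam_unspliced_read(qnames, model, pos, 99L)
      positions[[k]] <- pos
    }

    lines <- unlist(chunks)
    ord <- order(unlist(positions))
    writeLines(c(sam_header(model), lines[ord]), files[i])

    ar_base <- config$depth * exp(rnorm(1, 0, 0.3))
    ar_expr[i] <- ar_base * if (any_active) config$ar_expr_factor else 1
  }

  truth_samples <- do.call(rbind, truth_rows)
  ar <- data.frame(sample = ids, ar_expression = ar_expr,
                   stringsAsFactors = FALSE)
  ar_file <- file.path(dir, "ar_expression.tsv")
  clinical_file <- file.path(dir, "clinical.tsv")
  truth_file <- file.path(dir, "truth_samples.tsv")
  write.table(ar, ar_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(clin$observed, clinical_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth_samples, truth_file, sep = "\t", quote = FALSE,
              row.names = FALSE)

  prev_true <- tapply(truth_samples$true_positive, truth_samples$variant, sum)
  structure(list(
    files = files, ar_file = ar_file, clinical_file = clinical_file,
    truth = list(samples = truth_samples, clinical_truth = clin$truth,
                 cohort = list(true_prevalence = as.list(prev_true),
                               effects = config$effects)),
    locus = locus(model$chrom, 1L, model$chrom_len, model$strand,
                  model$genome_build),
    model = model, config = config, dir = dir),
    class = "arv_sim")
}

#' @export
print.arv_sim <- function(x, ...) {
  cat(sprintf("<arv_sim> %d sample(s) in %s\n", length(x$files), x$dir))
  cat(sprintf("  depth %g, %d variant(s), seed %s\n", x$config$depth,
              nrow(x$config$variants),
              ifelse(is.null(x$config$seed), "unset", x$config$seed)))
  invisible(x)
}

#' Recovery metrics against simulation truth
#'
#' Compares pipeline estimates with the simulator's recorded truth:
#' bias and RMSE of relative expression (over sample-variant pairs where both
#' truth and estimate are defined) and the positivity confusion counts.
#'
#' @param truth The `truth` element of an `"arv_sim"` object (or its
#'   `samples` data frame).
#' @param relexpr An `"arv_relexpr"` object computed from the simulated
#'   cohort.
#' @return List with `bias_pct`, `rmse_pct`, `n_pairs` and `confusion`
#'   (data frame with TP/FP/FN/TN counts).
#' @export
truth_recovery_report <- function(truth, relexpr) {
  ts <- if (is.data.frame(truth)) truth else truth$samples
  est <- as.data.frame(relexpr)
  est <- est[est$status != "exempt", ]
  key_t <- paste(ts$sample, ts$variant)
  key_e <- paste(est$sample, est$variant)
  idx <- match(key_t, key_e)
  if (anyNA(idx))
    stop("sample/variant ids in truth not found in estimates: ",
         paste(head(key_t[is.na(idx)]), collapse = ", "))
  est <- est[idx, ]
  both <- !is.na(ts$true_relexpr_pct) & !is.na(est$relative_expression_pct)
  err <- est$relative_expression_pct[both] - ts$true_relexpr_pct[both]
  conf <- table(truth = factor(ts$true_positive, c(FALSE, TRUE)),
                called = factor(est$positive, c(FALSE, TRUE)))
  list(bias_pct = if (length(err)) mean(err) else NA_real_,
       rmse_pct = if (length(err)) sqrt(mean(err^2)) else NA_real_,
       n_pairs = sum(both),
       confusion = data.frame(
         tp = conf["TRUE", "TRUE"], fp = conf["FALSE", "TRUE"],
         fn = conf["TRUE", "FALSE"], tn = conf["FALSE", "FALSE"]))
}
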