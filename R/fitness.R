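#' Aggregate per-individual scores into per-mCA fitness estimates
#'
#' The fitness of an mCA is estimated as the median PACER score over all
#' individuals carrying that lesion, grouped by (chromosome, arm,
#' copy type). Calls spanning the centromere carry arm `"whole"`;
#' `collapse_arms = TRUE` groups at the chromosome level instead. All
#' calls meeting the mosaic X-loss definition (loss of > 100 Mb of
#' chromosome X) are pooled into a single `X / whole / loss` reference
#' group regardless of nominal arm.
#'
#' @param object A [pacer()] fit, or its `scores` data frame.
#' @param cohort A `cohort_definition` (or its `cohort` data frame) with
#'   the per-sample mCA assignment; defaults to the assignment stored in
#'   the fit.
#' @param samples Optional sample table contributing `age_at_draw` for
#'   the per-group median age.
#' @param collapse_arms Group by chromosome and copy type only?
#' @param copy_types Copy types entering the table; `"undetermined"`
#'   calls are excluded from copy-type-specific aggregation by default.
#' @return Object of class `fitness_table`: data frame with columns
#'   `chromosome`, `arm`, `copy_type`, `n`, `fitness` (median score),
#'   `median_age`, `median_cf`, `median_count`, sorted by fitness
#'   descending.
#' @export
aggregate_fitness <- function(object, cohort = NULL, samples = NULL,
                              collapse_arms = FALSE,
                              copy_types = c("gain", "loss", "cnloh")) {
  scores <- if (inherits(object, "pacer")) object$scores else object
  if (is.null(cohort) && inherits(object, "pacer")) cohort <- object$mca
  cohort <- resolve_mca(cohort)
  if (is.null(cohort)) stop("a cohort assignment is required")
  dat <- merge(scores, cohort, by = "sample_id")
  dat <- dat[dat$copy_type %in% copy_types, , drop = FALSE]
  if (nrow(dat) == 0) stop("no scored individuals with an assigned mCA")
  if (!is.null(samples)) {
    dat <- merge(dat, samples[, c("sample_id", "age_at_draw")],
                 by = "sample_id", all.x = TRUE)
  }
  if (!"arm" %in% names(dat)) dat$arm <- "whole"
  if ("is_loss_of_x" %in% names(dat)) {
    dat$arm[dat$is_loss_of_x] <- "whole"
  }
  dat$.arm <- if (collapse_arms) "all" else dat$arm
  key <- interaction(dat$chromosome, dat$.arm, dat$copy_type, drop = TRUE)
  med <- function(v) if (is.null(v)) NA_real_ else
    as.numeric(stats::median(v, na.rm = TRUE))
  rows <- lapply(split(dat, key), function(g) {
    data.frame(chromosome = g$chromosome[1], arm = g$.arm[1],
               copy_type = g$copy_type[1], n = nrow(g),
               fitness = med(g$score),
               median_age = med(g$age_at_draw),
               median_cf = med(g$clonal_fraction),
               median_count = med(g$raw_count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$fitness), ]
  rownames(out) <- NULL
  class(out) <- c("fitness_table", "data.frame")
  out
}

#' @export
print.fitness_table <- function(x, digits = 3, ...) {
  cat("Per-mCA fitness (median PACER score), ", nrow(x), " groups\n",
      sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (isTRUE(attr(x, "reference_nonpositive"))) {
    cat("NOTE: reference fitness is <= 0; fold changes are sign-unstable,",
        "prefer fitness_diff\n")
  }
  invisible(x)
}

#' Fold change in fitness relative to mosaic X loss
#'
#' Adds `fold_change_vs_xloss = fitness / fitness(reference)` to a
#' fitness table, with loss of chromosome X as the reference lesion
#' (fold change exactly 1 for the reference row). Because fitness here is
#' a median of standard-normal-scale scores it can be negative or close
#' to zero; when the reference fitness is not positive the ratio is still
#' computed but every row is flagged (`sign_warning`), and the stable
#' difference-of-medians alternative `fitness_diff` is always included.
#'
#' @param table A `fitness_table` from [aggregate_fitness()].
#' @param reference Named list identifying the reference row; default
#'   mosaic X loss.
#' @return The augmented `fitness_table`.
#' @export
fold_change <- function(table,
                        reference = list(chromosome = "X",
                                         copy_type = "loss")) {
  stopifnot(is.data.frame(table), all(c("chromosome", "copy_type",
                                        "fitness") %in% names(table)))
  ref_idx <- which(table$chromosome == reference$chromosome &
                     table$copy_type == reference$copy_type)
  if (length(ref_idx) == 0) {
    stop("reference group not found: ", reference$chromosome, " ",
         reference$copy_type,
         " (a loss-of-X group is required for fold changes)")
  }
  if (length(ref_idx) > 1) ref_idx <- ref_idx[which.max(table$n[ref_idx])]
  ref_fit <- table$fitness[ref_idx]
  table$fold_change_vs_xloss <- table$fitness / ref_fit
  table$fold_change_vs_xloss[ref_idx] <- 1
  table$fitness_diff <- table$fitness - ref_fit
  table$sign_warning <- ref_fit <= 0
  attr(table, "reference_nonpositive") <- ref_fit <= 0
  attr(table, "reference_fitness") <- ref_fit
  class(table) <- c("fitness_table", "data.frame")
  table
}

#' Compare aggregated fitness against an external fitness table
#'
#' Regresses external per-mCA fitness values (e.g., estimates derived
#' from population clonal-fraction distributions) on the PACER-derived
#' fitness, median age, and median clonal fraction of each mCA group,
#' restricted to groups with more than `min_n` individuals. Reports the
#' full-model R-squared together with reduced models using median age
#' only and median passenger count only.
#'
#' @param table A `fitness_table` (with `median_age`, `median_cf`,
#'   `median_count` populated).
#' @param external Data frame with `chromosome`, `copy_type`, optionally
#'   `arm`, and `fitness_external`.
#' @param min_n Groups must have strictly more than this many
#'   individuals (default 25).
#' @return List with `model` (the `lm` fit), `coefficients` (estimate,
#'   95% CI, p), `r_squared`, `r_squared_age_only`,
#'   `r_squared_count_only`, and `n_groups`.
#' @export
compare_external <- function(table, external, min_n = 25) {
  stopifnot(is.data.frame(external),
            "fitness_external" %in% names(external))
  by_cols <- intersect(c("chromosome", "arm", "copy_type"),
                       names(external))
  dat <- merge(as.data.frame(table), external, by = by_cols)
  dat <- dat[dat$n > min_n, , drop = FALSE]
  if (nrow(dat) < 5) {
    stop("insufficient overlapping groups: ", nrow(dat),
         " after the n > ", min_n, " filter (need >= 5)")
  }
  full <- stats::lm(fitness_external ~ fitness + median_age + median_cf,
                    data = dat)
  age_only <- stats::lm(fitness_external ~ median_age, data = dat)
  count_only <- stats::lm(fitness_external ~ median_count, data = dat)
  cf <- summary(full)$coefficients
  ci <- stats::confint(full)
  list(model = full,
       coefficients = data.frame(term = rownames(cf),
                                 estimate = cf[, 1], se = cf[, 2],
                                 ci_low = ci[, 1], ci_high = ci[, 2],
                                 p = cf[, 4], row.names = NULL),
       r_squared = summary(full)$r.squared,
       r_squared_age_only = summary(age_only)$r.squared,
       r_squared_count_only = summary(count_only)$r.squared,
       n_groups = nrow(dat))
}

#' Curated malignancy-associated mCA sets
#'
#' Lesion sets associated with future lymphoid or myeloid hematologic
#' malignancy, and with polycythemia vera: lymphoid — gain of chromosome
#' 12, loss of 10q and 13q, CN-LOH of 8q, 9q and 13q; myeloid — loss of
#' 20q and 5q, gain of chromosome 8, CN-LOH of 9q, 14q and 22q;
#' polycythemia vera — CN-LOH or loss of 9p (the JAK2 locus). CN-LOH of
#' 9q appears in both curated lists; [classify_mca()] resolves the
#' overlap by its `ambiguous` argument.
#'
#' @return List of data frames `lymphoid`, `myeloid`, `pv`, each with
#'   columns `chromosome`, `arm` (`"any"` matches every arm), and
#'   `copy_type`.
#' @export
malignancy_classes <- function() {
  list(
    lymphoid = data.frame(
      chromosome = c("12", "10", "13", "8", "9", "13"),
      arm = c("any", "q", "q", "q", "q", "q"),
      copy_type = c("gain", "loss", "loss", "cnloh", "cnloh", "cnloh"),
      stringsAsFactors = FALSE),
    myeloid = data.frame(
      chromosome = c("20", "5", "8", "9", "14", "22"),
      arm = c("q", "q", "any", "q", "q", "q"),
      copy_type = c("loss", "loss", "gain", "cnloh", "cnloh", "cnloh"),
      stringsAsFactors = FALSE),
    pv = data.frame(
      chromosome = c("9", "9"), arm = c("p", "p"),
      copy_type = c("cnloh", "loss"), stringsAsFactors = FALSE))
}

match_class <- function(chromosome, arm, copy_type, spec) {
  vapply(seq_along(chromosome), function(i) {
    any(spec$chromosome == chromosome[i] &
          spec$copy_type == copy_type[i] &
          (spec$arm == "any" | spec$arm == arm[i]))
  }, logical(1))
}

#' Classify an mCA into malignancy-associated sets
#'
#' Deterministic membership test against [malignancy_classes()].
#' Whole-chromosome entries (arm `"any"`) match irrespective of the
#' call's arm. CN-LOH of 9q belongs to both the lymphoid and myeloid
#' curated sets; `ambiguous` selects which label such calls receive.
#'
#' @param chromosome,arm,copy_type Vectors describing the mCA(s); arm in
#'   `c("p", "q", "whole")`.
#' @param spec Class specification, defaults to [malignancy_classes()].
#' @param ambiguous Label for lesions in both the lymphoid and myeloid
#'   sets: `"lymphoid"` (list order, default), `"myeloid"`, or
#'   `"both"`.
#' @return Character vector in
#'   `c("lymphoid", "myeloid", "pv", "neither", "both")`.
#' @examples
#' classify_mca("12", "whole", "gain")  # lymphoid
#' classify_mca("9", "p", "cnloh")      # pv
#' @export
classify_mca <- function(chromosome, arm, copy_type,
                         spec = malignancy_classes(),
                         ambiguous = c("lymphoid", "myeloid", "both")) {
  ambiguous <- match.arg(ambiguous)
  chromosome <- normalize_chrom(chromosome)
  # whole-chromosome calls cover both arms for arm-specific entries
  lymph <- match_class(chromosome, arm, copy_type, spec$lymphoid) |
    (arm == "whole" &
       (match_class(chromosome, "p", copy_type, spec$lymphoid) |
          match_class(chromosome, "q", copy_type, spec$lymphoid)))
  mye <- match_class(chromosome, arm, copy_type, spec$myeloid) |
    (arm == "whole" &
       (match_class(chromosome, "p", copy_type, spec$myeloid) |
          match_class(chromosome, "q", copy_type, spec$myeloid)))
  pv <- match_class(chromosome, arm, copy_type, spec$pv) |
    (arm == "whole" &
       match_class(chromosome, "p", copy_type, spec$pv))
  out <- rep("neither", length(chromosome))
  out[pv] <- "pv"
  out[mye] <- "myeloid"
  out[lymph] <- "lymphoid"
  dual <- lymph & mye
  out[dual] <- switch(ambiguous, lymphoid = "lymphoid",
                      myeloid = "myeloid", both = "both")
  out
}

#' Fitness contrast across malignancy classes
#'
#' One-way ANOVA of per-individual PACER scores across the lymphoid,
#' myeloid and unclassified ("neither") groups.
#'
#' @param object A [pacer()] fit or its `scores` data frame.
#' @param cohort Cohort assignment (defaults to the fit's).
#' @param classes Optional precomputed class labels per scored sample;
#'   otherwise computed with [classify_mca()].
#' @param groups Class labels entering the contrast.
#' @return List with `f` (ANOVA F statistic), `p`, `group_means`,
#'   `group_n`, and the `aov` fit.
#' @export
class_contrast <- function(object, cohort = NULL, classes = NULL,
                           groups = c("lymphoid", "myeloid", "neither")) {
  scores <- if (inherits(object, "pacer")) object$scores else object
  if (is.null(cohort) && inherits(object, "pacer")) cohort <- object$mca
  cohort <- resolve_mca(cohort)
  dat <- merge(scores, cohort, by = "sample_id")
  if (is.null(classes)) {
    dat$class <- classify_mca(dat$chromosome, dat$arm, dat$copy_type)
  } else {
    dat$class <- classes[match(dat$sample_id, scores$sample_id)]
  }
  dat <- dat[dat$class %in% groups, , drop = FALSE]
  tab <- table(dat$class)
  if (sum(tab >= 2) < 2) {
    stop("need at least 2 groups with at least 2 members")
  }
  wvar <- tapply(dat$score, dat$class, stats::var)
  if (all(wvar[tab >= 2] == 0, na.rm = TRUE)) {
    stop("zero within-group variance: scores identical within groups")
  }
  fit <- stats::aov(score ~ class, data = dat)
  an <- summary(fit)[[1]]
  list(f = an$`F value`[1], p = an$`Pr(>F)`[1],
       group_means = tapply(dat$score, dat$class, mean),
       group_n = as.integer(tab), groups = names(tab), aov = fit)
}
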