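#' Sample-level quality filtering
#'
#' Excludes samples whose phased B-allele-frequency autocorrelation
#' exceeds 0.05 (contamination / poor DNA quality) or whose reported sex
#' is discordant with the genotype-inferred sex. Both rules are strict
#' inequalities / explicit flags; missing QC fields are treated as a pass
#' and logged.
#'
#' @param samples Data frame with `sample_id` and, where available,
#'   `baf_autocorrelation` (numeric) and `reported_sex_concordant`
#'   (logical).
#' @return List with `retained` (character vector of sample ids) and
#'   `exclusions` (data frame `sample_id`, `reason`; reason is one of
#'   `"baf_autocorrelation"`, `"sex_discordance"`,
#'   `"missing_qc_assumed_pass"`).
#' @export
filter_samples <- function(samples) {
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  n <- nrow(samples)
  baf <- if ("baf_autocorrelation" %in% names(samples)) {
    samples$baf_autocorrelation
  } else {
    rep(NA_real_, n)
  }
  conc <- if ("reported_sex_concordant" %in% names(samples)) {
    samples$reported_sex_concordant
  } else {
    rep(NA, n)
  }
  excl <- list()
  bad_baf <- !is.na(baf) & baf > 0.05
  if (any(bad_baf)) {
    excl$baf <- data.frame(sample_id = samples$sample_id[bad_baf],
                           reason = "baf_autocorrelation",
                           stringsAsFactors = FALSE)
  }
  bad_sex <- !is.na(conc) & !conc
  if (any(bad_sex)) {
    excl$sex <- data.frame(sample_id = samples$sample_id[bad_sex],
                           reason = "sex_discordance",
                           stringsAsFactors = FALSE)
  }
  miss <- is.na(baf) | is.na(conc)
  keep <- !(bad_baf | bad_sex)
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  log_notes <- if (any(miss & keep)) {
    data.frame(sample_id = samples$sample_id[miss & keep],
               reason = "missing_qc_assumed_pass", stringsAsFactors = FALSE)
  } else {
    exclusions[0, ]
  }
  list(retained = samples$sample_id[keep],
       exclusions = exclusions, notes = log_notes)
}

mca_size_mb <- function(calls) (calls$end - calls$start + 1) / 1e6

#' Call-level quality filtering of mCA calls
#'
#' Applies the post-caller exclusion rules for MoChA-style mCA calls:
#' minimum size 2 Mb; likely germline copy-number polymorphisms
#' (`lod_baf_phase` below 20 for autosomal and below 5 for sex-chromosome
#' calls); constitutional duplications (2-10 Mb segments with relative
#' coverage above 2.25, or 50-250 Mb segments with relative coverage
#' above 2.5); and germline deletions (relative coverage below 0.5). All
#' inequalities are strict as stated, so boundary values pass. Segments
#' in the 10-50 Mb window face no duplication-coverage rule. A dropped
#' call is logged with every rule it failed.
#'
#' @param calls Data frame with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `copy_type`, `clonal_fraction`, `lod_baf_phase`,
#'   `relative_coverage`. Coordinates are 1-based inclusive; size in Mb is
#'   `(end - start + 1) / 1e6`.
#' @return List with `retained` (the surviving calls, with a `size_mb`
#'   and `arm` column added) and `exclusions` (data frame `sample_id`,
#'   `chromosome`, `start`, `end`, `reason` with comma-joined failed
#'   rules).
#' @export
filter_calls <- function(calls) {
  need <- c("sample_id", "chromosome", "start", "end", "copy_type",
            "lod_baf_phase", "relative_coverage")
  stopifnot(is.data.frame(calls), all(need %in% names(calls)))
  calls$chromosome <- normalize_chrom(calls$chromosome)
  size <- mca_size_mb(calls)
  sexchrom <- calls$chromosome %in% c("X", "Y")
  fail <- list(
    min_size = size < 2,
    lod_baf_phase = ifelse(sexchrom, calls$lod_baf_phase < 5,
                           calls$lod_baf_phase < 20),
    constitutional_duplication =
      (size >= 2 & size <= 10 & calls$relative_coverage > 2.25) |
      (size >= 50 & size <= 250 & calls$relative_coverage > 2.5),
    deletion_coverage = calls$relative_coverage < 0.5)
  fail_mat <- do.call(cbind, fail)
  dropped <- rowSums(fail_mat) > 0
  reasons <- apply(fail_mat, 1, function(z) {
    paste(colnames(fail_mat)[z], collapse = ",")
  })
  retained <- calls[!dropped, , drop = FALSE]
  retained$size_mb <- size[!dropped]
  retained$arm <- if (nrow(retained)) {
    chrom_arm(retained$chromosome, retained$start, retained$end)
  } else {
    character(0)
  }
  rownames(retained) <- NULL
  exclusions <- data.frame(sample_id = calls$sample_id[dropped],
                           chromosome = calls$chromosome[dropped],
                           start = calls$start[dropped],
                           end = calls$end[dropped],
                           reason = reasons[dropped],
                           stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  list(retained = retained, exclusions = exclusions)
}

#' Mosaic loss of chromosome X (the fold-change reference lesion)
#'
#' A call qualifies as mosaic X loss when it is a loss on chromosome X
#' spanning more than 100 Mb with relative coverage below 2.5.
#'
#' @param call One-or-more-row data frame of mCA calls (same schema as
#'   [filter_calls()]).
#' @return Logical vector, one element per call.
#' @export
classify_loss_of_x <- function(call) {
  chrom <- normalize_chrom(call$chromosome)
  size <- mca_size_mb(call)
  chrom == "X" & call$copy_type == "loss" & size > 100 &
    call$relative_coverage < 2.5
}

#' Define the single-mCA, CHIP-free analysis cohort
#'
#' Starting from quality-filtered calls and samples, retains individuals
#' with exactly one retained mCA who do not carry a CHIP driver mutation.
#' When `include_sex_chromosomes = FALSE`, calls on X and Y are removed
#' before the single-mCA rule is applied (the fitness-by-chromosome
#' analyses exclude sex-chromosome events; the scoring and genotype
#' association cohorts include chromosome X).
#'
#' @param calls Retained calls from [filter_calls()].
#' @param samples Sample table; only ids in `retained_samples` (if given)
#'   are eligible.
#' @param chip_carriers Character vector of sample ids with CHIP driver
#'   mutations.
#' @param include_sex_chromosomes Count X/Y mCAs toward cohort membership?
#' @param retained_samples Optional character vector from
#'   [filter_samples()]; defaults to all of `samples$sample_id`.
#' @return Object of class `cohort_definition`: list with `cohort` (data
#'   frame `sample_id`, `chromosome`, `arm`, `copy_type`,
#'   `clonal_fraction`, `size_mb`, `relative_coverage`, `is_loss_of_x`)
#'   and `exclusions` (`sample_id`, `reason`).
#' @export
define_cohort <- function(calls, samples, chip_carriers = character(0),
                          include_sex_chromosomes = TRUE,
                          retained_samples = NULL) {
  stopifnot(is.data.frame(calls), is.data.frame(samples))
  if (is.null(retained_samples)) retained_samples <- samples$sample_id
  calls$chromosome <- normalize_chrom(calls$chromosome)
  excl <- list()
  calls <- calls[calls$sample_id %in% retained_samples, , drop = FALSE]
  if (!include_sex_chromosomes) {
    calls <- calls[!(calls$chromosome %in% c("X", "Y")), , drop = FALSE]
  }
  tab <- table(calls$sample_id)
  multi <- names(tab)[tab > 1]
  single <- names(tab)[tab == 1]
  if (length(multi)) {
    excl$multi <- data.frame(sample_id = multi, reason = "multiple_mca",
                             stringsAsFactors = FALSE)
  }
  chip_in <- intersect(single, chip_carriers)
  if (length(chip_in)) {
    excl$chip <- data.frame(sample_id = chip_in, reason = "chip_carrier",
                            stringsAsFactors = FALSE)
  }
  keep_ids <- setdiff(single, chip_carriers)
  cohort <- calls[calls$sample_id %in% keep_ids, , drop = FALSE]
  if (nrow(cohort) == 0) {
    stop("empty cohort: no individual has exactly one retained mCA and ",
         "no CHIP driver mutation")
  }
  if (!"size_mb" %in% names(cohort)) cohort$size_mb <- mca_size_mb(cohort)
  if (!"arm" %in% names(cohort)) {
    cohort$arm <- chrom_arm(cohort$chromosome, cohort$start, cohort$end)
  }
  cohort$is_loss_of_x <- classify_loss_of_x(cohort)
  cohort <- cohort[order(cohort$sample_id),
                   c("sample_id", "chromosome", "arm", "copy_type",
                     "clonal_fraction", "size_mb", "relative_coverage",
                     "is_loss_of_x")]
  rownames(cohort) <- NULL
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  structure(list(cohort = cohort, exclusions = exclusions),
            class = "cohort_definition")
}

#' @export
print.cohort_definition <- function(x, ...) {
  cat("mCA analysis cohort\n")
  cat(sprintf("  individuals (single mCA, CHIP-free): %d\n", nrow(x$cohort)))
  tt <- sort(table(paste(x$cohort$chromosome, x$cohort$arm,
                         x$cohort$copy_type)), decreasing = TRUE)
  top <- utils::head(tt, 5)
  cat("  most frequent lesions:\n")
  for (i in seq_along(top)) {
    cat(sprintf("    %-12s %d\n", names(top)[i], top[i]))
  }
  if (nrow(x$exclusions)) {
    cat("  exclusions:\n")
    print(table(x$exclusions$reason))
  }
  invisible(x)
}
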