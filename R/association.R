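#' Myeloid cell count
#'
#' Sum of neutrophil, basophil, eosinophil and monocyte counts
#' (10^9 cells/L). Missing any component yields a missing sum.
#'
#' @param samples Data frame with `neutrophils`, `basophils`,
#'   `eosinophils`, `monocytes`.
#' @return Numeric vector; `attr(, "n_missing")` counts incomplete rows.
#' @export
myeloid_sum <- function(samples) {
  need <- c("neutrophils", "basophils", "eosinophils", "monocytes")
  stopifnot(all(need %in% names(samples)))
  m <- as.matrix(samples[, need])
  out <- rowSums(m)                      # NA if any component missing
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Blood-count regression on PACER score within an mCA class
#'
#' Ordinary least squares of a peripheral blood count on age at blood
#' draw, sex, clonal fraction and PACER score, within individuals
#' carrying a curated class of lesions. For the polycythemia vera class
#' (chromosome 9p CN-LOH/loss predicting erythrocyte count) the
#' clonal-fraction covariate is omitted, matching the reduced
#' age + sex + score model used for that lesion. The `jak2_chip` class
#' selects individuals flagged in a logical `jak2_v617f` column of the
#' sample table instead of by mCA.
#'
#' @param object A [pacer()] fit.
#' @param samples Sample table with blood counts (and `jak2_v617f` for
#'   that class).
#' @param class One of `"lymphoid"`, `"myeloid"`, `"pv"`, `"jak2_chip"`.
#' @param outcome Blood-count column name; `"myeloid_cells"` uses
#'   [myeloid_sum()]. Defaults per class (lymphocytes for lymphoid,
#'   myeloid sum for myeloid, erythrocytes otherwise).
#' @param exclude_lymph_outliers Drop outcomes above
#'   `lymph_outlier_limit` (the lymphocyte-outlier sensitivity
#'   re-analysis).
#' @param lymph_outlier_limit Outlier threshold, 10^9 cells/L.
#' @return List with `coefficients` (estimate, 95% CI, p per term),
#'   `score_beta`, `score_ci`, `score_p`, `r_squared`,
#'   `r_squared_no_score`, `n`, and the `lm` fit.
#' @export
blood_count_model <- function(object, samples,
                              class = c("lymphoid", "myeloid", "pv",
                                        "jak2_chip"),
                              outcome = NULL,
                              exclude_lymph_outliers = FALSE,
                              lymph_outlier_limit = 10) {
  class <- match.arg(class)
  stopifnot(inherits(object, "pacer"))
  if (anyDuplicated(samples$sample_id)) stop("non-unique sample_id")
  if (is.null(outcome)) {
    outcome <- switch(class, lymphoid = "lymphocytes",
                      myeloid = "myeloid_cells", "erythrocytes")
  }
  samples$myeloid_cells <- tryCatch(myeloid_sum(samples),
                                    error = function(e) NA_real_)
  if (!outcome %in% names(samples)) stop("outcome not present: ", outcome)

  dat <- merge(object$scores, samples, by = "sample_id")
  mca <- object$mca
  if (class == "jak2_chip") {
    if (!"jak2_v617f" %in% names(samples)) {
      stop("jak2_chip class needs a logical 'jak2_v617f' sample column")
    }
    dat <- dat[isTRUE_vec(dat$jak2_v617f), , drop = FALSE]
  } else {
    if (is.null(mca)) stop("fit carries no mCA assignment")
    cls <- classify_mca(mca$chromosome, mca$arm, mca$copy_type)
    ids <- mca$sample_id[cls == class]
    dat <- dat[dat$sample_id %in% ids, , drop = FALSE]
  }
  if (!is.null(mca)) {
    dat$clonal_fraction <- mca$clonal_fraction[match(dat$sample_id,
                                                     mca$sample_id)]
  }
  dat$outcome <- dat[[outcome]]
  if (exclude_lymph_outliers) {
    dat <- dat[is.na(dat$outcome) | dat$outcome <= lymph_outlier_limit, ,
               drop = FALSE]
  }
  dat$female <- as.numeric(dat$sex == "female")
  use_cf <- class != "pv"   # the 9p erythrocyte model omits clonal fraction
  terms <- c("age_at_draw", "female", if (use_cf) "clonal_fraction",
             "score")
  dat <- dat[stats::complete.cases(dat[, c("outcome", terms)]), ,
             drop = FALSE]
  n_par <- length(terms) + 1
  if (nrow(dat) < max(8, n_par + 3)) {
    stop("too few complete cases (", nrow(dat), ") for ", n_par,
         " parameters")
  }
  fmla <- stats::as.formula(paste("outcome ~",
                                  paste(terms, collapse = " + ")))
  fit <- stats::lm(fmla, data = dat)
  red <- stats::lm(stats::as.formula(
    paste("outcome ~", paste(setdiff(terms, "score"), collapse = " + "))),
    data = dat)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  list(coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                                 se = cf[, 2], ci_low = ci[, 1],
                                 ci_high = ci[, 2], p = cf[, 4],
                                 row.names = NULL),
       score_beta = cf["score", 1],
       score_ci = ci["score", ],
       score_p = cf["score", 4],
       r_squared = summary(fit)$r.squared,
       r_squared_no_score = summary(red)$r.squared,
       n = nrow(dat), outcome = outcome, class = class, lm = fit)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Single-variant association scan of passenger counts
#'
#' Per-variant linear regression of rank-inverse-normal-transformed
#' total passenger counts on alternate allele count, adjusted for age,
#' sex, clonal fraction, study, and any supplied ancestry principal
#' component columns. This is a fixed-effects scan for unrelated
#' individuals (no kinship adjustment). Variants with minor allele
#' frequency at or below `maf_min` are excluded; constant genotype
#' columns are skipped and logged.
#'
#' @param genotypes Numeric matrix of allele counts (samples x variants,
#'   rownames = sample ids; 0/1/2, NA allowed).
#' @param counts A `passenger_counts` table.
#' @param samples Sample table.
#' @param mca Cohort assignment supplying clonal fraction (a
#'   `cohort_definition` or data frame).
#' @param covariates Covariate set as in [pacer()].
#' @param pcs Optional data frame/matrix of ancestry principal
#'   components (rownames or `sample_id` column aligning samples).
#' @param variant_meta Optional data frame (`id`, `chromosome`,
#'   `position`) merged into the output.
#' @param maf_min Minor-allele-frequency threshold (strict).
#' @param sig_threshold Genome-wide significance level for the
#'   `significant` flag.
#' @return Data frame with `id`, `chromosome`, `position`, `af`, `beta`,
#'   `se`, `p`, `n`, `significant`; skipped variants recorded in
#'   `attr(, "skipped")`.
#' @export
single_variant_scan <- function(genotypes, counts, samples, mca,
                                covariates = c("age", "sex", "cf",
                                               "study"),
                                pcs = NULL, variant_meta = NULL,
                                maf_min = 0.01, sig_threshold = 5e-8) {
  stopifnot(is.matrix(genotypes), !is.null(rownames(genotypes)))
  mca <- resolve_mca(mca)
  dat <- merge(counts[, c("sample_id", "total")], samples,
               by = "sample_id")
  dat <- merge(dat, mca[, c("sample_id", "clonal_fraction")],
               by = "sample_id")
  dat <- dat[dat$sample_id %in% rownames(genotypes), , drop = FALSE]
  if (nrow(dat) < 30) stop("too few individuals for the scan")
  g <- genotypes[dat$sample_id, , drop = FALSE]
  y <- rank_int(dat$total)
  covs <- list()
  if ("age" %in% covariates) covs$age <- dat$age_at_draw
  if ("sex" %in% covariates) covs$female <- as.numeric(dat$sex == "female")
  if ("cf" %in% covariates) covs$cf <- dat$clonal_fraction
  if ("study" %in% covariates && "study" %in% names(dat) &&
      length(unique(dat$study)) > 1) {
    covs$study <- factor(dat$study)
  }
  if (!is.null(pcs)) {
    pcs <- as.data.frame(pcs)
    if ("sample_id" %in% names(pcs)) {
      rownames(pcs) <- pcs$sample_id
      pcs$sample_id <- NULL
    }
    pcs <- pcs[dat$sample_id, , drop = FALSE]
    covs <- c(covs, as.list(pcs))
  }
  base <- stats::model.matrix(~ ., data = as.data.frame(covs))

  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  const <- apply(g, 2, function(v) length(unique(v[!is.na(v)])) <= 1)
  keep <- maf > maf_min & !const
  skipped <- data.frame(id = colnames(g)[!keep],
                        reason = ifelse(const[!keep], "constant_genotype",
                                        "maf_filter"),
                        stringsAsFactors = FALSE)
  res <- lapply(which(keep), function(j) {
    gj <- g[, j]
    ok <- !is.na(gj)
    fit <- stats::lm.fit(cbind(base[ok, , drop = FALSE], geno = gj[ok]),
                         y[ok])
    k <- length(fit$coefficients)
    rss <- sum(fit$residuals^2)
    dfree <- sum(ok) - k
    xtx_inv <- chol2inv(chol(crossprod(
      cbind(base[ok, , drop = FALSE], geno = gj[ok]))))
    se <- sqrt(rss / dfree * xtx_inv[k, k])
    beta <- fit$coefficients[k]
    tval <- beta / se
    data.frame(id = colnames(g)[j], af = af[j], beta = beta, se = se,
               p = 2 * stats::pt(-abs(tval), dfree), n = sum(ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(id = character(0), af = numeric(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE)
  }
  if (!is.null(variant_meta)) {
    out <- merge(variant_meta[, intersect(c("id", "chromosome",
                                            "position"),
                                          names(variant_meta))],
                 out, by = "id", sort = FALSE)
  }
  out$significant <- out$p < sig_threshold
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Conditional association test for a lead variant
#'
#' Refits the lead variant's regression with a second ("conditioned")
#' variant's allele count added as a covariate, reporting both marginal
#' and conditional effects — the standard check of whether a lead signal
#' is independent of a known variant in linkage disequilibrium.
#'
#' @param lead,conditioned Variant ids (columns of `genotypes`).
#' @inheritParams single_variant_scan
#' @return List with `marginal` and `conditional` one-row data frames
#'   (`beta`, `se`, `p`, `n`) and `collinear` (TRUE when the two
#'   variants are perfectly correlated, in which case the conditional
#'   effect is undefined and reported as NA).
#' @export
conditional_test <- function(lead, conditioned, genotypes, counts,
                             samples, mca,
                             covariates = c("age", "sex", "cf",
                                            "study"), pcs = NULL) {
  stopifnot(lead %in% colnames(genotypes),
            conditioned %in% colnames(genotypes))
  marg <- single_variant_scan(genotypes[, lead, drop = FALSE], counts,
                              samples, mca, covariates, pcs,
                              maf_min = 0)
  mca_df <- resolve_mca(mca)
  dat <- merge(counts[, c("sample_id", "total")], samples,
               by = "sample_id")
  dat <- merge(dat, mca_df[, c("sample_id", "clonal_fraction")],
               by = "sample_id")
  dat <- dat[dat$sample_id %in% rownames(genotypes), , drop = FALSE]
  gl <- genotypes[dat$sample_id, lead]
  gc <- genotypes[dat$sample_id, conditioned]
  ok <- !is.na(gl) & !is.na(gc)
  # a constant conditioned column carries no information: the conditional
  # test collapses to the marginal one exactly
  const_cond <- stats::var(gc[ok]) == 0
  if (!const_cond && abs(stats::cor(gl[ok], gc[ok])) > 1 - 1e-10) {
    cond <- data.frame(id = lead, beta = NA_real_, se = NA_real_,
                       p = NA_real_, n = sum(ok),
                       stringsAsFactors = FALSE)
    return(list(marginal = marg[, c("id", "beta", "se", "p", "n")],
                conditional = cond, collinear = TRUE))
  }
  y <- rank_int(dat$total)
  covs <- list()
  if ("age" %in% covariates) covs$age <- dat$age_at_draw
  if ("sex" %in% covariates) covs$female <- as.numeric(dat$sex == "female")
  if ("cf" %in% covariates) covs$cf <- dat$clonal_fraction
  if ("study" %in% covariates && "study" %in% names(dat) &&
      length(unique(dat$study)) > 1) {
    covs$study <- factor(dat$study)
  }
  base <- stats::model.matrix(~ ., data = as.data.frame(covs))
  X <- if (const_cond) {
    cbind(base[ok, , drop = FALSE], geno = gl[ok])
  } else {
    cbind(base[ok, , drop = FALSE], cond_geno = gc[ok], geno = gl[ok])
  }
  fit <- stats::lm.fit(X, y[ok])
  k <- ncol(X)
  dfree <- sum(ok) - k
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sum(fit$residuals^2) / dfree * xtx_inv[k, k])
  beta <- fit$coefficients[k]
  cond <- data.frame(id = lead, beta = beta, se = se,
                     p = 2 * stats::pt(-abs(beta / se), dfree),
                     n = sum(ok), stringsAsFactors = FALSE)
  list(marginal = marg[, c("id", "beta", "se", "p", "n")],
       conditional = cond, collinear = FALSE)
}

#' Composite linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of unphased allele counts between two
#' variants.
#'
#' @param genotypes Allele-count matrix (samples x variants).
#' @param a,b Variant ids.
#' @return Scalar r-squared.
#' @export
ld_r2 <- function(genotypes, a, b) {
  stopifnot(a %in% colnames(genotypes), b %in% colnames(genotypes))
  x <- genotypes[, a]
  y <- genotypes[, b]
  ok <- !is.na(x) & !is.na(y)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
    stop("constant genotype column: LD undefined")
  }
  stats::cor(x[ok], y[ok])^2
}
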