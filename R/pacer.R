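#' Negative binomial regression of passenger counts on covariates
#'
#' Fits an NB2 model (variance `mu + mu^2 / theta`, log link) of
#' nonnegative integer counts on a covariate table by maximum likelihood.
#' Constant covariate columns are dropped (an all-constant table reduces
#' to the intercept-only fit, whose fitted mean is the sample mean);
#' a rank-deficient design after that is an error. Convergence
#' diagnostics are carried on the returned object rather than discarded.
#'
#' @param counts Nonnegative integer vector.
#' @param covariates Data frame of covariates (numeric, logical or
#'   factor), one row per count; may have zero columns.
#' @return Object of class `nb_fit`: list with `coefficients`, `theta`
#'   (dispersion), `fitted`, `loglik`, `converged`, `iterations`,
#'   `warnings`, `dropped_covariates`, and the underlying `glm` object.
#' @export
fit_nb <- function(counts, covariates = NULL) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be finite nonnegative integers")
  }
  if (all(counts == 0)) stop("cannot fit: all counts are zero")
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_along(counts))
  }
  stopifnot(nrow(covariates) == length(counts))
  dropped <- character(0)
  keep <- vapply(covariates, function(col) length(unique(col)) > 1,
                 logical(1))
  if (length(keep)) {
    dropped <- names(covariates)[!keep]
    covariates <- covariates[, keep, drop = FALSE]
  }
  p <- ncol(covariates) + 1L
  if (length(counts) < 10 * p) {
    warning("fewer than 10 observations per model parameter (n = ",
            length(counts), ", p = ", p, ")")
  }
  dat <- data.frame(.count = counts, covariates,
                    stringsAsFactors = TRUE, check.names = TRUE)
  fmla <- if (ncol(covariates)) stats::as.formula(
    paste(".count ~", paste(names(dat)[-1], collapse = " + "))) else
      stats::as.formula(".count ~ 1")
  mm <- stats::model.matrix(fmla, dat)
  if (qr(mm)$rank < ncol(mm)) {
    stop("collinear design: covariates are linearly dependent")
  }
  warns <- character(0)
  fit <- withCallingHandlers(
    MASS::glm.nb(fmla, data = dat,
                 control = stats::glm.control(epsilon = 1e-8, maxit = 200)),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  out <- list(coefficients = stats::coef(fit),
              theta = fit$theta, se_theta = fit$SE.theta,
              fitted = as.numeric(stats::fitted(fit)),
              loglik = as.numeric(stats::logLik(fit)),
              converged = isTRUE(fit$converged),
              iterations = fit$iter,
              warnings = warns,
              dropped_covariates = dropped,
              glm = fit)
  class(out) <- "nb_fit"
  if (!out$converged) {
    warning("negative binomial fit did not converge; inspect $warnings")
  }
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("Negative binomial (NB2) count model\n")
  print(round(x$coefficients, 4))
  cat(sprintf("dispersion theta = %.4g, log-likelihood = %.4f\n",
              x$theta, x$loglik))
  if (length(x$dropped_covariates)) {
    cat("dropped constant covariates:",
        paste(x$dropped_covariates, collapse = ", "), "\n")
  }
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

# Yeo-Johnson forward transform (monotone increasing for every lambda).
yeo_johnson <- function(y, lambda) {
  pos <- y >= 0
  out <- numeric(length(y))
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((y[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(y[pos])
  }
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -((1 - y[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else {
    out[!pos] <- -log1p(-y[!pos])
  }
  out
}

# Profile log-likelihood of the Gaussianized Yeo-Johnson model.
yj_loglik <- function(y, lambda) {
  z <- yeo_johnson(y, lambda)
  n <- length(y)
  s2 <- stats::var(z) * (n - 1) / n
  if (!is.finite(s2) || s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(y) * log1p(abs(y)))
}

#' Yeo-Johnson inverse-normal transformation of residuals
#'
#' Estimates the Yeo-Johnson power parameter by maximum likelihood,
#' applies the transform, and standardizes the result to mean 0 and
#' variance 1. The map is strictly monotone, so ranks are preserved
#' exactly; on approximately normal input the estimated lambda is close
#' to 1 and the output close to the z-scored input.
#'
#' @param residuals Numeric vector (negative values allowed).
#' @param lambda_range Search interval for the power parameter.
#' @return Numeric vector of scores with `attr(, "lambda")` set.
#' @export
pacer_transform <- function(residuals, lambda_range = c(-3, 5)) {
  y <- residuals
  if (any(!is.finite(y))) stop("residuals must be finite")
  if (length(unique(y)) < 2) {
    stop("degenerate residuals: constant vector cannot be normalized")
  }
  opt <- stats::optimize(function(l) yj_loglik(y, l),
                         interval = lambda_range, maximum = TRUE,
                         tol = 1e-7)
  lambda <- opt$maximum
  z <- yeo_johnson(y, lambda)
  z <- (z - mean(z)) / stats::sd(z)
  attr(z, "lambda") <- lambda
  z
}

#' Rank-based inverse-normal transform (Blom offsets)
#'
#' `qnorm((rank - 3/8) / (n + 1/4))`, the transform applied to passenger
#' counts in the genotype-association analyses.
#'
#' @param x Numeric vector; ties share the average rank.
#' @return Numeric vector of normal scores.
#' @export
rank_int <- function(x) {
  if (any(!is.finite(x))) stop("input must be finite")
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
}

resolve_mca <- function(mca) {
  if (inherits(mca, "cohort_definition")) mca <- mca$cohort
  mca
}

#' Covariate-adjusted clonal expansion-rate (PACER) scores
#'
#' The central fit: regresses each individual's total clock-like
#' passenger count on age, sex, clonal fraction and study via negative
#' binomial (NB2) regression, and converts the residuals to
#' standard-normal-scale scores with a Yeo-Johnson inverse-normal
#' transformation. Higher scores mean more passengers than expected for
#' the individual's age, sex and clone size — i.e., an older, hence
#' faster-expanding, clone. When the mCA assignment is supplied the full
#' pipeline is repeated on counts excluding each individual's
#' mCA-bearing chromosome (`score_excluding_mca_chrom`), the sensitivity
#' analysis for structural artifacts on the rearranged chromosome.
#'
#' @param counts A `passenger_counts` table from [count_passengers()].
#' @param samples Sample table with `sample_id`, `age_at_draw`, `sex`,
#'   and `study` (if used).
#' @param mca Per-sample mCA assignment (a `cohort_definition` or its
#'   `cohort` data frame) providing `clonal_fraction` and `chromosome`.
#' @param covariates Any subset of `c("age", "sex", "cf", "study")`.
#'   `study` enters as fixed-effect indicators and is dropped
#'   automatically when only one study is present.
#' @param residual_type Residuals fed to the transform: `"raw"`
#'   (response-scale, default), `"pearson"` or `"deviance"`. The
#'   transform is monotone per-vector, so the choice affects spacing,
#'   not ranks.
#' @param transform `"yeo_johnson"` (default) or `"rank_int"`.
#' @param exclude_mca_chrom Also compute the chromosome-exclusion score?
#' @return Object of class `pacer`; see [summary.pacer()]. The `scores`
#'   element is a data frame with `sample_id`, `raw_count`, `fitted`,
#'   `residual`, `score`, and (when computed)
#'   `score_excluding_mca_chrom`. Samples missing a required covariate
#'   are dropped and logged in `$dropped`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 400, seed = 7))
#' cd <- define_cohort(filter_calls(cohort$calls)$retained, cohort$samples,
#'                     cohort$chip_carriers)
#' pc <- count_passengers(cohort$variants,
#'                        sample_ids = cd$cohort$sample_id)
#' fit <- pacer(pc, cohort$samples, cd)
#' summary(fit)
#' @export
pacer <- function(counts, samples, mca = NULL,
                  covariates = c("age", "sex", "cf", "study"),
                  residual_type = c("raw", "pearson", "deviance"),
                  transform = c("yeo_johnson", "rank_int"),
                  exclude_mca_chrom = !is.null(mca)) {
  residual_type <- match.arg(residual_type)
  transform <- match.arg(transform)
  covariates <- match.arg(covariates, several.ok = TRUE)
  stopifnot(is.data.frame(counts), "total" %in% names(counts))
  mca <- resolve_mca(mca)
  if (("cf" %in% covariates || exclude_mca_chrom) && is.null(mca)) {
    stop("an mCA assignment is required for the clonal-fraction ",
         "covariate and the chromosome-exclusion score")
  }

  dat <- counts[, c("sample_id", "total")]
  names(dat)[2] <- "raw_count"
  dat <- merge(dat, samples, by = "sample_id", sort = TRUE)
  if (!is.null(mca)) {
    dat <- merge(dat,
                 mca[, intersect(c("sample_id", "chromosome",
                                   "clonal_fraction"), names(mca))],
                 by = "sample_id", sort = TRUE)
  }

  dropped <- data.frame(sample_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_missing <- function(dat, col, reason) {
    bad <- is.na(dat[[col]])
    if (any(bad)) {
      dropped <<- rbind(dropped,
                        data.frame(sample_id = dat$sample_id[bad],
                                   reason = reason,
                                   stringsAsFactors = FALSE))
    }
    dat[!bad, , drop = FALSE]
  }
  design_cols <- list()
  if ("age" %in% covariates) {
    dat <- drop_missing(dat, "age_at_draw", "missing_age")
  }
  if ("sex" %in% covariates) {
    dat <- drop_missing(dat, "sex", "missing_sex")
  }
  if ("cf" %in% covariates) {
    dat <- drop_missing(dat, "clonal_fraction", "missing_clonal_fraction")
  }
  if (nrow(dat) < 3) stop("too few scoreable samples after drops")
  if ("age" %in% covariates) design_cols$age <- dat$age_at_draw
  if ("sex" %in% covariates) {
    design_cols$female <- as.numeric(dat$sex == "female")
  }
  if ("cf" %in% covariates) design_cols$cf <- dat$clonal_fraction
  if ("study" %in% covariates && "study" %in% names(dat)) {
    design_cols$study <- factor(dat$study)
  }
  design <- as.data.frame(design_cols, stringsAsFactors = FALSE)

  score_pipeline <- function(y) {
    fit <- fit_nb(y, design)
    res <- switch(residual_type,
                  raw = y - fit$fitted,
                  pearson = (y - fit$fitted) /
                    sqrt(fit$fitted + fit$fitted^2 / fit$theta),
                  deviance = stats::residuals(fit$glm, type = "deviance"))
    sc <- if (transform == "yeo_johnson") pacer_transform(res) else {
      z <- rank_int(res)
      attr(z, "lambda") <- NA_real_
      z
    }
    list(fit = fit, residual = res, score = as.numeric(sc),
         lambda = attr(sc, "lambda"))
  }

  main <- score_pipeline(dat$raw_count)
  scores <- data.frame(sample_id = dat$sample_id,
                       raw_count = dat$raw_count,
                       fitted = main$fit$fitted,
                       residual = main$residual,
                       score = main$score,
                       stringsAsFactors = FALSE)
  excl <- NULL
  if (exclude_mca_chrom) {
    idx <- match(dat$sample_id, counts$sample_id)
    tot_ex <- total_excluding(counts[idx, , drop = FALSE],
                              dat$chromosome)
    excl <- score_pipeline(tot_ex)
    scores$count_excluding_mca_chrom <- tot_ex
    scores$score_excluding_mca_chrom <- excl$score
  }

  structure(list(scores = scores, fit = main$fit,
                 fit_excluding = if (!is.null(excl)) excl$fit,
                 lambda = main$lambda,
                 lambda_excluding = if (!is.null(excl)) excl$lambda,
                 covariates = names(design),
                 residual_type = residual_type,
                 transform = transform,
                 design = design,
                 mca = if (!is.null(mca))
                   mca[mca$sample_id %in% dat$sample_id, , drop = FALSE],
                 counts = counts,
                 dropped = dropped,
                 call = match.call()),
            class = "pacer")
}

#' @export
print.pacer <- function(x, ...) {
  cat("PACER clonal expansion-rate scores\n")
  cat(sprintf("  %d individuals scored (%d dropped)\n",
              nrow(x$scores), nrow(x$dropped)))
  cat(sprintf("  covariates: %s | residuals: %s | transform: %s\n",
              paste(x$covariates, collapse = ", "),
              x$residual_type, x$transform))
  if (is.finite(x$lambda %||% NA)) {
    cat(sprintf("  Yeo-Johnson lambda = %.3f\n", x$lambda))
  }
  cat(sprintf("  passenger counts: min %d / median %g / max %d\n",
              min(x$scores$raw_count), stats::median(x$scores$raw_count),
              max(x$scores$raw_count)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
summary.pacer <- function(object, ...) {
  s <- object$scores$score
  out <- list(n = nrow(object$scores),
              coefficients = object$fit$coefficients,
              theta = object$fit$theta,
              lambda = object$lambda,
              score_summary = summary(s),
              score_sd = stats::sd(s),
              count_summary = summary(object$scores$raw_count),
              dropped = object$dropped,
              has_exclusion =
                "score_excluding_mca_chrom" %in% names(object$scores))
  class(out) <- "summary.pacer"
  out
}

#' @export
print.summary.pacer <- function(x, ...) {
  cat("PACER scoring summary\n")
  cat(sprintf("  n = %d scored individuals\n", x$n))
  cat("  NB regression coefficients (log mean scale):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  dispersion theta = %.3f", x$theta))
  if (is.finite(x$lambda %||% NA)) {
    cat(sprintf(", Yeo-Johnson lambda = %.3f", x$lambda))
  }
  cat("\n  passenger count distribution:\n")
  print(x$count_summary)
  cat(sprintf("  score mean = %.3g, sd = %.3f\n",
              unname(x$score_summary["Mean"]), x$score_sd))
  if (x$has_exclusion) {
    cat("  chromosome-exclusion scores available\n")
  }
  invisible(x)
}

#' @export
coef.pacer <- function(object, ...) object$fit$coefficients

#' @export
fitted.pacer <- function(object, ...) object$scores$fitted

#' @export
residuals.pacer <- function(object, ...) object$scores$residual

#' Predicted passenger counts for new covariate values
#'
#' @param object A fitted [pacer()] object.
#' @param newdata Data frame with the covariate columns used in the fit
#'   (`age_at_draw`, `sex`, `clonal_fraction`, `study` as applicable);
#'   defaults to the training data.
#' @param type `"response"` (expected count) or `"link"` (log mean).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.pacer <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mu <- object$scores$fitted
    return(if (type == "response") mu else log(mu))
  }
  nd <- list()
  if ("age" %in% object$covariates) nd$age <- newdata$age_at_draw
  if ("female" %in% object$covariates) {
    nd$female <- as.numeric(newdata$sex == "female")
  }
  if ("cf" %in% object$covariates) nd$cf <- newdata$clonal_fraction
  if ("study" %in% object$covariates) {
    nd$study <- factor(newdata$study,
                       levels = levels(object$design$study))
  }
  stats::predict(object$fit$glm, newdata = as.data.frame(nd), type = type)
}

#' Simulate passenger counts from the fitted count model
#'
#' Draws negative binomial counts at the fitted per-sample means and
#' dispersion; useful for posterior-predictive style checks of the
#' covariate model.
#'
#' @param object A fitted [pacer()] object.
#' @param nsim Number of replicate count vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated totals.
#' @export
simulate.pacer <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$scores$fitted
  out <- as.data.frame(replicate(
    nsim, stats::rnbinom(length(mu), size = object$fit$theta, mu = mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$scores$sample_id
  out
}

#' Diagnostic plots for PACER scores
#'
#' Left: observed versus model-fitted passenger counts. Right: normal
#' quantile plot of the transformed scores.
#'
#' @param x A fitted [pacer()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pacer <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$scores$fitted, x$scores$raw_count,
                 xlab = "fitted mean passenger count",
                 ylab = "observed passenger count",
                 main = "NB covariate model", ...)
  graphics::abline(0, 1, lty = 2)
  stats::qqnorm(x$scores$score, main = "PACER score normality")
  stats::qqline(x$scores$score, lty = 2)
  invisible(x)
}

#' Chromosome-exclusion sensitivity check
#'
#' Quantifies whether the mCA-bearing chromosome distorts passenger-based
#' scores: (1) the Spearman rank correlation between scores computed with
#' and without the mCA chromosome (or a random non-mCA chromosome); and
#' (2) a per-sample rate test of passenger density on the mCA chromosome
#' against the rest of the genome using chromosome-length exposures
#' (binomial test per sample, plus a length-standardized aggregate
#' z-test across samples).
#'
#' @param object A [pacer()] fit with the exclusion score populated.
#' @param mode `"mca_chrom"` (default) or `"random_chrom"`, which
#'   substitutes a uniformly drawn non-mCA chromosome per sample.
#' @param seed RNG seed for `"random_chrom"`.
#' @return List with `rho` (Spearman correlation of the two score
#'   vectors), `aggregate_z`, `aggregate_p`, and `per_sample` (data frame
#'   with observed/expected mCA-chromosome counts and binomial p-values).
#' @export
chromosome_exclusion_check <- function(object,
                                       mode = c("mca_chrom",
                                                "random_chrom"),
                                       seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(object, "pacer"))
  if (is.null(object$mca)) stop("fit carries no mCA assignment")
  sc <- object$scores
  if (nrow(sc) < 10) stop("need at least 10 scored samples")
  counts <- object$counts
  idx <- match(sc$sample_id, counts$sample_id)
  mca_chrom <- object$mca$chromosome[match(sc$sample_id,
                                           object$mca$sample_id)]
  if (mode == "random_chrom") {
    if (!is.null(seed)) set.seed(seed)
    all_chroms <- names(chrom_lengths())
    chrom <- vapply(mca_chrom, function(mc) {
      sample(setdiff(all_chroms, mc), 1)
    }, character(1))
    tot_ex <- total_excluding(counts[idx, , drop = FALSE], chrom)
    fitx <- fit_nb(tot_ex, object$design)
    resx <- tot_ex - fitx$fitted
    score_ex <- as.numeric(pacer_transform(resx))
  } else {
    chrom <- mca_chrom
    if (!"score_excluding_mca_chrom" %in% names(sc)) {
      stop("fit computed without the chromosome-exclusion score")
    }
    score_ex <- sc$score_excluding_mca_chrom
  }
  rho <- stats::cor(sc$score, score_ex, method = "spearman")

  lens <- chrom_lengths()
  cols <- paste0("chr", chrom)
  ci <- match(cols, names(counts))
  x_on <- ifelse(is.na(ci), 0L,
                 as.integer(counts[cbind(idx, ci)]))
  total <- counts$total[idx]
  p0 <- lens[chrom] / sum(lens)
  per_p <- mapply(function(x, n, p) {
    if (n == 0) return(NA_real_)
    stats::binom.test(x, n, p)$p.value
  }, x_on, total, p0)
  expected <- total * p0
  z <- (sum(x_on) - sum(expected)) /
    sqrt(sum(total * p0 * (1 - p0)))
  list(rho = rho, mode = mode,
       aggregate_z = as.numeric(z),
       aggregate_p = 2 * stats::pnorm(-abs(z)),
       per_sample = data.frame(sample_id = sc$sample_id,
                               chromosome = chrom,
                               observed = x_on, total = total,
                               expected = as.numeric(expected),
                               p = as.numeric(per_p),
                               stringsAsFactors = FALSE))
}
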