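nb_loglik <- function(y, X, beta, theta) {
  mu <- exp(drop(X %*% beta))
  sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
}

test_that("intercept-only NB fit recovers the sample mean", {
  set.seed(1)
  y <- rnbinom(500, size = 5, mu = 40)
  fit <- fit_nb(y)
  expect_equal(unname(fit$fitted[1]), mean(y), tolerance = 1e-6)
  # an all-constant covariate table reduces to the same fit
  fit2 <- fit_nb(y, data.frame(a = rep(2, 500), b = rep("x", 500)))
  expect_equal(unname(fit2$fitted[1]), mean(y), tolerance = 1e-6)
  expect_setequal(fit2$dropped_covariates, c("a", "b"))
})

test_that("NB regression recovers known coefficients", {
  set.seed(2)
  n <- 5000
  age <- runif(n, 40, 90)
  female <- rbinom(n, 1, 0.5)
  beta <- c(intercept = 2.5, age = log(0.8) / 10, female = 0.15)
  mu <- exp(beta[1] + beta[2] * age + beta[3] * female)
  y <- rnbinom(n, size = 4, mu = mu)
  fit <- fit_nb(y, data.frame(age = age, female = female))
  se <- summary(fit$glm)$coefficients[, 2]
  expect_lt(abs(fit$coefficients["age"] - beta[2]), 2 * se["age"])
  expect_lt(abs(fit$coefficients["female"] - beta[3]), 2 * se["female"])
  expect_lt(abs(fit$theta - 4) / 4, 0.25)
})

test_that("NB fit approaches the Poisson likelihood on Poisson data", {
  set.seed(3)
  x <- runif(800)
  y <- rpois(800, exp(2 + 0.5 * x))
  nb <- fit_nb(y, data.frame(x = x))
  po <- glm(y ~ x, family = poisson)
  expect_lt(abs(nb$loglik - as.numeric(logLik(po))), 0.1)
})

test_that("fitted NB likelihood dominates a brute-force parameter grid", {
  set.seed(4)
  n <- 30
  x1 <- rnorm(n); x2 <- runif(n)
  y <- rnbinom(n, size = 2, mu = exp(1.5 + 0.6 * x1 - 0.4 * x2))
  fit <- fit_nb(y, data.frame(x1 = x1, x2 = x2))
  X <- cbind(1, x1, x2)
  ll_hat <- nb_loglik(y, X, fit$coefficients, fit$theta)
  expect_equal(ll_hat, fit$loglik, tolerance = 1e-6)
  grid_b <- lapply(fit$coefficients,
                   function(b) seq(b - 2, b + 2, length.out = 9))
  thetas <- exp(seq(log(0.1), log(50), length.out = 12))
  best <- -Inf
  for (b0 in grid_b[[1]]) for (b1 in grid_b[[2]]) for (b2 in grid_b[[3]]) {
    mu <- exp(X %*% c(b0, b1, b2))
    for (th in thetas) {
      ll <- sum(dnbinom(y, size = th, mu = mu, log = TRUE))
      if (ll > best) best <- ll
    }
  }
  expect_gte(ll_hat + 1e-6, best)
})

test_that("degenerate count inputs raise explicit errors", {
  expect_error(fit_nb(rep(0, 50)), "all counts are zero")
  expect_error(fit_nb(c(1.5, 2, 3)), "nonnegative integers")
  set.seed(5)
  x <- rnorm(100)
  y <- rpois(100, 10)
  expect_error(fit_nb(y, data.frame(a = x, b = 2 * x)), "collinear")
})

test_that("Yeo-Johnson scoring is a standardizing, rank-preserving map", {
  set.seed(6)
  y <- rnorm(10000)
  z <- pacer_transform(y)
  expect_lt(abs(attr(z, "lambda") - 1), 0.05)
  expect_lt(max(abs(z - scale(y)[, 1])), 0.05)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)
  # rank preservation on skewed input
  y2 <- rexp(500)^2 - 0.5
  z2 <- pacer_transform(y2)
  expect_equal(cor(y2, z2, method = "spearman"), 1)
  # symmetric three-point input maps to a symmetric output
  z3 <- pacer_transform(c(-1, 0, 1))
  expect_equal(sort(as.numeric(z3)), sort(-as.numeric(z3)),
               tolerance = 1e-6)
  expect_error(pacer_transform(rep(1, 30)), "degenerate")
})

test_that("in-package Yeo-Johnson MLE matches an independent implementation", {
  set.seed(7)
  y <- rexp(800) - 0.3          # skewed, mixed-sign
  lam_pkg <- attr(pacer_transform(y), "lambda")
  pt <- car::powerTransform(y ~ 1, family = "yjPower")
  expect_equal(lam_pkg, unname(coef(pt)), tolerance = 0.01)
})

test_that("rank-based inverse normal uses Blom offsets", {
  x <- c(3, 1, 2)
  expect_equal(rank_int(x), qnorm((c(3, 1, 2) - 0.375) / 3.25))
  set.seed(8)
  z <- rank_int(runif(200))
  expect_equal(cor(z, sort(z)[rank(z)]), 1)
})

test_that("scoring is monotone in counts and invariant to row order", {
  set.seed(9)
  n <- 60
  samples <- data.frame(sample_id = sprintf("p%02d", 1:n),
                        age_at_draw = 65, sex = "female",
                        study = "S1", stringsAsFactors = FALSE)
  mca <- data.frame(sample_id = samples$sample_id, chromosome = "12",
                    clonal_fraction = 0.2, stringsAsFactors = FALSE)
  counts <- data.frame(sample_id = samples$sample_id,
                       total = c(80, 20, rpois(n - 2, 40)),
                       chr12 = 0L, stringsAsFactors = FALSE)
  class(counts) <- c("passenger_counts", "data.frame")
  fit <- pacer(counts, samples, mca, covariates = c("age", "sex", "cf"))
  sc <- fit$scores
  expect_gt(sc$score[sc$sample_id == "p01"],
            sc$score[sc$sample_id == "p02"])
  # permuted input rows give identical per-sample scores
  perm <- sample(n)
  fit2 <- pacer(counts[perm, ], samples[sample(n), ], mca[sample(n), ],
                covariates = c("age", "sex", "cf"))
  m <- match(sc$sample_id, fit2$scores$sample_id)
  expect_equal(fit2$scores$score[m], sc$score)
})

test_that("scores are invariant to affine rescaling of covariates", {
  co <- make_cohort(seed = 101, n = 400)
  s2 <- co$bundle$samples
  s2$age_at_draw <- 10 * s2$age_at_draw - 100
  fit2 <- pacer(co$counts, s2, co$cohort)
  expect_lt(max(abs(fit2$scores$score - co$fit$scores$score)), 1e-6)
})

test_that("cohort scores are standardized with both score variants", {
  co <- acceptance_cohort()
  sc <- co$fit$scores
  expect_lt(abs(mean(sc$score)), 0.05)
  expect_lt(abs(sd(sc$score) - 1), 0.05)
  expect_lt(abs(mean(sc$score_excluding_mca_chrom)), 0.05)
  expect_true(all(is.finite(sc$score)))
})

test_that("scores are close to normal when the count model is well specified", {
  # counts drawn straight from the NB covariate model (no detectability
  # thinning, so no discrete lower mass): the transformed scores should
  # pass a normality sanity check
  set.seed(14)
  n <- 2000
  age <- runif(n, 45, 90)
  cf <- runif(n, 0.05, 0.6)
  mu <- exp(2.5 + 0.015 * age - 0.8 * cf)
  y <- rnbinom(n, size = 10, mu = mu)
  fit <- fit_nb(y, data.frame(age = age, cf = cf))
  z <- pacer_transform(y - fit$fitted)
  ks <- suppressWarnings(ks.test(as.numeric(z), "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("samples missing covariates are dropped with a log entry", {
  co <- make_cohort(seed = 101, n = 400)
  s2 <- co$bundle$samples
  s2$sex[1] <- NA
  victim <- s2$sample_id[1]
  fit2 <- pacer(co$counts, s2, co$cohort)
  if (victim %in% co$fit$scores$sample_id) {
    expect_false(victim %in% fit2$scores$sample_id)
    expect_true(victim %in% fit2$dropped$sample_id)
    expect_equal(fit2$dropped$reason[fit2$dropped$sample_id == victim],
                 "missing_sex")
  }
})

test_that("model methods expose coefficients, predictions and simulations", {
  co <- make_cohort(seed = 101, n = 400)
  fit <- co$fit
  expect_named(coef(fit))
  expect_equal(length(fitted(fit)), nrow(fit$scores))
  expect_equal(length(residuals(fit)), nrow(fit$scores))
  expect_equal(unname(predict(fit)[1]), fit$scores$fitted[1])
  nd <- data.frame(age_at_draw = c(60, 80), sex = "female",
                   clonal_fraction = 0.2, study = "STUDY_A")
  pr <- predict(fit, nd)
  expect_length(pr, 2)
  expect_true(all(pr > 0))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(fit$scores), 3))
  expect_output(print(fit), "PACER")
  expect_output(print(summary(fit)), "dispersion")
})

test_that("an mCA chromosome without passengers leaves scores unchanged", {
  set.seed(10)
  n <- 80
  samples <- data.frame(sample_id = sprintf("q%02d", 1:n),
                        age_at_draw = runif(n, 50, 85),
                        sex = sample(c("female", "male"), n, TRUE),
                        study = "S1", stringsAsFactors = FALSE)
  mca <- data.frame(sample_id = samples$sample_id, chromosome = "21",
                    clonal_fraction = runif(n, 0.05, 0.5),
                    stringsAsFactors = FALSE)
  counts <- data.frame(sample_id = samples$sample_id,
                       total = rpois(n, 30) + 1L,
                       stringsAsFactors = FALSE)
  counts$chr1 <- counts$total   # everything off the mCA chromosome
  counts$chr21 <- 0L
  class(counts) <- c("passenger_counts", "data.frame")
  fit <- pacer(counts, samples, mca, covariates = c("age", "sex", "cf"))
  chk <- chromosome_exclusion_check(fit)
  expect_equal(chk$rho, 1)
  expect_equal(fit$scores$score, fit$scores$score_excluding_mca_chrom)
})

test_that("passenger enrichment on the mCA chromosome degrades concordance", {
  null_co <- make_cohort(seed = 303, n = 500)
  adv_co <- make_cohort(seed = 303, n = 500, mca_chrom_enrichment = 0.5)
  rho_null <- chromosome_exclusion_check(null_co$fit)$rho
  rho_adv <- chromosome_exclusion_check(adv_co$fit)$rho
  expect_lt(rho_adv, rho_null)
  # and the density test flags the enrichment
  chk_adv <- chromosome_exclusion_check(adv_co$fit)
  expect_lt(chk_adv$aggregate_p, 0.01)
  expect_gt(chk_adv$aggregate_z, 0)
})

test_that("random-chromosome exclusion mode is seeded and comparable", {
  co <- make_cohort(seed = 101, n = 400)
  chk1 <- chromosome_exclusion_check(co$fit, mode = "random_chrom",
                                     seed = 42)
  chk2 <- chromosome_exclusion_check(co$fit, mode = "random_chrom",
                                     seed = 42)
  expect_equal(chk1$rho, chk2$rho)
  expect_true(all(chk1$per_sample$chromosome !=
                    co$fit$mca$chromosome[match(chk1$per_sample$sample_id,
                                                co$fit$mca$sample_id)]))
  expect_gt(chk1$rho, 0.5)
})
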