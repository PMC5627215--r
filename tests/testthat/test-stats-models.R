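test_that("transforms follow their closed forms and round-trip", {
  expect_equal(apply_transform(0.9, "log10_one_minus"), -1)
  expect_equal(apply_transform(1, "log10"), 0)
  expect_equal(apply_transform(c(1, 10, 100), "log10"), c(0, 1, 2))
  expect_error(apply_transform(1.0, "log10_one_minus"), "offending rows")
  expect_error(apply_transform(c(2, 0, 3), "log10"), "2")
  set.seed(15)
  x <- runif(50, 0.01, 0.99)
  expect_equal(shoalnoise:::invert_transform(
    apply_transform(x, "log10_one_minus"), "log10_one_minus"), x,
    tolerance = 1e-12)
  expect_equal(shoalnoise:::invert_transform(
    apply_transform(x, "log10"), "log10"), x, tolerance = 1e-12)
})

test_that("a forced treatment-by-half signal is detected overwhelmingly", {
  set.seed(16)
  tab <- make_response_table(
    effects = function(tr, h) {
      10 + 5 * (tr == "pile_driving") * (h == "second")
    },
    fish_sd = 1, trial_sd = 1, resid_sd = 0.01
  )
  fit <- fit_lmm(tab, "y", transform = "none")
  expect_lt(fit$interaction$p, 1e-6)
  expect_equal(fit$pruning, "interaction_kept")
})

test_that("LMM fitting is deterministic and prunes null interactions", {
  set.seed(27)
  tab <- make_response_table(effects = function(tr, h) 10,
                             fish_sd = 1, trial_sd = 1, resid_sd = 1)
  f1 <- fit_lmm(tab, "y", transform = "none")
  f2 <- fit_lmm(tab, "y", transform = "none")
  expect_equal(f1$fixef, f2$fixef, tolerance = 1e-10)
  expect_equal(f1$interaction$p, f2$interaction$p, tolerance = 1e-10)
  # with no interaction in truth, pruning is the overwhelmingly likely
  # outcome for this draw
  expect_equal(f1$pruning, "interaction_dropped")
  expect_true(all(c("(Intercept)", "treatmentpile_driving", "halfsecond")
                  %in% rownames(f1$fixef)))
})

test_that("the speed covariate joins the fixed effects when requested", {
  set.seed(18)
  tab <- make_response_table(effects = function(tr, h) 10,
                             fish_sd = 1, trial_sd = 1, resid_sd = 1)
  fit <- fit_lmm(tab, "y", covariate_speed = TRUE, transform = "none")
  expect_true("median_speed" %in% rownames(fit$fixef))
})

test_that("unbalanced halves are rejected", {
  set.seed(19)
  tab <- make_response_table(effects = function(tr, h) 10, resid_sd = 1)
  expect_error(fit_lmm(tab[-1, ], "y", transform = "none"), "unbalanced")
})

test_that("NB GLMM recovers a known shape parameter", {
  set.seed(20)
  tab <- make_response_table(effects = function(tr, h) 0)
  tab$y <- rnbinom(nrow(tab), mu = 50, size = 5)
  fit <- fit_nb_glmm(tab, "y")
  expect_false(fit$shape_boundary)
  expect_lt(abs(fit$k - 5) / 5, 0.3)
  expect_equal(fit$family, "nb_glmm")
})

test_that("a strong built-in interaction is detected by the NB LRT", {
  set.seed(21)
  hits <- vapply(1:100, function(i) {
    tab <- make_response_table(n_trials_per_treatment = 15)
    mu <- ifelse(tab$treatment == "pile_driving" & tab$half == "second",
                 60, 30)
    tab$y <- rnbinom(nrow(tab), mu = mu, size = 8)
    fit <- fit_nb_glmm(tab, "y")
    fit$interaction$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("all-zero responses are rejected", {
  tab <- make_response_table(effects = function(tr, h) 0)
  tab$y <- 0
  expect_error(fit_nb_glmm(tab, "y"), "all-zero")
})

test_that("the dispersion check accepts well-specified NB data", {
  set.seed(22)
  passes <- vapply(1:100, function(i) {
    tab <- make_response_table()
    tab$y <- rnbinom(nrow(tab), mu = 40, size = 6)
    dispersion_check(tab, "y")$pass
  }, logical(1))
  expect_gte(mean(passes), 0.95)
})

test_that("gross overdispersion beyond the NB fit raises the fail flag", {
  set.seed(23)
  tab <- make_response_table()
  n <- nrow(tab)
  # rare huge outbreaks that no single NB shape can absorb
  y <- rpois(n, 10)
  y[sample(n, 12)] <- rpois(12, 2000)
  tab$y <- y
  d <- dispersion_check(tab, "y")
  expect_false(d$pass)
  expect_gt(d$dispersion, 2)
})

test_that("near-Poisson data pass the dispersion window comfortably", {
  set.seed(24)
  tab <- make_response_table()
  tab$y <- rpois(nrow(tab), 40)
  d <- dispersion_check(tab, "y")
  expect_true(d$pass)
  expect_lt(abs(d$dispersion - 1), 0.5)
})

test_that("effect sizes of change follow Cohen's d with the pile sign", {
  # identical change distributions: d is exactly zero
  set.seed(25)
  base <- make_response_table(effects = function(tr, h) 10)
  deltas <- rnorm(15)
  for (tr in c("ambient", "pile_driving")) {
    trials <- unique(base$trial[base$treatment == tr])
    for (i in seq_along(trials)) {
      sel <- base$trial == trials[i] & base$half == "second"
      base$y[sel] <- base$y[sel] + deltas[i]
    }
  }
  expect_equal(effect_size_of_change(base, "y")$d, 0, tolerance = 1e-12)

  # shifting one arm by exactly one pooled SD gives d = 1
  z <- as.numeric(scale(rnorm(15)))  # mean 0, sd exactly 1
  tab <- make_response_table(effects = function(tr, h) 0)
  for (tr in c("ambient", "pile_driving")) {
    trials <- unique(tab$trial[tab$treatment == tr])
    for (i in seq_along(trials)) {
      sel <- tab$trial == trials[i] & tab$half == "second"
      tab$y[sel] <- z[i] + (tr == "pile_driving")
    }
  }
  es <- effect_size_of_change(tab, "y")
  expect_equal(es$d, 1, tolerance = 1e-12)
  expect_gt(es$d, 0)  # larger half-2 increase under pile is positive
  expect_equal(unname(es$n_trials), c(15L, 15L))
  expect_error(
    effect_size_of_change(tab[tab$trial %in% c("T01", "T16"), ], "y"),
    "at least 2")
})
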