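test_that("path_model_spec rejects cycles and shared indicators", {
  expect_error(
    path_model_spec(list(A = "a", B = "b"),
                    data.frame(from = c("A", "B"), to = c("B", "A"))),
    class = "anspm_cyclic_model")
  expect_error(
    path_model_spec(list(A = c("a", "b"), B = "b"),
                    data.frame(from = "A", to = "B")),
    class = "anspm_invalid_argument")
  expect_error(
    path_model_spec(list(A = "a"), data.frame(from = "A", to = "Ghost")),
    class = "anspm_invalid_argument")
})

test_that("align_indicator_signs flips against the block principal component", {
  set.seed(2)
  x <- rnorm(100)
  tab <- data.frame(m1 = x, m2 = -x, m3 = x + rnorm(100, 0, 0.05),
                    y = rnorm(100))
  spec <- path_model_spec(list(A = c("m1", "m2", "m3"), B = "y"),
                          data.frame(from = "A", to = "B"))
  al <- align_indicator_signs(tab, spec)
  expect_identical(al$flipped, "m2")
  cors <- cor(al$table[, c("m1", "m2", "m3")])
  expect_true(all(cors >= 0))

  # mutually positively correlated block: identity
  tab2 <- data.frame(m1 = x, m2 = x + rnorm(100, 0, 0.1),
                     m3 = x + rnorm(100, 0, 0.1), y = rnorm(100))
  expect_no_flips(align_indicator_signs(tab2, spec))

  tab3 <- tab; tab3$m2 <- 1
  expect_error(align_indicator_signs(tab3, spec), class = "anspm_zero_variance")
})

test_that("two-block single-indicator model: beta equals the correlation", {
  for (seed in 1:5) {
    tab <- two_block_table(n = 150, beta = runif(1, -0.8, 0.8), seed = seed)
    fit <- fit_plspm(tab, two_block_spec())
    r <- cor(tab$a, tab$b)
    expect_equal(fit$paths$beta, abs(r) * sign(r), tolerance = 1e-9)
    expect_equal(unname(fit$r_squared["B"]), r^2, tolerance = 1e-9)
  }
})

test_that("closed-form equivalence holds on 50 random two-block datasets", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    b <- runif(1, -0.9, 0.9)
    tab <- two_block_table(n = n, beta = b, seed = 1000 + i)
    fit <- fit_plspm(tab, two_block_spec())
    expect_equal(fit$paths$beta, cor(tab$a, tab$b), tolerance = 1e-9)
  }
})

test_that("noise-free indicator tables recover the generating coefficients", {
  truth <- latent_ground_truth(1, c(0.6, -0.5, 0.4), 0, 1000, seed = 7)
  fit <- fit_plspm(generate_indicator_table(truth))
  expect_equal(fit$paths$beta, c(0.6, -0.5, 0.4), tolerance = 0.05)

  null_truth <- latent_ground_truth(1, c(0, 0, 0), 0, 1000, seed = 8)
  fit0 <- fit_plspm(generate_indicator_table(null_truth))
  expect_true(all(abs(fit0$paths$beta) <= 0.08))
})

test_that("fit_plspm validates inputs", {
  tab <- random_truth_table(n = 50)
  tab$lf <- 1
  expect_error(fit_plspm(tab), class = "anspm_zero_variance")
  expect_error(fit_plspm(random_truth_table(n = 300)[1:3, ]),
               class = "anspm_invalid_argument")
  expect_error(fit_plspm(random_truth_table(n = 50)[, 1:4]),
               class = "anspm_invalid_argument")
})

test_that("fit invariants: unit-variance scores, R2 identity, GoF identity", {
  for (seed in c(1, 2, 3)) {
    tab <- random_truth_table(n = 200, seed = seed)
    fit <- fit_plspm(tab)
    expect_true(all(abs(apply(fit$lv_scores, 2, var) - 1) < 1e-9))
    # single-predictor endogenous LV: beta is the score correlation
    b_ar <- fit$paths$beta[fit$paths$from == "ANS"]
    expect_equal(b_ar, cor(fit$lv_scores[, "ANS"], fit$lv_scores[, "Recall"]),
                 tolerance = 1e-9)
    expect_equal(unname(fit$r_squared["Recall"]), b_ar^2, tolerance = 1e-9)
    expect_equal(fit$gof^2, mean(fit$communality) * mean(fit$r_squared),
                 tolerance = 1e-12)
    expect_true(all(fit$r_squared >= 0 & fit$r_squared <= 1))
  }
})

test_that("negating an indicator column changes nothing after re-alignment", {
  tab <- random_truth_table(n = 150, seed = 6)
  fit1 <- fit_plspm(tab)
  for (mv in c("sdnn", "rmssd", "avnn")) {
    tab2 <- tab
    tab2[[mv]] <- -tab2[[mv]]
    fit2 <- fit_plspm(tab2)
    expect_equal(fit2$paths$beta, fit1$paths$beta, tolerance = 1e-9)
    expect_equal(abs(fit2$loadings), abs(fit1$loadings), tolerance = 1e-9)
  }
})

test_that("all three inner weighting schemes converge to similar paths", {
  tab <- random_truth_table(n = 400, seed = 12)
  fits <- lapply(c("path", "centroid", "factorial"), function(s) {
    fit_plspm(tab, scheme = s)
  })
  for (f in fits) expect_true(f$converged)
  expect_equal(fits[[1]]$paths$beta, fits[[2]]$paths$beta, tolerance = 0.02)
  expect_equal(fits[[1]]$paths$beta, fits[[3]]$paths$beta, tolerance = 0.02)
})

test_that("goodness_of_fit follows its closed form and bounds", {
  tab <- random_truth_table(n = 200, seed = 4)
  fit <- fit_plspm(tab)
  expect_equal(goodness_of_fit(fit), fit$gof, tolerance = 1e-12)
  # direct-formula check: mean communality 0.64, mean R2 0.25 -> 0.4
  fake <- fit
  fake$communality[] <- 0.64
  fake$r_squared[] <- 0.25
  expect_equal(goodness_of_fit(fake), 0.4, tolerance = 1e-12)
  # perfect-fit bound
  fake$communality[] <- 1; fake$r_squared[] <- 1
  expect_equal(goodness_of_fit(fake), 1)
  fake$converged <- FALSE
  expect_error(goodness_of_fit(fake), class = "anspm_not_converged")
})

test_that("bootstrap flags a strong path significant and rejects tiny n_boot", {
  truth <- latent_ground_truth(1, c(0.6, -0.5, 0.4), 0, 400, seed = 3)
  tab <- generate_indicator_table(truth)
  boot <- bootstrap_paths(tab, n_boot = 200, seed = 5)
  edge <- boot[boot$from == "Sympathetic", ]
  expect_true(edge$significant)
  expect_true(edge$ci_lo > 0)
  expect_lt(edge$se, 0.1)
  expect_error(bootstrap_paths(tab, n_boot = 10), class = "anspm_invalid_argument")
})

test_that("permutation test separates opposite group effects", {
  t1 <- generate_indicator_table(
    latent_ground_truth(0.95, c(0.6, -0.3, 0.5), 0.2, 200, seed = 21))
  t2 <- generate_indicator_table(
    latent_ground_truth(0.95, c(-0.6, -0.3, 0.5), 0.2, 200, seed = 22))
  tab <- rbind(t1, t2)
  grp <- rep(c("A", "B"), each = 200)
  cmp <- permutation_group_test(tab, group = grp, n_perm = 199, seed = 9)
  p_symp <- cmp$edges$p_value[cmp$edges$from == "Sympathetic"]
  expect_lt(p_symp, 0.01)
  expect_true(all(cmp$edges$p_value > 0 & cmp$edges$p_value <= 1))
  expect_error(permutation_group_test(tab, group = grp, n_perm = 10),
               class = "anspm_invalid_argument")
  expect_error(permutation_group_test(tab, group = rep(c("A", "B"), c(398, 2)),
                                      n_perm = 199),
               class = "anspm_invalid_argument")
})
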