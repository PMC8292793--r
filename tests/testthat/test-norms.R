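# Norm parameters and the CFA -> ANOVA sampling-distribution transformation.

norms <- case_study_norms()

test_that("reciprocity correlations convert to covariances", {
  cov <- reciprocity_to_covariance(norms)
  expect_equal(cov$reciprocity_scale, "covariance")
  # closed-form: r * sqrt(v1 * v2)
  expect_equal(cov$generalized_reciprocity[["M"]],
               0.40 * sqrt(0.163 * 0.044), tolerance = 1e-12)
  expect_equal(cov$dyadic_reciprocity[["M<->F"]],
               0.35 * sqrt(0.491 * 0.616), tolerance = 1e-12)
  expect_equal(cov$dyadic_reciprocity[["M<->C2"]], 0)

  # covariance-scale input passes through unchanged
  expect_identical(reciprocity_to_covariance(cov), cov)

  # zero correlations give zero covariances
  z <- norms
  z$generalized_reciprocity[] <- 0
  z$dyadic_reciprocity[] <- 0
  zc <- reciprocity_to_covariance(z)
  expect_true(all(zc$generalized_reciprocity == 0))
  expect_true(all(zc$dyadic_reciprocity == 0))
})

test_that("out-of-range reciprocities and negative variances are rejected", {
  bad_r <- norms
  bad_r$generalized_reciprocity[["M"]] <- 1.2
  expect_error(do.call(srm_norms, c(
    list(roles = bad_r$roles, family_mean = bad_r$family_mean,
         family_var = bad_r$family_var),
    bad_r[c("actor_mean", "actor_var", "partner_mean", "partner_var",
            "rel_mean", "rel_var", "generalized_reciprocity",
            "dyadic_reciprocity", "reciprocity_scale")])),
    "outside \\[-1, 1\\]")

  cov <- reciprocity_to_covariance(norms)
  cov$dyadic_reciprocity[["M<->F"]] <- 1  # > sqrt(0.491 * 0.616)
  expect_error(do.call(srm_norms, c(
    list(roles = cov$roles, family_mean = cov$family_mean,
         family_var = cov$family_var),
    cov[c("actor_mean", "actor_var", "partner_mean", "partner_var",
          "rel_mean", "rel_var", "generalized_reciprocity",
          "dyadic_reciprocity", "reciprocity_scale")])),
    "Cauchy-Schwarz")

  neg <- norms
  neg$family_var <- -0.01
  d <- validate_srm_norms(neg)
  expect_true(any(d$severity == "error" & grepl("negative variance", d$message)))
})

test_that("zero-sum mean constraints are diagnosed as warnings", {
  expect_identical(nrow(validate_srm_norms(norms)), 0L)

  off <- norms
  off$actor_mean[] <- 0.5
  d <- validate_srm_norms(off)
  expect_true(any(d$severity == "warning" &
                    grepl("actor means sum", d$message)))
})

test_that("the model-implied dyad distribution is assembled correctly", {
  law <- dyad_law(norms)

  # worked dyad mean: family + actor F + partner C2 + relationship F->C2
  expect_equal(law$mean[["F->C2"]], 1.838 + 0.103 + 0.109 - 0.050,
               tolerance = 1e-12)
  # all 12 model-implied means match the published norm-sample dyad means
  expect_lt(max(abs(law$mean - case_study_dyad_norms()$mean)), 0.01)

  expect_true(isSymmetric(law$cov))
  expect_gt(attr(law, "min_eigenvalue"), 0)

  # degenerate population: zero covariance matrix
  law0 <- dyad_law(zero_variance_norms(norms))
  expect_true(all(law0$cov == 0))
  expect_equal(law0$mean, law$mean)
})

test_that("simulated dyad covariance converges to the analytic one", {
  set.seed(404)
  sim <- srm_simulate(norms, 100000)
  emp <- stats::cov(sim$values)
  S <- dyad_law(norms)$cov
  rel_frob <- norm(emp - S, "F") / norm(S, "F")
  expect_lt(rel_frob, 0.02)
  expect_lt(max(abs(colMeans(sim$values) - dyad_law(norms)$mean)), 0.01)
})

test_that("the ANOVA weight matrix has the documented structure", {
  W <- anova_weight_matrix(test_roles)
  expect_identical(dim(W), c(21L, 12L))
  expect_true(all(W["family", ] == 1 / 12))
  expect_equal(sum(W["family", ]), 1)
  expect_equal(unname(rowSums(W[-1, ])), rep(0, 20), tolerance = 1e-12)

  # actor row: 1/4 outgoing, 0 incoming, -1/8 elsewhere
  p <- dyad_pairs(test_roles)
  a <- W["actor:C2", ]
  expect_equal(unname(a[p$actor == "C2"]), rep(1 / 4, 3))
  expect_equal(unname(a[p$partner == "C2"]), rep(0, 3))
  expect_equal(unname(a[p$actor != "C2" & p$partner != "C2"]),
               rep(-1 / 8, 6))

  expect_lt(abs(sum(a * case_study_dyads()$values) - 1.446), 6e-4)
})

test_that("sampling distribution matches independent hand propagation", {
  d <- sampling_distribution(norms)
  fam <- d[d$effect == "family", ]
  # frozen from the closed-form propagation of the published parameters:
  # mean = family_mean + mean(actor means) + mean(partner means)
  #      + mean(relationship means)
  # var  = family_var + 9/144 (sum actor vars + sum partner vars)
  #      + 18/144 sum generalized covs + 1/144 sum relationship vars
  #      + 2/144 sum dyadic covs
  expect_equal(fam$mean, 1.83775, tolerance = 1e-6)
  expect_equal(fam$sd, 0.3944591, tolerance = 1e-6)

  # near-unbiasedness for the actor effect (published means are rounded)
  expect_lt(abs(d$mean[d$effect == "actor:C2"] - 0.117), 0.002)

  # degenerate population: every effect non-assessable
  d0 <- sampling_distribution(zero_variance_norms(norms))
  expect_true(all(d0$sd == 0))
  expect_false(any(d0$assessable))
})

test_that("exactly-constrained latent means make the ANOVA scores unbiased", {
  set.seed(505)
  for (i in 1:20) {
    prm <- random_norms(constrained = TRUE)
    d <- sampling_distribution(prm)
    expect_equal(d$mean[d$effect == "family"], prm$family_mean,
                 tolerance = 1e-6)
    for (r in prm$roles) {
      expect_equal(d$mean[d$effect == paste0("actor:", r)],
                   prm$actor_mean[[r]], tolerance = 1e-6)
      expect_equal(d$mean[d$effect == paste0("partner:", r)],
                   prm$partner_mean[[r]], tolerance = 1e-6)
    }
  }
})

test_that("the transformation is scale-equivariant", {
  c0 <- 2.5
  scaled <- srm_norms(
    roles = norms$roles,
    family_mean = c0 * norms$family_mean,
    family_var = c0^2 * norms$family_var,
    actor_mean = c0 * norms$actor_mean,
    actor_var = c0^2 * norms$actor_var,
    partner_mean = c0 * norms$partner_mean,
    partner_var = c0^2 * norms$partner_var,
    rel_mean = c0 * norms$rel_mean,
    rel_var = c0^2 * norms$rel_var,
    generalized_reciprocity = norms$generalized_reciprocity,
    dyadic_reciprocity = norms$dyadic_reciprocity,
    reciprocity_scale = "correlation"
  )
  d0 <- sampling_distribution(norms)
  d1 <- sampling_distribution(scaled)
  expect_equal(d1$mean, c0 * d0$mean, tolerance = 1e-9)
  expect_equal(d1$sd, c0 * d0$sd, tolerance = 1e-9)
})
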