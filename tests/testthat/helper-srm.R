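# Shared generators for property-style tests.

test_roles <- c("M", "F", "C1", "C2")

random_round_robin <- function(roles = test_roles, mu = 2, sigma = 1) {
  vals <- stats::setNames(stats::rnorm(12, mu, sigma), dyad_keys(roles))
  round_robin(vals, roles = roles)
}

# A random valid parameter set. With constrained = TRUE the latent means
# satisfy the zero-sum identification constraints exactly.
random_norms <- function(roles = test_roles, constrained = TRUE) {
  ctr <- function(x) x - mean(x)
  am <- stats::rnorm(4, 0, 0.2)
  pm <- stats::rnorm(4, 0, 0.2)
  rm_ <- matrix(stats::rnorm(16, 0, 0.2), 4, 4)
  if (constrained) {
    am <- ctr(am)
    pm <- ctr(pm)
    # double-center the off-diagonal relationship means so each actor row
    # and each partner column sums to zero
    for (it in 1:200) {
      for (i in 1:4) rm_[i, -i] <- rm_[i, -i] - mean(rm_[i, -i])
      for (j in 1:4) rm_[-j, j] <- rm_[-j, j] - mean(rm_[-j, j])
    }
  }
  p <- dyad_pairs(roles)
  idx <- cbind(match(p$actor, roles), match(p$partner, roles))
  srm_norms(
    roles = roles,
    family_mean = stats::rnorm(1, 2, 0.5),
    family_var = stats::runif(1, 0.02, 0.3),
    actor_mean = stats::setNames(am, roles),
    actor_var = stats::setNames(stats::runif(4, 0.05, 0.4), roles),
    partner_mean = stats::setNames(pm, roles),
    partner_var = stats::setNames(stats::runif(4, 0.05, 0.4), roles),
    rel_mean = stats::setNames(rm_[idx], dyad_keys(roles)),
    rel_var = stats::setNames(stats::runif(12, 0.05, 0.6), dyad_keys(roles)),
    generalized_reciprocity =
      stats::setNames(stats::runif(4, -0.8, 0.8), roles),
    dyadic_reciprocity =
      stats::setNames(stats::runif(6, -0.8, 0.8), unordered_keys(roles)),
    reciprocity_scale = "correlation"
  )
}

reorder_norms_for_test <- function(params, roles) {
  srmassess:::reorder_norms(params, roles)
}

# Zero-variance copy of a parameter set (degenerate norm population).
zero_variance_norms <- function(params) {
  srm_norms(
    roles = params$roles,
    family_mean = params$family_mean, family_var = 0,
    actor_mean = params$actor_mean,
    actor_var = params$actor_var * 0,
    partner_mean = params$partner_mean,
    partner_var = params$partner_var * 0,
    rel_mean = params$rel_mean,
    rel_var = params$rel_var * 0,
    generalized_reciprocity = params$generalized_reciprocity * 0,
    dyadic_reciprocity = params$dyadic_reciprocity * 0,
    reciprocity_scale = "correlation"
  )
}
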