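# Generative simulation of round-robin families under the SRM.
#
# Latent effects are drawn multivariate normal with the independence
# structure of the model: one family effect per family; per person a
# bivariate (actor, partner) pair coupled by the generalized reciprocity;
# per unordered dyad a bivariate pair of directed relationship effects
# coupled by the dyadic reciprocity.  Dyadic measurements are then
# assembled additively.  Note that the zero-sum constraints hold for the
# population MEANS only; individual families are not constrained, exactly
# as in the latent model.

# n draws from a bivariate normal via the 2x2 Cholesky factor; zero-variance
# margins short-circuit to constants so degenerate norms simulate cleanly.
rbvnorm <- function(n, mu, v1, v2, cv, what = "block") {
  eps <- 1e-12
  if (v1 < 0 || v2 < 0) stop("negative variance in ", what, call. = FALSE)
  if (v1 <= eps && v2 <= eps) {
    if (abs(cv) > eps) stop("nonzero covariance with zero variances in ",
                            what, call. = FALSE)
    return(cbind(rep(mu[1L], n), rep(mu[2L], n)))
  }
  if (v1 <= eps) {
    if (abs(cv) > eps) stop("covariance incompatible with zero variance in ",
                            what, call. = FALSE)
    return(cbind(rep(mu[1L], n), stats::rnorm(n, mu[2L], sqrt(v2))))
  }
  if (v2 <= eps) {
    if (abs(cv) > eps) stop("covariance incompatible with zero variance in ",
                            what, call. = FALSE)
    return(cbind(stats::rnorm(n, mu[1L], sqrt(v1)), rep(mu[2L], n)))
  }
  l11 <- sqrt(v1)
  l21 <- cv / l11
  resid <- v2 - l21^2
  if (resid < -1e-8 * v2) {
    stop("covariance block for ", what, " is not positive semi-definite ",
         "(implied correlation ", format(cv / sqrt(v1 * v2)), ")",
         call. = FALSE)
  }
  l22 <- sqrt(max(resid, 0))
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  cbind(mu[1L] + l11 * z1, mu[2L] + l21 * z1 + l22 * z2)
}

#' Simulate round-robin families from SRM norm parameters
#'
#' Draws `n_families` four-person families from the generative SRM: family
#' effect, per-person (actor, partner) pairs with the generalized
#' reciprocity covariance, and per-dyad pairs of directed relationship
#' effects with the dyadic reciprocity covariance, all normal; the 12 dyadic
#' measurements are assembled additively. The draw order (family effect,
#' then persons in role order, then unordered dyads in canonical order) is
#' fixed, so a given seed reproduces the run bit for bit.
#'
#' @inheritParams validate_srm_norms
#' @param n_families number of families to draw (>= 1).
#' @param seed optional integer seed; when supplied the RNG is seeded at the
#'   start of the run.
#' @return an object of class `srm_simulation`: list with `values`
#'   (`n_families` x 12 matrix of dyad vectors, columns in canonical order),
#'   `scores` (`n_families` x 21 matrix of ANOVA scores), `roles`,
#'   `n_families`, `seed` and `summary` (data frame of empirical mean and SD
#'   per effect).
#' @export
#' @examples
#' sim <- srm_simulate(case_study_norms(), n_families = 50, seed = 1)
#' head(sim$summary)
srm_simulate <- function(params, n_families, seed = NULL) {
  stopifnot(inherits(params, "srm_norms"))
  if (!is.numeric(n_families) || length(n_families) != 1L ||
      n_families < 1 || n_families != round(n_families)) {
    stop("n_families must be a positive integer", call. = FALSE)
  }
  n_families <- as.integer(n_families)
  if (!is.null(seed)) set.seed(seed)
  params <- reciprocity_to_covariance(params)
  roles <- params$roles
  p <- dyad_pairs(roles)
  keys <- dyad_keys(roles)

  fam <- if (params$family_var <= 1e-12) {
    rep(params$family_mean, n_families)
  } else {
    stats::rnorm(n_families, params$family_mean, sqrt(params$family_var))
  }

  act <- par <- matrix(0, n_families, 4L, dimnames = list(NULL, roles))
  for (r in roles) {
    ap <- rbvnorm(
      n_families,
      mu = c(params$actor_mean[[r]], params$partner_mean[[r]]),
      v1 = params$actor_var[[r]], v2 = params$partner_var[[r]],
      cv = params$generalized_reciprocity[[r]],
      what = paste0("person ", r, " (actor, partner)"))
    act[, r] <- ap[, 1L]
    par[, r] <- ap[, 2L]
  }

  rel <- matrix(0, n_families, 12L, dimnames = list(NULL, keys))
  for (k in unordered_keys(roles)) {
    ab <- strsplit(k, "<->", fixed = TRUE)[[1L]]
    fwd <- paste0(ab[1L], "->", ab[2L])
    bwd <- paste0(ab[2L], "->", ab[1L])
    rr <- rbvnorm(
      n_families,
      mu = c(params$rel_mean[[fwd]], params$rel_mean[[bwd]]),
      v1 = params$rel_var[[fwd]], v2 = params$rel_var[[bwd]],
      cv = params$dyadic_reciprocity[[k]],
      what = paste0("dyad ", k, " relationship pair"))
    rel[, fwd] <- rr[, 1L]
    rel[, bwd] <- rr[, 2L]
  }

  values <- fam + act[, p$actor, drop = FALSE] +
    par[, p$partner, drop = FALSE] + rel
  colnames(values) <- keys

  W <- anova_weight_matrix(roles)
  scores <- values %*% t(W)

  summary <- data.frame(
    effect = colnames(scores),
    mean = colMeans(scores),
    sd = apply(scores, 2L, stats::sd),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(values = values, scores = scores, roles = roles,
         n_families = n_families, seed = seed, summary = summary),
    class = "srm_simulation"
  )
}

#' Extract one simulated family as a round robin
#'
#' @param sim an `srm_simulation`.
#' @param i family index.
#' @return a [round_robin] object.
#' @export
sim_family <- function(sim, i) {
  stopifnot(inherits(sim, "srm_simulation"),
            i >= 1, i <= sim$n_families)
  round_robin(sim$values[i, ], roles = sim$roles)
}

#' @export
print.srm_simulation <- function(x, ...) {
  cat("SRM simulation:", x$n_families, "families, roles",
      paste(x$roles, collapse = ", "),
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' Monte-Carlo check of the analytic sampling distribution
#'
#' Simulates families from the norm parameters, computes each family's
#' ANOVA scores, and compares the empirical mean and SD of every effect
#' with the analytic values from [sampling_distribution()]. Agreement is
#' judged at `k` Monte-Carlo standard errors (SE of a mean: `sd/sqrt(n)`;
#' SE of an SD under normality: `sd/sqrt(2(n-1))`).
#'
#' @inheritParams srm_simulate
#' @param k pass/fail multiple of the Monte-Carlo standard error.
#' @return data frame with one row per effect and columns `effect`,
#'   `mean_analytic`, `mean_empirical`, `mean_mcse`, `mean_ok`,
#'   `sd_analytic`, `sd_empirical`, `sd_mcse`, `sd_ok`.
#' @export
empirical_sampling_check <- function(params, n_families = 10000,
                                     seed = NULL, k = 3) {
  dist <- sampling_distribution(params)
  sim <- srm_simulate(params, n_families, seed = seed)
  emp <- sim$summary
  stopifnot(identical(dist$effect, emp$effect))
  mean_mcse <- dist$sd / sqrt(n_families)
  sd_mcse <- dist$sd / sqrt(2 * (n_families - 1))
  data.frame(
    effect = dist$effect,
    mean_analytic = dist$mean,
    mean_empirical = emp$mean,
    mean_mcse = mean_mcse,
    mean_ok = abs(emp$mean - dist$mean) <= k * mean_mcse + 1e-12,
    sd_analytic = dist$sd,
    sd_empirical = emp$sd,
    sd_mcse = sd_mcse,
    sd_ok = abs(emp$sd - dist$sd) <= k * sd_mcse + 1e-12,
    stringsAsFactors = FALSE
  )
}
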