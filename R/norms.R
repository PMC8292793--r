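# Normative SRM population parameters and their transformation into the
# sampling distribution of the ANOVA scores.
#
# A norm sample's SRM is usually summarised by CFA estimates of the latent
# component means and variances plus two kinds of reciprocity (the
# actor-partner correlation within a person and the correlation between the
# two directed relationship effects of a dyad).  Those latent-scale
# parameters are not the mean and SD of the ANOVA scores that a
# norm-referenced Z score needs.  The link is linear: the 12 dyadic
# measurements are a fixed linear function of the latent effects, and each
# ANOVA score is a fixed linear function (weight row w) of the 12
# measurements, so
#
#   mean(score) = w %*% mu,   var(score) = w %*% Sigma %*% t(w)
#
# with mu and Sigma the model-implied mean vector and covariance matrix of
# the dyad vector.  This module assembles mu and Sigma from the published
# parameters and propagates them through the weight matrix exactly.

unordered_keys <- function(roles) {
  roles <- check_roles(roles)
  cmb <- utils::combn(4L, 2L)
  paste0(roles[cmb[1L, ]], "<->", roles[cmb[2L, ]])
}

# Accept unordered-pair names in either orientation and return them in
# canonical "first-role<->later-role" form.
normalize_unordered <- function(x, roles) {
  keys <- unordered_keys(roles)
  parts <- strsplit(names(x), "<->", fixed = TRUE)
  canon <- vapply(parts, function(p) {
    if (length(p) != 2L || !all(p %in% roles)) return(NA_character_)
    i <- sort(match(p, roles))
    paste0(roles[i[1L]], "<->", roles[i[2L]])
  }, "")
  if (anyNA(canon)) {
    stop("malformed unordered dyad key(s): ",
         paste(names(x)[is.na(canon)], collapse = ", "), call. = FALSE)
  }
  names(x) <- canon
  if (!setequal(names(x), keys) || anyDuplicated(names(x))) {
    stop("dyadic reciprocities must cover each of the 6 unordered dyads ",
         "exactly once; expected keys: ", paste(keys, collapse = ", "),
         call. = FALSE)
  }
  x[keys]
}

align_named <- function(x, keys, what) {
  if (length(x) != length(keys) || is.null(names(x)) ||
      !setequal(names(x), keys) || anyDuplicated(names(x))) {
    stop(what, " must be a named vector covering exactly: ",
         paste(keys, collapse = ", "), call. = FALSE)
  }
  x[keys]
}

#' Normative SRM population parameters
#'
#' Container for the CFA-estimated population parameters of the latent SRM
#' components in a norm sample: family mean/variance, four actor and four
#' partner means/variances, twelve relationship means/variances, four
#' generalized reciprocities (actor-partner association within a person) and
#' six dyadic reciprocities (association between the two directed
#' relationship effects of an unordered dyad). Reciprocities may be supplied
#' as correlations or covariances; `reciprocity_scale` says which.
#'
#' Because relationship effects absorb measurement error in single-indicator
#' designs, no separate error-variance parameter is accepted.
#'
#' @param roles character vector of 4 distinct role labels (canonical order).
#' @param family_mean,family_var family-effect mean and variance.
#' @param actor_mean,actor_var,partner_mean,partner_var named numeric
#'   vectors, one entry per role.
#' @param rel_mean,rel_var named numeric vectors with `"actor->partner"`
#'   keys, one entry per ordered dyad (12 each).
#' @param generalized_reciprocity named numeric vector, one entry per role.
#' @param dyadic_reciprocity named numeric vector with `"a<->b"` keys, one
#'   entry per unordered dyad (6).
#' @param reciprocity_scale `"correlation"` or `"covariance"`.
#' @return an object of class `srm_norms`.
#' @seealso [validate_srm_norms()], [sampling_distribution()],
#'   [case_study_norms()]
#' @export
srm_norms <- function(roles, family_mean, family_var,
                      actor_mean, actor_var,
                      partner_mean, partner_var,
                      rel_mean, rel_var,
                      generalized_reciprocity, dyadic_reciprocity,
                      reciprocity_scale = c("correlation", "covariance")) {
  roles <- check_roles(roles)
  reciprocity_scale <- match.arg(reciprocity_scale)
  dk <- dyad_keys(roles)
  out <- structure(list(
    roles = roles,
    family_mean = as.numeric(family_mean),
    family_var = as.numeric(family_var),
    actor_mean = align_named(actor_mean, roles, "actor_mean"),
    actor_var = align_named(actor_var, roles, "actor_var"),
    partner_mean = align_named(partner_mean, roles, "partner_mean"),
    partner_var = align_named(partner_var, roles, "partner_var"),
    rel_mean = align_named(rel_mean, dk, "rel_mean"),
    rel_var = align_named(rel_var, dk, "rel_var"),
    generalized_reciprocity =
      align_named(generalized_reciprocity, roles, "generalized_reciprocity"),
    dyadic_reciprocity = normalize_unordered(dyadic_reciprocity, roles),
    reciprocity_scale = reciprocity_scale
  ), class = "srm_norms")

  diag <- validate_srm_norms(out)
  err <- diag$message[diag$severity == "error"]
  if (length(err)) {
    stop("invalid SRM norm parameters:\n  - ",
         paste(err, collapse = "\n  - "), call. = FALSE)
  }
  wrn <- diag$message[diag$severity == "warning"]
  for (w in wrn) warning(w, call. = FALSE)
  out
}

#' Diagnostic checks on SRM norm parameters
#'
#' Returns a diagnostics table rather than throwing, so callers can decide
#' severity. Errors: negative variances; correlations outside `[-1, 1]`;
#' covariance-scale reciprocities violating the Cauchy-Schwarz bound.
#' Warnings: the identification constraints on the latent means (actor means
#' sum to 0, partner means sum to 0, relationship means sum to 0 within each
#' actor row and each partner column) violated beyond `tol`. The default
#' tolerance of 0.01 accommodates parameters published with 3-decimal
#' rounding.
#'
#' @param params an [srm_norms] object.
#' @param tol absolute tolerance for the zero-sum mean constraints.
#' @return data frame with columns `check`, `severity` (`"error"` or
#'   `"warning"`) and `message`; zero rows when everything passes.
#' @export
validate_srm_norms <- function(params, tol = 0.01) {
  stopifnot(inherits(params, "srm_norms"))
  out <- list()
  add <- function(check, severity, message) {
    out[[length(out) + 1L]] <<- data.frame(
      check = check, severity = severity, message = message,
      stringsAsFactors = FALSE)
  }

  vars <- c(family = params$family_var,
            stats::setNames(params$actor_var, paste0("actor:", params$roles)),
            stats::setNames(params$partner_var, paste0("partner:", params$roles)),
            stats::setNames(params$rel_var,
                            paste0("relationship:", names(params$rel_var))))
  neg <- vars < 0
  if (any(neg)) {
    add("variance", "error",
        paste0("negative variance for ",
               paste(names(vars)[neg], collapse = ", ")))
  }

  if (params$reciprocity_scale == "correlation") {
    r <- c(params$generalized_reciprocity, params$dyadic_reciprocity)
    bad <- abs(r) > 1
    if (any(bad)) {
      add("reciprocity", "error",
          paste0("reciprocity correlation outside [-1, 1] for ",
                 paste(names(r)[bad], collapse = ", ")))
    }
  } else {
    slack <- 1e-9
    bnd <- sqrt(params$actor_var * params$partner_var)
    bad <- abs(params$generalized_reciprocity) > bnd + slack
    if (any(bad)) {
      add("reciprocity", "error",
          paste0("generalized reciprocity covariance exceeds the ",
                 "Cauchy-Schwarz bound for role(s) ",
                 paste(params$roles[bad], collapse = ", ")))
    }
    for (k in names(params$dyadic_reciprocity)) {
      ab <- strsplit(k, "<->", fixed = TRUE)[[1L]]
      b <- sqrt(params$rel_var[[paste0(ab[1L], "->", ab[2L])]] *
                  params$rel_var[[paste0(ab[2L], "->", ab[1L])]])
      if (abs(params$dyadic_reciprocity[[k]]) > b + slack) {
        add("reciprocity", "error",
            paste0("dyadic reciprocity covariance exceeds the ",
                   "Cauchy-Schwarz bound for dyad ", k))
      }
    }
  }

  if (abs(sum(params$actor_mean)) > tol) {
    add("mean_constraint", "warning",
        sprintf("actor means sum to %.4f, not 0 (identification constraint)",
                sum(params$actor_mean)))
  }
  if (abs(sum(params$partner_mean)) > tol) {
    add("mean_constraint", "warning",
        sprintf("partner means sum to %.4f, not 0 (identification constraint)",
                sum(params$partner_mean)))
  }
  p <- dyad_pairs(params$roles)
  for (r in params$roles) {
    s <- sum(params$rel_mean[p$actor == r])
    if (abs(s) > tol) {
      add("mean_constraint", "warning",
          sprintf("relationship means for actor %s sum to %.4f, not 0", r, s))
    }
    s <- sum(params$rel_mean[p$partner == r])
    if (abs(s) > tol) {
      add("mean_constraint", "warning",
          sprintf("relationship means for partner %s sum to %.4f, not 0", r, s))
    }
  }

  if (length(out)) do.call(rbind, out) else
    data.frame(check = character(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Convert reciprocities to the covariance scale
#'
#' Reciprocities published as correlations are rescaled to covariances:
#' `cov(actor_i, partner_i) = r * sqrt(actor_var_i * partner_var_i)` for the
#' generalized reciprocity of role i, and
#' `cov(rel_ij, rel_ji) = r * sqrt(rel_var_ij * rel_var_ji)` for the dyadic
#' reciprocity of an unordered dyad. Covariance-scale input passes through
#' unchanged (after a Cauchy-Schwarz check in [validate_srm_norms()]).
#'
#' @inheritParams validate_srm_norms
#' @return an [srm_norms] object with `reciprocity_scale = "covariance"`.
#' @export
reciprocity_to_covariance <- function(params) {
  stopifnot(inherits(params, "srm_norms"))
  if (params$reciprocity_scale == "covariance") return(params)
  gen <- params$generalized_reciprocity *
    sqrt(params$actor_var * params$partner_var)
  dy <- params$dyadic_reciprocity
  for (k in names(dy)) {
    ab <- strsplit(k, "<->", fixed = TRUE)[[1L]]
    dy[[k]] <- dy[[k]] * sqrt(params$rel_var[[paste0(ab[1L], "->", ab[2L])]] *
                                params$rel_var[[paste0(ab[2L], "->", ab[1L])]])
  }
  params$generalized_reciprocity <- gen
  params$dyadic_reciprocity <- dy
  params$reciprocity_scale <- "covariance"
  params
}

#' Model-implied distribution of the 12 dyadic measurements
#'
#' Under the additive SRM with independent components (apart from the two
#' reciprocity patterns), the dyad vector has mean
#' `mu[i->j] = family_mean + actor_mean[i] + partner_mean[j] + rel_mean[i->j]`
#' and a 12 x 12 covariance assembled from: the family variance (all cells),
#' shared-actor and shared-partner variances, generalized-reciprocity
#' covariances wherever one dyad's actor is the other dyad's partner,
#' relationship variances on the diagonal and dyadic-reciprocity covariances
#' between the two directions of each dyad. All other cross terms are zero.
#'
#' @inheritParams validate_srm_norms
#' @return an object of class `srm_dyad_law`: list with `mean` (named
#'   numeric 12), `cov` (12 x 12 dimnamed matrix) and `roles`; the smallest
#'   eigenvalue of `cov` is stored in attribute `min_eigenvalue`.
#' @export
dyad_law <- function(params) {
  stopifnot(inherits(params, "srm_norms"))
  params <- reciprocity_to_covariance(params)
  roles <- params$roles
  p <- dyad_pairs(roles)
  keys <- dyad_keys(roles)

  mu <- params$family_mean + params$actor_mean[p$actor] +
    params$partner_mean[p$partner] + params$rel_mean
  mu <- stats::setNames(as.numeric(mu), keys)

  ukey <- function(a, b) {
    i <- sort(match(c(a, b), roles))
    paste0(roles[i[1L]], "<->", roles[i[2L]])
  }
  S <- matrix(0, 12L, 12L, dimnames = list(keys, keys))
  for (q in 1:12) {
    for (r in q:12) {
      s <- params$family_var
      if (p$actor[q] == p$actor[r]) s <- s + params$actor_var[[p$actor[q]]]
      if (p$partner[q] == p$partner[r]) s <- s + params$partner_var[[p$partner[q]]]
      if (p$actor[q] == p$partner[r])
        s <- s + params$generalized_reciprocity[[p$actor[q]]]
      if (p$partner[q] == p$actor[r])
        s <- s + params$generalized_reciprocity[[p$partner[q]]]
      if (q == r) s <- s + params$rel_var[[q]]
      if (q != r && p$actor[q] == p$partner[r] && p$partner[q] == p$actor[r])
        s <- s + params$dyadic_reciprocity[[ukey(p$actor[q], p$partner[q])]]
      S[q, r] <- S[r, q] <- s
    }
  }
  out <- structure(list(mean = mu, cov = S, roles = roles),
                   class = "srm_dyad_law")
  attr(out, "min_eigenvalue") <- min(eigen(S, symmetric = TRUE,
                                           only.values = TRUE)$values)
  out
}

#' ANOVA weight matrix
#'
#' The 21 x 12 matrix W mapping the canonical dyad vector to the 21 ANOVA
#' scores: `scores = W %*% x`. The family row is 1/12 everywhere; the
#' actor-i row puts 1/4 on i's three outgoing dyads, 0 on its incoming dyads
#' and -1/8 elsewhere (the n = 4 reweighting of row, column and grand
#' means); partner rows mirror actor rows; each relationship row is the
#' dyad's indicator minus the family, actor and partner rows. Every
#' non-family row sums to 0 and the family row sums to 1, so all effects
#' other than the family effect are invariant to adding a constant to the
#' measurements.
#'
#' @inheritParams dyad_pairs
#' @return numeric 21 x 12 matrix with effect ids as row names and dyad keys
#'   as column names.
#' @export
anova_weight_matrix <- function(roles) {
  roles <- check_roles(roles)
  p <- dyad_pairs(roles)
  keys <- dyad_keys(roles)
  w <- srm_weights()
  W <- matrix(0, 21L, 12L, dimnames = list(effect_ids(roles), keys))
  W["family", ] <- 1 / 12

  for (r in roles) {
    out <- p$actor == r
    inc <- p$partner == r
    # row mean spreads over 3 outgoing cells, column mean over 3 incoming,
    # grand mean over all 12
    W[paste0("actor:", r), ] <- w$a * out / 3 + w$b * inc / 3 - w$g / 12
    W[paste0("partner:", r), ] <- w$a * inc / 3 + w$b * out / 3 - w$g / 12
  }
  for (q in 1:12) {
    ind <- numeric(12L)
    ind[q] <- 1
    W[paste0("relationship:", keys[q]), ] <-
      ind - W[paste0("actor:", p$actor[q]), ] -
      W[paste0("partner:", p$partner[q]), ] - W["family", ]
  }
  W
}

#' Sampling distribution of the ANOVA scores under the norm population
#'
#' Propagates the norm parameters through the ANOVA weight matrix: for each
#' effect k with weight row w_k, the norm mean is `w_k %*% mu` and the norm
#' SD is `sqrt(w_k %*% Sigma %*% t(w_k))`, with mu and Sigma from
#' [dyad_law()]. These are exactly the mean and SD that the ANOVA scores of
#' the norm sample's families would have, which is what a norm-referenced
#' Z score divides by.
#'
#' Effects whose propagated SD falls below `sd_tol` are marked
#' non-assessable (a Z score is undefined there). A negative propagated
#' variance can only arise from an inconsistent (non positive semi-definite)
#' published covariance structure and is an error.
#'
#' @inheritParams validate_srm_norms
#' @param sd_tol SDs below this are treated as exactly zero.
#' @return an object of class `srm_sampling`: a data frame with columns
#'   `effect`, `mean`, `sd`, `assessable`; the role labels and the smallest
#'   eigenvalue of the assembled dyad covariance are kept as attributes.
#' @export
#' @examples
#' sampling_distribution(case_study_norms())
sampling_distribution <- function(params, sd_tol = 1e-8) {
  stopifnot(inherits(params, "srm_norms"))
  law <- dyad_law(params)
  W <- anova_weight_matrix(params$roles)
  mu <- as.numeric(W %*% law$mean)
  v <- rowSums((W %*% law$cov) * W)
  if (any(v < -1e-10)) {
    stop("negative propagated variance for ",
         paste(rownames(W)[v < -1e-10], collapse = ", "),
         "; the published covariance structure is not positive ",
         "semi-definite (smallest eigenvalue ",
         format(attr(law, "min_eigenvalue")), ")", call. = FALSE)
  }
  sd <- sqrt(pmax(v, 0))
  out <- data.frame(
    effect = rownames(W),
    mean = mu,
    sd = sd,
    assessable = sd >= sd_tol,
    stringsAsFactors = FALSE
  )
  class(out) <- c("srm_sampling", "data.frame")
  attr(out, "roles") <- params$roles
  attr(out, "min_eigenvalue") <- attr(law, "min_eigenvalue")
  out
}

#' @export
print.srm_norms <- function(x, ...) {
  cat("SRM norm parameters (roles: ", paste(x$roles, collapse = ", "),
      "; reciprocities as ", x$reciprocity_scale, "s)\n", sep = "")
  cat(sprintf("  family: mean %.3f, var %.3f\n", x$family_mean, x$family_var))
  cat("  actor means:   ",
      paste(sprintf("%s %.3f", x$roles, x$actor_mean), collapse = "  "), "\n")
  cat("  partner means: ",
      paste(sprintf("%s %.3f", x$roles, x$partner_mean), collapse = "  "), "\n")
  invisible(x)
}
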