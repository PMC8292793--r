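# Norm-referenced Z scores, p-values and qualitative flags.

#' Z score of an ANOVA effect against its norm distribution
#'
#' `(score - mean) / sd`, the standardized deviation of the family's score
#' from the norm population. A non-positive or numerically zero `sd` yields
#' `NA` (the effect is not assessable) rather than an infinite Z.
#'
#' @param score the family's ANOVA score.
#' @param mean,sd norm mean and standard deviation of that score.
#' @param sd_tol SDs below this are treated as zero.
#' @return a number, or `NA_real_` when the effect is not assessable.
#' @export
z_score <- function(score, mean, sd, sd_tol = 1e-8) {
  ifelse(is.finite(sd) & sd >= sd_tol, (score - mean) / sd, NA_real_)
}

#' Two-sided normal p-value for a Z score
#'
#' `2 * (1 - pnorm(|z|))`, the two-sided tail probability under a standard
#' normal reference distribution. The normal reference matches the
#' large-norm-sample setting in which the published parameters were
#' estimated; no finite-sample correction is applied because the norm-sample
#' size is not an input.
#'
#' @param z Z score(s); `NA` propagates.
#' @return p-value(s) in `[0, 1]`.
#' @export
p_value <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Qualitative flag for a Z score
#'
#' `"extreme"` when `|z| >= extreme` (conventionally 2, i.e. more than two
#' norm SDs from the norm mean), `"elevated"` when
#' `elevated <= |z| < extreme` (a potential risk factor worth a closer
#' look), otherwise `"typical"`. An `NA` Z is flagged `"non_assessable"`.
#'
#' @param z Z score(s).
#' @param elevated,extreme thresholds; must satisfy
#'   `0 < elevated < extreme`.
#' @return character vector of flags.
#' @export
classify_z <- function(z, elevated = 1, extreme = 2) {
  if (!is.numeric(elevated) || !is.numeric(extreme) ||
      length(elevated) != 1L || length(extreme) != 1L ||
      !is.finite(elevated) || !is.finite(extreme) ||
      elevated <= 0 || extreme <= elevated) {
    stop("thresholds must satisfy 0 < elevated < extreme (got elevated = ",
         elevated, ", extreme = ", extreme, ")", call. = FALSE)
  }
  ifelse(is.na(z), "non_assessable",
         ifelse(abs(z) >= extreme, "extreme",
                ifelse(abs(z) >= elevated, "elevated", "typical")))
}

#' Norm-referenced SRM family assessment
#'
#' The full pipeline for one family: decompose the round robin into the 21
#' ANOVA scores, transform the norm parameters into the sampling
#' distribution of those scores, and report per effect the score, its Z,
#' the two-sided p-value and a qualitative flag.
#'
#' The sign convention follows `score - norm mean`: a negative Z means the
#' family sits below the norm population on that effect. P-values are raw by
#' default, matching the screening character of the assessment; `adjust =
#' "holm"` adds a `p_adj` column with a Holm familywise correction over the
#' 21 tests for users worried about false positives.
#'
#' When the norm file marks some effect variances as not significant in the
#' normative sample (see `variance_significant` in [read_norms()]), those
#' rows keep their Z scores but carry `norm_var_significant = FALSE`; Z
#' scores of effects without relevant norm variance should be interpreted
#' with caution, not suppressed.
#'
#' @param data a [round_robin] object.
#' @param params an [srm_norms] object with the same role set.
#' @param elevated,extreme flag thresholds, see [classify_z()].
#' @param adjust `"none"` (default) or `"holm"`.
#' @return an object of class `srm_assessment`: a data frame with 21 rows
#'   and columns `effect`, `anova_score`, `norm_mean`, `norm_sd`, `z`, `p`
#'   (plus `p_adj` if requested), `flag`, `norm_var_significant` (if
#'   provided); attributes record roles and thresholds.
#' @export
#' @examples
#' report <- srm_assess(case_study_dyads(), case_study_norms())
#' print(report)
srm_assess <- function(data, params, elevated = 1, extreme = 2,
                       adjust = c("none", "holm")) {
  stopifnot(inherits(data, "round_robin"), inherits(params, "srm_norms"))
  adjust <- match.arg(adjust)
  classify_z(numeric(0), elevated, extreme)  # threshold validation

  if (!setequal(data$roles, params$roles)) {
    stop("role mismatch between family data (",
         paste(data$roles, collapse = ", "), ") and norm parameters (",
         paste(params$roles, collapse = ", "), ")", call. = FALSE)
  }
  if (!identical(data$roles, params$roles)) {
    params <- reorder_norms(params, data$roles)
  }

  scores <- as.data.frame(srm_scores(data))
  dist <- sampling_distribution(params)
  stopifnot(identical(scores$effect, dist$effect))

  z <- z_score(scores$score, dist$mean, dist$sd)
  out <- data.frame(
    effect = scores$effect,
    anova_score = scores$score,
    norm_mean = dist$mean,
    norm_sd = dist$sd,
    z = z,
    p = p_value(z),
    stringsAsFactors = FALSE
  )
  if (adjust == "holm") {
    out$p_adj <- NA_real_
    ok <- !is.na(out$p)
    out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "holm")
  }
  out$flag <- classify_z(z, elevated, extreme)
  sig <- attr(params, "variance_significant")
  if (!is.null(sig)) {
    out$norm_var_significant <- unname(sig[out$effect])
  }
  class(out) <- c("srm_assessment", "data.frame")
  attr(out, "roles") <- data$roles
  attr(out, "thresholds") <- c(elevated = elevated, extreme = extreme)
  attr(out, "adjust") <- adjust
  out
}

# Re-express norm parameters with roles in a different canonical order.
reorder_norms <- function(params, roles) {
  stopifnot(setequal(params$roles, roles))
  dk <- dyad_keys(roles)
  out <- srm_norms(
    roles = roles,
    family_mean = params$family_mean,
    family_var = params$family_var,
    actor_mean = params$actor_mean[roles],
    actor_var = params$actor_var[roles],
    partner_mean = params$partner_mean[roles],
    partner_var = params$partner_var[roles],
    rel_mean = params$rel_mean[dk],
    rel_var = params$rel_var[dk],
    generalized_reciprocity = params$generalized_reciprocity[roles],
    dyadic_reciprocity = params$dyadic_reciprocity,
    reciprocity_scale = params$reciprocity_scale
  )
  sig <- attr(params, "variance_significant")
  if (!is.null(sig)) attr(out, "variance_significant") <- sig
  out
}

#' @export
print.srm_assessment <- function(x, digits = 3L, ...) {
  th <- attr(x, "thresholds")
  if (!is.null(th)) {
    cat("SRM family assessment (|Z| >= ", th[["extreme"]], " extreme, >= ",
        th[["elevated"]], " elevated)\n", sep = "")
  }
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], round, digits = digits)
  print(d, row.names = FALSE)
  if (!is.null(x$norm_var_significant) && any(!x$norm_var_significant)) {
    cat("Note: effects with norm_var_significant = FALSE lacked significant",
        "variance in the normative sample; interpret their Z scores with",
        "caution.\n")
  }
  invisible(x)
}
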