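# Built-in worked example: a published textbook case on relationship
# anxiety (RS-anxiety, five-item scale averaged per directed relationship)
# in one mother/father/two-child family, together with the CFA norm
# parameters of a 208-family normative sample and the reference assessment
# table those inputs produce.  Values are carried at their published
# precision (2 decimals for dyads, 3 for parameters).

cs_roles <- c("M", "F", "C1", "C2")

#' Case-study round robin
#'
#' The 12 directed RS-anxiety dyad scores of the worked-example family
#' (M = mother, F = father, C1 = oldest child, C2 = youngest child), each
#' the mean of five 5-point Likert items.
#'
#' @return a [round_robin] object.
#' @export
#' @examples
#' grand_mean(case_study_dyads())  # 2.090
case_study_dyads <- function() {
  round_robin(data.frame(
    actor = rep(cs_roles, each = 3L),
    partner = c("F", "C1", "C2",
                "M", "C1", "C2",
                "M", "F", "C2",
                "M", "F", "C1"),
    value = c(1.00, 1.00, 2.00,
              1.17, 1.50, 3.83,
              1.09, 1.33, 2.83,
              1.17, 4.83, 3.33),
    stringsAsFactors = FALSE
  ))
}

#' Case-study norm parameters
#'
#' CFA estimates of the SRM component means, variances and reciprocity
#' correlations for RS-anxiety in the 208-family normative sample of the
#' worked example. All 21 component variances were significant at the 0.05
#' level in that sample, so every effect is assessable.
#'
#' @return an [srm_norms] object (`reciprocity_scale = "correlation"`).
#' @export
case_study_norms <- function() {
  dk <- dyad_keys(cs_roles)
  srm_norms(
    roles = cs_roles,
    family_mean = 1.838, family_var = 0.039,
    actor_mean = c(M = -0.087, F = 0.103, C1 = -0.134, C2 = 0.117),
    actor_var = c(M = 0.163, F = 0.217, C1 = 0.215, C2 = 0.232),
    partner_mean = c(M = -0.169, F = 0.038, C1 = 0.022, C2 = 0.109),
    partner_var = c(M = 0.044, F = 0.056, C1 = 0.064, C2 = 0.079),
    rel_mean = stats::setNames(
      c(0.040, -0.028, -0.012,
        0.116, -0.066, -0.050,
        -0.059, -0.003, 0.062,
        -0.057, -0.037, 0.094), dk),
    rel_var = stats::setNames(
      c(0.491, 0.223, 0.338,
        0.616, 0.170, 0.205,
        0.107, 0.204, 0.205,
        0.204, 0.336, 0.356), dk),
    generalized_reciprocity = c(M = 0.40, F = 0.03, C1 = 0.51, C2 = 0.54),
    dyadic_reciprocity = c("M<->F" = 0.35, "M<->C1" = 0.16, "M<->C2" = 0.00,
                           "F<->C1" = 0.22, "F<->C2" = 0.19,
                           "C1<->C2" = 0.05),
    reciprocity_scale = "correlation"
  )
}

#' Case-study dyad means and SDs in the normative sample
#'
#' The published per-dyad mean and standard deviation of the 12 raw
#' measurements across the normative sample; useful as a cross-check of the
#' model-implied dyad distribution.
#'
#' @return data frame with columns `actor`, `partner`, `mean`, `sd`.
#' @export
case_study_dyad_norms <- function() {
  p <- dyad_pairs(cs_roles)
  data.frame(
    p,
    mean = c(1.83, 1.75, 1.85, 1.89, 1.90, 2.00,
             1.48, 1.74, 1.88, 1.73, 1.96, 2.07),
    sd = c(0.88, 0.71, 0.78, 0.91, 0.70, 0.74,
           0.62, 0.74, 0.75, 0.73, 0.83, 0.77),
    stringsAsFactors = FALSE
  )
}

#' Case-study reference assessment table
#'
#' The published assessment of the worked-example family: per effect the
#' ANOVA score, the Z score against the transformed norms and the two-sided
#' p-value, at the precision of the original report. Used by the test suite
#' as the expected end-to-end output.
#'
#' @return data frame with columns `effect`, `anova_score`, `z`, `p`.
#' @export
case_study_reference <- function() {
  data.frame(
    effect = effect_ids(cs_roles),
    anova_score = c(2.090,
                    -1.206, 0.198, -0.438, 1.446,
                    -1.349, 0.363, -0.292, 1.279,
                    -0.246, 0.409, -0.163,
                    0.231, -0.497, 0.264,
                    0.786, -0.685, -0.101,
                    -1.018, 0.931, 0.086),
    z = c(0.639,
          -2.358, 0.191, -0.628, 2.607,
          -3.385, 0.896, -0.853, 3.151,
          -0.767, 1.304, -0.436,
          0.305, -1.350, 0.989,
          2.856, -2.203, -0.481,
          -2.910, 2.803, -0.02),
    p = c(0.523,
          0.018, 0.849, 0.530, 0.009,
          0.001, 0.370, 0.393, 0.002,
          0.443, 0.192, 0.663,
          0.761, 0.177, 0.323,
          0.004, 0.028, 0.631,
          0.004, 0.005, 0.984),
    stringsAsFactors = FALSE
  )
}
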