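# Round-robin data model and per-family SRM ANOVA scores.
#
# A four-person round robin yields the 12 directed dyadic measurements
# X[i, j] (actor i rates partner j, i != j, no self-ratings).  The SRM
# decomposes each measurement additively:
#
#   X[i, j] = family + actor_i + partner_j + relationship_ij
#
# With the diagonal of the 4 x 4 actor-by-partner table missing, raw row
# and column means are biased for the actor and partner effects; the
# classical closed-form estimators reweight the row mean, column mean and
# grand mean to correct for the missing cells.

#' Validate a set of four role labels
#'
#' @param roles character vector of role labels.
#' @return `roles`, invisibly validated.
#' @noRd
check_roles <- function(roles) {
  if (is.factor(roles)) roles <- as.character(roles)
  if (!is.character(roles) || length(roles) != 4L) {
    stop("exactly 4 role labels are required: the round-robin decomposition ",
         "implemented here is specific to four-person families (got ",
         length(roles), " label(s))", call. = FALSE)
  }
  if (anyNA(roles) || any(!nzchar(trimws(roles)))) {
    stop("role labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(roles)) {
    stop("role labels must be distinct, got: ",
         paste(roles, collapse = ", "), call. = FALSE)
  }
  roles
}

#' Canonical ordered dyads for a role set
#'
#' Dyads are listed actor-major: all ordered pairs with the first role as
#' actor, then the second, and so on. This fixed order defines the layout of
#' every dyad vector and of the ANOVA weight matrix.
#'
#' @param roles character vector of exactly 4 distinct role labels.
#' @return a data frame with columns `actor` and `partner` (12 rows).
#' @export
#' @examples
#' dyad_pairs(c("M", "F", "C1", "C2"))
dyad_pairs <- function(roles) {
  roles <- check_roles(roles)
  data.frame(
    actor = rep(roles, each = 3L),
    partner = unlist(lapply(1:4, function(i) roles[-i]), use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname dyad_pairs
#' @return for `dyad_keys`, the 12 canonical `"actor->partner"` keys.
#' @export
dyad_keys <- function(roles) {
  p <- dyad_pairs(roles)
  paste0(p$actor, "->", p$partner)
}

#' Canonical effect identifiers
#'
#' The 21 SRM effects in their fixed order: the family effect, the four
#' actor effects, the four partner effects, then the twelve relationship
#' effects in canonical dyad order.
#'
#' @inheritParams dyad_pairs
#' @return character vector of 21 effect identifiers such as `"family"`,
#'   `"actor:M"`, `"relationship:C2->F"`.
#' @export
effect_ids <- function(roles) {
  roles <- check_roles(roles)
  c("family",
    paste0("actor:", roles),
    paste0("partner:", roles),
    paste0("relationship:", dyad_keys(roles)))
}

#' Construct a four-person round-robin data set
#'
#' Bundles one family's 12 directed dyadic measurements with its role
#' labels. Input may be a long-format data frame (`actor`, `partner`,
#' `value`), a numeric vector named with `"actor->partner"` keys, or a
#' 4 x 4 matrix with role labels as dimnames and an empty (NA) diagonal.
#'
#' All 12 ordered pairs must be present exactly once, with finite values;
#' self-pairs and missing or duplicated pairs are errors (the ANOVA weights
#' assume a complete round robin without self-ratings, and no imputation is
#' attempted). Values are accepted on any common measurement scale (item
#' means or sum scores); no range check is applied.
#'
#' @param x measurements in one of the three accepted layouts.
#' @param roles character vector of 4 distinct role labels fixing the
#'   canonical order. Defaults to the order of first appearance in `x`
#'   (data frame / named vector) or the matrix dimnames.
#' @return an object of class `round_robin`: a list with elements `roles`
#'   (character 4) and `values` (numeric 12, named by dyad key, canonical
#'   actor-major order).
#' @export
#' @examples
#' rr <- round_robin(data.frame(
#'   actor = c("A", "A", "A", "B", "B", "B", "C", "C", "C", "D", "D", "D"),
#'   partner = c("B", "C", "D", "A", "C", "D", "A", "B", "D", "A", "B", "C"),
#'   value = 1:12
#' ))
#' grand_mean(rr)
round_robin <- function(x, roles = NULL) {
  UseMethod("round_robin")
}

#' @export
round_robin.data.frame <- function(x, roles = NULL) {
  need <- c("actor", "partner", "value")
  if (!all(need %in% names(x))) {
    stop("long-format dyad data needs columns actor, partner, value; got: ",
         paste(names(x), collapse = ", "), call. = FALSE)
  }
  actor <- as.character(x$actor)
  partner <- as.character(x$partner)
  value <- x$value
  if (is.character(value)) value <- suppressWarnings(as.numeric(value))
  if (is.null(roles)) roles <- unique(c(rbind(actor, partner)))
  roles <- check_roles(roles)

  bad_role <- setdiff(c(actor, partner), roles)
  if (length(bad_role)) {
    stop("unknown role label(s) in dyad data: ",
         paste(unique(bad_role), collapse = ", "), call. = FALSE)
  }
  self <- actor == partner
  if (any(self)) {
    stop("self-pairs are not part of a round robin without self-ratings: ",
         paste(unique(actor[self]), collapse = ", "), call. = FALSE)
  }
  key <- paste0(actor, "->", partner)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicated dyad(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  wanted <- dyad_keys(roles)
  missing <- setdiff(wanted, key)
  if (length(missing)) {
    stop("incomplete round robin; missing dyad(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  values <- value[match(wanted, key)]
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- wanted[!is.finite(values)]
    stop("non-finite or non-numeric value(s) for dyad(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  names(values) <- wanted
  structure(list(roles = roles, values = values), class = "round_robin")
}

#' @export
round_robin.numeric <- function(x, roles = NULL) {
  if (is.null(names(x)) || any(!grepl("->", names(x), fixed = TRUE))) {
    stop("a numeric input must be named with 'actor->partner' dyad keys",
         call. = FALSE)
  }
  parts <- strsplit(names(x), "->", fixed = TRUE)
  round_robin(data.frame(
    actor = vapply(parts, `[`, "", 1L),
    partner = vapply(parts, `[`, "", 2L),
    value = as.numeric(x),
    stringsAsFactors = FALSE
  ), roles = roles)
}

#' @export
round_robin.matrix <- function(x, roles = NULL) {
  if (is.null(roles)) roles <- rownames(x)
  roles <- check_roles(roles)
  if (!identical(dim(x), c(4L, 4L))) {
    stop("matrix input must be 4 x 4 (actors in rows, partners in columns)",
         call. = FALSE)
  }
  if (!is.null(colnames(x)) && !identical(colnames(x), roles)) {
    stop("matrix row and column labels disagree: rows ",
         paste(roles, collapse = ","), " vs columns ",
         paste(colnames(x), collapse = ","), call. = FALSE)
  }
  diag_vals <- diag(x)
  if (any(!is.na(suppressWarnings(as.numeric(diag_vals))))) {
    stop("the diagonal (self-ratings) must be empty in a round robin",
         call. = FALSE)
  }
  p <- dyad_pairs(roles)
  round_robin(data.frame(
    actor = p$actor, partner = p$partner,
    value = as.numeric(x[cbind(match(p$actor, roles), match(p$partner, roles))]),
    stringsAsFactors = FALSE
  ), roles = roles)
}

#' @export
as.matrix.round_robin <- function(x, ...) {
  m <- matrix(NA_real_, 4L, 4L, dimnames = list(x$roles, x$roles))
  p <- dyad_pairs(x$roles)
  m[cbind(match(p$actor, x$roles), match(p$partner, x$roles))] <- x$values
  m
}

#' @export
as.data.frame.round_robin <- function(x, ...) {
  cbind(dyad_pairs(x$roles),
        data.frame(value = unname(x$values)))
}

#' @export
print.round_robin <- function(x, digits = 3L, ...) {
  cat("Four-person round robin (roles: ",
      paste(x$roles, collapse = ", "), ")\n", sep = "")
  print(round(as.matrix(x), digits))
  invisible(x)
}

stop_unknown_role <- function(role, roles) {
  if (length(role) != 1L || !(role %in% roles)) {
    stop("unknown role '", paste(role, collapse = ","),
         "'; expected one of: ", paste(roles, collapse = ", "),
         call. = FALSE)
  }
  role
}

# Weights of the n = 4 closed-form estimators:
# actor_i = a * row_mean_i + b * column_mean_i - g * grand_mean,
# with a = (n-1)^2 / (n (n-2)), b = (n-1) / (n (n-2)), g = (n-1) / (n-2).
srm_weights <- function(n = 4L) {
  list(a = (n - 1)^2 / (n * (n - 2)),
       b = (n - 1) / (n * (n - 2)),
       g = (n - 1) / (n - 2))
}

#' Grand (family) mean of a round robin
#'
#' The arithmetic mean of the 12 dyadic measurements; it is the ANOVA
#' estimate of the family effect.
#'
#' @param data a [round_robin] object.
#' @return a single number.
#' @export
grand_mean <- function(data) {
  stopifnot(inherits(data, "round_robin"))
  mean(data$values)
}

#' Row and column means of the round-robin table
#'
#' The row mean of a role is the average of its 3 outgoing ratings (how the
#' person rates the others); the column mean averages its 3 incoming ratings
#' (how the others rate the person).
#'
#' @inheritParams grand_mean
#' @return a list with named numeric vectors `row` and `column` (one entry
#'   per role).
#' @export
row_col_means <- function(data) {
  stopifnot(inherits(data, "round_robin"))
  p <- dyad_pairs(data$roles)
  row <- vapply(data$roles, function(r) mean(data$values[p$actor == r]), 0.0)
  column <- vapply(data$roles, function(r) mean(data$values[p$partner == r]), 0.0)
  list(row = row, column = column)
}

#' Actor, partner and relationship ANOVA scores
#'
#' Closed-form per-family estimates of the SRM effects. Because the
#' round-robin table has no diagonal, the actor score weights the row mean,
#' column mean and grand mean as 9/8, 3/8 and -3/2 (the n = 4 case of the
#' general missing-diagonal estimator); the partner score swaps the row and
#' column means. The relationship score is the dyadic measurement minus the
#' actor, partner and family components.
#'
#' @inheritParams grand_mean
#' @param role,actor,partner role labels present in `data`.
#' @return a single number.
#' @export
#' @examples
#' rr <- case_study_dyads()
#' actor_score(rr, "C2")        # 1.446
#' partner_score(rr, "F")       # 0.363
#' relationship_score(rr, "C2", "F")  # 0.931
actor_score <- function(data, role) {
  stopifnot(inherits(data, "round_robin"))
  stop_unknown_role(role, data$roles)
  w <- srm_weights()
  m <- row_col_means(data)
  w$a * m$row[[role]] + w$b * m$column[[role]] - w$g * grand_mean(data)
}

#' @rdname actor_score
#' @export
partner_score <- function(data, role) {
  stopifnot(inherits(data, "round_robin"))
  stop_unknown_role(role, data$roles)
  w <- srm_weights()
  m <- row_col_means(data)
  w$a * m$column[[role]] + w$b * m$row[[role]] - w$g * grand_mean(data)
}

#' @rdname actor_score
#' @export
relationship_score <- function(data, actor, partner) {
  stopifnot(inherits(data, "round_robin"))
  stop_unknown_role(actor, data$roles)
  stop_unknown_role(partner, data$roles)
  if (actor == partner) {
    stop("relationship effects are defined for ordered pairs of distinct ",
         "roles; got actor == partner == '", actor, "'", call. = FALSE)
  }
  data$values[[paste0(actor, "->", partner)]] -
    actor_score(data, actor) - partner_score(data, partner) -
    grand_mean(data)
}

#' Full SRM decomposition of one family's round robin
#'
#' Computes all 21 ANOVA scores: the family effect (grand mean), four actor
#' effects, four partner effects and twelve relationship effects. By
#' construction the actor scores sum to zero, the partner scores sum to
#' zero, the relationship scores sum to zero within each actor row and each
#' partner column, and
#' `family + actor[i] + partner[j] + relationship[i->j]` reconstructs every
#' measurement exactly.
#'
#' @inheritParams grand_mean
#' @return an object of class `srm_scores`: a list with elements `roles`,
#'   `family` (number), `actor` and `partner` (named numeric 4) and
#'   `relationship` (named numeric 12, dyad keys).
#' @export
#' @examples
#' s <- srm_scores(case_study_dyads())
#' as.data.frame(s)
srm_scores <- function(data) {
  stopifnot(inherits(data, "round_robin"))
  w <- srm_weights()
  g <- grand_mean(data)
  m <- row_col_means(data)
  actor <- w$a * m$row + w$b * m$column - w$g * g
  partner <- w$a * m$column + w$b * m$row - w$g * g
  p <- dyad_pairs(data$roles)
  relationship <- data$values - actor[p$actor] - partner[p$partner] - g
  names(relationship) <- dyad_keys(data$roles)
  structure(
    list(roles = data$roles, family = g,
         actor = actor, partner = partner, relationship = relationship),
    class = "srm_scores"
  )
}

#' @export
as.data.frame.srm_scores <- function(x, ...) {
  data.frame(
    effect = effect_ids(x$roles),
    score = unname(c(x$family, x$actor, x$partner, x$relationship)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.srm_scores <- function(x, digits = 3L, ...) {
  d <- as.data.frame(x)
  d$score <- round(d$score, digits)
  cat("SRM ANOVA scores (", paste(x$roles, collapse = ", "), ")\n", sep = "")
  print(d, row.names = FALSE)
  invisible(x)
}
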