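# File readers and writers.
#
# Dyad tables travel as CSV in either long form (actor,partner,value; 12
# rows) or matrix form (4 x 4 with role labels and an empty diagonal).
# Norm parameters travel as JSON or YAML with an explicit reciprocity
# scale.  Decimal parsing is locale-independent (dot separator only, the
# R default).  Report numbers are rounded only at write time; the JSON
# report keeps full precision.

#' Read a round robin from CSV
#'
#' Accepts either layout. A file whose header contains `actor`, `partner`
#' and `value` columns is parsed as long form; anything else is parsed as a
#' 4 x 4 matrix with role labels in the first row and column and empty
#' diagonal cells. Role order is taken from the file. Validation errors
#' (missing, duplicated or self pairs; non-numeric cells) name the
#' offending dyads.
#'
#' @param path path to a CSV file.
#' @return a [round_robin] object.
#' @export
read_dyads <- function(path) {
  if (!file.exists(path)) stop("dyad file not found: ", path, call. = FALSE)
  header <- tolower(strsplit(readLines(path, n = 1L), ",")[[1L]])
  header <- trimws(gsub('"', "", header, fixed = TRUE))
  if (all(c("actor", "partner", "value") %in% header)) {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(d) <- tolower(names(d))
    return(round_robin(d[c("actor", "partner", "value")]))
  }
  m <- utils::read.csv(path, row.names = 1L, check.names = FALSE,
                       stringsAsFactors = FALSE, colClasses = "character")
  mm <- as.matrix(m)
  num <- suppressWarnings(matrix(as.numeric(mm), nrow(mm), ncol(mm),
                                 dimnames = dimnames(mm)))
  blank <- mm == "" | is.na(mm)
  bad <- !blank & is.na(num)
  if (any(bad)) {
    stop("non-numeric cell(s) in matrix dyad file at: ",
         paste(paste0(rownames(mm)[row(mm)[bad]], "->",
                      colnames(mm)[col(mm)[bad]]), collapse = ", "),
         call. = FALSE)
  }
  round_robin(num)
}

#' Write a round robin to CSV
#'
#' @param data a [round_robin] object.
#' @param path output path.
#' @param format `"long"` (actor,partner,value) or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_dyads <- function(data, path, format = c("long", "matrix")) {
  stopifnot(inherits(data, "round_robin"))
  format <- match.arg(format)
  if (format == "long") {
    utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    m <- as.matrix(data)
    df <- as.data.frame(ifelse(is.na(m), "", format(m, trim = TRUE)))
    utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

norms_field <- function(lst, key, path) {
  if (is.null(lst[[key]])) {
    stop("norm file ", path, ": missing key '", key, "'", call. = FALSE)
  }
  lst[[key]]
}

mean_var_vec <- function(lst, keys, field, path) {
  m <- v <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys) {
    entry <- lst[[k]]
    if (is.null(entry) || is.null(entry$mean) || is.null(entry$var)) {
      stop("norm file ", path, ": '", field, "/", k,
           "' must have numeric 'mean' and 'var'", call. = FALSE)
    }
    m[[k]] <- as.numeric(entry$mean)
    v[[k]] <- as.numeric(entry$var)
  }
  list(mean = m, var = v)
}

#' Read SRM norm parameters from JSON or YAML
#'
#' The file layout mirrors how these parameters are reported: a `roles`
#' array; `family`, per-role `actor` and `partner`, and per-ordered-dyad
#' `relationship` blocks each holding `mean` and `var`; per-role
#' `generalized_reciprocity`; per-unordered-dyad `dyadic_reciprocity`
#' (`"a<->b"` keys); and `reciprocity_scale` set to `"correlation"` or
#' `"covariance"`. An optional `variance_significant` block of booleans
#' (keys `family`, roles under `actor`/`partner`, ordered dyads under
#' `relationship`) records which norm variances were significant; it is
#' carried into assessment reports as a caution flag.
#'
#' The format is chosen by extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path path to the parameter file.
#' @return an [srm_norms] object.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norm file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported norm file extension '", ext,
         "'; use .json, .yml or .yaml", call. = FALSE)
  )
  roles <- as.character(norms_field(lst, "roles", path))
  fam <- norms_field(lst, "family", path)
  if (is.null(fam$mean) || is.null(fam$var)) {
    stop("norm file ", path, ": 'family' must have 'mean' and 'var'",
         call. = FALSE)
  }
  act <- mean_var_vec(norms_field(lst, "actor", path), roles, "actor", path)
  par <- mean_var_vec(norms_field(lst, "partner", path), roles, "partner",
                      path)
  dk <- dyad_keys(roles)
  rel <- mean_var_vec(norms_field(lst, "relationship", path), dk,
                      "relationship", path)
  gr <- unlist(norms_field(lst, "generalized_reciprocity", path))
  dr <- unlist(norms_field(lst, "dyadic_reciprocity", path))
  scale <- as.character(norms_field(lst, "reciprocity_scale", path))

  out <- srm_norms(
    roles = roles,
    family_mean = fam$mean, family_var = fam$var,
    actor_mean = act$mean, actor_var = act$var,
    partner_mean = par$mean, partner_var = par$var,
    rel_mean = rel$mean, rel_var = rel$var,
    generalized_reciprocity = gr,
    dyadic_reciprocity = dr,
    reciprocity_scale = scale
  )
  if (!is.null(lst$variance_significant)) {
    vs <- lst$variance_significant
    sig <- stats::setNames(rep(NA, 21L), effect_ids(roles))
    if (!is.null(vs$family)) sig[["family"]] <- isTRUE(vs$family)
    for (r in roles) {
      if (!is.null(vs$actor[[r]]))
        sig[[paste0("actor:", r)]] <- isTRUE(vs$actor[[r]])
      if (!is.null(vs$partner[[r]]))
        sig[[paste0("partner:", r)]] <- isTRUE(vs$partner[[r]])
    }
    for (k in dk) {
      if (!is.null(vs$relationship[[k]]))
        sig[[paste0("relationship:", k)]] <- isTRUE(vs$relationship[[k]])
    }
    attr(out, "variance_significant") <- sig
  }
  out
}

#' Write SRM norm parameters to JSON or YAML
#'
#' Inverse of [read_norms()]; the format follows the file extension.
#'
#' @param params an [srm_norms] object.
#' @param path output path (`.json`, `.yml` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_norms <- function(params, path) {
  stopifnot(inherits(params, "srm_norms"))
  roles <- params$roles
  mv <- function(m, v) {
    stats::setNames(
      lapply(seq_along(m), function(i) list(mean = m[[i]], var = v[[i]])),
      names(m))
  }
  lst <- list(
    roles = roles,
    family = list(mean = params$family_mean, var = params$family_var),
    actor = mv(params$actor_mean, params$actor_var),
    partner = mv(params$partner_mean, params$partner_var),
    relationship = mv(params$rel_mean, params$rel_var),
    generalized_reciprocity = as.list(params$generalized_reciprocity),
    dyadic_reciprocity = as.list(params$dyadic_reciprocity),
    reciprocity_scale = params$reciprocity_scale
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(lst, path)
  } else {
    stop("unsupported norm file extension '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

#' Write an assessment report to CSV or JSON
#'
#' The CSV carries the columns `effect`, `anova_score`, `z`, `p`, `flag`
#' (plus `p_adj` when present), rounded to `digits` decimals. The JSON
#' report keeps full precision and adds a metadata block (roles,
#' thresholds, adjustment).
#'
#' @param report an `srm_assessment` from [srm_assess()].
#' @param path output path, or `""` for standard output (CSV only).
#' @param format `"csv"` or `"json"`.
#' @param digits decimals for the CSV report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json"),
                         digits = 3L) {
  stopifnot(inherits(report, "srm_assessment"))
  format <- match.arg(format)
  if (format == "csv") {
    cols <- intersect(c("effect", "anova_score", "z", "p", "p_adj", "flag"),
                      names(report))
    d <- as.data.frame(report)[cols]
    num <- vapply(d, is.numeric, TRUE)
    d[num] <- lapply(d[num], round, digits = digits)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    th <- attr(report, "thresholds")
    out <- list(
      metadata = list(
        roles = attr(report, "roles"),
        thresholds = list(elevated = th[["elevated"]],
                          extreme = th[["extreme"]]),
        adjust = attr(report, "adjust")
      ),
      effects = as.data.frame(report)
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null", dataframe = "rows")
  }
  invisible(path)
}

#' Write the built-in case-study fixture files
#'
#' Materializes the worked example as files: the family's dyads in long and
#' matrix CSV form, the norm parameters as JSON, and the reference
#' assessment table as CSV. Repeated runs produce byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @return character vector of the paths written, invisibly.
#' @export
srm_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("case_study_dyads.csv",
                            "case_study_dyads_matrix.csv",
                            "case_study_norms.json",
                            "case_study_reference.csv"))
  write_dyads(case_study_dyads(), paths[1L], format = "long")
  write_dyads(case_study_dyads(), paths[2L], format = "matrix")
  write_norms(case_study_norms(), paths[3L])
  ref <- case_study_reference()
  utils::write.csv(ref, paths[4L], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
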