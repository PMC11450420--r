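#' Define one binary complexity indicator
#'
#' @param name unique indicator identifier.
#' @param source_fields visit-table columns the rule reads.
#' @param rule function taking the visits tibble and returning one logical
#'   per visit: `TRUE` when the risk factor is present at that visit, `NA`
#'   when its source fields were not measured at that visit.
#' @param description human-readable rule statement.
#' @return object of class `indicator_definition`.
#' @export
indicator_definition <- function(name, source_fields, rule, description = "") {
  stopifnot(is.character(name), length(name) == 1, is.function(rule))
  structure(
    list(name = name, source_fields = source_fields, rule = rule,
         description = description, aggregation = "any_visit"),
    class = "indicator_definition"
  )
}

#' The default set of 13 complexity indicator definitions
#'
#' Reconstructs the study's indicator set from the published thresholds and
#' axis labels: very high psychological distress (K10 > 30), low quality of
#' life (MLT below its configurable cut), low functioning (SOFAS <= 60),
#' later illness stage (stage >= 2), a severe/complex-disorder diagnosis
#' (psychotic, bipolar, personality or neurodevelopmental), self-harm or
#' suicidality as the presenting issue, alcohol-and-other-drug treatment
#' issue, trauma history, housing issues, NEET status, an
#' education/employment engagement issue, government benefits, and
#' co-occurring difficulties. Every indicator is coded "yes" when its rule
#' fires at any visit of the episode. The exact published definitions sit in
#' unavailable supplementary material, so this set is a documented
#' reconstruction with configurable thresholds and severe-diagnosis list.
#'
#' @param thresholds output of [complexity_thresholds()].
#' @param severe_codes diagnosis categories counting as severe/complex.
#' @return named list of 13 [indicator_definition()]s, in the canonical
#'   order of [complexity_indicator_names()].
#' @export
default_indicator_set <- function(thresholds = complexity_thresholds(),
                                  severe_codes = severe_diagnosis_codes()) {
  th <- thresholds
  stage_num <- function(stage) {
    suppressWarnings(as.numeric(sub("[ab]$", "", stage)))
  }
  defs <- list(
    indicator_definition(
      "distress", "k10_total",
      function(v) v$k10_total > th$k10_above,
      sprintf("K10 total > %d at any visit", th$k10_above)
    ),
    indicator_definition(
      "low_quality_of_life", "mlt_total",
      function(v) v$mlt_total < th$mlt_below,
      sprintf("MyLifeTracker total < %d at any visit", th$mlt_below)
    ),
    indicator_definition(
      "low_functioning", "sofas",
      function(v) v$sofas <= th$sofas_at_or_below,
      sprintf("SOFAS <= %d at any visit", th$sofas_at_or_below)
    ),
    indicator_definition(
      "later_stage", "stage",
      function(v) stage_num(v$stage) >= th$stage_at_or_above,
      sprintf("clinician illness stage >= %s", th$stage_at_or_above)
    ),
    indicator_definition(
      "severe_disorder", "diagnosis_code",
      function(v) ifelse(is.na(v$diagnosis_code), NA,
                         v$diagnosis_code %in% severe_codes),
      paste("primary/secondary diagnosis in:",
            paste(severe_codes, collapse = ", "))
    ),
    indicator_definition(
      "self_harm_suicidality", "presenting_issue",
      function(v) ifelse(is.na(v$presenting_issue), NA,
                         v$presenting_issue == "self_harm_suicidality"),
      "self-harm/suicidality as primary presenting issue"
    ),
    indicator_definition(
      "aod_treatment", "aod_treatment_flag",
      function(v) v$aod_treatment_flag > 0,
      "alcohol and other drug treatment issue flagged"
    ),
    indicator_definition(
      "trauma_history", "trauma_flag",
      function(v) v$trauma_flag > 0,
      "trauma history flagged"
    ),
    indicator_definition(
      "housing_issues", "housing_issue_flag",
      function(v) v$housing_issue_flag > 0,
      "housing issue flagged"
    ),
    indicator_definition(
      "neet", "neet_flag",
      function(v) v$neet_flag > 0,
      "not in employment, education or training"
    ),
    indicator_definition(
      "vocational_issue", "presenting_issue",
      function(v) ifelse(is.na(v$presenting_issue), NA,
                         v$presenting_issue == "education_employment"),
      "education/employment engagement as presenting issue"
    ),
    indicator_definition(
      "government_benefits", "benefits_flag",
      function(v) v$benefits_flag > 0,
      "receiving government benefits"
    ),
    indicator_definition(
      "cooccurring_difficulties", "cooccurring_flag",
      function(v) v$cooccurring_flag > 0,
      "co-occurring difficulties flagged"
    )
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  stopifnot(identical(names(defs), complexity_indicator_names()))
  defs
}

#' Construct an indicator matrix directly
#'
#' For programmatic construction (tests, simulations, external data):
#' `NA` cells are treated as unobserved unless an explicit mask is given.
#'
#' @param values n x p matrix of 0/1 values, `NA` where unobserved.
#' @param episode_ids optional row identifiers (default sequential).
#' @param observed_mask optional logical matrix; default `!is.na(values)`.
#' @return an `indicator_matrix`.
#' @export
indicator_matrix <- function(values, episode_ids = NULL,
                             observed_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(observed_mask)) observed_mask <- !is.na(values)
  if (is.null(episode_ids)) episode_ids <- seq_len(nrow(values))
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("item", seq_len(ncol(values)))
  }
  new_indicator_matrix(episode_ids, values, observed_mask, colnames(values))
}

new_indicator_matrix <- function(episode_ids, values, observed_mask,
                                 indicator_names = colnames(values)) {
  values <- as.matrix(values)
  observed_mask <- as.matrix(observed_mask)
  stopifnot(
    length(episode_ids) == nrow(values),
    identical(dim(values), dim(observed_mask)),
    all(values[observed_mask] %in% c(0L, 1L))
  )
  values[!observed_mask] <- NA_integer_
  storage.mode(values) <- "integer"
  dimnames(values) <- list(NULL, indicator_names)
  dimnames(observed_mask) <- list(NULL, indicator_names)
  structure(
    list(episode_ids = episode_ids, values = values,
         observed_mask = observed_mask, indicator_names = indicator_names),
    class = "indicator_matrix"
  )
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat(sprintf(
    "<indicator_matrix> %d episodes x %d indicators; %.1f%% cells observed\n",
    nrow(x$values), ncol(x$values), 100 * mean(x$observed_mask)
  ))
  invisible(x)
}

#' @export
dim.indicator_matrix <- function(x) dim(x$values)

#' Derive the binary indicator matrix from an episode-of-care cohort
#'
#' Applies each indicator rule at every visit and aggregates by any-visit
#' OR: an indicator is 1 if its rule fires at any visit of the episode, 0 if
#' its source fields were measured at one or more visits and the rule never
#' fired, and missing if the sources were never measured in the episode.
#'
#' @param cohort an `eoc_cohort` (or a list with `episodes` and `visits`
#'   tibbles).
#' @param defs list of [indicator_definition()]s, default
#'   [default_indicator_set()].
#' @return an `indicator_matrix`.
#' @export
derive_indicators <- function(cohort, defs = default_indicator_set()) {
  visits <- cohort$visits
  episodes <- cohort$episodes
  stopifnot(nrow(episodes) > 0, nrow(visits) > 0)
  for (d in defs) {
    missing_fields <- setdiff(d$source_fields, names(visits))
    if (length(missing_fields)) {
      abort_config("indicator '%s' references unknown source field(s): %s",
                   d$name, paste(missing_fields, collapse = ", "))
    }
  }
  fired <- lapply(defs, function(d) as.logical(d$rule(visits)))
  names(fired) <- vapply(defs, `[[`, "", "name")

  dt <- data.table::as.data.table(fired)
  data.table::set(dt, j = ".eid_", value = visits$episode_id)
  agg_val <- dt[, lapply(.SD, function(x) any(x, na.rm = TRUE)), by = ".eid_"]
  agg_obs <- dt[, lapply(.SD, function(x) any(!is.na(x))), by = ".eid_"]
  ord <- match(episodes$episode_id, agg_val[[".eid_"]])
  stopifnot(!anyNA(ord))
  values <- as.matrix(agg_val[ord, -1]) * 1L
  observed <- as.matrix(agg_obs[ord, -1])
  values[!observed] <- NA_integer_
  new_indicator_matrix(episodes$episode_id, values, observed, names(fired))
}

#' Remove episodes with every indicator missing
#'
#' Episodes with an all-missing indicator row carry no information for the
#' complexity analysis and are excluded, mirroring the analytic-sample
#' construction. Idempotent; conservation `n_total = n_excluded + n_retained`
#' always holds.
#'
#' @param m an `indicator_matrix`.
#' @return list with the filtered `matrix` and a `report` (n_total,
#'   n_excluded, n_retained, excluded_ids).
#' @export
exclusion_filter <- function(m) {
  stopifnot(inherits(m, "indicator_matrix"))
  all_missing <- rowSums(m$observed_mask) == 0
  n_total <- nrow(m$values)
  n_excluded <- sum(all_missing)
  if (n_excluded == n_total) {
    stop("exclusion_filter: no episodes retained (all rows fully missing)",
         call. = FALSE)
  }
  keep <- !all_missing
  out <- new_indicator_matrix(
    m$episode_ids[keep], m$values[keep, , drop = FALSE],
    m$observed_mask[keep, , drop = FALSE], m$indicator_names
  )
  list(
    matrix = out,
    report = list(
      n_total = n_total,
      n_excluded = n_excluded,
      n_retained = n_total - n_excluded,
      excluded_ids = m$episode_ids[all_missing]
    )
  )
}

#' Indicator prevalence by group
#'
#' Prevalence of each indicator among its observed entries, overall or
#' within levels of a grouping variable (e.g. age group). Groups with zero
#' observed entries for an indicator report `NA`, never zero.
#'
#' @param m an `indicator_matrix`.
#' @param grouping optional categorical vector of length `nrow(m$values)`.
#' @return tibble with group, indicator, n_observed, n_yes, prevalence.
#' @export
prevalence_by_group <- function(m, grouping = NULL) {
  stopifnot(inherits(m, "indicator_matrix"))
  n <- nrow(m$values)
  if (is.null(grouping)) grouping <- rep("overall", n)
  stopifnot(length(grouping) == n)
  groups <- sort(unique(as.character(grouping)))
  out <- lapply(groups, function(g) {
    rows <- grouping == g
    n_obs <- colSums(m$observed_mask[rows, , drop = FALSE])
    n_yes <- colSums(m$values[rows, , drop = FALSE] == 1L, na.rm = TRUE)
    tibble::tibble(
      group = g,
      indicator = m$indicator_names,
      n_observed = as.integer(unname(n_obs)),
      n_yes = as.integer(unname(n_yes)),
      prevalence = unname(ifelse(n_obs > 0, n_yes / n_obs, NA_real_))
    )
  })
  dplyr::bind_rows(out)
}

#' Write / read an indicator matrix as delimited text
#'
#' One row per episode with paired value and `__observed` columns.
#'
#' @param m an `indicator_matrix`.
#' @param path CSV file path.
#' @return `write_indicator_matrix()` the path invisibly;
#'   `read_indicator_matrix()` an `indicator_matrix`.
#' @export
write_indicator_matrix <- function(m, path) {
  df <- data.table::data.table(episode_id = m$episode_ids)
  for (j in seq_along(m$indicator_names)) {
    nm <- m$indicator_names[j]
    df[[nm]] <- m$values[, j]
    df[[paste0(nm, "__observed")]] <- m$observed_mask[, j]
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_indicator_matrix
#' @export
read_indicator_matrix <- function(path) {
  df <- data.table::fread(path)
  nms <- setdiff(names(df), "episode_id")
  ind <- nms[!endsWith(nms, "__observed")]
  values <- as.matrix(df[, ind, with = FALSE])
  observed <- as.matrix(df[, paste0(ind, "__observed"), with = FALSE])
  new_indicator_matrix(df$episode_id, values, observed, ind)
}
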