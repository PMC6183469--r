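#' @importFrom stats plogis qlogis qnorm rbinom rnorm rmultinom runif optim
#'   quantile median setNames model.matrix dbinom
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

# Canonical factor levels. Adders are the reference species throughout:
# the identification model's intercept is the probability an adder picture
# is called "adder".
species_levels <- function() c("adder", "smooth", "grass")
response_levels <- function() c("adder", "smooth", "grass", "unknown")
attitude_levels <- function() c("no_kill", "kill_all", "kill_selective")
seen_where_levels <- function() c("yard", "nature", "both", "none")

mr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mimicryrisk_error")))
}

#' Construct a snake-identification survey dataset
#'
#' Bundles a respondent table (attitudes toward killing snakes, sightings)
#' with an identification-trial table (one row per respondent x picture,
#' recording which species the respondent believed the picture showed).
#'
#' @param respondents data frame with columns `respondent_id`,
#'   `municipality`, `saw_snake_last_year` (logical), `seen_where`
#'   (`"yard"`, `"nature"`, `"both"`, `"none"`) and `attitude`
#'   (`"no_kill"`, `"kill_all"`, `"kill_selective"`).
#' @param trials data frame with columns `respondent_id`, `picture_id`,
#'   `true_species` (`"adder"`, `"smooth"`, `"grass"`) and `response`
#'   (a species or `"unknown"`).
#' @param check if `TRUE` (default), run [validate_survey()] and abort on
#'   any violation. Set `FALSE` to build a deliberately invalid dataset,
#'   e.g. to exercise the validator.
#' @return An object of class `survey_dataset`: a list with elements
#'   `respondents` and `trials`.
#' @seealso [read_survey()], [validate_survey()], [generate_survey()]
#' @export
survey_dataset <- function(respondents, trials, check = TRUE) {
  respondents <- as.data.frame(respondents, stringsAsFactors = FALSE)
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)

  req_resp <- c("respondent_id", "saw_snake_last_year", "seen_where", "attitude")
  req_tr <- c("respondent_id", "picture_id", "true_species", "response")
  for (col in req_resp) {
    if (!col %in% names(respondents)) {
      mr_error(sprintf("respondents table is missing required column '%s'", col),
               "mimicryrisk_schema_error")
    }
  }
  for (col in req_tr) {
    if (!col %in% names(trials)) {
      mr_error(sprintf("trials table is missing required column '%s'", col),
               "mimicryrisk_schema_error")
    }
  }
  if (!"municipality" %in% names(respondents)) respondents$municipality <- NA_character_

  respondents$respondent_id <- as.character(respondents$respondent_id)
  respondents$municipality <- as.character(respondents$municipality)
  respondents$saw_snake_last_year <- as_logical_strict(
    respondents$saw_snake_last_year, "saw_snake_last_year")
  respondents$seen_where <- tolower(as.character(respondents$seen_where))
  respondents$attitude <- tolower(as.character(respondents$attitude))
  trials$respondent_id <- as.character(trials$respondent_id)
  trials$picture_id <- as.character(trials$picture_id)
  trials$true_species <- tolower(as.character(trials$true_species))
  trials$response <- tolower(as.character(trials$response))

  out <- structure(list(respondents = respondents, trials = trials),
                   class = "survey_dataset")
  if (check) {
    viol <- validate_survey(out)
    if (length(viol) > 0) {
      cls <- "mimicryrisk_validation_error"
      if (any(grepl("no matching respondent", viol))) {
        cls <- c("mimicryrisk_referential_error", cls)
      } else if (any(grepl("more than one true_species", viol))) {
        cls <- c("mimicryrisk_consistency_error", cls)
      }
      mr_error(paste0("invalid survey dataset:\n  - ",
                      paste(viol, collapse = "\n  - ")), cls)
    }
  }
  out
}

as_logical_strict <- function(x, name) {
  if (is.logical(x)) return(x)
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && !anyNA(x)) {
    mr_error(sprintf("column '%s' contains values not interpretable as true/false", name),
             "mimicryrisk_schema_error")
  }
  out
}

#' List invariant violations in a survey dataset
#'
#' Checks the structural rules a well-formed survey must satisfy and returns
#' violations as descriptions instead of raising errors, so datasets built
#' with `check = FALSE` can be inspected.
#'
#' Rules checked: unique respondent ids; enumerated values for attitude,
#' sighting location, species and response; every trial refers to a known
#' respondent; each picture id maps to a single true species; at most 3
#' trials per species and 9 total per respondent; `seen_where == "none"`
#' exactly for respondents who saw no snake. (Presence of all three
#' attitude categories is a pipeline precondition checked by
#' [run_analysis()], not a structural defect.)
#'
#' @param dataset a [survey_dataset()].
#' @return character vector of violation descriptions; empty if valid.
#' @export
validate_survey <- function(dataset) {
  r <- dataset$respondents
  t <- dataset$trials
  viol <- character(0)

  dup <- unique(r$respondent_id[duplicated(r$respondent_id)])
  if (length(dup) > 0) {
    viol <- c(viol, sprintf("duplicate respondent_id: %s",
                            paste(dup, collapse = ", ")))
  }
  bad_att <- unique(r$attitude[!r$attitude %in% attitude_levels()])
  if (length(bad_att) > 0) {
    viol <- c(viol, sprintf("attitude outside {%s}: %s",
                            paste(attitude_levels(), collapse = ", "),
                            paste(bad_att, collapse = ", ")))
  }
  bad_seen <- unique(r$seen_where[!r$seen_where %in% seen_where_levels()])
  if (length(bad_seen) > 0) {
    viol <- c(viol, sprintf("seen_where outside {%s}: %s",
                            paste(seen_where_levels(), collapse = ", "),
                            paste(bad_seen, collapse = ", ")))
  }
  mism <- r$respondent_id[!is.na(r$saw_snake_last_year) &
                            ((r$seen_where == "none") != !r$saw_snake_last_year)]
  if (length(mism) > 0) {
    viol <- c(viol, sprintf(
      "seen_where must be 'none' exactly when saw_snake_last_year is false; violated by: %s",
      paste(mism, collapse = ", ")))
  }

  bad_sp <- unique(t$true_species[!t$true_species %in% species_levels()])
  if (length(bad_sp) > 0) {
    viol <- c(viol, sprintf("true_species outside {%s}: %s",
                            paste(species_levels(), collapse = ", "),
                            paste(bad_sp, collapse = ", ")))
  }
  bad_resp <- unique(t$response[!t$response %in% response_levels()])
  if (length(bad_resp) > 0) {
    viol <- c(viol, sprintf("response outside {%s}: %s",
                            paste(response_levels(), collapse = ", "),
                            paste(bad_resp, collapse = ", ")))
  }

  orphan <- unique(t$respondent_id[!t$respondent_id %in% r$respondent_id])
  if (length(orphan) > 0) {
    viol <- c(viol, sprintf("trial rows with no matching respondent: %s",
                            paste(orphan, collapse = ", ")))
  }

  pic_map <- unique(t[, c("picture_id", "true_species")])
  multi <- unique(pic_map$picture_id[duplicated(pic_map$picture_id)])
  if (length(multi) > 0) {
    viol <- c(viol, sprintf(
      "picture_id mapped to more than one true_species: %s",
      paste(multi, collapse = ", ")))
  }

  if (nrow(t) > 0) {
    cnt <- table(t$respondent_id, t$true_species)
    over3 <- rownames(cnt)[apply(cnt, 1, max) > 3]
    if (length(over3) > 0) {
      viol <- c(viol, sprintf(
        "more than 3 trials for a single species (limit 3 per species) for respondent(s): %s",
        paste(over3, collapse = ", ")))
    }
    tot <- table(t$respondent_id)
    over9 <- names(tot)[tot > 9]
    if (length(over9) > 0) {
      viol <- c(viol, sprintf(
        "more than 9 trials in total for respondent(s): %s",
        paste(over9, collapse = ", ")))
    }
  }

  viol
}

# All three attitude categories are needed before the full pipeline can run
# (mu0, muv and the attitude-skill model are undefined otherwise); this is a
# pipeline precondition rather than a structural defect of the dataset.
check_attitudes_complete <- function(dataset) {
  missing_att <- setdiff(attitude_levels(), unique(dataset$respondents$attitude))
  if (length(missing_att) > 0) {
    mr_error(sprintf(
      "attitude categories unrepresented (full pipeline requires all three): %s",
      paste(missing_att, collapse = ", ")),
      "mimicryrisk_pipeline_error")
  }
  invisible(dataset)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Snake-identification survey dataset\n")
  cat(sprintf("  respondents: %d\n", nrow(x$respondents)))
  cat(sprintf("  trials:      %d (%d pictures)\n",
              nrow(x$trials), length(unique(x$trials$picture_id))))
  tab <- table(factor(x$respondents$attitude, levels = attitude_levels()))
  cat(sprintf("  attitudes:   no_kill %d, kill_all %d, kill_selective %d\n",
              tab[["no_kill"]], tab[["kill_all"]], tab[["kill_selective"]]))
  invisible(x)
}

#' Read a survey from a pair of CSV files
#'
#' Expects the normalized two-file layout: a respondents table and a trials
#' table (see [survey_dataset()] for columns). A column-mapping list allows
#' ingesting files whose headers differ from the canonical names without
#' editing them: names are canonical keys, values the column names present
#' in the file. Unknown columns are preserved but ignored by the analysis.
#'
#' @param respondents_path,trials_path CSV file paths.
#' @param column_map optional named character vector / list, or path to a
#'   JSON file holding one, e.g.
#'   `list(respondent_id = "ID", attitude = "kill_attitude")`. Keys may
#'   target either file; only matching columns are renamed. An optional
#'   `values` entry may remap factor codes, e.g.
#'   `values = list(attitude = c(none = "no_kill"))`.
#' @param check passed to [survey_dataset()].
#' @return a [survey_dataset()].
#' @export
read_survey <- function(respondents_path, trials_path, column_map = NULL,
                        check = TRUE) {
  for (p in c(respondents_path, trials_path)) {
    if (!file.exists(p)) {
      mr_error(sprintf("file not found: %s", p), "mimicryrisk_io_error")
    }
  }
  map <- load_column_map(column_map)
  r <- apply_column_map(read.csv(respondents_path, stringsAsFactors = FALSE), map)
  t <- apply_column_map(read.csv(trials_path, stringsAsFactors = FALSE), map)
  survey_dataset(r, t, check = check)
}

load_column_map <- function(column_map) {
  if (is.null(column_map)) return(NULL)
  if (is.character(column_map) && length(column_map) == 1 &&
      file.exists(column_map)) {
    column_map <- jsonlite::read_json(column_map, simplifyVector = TRUE)
  }
  as.list(column_map)
}

apply_column_map <- function(df, map) {
  if (is.null(map)) return(df)
  vals <- map$values
  map$values <- NULL
  for (key in names(map)) {
    src <- map[[key]]
    if (src %in% names(df) && !key %in% names(df)) {
      names(df)[names(df) == src] <- key
    }
  }
  for (key in names(vals)) {
    if (key %in% names(df)) {
      vmap <- unlist(vals[[key]])
      hit <- df[[key]] %in% names(vmap)
      df[[key]][hit] <- unname(vmap[df[[key]][hit]])
    }
  }
  df
}

#' Write a survey to the two-file CSV layout
#'
#' Round-trips exactly through [read_survey()].
#'
#' @param dataset a [survey_dataset()].
#' @param respondents_path,trials_path output CSV paths.
#' @return invisibly, the dataset.
#' @export
write_survey <- function(dataset, respondents_path, trials_path) {
  write.csv(dataset$respondents, respondents_path, row.names = FALSE)
  write.csv(dataset$trials, trials_path, row.names = FALSE)
  invisible(dataset)
}

#' Read a survey from a single wide CSV file
#'
#' Adapter for deposits that store one row per trial with respondent-level
#' columns repeated; splits it into the normalized respondents/trials pair.
#'
#' @inheritParams read_survey
#' @param path CSV path with both respondent- and trial-level columns.
#' @return a [survey_dataset()].
#' @export
read_survey_wide <- function(path, column_map = NULL, check = TRUE) {
  if (!file.exists(path)) {
    mr_error(sprintf("file not found: %s", path), "mimicryrisk_io_error")
  }
  df <- apply_column_map(read.csv(path, stringsAsFactors = FALSE),
                         load_column_map(column_map))
  resp_cols <- intersect(
    c("respondent_id", "municipality", "saw_snake_last_year", "seen_where",
      "attitude"), names(df))
  trial_cols <- intersect(
    c("respondent_id", "picture_id", "true_species", "response"), names(df))
  r <- unique(df[, resp_cols, drop = FALSE])
  t <- df[, trial_cols, drop = FALSE]
  survey_dataset(r, t, check = check)
}

#' Attitude proportions with binomial-GLM uncertainty
#'
#' For each attitude category, estimates the proportion of respondents in
#' that category as an intercept-only binomial GLM on the logit scale (see
#' [fit_intercept_glm()]). The `kill_all` estimate is the baseline kill
#' probability mu0; `kill_selective` is the selective kill probability muv.
#'
#' @param dataset a [survey_dataset()].
#' @return named list (one [fit_intercept_glm()] result per category) of
#'   class `attitude_proportions`.
#' @export
attitude_proportions <- function(dataset) {
  n <- nrow(dataset$respondents)
  if (n == 0) {
    mr_error("dataset has no respondents", "mimicryrisk_empty_input_error")
  }
  att <- factor(dataset$respondents$attitude, levels = attitude_levels())
  counts <- table(att)
  out <- lapply(attitude_levels(), function(a) {
    fit_intercept_glm(k = as.integer(counts[[a]]), n = n)
  })
  names(out) <- attitude_levels()
  structure(out, class = "attitude_proportions")
}

#' @export
print.attitude_proportions <- function(x, ...) {
  cat("Attitude proportions (intercept-only binomial GLM)\n")
  for (a in names(x)) {
    e <- x[[a]]
    cat(sprintf("  %-15s %3d/%3d  p = %.3f  [%.3f, %.3f]\n",
                a, e$k, e$n, e$p_hat, e$ci_low, e$ci_high))
  }
  invisible(x)
}
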