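#' Regression recipes for trial-level N400 data
#'
#' Two preset fixed/random-effects structures are built in, mirroring the two
#' analysis traditions for the datasets this package targets:
#'
#' * `"lab_random_subject"` — multi-lab design: baselined N400 amplitude as
#'   the dependent variable, the metric and laboratory as fixed effects, and
#'   a random intercept for each subject.
#' * `"baseline_covariates"` — single-lab design: raw (un-baselined) N400
#'   amplitude as the dependent variable; baseline voltage, concreteness,
#'   log frequency, orthographic neighborhood (OLD20), sentence position and
#'   the metric as fixed effects; random baseline slopes for subject and
#'   item plus intercepts (subject intercept included by default as the
#'   maximal structure consistent with the stated slopes;
#'   `subject_intercept = FALSE` gives the slope-only reading).
#'
#' @param name Preset name.
#' @param subject_intercept For `"baseline_covariates"`: include a random
#'   intercept for subject alongside the baseline slope.
#'
#' @return An object of class `regression_recipe`: fields `name`, `dv`
#'   (`"baselined_amplitude"` or `"raw_amplitude"`), `fixed_terms`,
#'   `random_terms` (list of `(group, slopes, intercept)`).
#' @export
preset_recipe <- function(name = c("lab_random_subject", "baseline_covariates"),
                          subject_intercept = TRUE) {
  name <- match.arg(name)
  if (name == "lab_random_subject") {
    recipe <- list(
      name = name,
      dv = "baselined_amplitude",
      fixed_terms = c("metric", "lab"),
      random_terms = list(
        list(group = "subject_id", slopes = character(0), intercept = TRUE)
      )
    )
  } else {
    recipe <- list(
      name = name,
      dv = "raw_amplitude",
      fixed_terms = c("baseline", "concreteness", "log_frequency", "old20",
                      "sentence_position", "metric"),
      random_terms = list(
        list(group = "subject_id", slopes = "baseline",
             intercept = subject_intercept),
        list(group = "item_id", slopes = "baseline", intercept = TRUE)
      )
    )
  }
  structure(recipe, class = "regression_recipe")
}

#' @export
print.regression_recipe <- function(x, ...) {
  cat("<regression_recipe> ", x$name, "\n", sep = "")
  cat("  dv: ", x$dv, "\n", sep = "")
  cat("  fixed: ", paste(x$fixed_terms, collapse = " + "), "\n", sep = "")
  for (rt in x$random_terms) {
    lhs <- paste(c(if (rt$intercept) "1" else "0", rt$slopes), collapse = " + ")
    cat("  random: (", lhs, " | ", rt$group, ")\n", sep = "")
  }
  invisible(x)
}

#' Bundle trials with a recipe into an analysis dataset
#'
#' @param trials Tibble of trial records (one EEG epoch per row). Must have
#'   `subject_id`, `item_id` and `amplitude`; recipe-required covariates
#'   (`lab`, `baseline`, `concreteness`, `log_frequency`, `old20`,
#'   `sentence_position`) as needed.
#' @param name Dataset label.
#' @param recipe A [preset_recipe()] (or compatible `regression_recipe`).
#' @param dropped Optional tibble logging rows removed during loading.
#'
#' @return An object of class `n400_dataset`.
#' @export
n400_dataset <- function(trials, name, recipe, dropped = NULL) {
  stopifnot(inherits(recipe, "regression_recipe"))
  trials <- tibble::as_tibble(trials)
  req <- c("subject_id", "item_id", "amplitude")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols) > 0L) {
    abort(paste0("trials lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(trials$amplitude))) abort("non-finite amplitude")
  if (any(!nzchar(trials$subject_id)) || any(!nzchar(trials$item_id))) {
    abort("empty subject_id or item_id")
  }
  structure(
    list(trials = trials, name = name, recipe = recipe,
         dropped = dropped %||% tibble::tibble(reason = character(0),
                                               n = integer(0))),
    class = "n400_dataset"
  )
}

#' @export
print.n400_dataset <- function(x, ...) {
  cat("<n400_dataset> ", x$name, ": ", nrow(x$trials), " trials, ",
      dplyr::n_distinct(x$trials$subject_id), " subjects, ",
      dplyr::n_distinct(x$trials$item_id), " items\n", sep = "")
  cat("  recipe: ", x$recipe$name, "\n", sep = "")
  if (sum(x$dropped$n) > 0) {
    cat("  dropped during load: ", sum(x$dropped$n), " rows\n", sep = "")
  }
  invisible(x)
}

#' Load trial-level data from a delimited file
#'
#' Reads a CSV/TSV of single-trial N400 records, applies an optional column
#' mapping, drops (and counts) rows missing any required field, and bundles
#' the result with a recipe.
#'
#' @param path File path (delimiter inferred from extension: `.tsv` = tab,
#'   otherwise comma).
#' @param recipe A [preset_recipe()]; determines which columns are required.
#' @param name Dataset label (defaults to the file name).
#' @param schema Optional named character vector mapping package column names
#'   to file column names, e.g. `c(subject_id = "subj", amplitude = "n400")`.
#'
#' @return An [n400_dataset()]; rows dropped for missing values are recorded
#'   in its `dropped` log.
#' @export
load_trials <- function(path, recipe = preset_recipe("lab_random_subject"),
                        name = basename(path), schema = NULL) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(schema)) {
    for (pkg_col in names(schema)) {
      file_col <- schema[[pkg_col]]
      if (!file_col %in% names(raw)) {
        abort(paste0("schema maps '", pkg_col, "' to missing column '",
                     file_col, "'"))
      }
      names(raw)[names(raw) == file_col] <- pkg_col
    }
  }
  required <- c("subject_id", "item_id", "amplitude",
                if (identical(recipe$dv, "baselined_amplitude")) "lab",
                setdiff(recipe$fixed_terms, c("metric", "lab")))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw$subject_id <- as.character(raw$subject_id)
  raw$item_id <- as.character(raw$item_id)
  complete <- stats::complete.cases(raw[required])
  dropped <- tibble::tibble(reason = "missing required field",
                            n = sum(!complete))
  n400_dataset(raw[complete, , drop = FALSE], name = name, recipe = recipe,
               dropped = dropped[dropped$n > 0, ])
}

#' Write trials back to a delimited file
#'
#' Round-trip companion to [load_trials()]: the analyzed field values are
#' reproduced exactly.
#'
#' @param dataset An [n400_dataset()].
#' @param path Output path (`.tsv` for tab-delimited, else CSV).
#' @return `path`, invisibly.
#' @export
write_trials <- function(dataset, path) {
  stopifnot(inherits(dataset, "n400_dataset"))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(dataset$trials, path, delim = delim)
  invisible(path)
}

#' Build a model frame for one metric under a dataset's recipe
#'
#' Joins a metric column onto the trials, z-scores every numeric variable
#' (including, by default, the dependent variable), codes `lab` as a factor,
#' and assembles the mixed-model formula implied by the recipe. Nothing is
#' dropped silently: trials without a metric value are removed with a count.
#'
#' @param dataset An [n400_dataset()].
#' @param metric Either a numeric vector aligned with `dataset$trials`, or a
#'   data frame with columns `item_id` and `value` joined by item.
#' @param scale_dv Z-score the dependent variable (default `TRUE`). Metric
#'   AIC comparisons are invariant to this common affine transform.
#'
#' @return A list of class `lmm_design`: `data` (model frame), `formula`,
#'   `fixed_terms`, `dv`, `n_dropped`.
#' @export
build_design <- function(dataset, metric, scale_dv = TRUE) {
  stopifnot(inherits(dataset, "n400_dataset"))
  recipe <- dataset$recipe
  trials <- dataset$trials

  if (is.data.frame(metric)) {
    stopifnot(all(c("item_id", "value") %in% names(metric)))
    idx <- match(trials$item_id, metric$item_id)
    metric_vec <- metric$value[idx]
  } else {
    stopifnot(is.numeric(metric), length(metric) == nrow(trials))
    metric_vec <- metric
  }
  keep <- is.finite(metric_vec)
  n_dropped <- sum(!keep)
  trials <- trials[keep, , drop = FALSE]
  metric_vec <- metric_vec[keep]
  if (nrow(trials) < 2L) abort("fewer than 2 usable trials")

  dv_col <- "amplitude"
  data <- tibble::tibble(
    response = if (scale_dv) zscore(trials[[dv_col]]) else trials[[dv_col]],
    subject_id = factor(trials$subject_id),
    item_id = factor(trials$item_id)
  )
  for (term in recipe$fixed_terms) {
    if (term == "metric") {
      data$metric <- zscore(metric_vec)
    } else if (term == "lab") {
      if (!"lab" %in% names(trials)) abort("recipe requires a 'lab' column")
      lab <- factor(trials$lab)
      if (nlevels(lab) < 2L) {
        abort("degenerate design: 'lab' has a single level")
      }
      data$lab <- lab
    } else {
      if (!term %in% names(trials)) {
        abort(paste0("recipe requires column '", term, "'"))
      }
      if (any(!is.finite(trials[[term]]))) {
        abort(paste0("non-finite values in covariate '", term, "'"))
      }
      data[[term]] <- zscore(trials[[term]])
    }
  }

  random_parts <- vapply(recipe$random_terms, function(rt) {
    lhs <- paste(c(if (rt$intercept) "1" else "0", rt$slopes), collapse = " + ")
    paste0("(", lhs, " | ", rt$group, ")")
  }, character(1))
  fml <- as.formula(paste(
    "response ~", paste(c(recipe$fixed_terms, random_parts), collapse = " + ")
  ))

  structure(
    list(data = data, formula = fml, fixed_terms = recipe$fixed_terms,
         dv = recipe$dv, n_dropped = n_dropped),
    class = "lmm_design"
  )
}
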