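#' Curated feature tables for 52 FDA-approved therapeutic antibodies
#'
#' Published reference features and clinical immunogenicity labels for the 52
#' humanized and full-human antibodies approved as of April 2018 (bispecifics
#' excluded). The `crystal` table holds the 29 antibodies with crystal
#' structures (CDR cavity volume, CDR-H3 hydrophobic area and CDR-H2-turn
#' glycine count computed from the deposited structures); the `modeled` table
#' holds the 23 antibodies whose features were computed from homology models,
#' plus the originally reported SVM prediction for each. An antibody is
#' labeled non-immunogenic (`label = 0`) when a treatment-emergent
#' anti-antibody response was reported in fewer than 2\% of patients, else
#' immunogenic (`label = 1`).
#'
#' @param source `"crystal"`, `"modeled"`, or `"all"` (both tables stacked).
#' @return An `antibody_dataset` data.frame with columns `antibody`,
#'   `cavity_volume` (NA for modeled rows), `h3_hydrophobic_area`,
#'   `gly_count`, `gly_h2_turn_present`, `label`, `structure_source`, and
#'   `pdb_code` / `reported_prediction` where applicable. Row counts and
#'   label tallies are checked against the published values on every load.
#' @export
load_antibody_features <- function(source = c("crystal", "modeled", "all")) {
  source <- match.arg(source)
  if (source == "all") {
    crystal <- load_antibody_features("crystal")
    modeled <- load_antibody_features("modeled")
    crystal$reported_prediction <- NA_integer_
    modeled$pdb_code <- NA_character_
    modeled$cavity_volume <- NA_real_
    cols <- c("antibody", "pdb_code", "cavity_volume", "h3_hydrophobic_area",
              "gly_count", "gly_h2_turn_present", "label", "structure_source",
              "reported_prediction")
    out <- rbind(crystal[, cols], modeled[, cols])
    rownames(out) <- NULL
    class(out) <- c("antibody_dataset", "data.frame")
    return(out)
  }

  file <- system.file("extdata",
                      paste0("antibody_features_", source, ".csv"),
                      package = "pitha", mustWork = TRUE)
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$structure_source <- source
  df$gly_h2_turn_present <- gly_present(df$gly_count)

  expected <- if (source == "crystal") c(n = 29L, pos = 15L) else c(n = 23L, pos = 13L)
  if (nrow(df) != expected["n"] || sum(df$label == 1) != expected["pos"]) {
    stop("bundled ", source, " table failed its integrity check (",
         nrow(df), " rows, ", sum(df$label == 1), " immunogenic)",
         call. = FALSE)
  }
  class(df) <- c("antibody_dataset", "data.frame")
  df
}

#' Group means and t-test for a feature
#'
#' Arithmetic means of a feature by immunogenicity label, with a two-sample
#' Student's t-test (pooled variance by default) for the group difference.
#'
#' @param dataset An `antibody_dataset` (or any data.frame with `label`).
#' @param feature Feature column name.
#' @param var_equal Pooled-variance t-test when `TRUE` (default); Welch
#'   otherwise.
#' @return List with `mean_immunogenic`, `mean_non_immunogenic` (rounded to
#'   integers as conventionally printed, with unrounded values in
#'   `mean_immunogenic_raw` / `mean_non_immunogenic_raw`), group sizes, and
#'   `p_value`.
#' @export
feature_summary <- function(dataset, feature, var_equal = TRUE) {
  x <- dataset[[feature]]
  if (is.null(x)) stop("no such feature: ", feature, call. = FALSE)
  pos <- x[dataset$label == 1]
  neg <- x[dataset$label == 0]
  if (!length(pos) || !length(neg)) stop("empty group", call. = FALSE)
  tt <- stats::t.test(pos, neg, var.equal = var_equal)
  list(mean_immunogenic = round(mean(pos)),
       mean_non_immunogenic = round(mean(neg)),
       mean_immunogenic_raw = mean(pos),
       mean_non_immunogenic_raw = mean(neg),
       n_immunogenic = length(pos),
       n_non_immunogenic = length(neg),
       p_value = tt$p.value)
}

#' Census of glycine-free CDR-H2 turns
#'
#' Across a labeled feature table, counts antibodies whose CDR-H2 beta-turn
#' contains no glycine and how many of those are immunogenic. Glycine-free
#' turns are a strong immunogenicity flag.
#'
#' @param dataset An `antibody_dataset` with `gly_count` and `label`.
#' @return List with `n_zero_gly` and `n_zero_gly_immunogenic`.
#' @export
gly_census <- function(dataset) {
  zero <- dataset$gly_count == 0
  list(n_zero_gly = sum(zero),
       n_zero_gly_immunogenic = sum(zero & dataset$label == 1))
}

# Published headline values the reproduce command prints next to the
# recomputed ones.
published_values <- function() {
  list(
    "loo-crystal-2feat" = c(accuracy = 83),
    "loo-crystal-3feat" = c(accuracy = 76),
    "loo-crystal-h3gly" = c(accuracy = 79),
    "test-modeled" = c(accuracy = 65),
    "loo-modeled" = c(accuracy = 78),
    "summary-stats" = c(cavity_mean_immunogenic = 361,
                        cavity_mean_non_immunogenic = 798,
                        h3_modeled_mean_immunogenic = 356,
                        h3_modeled_mean_non_immunogenic = 432),
    "gly-census" = c(n_zero_gly = 7, n_zero_gly_immunogenic = 6)
  )
}

#' Re-run a published classification or statistics experiment
#'
#' Recomputes one of the headline results from the bundled feature tables and
#' returns it alongside the originally published value.
#'
#' @param experiment One of `"loo-crystal-2feat"` (LOO on the 29
#'   crystal-structure antibodies, cavity + H3 area), `"loo-crystal-3feat"`
#'   (plus binary glycine), `"loo-crystal-h3gly"` (H3 area + glycine),
#'   `"test-modeled"` (train on the 29, test on the 23 modeled),
#'   `"loo-modeled"` (LOO on the 23), `"summary-stats"` (group means), or
#'   `"gly-census"`.
#' @return List with `experiment`, `computed` (named numeric), and
#'   `published` (named numeric).
#' @export
reproduce_experiment <- function(experiment) {
  valid <- names(published_values())
  if (!experiment %in% valid) {
    stop("unknown experiment '", experiment, "'; valid: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  crystal <- load_antibody_features("crystal")
  modeled <- load_antibody_features("modeled")

  computed <- switch(
    experiment,
    "loo-crystal-2feat" = {
      r <- loo_accuracy(crystal, features = c("cavity_volume",
                                              "h3_hydrophobic_area"))
      c(accuracy = r$accuracy, n_correct = r$n_correct, n = r$n)
    },
    "loo-crystal-3feat" = {
      r <- loo_accuracy(crystal, features = c("cavity_volume",
                                              "h3_hydrophobic_area",
                                              "gly_h2_turn_present"))
      c(accuracy = r$accuracy, n_correct = r$n_correct, n = r$n)
    },
    "loo-crystal-h3gly" = {
      r <- loo_accuracy(crystal, variant = "modeled")
      c(accuracy = r$accuracy, n_correct = r$n_correct, n = r$n)
    },
    "test-modeled" = {
      model <- train_svm(crystal, variant = "modeled")
      pred <- predict(model, modeled)
      c(accuracy = prediction_accuracy(pred, modeled$label),
        n_correct = sum(pred == modeled$label), n = nrow(modeled))
    },
    "loo-modeled" = {
      r <- loo_accuracy(modeled, variant = "modeled")
      c(accuracy = r$accuracy, n_correct = r$n_correct, n = r$n)
    },
    "summary-stats" = {
      cav <- feature_summary(crystal, "cavity_volume")
      h3m <- feature_summary(modeled, "h3_hydrophobic_area")
      c(cavity_mean_immunogenic = cav$mean_immunogenic,
        cavity_mean_non_immunogenic = cav$mean_non_immunogenic,
        cavity_p_value = cav$p_value,
        h3_modeled_mean_immunogenic = h3m$mean_immunogenic,
        h3_modeled_mean_non_immunogenic = h3m$mean_non_immunogenic)
    },
    "gly-census" = {
      cen <- gly_census(load_antibody_features("all"))
      c(n_zero_gly = cen$n_zero_gly,
        n_zero_gly_immunogenic = cen$n_zero_gly_immunogenic)
    }
  )
  list(experiment = experiment, computed = computed,
       published = published_values()[[experiment]])
}
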