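# Per-subject design matrix: 19 channels x 4 bands complexity features for
# one estimator, plus the encoded clinical covariates.

.CLINICAL_BINARY <- c(sex = "M", comorbidity = "Y", inducement = "Y",
                      perinatal_injury = "Y", physical_development = "AN",
                      family_history = "Y", mri = "P", tle = "Y",
                      cns_infection = "Y", head_injury = "Y")
.CLINICAL_QUANT <- c("age", "age_at_onset", "follow_up",
                     "seizure_freq_before_oxc")
.CIRCADIAN_LEVELS <- c("day", "night", "both")

# Encode the clinical table numerically with a fixed column order: binary
# fields 0/1 (1 = the level named in .CLINICAL_BINARY), the 3-level circadian
# rhythm one-hot, quantitative fields passed through.
encode_clinical <- function(clinical, drop_follow_up = FALSE) {
  need <- c(names(.CLINICAL_BINARY), .CLINICAL_QUANT, "circadian_rhythm")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table is missing fields: ", paste(missing, collapse = ", "))
  quant <- setdiff(.CLINICAL_QUANT, if (drop_follow_up) "follow_up" else NULL)
  cols <- lapply(quant, function(f) as.numeric(clinical[[f]]))
  names(cols) <- quant
  for (f in names(.CLINICAL_BINARY))
    cols[[f]] <- as.numeric(clinical[[f]] == .CLINICAL_BINARY[[f]])
  for (lv in .CIRCADIAN_LEVELS)
    cols[[paste0("circadian_", lv)]] <-
      as.numeric(clinical$circadian_rhythm == lv)
  m <- do.call(cbind, cols)
  rownames(m) <- clinical$subject_id
  m
}

#' Assemble the per-subject feature matrix
#'
#' Combines the band-wise complexity features of one estimator (all
#' channel-band pairs, named `"<band>-<channel>"`, e.g. `"theta-T3"`) with
#' the encoded clinical covariates into a subjects x features matrix with a
#' class label per subject. Rows are aligned by `subject_id`, so the result
#' is invariant to the input row order. Column order is deterministic:
#' complexity features band-major in band/channel order, then clinical
#' columns in a fixed order.
#'
#' @param complexity_features data frame with columns `subject_id`,
#'   `channel`, `band`, `estimator`, `value` (as produced by
#'   [extract_complexity_features()]).
#' @param clinical clinical table with `subject_id`, `label`, and the 15
#'   clinical features.
#' @param estimator which complexity estimator to use: `"lzc"` or `"kc"`.
#' @param channels,bands expected channel and band grids (defaults: the
#'   19-channel montage and the four clinical bands).
#' @param drop_follow_up if `TRUE`, exclude the post-treatment follow-up time
#'   from the predictors.
#' @return An object of class `feature_matrix`: list with `values`
#'   (numeric matrix), `subject_ids`, `feature_names`, `labels`
#'   (factor with levels NSF, SF).
#' @export
assemble_features <- function(complexity_features, clinical,
                              estimator = c("lzc", "kc"),
                              channels = default_channels(),
                              bands = default_bands()$name,
                              drop_follow_up = FALSE) {
  estimator <- match.arg(estimator)
  cf <- complexity_features[complexity_features$estimator == estimator, ]
  ids <- sort(union(unique(clinical$subject_id), unique(cf$subject_id)))
  cf_names <- as.vector(t(outer(bands, channels, paste, sep = "-")))
  wide <- matrix(NA_real_, nrow = length(ids), ncol = length(cf_names),
                 dimnames = list(ids, cf_names))
  key <- paste(cf$band, cf$channel, sep = "-")
  ok <- cf$subject_id %in% ids & key %in% cf_names
  wide[cbind(match(cf$subject_id[ok], ids), match(key[ok], cf_names))] <-
    cf$value[ok]
  if (anyNA(wide)) {
    bad <- which(is.na(wide), arr.ind = TRUE)
    stop("missing complexity values, e.g. subject ", ids[bad[1, 1]],
         " feature ", cf_names[bad[1, 2]])
  }
  clin <- clinical[match(ids, clinical$subject_id), ]
  if (anyNA(clin$subject_id))
    stop("clinical table is missing subjects: ",
         paste(setdiff(ids, clinical$subject_id), collapse = ", "))
  enc <- encode_clinical(clin, drop_follow_up = drop_follow_up)
  values <- cbind(wide, enc)
  structure(list(values = values, subject_ids = ids,
                 feature_names = colnames(values),
                 labels = factor(clin$label, levels = c("NSF", "SF")),
                 estimator = estimator),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects x %d features (%s), %d SF / %d NSF\n",
              nrow(x$values), ncol(x$values), x$estimator,
              sum(x$labels == "SF"), sum(x$labels == "NSF")))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has one row per subject: `subject_id`, `label`, then one column
#' per feature. Reading back reproduces the matrix exactly (values are
#' written at full precision).
#'
#' @param fm a [assemble_features()] result.
#' @param path CSV file path.
#' @return `write_feature_matrix`: `path` invisibly;
#'   `read_feature_matrix`: a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  vals <- apply(fm$values, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(subject_id = fm$subject_ids, label = as.character(fm$labels),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, setdiff(names(df), c("subject_id", "label")),
                        drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(values = values, subject_ids = df$subject_id,
                 feature_names = colnames(values),
                 labels = factor(df$label, levels = c("NSF", "SF")),
                 estimator = NA_character_),
            class = "feature_matrix")
}
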