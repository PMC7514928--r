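# File formats: rank-matrix tables, long-format sample batches, consensus
# reports.  TSV is the canonical dialect (UTF-8, header row); CSV is accepted
# on read, chosen by extension or forced with `delim`.

#' @noRd
pick_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a rank matrix from a delimited file
#'
#' Expected layout: a header row naming the classifiers, a first column of
#' class labels, and one integer column per classifier.  Every column must
#' be a permutation of `1..K`; violations are reported with the offending
#' column (and the duplicated / missing rank values).
#'
#' @param path file path; `.csv` selects comma separation, anything else tab.
#' @param delim optional explicit field separator overriding the extension.
#' @return a [rank_matrix()].
#' @examples
#' path <- system.file("extdata", "mnist_digit_ranks.tsv", package = "rankfuse")
#' read_rank_matrix(path)
#' @export
read_rank_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) rf_validation_error(paste0("file not found: ", path))
  delim <- pick_delim(path, delim)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) rf_validation_error("expected a class-label column plus at least one classifier column")
  labels <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  num <- matrix(num, nrow = nrow(body))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    rf_validation_error(sprintf(
      "non-integer cell at row %d, column '%s'",
      bad[1L, 1L], colnames(body)[bad[1L, 2L]]))
  }
  rank_matrix(num, class_labels = labels, classifier_labels = colnames(body))
}

#' Write a rank matrix to a delimited file
#'
#' Inverse of [read_rank_matrix()]; the write-then-read round trip is the
#' identity.
#'
#' @param R a [rank_matrix()].
#' @param path output path; `.csv` selects comma separation.
#' @param delim optional explicit field separator.
#' @return `path`, invisibly.
#' @export
write_rank_matrix <- function(R, path, delim = NULL) {
  R <- as_rank_matrix(R)
  delim <- pick_delim(path, delim)
  df <- data.frame(class = rownames(R), unclass(R), check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a consensus report (TSV + JSON sidecar)
#'
#' Writes a table with one row per class and one consensus-rank column per
#' metric, plus a JSON sidecar (`<path>.json`) recording objectives, optimum
#' counts, tie-break flags, conjunction coefficients with their attainable
#' bounds, the package version and the seed, so a run can be reproduced and
#' audited.
#'
#' @param R the input [rank_matrix()].
#' @param results a named list of `consensus_result` objects (names are the
#'   metrics).
#' @param path output TSV path.
#' @param seed optional seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_consensus_report <- function(R, results, path, seed = NULL) {
  R <- as_rank_matrix(R)
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  df <- data.frame(class = rownames(R), check.names = FALSE)
  for (nm in names(results)) df[[paste0("rank_", nm)]] <- unname(results[[nm]]$ranks)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    input = list(K = nrow(R), M = ncol(R),
                 classes = rownames(R), classifiers = colnames(R)),
    metrics = lapply(results, function(res) {
      co <- if (ncol(R) >= 2L) {
        rep <- if (res$metric == "condorcet") conjunction_condorcet(R)
               else conjunction_disagreement(R)
        list(coefficient = rep$coefficient,
             lower_bound = rep$lower_bound, upper_bound = rep$upper_bound)
      } else NULL
      list(objective = res$objective,
           optimum_count_hint = res$optimum_count_hint,
           tiebreak_applied = res$tiebreak_applied,
           concordance = co)
    }),
    seed = seed,
    package_version = as.character(utils::packageVersion("rankfuse")))
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a sample batch in long format
#'
#' One row per (sample, class, classifier) triple with the assigned rank;
#' optional companion labels file with one row per sample.
#'
#' @param batch a [sample_batch()].
#' @param path output TSV path for the rank table.
#' @param labels_path optional output TSV path for `(sample_id, true_class)`.
#' @return `path`, invisibly.
#' @export
write_sample_batch <- function(batch, path, labels_path = NULL) {
  stopifnot(inherits(batch, "sample_batch"))
  long <- expand.grid(class = seq_len(batch$K), classifier = seq_len(batch$M),
                      sample_id = seq_len(batch$n))
  long <- long[, c("sample_id", "class", "classifier")]
  long$rank <- as.vector(batch$ranks)
  long$class <- batch$class_labels[long$class]
  long$classifier <- batch$classifier_labels[long$classifier]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path) && !is.null(batch$true_labels)) {
    lab <- data.frame(sample_id = seq_len(batch$n),
                      true_class = batch$class_labels[batch$true_labels])
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample batch from a long-format file
#'
#' @param path TSV/CSV with columns `sample_id`, `class`, `classifier`,
#'   `rank`.
#' @param labels_path optional TSV/CSV with columns `sample_id`,
#'   `true_class`.
#' @param positive_class optional positive class label (resolved against the
#'   class labels found in the file).
#' @param delim optional explicit field separator.
#' @return a [sample_batch()].
#' @export
read_sample_batch <- function(path, labels_path = NULL, positive_class = NULL,
                              delim = NULL) {
  if (!file.exists(path)) rf_validation_error(paste0("file not found: ", path))
  df <- utils::read.table(path, sep = pick_delim(path, delim), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "classifier", "rank")
  if (!all(need %in% colnames(df))) {
    rf_validation_error(paste0("batch file must have columns: ",
                               paste(need, collapse = ", ")))
  }
  samples <- sort(unique(df$sample_id))
  classes <- sort(unique(df$class))
  classifiers <- sort(unique(df$classifier))
  K <- length(classes); M <- length(classifiers); n <- length(samples)
  tensor <- array(NA_integer_, dim = c(K, M, n))
  ci <- match(df$class, classes)
  ki <- match(df$classifier, classifiers)
  si <- match(df$sample_id, samples)
  tensor[cbind(ci, ki, si)] <- as.integer(df$rank)
  if (anyNA(tensor)) {
    miss <- which(is.na(tensor), arr.ind = TRUE)[1L, ]
    rf_validation_error(sprintf(
      "missing rank for sample '%s', class '%s', classifier '%s'",
      samples[miss[3L]], classes[miss[1L]], classifiers[miss[2L]]))
  }
  truth <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.table(labels_path, sep = pick_delim(labels_path, delim),
                             header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!all(c("sample_id", "true_class") %in% colnames(lab))) {
      rf_validation_error("labels file must have columns: sample_id, true_class")
    }
    truth <- match(lab$true_class[match(samples, lab$sample_id)], classes)
  }
  pos <- if (!is.null(positive_class)) {
    p <- match(as.character(positive_class), as.character(classes))
    if (is.na(p)) rf_validation_error(paste0("positive class not found: ", positive_class))
    p
  } else NULL
  sample_batch(tensor, true_labels = truth, positive_class = pos,
               class_labels = as.character(classes),
               classifier_labels = as.character(classifiers))
}
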