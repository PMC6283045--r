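#' Construct a participant-level IPD meta-analysis dataset
#'
#' Validates and packages individual participant data (IPD) from `K`
#' randomized trials for one-stage meta-analysis of a continuous outcome.
#' Each record carries a trial label, a 0/1 treatment indicator, a continuous
#' final (end-of-trial) outcome and, optionally, a continuous baseline value
#' of the same outcome.
#'
#' Trial labels are mapped to contiguous indices `1..K` in order of first
#' appearance; all model output referring to trial-specific terms uses the
#' original labels.
#'
#' @param data data frame holding one row per participant.
#' @param trial name of the trial identifier column.
#' @param treat name of the 0/1 treatment indicator column.
#' @param outcome name of the continuous final outcome column.
#' @param baseline optional name of the continuous baseline outcome column;
#'   when supplied it must be observed for every participant.
#' @param require_both_arms if `TRUE` (default), every trial must contain at
#'   least one treated and one control participant, as required whenever a
#'   treatment effect is to be estimated.
#'
#' @return An object of class `ipd_data`: a data frame with standardized
#'   columns `trial` (factor, levels in first-appearance order), `treat`
#'   (integer 0/1), `yf` (double) and optionally `yb` (double), plus
#'   attributes `K` (number of trials) and `n_i` (named vector of per-trial
#'   sizes).
#'
#' @examples
#' d <- data.frame(trial = rep(c("a", "b"), each = 4),
#'                 treat = rep(c(0, 1), 4),
#'                 yf = rnorm(8, 160, 18))
#' ipd <- ipd_dataset(d)
#' attr(ipd, "K")
#' @seealso [read_ipd()], [build_design()], [fit_onestage()]
#' @export
ipd_dataset <- function(data, trial = "trial", treat = "treat", outcome = "yf",
                        baseline = NULL, require_both_arms = TRUE) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  needed <- c(trial, treat, outcome, baseline)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("configuration error: column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  tr_raw <- data[[trial]]
  if (anyNA(tr_raw)) stop("data error: missing trial identifier", call. = FALSE)
  labels <- as.character(unique(tr_raw))   # first-appearance order
  trial_f <- factor(as.character(tr_raw), levels = labels)

  tv <- data[[treat]]
  bad_treat <- which(!(tv %in% c(0, 1)) | is.na(tv))
  if (length(bad_treat) > 0L) {
    stop("data error: non-binary treatment value in row(s) ",
         paste(utils::head(bad_treat, 5L), collapse = ", "), call. = FALSE)
  }

  yv <- data[[outcome]]
  if (!is.numeric(yv)) stop("data error: outcome column is not numeric",
                            call. = FALSE)
  bad_y <- which(!is.finite(yv))
  if (length(bad_y) > 0L) {
    stop("data error: missing or non-finite outcome in row(s) ",
         paste(utils::head(bad_y, 5L), collapse = ", "), call. = FALSE)
  }

  out <- data.frame(trial = trial_f, treat = as.integer(tv),
                    yf = as.double(yv))

  if (!is.null(baseline)) {
    bv <- data[[baseline]]
    if (!is.numeric(bv)) stop("data error: baseline column is not numeric",
                              call. = FALSE)
    if (anyNA(bv) || any(!is.finite(bv))) {
      stop("data error: baseline outcome must be present (and finite) for ",
           "all participants or omitted entirely", call. = FALSE)
    }
    out$yb <- as.double(bv)
  }

  n_i <- table(out$trial)
  if (any(n_i < 2L)) {
    stop("validation error: trial(s) with fewer than 2 participants: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "), call. = FALSE)
  }
  if (require_both_arms) {
    arm_tab <- table(out$trial, out$treat)
    single <- rownames(arm_tab)[arm_tab[, "0"] == 0L | arm_tab[, "1"] == 0L]
    if (length(single) > 0L) {
      stop("validation error: trial(s) with a single arm: ",
           paste(single, collapse = ", "), call. = FALSE)
    }
  }

  structure(out,
            K = length(labels),
            n_i = stats::setNames(as.integer(n_i), labels),
            class = c("ipd_data", "data.frame"))
}

#' Read an IPD meta-analysis dataset from a delimited text file
#'
#' Thin wrapper around [utils::read.csv()] followed by [ipd_dataset()]
#' validation.  The file must have a header row.
#'
#' @param path path to a comma-delimited text file.
#' @param trial_col,treat_col,outcome_col,baseline_col column names in the
#'   file; `baseline_col = NULL` (default) means no baseline outcome.
#' @param sep field separator, `","` by default.
#' @inheritParams ipd_dataset
#' @return An [ipd_dataset()] object.
#' @export
read_ipd <- function(path, trial_col = "trial", treat_col = "treat",
                     outcome_col = "yf", baseline_col = NULL, sep = ",",
                     require_both_arms = TRUE) {
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  ipd_dataset(raw, trial = trial_col, treat = treat_col,
              outcome = outcome_col, baseline = baseline_col,
              require_both_arms = require_both_arms)
}

#' Write an IPD dataset to a comma-delimited file
#'
#' Inverse of [read_ipd()]: writing and re-reading reproduces the records.
#'
#' @param x an `ipd_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ipd <- function(x, path) {
  stopifnot(inherits(x, "ipd_data"))
  df <- as.data.frame(x)
  df$trial <- as.character(df$trial)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ipd_data <- function(x, ...) {
  n_i <- attr(x, "n_i")
  cat("IPD meta-analysis dataset: ", attr(x, "K"), " trials, ",
      nrow(x), " participants\n", sep = "")
  cat("  baseline outcome: ", if ("yb" %in% names(x)) "present" else "absent",
      "\n", sep = "")
  cat("  participants per trial: ")
  if (length(unique(n_i)) == 1L) {
    cat(unique(n_i), "(all trials)\n")
  } else {
    cat("min", min(n_i), "/ median", stats::median(n_i), "/ max", max(n_i), "\n")
  }
  invisible(x)
}
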