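#' Read and write trial logs
#'
#' Trial logs are UTF-8 comma-delimited text with the header
#' \code{participant,item,onset_s,kind,correct,rt_s}, one row per trial.
#' Reading validates every row (kind must be \code{study} or \code{test},
#' response times positive, onsets strictly increasing within participant)
#' and reports the first offending line; a write followed by a read
#' round-trips the records exactly.
#'
#' @param path File path.
#' @return \code{read_trial_log}: a validated data frame of trial records.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  want <- c("participant", "item", "onset_s", "kind", "correct", "rt_s")
  if (!identical(names(df), want))
    stop("trial log header must be exactly: ", paste(want, collapse = ","))
  if (nrow(df) == 0L) {
    df$participant <- character(0); df$item <- character(0)
    return(df)
  }
  df$participant <- as.character(df$participant)
  df$item <- as.character(df$item)
  df$correct <- as.logical(df$correct)
  bad_kind <- which(!df$kind %in% c("study", "test"))
  if (length(bad_kind))
    stop("invalid trial kind at line ", bad_kind[1] + 1L, ": ",
         df$kind[bad_kind[1]])
  bad_rt <- which(!is.finite(df$rt_s) | df$rt_s <= 0)
  if (length(bad_rt)) stop("non-positive rt_s at line ", bad_rt[1] + 1L)
  if (anyNA(df$correct)) stop("unparseable correct flag at line ",
                              which(is.na(df$correct))[1] + 1L)
  for (p in unique(df$participant)) {
    on <- df$onset_s[df$participant == p]
    if (length(on) > 1L && any(diff(on) <= 0))
      stop("onsets not strictly increasing for participant ", p)
  }
  df
}

#' @rdname read_trial_log
#' @param records Trial-record data frame (see \code{\link{run_session}}).
#' @export
write_trial_log <- function(records, path) {
  want <- c("participant", "item", "onset_s", "kind", "correct", "rt_s")
  stopifnot(identical(names(records), want))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write connectivity matrices
#'
#' Delimited text with network names as both header row and first column.
#'
#' @param m A \code{connectivity_matrix}.
#' @param path File path.
#' @export
write_connectivity_matrix <- function(m, path) {
  df <- data.frame(network = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_matrix
#' @param kind Matrix kind (\code{"pearson"} or \code{"partial"}).
#' @export
read_connectivity_matrix <- function(path, kind = "partial") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m <- (m + t(m)) / 2   # absorb text round-off below 1e-12
  connectivity_matrix(m, kind)
}

#' Read and write ROI time-series matrices
#'
#' Delimited text, one row per volume, header = network names.
#'
#' @param ts Numeric matrix volumes x networks.
#' @param path File path.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  as.matrix(utils::read.csv(path, check.names = FALSE))
}

#' Run the complete analysis pipeline on a synthetic cohort
#'
#' Binds the stages end to end: simulate behavioral sessions, estimate each
#' participant's speed of forgetting, simulate ROI time series with the
#' planted connectivity signal, compute partial-correlation connectomes and
#' the DMN-anchored features, fit the cross-validated lasso with held-out
#' validation, optionally run the permutation null, and summarize network
#' importance. Every intermediate table is written to \code{out_dir} as
#' delimited text; a single master seed (the spec's) governs all
#' randomness.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param config A \code{\link{scheduler_config}}.
#' @param params A \code{\link{model_params}}.
#' @param out_dir Output directory (created if missing); NULL writes
#'   nothing.
#' @param n_permutations Permutation count for the null calibration; 0
#'   skips the permutation stage. Default 0.
#' @return List with \code{truth}, \code{phenotypes}, \code{features},
#'   \code{report} (\code{lasso_report}), \code{importance},
#'   \code{storage_test}, \code{sign_adjusted}, and \code{permutation}
#'   (NULL when skipped).
#' @export
run_full_pipeline <- function(spec = cohort_spec(),
                              config = scheduler_config(),
                              params = model_params(), out_dir = NULL,
                              n_permutations = 0L) {
  beh <- simulate_cohort_behavior(spec, config, params)
  pheno <- cohort_phenotypes(beh)
  tss <- simulate_cohort_timeseries(spec, beh$truth)
  mats <- lapply(tss, partial_connectome)
  X <- feature_matrix(mats)
  y <- pheno$sof[match(rownames(X), pheno$participant)]
  report <- final_fit_and_report(X, y)
  gavg <- fisher_group_average(mats)
  sel <- report$beta[report$beta != 0]
  imp <- node_importance(sel)
  st <- storage_retrieval_test(imp)
  sgn <- if (length(sel)) sign_adjusted_weights(sel, gavg) else NULL
  perm <- if (n_permutations > 0)
    permutation_test(X, y, n_shuffles = n_permutations,
                     seed = spec$seed + 2L) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_log(beh$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(beh$truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    utils::write.csv(pheno, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(participant = rownames(X), X,
                                check.names = FALSE),
                     file.path(out_dir, "features.csv"), row.names = FALSE)
    write_connectivity_matrix(gavg, file.path(out_dir,
                                              "group_partial_connectome.csv"))
    utils::write.csv(data.frame(feature = names(report$beta),
                                beta = unname(report$beta)),
                     file.path(out_dir, "lasso_betas.csv"), row.names = FALSE)
    utils::write.csv(imp, file.path(out_dir, "node_importance.csv"),
                     row.names = FALSE)
  }
  list(truth = beh$truth, phenotypes = pheno, features = X, report = report,
       importance = imp, storage_test = st, sign_adjusted = sgn,
       permutation = perm)
}
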