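#' Read a network parcellation from a (name, group) table
#'
#' @param path CSV file with columns \code{network} and \code{group}
#'   (\code{DMN}, \code{Storage} or \code{Retrieval}); row order defines the
#'   canonical network order.
#' @return An object of class \code{parcellation}: \code{networks} (ordered
#'   names) and \code{group} (named character vector).
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("network", "group") %in% names(df)))
  if (anyDuplicated(df$network)) stop("duplicated network names")
  bad <- setdiff(unique(df$group), c("DMN", "Storage", "Retrieval"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  structure(list(networks = df$network,
                 group = stats::setNames(df$group, df$network)),
            class = "parcellation")
}

#' The 17-network cortical parcellation with memory-group assignments
#'
#' The package's shipped default: the 17 resting-state networks of the Yeo
#' parcellation, each assigned to one of three functional groups -- the
#' Default Mode Network (Default A/B/C), a Retrieval group of six
#' frontoparietal-control networks (Control A/B, Dorsal Attention A,
#' Salience B, Limbic B, Temporal Parietal), and a Storage group of eight
#' sensory/consolidation networks (Visual A/B, Somatomotor A/B, Dorsal
#' Attention B, Salience A, Limbic A, Control C).
#'
#' @return A \code{parcellation} object.
#' @examples
#' p <- yeo17_parcellation()
#' table(p$group)
#' @export
yeo17_parcellation <- function() {
  read_parcellation(system.file("extdata", "yeo17_parcellation.csv",
                                package = "sofcpm", mustWork = TRUE))
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d networks (DMN=%d, Storage=%d, Retrieval=%d)\n",
              length(x$networks), sum(x$group == "DMN"),
              sum(x$group == "Storage"), sum(x$group == "Retrieval")))
  invisible(x)
}

#' Construct a validated connectivity matrix
#'
#' @param values Square symmetric numeric matrix with network names as
#'   dimnames; off-diagonals in [-1, 1], diagonal 1 by convention.
#' @param kind \code{"pearson"} or \code{"partial"}.
#' @return An object of class \code{connectivity_matrix} (a matrix with
#'   attributes).
#' @export
connectivity_matrix <- function(values, kind = c("pearson", "partial")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)))
  if (max(abs(values - t(values))) > 1e-12) stop("matrix is not symmetric")
  off <- values[row(values) != col(values)]
  if (any(off < -1 - 1e-12 | off > 1 + 1e-12))
    stop("off-diagonal values outside [-1, 1]")
  diag(values) <- 1
  structure(values, kind = kind, class = c("connectivity_matrix", "matrix"))
}

check_ts <- function(ts) {
  stopifnot(is.matrix(ts), !is.null(colnames(ts)))
  v <- apply(ts, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance time series for network(s): ",
         paste(colnames(ts)[v == 0], collapse = ", "))
}

#' Pearson-correlation connectome
#'
#' Product-moment correlation between every pair of network time series.
#'
#' @param ts Numeric matrix, volumes x networks, with network names as
#'   column names; at least 3 volumes and no constant column.
#' @return A \code{connectivity_matrix} of kind \code{"pearson"}.
#' @export
pearson_connectome <- function(ts) {
  stopifnot(nrow(ts) >= 3L)
  check_ts(ts)
  r <- stats::cor(ts)
  r <- (r + t(r)) / 2
  connectivity_matrix(r, "pearson")
}

#' Partial-correlation connectome
#'
#' For each pair of networks, the correlation remaining after the other 15
#' network time series are partialled out of both. Computed in one pass from
#' the inverse covariance: \eqn{\rho_{ij} = -\Omega_{ij} /
#' \sqrt{\Omega_{ii}\Omega_{jj}}}. A near-singular covariance falls back to
#' a ridge-regularized inverse (ridge = 1e-6 times the mean diagonal) with a
#' warning.
#'
#' @param ts Numeric matrix, volumes x networks (more volumes than networks
#'   plus one), with network names as column names.
#' @return A \code{connectivity_matrix} of kind \code{"partial"}.
#' @export
partial_connectome <- function(ts) {
  stopifnot(nrow(ts) > ncol(ts) + 1L)
  check_ts(ts)
  S <- stats::cov(ts)
  Om <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(Om) || !all(is.finite(Om))) {
    warning("singular covariance: using ridge-regularized inverse")
    Om <- solve(S + diag(1e-6 * mean(diag(S)), ncol(S)))
  }
  d <- sqrt(diag(Om))
  rho <- -Om / tcrossprod(d)
  diag(rho) <- 1
  rho <- (rho + t(rho)) / 2
  dimnames(rho) <- dimnames(S)
  connectivity_matrix(rho, "partial")
}

#' Fisher-z group average of connectivity matrices
#'
#' Each coefficient is transformed to a z-value with Fisher's r-to-z
#' (atanh), z-values are averaged across participants, and the mean is
#' transformed back (tanh). Coefficients at exactly +/-1 are clipped to
#' 1 - 1e-7 in magnitude with a warning.
#'
#' @param matrices List of \code{connectivity_matrix} objects of the same
#'   kind over the same networks.
#' @return The group-average \code{connectivity_matrix}.
#' @export
fisher_group_average <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  kind <- attr(matrices[[1]], "kind")
  nms <- rownames(matrices[[1]])
  zs <- lapply(matrices, function(m) {
    stopifnot(identical(attr(m, "kind"), kind), identical(rownames(m), nms))
    r <- unclass(m)
    if (any(abs(r[row(r) != col(r)]) >= 1)) {
      warning("|r| = 1 clipped before Fisher transform")
      r[] <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    }
    atanh(r)
  })
  zbar <- Reduce(`+`, zs) / length(zs)
  avg <- tanh(zbar)
  diag(avg) <- 1
  connectivity_matrix(avg, kind)
}

#' Canonical DMN-anchored edge features
#'
#' The edge list behind the 45-dimensional feature vector: the 3 within-DMN
#' pairs (Default A-B, A-C, B-C) followed by each DMN subnetwork's
#' connections to the 14 non-DMN networks in parcellation order
#' (3 x 14 + 3 = 45).
#'
#' @param parcellation A \code{parcellation}; default
#'   \code{\link{yeo17_parcellation}}.
#' @return Data frame with columns \code{feature}, \code{network_a},
#'   \code{network_b}.
#' @export
feature_edges <- function(parcellation = yeo17_parcellation()) {
  dmn <- parcellation$networks[parcellation$group == "DMN"]
  other <- parcellation$networks[parcellation$group != "DMN"]
  a <- c(dmn[1], dmn[1], dmn[2],
         rep(dmn, each = length(other)))
  b <- c(dmn[2], dmn[3], dmn[3], rep(other, times = length(dmn)))
  data.frame(feature = paste(a, b, sep = "--"),
             network_a = a, network_b = b, stringsAsFactors = FALSE)
}

#' Extract the DMN-anchored feature vector from a connectome
#'
#' @param matrix A \code{connectivity_matrix} whose networks match the
#'   parcellation.
#' @param parcellation A \code{parcellation}.
#' @return Named numeric vector of length 45 in canonical feature order.
#' @export
extract_features <- function(matrix, parcellation = yeo17_parcellation()) {
  if (!setequal(rownames(matrix), parcellation$networks))
    stop("matrix networks do not match the parcellation")
  ed <- feature_edges(parcellation)
  stats::setNames(
    unclass(matrix)[cbind(ed$network_a, ed$network_b)], ed$feature)
}

#' Stack per-participant connectomes into a feature matrix
#'
#' @param matrices Named list of \code{connectivity_matrix} objects (names =
#'   participants).
#' @param parcellation A \code{parcellation}.
#' @return Numeric matrix, participants x features, canonical column order.
#' @export
feature_matrix <- function(matrices, parcellation = yeo17_parcellation()) {
  X <- t(vapply(matrices, extract_features,
                numeric(nrow(feature_edges(parcellation))),
                parcellation = parcellation))
  rownames(X) <- names(matrices)
  X
}
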