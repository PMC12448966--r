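#' Eight-edge reference weight set
#'
#' The package's worked-example weight table: eight DMN-anchored network
#' connections with their regression weights, shipped as plain text under
#' \code{inst/extdata}. Used throughout the documentation and acceptance
#' checks to exercise the network-importance summaries on a fixed input.
#'
#' @return Data frame with columns \code{network_a}, \code{network_b},
#'   \code{beta}.
#' @examples
#' w <- example_edge_weights()
#' node_importance(w)
#' @export
example_edge_weights <- function() {
  utils::read.csv(system.file("extdata", "dmn_edge_weights.csv",
                              package = "sofcpm", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

# Normalize betas to an edge table (network_a, network_b, beta), accepting
# either that data frame or a named vector keyed "A--B" in feature order.
as_edge_table <- function(betas, parcellation) {
  if (is.data.frame(betas)) {
    stopifnot(all(c("network_a", "network_b", "beta") %in% names(betas)))
    ed <- betas[, c("network_a", "network_b", "beta")]
  } else {
    stopifnot(!is.null(names(betas)))
    parts <- strsplit(names(betas), "--", fixed = TRUE)
    ed <- data.frame(network_a = vapply(parts, `[`, "", 1L),
                     network_b = vapply(parts, `[`, "", 2L),
                     beta = as.numeric(betas), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(c(ed$network_a, ed$network_b), parcellation$networks)
  if (length(unknown))
    stop("unknown network name(s): ", paste(unknown, collapse = ", "))
  ed
}

#' Node importance of the selected model
#'
#' A network's importance is the L1 norm of the selected regression weights
#' on edges incident to it; every edge contributes its absolute weight to
#' both endpoints, and networks touching no selected edge score zero. The
#' total importance is therefore twice the L1 norm of the weights.
#'
#' @param betas Either a data frame (\code{network_a}, \code{network_b},
#'   \code{beta}) or a named weight vector keyed \code{"A--B"} as produced
#'   by \code{\link{final_fit_and_report}} (zero entries are dropped).
#' @param parcellation A \code{parcellation}.
#' @return Data frame with one row per network: \code{network},
#'   \code{group}, \code{importance}, in parcellation order.
#' @export
node_importance <- function(betas, parcellation = yeo17_parcellation()) {
  ed <- as_edge_table(betas, parcellation)
  ed <- ed[ed$beta != 0, , drop = FALSE]
  imp <- stats::setNames(numeric(length(parcellation$networks)),
                         parcellation$networks)
  for (k in seq_len(nrow(ed))) {
    w <- abs(ed$beta[k])
    imp[ed$network_a[k]] <- imp[ed$network_a[k]] + w
    imp[ed$network_b[k]] <- imp[ed$network_b[k]] + w
  }
  data.frame(network = parcellation$networks,
             group = unname(parcellation$group[parcellation$networks]),
             importance = unname(imp), stringsAsFactors = FALSE)
}

#' Storage-network importance contrast
#'
#' One-sample two-sided t test of the storage-group node importances
#' against zero, with zeros included for storage networks untouched by the
#' selected model. Because no retrieval network is ever selected in the
#' reference solution, the retrieval-group mean is zero and this test
#' doubles as the storage-greater-than-retrieval contrast.
#'
#' @param importances Output of \code{\link{node_importance}}.
#' @param group Which group to test. Default \code{"Storage"}.
#' @return List with \code{mean}, \code{sd}, \code{t}, \code{dof},
#'   \code{p}, \code{n}, and \code{undefined} (TRUE when the importances
#'   have zero variance, where the statistic does not exist).
#' @export
storage_retrieval_test <- function(importances, group = "Storage") {
  x <- importances$importance[importances$group == group]
  if (length(x) < 2L) stop("need at least 2 networks in group ", group)
  if (stats::sd(x) == 0)
    return(list(mean = mean(x), sd = 0, t = NA_real_,
                dof = length(x) - 1L, p = NA_real_, n = length(x),
                undefined = TRUE))
  tt <- stats::t.test(x, mu = 0)
  list(mean = mean(x), sd = stats::sd(x), t = unname(tt$statistic),
       dof = unname(tt$parameter), p = tt$p.value, n = length(x),
       undefined = FALSE)
}

#' Probability that a selected edge set is storage-only
#'
#' Exact hypergeometric probability that \code{k} edges drawn uniformly
#' without replacement from the DMN-anchored feature pool all have a
#' storage-group non-DMN endpoint. By the default convention the pool is
#' the 42 DMN-to-other edges (3 x 14) and within-DMN edges are excluded
#' from the draw count; set \code{include_within_dmn} to count them in the
#' pool (they can never be storage edges, so this shrinks the probability).
#'
#' @param selected_edges Edge table or named weight vector of the selected
#'   edges (see \code{\link{node_importance}}).
#' @param parcellation A \code{parcellation}.
#' @param include_within_dmn Pool convention, see above. Default FALSE.
#' @return List with \code{p} (the probability), \code{k} (edges drawn),
#'   \code{n_pool}, \code{n_storage}, and \code{convention} (text).
#' @export
selection_enrichment <- function(selected_edges,
                                 parcellation = yeo17_parcellation(),
                                 include_within_dmn = FALSE) {
  ed <- as_edge_table(selected_edges, parcellation)
  grp <- parcellation$group
  other_end <- ifelse(grp[ed$network_a] == "DMN", grp[ed$network_b],
                      grp[ed$network_a])
  within <- grp[ed$network_a] == "DMN" & grp[ed$network_b] == "DMN"
  n_dmn <- sum(grp == "DMN")
  n_storage_pool <- n_dmn * sum(grp == "Storage")
  n_pool <- n_dmn * sum(grp != "DMN")
  if (include_within_dmn) {
    n_pool <- n_pool + choose(n_dmn, 2)
    k <- nrow(ed)
  } else {
    ed <- ed[!within, , drop = FALSE]
    other_end <- other_end[!within]
    k <- nrow(ed)
  }
  if (k > n_pool) stop("more selected edges than the pool holds")
  all_storage <- all(other_end == "Storage" | ed$network_a == ed$network_b)
  p <- if (k == 0L) 1 else choose(n_storage_pool, k) / choose(n_pool, k)
  list(p = p, k = k, n_pool = n_pool, n_storage = n_storage_pool,
       all_storage = all_storage,
       convention = paste0("P(all ", k, " draws from the ", n_storage_pool,
                           " storage-incident edges of a ", n_pool,
                           "-edge pool) = C(", n_storage_pool, ",", k,
                           ")/C(", n_pool, ",", k, ")"))
}

#' Sign-adjusted interpretable weights
#'
#' Multiplies each selected weight by the sign of the edge's group-mean
#' connectivity, so a positive adjusted weight always reads "stronger
#' connectivity on this edge predicts faster forgetting" regardless of
#' whether the edge's typical partial correlation is positive or negative.
#'
#' @param betas Edge table or named weight vector of selected edges.
#' @param group_mean_connectome Group-average \code{connectivity_matrix}
#'   (see \code{\link{fisher_group_average}}).
#' @param parcellation A \code{parcellation}.
#' @return Edge data frame with added columns \code{mean_r} and
#'   \code{adjusted}; a group mean of exactly zero yields weight 0 with a
#'   warning.
#' @export
sign_adjusted_weights <- function(betas, group_mean_connectome,
                                  parcellation = yeo17_parcellation()) {
  ed <- as_edge_table(betas, parcellation)
  m <- unclass(group_mean_connectome)
  ed$mean_r <- m[cbind(ed$network_a, ed$network_b)]
  if (any(ed$mean_r == 0))
    warning("group-mean connectivity exactly 0 on some edge; weight set to 0")
  ed$adjusted <- ed$beta * sign(ed$mean_r)
  ed
}
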