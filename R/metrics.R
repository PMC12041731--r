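#' Node strength centrality
#'
#' The sum of absolute edge weights incident to each node,
#' `sum_j |w_ij|`.
#'
#' @param W Symmetric partial-correlation weight matrix with zero
#'   diagonal (or a `network_model`).
#' @param node Optional node index or label; default all nodes.
#' @return Named numeric vector (or scalar if `node` given).
#' @export
strength <- function(W, node = NULL) {
  W <- .as_weight_matrix(W)
  s <- rowSums(abs(W))
  if (is.null(node)) s else s[node]
}

#' Node expected influence (one-step)
#'
#' The signed sum of edge weights incident to each node, `sum_j w_ij`:
#' like strength but negative edges subtract, so it tracks a node's net
#' activating effect on the rest of the network.
#'
#' @inheritParams strength
#' @return Named numeric vector (or scalar if `node` given).
#' @export
expected_influence <- function(W, node = NULL) {
  W <- .as_weight_matrix(W)
  s <- rowSums(W)
  if (is.null(node)) s else s[node]
}

#' Global strength of a network
#'
#' Sum of absolute weights over unique edges (upper triangle). This is
#' the quantity whose between-group difference forms the S statistic of
#' the network comparison test.
#'
#' @param W Symmetric weight matrix with zero diagonal (or a
#'   `network_model`).
#' @return Scalar.
#' @export
global_strength <- function(W) {
  W <- .as_weight_matrix(W)
  sum(abs(W[upper.tri(W)]))
}

#' z-standardize a vector of centralities
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#' A constant input returns zeros with a warning.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
z_standardize <- function(values) {
  stopifnot(length(values) >= 2)
  s <- stats::sd(values)
  if (s == 0) {
    warning("constant values: z-scores set to 0")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Centrality table of a network
#'
#' Strength and expected influence for every node, raw and
#' z-standardized within the network. Covariate nodes are flagged so
#' substantive rankings can exclude them.
#'
#' @param model A `network_model`, or a weight matrix.
#' @param registry Optional registry supplying node categories.
#' @return Data frame with columns `node`, `category`, `strength`,
#'   `expected_influence`, `z_strength`, `z_expected_influence`,
#'   `is_covariate`.
#' @export
centrality_table <- function(model, registry = NULL) {
  W <- .as_weight_matrix(model)
  labels <- colnames(W)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(W)))
  category <- rep(NA_character_, length(labels))
  if (!is.null(registry)) {
    validate_registry(registry)
    category <- registry$category[match(labels, registry$name)]
  }
  st <- strength(W)
  ei <- expected_influence(W)
  data.frame(
    node = labels, category = category,
    strength = as.numeric(st),
    expected_influence = as.numeric(ei),
    z_strength = z_standardize(as.numeric(st)),
    z_expected_influence = z_standardize(as.numeric(ei)),
    is_covariate = !is.na(category) & category == "covariate",
    row.names = NULL, stringsAsFactors = FALSE
  )
}

.as_weight_matrix <- function(x) {
  if (inherits(x, "network_model")) x <- x$W
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("weight matrix must be square")
  if (any(diag(x) != 0)) stop("weight matrix must have a zero diagonal")
  x
}
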