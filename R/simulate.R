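#' Chain-graph precision matrix
#'
#' Builds a tridiagonal precision matrix with unit diagonal whose implied
#' partial-correlation graph is a chain: node i is conditionally associated
#' only with nodes i-1 and i+1, each with partial correlation
#' `edge_weight * boost`. `boost > 1` yields the "denser/stronger" network
#' condition used to emulate the female-network scenario.
#'
#' Because the diagonal is 1, the partial correlation between adjacent
#' nodes equals `-theta_ij`, i.e. `edge_weight * boost` exactly.
#'
#' @param p Number of nodes (>= 2).
#' @param edge_weight Base partial correlation of each chain edge.
#' @param boost Multiplier applied to every edge (default 1).
#' @return A symmetric positive-definite `p x p` matrix.
#' @examples
#' Theta <- make_chain_precision(5, 0.3)
#' precision_to_partial(Theta)[1, 2]  # 0.3
#' @export
make_chain_precision <- function(p, edge_weight, boost = 1) {
  stopifnot(p >= 2, is.numeric(edge_weight), is.numeric(boost))
  w <- edge_weight * boost
  Theta <- diag(p)
  if (p >= 2) {
    idx <- cbind(seq_len(p - 1), seq_len(p - 1) + 1L)
    Theta[idx] <- -w
    Theta[idx[, 2:1, drop = FALSE]] <- -w
  }
  ev <- min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    stop("chain precision not positive definite: edge_weight * boost = ",
         signif(w, 4), " is too large for p = ", p)
  }
  Theta
}

#' Configuration for the synthetic twin-pair generator
#'
#' Encodes the study conditions the generator emulates: per-stratum pair
#' counts, gender-specific ground-truth precision matrices, an
#' equicorrelated ACE-style cross-twin structure (`rho_mz = h2 + c2`,
#' `rho_dz = h2/2 + c2`), and a set of columns passed through a monotone
#' skewing map so some marginals have |skew| > 1.
#'
#' Default pair counts mirror the four gender-by-zygosity strata of a
#' middle-aged like-sex twin cohort (918/1122 MZ/DZ women and 730/982
#' MZ/DZ men) proportionally at quarter scale. Defaults `h2 = 0.6`,
#' `c2 = 0.2` give cross-twin correlations 0.8 (MZ) and 0.5 (DZ). The
#' default ground truth is a chain graph with partial correlations 0.25,
#' boosted by 1.8 in women, so female networks are stronger — the
#' qualitative pattern the three-level design is meant to detect.
#'
#' @param n_pairs Named integer vector of pair counts per stratum with
#'   names `MZ_F`, `DZ_F`, `MZ_M`, `DZ_M`.
#' @param registry Variable registry (defaults to the 39-node battery).
#' @param theta_f,theta_m Ground-truth precision matrices for women / men.
#' @param h2,c2 Additive-genetic and shared-environment proportions,
#'   `h2 >= 0`, `c2 >= 0`, `h2 + c2 <= 1`.
#' @param skew_columns Character vector of registry names to skew
#'   (default: a handful of frequency/count columns plus alcohol, picked
#'   from whatever the registry contains).
#' @param skew_scale Scale `s` of the skewing map `x -> exp(x / s)`;
#'   `s = 1` makes skewed columns roughly lognormal (skew ~ 6).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `twin_config`.
#' @export
twin_config <- function(n_pairs = c(MZ_F = 115, DZ_F = 140, MZ_M = 91, DZ_M = 123),
                        registry = variable_registry(),
                        theta_f = make_chain_precision(nrow(registry), 0.25, boost = 1.8),
                        theta_m = make_chain_precision(nrow(registry), 0.25),
                        h2 = 0.6, c2 = 0.2,
                        skew_columns = default_skew_columns(registry),
                        skew_scale = 1,
                        seed = 1L) {
  validate_registry(registry)
  p <- nrow(registry)
  strata <- c("MZ_F", "DZ_F", "MZ_M", "DZ_M")
  if (!all(strata %in% names(n_pairs))) {
    stop("n_pairs must be named with: ", paste(strata, collapse = ", "))
  }
  n_pairs <- n_pairs[strata]
  stopifnot(all(n_pairs >= 1))
  check_spd <- function(Theta, label) {
    if (!isTRUE(all.equal(Theta, t(Theta), tolerance = 1e-10)) ||
        nrow(Theta) != p) {
      stop(label, " must be a symmetric ", p, "x", p, " matrix")
    }
    if (min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop(label, " is not positive definite")
    }
  }
  check_spd(theta_f, "theta_f")
  check_spd(theta_m, "theta_m")
  stopifnot(h2 >= 0, c2 >= 0)
  if (h2 + c2 > 1) stop("h2 + c2 must not exceed 1")
  bad <- setdiff(skew_columns, registry$name)
  if (length(bad)) stop("skew_columns not in registry: ",
                        paste(bad, collapse = ", "))
  structure(list(
    n_pairs = n_pairs, registry = registry,
    theta_f = theta_f, theta_m = theta_m,
    h2 = h2, c2 = c2,
    rho_mz = h2 + c2, rho_dz = 0.5 * h2 + c2,
    skew_columns = skew_columns, skew_scale = skew_scale,
    seed = as.integer(seed)
  ), class = "twin_config")
}

#' Default skewed columns for a registry
#'
#' Picks the alcohol covariate (notoriously right-skewed) plus up to five
#' frequency/count columns, so the generated data always exercises the
#' skew screen and nonparanormal step. For generic registries the last
#' three columns are used.
#'
#' @param registry A variable registry.
#' @return Character vector of column names.
#' @export
default_skew_columns <- function(registry) {
  if (all(registry$category == "generic")) {
    return(utils::tail(registry$name, 3))
  }
  cand <- registry$name[registry$scale %in% c("frequency", "count")]
  out <- utils::head(cand, 5)
  if ("Alcohol" %in% registry$name) out <- c(out, "Alcohol")
  out
}

# Monotone skewing map: x -> exp(x / s), standardized to mean 0 / sd 1
# using the exact lognormal moments for x ~ N(0, sigma^2). Sample-moment
# standardization would give every generated batch its own random scale
# factor, silently breaking row exchangeability across batches on these
# heavy-tailed columns; the closed-form constants keep rows iid.
.skew_map <- function(x, s, sigma) {
  v <- (sigma / s)^2
  (exp(x / s) - exp(v / 2)) / sqrt((exp(v) - 1) * exp(v))
}

#' Generate a synthetic twin-pair table
#'
#' For each stratum, pairs are drawn from a 2p-dimensional Gaussian whose
#' within-twin covariance is `solve(Theta_g)` (g = gender) and whose
#' cross-twin covariance is `rho_z * solve(Theta_g)` (z = zygosity), the
#' equicorrelated ACE simplification: every variable has cross-twin
#' correlation `rho_mz` in MZ pairs and `rho_dz` in DZ pairs. Designated
#' columns are then passed through the monotone skewing map, which breaks
#' marginal normality (|skew| > 1) while preserving ranks, so the
#' nonparanormal preprocessing step has real work to do.
#'
#' @param config A [twin_config()].
#' @return A `data.frame` with columns `pair_id`, `twin_index`, `zygosity`,
#'   `gender`, then one numeric column per registry variable, two rows per
#'   pair. Deterministic given `config$seed`.
#' @examples
#' cfg <- twin_config(n_pairs = c(MZ_F = 20, DZ_F = 20, MZ_M = 20, DZ_M = 20),
#'                    registry = variable_registry(p = 6),
#'                    theta_f = make_chain_precision(6, 0.3),
#'                    theta_m = make_chain_precision(6, 0.3), seed = 7)
#' tw <- generate_twin_pairs(cfg)
#' table(tw$zygosity, tw$gender)
#' @export
generate_twin_pairs <- function(config) {
  stopifnot(inherits(config, "twin_config"))
  reg <- config$registry
  p <- nrow(reg)
  set.seed(config$seed)
  strata <- names(config$n_pairs)
  out <- vector("list", length(strata))
  pair_counter <- 0L
  for (si in seq_along(strata)) {
    st <- strata[si]
    zyg <- sub("_.*$", "", st)
    gen <- sub("^.*_", "", st)
    n <- config$n_pairs[[st]]
    Theta <- if (gen == "F") config$theta_f else config$theta_m
    Sigma <- solve(Theta)
    rho <- if (zyg == "MZ") config$rho_mz else config$rho_dz
    # pair covariance [[Sigma, rho*Sigma], [rho*Sigma, Sigma]]
    # = kron([[1, rho], [rho, 1]], Sigma): PD iff rho in (-1, 1)
    if (rho >= 1) stop("cross-twin correlation must be < 1")
    Pair <- kronecker(matrix(c(1, rho, rho, 1), 2), Sigma)
    L <- chol(Pair)
    Z <- matrix(stats::rnorm(n * 2L * p), nrow = n) %*% L
    X1 <- Z[, seq_len(p), drop = FALSE]
    X2 <- Z[, p + seq_len(p), drop = FALSE]
    skew_idx <- match(config$skew_columns, reg$name)
    for (j in skew_idx) {
      sig_j <- sqrt(Sigma[j, j])
      X1[, j] <- .skew_map(X1[, j], config$skew_scale, sig_j)
      X2[, j] <- .skew_map(X2[, j], config$skew_scale, sig_j)
    }
    ids <- sprintf("%s_%04d", st, pair_counter + seq_len(n))
    pair_counter <- pair_counter + n
    mk <- function(X, tw) {
      d <- data.frame(pair_id = ids, twin_index = tw, zygosity = zyg,
                      gender = gen, stringsAsFactors = FALSE)
      X <- as.data.frame(X)
      names(X) <- reg$name
      cbind(d, X)
    }
    block <- rbind(mk(X1, 1L), mk(X2, 2L))
    out[[si]] <- block[order(block$pair_id, block$twin_index), ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Split a twin table into its four gender-by-zygosity strata
#'
#' @param table A twin-pair table.
#' @return Named list of data frames (`MZ_F`, `DZ_F`, `MZ_M`, `DZ_M`);
#'   empty strata are dropped.
#' @export
split_strata <- function(table) {
  key <- paste(table$zygosity, table$gender, sep = "_")
  split(table, factor(key, levels = c("MZ_F", "DZ_F", "MZ_M", "DZ_M")),
        drop = TRUE)
}

#' Extract the numeric variable matrix from a twin table
#'
#' @param table A twin-pair table.
#' @param registry Optional registry defining the variable order; by
#'   default all non-metadata columns in their current order.
#' @return Numeric matrix, individuals x variables.
#' @export
twin_matrix <- function(table, registry = NULL) {
  vars <- setdiff(names(table), .meta_cols)
  if (!is.null(registry)) {
    validate_registry(registry)
    missing <- setdiff(registry$name, vars)
    if (length(missing)) stop("table lacks registry variables: ",
                              paste(missing, collapse = ", "))
    vars <- registry$name
  }
  as.matrix(table[, vars, drop = FALSE])
}
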