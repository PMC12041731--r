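#' Analysis configuration for the three-level study
#'
#' Bundles every tunable of the pipeline with validation. Defaults are
#' the study's stated settings: EBIC `gamma = 0.5`, a 100-model penalty
#' path, 1000 NCT permutations, 1000 co-twin reassignments, skew
#' threshold 1, bootstrap B = 1000, 95% intervals, alpha = 0.05, and
#' pair-respecting permutation.
#'
#' @param gamma EBIC hyperparameter.
#' @param n_lambdas Penalty-path length.
#' @param n_permutations NCT permutations at levels 2 and 3.
#' @param n_reassignments Level-1 reassignment iterations.
#' @param inner_permutations Permutations inside each level-1 NCT.
#' @param skew_threshold Absolute-skewness threshold for the
#'   nonparanormal step.
#' @param bootstrap_B Bootstrap resamples for stability analyses.
#' @param ci_level Bootstrap interval level.
#' @param alpha Significance level for gates and decisions.
#' @param permutation `"pair"` or `"plain"` NCT permutation at levels
#'   2-3.
#' @param seed Integer master seed; all stages derive substreams from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(gamma = 0.5, n_lambdas = 100,
                         n_permutations = 1000, n_reassignments = 1000,
                         inner_permutations = 1000,
                         skew_threshold = 1, bootstrap_B = 1000,
                         ci_level = 0.95, alpha = 0.05,
                         permutation = c("pair", "plain"), seed = 1L) {
  permutation <- match.arg(permutation)
  num1 <- function(x, nm, lo, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
      stop(nm, " must be a single number in [", lo, ", ", hi, "]")
    }
    x
  }
  structure(list(
    gamma = num1(gamma, "gamma", 0),
    n_lambdas = as.integer(num1(n_lambdas, "n_lambdas", 2)),
    n_permutations = as.integer(num1(n_permutations, "n_permutations", 1)),
    n_reassignments = as.integer(num1(n_reassignments, "n_reassignments", 1)),
    inner_permutations = as.integer(num1(inner_permutations,
                                         "inner_permutations", 1)),
    skew_threshold = num1(skew_threshold, "skew_threshold", 0),
    bootstrap_B = as.integer(num1(bootstrap_B, "bootstrap_B", 1)),
    ci_level = num1(ci_level, "ci_level", 0.5, 1),
    alpha = num1(alpha, "alpha", 0, 0.5),
    permutation = permutation,
    seed = as.integer(num1(seed, "seed", -.Machine$integer.max,
                           .Machine$integer.max))
  ), class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' Round-trips a [study_config()] through a plain-text key/value file.
#'
#' @param config A `study_config`.
#' @param path File path.
#' @return The path (write) or the re-validated config (read).
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}
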