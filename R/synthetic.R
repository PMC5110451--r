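# Synthetic case tables: forward (ancestral) sampling from a ground-truth
# network followed by MCAR masking. Stands in for the literature-derived
# material datasets (46 CNT / 39 Ag / 55 TiO2 rows with high missingness)
# so the whole pipeline is testable without any external data.

default_rows <- c(CNT = 46L, Ag = 39L, TiO2 = 55L, custom = 50L)

#' Fixture specification for synthetic case tables
#'
#' @param material `"CNT"`, `"Ag"`, `"TiO2"` or `"custom"`. Sets the default
#'   row count (46 / 39 / 55) and, unless `truth` is given, the ground-truth
#'   network.
#' @param n_rows Number of cases; defaults to the material's row count.
#' @param missing_rate MCAR cell-masking probability in `[0, 1)`; default
#'   0.3, echoing the high missingness of literature-derived tables while
#'   keeping EM identifiable at fixture sizes.
#' @param seed Integer seed; fixtures are byte-reproducible given the spec.
#' @param truth Optional ground-truth [bn_network()]; defaults to
#'   [truth_network()] for the material.
#' @param missing_weights Optional named per-column multipliers on the
#'   masking probability (renormalized to mean 1); default uniform.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(material = c("CNT", "Ag", "TiO2", "custom"),
                         n_rows = NULL, missing_rate = 0.3, seed = 1L,
                         truth = NULL, missing_weights = NULL) {
  material <- match.arg(material)
  n_rows <- as.integer(n_rows %||% default_rows[[material]])
  if (n_rows < 1L) stop("n_rows must be >= 1", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  truth <- truth %||% truth_network(material)
  stopifnot(isTRUE(truth$validated))
  structure(list(material = material, n_rows = n_rows,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 truth = truth, missing_weights = missing_weights),
            class = "fixture_spec")
}

with_preserved_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  force(expr)
}

# Vectorized ancestral sampling: integer state matrix n x |vars|.
sample_states <- function(net, n) {
  vars <- bn_vars(net)
  m <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  for (v in net$topo_order) {
    cp <- net$cpts[[v]]
    if (length(cp$parents) == 0L) {
      ri <- rep(1L, n)
    } else {
      pc <- bn_card(net, cp$parents)
      strides <- cumprod(c(1, pc[-length(pc)]))
      ri <- 1L + as.integer((m[, cp$parents, drop = FALSE] - 1L) %*% strides)
    }
    cum <- t(apply(cp$prob, 1L, cumsum))
    u <- stats::runif(n)
    m[, v] <- 1L + as.integer(rowSums(cum[ri, , drop = FALSE] < u))
  }
  m
}

#' Generate a synthetic case table
#'
#' Forward-samples complete cases from the fixture's ground-truth network in
#' topological order, then masks each cell independently with the fixture's
#' missing rate (missing completely at random). Fully reproducible from the
#' fixture seed.
#'
#' @param fix A [fixture_spec()].
#' @return A tibble of state labels (one column per network variable) with
#'   `NA` for masked cells.
#' @export
generate_cases <- function(fix) {
  stopifnot(inherits(fix, "fixture_spec"))
  net <- fix$truth
  vars <- bn_vars(net)
  with_preserved_seed(fix$seed, {
    m <- sample_states(net, fix$n_rows)
    if (fix$missing_rate > 0) {
      w <- rep(1, length(vars))
      names(w) <- vars
      if (!is.null(fix$missing_weights)) {
        w[names(fix$missing_weights)] <- fix$missing_weights
        w <- w / mean(w)
      }
      p_col <- pmin(fix$missing_rate * w, 0.99)
      mask <- matrix(stats::runif(length(m)), nrow(m)) <
        matrix(p_col, nrow(m), length(vars), byrow = TRUE)
      m[mask] <- NA_integer_
    }
    cols <- lapply(vars, function(v) net$variables[[v]]$states[m[, v]])
    tibble::as_tibble(stats::setNames(cols, vars))
  })
}

# Smallest posterior-mass set of states reaching `level`, by descending
# probability with stable index tie-break.
predictive_set <- function(prob, level = 0.9) {
  ord <- order(prob, decreasing = TRUE)
  k <- which(cumsum(prob[ord]) >= level - 1e-12)[1]
  sort(ord[seq_len(k)])
}

#' Out-of-sample predictive coverage check
#'
#' Samples fresh complete cases from the ground-truth network, hides the
#' target variable (the concentration bin by default), feeds every other
#' sampled value to the fitted network as evidence, and checks whether the
#' true bin falls in the fitted model's smallest 90% posterior-mass set.
#' Because the sets are discrete they carry at least the nominal mass, so a
#' correctly fitted model is conservative: empirical coverage at or above
#' the nominal level.
#'
#' @param truth Ground-truth validated [bn_network()].
#' @param fitted Fitted network sharing `truth`'s structure.
#' @param n_test Number of fresh test cases (>= 1).
#' @param seed Integer seed for the test draw.
#' @param level Nominal level of the predictive set (default 0.90).
#' @param var Hidden target variable (default `"concentration"`).
#' @return A one-row tibble: `coverage` (%), `mean_set_size`,
#'   `mean_set_mass`, `n_test`, `level`. Near-vacuous (very wide) sets show
#'   up as a large `mean_set_size`.
#' @export
out_of_sample_check <- function(truth, fitted, n_test = 1000L, seed = 1L,
                                level = 0.9, var = "concentration") {
  stopifnot(isTRUE(truth$validated), isTRUE(fitted$validated))
  if (n_test < 1L) stop("n_test must be >= 1", call. = FALSE)
  same <- identical(bn_vars(truth), bn_vars(fitted)) &&
    identical(truth$edges[order(truth$edges[, 1], truth$edges[, 2]), ],
              fitted$edges[order(fitted$edges[, 1], fitted$edges[, 2]), ]) &&
    identical(lapply(truth$variables, `[[`, "states"),
              lapply(fitted$variables, `[[`, "states"))
  if (!same) stop("truth and fitted networks differ in structure", call. = FALSE)
  if (!var %in% bn_vars(truth)) stop("unknown target variable '", var, "'", call. = FALSE)

  m <- with_preserved_seed(seed, sample_states(truth, n_test))
  others <- setdiff(bn_vars(truth), var)
  covered <- logical(n_test)
  set_size <- integer(n_test)
  set_mass <- numeric(n_test)
  for (i in seq_len(n_test)) {
    ev <- stats::setNames(as.integer(m[i, others]), others)
    post <- ve_query(fitted, ev, var)$factor$val
    s <- predictive_set(post, level)
    covered[i] <- m[i, var] %in% s
    set_size[i] <- length(s)
    set_mass[i] <- sum(post[s])
  }
  tibble::tibble(coverage = 100 * mean(covered),
                 mean_set_size = mean(set_size),
                 mean_set_mass = mean(set_mass),
                 n_test = n_test, level = level)
}
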