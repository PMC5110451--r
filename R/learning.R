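# Parameter learning: EM from case tables with missing cells, and
# experience-weighted sequential Dirichlet updating.
#
# Expected sufficient statistics are computed exactly: rows are grouped by
# their unique observed pattern and, per group, the joint over the (small)
# hidden set is enumerated directly. This is exact and fast for networks in
# this tool's scope; production single-variable queries go through variable
# elimination instead (inference.R).

# Case table -> integer state matrix (NA = missing), columns = network vars
# present in the table. All-missing columns are dropped with a warning.
case_matrix <- function(net, cases) {
  cases <- as.data.frame(cases)
  bad <- setdiff(names(cases), bn_vars(net))
  if (length(bad))
    stop("case table column '", bad[1], "' is not a network variable", call. = FALSE)
  if (nrow(cases) == 0L)
    return(matrix(integer(), 0L, ncol(cases), dimnames = list(NULL, names(cases))))
  m <- vapply(names(cases), function(v) {
    x <- as.character(cases[[v]])
    idx <- match(x, net$variables[[v]]$states)
    if (any(!is.na(x) & is.na(idx)))
      stop("invalid state '", x[!is.na(x) & is.na(idx)][1], "' in column '", v, "'",
           call. = FALSE)
    idx
  }, integer(nrow(cases)))
  m <- matrix(m, nrow = nrow(cases),
              dimnames = list(NULL, names(cases)))
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warning("ignoring all-missing column(s): ",
            paste(colnames(m)[all_na], collapse = ", "), call. = FALSE)
    m <- m[, !all_na, drop = FALSE]
  }
  m
}

empty_counts <- function(net) {
  lapply(net$cpts, function(cp) array(0, dim = dim(cp$prob)))
}

# Expected family counts and log-evidence for one observed pattern.
# obs: named integer vector of observed state indices.
row_expected <- function(net, obs) {
  vars <- bn_vars(net)
  card <- bn_card(net)
  hidden <- setdiff(vars, names(obs))
  if (prod(card[hidden]) > 2^20)
    stop("hidden state space too large for exact E-step", call. = FALSE)
  if (length(hidden)) {
    grid <- as.matrix(expand.grid(lapply(card[hidden], seq_len),
                                  KEEP.OUT.ATTRS = FALSE))
  } else {
    grid <- matrix(integer(), nrow = 1L, ncol = 0L)
  }
  n <- nrow(grid)
  assign_full <- matrix(0L, n, length(vars), dimnames = list(NULL, vars))
  if (length(hidden)) assign_full[, hidden] <- grid
  for (v in names(obs)) assign_full[, v] <- obs[[v]]
  p <- rep(1, n)
  row_idx_by_var <- list()
  for (v in vars) {
    cp <- net$cpts[[v]]
    if (length(cp$parents) == 0L) {
      ri <- rep(1L, n)
    } else {
      pc <- bn_card(net, cp$parents)
      strides <- cumprod(c(1, pc[-length(pc)]))
      ri <- 1L + as.integer((assign_full[, cp$parents, drop = FALSE] - 1L) %*% strides)
    }
    row_idx_by_var[[v]] <- ri
    p <- p * cp$prob[cbind(ri, assign_full[, v])]
  }
  z <- sum(p)
  if (z <= 0) {
    if (length(hidden)) zero_evidence_error()
    # fully observed case that the current CPTs assign probability zero:
    # the sufficient statistics are still the deterministic indicators
    w <- rep(1, n)
  } else {
    w <- p / z
  }
  counts <- lapply(vars, function(v) {
    cp <- net$cpts[[v]]
    out <- array(0, dim = dim(cp$prob))
    flat <- (assign_full[, v] - 1L) * nrow(cp$prob) + row_idx_by_var[[v]]
    agg <- rowsum(w, flat)
    out[as.integer(rownames(agg))] <- agg[, 1L]
    out
  })
  list(counts = stats::setNames(counts, vars), log_z = log(z))
}

# One exact E-step over a whole table: expected counts per CPT cell plus the
# observed-data log-likelihood, with rows grouped by unique pattern.
expected_counts <- function(net, m) {
  keys <- apply(m, 1L, paste, collapse = ",")
  groups <- table(keys)
  counts <- empty_counts(net)
  loglik <- 0
  first_of <- m[match(names(groups), keys), , drop = FALSE]
  for (g in seq_along(groups)) {
    row <- first_of[g, ]
    obs <- row[!is.na(row)]
    re <- row_expected(net, obs)
    wt <- as.numeric(groups[[g]])
    loglik <- loglik + wt * re$log_z
    for (v in names(counts)) counts[[v]] <- counts[[v]] + wt * re$counts[[v]]
  }
  list(counts = counts, loglik = loglik)
}

dirichlet_penalty <- function(net, prior_strength) {
  if (prior_strength <= 0) return(0)
  sum(vapply(net$cpts, function(cp) prior_strength * sum(log(cp$prob)), 0))
}

#' Fit CPT parameters by expectation-maximization
#'
#' Refines the network's conditional probabilities from a case table whose
#' cells may be missing (assumed missing completely at random). The E-step
#' computes exact expected sufficient statistics per row by conditioning on
#' that row's observed cells; the M-step sets each CPT row to
#' `(expected counts + prior_strength) / normalizer`. Iteration stops when
#' the relative change of the objective drops below `tol` or after
#' `max_iter` iterations.
#'
#' The recorded trace is the objective EM maximizes: the observed-data
#' log-likelihood plus, when `prior_strength > 0`, the Dirichlet smoothing
#' term `prior_strength * sum(log theta)`. It is non-decreasing across
#' iterations. With complete data and `prior_strength = 0` the fit equals
#' the relative-frequency maximum-likelihood estimate exactly.
#'
#' @param net A validated [bn_network()]; its current CPTs are the starting
#'   point (exactly-uniform rows get a small seeded jitter to break
#'   symmetry).
#' @param cases Data frame of state labels, columns a subset of the network
#'   variables, `NA`/empty = missing.
#' @param prior_strength Dirichlet pseudo-count added to every CPT cell
#'   (default 1, add-one smoothing; 0 for the pure MLE).
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Iteration cap.
#' @param seed Seed for the symmetry-breaking jitter.
#' @param jitter Magnitude of the uniform jitter applied to exactly-uniform
#'   starting rows.
#' @return A `bn_fit` object: `network` (fitted), `loglik` (objective
#'   trace), `iterations`, `converged`, plus the settings used. Has
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
em_fit <- function(net, cases, prior_strength = 1, tol = 1e-6,
                   max_iter = 200L, seed = 1L, jitter = 0.01) {
  stopifnot(isTRUE(net$validated), prior_strength >= 0)
  m <- case_matrix(net, cases)
  if (nrow(m) == 0L) stop("empty case table", call. = FALSE)
  if (sum(!is.na(m)) == 0L) stop("case table has no observed cells", call. = FALSE)

  # symmetry-breaking jitter on exactly-uniform rows, seeded and restored
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (v in bn_vars(net)) {
    pr <- net$cpts[[v]]$prob
    k <- ncol(pr)
    uni <- abs(pr - 1 / k) < 1e-12
    for (r in which(rowSums(uni) == k)) {
      row <- pr[r, ] + stats::runif(k, 0, jitter)
      pr[r, ] <- row / sum(row)
    }
    net$cpts[[v]]$prob <- pr
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    es <- expected_counts(net, m)
    obj <- es$loglik + dirichlet_penalty(net, prior_strength)
    trace <- c(trace, obj)
    iter <- iter + 1L
    if (length(trace) > 1L) {
      prev <- trace[length(trace) - 1L]
      if (abs(obj - prev) <= tol * max(1, abs(prev))) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
    for (v in bn_vars(net)) {
      cnt <- es$counts[[v]] + prior_strength
      tot <- rowSums(cnt)
      upd <- tot > 0
      pr <- net$cpts[[v]]$prob
      pr[upd, ] <- cnt[upd, , drop = FALSE] / tot[upd]
      net$cpts[[v]]$prob <- pr
    }
  }
  structure(list(network = net, loglik = trace, iterations = iter,
                 converged = converged, prior_strength = prior_strength,
                 tol = tol, seed = seed, n_cases = nrow(m)),
            class = "bn_fit")
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("<bn_fit> ", x$iterations, " EM iterations, ",
      if (x$converged) "converged" else "not converged",
      "; final objective ", format(x$loglik[length(x$loglik)]), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy bn_fit
#' @export
tidy.bn_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$loglik), objective = x$loglik)
}

#' @method glance bn_fit
#' @export
glance.bn_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations, converged = x$converged,
                 objective = x$loglik[length(x$loglik)],
                 n_cases = x$n_cases, prior_strength = x$prior_strength)
}

zero_experience <- function(net) {
  lapply(net$cpts, function(cp) numeric(nrow(cp$prob)))
}

#' Experience-weighted sequential update
#'
#' Treats each CPT row times its experience count as Dirichlet pseudo-counts,
#' adds the (expected, when cells are missing) counts contributed by the new
#' cases, and renormalizes. The returned experience equals the old experience
#' plus the per-parent-configuration case mass, so after updating a
#' zero-experience network with n complete cases the experience summed over a
#' variable's parent configurations is exactly n. High experience damps the
#' influence of new data; low experience lets new data move the CPTs.
#'
#' @param net A validated [bn_network()].
#' @param cases New case table (may have missing cells; may have zero rows,
#'   in which case everything is returned unchanged).
#' @param experience Named list of per-row counts; defaults to the
#'   experience stored in `net`, else zero.
#' @return A list with elements `network` (updated, with experience stored)
#'   and `experience`.
#' @export
update_with_cases <- function(net, cases, experience = NULL) {
  stopifnot(isTRUE(net$validated))
  exp_tab <- experience %||% net$experience %||% zero_experience(net)
  exp_tab <- exp_tab[bn_vars(net)]
  names(exp_tab) <- bn_vars(net)
  for (v in bn_vars(net)) {
    if (is.null(exp_tab[[v]])) exp_tab[[v]] <- numeric(nrow(net$cpts[[v]]$prob))
    if (any(exp_tab[[v]] < 0)) stop("negative experience for '", v, "'", call. = FALSE)
  }
  m <- if (NROW(cases)) case_matrix(net, cases) else
    matrix(integer(), 0L, 0L)
  if (nrow(m) == 0L) {
    net$experience <- exp_tab
    return(list(network = net, experience = exp_tab))
  }
  es <- expected_counts(net, m)
  for (v in bn_vars(net)) {
    cnt <- es$counts[[v]]
    row_n <- rowSums(cnt)
    pseudo <- net$cpts[[v]]$prob * exp_tab[[v]]
    tot <- exp_tab[[v]] + row_n
    upd <- tot > 0
    pr <- net$cpts[[v]]$prob
    pr[upd, ] <- (pseudo[upd, , drop = FALSE] + cnt[upd, , drop = FALSE]) / tot[upd]
    net$cpts[[v]]$prob <- pr
    exp_tab[[v]] <- tot
  }
  net$experience <- exp_tab
  list(network = net, experience = exp_tab)
}
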