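#' Define a discrete network variable
#'
#' A variable is either categorical or a discretized continuous quantity
#' (for example airborne concentration in ug/m3, carried as labelled bins).
#'
#' @param name Variable name (unique within a network).
#' @param states Ordered character vector of state labels; labels are
#'   case-sensitive exact strings.
#' @param bin_edges For discretized-continuous variables, a strictly
#'   increasing numeric vector of `length(states) + 1` edges in the
#'   variable's declared units. `NULL` for categorical variables.
#' @param tag One of `"physicochemical"`, `"exposure"`, `"dose-response"`,
#'   `"risk"`; used to audit the network layout (e.g. counting the
#'   physicochemical characteristics block).
#' @return An object of class `bn_variable`.
#' @export
bn_variable <- function(name, states,
                        bin_edges = NULL,
                        tag = c("physicochemical", "exposure",
                                "dose-response", "risk")) {
  tag <- match.arg(tag)
  states <- as.character(states)
  if (length(states) == 0L) stop("variable '", name, "': states must be nonempty", call. = FALSE)
  if (anyDuplicated(states)) stop("variable '", name, "': duplicate state labels", call. = FALSE)
  kind <- if (is.null(bin_edges)) "categorical" else "discretized-continuous"
  if (!is.null(bin_edges)) {
    bin_edges <- as.numeric(bin_edges)
    if (length(bin_edges) != length(states) + 1L)
      stop("variable '", name, "': need length(states) + 1 bin edges", call. = FALSE)
    if (any(diff(bin_edges) <= 0))
      stop("variable '", name, "': bin edges must be strictly increasing", call. = FALSE)
  }
  structure(
    list(name = as.character(name), kind = kind, states = states,
         bin_edges = bin_edges, is_marginal = NA, tag = tag),
    class = "bn_variable")
}

#' Conditional probability table for one variable
#'
#' Rows index joint parent-state configurations (the first parent varies
#' fastest); columns index the child's states. A parentless variable has a
#' single row, its marginal distribution.
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names, possibly empty.
#' @param prob Numeric matrix, `prod(parent cardinalities)` rows by
#'   `length(child states)` columns; every row must sum to 1.
#' @return An object of class `bn_cpt`.
#' @export
bn_cpt <- function(child, parents = character(), prob) {
  prob <- rbind(prob)
  structure(list(child = as.character(child),
                 parents = as.character(parents),
                 prob = unname(prob)),
            class = "bn_cpt")
}

#' Assemble a discrete Bayesian network
#'
#' @param variables List of [bn_variable()] objects.
#' @param edges Two-column character matrix or data frame of
#'   (parent, child) pairs; may have zero rows.
#' @param cpts List of [bn_cpt()] objects. Parentless variables may omit
#'   theirs; [validate_network()] fills a uniform distribution.
#' @param experience Optional named list of per-variable equivalent-sample
#'   counts (one non-negative number per CPT row), the confidence backing
#'   sequential updates.
#' @return An object of class `bn_network`. Run [validate_network()] before
#'   inference or learning.
#' @seealso [validate_network()], [default_network()]
#' @export
bn_network <- function(variables, edges = NULL, cpts = list(), experience = NULL) {
  names(variables) <- vapply(variables, `[[`, "", "name")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(as.data.frame(edges, stringsAsFactors = FALSE))
  }
  colnames(edges) <- c("parent", "child")
  names(cpts) <- vapply(cpts, `[[`, "", "child")
  structure(list(variables = variables, edges = edges, cpts = cpts,
                 experience = experience, validated = FALSE),
            class = "bn_network")
}

bn_vars <- function(net) names(net$variables)
bn_card <- function(net, vars = bn_vars(net)) {
  vapply(net$variables[vars], function(v) length(v$states), 0L)
}
bn_parents <- function(net, var) {
  unname(net$edges[net$edges[, "child"] == var, "parent"])
}
state_index <- function(net, var, label) {
  i <- match(label, net$variables[[var]]$states)
  if (anyNA(i)) stop("unknown state '", label[is.na(i)][1], "' for variable '", var, "'",
                     call. = FALSE)
  i
}

# CPT as a factor with scope (child, parents...), child varying fastest.
cpt_factor <- function(net, var) {
  cp <- net$cpts[[var]]
  vars <- c(cp$child, cp$parents)
  new_factor(vars, bn_card(net, vars), as.numeric(t(cp$prob)))
}

topological_order <- function(net) {
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = bn_vars(net), stringsAsFactors = FALSE))
  if (!igraph::is_dag(g)) stop("cycle detected in network edges", call. = FALSE)
  names(igraph::topo_sort(g, mode = "out"))
}

#' Validate a network and fill default marginals
#'
#' Checks acyclicity, agreement between the edge list and every CPT's parent
#' list, state-label validity, CPT row normalization (tolerance 1e-9) and
#' experience-count shape. Parentless variables without an explicit CPT are
#' assigned a uniform distribution, the unbiased default when no knowledge is
#' available. Validation is idempotent.
#'
#' @param net A [bn_network()].
#' @return The validated network, with `is_marginal` flags set and uniform
#'   marginals filled in.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "bn_network"))
  ord <- topological_order(net)  # errors on cycles
  bad <- setdiff(unique(as.vector(net$edges)), bn_vars(net))
  if (length(bad)) stop("edge references unknown variable '", bad[1], "'", call. = FALSE)

  for (v in bn_vars(net)) {
    parents <- bn_parents(net, v)
    net$variables[[v]]$is_marginal <- length(parents) == 0L
    k <- length(net$variables[[v]]$states)
    cp <- net$cpts[[v]]
    if (is.null(cp)) {
      if (length(parents) > 0L)
        stop("variable '", v, "' has parents but no CPT", call. = FALSE)
      net$cpts[[v]] <- bn_cpt(v, character(), matrix(1 / k, 1L, k))
      next
    }
    if (!setequal(cp$parents, parents) ||
        !identical(sort(cp$parents), sort(parents)))
      stop("CPT parents for '", v, "' do not match the edge list", call. = FALSE)
    n_rows <- prod(bn_card(net, cp$parents))
    if (nrow(cp$prob) != n_rows)
      stop("CPT for '", v, "': expected ", n_rows, " rows, got ", nrow(cp$prob),
           call. = FALSE)
    if (ncol(cp$prob) != k)
      stop("CPT for '", v, "': expected ", k, " columns, got ", ncol(cp$prob),
           call. = FALSE)
    if (any(cp$prob < 0) || any(cp$prob > 1))
      stop("CPT for '", v, "': probabilities outside [0, 1]", call. = FALSE)
    if (any(abs(rowSums(cp$prob) - 1) > 1e-9))
      stop("CPT for '", v, "': row not normalized", call. = FALSE)
  }
  net$cpts <- net$cpts[bn_vars(net)]

  if (!is.null(net$experience)) {
    for (v in names(net$experience)) {
      if (!v %in% bn_vars(net))
        stop("experience for unknown variable '", v, "'", call. = FALSE)
      e <- net$experience[[v]]
      if (length(e) != nrow(net$cpts[[v]]$prob))
        stop("experience for '", v, "' has wrong length", call. = FALSE)
      if (any(e < 0)) stop("negative experience for '", v, "'", call. = FALSE)
    }
  }
  net$topo_order <- ord
  net$validated <- TRUE
  net
}

#' @export
print.bn_network <- function(x, ...) {
  cat("<bn_network> ", length(x$variables), " variables, ",
      nrow(x$edges), " edges",
      if (isTRUE(x$validated)) " (validated)", "\n", sep = "")
  for (v in x$variables) {
    cat("  ", v$name, " [", v$tag, "]: ",
        paste(v$states, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Width-growing concentration bins
#'
#' Builds bin edges whose widths grow geometrically, concentrating
#' granularity at the left tail where airborne-concentration values are most
#' likely. With `growth = 1` the bins are equal-width.
#'
#' @param lower,upper Range to cover (e.g. ug/m3); `lower < upper`.
#' @param n_bins Number of bins, at least 2.
#' @param growth Multiplier applied to successive bin widths; must be >= 1 so
#'   widths never decrease.
#' @return Numeric vector of `n_bins + 1` strictly increasing edges.
#' @examples
#' make_concentration_bins(0, 31, n_bins = 5, growth = 2)  # widths 1,2,4,8,16
#' @export
make_concentration_bins <- function(lower, upper, n_bins = 8L, growth = 2) {
  if (!(lower < upper)) stop("lower must be strictly below upper", call. = FALSE)
  if (n_bins < 2L) stop("need at least 2 bins", call. = FALSE)
  if (growth < 1) stop("growth must be >= 1", call. = FALSE)
  w1 <- if (growth == 1) (upper - lower) / n_bins
        else (upper - lower) * (growth - 1) / (growth^n_bins - 1)
  widths <- w1 * growth^(seq_len(n_bins) - 1L)
  edges <- lower + c(0, cumsum(widths))
  edges[n_bins + 1L] <- upper  # absorb rounding
  edges
}

#' Map a value to its bin
#'
#' Bins are half-open `[lo, hi)`; the final bin is closed on the right so the
#' upper edge itself is assignable.
#'
#' @param value Numeric value in `[edges[1], edges[length(edges)]]`.
#' @param edges Strictly increasing bin edges.
#' @return Integer bin index (1-based).
#' @export
assign_bin <- function(value, edges) {
  if (any(value < edges[1]) || any(value > edges[length(edges)]))
    stop("value outside the binned range", call. = FALSE)
  idx <- findInterval(value, edges, rightmost.closed = TRUE)
  pmin(idx, length(edges) - 1L)
}

# Representative value of a positive bin: geometric midpoint sqrt(lo*hi),
# arithmetic midpoint when the bin touches zero (geometric undefined there).
bin_representatives <- function(edges) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  ifelse(lo <= 0, (lo + hi) / 2, sqrt(lo * hi))
}
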