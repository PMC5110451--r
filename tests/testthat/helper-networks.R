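# Networks built in code for the tests: a hand-set 3-node chain (for
# hand-computed posteriors), a 6-node ground truth for learning recovery,
# a 4-node truth small enough for joint goodness-of-fit, and a seeded
# random-network generator for oracle-equivalence sweeps.

chain_net <- function() {
  validate_network(bn_network(
    list(bn_variable("A", c("a0", "a1")),
         bn_variable("B", c("b0", "b1")),
         bn_variable("C", c("c0", "c1"))),
    rbind(c("A", "B"), c("B", "C")),
    list(bn_cpt("A", prob = c(0.3, 0.7)),
         bn_cpt("B", "A", rbind(c(0.9, 0.1), c(0.2, 0.8))),
         bn_cpt("C", "B", rbind(c(0.6, 0.4), c(0.25, 0.75))))))
}

# Recovery ground truth: every parent configuration keeps comfortable sample
# support at fixture sizes and CPT rows stay away from 50/50, so the
# parameter-recovery bound has statistical headroom over the binomial noise
# left after masking.
six_node_net <- function() {
  validate_network(bn_network(
    list(bn_variable("A", c("a0", "a1")),
         bn_variable("B", c("b0", "b1")),
         bn_variable("C", c("c0", "c1", "c2")),
         bn_variable("D", c("d0", "d1")),
         bn_variable("E", c("e0", "e1")),
         bn_variable("F", c("f0", "f1", "f2"))),
    rbind(c("A", "B"), c("A", "C"), c("C", "D"), c("B", "E"), c("D", "E"),
          c("C", "F")),
    list(bn_cpt("A", prob = c(0.5, 0.5)),
         bn_cpt("B", "A", rbind(c(0.8, 0.2), c(0.25, 0.75))),
         bn_cpt("C", "A", rbind(c(0.6, 0.25, 0.15), c(0.15, 0.6, 0.25))),
         bn_cpt("D", "C", rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.75, 0.25))),
         bn_cpt("E", c("B", "D"), rbind(
           c(0.9, 0.1), c(0.25, 0.75),
           c(0.8, 0.2), c(0.15, 0.85))),
         bn_cpt("F", "C", rbind(
           c(0.7, 0.2, 0.1), c(0.2, 0.65, 0.15), c(0.1, 0.25, 0.65))))))
}

four_node_net <- function() {
  validate_network(bn_network(
    list(bn_variable("A", c("a0", "a1")),
         bn_variable("B", c("b0", "b1", "b2")),
         bn_variable("C", c("c0", "c1")),
         bn_variable("D", c("d0", "d1"))),
    rbind(c("A", "C"), c("B", "C"), c("C", "D")),
    list(bn_cpt("A", prob = c(0.4, 0.6)),
         bn_cpt("B", prob = c(0.3, 0.45, 0.25)),
         bn_cpt("C", c("A", "B"), rbind(
           c(0.85, 0.15), c(0.55, 0.45),
           c(0.6, 0.4), c(0.35, 0.65),
           c(0.3, 0.7), c(0.15, 0.85))),
         bn_cpt("D", "C", rbind(c(0.75, 0.25), c(0.2, 0.8))))))
}

rand_prob_rows <- function(n_rows, k) {
  m <- matrix(stats::rgamma(n_rows * k, shape = 1) + 0.05, n_rows, k)
  m / rowSums(m)
}

# Random DAG over n_nodes variables (each <= max_states states), random
# strictly positive CPTs; deterministic given the current RNG state.
random_network <- function(n_nodes = 6L, max_states = 3L) {
  nm <- paste0("N", seq_len(n_nodes))
  card <- sample(2:max_states, n_nodes, replace = TRUE)
  vars <- lapply(seq_len(n_nodes), function(i)
    bn_variable(nm[i], paste0(nm[i], "_s", seq_len(card[i]))))
  edges <- NULL
  cpts <- list()
  for (i in seq_len(n_nodes)) {
    pool <- seq_len(i - 1L)
    n_par <- if (length(pool)) min(stats::rbinom(1, length(pool), 0.4), 3L) else 0L
    parents <- if (n_par > 0L) nm[sort(sample(pool, n_par))] else character()
    if (n_par > 0L) edges <- rbind(edges, cbind(parents, nm[i]))
    cpts[[i]] <- bn_cpt(nm[i], parents,
                        rand_prob_rows(prod(card[match(parents, nm)], 1), card[i]))
  }
  validate_network(bn_network(vars, edges, cpts))
}

random_evidence <- function(net, p_observe = 0.4) {
  vars <- names(net$variables)
  obs <- vars[stats::runif(length(vars)) < p_observe]
  if (length(obs) == length(vars)) obs <- obs[-1]
  ev <- vapply(obs, function(v) sample(net$variables[[v]]$states, 1), "")
  if (length(ev)) ev else NULL
}

# Total-variation distance between matching CPT rows of two networks.
cpt_row_tv <- function(net1, net2, var) {
  0.5 * rowSums(abs(net1$cpts[[var]]$prob - net2$cpts[[var]]$prob))
}

# P(parent configuration) rows of a variable's CPT under a network,
# computed from the enumeration oracle's joint (order: first parent fastest).
parent_config_probs <- function(net, var) {
  cp <- net$cpts[[var]]
  if (length(cp$parents) == 0L) return(1)
  post <- joint_enumeration(net)
  # exact joint over parents by enumeration over the full grid
  card <- vapply(net$variables, function(v) length(v$states), 0L)
  grid <- as.matrix(expand.grid(lapply(card, seq_len), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- names(net$variables)
  p <- rep(1, nrow(grid))
  for (v in names(net$variables)) {
    cpv <- net$cpts[[v]]
    if (length(cpv$parents) == 0L) ri <- rep(1L, nrow(grid))
    else {
      pc <- card[cpv$parents]
      strides <- cumprod(c(1, pc[-length(pc)]))
      ri <- 1L + as.integer((grid[, cpv$parents, drop = FALSE] - 1L) %*% strides)
    }
    p <- p * cpv$prob[cbind(ri, grid[, v])]
  }
  pc <- card[cp$parents]
  strides <- cumprod(c(1, pc[-length(pc)]))
  cfg <- 1L + as.integer((grid[, cp$parents, drop = FALSE] - 1L) %*% strides)
  as.numeric(rowsum(p, cfg))
}
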