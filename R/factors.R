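# Internal factor algebra for discrete networks.
#
# A factor is list(vars = character(), card = integer(), val = numeric()) with
# val stored column-major: vars[1] varies fastest. All engine code (enumeration,
# variable elimination, EM sufficient statistics) is built on these three
# primitives plus product/marginalize/reduce.

new_factor <- function(vars, card, val) {
  stopifnot(length(vars) == length(card), length(val) == prod(card))
  list(vars = as.character(vars), card = as.integer(card), val = as.numeric(val))
}

# For every joint assignment over (vars, card), the 1-based index of the
# corresponding assignment of the sub-scope (sub_vars, sub_card).
assignment_index <- function(vars, card, sub_vars, sub_card) {
  n <- prod(card)
  if (length(sub_vars) == 0L) return(rep(1L, n))
  strides <- cumprod(c(1, card[-length(card)]))
  sub_strides <- cumprod(c(1, sub_card[-length(sub_card)]))
  pos <- match(sub_vars, vars)
  seq0 <- seq_len(n) - 1L
  out <- numeric(n)
  for (j in seq_along(sub_vars)) {
    digit <- (seq0 %/% strides[pos[j]]) %% card[pos[j]]
    out <- out + digit * sub_strides[j]
  }
  as.integer(out + 1)
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0L) return(new_factor(f2$vars, f2$card, f2$val * f1$val))
  if (length(f2$vars) == 0L) return(new_factor(f1$vars, f1$card, f1$val * f2$val))
  vars <- union(f1$vars, f2$vars)
  card <- integer(length(vars))
  card[match(f1$vars, vars)] <- f1$card
  card[match(f2$vars, vars)] <- f2$card
  i1 <- assignment_index(vars, card, f1$vars, f1$card)
  i2 <- assignment_index(vars, card, f2$vars, f2$card)
  new_factor(vars, card, f1$val[i1] * f2$val[i2])
}

# Sum out `drop_vars`, keeping the remaining scope in its original order.
factor_marginalize <- function(f, drop_vars) {
  keep <- setdiff(f$vars, drop_vars)
  if (length(keep) == length(f$vars)) return(f)
  if (length(keep) == 0L) return(new_factor(character(), integer(), sum(f$val)))
  keep_card <- f$card[match(keep, f$vars)]
  idx <- assignment_index(f$vars, f$card, keep, keep_card)
  val <- numeric(prod(keep_card))
  agg <- rowsum(f$val, group = idx)
  val[as.integer(rownames(agg))] <- agg[, 1L]
  new_factor(keep, keep_card, val)
}

# Condition on var = state (1-based state index); var leaves the scope.
factor_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  stride <- prod(f$card[seq_len(pos - 1L)])
  digit <- ((seq_along(f$val) - 1L) %/% stride) %% f$card[pos]
  keep <- digit == (state - 1L)
  new_factor(f$vars[-pos], f$card[-pos], f$val[keep])
}

factor_normalize <- function(f) {
  z <- sum(f$val)
  if (z <= 0) stop("factor normalizer is zero", call. = FALSE)
  new_factor(f$vars, f$card, f$val / z)
}

# Reorder a factor's scope (val permuted accordingly).
factor_permute <- function(f, vars) {
  stopifnot(setequal(vars, f$vars))
  card <- f$card[match(vars, f$vars)]
  idx <- assignment_index(vars, card, f$vars, f$card)
  new_factor(vars, card, f$val[idx])
}
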