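# Shared helpers: small factor sets and an all-combinations enumerator
# used as an independent oracle for additive objectives.

toy_factors3 <- function() {
  list(
    factor_spec("lr", c(0.25, 0.30, 0.35), role = "numeric"),
    factor_spec("mom", c(0.85, 0.90, 0.95), role = "numeric"),
    factor_spec("nodes", c(6, 8, 10), role = "integer")
  )
}

toy_factors6 <- function() {
  list(
    factor_spec("layers", c(4, 8, 12), role = "integer", structural = TRUE),
    factor_spec("act", c("logistic", "tanh", "relu")),
    factor_spec("opt", c("lbfgs", "sgd", "adam")),
    factor_spec("lr", c(0.2, 0.3, 0.4), role = "numeric"),
    factor_spec("mom", c(0.7, 0.8, 0.9), role = "numeric"),
    factor_spec("nodes", c(4, 8, 12), role = "integer")
  )
}

# Exhaustively enumerate all level combinations of <= 3 factors and return
# the best assignment under a noise-free objective (brute-force oracle).
enumerate_optimum <- function(factors, objective) {
  grids <- lapply(factors, function(f) f$levels)
  names(grids) <- vapply(factors, `[[`, "", "name")
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  vals <- vapply(seq_len(nrow(combos)), function(i) {
    objective(as.list(combos[i, , drop = FALSE]), 1L, 0L)
  }, numeric(1))
  list(best = as.list(combos[which.max(vals), , drop = FALSE]),
       value = max(vals), all = cbind(combos, value = vals))
}

stage1_assignment <- function() {
  c(hidden_layers = 2, activation = 3, optimizer = 4,
    learning_rate = 5, moment_rate = 6, hidden_nodes = 7)
}
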