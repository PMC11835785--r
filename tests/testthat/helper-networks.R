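# Shared fixtures: tiny hand-specified networks and random-network
# generators used across the test files. All randomness is seeded by the
# caller.

binary_schema <- function(nms, outcome = nms[length(nms)]) {
  domain_schema(lapply(nms, variable_spec, states = c("false", "true")),
                outcome = outcome)
}

# chain A -> B with P(A=t) = pa, P(B=t|A) = (pb_f, pb_t)
two_node_network <- function(pa = 0.3, pb_f = 0.2, pb_t = 0.9) {
  schema <- binary_schema(c("A", "B"))
  st <- network_structure(c("A", "B"), arcs = rbind(c("A", "B")))
  cpts <- list(
    A = cpt("A", character(0),
            array(c(1 - pa, pa), 2, list(A = c("false", "true")))),
    B = cpt("B", "A",
            array(c(1 - pb_f, pb_f, 1 - pb_t, pb_t), c(2, 2),
                  list(B = c("false", "true"), A = c("false", "true")))))
  fitted_network(st, cpts, schema)
}

# random DAG + random Dirichlet CPTs over n_nodes variables with 2-3 states
random_network <- function(n_nodes, seed, arc_prob = 0.4) {
  random_discrete_network(n_nodes, seed, arc_prob)
}

# random full assignment / partial evidence for a network
random_assignment <- function(network) {
  schema <- network$schema
  vapply(names(schema$variables), function(v) {
    sample(schema$variables[[v]]$states, 1)
  }, character(1))
}

# brute-force conditional by direct summation over all joint cells,
# multiplying CPT entries cell by cell (independent of the package's
# enumeration internals)
brute_force_query <- function(network, target, ev_list) {
  schema <- network$schema
  states <- lapply(schema$variables, `[[`, "states")
  grid <- expand.grid(states, stringsAsFactors = FALSE)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(network, as.list(grid[i, , drop = FALSE]))
  }, numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(ev_list)) keep <- keep & grid[[nm]] == ev_list[[nm]]
  num <- vapply(states[[target]], function(s) {
    sum(p[keep & grid[[target]] == s])
  }, numeric(1))
  num / sum(num)
}

# one-variable cohort with given per-state counts
cohort_from_counts <- function(counts, name = "x",
                               states = names(counts)) {
  schema <- domain_schema(list(variable_spec(name, states)), outcome = name)
  df <- stats::setNames(
    data.frame(rep(states, times = counts), stringsAsFactors = FALSE), name)
  as_cohort(df, schema)
}

# cohort over an explicitly given binary schema from state columns
binary_cohort <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  as_cohort(df, binary_schema(names(df)))
}
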