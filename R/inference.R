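# Exact inference over the discrete network. The default schema has a
# 20,736-cell joint, so full enumeration is cheap and exact; a factor-based
# variable-elimination path is provided for larger schemas and doubles as
# an independent cross-check of the enumeration code.

# all joint cells as an n_cells x n_nodes integer matrix (schema order),
# first variable fastest
joint_cells <- function(schema) {
  card <- schema_cardinalities(schema)
  n_cells <- prod(card)
  m <- matrix(0L, n_cells, length(card),
              dimnames = list(NULL, schema_names(schema)))
  rep_each <- 1L
  for (j in seq_along(card)) {
    m[, j] <- rep(rep(seq_len(card[[j]]), each = rep_each),
                  length.out = n_cells)
    rep_each <- rep_each * card[[j]]
  }
  m
}

# joint probability vector over all cells, in joint_cells() order.
# Computed in log space whenever any CPT entry is tiny, to guard underflow.
joint_vector <- function(network, cells = NULL) {
  schema <- network$schema
  card <- schema_cardinalities(schema)
  if (is.null(cells)) cells <- joint_cells(schema)
  tiny <- any(vapply(network$cpts,
                     function(ct) min(ct$prob) < 1e-12, logical(1L)))
  acc <- if (tiny) numeric(nrow(cells)) else rep(1, nrow(cells))
  for (node in network$structure$nodes) {
    ct <- network$cpts[[node]]
    idx <- cells[, node]
    mult <- card[[node]]
    for (p in ct$parents) {
      idx <- idx + mult * (cells[, p] - 1L)
      mult <- mult * card[[p]]
    }
    p <- as.numeric(ct$prob)[idx]
    if (tiny) acc <- acc + log(p) else acc <- acc * p
  }
  if (tiny) exp(acc) else acc
}

#' Joint probability of one complete assignment
#'
#' Product over nodes of the CPT entry of the node's state given its
#' parents' states — the factorization the network encodes.
#'
#' @param network A `bnaf_fitted`.
#' @param assignment Named character vector or list mapping every variable
#'   to a state.
#' @return A probability in `[0, 1]`.
#' @export
joint_probability <- function(network, assignment) {
  assignment <- unlist(assignment)
  nodes <- network$structure$nodes
  if (!setequal(names(assignment), nodes)) {
    stop("assignment must cover every node exactly once", call. = FALSE)
  }
  prob <- 1
  for (node in nodes) {
    ct <- network$cpts[[node]]
    states <- dimnames(ct$prob)[[1L]]
    k <- match(assignment[[node]], states)
    if (is.na(k)) {
      stop("'", assignment[[node]], "' is not a state of '", node, "'",
           call. = FALSE)
    }
    sub <- c(list(k), lapply(ct$parents, function(p) {
      match(assignment[[p]], dimnames(ct$prob)[[p]])
    }))
    prob <- prob * do.call(`[`, c(list(ct$prob), sub))
  }
  unname(prob)
}

#' Build evidence for a conditional query
#'
#' A partial assignment of observed variables; unassigned variables are
#' marginalized out by the query — the mechanism by which predictions
#' remain available when some clinical measurements are missing.
#'
#' @param ... Named states, e.g. `evidence(sex = "female", age = "over65")`,
#'   or a single named list/vector.
#' @return An object of class `bnaf_evidence`.
#' @export
evidence <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L &&
      (is.null(names(dots)) || !nzchar(names(dots)[1L]))) {
    dots <- as.list(dots[[1L]])
  }
  if (length(dots) && (is.null(names(dots)) || any(!nzchar(names(dots))))) {
    stop("every evidence entry must be named", call. = FALSE)
  }
  vals <- vapply(dots, function(x) as.character(x)[1L], character(1L))
  structure(list(assignments = as.list(vals)), class = "bnaf_evidence")
}

check_evidence <- function(ev, schema, target = NULL) {
  if (!inherits(ev, "bnaf_evidence")) ev <- evidence(ev)
  for (nm in names(ev$assignments)) {
    if (!nm %in% schema_names(schema)) {
      stop("evidence variable '", nm, "' is not in the schema", call. = FALSE)
    }
    st <- ev$assignments[[nm]]
    if (!st %in% schema_states(schema, nm)) {
      stop("'", st, "' is not a state of '", nm, "' (allowed: ",
           paste(schema_states(schema, nm), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  if (!is.null(target) && target %in% names(ev$assignments)) {
    stop("evidence must not assign the query target '", target, "'",
         call. = FALSE)
  }
  ev
}

#' Exact conditional-probability query
#'
#' Computes `P(target | evidence)` by summing the joint distribution over
#' every unassigned non-target variable and normalizing — exact inference,
#' feasible because the clinical state space is small. Variables absent
#' from the evidence are marginalized, so partial clinical profiles are
#' queried the same way as complete ones.
#'
#' @param network A `bnaf_fitted`.
#' @param target Variable to query (not in the evidence).
#' @param ev An [evidence()] object (or named list of states); empty
#'   evidence gives the marginal of `target`.
#' @param method `"enumeration"` (default) or `"ve"` (variable
#'   elimination); both are exact and agree to numerical precision.
#' @return An object of class `bnaf_query`: `target`, named probability
#'   vector `distribution` (sums to 1), and `evidence_used`.
#' @export
query <- function(network, target, ev = evidence(),
                  method = c("enumeration", "ve")) {
  method <- match.arg(method)
  schema <- network$schema
  if (!target %in% schema_names(schema)) {
    stop("unknown target '", target, "'", call. = FALSE)
  }
  ev <- check_evidence(ev, schema, target = target)
  dist <- if (method == "enumeration") {
    query_enumeration(network, target, ev)
  } else {
    query_ve(network, target, ev)
  }
  structure(list(target = target, distribution = dist, evidence_used = ev),
            class = "bnaf_query")
}

#' @export
print.bnaf_query <- function(x, ...) {
  cat("P(", x$target, " | ",
      if (length(x$evidence_used$assignments) == 0L) "no evidence" else
        paste(names(x$evidence_used$assignments), "=",
              unlist(x$evidence_used$assignments), collapse = ", "),
      ")\n", sep = "")
  print(round(x$distribution, 6))
  invisible(x)
}

query_enumeration <- function(network, target, ev) {
  schema <- network$schema
  cells <- joint_cells(schema)
  p <- joint_vector(network, cells)
  keep <- rep(TRUE, length(p))
  for (nm in names(ev$assignments)) {
    k <- match(ev$assignments[[nm]], schema_states(schema, nm))
    keep <- keep & cells[, nm] == k
  }
  states <- schema_states(schema, target)
  num <- vapply(seq_along(states), function(k) {
    sum(p[keep & cells[, target] == k])
  }, numeric(1L))
  tot <- sum(num)
  if (tot <= 0) {
    stop("impossible evidence: the observed configuration has probability 0 ",
         "under the network", call. = FALSE)
  }
  stats::setNames(num / tot, states)
}

# ---- variable elimination -------------------------------------------------

# a factor: list(vars = character vector, tab = array with dimnames)
cpt_factor <- function(ct) {
  vars <- c(ct$child, ct$parents)
  list(vars = vars, tab = ct$prob)
}

factor_reduce <- function(f, var, state) {
  if (!var %in% f$vars) return(f)
  i <- match(var, f$vars)
  k <- match(state, dimnames(f$tab)[[i]])
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[i]] <- k
  tab <- do.call(`[`, c(list(f$tab), idx, list(drop = FALSE)))
  dims <- dim(tab)[-i]
  dn <- dimnames(tab)[-i]
  if (length(dims) == 0L) {
    list(vars = character(0L), tab = as.numeric(tab))
  } else {
    list(vars = f$vars[-i], tab = array(tab, dims, dn))
  }
}

factor_multiply <- function(a, b) {
  if (length(a$vars) == 0L) return(list(vars = b$vars, tab = b$tab * as.numeric(a$tab)))
  if (length(b$vars) == 0L) return(list(vars = a$vars, tab = a$tab * as.numeric(b$tab)))
  vars <- union(a$vars, b$vars)
  dn <- stats::setNames(lapply(vars, function(v) {
    if (v %in% a$vars) dimnames(a$tab)[[match(v, a$vars)]]
    else dimnames(b$tab)[[match(v, b$vars)]]
  }), vars)
  dims <- vapply(dn, length, integer(1L))
  grid <- joint_cells_generic(dims)
  lin_index <- function(f) {
    pos <- match(f$vars, vars)
    idx <- grid[, pos[1L]]
    mult <- dims[[pos[1L]]]
    if (length(pos) > 1L) for (j in 2:length(pos)) {
      idx <- idx + mult * (grid[, pos[j]] - 1L)
      mult <- mult * dims[[pos[j]]]
    }
    idx
  }
  tab <- as.numeric(a$tab)[lin_index(a)] * as.numeric(b$tab)[lin_index(b)]
  list(vars = vars, tab = array(tab, dims, dn))
}

joint_cells_generic <- function(dims) {
  n_cells <- prod(dims)
  m <- matrix(0L, n_cells, length(dims))
  rep_each <- 1L
  for (j in seq_along(dims)) {
    m[, j] <- rep(rep(seq_len(dims[[j]]), each = rep_each),
                  length.out = n_cells)
    rep_each <- rep_each * dims[[j]]
  }
  m
}

factor_marginalize <- function(f, var) {
  if (!var %in% f$vars) return(f)
  if (length(f$vars) == 1L) {
    return(list(vars = character(0L), tab = sum(f$tab)))
  }
  i <- match(var, f$vars)
  tab <- apply(f$tab, seq_along(f$vars)[-i], sum)
  vars <- f$vars[-i]
  if (length(vars) == 0L) {
    list(vars = character(0L), tab = as.numeric(sum(f$tab)))
  } else {
    list(vars = vars, tab = as.array(tab))
  }
}

query_ve <- function(network, target, ev) {
  schema <- network$schema
  factors <- lapply(network$cpts, cpt_factor)
  for (nm in names(ev$assignments)) {
    factors <- lapply(factors, factor_reduce, var = nm,
                      state = ev$assignments[[nm]])
  }
  hidden <- setdiff(schema_names(schema),
                    c(target, names(ev$assignments)))
  for (var in hidden) {
    touching <- vapply(factors, function(f) var %in% f$vars, logical(1L))
    if (!any(touching)) next
    prod_f <- Reduce(factor_multiply, factors[touching])
    factors <- c(factors[!touching], list(factor_marginalize(prod_f, var)))
  }
  out <- Reduce(factor_multiply, factors)
  stopifnot(identical(out$vars, target) || setequal(out$vars, target))
  num <- as.numeric(out$tab)
  names(num) <- dimnames(as.array(out$tab))[[1L]]
  if (length(out$vars)) num <- num[schema_states(schema, target)]
  tot <- sum(num)
  if (tot <= 0) {
    stop("impossible evidence: the observed configuration has probability 0 ",
         "under the network", call. = FALSE)
  }
  num / tot
}

# ---- cohort-level prediction ---------------------------------------------

#' Expand a named predictor set
#'
#' `atlas5` is the five-variable clinical score set (age, sex, smoking,
#' preablation AF type, OSA as used here); `easy6` adds BMI — measurements
#' available without imaging; `full7` instead adds the two imaging-derived
#' variables, left-atrial volume and epicardial fat.
#'
#' @param name One of `"atlas5"`, `"easy6"`, `"full7"`, or a character
#'   vector of variable names (returned as-is).
#' @return Character vector of predictor names.
#' @export
predictor_set <- function(name) {
  if (length(name) != 1L) return(as.character(name))
  atlas5 <- c("age", "sex", "smoking", "af_type", "osa")
  switch(name,
         atlas5 = atlas5,
         easy6 = c(atlas5, "bmi"),
         full7 = c(atlas5, "la_volume", "epicardial_fat"),
         as.character(name))
}

# posterior of the outcome's positive state for every configuration of the
# predictor set, via one marginalization pass over the full joint
outcome_posterior_table <- function(network, predictors, outcome = NULL) {
  schema <- network$schema
  if (is.null(outcome)) outcome <- schema$outcome
  card <- schema_cardinalities(schema)
  cells <- joint_cells(schema)
  p <- joint_vector(network, cells)
  idx <- rep(1L, nrow(cells))
  mult <- 1L
  for (v in predictors) {
    idx <- idx + mult * (cells[, v] - 1L)
    mult <- mult * card[[v]]
  }
  q <- as.integer(mult)
  pos_state <- match("true", schema_states(schema, outcome))
  if (is.na(pos_state)) pos_state <- length(schema_states(schema, outcome))
  pos <- cells[, outcome] == pos_state
  num <- numeric(q); den <- numeric(q)
  agg_pos <- rowsum(p[pos], idx[pos])
  agg_all <- rowsum(p, idx)
  den[as.integer(rownames(agg_all))] <- agg_all
  num[as.integer(rownames(agg_pos))] <- agg_pos
  list(num = num, den = den, card = card[predictors])
}

#' Predict outcome probability for every cohort row
#'
#' For each patient, the variables in `predictors` are taken as evidence
#' and the exact posterior probability of the positive outcome state is
#' returned; all other variables (including any recorded but unused ones)
#' are marginalized out. Row order is preserved, and rows identical on the
#' predictor set receive identical probabilities.
#'
#' @param network A `bnaf_fitted`.
#' @param cohort A cohort over the network's schema (the outcome column,
#'   if present, is ignored as evidence).
#' @param predictors Predictor names or a [predictor_set()] name; may be
#'   empty, in which case every row gets the marginal outcome probability.
#' @return Numeric vector of probabilities, one per row.
#' @export
predict_cohort <- function(network, cohort, predictors = "full7") {
  schema <- network$schema
  predictors <- predictor_set(predictors)
  outcome <- schema$outcome
  if (outcome %in% predictors) {
    stop("the outcome cannot be a predictor", call. = FALSE)
  }
  bad <- setdiff(predictors, schema_names(schema))
  if (length(bad)) {
    stop("unknown predictor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(predictors) == 0L) {
    qr <- query(network, outcome)
    return(rep(unname(qr$distribution[["true"]]), nrow(cohort)))
  }
  tab <- outcome_posterior_table(network, predictors)
  codes <- cohort_codes(cohort)
  idx <- rep(1L, nrow(cohort))
  mult <- 1L
  for (v in predictors) {
    idx <- idx + mult * (codes[, v] - 1L)
    mult <- mult * tab$card[[v]]
  }
  den <- tab$den[idx]
  if (any(den <= 0)) {
    stop("impossible evidence: some rows have probability 0 under the network",
         call. = FALSE)
  }
  tab$num[idx] / den
}
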