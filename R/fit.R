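#' Construct a conditional probability table
#'
#' Probabilities of each child state for every configuration of the parent
#' states, stored as an array whose first dimension is the child. Every
#' column (fixed parent configuration) must sum to 1.
#'
#' @param child Child variable name.
#' @param parents Ordered character vector of parent names (may be empty).
#' @param prob Numeric array, `dim = c(r_child, r_parent1, ...)`, with
#'   `dimnames` naming the states.
#' @param pseudocount Per-cell Dirichlet pseudo-count used in fitting
#'   (0 for maximum likelihood).
#' @return An object of class `bnaf_cpt`.
#' @export
cpt <- function(child, parents, prob, pseudocount = 0) {
  prob <- as.array(prob)
  stopifnot(is.numeric(prob), pseudocount >= 0)
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) {
    stop("CPT entries must lie in [0, 1]", call. = FALSE)
  }
  r <- dim(prob)[1L]
  cols <- matrix(prob, nrow = r)
  sums <- colSums(cols)
  ok <- is.na(sums) | abs(sums - 1) < 1e-9
  if (!all(ok)) {
    stop("CPT for '", child, "': ", sum(!ok),
         " parent configuration(s) do not sum to 1", call. = FALSE)
  }
  structure(list(child = child, parents = as.character(parents),
                 prob = prob, pseudocount = pseudocount),
            class = "bnaf_cpt")
}

cpt_cardinalities <- function(x) dim(as.array(x$prob))

#' Fit conditional probability tables by Bayesian posterior estimation
#'
#' For each node X with `r` states and `q` parent configurations, the CPT
#' entry for state k under configuration j is the Dirichlet posterior mean
#' \deqn{(N_{jk} + \alpha) / (N_{j\cdot} + r\alpha),}
#' with uniform per-cell pseudo-counts \eqn{\alpha = ESS / (r q)} (a
#' BDeu-style prior: the equivalent sample size ESS is an imaginary sample
#' spread evenly over the CPT's cells). As ESS shrinks toward zero the fit
#' approaches maximum-likelihood frequencies wherever counts are nonzero.
#'
#' @param structure A `bnaf_structure` whose nodes equal the cohort's
#'   schema variables.
#' @param cohort A cohort from [as_cohort()]; an empty cohort yields the
#'   prior alone (every CPT uniform).
#' @param ess Equivalent sample size of the uniform prior; must be
#'   positive (default 1).
#' @return An object of class `bnaf_fitted`: the structure, one `bnaf_cpt`
#'   per node, and the ess used.
#' @export
fit_cpts <- function(structure, cohort, ess = 1) {
  if (!is.numeric(ess) || length(ess) != 1L || is.na(ess) || ess <= 0) {
    stop("ess must be a single positive number", call. = FALSE)
  }
  schema <- cohort_schema(cohort)
  if (!setequal(structure$nodes, schema_names(schema))) {
    stop("structure nodes do not match the cohort schema", call. = FALSE)
  }
  n <- nrow(cohort)
  codes <- if (n) cohort_codes(cohort) else NULL
  card <- schema_cardinalities(schema)
  cpts <- lapply(structure$nodes, function(node) {
    pars <- parents_of(structure, node)
    r <- card[[node]]
    q <- if (length(pars)) prod(card[pars]) else 1L
    counts <- if (n) {
      idx <- codes[, node]
      if (length(pars)) {
        mult <- r
        for (p in pars) {
          idx <- idx + mult * (codes[, p] - 1L)
          mult <- mult * card[[p]]
        }
      }
      tabulate(idx, nbins = r * q)
    } else {
      numeric(r * q)
    }
    alpha <- ess / (r * q)
    m <- matrix(counts + alpha, nrow = r)
    prob <- sweep(m, 2L, colSums(m), "/")
    dims <- c(r, if (length(pars)) card[pars])
    dn <- c(list(schema_states(schema, node)),
            lapply(pars, function(p) schema_states(schema, p)))
    names(dn) <- c(node, pars)
    cpt(node, pars, array(prob, dim = dims, dimnames = dn),
        pseudocount = alpha)
  })
  names(cpts) <- structure$nodes
  structure(list(structure = structure, cpts = cpts, ess = ess,
                 schema = schema),
            class = "bnaf_fitted")
}

#' Assemble a fitted network from explicit CPTs
#'
#' Builds a `bnaf_fitted` from a structure and hand-specified [cpt()]s —
#' useful for encoding a known distribution directly. Each CPT's parent
#' set must equal the node's parents in the structure.
#'
#' @param structure A `bnaf_structure`.
#' @param cpts Named list with one `bnaf_cpt` per node.
#' @param schema The [domain_schema()] the network is defined over.
#' @param ess Equivalent sample size to record (NA when not fitted from
#'   data).
#' @return A `bnaf_fitted`.
#' @export
fitted_network <- function(structure, cpts, schema, ess = NA_real_) {
  stopifnot(setequal(structure$nodes, schema_names(schema)))
  if (!setequal(names(cpts), structure$nodes)) {
    stop("cpts must be a named list covering every node", call. = FALSE)
  }
  for (node in structure$nodes) {
    ct <- cpts[[node]]
    if (!inherits(ct, "bnaf_cpt")) stop("cpts must be bnaf_cpt objects",
                                        call. = FALSE)
    if (!setequal(ct$parents, parents_of(structure, node)) ||
        !identical(ct$child, node)) {
      stop("CPT for '", node, "' does not match the structure's parent set",
           call. = FALSE)
    }
  }
  structure(list(structure = structure, cpts = cpts[structure$nodes],
                 ess = ess, schema = schema),
            class = "bnaf_fitted")
}

#' @export
print.bnaf_fitted <- function(x, ...) {
  cat("Fitted network:", length(x$cpts), "nodes, ess =", x$ess, "\n")
  invisible(x)
}

#' Log-likelihood of a cohort under a fitted network
#'
#' Sum over rows of the log joint probability; by the factorization of the
#' joint, equal to the sum of per-node log CPT entries. A zero-probability
#' cell (possible only with pseudocount 0) yields `-Inf` with attribute
#' `zero_cells` giving how many row-node terms vanished.
#'
#' @param network A `bnaf_fitted`.
#' @param cohort A cohort over the same schema.
#' @return Nonpositive number (or `-Inf`, flagged).
#' @export
loglikelihood <- function(network, cohort) {
  schema <- cohort_schema(cohort)
  if (!setequal(schema_names(schema), network$structure$nodes)) {
    stop("cohort schema does not match the network", call. = FALSE)
  }
  codes <- cohort_codes(cohort)
  card <- schema_cardinalities(schema)
  total <- 0
  zero_cells <- 0L
  for (node in network$structure$nodes) {
    ct <- network$cpts[[node]]
    idx <- codes[, node]
    mult <- card[[node]]
    for (p in ct$parents) {
      idx <- idx + mult * (codes[, p] - 1L)
      mult <- mult * card[[p]]
    }
    p <- as.numeric(ct$prob)[idx]
    zero_cells <- zero_cells + sum(p == 0)
    total <- total + sum(log(p))
  }
  if (zero_cells > 0L) {
    total <- -Inf
    attr(total, "zero_cells") <- zero_cells
  }
  total
}
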