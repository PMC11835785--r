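# Local BIC machinery. Counts are accumulated over integer state codes, so
# a single pass over the rows scores one (child, parent set) pair; scores
# are cached per pair during hill climbing because a single-arc move only
# changes the local score of the affected child (decomposability).

local_bic <- function(codes, card, child, parents) {
  n <- nrow(codes)
  r <- card[[child]]
  q <- if (length(parents)) prod(card[parents]) else 1L
  idx <- codes[, child]
  mult <- r
  for (p in parents) {
    idx <- idx + mult * (codes[, p] - 1L)
    mult <- mult * card[[p]]
  }
  njk <- tabulate(idx, nbins = r * q)
  m <- matrix(njk, nrow = r)
  nj <- colSums(m)
  pos <- njk > 0
  ll <- sum(njk[pos] * log(njk[pos] / rep(nj, each = r)[pos]))
  ll - log(n) / 2 * q * (r - 1)
}

#' BIC score of a network structure
#'
#' Decomposable score: for each node, the maximized multinomial
#' log-likelihood of the node given its parents minus a complexity penalty
#' of `log(n)/2` per free parameter (`q * (r - 1)` for a node with `r`
#' states and `q` parent configurations). Higher is better; the total is
#' the sum of the per-node local scores.
#'
#' @param structure A `bnaf_structure` over the cohort's variables.
#' @param cohort A cohort with at least one row.
#' @return An object of class `bnaf_score`: `total`, `per_node`, `n`,
#'   `score_name = "bic"`.
#' @export
bic_score <- function(structure, cohort) {
  schema <- cohort_schema(cohort)
  if (!setequal(structure$nodes, schema_names(schema))) {
    stop("structure nodes do not match the cohort schema", call. = FALSE)
  }
  if (nrow(cohort) < 1L) stop("cohort must have at least one row", call. = FALSE)
  codes <- cohort_codes(cohort)
  card <- schema_cardinalities(schema)
  per_node <- vapply(structure$nodes, function(node) {
    local_bic(codes, card, node, parents_of(structure, node))
  }, numeric(1L))
  structure(list(total = sum(per_node), per_node = per_node,
                 n = nrow(cohort), score_name = "bic"),
            class = "bnaf_score")
}

#' @export
print.bnaf_score <- function(x, ...) {
  cat("BIC score:", format(x$total), "(n =", x$n, ")\n")
  invisible(x)
}

#' Learn a structure by constraint-respecting hill climbing
#'
#' Greedy search over single-arc moves (add, delete, reverse), maximizing
#' the BIC score. The search starts from the whitelist-only graph; moves
#' never delete or reverse a whitelisted arc, never add a blacklisted arc
#' (nor one whose addition a reversal would imply), and never create a
#' directed cycle. At each step the best strictly improving move is taken;
#' ties are broken by enumerating candidates in lexicographic
#' (operation, parent, child) order and keeping the first maximum, so the
#' result is deterministic. The search stops when no move improves the
#' score.
#'
#' @param cohort A complete cohort.
#' @param constraints An [arc_constraints()] object (default: none).
#' @param max_parents Optional cap on the number of parents per node
#'   (default unbounded).
#' @param epsilon Minimum score gain to accept a move.
#' @return A `bnaf_structure` carrying the constraints used.
#' @export
hill_climb <- function(cohort, constraints = arc_constraints(),
                       max_parents = Inf, epsilon = 1e-9) {
  schema <- cohort_schema(cohort)
  nodes <- schema_names(schema)
  bad <- setdiff(c(constraints$whitelist, constraints$blacklist), nodes)
  if (length(bad)) {
    stop("constraints mention unknown node(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(arc_keys(constraints$whitelist),
                       arc_keys(constraints$blacklist)))) {
    stop("contradictory constraints: whitelist and blacklist overlap",
         call. = FALSE)
  }
  if (!is_acyclic(nodes, constraints$whitelist)) {
    stop("contradictory constraints: whitelist is cyclic", call. = FALSE)
  }
  codes <- cohort_codes(cohort)
  card <- schema_cardinalities(schema)
  cache <- new.env(parent = emptyenv())
  score_node <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- local_bic(codes, card, child, parents)
      cache[[key]] <- got
    }
    got
  }

  arcs <- as_arc_matrix(constraints$whitelist)
  wl_keys <- arc_keys(constraints$whitelist)
  bl_keys <- arc_keys(constraints$blacklist)
  local <- vapply(nodes, function(v) {
    score_node(v, arcs[arcs[, 2L] == v, 1L])
  }, numeric(1L))

  # candidate ordering: nodes sorted lexicographically, operations in
  # add < delete < reverse order
  snodes <- sort(nodes)
  repeat {
    best <- NULL
    consider <- function(op, from, to, gain, new_arcs) {
      if (gain > epsilon && (is.null(best) || gain > best$gain + epsilon)) {
        best <<- list(op = op, from = from, to = to, gain = gain,
                      new_arcs = new_arcs)
      }
    }
    for (from in snodes) for (to in snodes) {
      if (from == to) next
      key <- paste(from, to, sep = "\r")
      present <- key %in% arc_keys(arcs)
      if (!present) {
        # add
        if (key %in% bl_keys) next
        if (path_exists(arcs, to, from)) next
        pars <- arcs[arcs[, 2L] == to, 1L]
        if (length(pars) + 1L > max_parents) next
        gain <- score_node(to, c(pars, from)) - local[[to]]
        consider("add", from, to, gain, rbind(arcs, c(from, to)))
      }
    }
    for (from in snodes) for (to in snodes) {
      if (from == to) next
      key <- paste(from, to, sep = "\r")
      if (!key %in% arc_keys(arcs) || key %in% wl_keys) next
      # delete
      pars <- arcs[arcs[, 2L] == to, 1L]
      gain <- score_node(to, setdiff(pars, from)) - local[[to]]
      keep <- !(arcs[, 1L] == from & arcs[, 2L] == to)
      consider("delete", from, to, gain, arcs[keep, , drop = FALSE])
    }
    for (from in snodes) for (to in snodes) {
      if (from == to) next
      key <- paste(from, to, sep = "\r")
      if (!key %in% arc_keys(arcs) || key %in% wl_keys) next
      rev_key <- paste(to, from, sep = "\r")
      if (rev_key %in% bl_keys) next
      # reverse from->to into to->from
      keep <- !(arcs[, 1L] == from & arcs[, 2L] == to)
      without <- arcs[keep, , drop = FALSE]
      if (path_exists(without, from, to)) next
      pars_from <- c(without[without[, 2L] == from, 1L], to)
      if (length(pars_from) > max_parents) next
      pars_to <- without[without[, 2L] == to, 1L]
      gain <- (score_node(to, pars_to) - local[[to]]) +
        (score_node(from, pars_from) - local[[from]])
      consider("reverse", from, to, gain, rbind(without, c(to, from)))
    }
    if (is.null(best)) break
    arcs <- best$new_arcs
    affected <- if (best$op == "reverse") c(best$from, best$to) else best$to
    for (v in affected) {
      local[[v]] <- score_node(v, arcs[arcs[, 2L] == v, 1L])
    }
  }
  network_structure(nodes, arcs = arcs,
                    whitelist = constraints$whitelist,
                    blacklist = constraints$blacklist)
}
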