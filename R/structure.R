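#' Build a network structure (DAG with arc constraints)
#'
#' @param nodes Character vector of variable names.
#' @param arcs Two-column character matrix (from, to), or an empty set.
#' @param whitelist Arcs that must be present (subset of `arcs`).
#' @param blacklist Arcs that must be absent.
#' @return An object of class `bnaf_structure`.
#' @export
network_structure <- function(nodes, arcs = empty_arcs(),
                              whitelist = empty_arcs(),
                              blacklist = empty_arcs()) {
  nodes <- as.character(nodes)
  stopifnot(length(nodes) >= 1L, !anyDuplicated(nodes))
  arcs <- as_arc_matrix(arcs)
  whitelist <- as_arc_matrix(whitelist)
  blacklist <- as_arc_matrix(blacklist)
  for (m in list(arcs, whitelist, blacklist)) {
    bad <- setdiff(c(m), nodes)
    if (length(bad)) {
      stop("arc endpoint(s) not in node set: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(arcs[, 1L] == arcs[, 2L])) stop("self-loop arc", call. = FALSE)
  if (anyDuplicated(arc_keys(arcs))) stop("duplicated arc", call. = FALSE)
  if (length(setdiff(arc_keys(whitelist), arc_keys(arcs)))) {
    stop("whitelist arcs must all be present in the arc set", call. = FALSE)
  }
  if (length(intersect(arc_keys(arcs), arc_keys(blacklist)))) {
    stop("arc set intersects the blacklist", call. = FALSE)
  }
  if (length(intersect(arc_keys(whitelist), arc_keys(blacklist)))) {
    stop("whitelist and blacklist overlap", call. = FALSE)
  }
  st <- structure(list(nodes = nodes, arcs = arcs,
                       whitelist = whitelist, blacklist = blacklist),
                  class = "bnaf_structure")
  if (is.null(topological_order(st))) {
    stop("arc set contains a directed cycle", call. = FALSE)
  }
  st
}

#' @export
print.bnaf_structure <- function(x, ...) {
  cat("Network structure:", length(x$nodes), "nodes,", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs)) {
    wl <- arc_keys(x$arcs) %in% arc_keys(x$whitelist)
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L],
               ifelse(wl, "  [whitelisted]", ""), collapse = "\n"), "\n")
  }
  invisible(x)
}

empty_arcs <- function() {
  matrix(character(0L), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

as_arc_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(empty_arcs())
  }
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, lapply(x, unlist))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.character(x) && is.null(dim(x)) && length(x) == 2L) {
    x <- matrix(x, ncol = 2L)
  }
  stopifnot(is.matrix(x), ncol(x) == 2L)
  x <- matrix(as.character(x), ncol = 2L)
  colnames(x) <- c("from", "to")
  x
}

arc_keys <- function(arcs) {
  if (nrow(arcs) == 0L) return(character(0L))
  paste(arcs[, 1L], arcs[, 2L], sep = "\r")
}

has_arc <- function(arcs, from, to) {
  any(arcs[, 1L] == from & arcs[, 2L] == to)
}

parents_of <- function(structure, node) {
  structure$arcs[structure$arcs[, 2L] == node, 1L]
}

# Kahn's algorithm; NULL if cyclic
topological_order <- function(structure) {
  nodes <- structure$nodes
  arcs <- structure$arcs
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(arcs)) {
    tab <- table(arcs[, 2L])
    indeg[names(tab)] <- as.integer(tab)
  }
  order <- character(0L)
  queue <- nodes[indeg == 0L]
  remaining <- arcs
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, v)
    if (nrow(remaining)) {
      out <- remaining[, 1L] == v
      for (w in remaining[out, 2L]) {
        indeg[[w]] <- indeg[[w]] - 1L
        if (indeg[[w]] == 0L) queue <- c(queue, w)
      }
      remaining <- remaining[!out, , drop = FALSE]
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

#' Test whether an arc set is acyclic
#'
#' @param nodes Node names.
#' @param arcs Two-column arc matrix.
#' @return Logical.
#' @export
is_acyclic <- function(nodes, arcs) {
  st <- structure(list(nodes = nodes, arcs = as_arc_matrix(arcs)),
                  class = "bnaf_structure")
  !is.null(topological_order(st))
}

# does a directed path from -> to exist?
path_exists <- function(arcs, from, to) {
  if (nrow(arcs) == 0L) return(FALSE)
  frontier <- from
  seen <- character(0L)
  while (length(frontier)) {
    nxt <- unique(arcs[arcs[, 1L] %in% frontier, 2L])
    if (to %in% nxt) return(TRUE)
    seen <- union(seen, frontier)
    frontier <- setdiff(nxt, seen)
  }
  FALSE
}

#' Build arc constraints
#'
#' @param whitelist Arcs forced into the structure (must be acyclic on
#'   their own).
#' @param blacklist Arcs that may never be added.
#' @return An object of class `bnaf_constraints`.
#' @export
arc_constraints <- function(whitelist = empty_arcs(), blacklist = empty_arcs()) {
  whitelist <- as_arc_matrix(whitelist)
  blacklist <- as_arc_matrix(blacklist)
  if (length(intersect(arc_keys(whitelist), arc_keys(blacklist)))) {
    stop("whitelist and blacklist overlap", call. = FALSE)
  }
  nodes <- unique(c(whitelist, blacklist))
  if (nrow(whitelist) && !is_acyclic(unique(c(whitelist)), whitelist)) {
    stop("whitelist alone is cyclic", call. = FALSE)
  }
  structure(list(whitelist = whitelist, blacklist = blacklist),
            class = "bnaf_constraints")
}

#' Default clinical arc constraints
#'
#' The knowledge-driven constraint set used throughout: the seven
#' established relapse predictors (the five ATLAS variables plus epicardial
#' fat and OSA) are whitelisted into the outcome, the configured risk-factor
#' arcs feed diabetes / high blood pressure / OSA, and every arc out of the
#' outcome is blacklisted (relapse is a sink). Shipped as an editable JSON
#' file under `extdata` so that structure-dependent analyses read one
#' source of truth.
#'
#' @param path Constraints JSON file; defaults to the packaged file.
#' @return A `bnaf_constraints` object.
#' @export
default_constraints <- function(path = system.file("extdata",
                                                   "default_constraints.json",
                                                   package = "bnaf")) {
  read_constraints_json(path)
}

#' Read / write arc constraints as JSON
#'
#' Format: `{"whitelist": [[from, to], ...], "blacklist": [[from, to], ...]}`.
#'
#' @param path File path.
#' @param constraints A `bnaf_constraints` object.
#' @return `read_constraints_json` returns a `bnaf_constraints`.
#' @export
read_constraints_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  arc_constraints(whitelist = x$whitelist, blacklist = x$blacklist)
}

#' @rdname read_constraints_json
#' @export
write_constraints_json <- function(constraints, path) {
  jsonlite::write_json(list(whitelist = constraints$whitelist,
                            blacklist = constraints$blacklist),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write a structure as JSON, and export DOT
#'
#' Structure JSON: `{"nodes": [...], "arcs": [[from, to], ...],
#' "whitelist": [...], "blacklist": [...]}`. The DOT export classes arcs as
#' whitelisted (grey, expert knowledge) versus learned (orange, found by
#' the search) for rendering with graphviz.
#'
#' @param structure A `bnaf_structure`.
#' @param path File path.
#' @return `read_structure_json` returns a `bnaf_structure`.
#' @export
write_structure_json <- function(structure, path) {
  jsonlite::write_json(list(nodes = structure$nodes, arcs = structure$arcs,
                            whitelist = structure$whitelist,
                            blacklist = structure$blacklist),
                       path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  network_structure(x$nodes, arcs = x$arcs,
                    whitelist = x$whitelist, blacklist = x$blacklist)
}

#' @rdname write_structure_json
#' @export
write_dot <- function(structure, path) {
  wl <- arc_keys(structure$arcs) %in% arc_keys(structure$whitelist)
  lines <- c("digraph bn {",
             "  rankdir=LR;",
             paste0("  \"", structure$nodes, "\";"))
  if (nrow(structure$arcs)) {
    col <- ifelse(wl, "grey40", "orange")
    cls <- ifelse(wl, "whitelisted", "learned")
    lines <- c(lines,
               paste0("  \"", structure$arcs[, 1L], "\" -> \"",
                      structure$arcs[, 2L], "\" [color=", col,
                      ", class=", cls, "];"))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' Structural Hamming distance between two DAGs
#'
#' Number of single-arc edits (insertion, deletion, reversal) needed to turn
#' one arc set into the other; a reversed arc counts once.
#'
#' @param a,b `bnaf_structure` objects over the same node set.
#' @return Nonnegative integer; zero iff the arc sets are identical.
#' @export
structural_hamming_distance <- function(a, b) {
  if (!setequal(a$nodes, b$nodes)) stop("node sets differ", call. = FALSE)
  ka <- arc_keys(a$arcs); kb <- arc_keys(b$arcs)
  ra <- arc_keys(a$arcs[, 2:1, drop = FALSE])
  only_a <- setdiff(ka, kb); only_b <- setdiff(kb, ka)
  # an arc unique to a whose reversal is unique to b: one reversal, not two edits
  reversed <- intersect(ra[ka %in% only_a], only_b)
  length(only_a) + length(only_b) - length(reversed)
}
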