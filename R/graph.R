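#' Weighted directed graph over named variables
#'
#' Lightweight edge-list container used between ensemble aggregation and
#' reporting. No self-loops; at most one edge per ordered pair; zero
#' weights are not edges.
#'
#' @param nodes character vector of node names.
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @return object of class `weighted_digraph`.
#' @export
weighted_digraph <- function(nodes, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  edges <- edges[, c("from", "to", "weight")]
  if (nrow(edges)) {
    stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
              all(edges$weight != 0), all(is.finite(edges$weight)))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges for an ordered pair")
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "weighted_digraph")
}

#' Build a graph from a weight matrix
#'
#' `W[i, j]` is the effect of column j on row i; entries with
#' `|W| > threshold` become edges `j -> i`.
#'
#' @param W square weight matrix with dimnames.
#' @param threshold retain edges with absolute weight strictly above this.
#' @export
graph_from_matrix <- function(W, threshold = 0) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W), !is.null(rownames(W)))
  idx <- which(abs(W) > threshold & row(W) != col(W), arr.ind = TRUE)
  edges <- data.frame(from = colnames(W)[idx[, "col"]],
                      to = rownames(W)[idx[, "row"]],
                      weight = W[idx], stringsAsFactors = FALSE)
  weighted_digraph(rownames(W), edges)
}

#' @export
print.weighted_digraph <- function(x, ...) {
  cat("<weighted_digraph> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Resolve bidirectional edges by keeping the stronger direction
#'
#' Whenever both `a -> b` and `b -> a` are present, only the direction with
#' the larger absolute weight is retained. Exact ties are broken in favor
#' of the lexicographically smaller (source, target) pair, with a warning.
#'
#' @param g a [weighted_digraph()].
#' @return graph with no bidirectional pairs; dropped edges in attribute
#'   `resolved`.
#' @export
resolve_bidirectional <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  e <- g$edges
  if (!nrow(e)) return(g)
  key <- paste(e$from, e$to, sep = "\r")
  rev_key <- paste(e$to, e$from, sep = "\r")
  drop <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    j <- match(rev_key[i], key)
    if (is.na(j) || drop[i] || drop[j]) next
    wi <- abs(e$weight[i]); wj <- abs(e$weight[j])
    if (wi > wj) {
      drop[j] <- TRUE
    } else if (wj > wi) {
      drop[i] <- TRUE
    } else {
      # tie: keep the lexicographically smaller (source, target)
      keep_i <- order(c(key[i], key[j]))[1L] == 1L
      drop[if (keep_i) j else i] <- TRUE
      warning("bidirectional tie between ", e$from[i], " and ", e$to[i],
              ": kept ", if (keep_i) key[i] else key[j], " by lexicographic order")
    }
  }
  out <- weighted_digraph(g$nodes, e[!drop, , drop = FALSE])
  attr(out, "resolved") <- e[drop, , drop = FALSE]
  out
}

# Deterministic DFS cycle finder: nodes and neighbors visited in sorted
# order; returns the edge rows of one directed cycle, or NULL if acyclic.
.find_cycle <- function(g) {
  e <- g$edges
  if (!nrow(e)) return(NULL)
  nodes <- sort(unique(c(e$from, e$to)))
  adj <- lapply(stats::setNames(nodes, nodes),
                function(v) sort(e$to[e$from == v]))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 stack, 2 done
  stack <- character(0)
  cycle <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in adj[[v]]) {
      if (!is.null(cycle)) return()
      if (color[w] == 1L) {
        ring <- c(stack[seq(match(w, stack), length(stack))], w)
        cycle <<- data.frame(from = ring[-length(ring)], to = ring[-1],
                             stringsAsFactors = FALSE)
        return()
      }
      if (color[w] == 0L) visit(w)
    }
    stack <<- stack[-length(stack)]
    color[v] <<- 2L
  }
  for (v in nodes) {
    if (color[v] == 0L && is.null(cycle)) visit(v)
  }
  cycle
}

#' Repair cycles by iteratively removing the weakest edge
#'
#' While a directed cycle exists, one cycle is located (deterministic
#' depth-first search in sorted node order) and its minimum-absolute-weight
#' edge is removed; magnitude ties fall to the lexicographically smallest
#' (source, target) pair. Each step removes one edge, so termination is
#' guaranteed. The removed edges are kept in attribute `removed`.
#'
#' @param g a [weighted_digraph()] with no bidirectional pairs.
#' @return an acyclic [weighted_digraph()].
#' @export
make_acyclic <- function(g) {
  stopifnot(inherits(g, "weighted_digraph"))
  removed <- g$edges[0, , drop = FALSE]
  repeat {
    cyc <- .find_cycle(g)
    if (is.null(cyc)) break
    e <- g$edges
    key <- paste(e$from, e$to, sep = "\r")
    in_cycle <- key %in% paste(cyc$from, cyc$to, sep = "\r")
    cand <- e[in_cycle, , drop = FALSE]
    cand <- cand[order(abs(cand$weight), cand$from, cand$to), , drop = FALSE]
    victim <- cand[1L, , drop = FALSE]
    removed <- rbind(removed, victim)
    keep <- !(e$from == victim$from & e$to == victim$to)
    g <- weighted_digraph(g$nodes, e[keep, , drop = FALSE])
  }
  # independent acyclicity assertion via igraph
  if (nrow(g$edges) &&
      !igraph::is_dag(igraph::graph_from_data_frame(g$edges[, 1:2],
                                                    vertices = g$nodes)))
    stop("internal error: cycle repair left a cyclic graph")
  attr(g, "removed") <- removed
  g
}

#' Parents of the outcome node, strongest first
#'
#' @param g a [weighted_digraph()].
#' @param outcome outcome node name.
#' @return character vector of source nodes of edges into the outcome,
#'   ordered by decreasing absolute weight; the weights are attached as
#'   names-preserving attribute `weights`.
#' @export
select_outcome_parents <- function(g, outcome) {
  stopifnot(inherits(g, "weighted_digraph"))
  if (!outcome %in% g$nodes) stop("outcome node not in graph: ", outcome)
  e <- g$edges[g$edges$to == outcome, , drop = FALSE]
  e <- e[order(-abs(e$weight), e$from), , drop = FALSE]
  structure(e$from, weights = stats::setNames(e$weight, e$from))
}

#' Export a graph's edge list as CSV, JSON, or DOT
#'
#' @param g a [weighted_digraph()].
#' @param path output path.
#' @export
write_edges_csv <- function(g, path) {
  utils::write.csv(g$edges, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_csv
#' @export
write_edges_json <- function(g, path) {
  jsonlite::write_json(list(nodes = g$nodes, edges = g$edges), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_edges_csv
#' @export
write_dot <- function(g, path) {
  lines <- c("digraph causal {",
             sprintf("  \"%s\";", g$nodes))
  if (nrow(g$edges)) {
    style <- ifelse(abs(g$edges$weight) > 0.20, "solid", "dashed")
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.3f\", style=%s];",
      g$edges$from, g$edges$to, g$edges$weight, style))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
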