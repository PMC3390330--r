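#' Count closed loops of a chord diagram
#'
#' The diagram is fattened into a graph: one vertex per paired position,
#' bidirected arcs between the two positions of each pair, and backbone
#' edges between rank-consecutive vertices, closed into a cycle (the last
#' rank succeeds to the first). A loop alternates arc and backbone steps;
#' `count_loops` walks the graph marking directed arcs as visited and
#' counts the loops traversed, per the classic fatgraph boundary-cycle
#' construction.
#'
#' @param d A `pk_diagram` (or token / structure coercible to one).
#' @param method `"traversal"` (explicit walk, the default) or
#'   `"cycles"` (permutation-cycle formulation, used as an internal
#'   cross-check: with `sigma` the pairing involution and `tau` the cyclic
#'   rank successor, L is the number of cycles of `tau o sigma`).
#' @return Integer L, the number of closed loops.
#' @examples
#' count_loops(token_diagram("ABAB"))    # 1
#' count_loops(token_diagram("ABACBC"))  # 2
#' @export
count_loops <- function(d, method = c("traversal", "cycles")) {
  method <- match.arg(method)
  d <- as_pk_diagram(d)
  arcs <- d$arcs
  P <- nrow(arcs)
  if (P == 0L) return(0L)
  n2 <- 2L * P
  # rank endpoints 1..2P; sigma = partner rank
  ends <- as.vector(t(arcs))
  rk <- rank(ends)
  sigma <- integer(n2)
  for (r in seq_len(P)) {
    a <- rk[2L * r - 1L]; b <- rk[2L * r]
    sigma[a] <- b; sigma[b] <- a
  }
  if (method == "cycles") return(perm_cycle_count(sigma, n2))
  # explicit traversal with visited marks on directed arcs: from a vertex
  # with an unvisited outgoing arc, cross the arc, then step along the
  # backbone successor edge; when the walk returns to a visited arc the
  # loop closes and a new start vertex is sought.
  arc_visited <- logical(n2)  # outgoing directed arc of each vertex
  L <- 0L
  v <- 1L
  while (!is.na(v)) {
    if (arc_visited[v]) {
      # walk returned to a visited arc: one loop closed
      L <- L + 1L
      v <- which(!arc_visited)[1L]
    } else {
      arc_visited[v] <- TRUE
      w <- sigma[v]                      # cross the base-pair arc
      v <- if (w == n2) 1L else w + 1L   # backbone successor edge
    }
  }
  L
}

# Number of cycles of the map r -> tau(sigma(r)) on 1..n2.
perm_cycle_count <- function(sigma, n2) {
  nxt <- sigma %% n2 + 1L
  seen <- logical(n2)
  L <- 0L
  for (s in seq_len(n2)) {
    if (seen[s]) next
    L <- L + 1L
    r <- s
    while (!seen[r]) {
      seen[r] <- TRUE
      r <- nxt[r]
    }
  }
  L
}

#' Genus of a chord diagram
#'
#' With P base pairs and L closed loops (see [count_loops]), the genus is
#' `g = (P - L + 1) / 2`; the empty diagram has genus 0. The genus is 0
#' exactly for pseudoknot-free diagrams and positive as soon as arcs
#' cross; it is invariant under stem collapse and additive over primitive
#' components.
#'
#' @param d A `pk_diagram`, pattern token string, or [rna_structure]
#'   (taken as one whole diagram).
#' @return List of class `pk_genus` with fields `P`, `L`, `g`.
#' @examples
#' genus_of("ABAB")$g      # 1
#' genus_of("ABCACDBD")$g  # 2
#' @export
genus_of <- function(d) {
  d <- as_pk_diagram(d)
  P <- nrow(d$arcs)
  if (P == 0L)
    return(structure(list(P = 0L, L = 0L, g = 0L), class = "pk_genus"))
  L <- count_loops(d)
  num <- P - L + 1L
  if (num < 0L || num %% 2L != 0L)
    stop(sprintf("internal consistency error: P = %d, L = %d", P, L))
  structure(list(P = P, L = L, g = num %/% 2L), class = "pk_genus")
}

#' @export
print.pk_genus <- function(x, ...) {
  cat(sprintf("P = %d base pairs, L = %d closed loops, genus g = %d\n",
              x$P, x$L, x$g))
  invisible(x)
}

#' @rdname genus_of
#' @param token A pattern token string such as `"ABACBC"`.
#' @export
genus_of_token <- function(token) genus_of(token_diagram(token))

#' Total genus of a secondary structure
#'
#' Sum of the genera of the primitive components, which equals the genus
#' of the whole structure taken as one diagram (genus is additive over
#' the decomposition).
#'
#' @param s An [rna_structure].
#' @return Integer total genus.
#' @examples
#' total_genus(parse_dotbracket("([)]([)]([)]"))  # 3
#' @export
total_genus <- function(s) {
  comps <- extract_primitive(s)
  if (length(comps) == 0L) return(0L)
  sum(vapply(comps, function(co) genus_of(co$diagram)$g, integer(1)))
}
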