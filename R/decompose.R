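#' Split a structure into irreducible components
#'
#' Scans the backbone keeping a count of pairs that span each position;
#' wherever no pair spans the gap between two positions the structure can
#' be cut, which is exactly where a per-family bracket count in
#' dot-bracket notation returns to zero. Segments without pairs are
#' dropped. Original coordinates are preserved in the returned diagrams.
#'
#' @param s An [rna_structure] or `pk_diagram`.
#' @return List of `pk_diagram`, left to right; empty list if no pairs.
#' @examples
#' split_irreducible(parse_dotbracket("((..))((..))"))
#' @export
split_irreducible <- function(s) {
  d <- as_pk_diagram(s)
  arcs <- d$arcs
  if (nrow(arcs) == 0L) return(list())
  # component id by overlap of arc spans: sweep by left endpoint,
  # cutting whenever the running maximum right end is passed
  out <- list()
  start <- 1L
  reach <- arcs[1L, 2L]
  for (r in seq_len(nrow(arcs))) {
    if (arcs[r, 1L] > reach) {
      out[[length(out) + 1L]] <- pk_diagram(arcs[start:(r - 1L), , drop = FALSE])
      start <- r
      reach <- arcs[r, 2L]
    } else reach <- max(reach, arcs[r, 2L])
  }
  out[[length(out) + 1L]] <- pk_diagram(arcs[start:nrow(arcs), , drop = FALSE])
  out
}

#' Crossing closure of the leftmost arc
#'
#' Seeds with the leftmost arc of an irreducible diagram and repeatedly
#' adds every arc that crosses a member until a fixpoint: the non-nested
#' arc set of the component. Arcs `(a,b)` and `(x,y)` cross iff
#' `a < x < b < y` or `x < a < y < b`.
#'
#' @param d A `pk_diagram` (irreducible).
#' @return Two-column matrix: the arcs in the closure.
#' @export
nonnested_closure <- function(d) {
  d <- as_pk_diagram(d)
  arcs <- d$arcs
  n <- nrow(arcs)
  if (n == 0L) return(arcs)
  M <- crossing_matrix(arcs)
  inc <- logical(n)
  inc[which.min(arcs[, 1L])] <- TRUE
  repeat {
    new <- which(!inc & apply(M[, inc, drop = FALSE], 1L, any))
    if (length(new) == 0L) break
    inc[new] <- TRUE
  }
  arcs[inc, , drop = FALSE]
}

#' Primitive component of a structure
#'
#' A primitive component is irreducible (cannot be cut at a backbone
#' point) and non-nested (the crossing closure of its leftmost arc covers
#' all of its arcs). Original coordinates are preserved; the gaps left by
#' extracted nested parts are rank gaps and semantically inert.
#'
#' @param diagram A `pk_diagram` of the component's arcs.
#' @param origin Identifier of the source structure, or `NA`.
#' @return Object of class `pk_component` with fields `diagram`, `span`
#'   (leftmost and rightmost paired position) and `origin`.
#' @export
pk_component <- function(diagram, origin = NA_character_) {
  diagram <- as_pk_diagram(diagram)
  arcs <- diagram$arcs
  span <- if (nrow(arcs) == 0L) c(NA_integer_, NA_integer_)
          else c(min(arcs[, 1L]), max(arcs[, 2L]))
  structure(list(diagram = diagram, span = span, origin = origin),
            class = "pk_component")
}

#' @export
print.pk_component <- function(x, ...) {
  g <- genus_of(x$diagram)
  cat(sprintf(
    "primitive component: %d arcs, span %d..%d, genus %d, token %s\n",
    nrow(x$diagram$arcs), x$span[1L], x$span[2L], g$g,
    pattern_token(collapse_stems(x$diagram))))
  invisible(x)
}

#' Decompose a structure into primitive components
#'
#' Recursively: split into irreducible components; in each, take the
#' crossing closure of the leftmost arc as one primitive component; the
#' remaining (nested) arcs are split and recursed upon. Components are
#' reported left to right at each recursion level, and their arcs
#' partition the pairs of the input. Pseudoknot-free closures come out as
#' genus-0 components; only genus >= 1 components are pseudoknots.
#'
#' @param s An [rna_structure] or `pk_diagram`.
#' @param origin Identifier attached to each component.
#' @return List of `pk_component`.
#' @examples
#' extract_primitive(parse_dotbracket("([)]"))
#' @export
extract_primitive <- function(s, origin = NA_character_) {
  d <- as_pk_diagram(s)
  out <- list()
  for (irr in split_irreducible(d)) {
    closure <- nonnested_closure(irr)
    out[[length(out) + 1L]] <- pk_component(pk_diagram(closure), origin)
    key <- paste(irr$arcs[, 1L], irr$arcs[, 2L])
    rest <- irr$arcs[!(key %in% paste(closure[, 1L], closure[, 2L])), ,
                     drop = FALSE]
    if (nrow(rest) > 0L)
      out <- c(out, extract_primitive(pk_diagram(rest), origin))
  }
  out
}

#' Collapse stems of a diagram to single arcs
#'
#' Repeatedly merges arc pairs `(i,j)`, `(k,l)` with `i < k <= l < j`
#' where no arc endpoint lies strictly between `i` and `k` nor between
#' `l` and `j` — directly stacked pairs, possibly separated by unpaired
#' bulges — until no such pair remains. The result is the shadow of the
#' diagram; its genus equals that of the input.
#'
#' @param d A `pk_diagram` (or anything [pattern_token] accepts).
#' @return The collapsed `pk_diagram`; outermost arc of each stem kept.
#' @examples
#' collapse_stems(pk_diagram(rbind(c(1, 8), c(2, 7), c(3, 6), c(4, 5))))
#' @export
collapse_stems <- function(d) {
  d <- as_pk_diagram(d)
  arcs <- d$arcs
  repeat {
    n <- nrow(arcs)
    if (n < 2L) break
    ends <- sort(as.vector(arcs))
    merged <- FALSE
    for (r in seq_len(n - 1L)) {
      # candidate inner partner: next arc by left endpoint
      q <- r + 1L
      i <- arcs[r, 1L]; j <- arcs[r, 2L]
      k <- arcs[q, 1L]; l <- arcs[q, 2L]
      if (!(i < k && l < j)) next
      gap_left <- any(ends > i & ends < k)
      gap_right <- any(ends > l & ends < j)
      if (!gap_left && !gap_right) {
        arcs <- arcs[-q, , drop = FALSE]  # keep the outer arc
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  pk_diagram(arcs)
}
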