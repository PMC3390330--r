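#' Enumerate all primitive pseudoknot shadows with n arcs
#'
#' Depth-first tree generation of every distinct pseudoknot pattern token
#' with `n` arcs that is primitive (irreducible, with the crossing
#' closure of its leftmost arc covering all arcs) and collapse-free (no
#' two arcs that would merge into one stem). Tokens are produced in a
#' fixed depth-first order; each valid token appears exactly once.
#'
#' The number of tokens grows roughly like `(2n-1)!!`, so collecting or
#' visiting them is only sensible for small `n`; [count_by_genus] bins
#' leaves into counters without storing them and is the route for larger
#' `n`.
#'
#' @param n Number of arcs, at least 2.
#' @param visit Optional function called with each completed token, in
#'   generation order.
#' @param allow_long Set `TRUE` to permit `n > 9` (minutes to far
#'   beyond; the count itself via [count_by_genus] is the cheaper path).
#' @return Invisibly, the number of tokens visited.
#' @examples
#' enumerate_primitive(3, visit = print)  # ABCABC then ABACBC
#' @export
enumerate_primitive <- function(n, visit = NULL, allow_long = FALSE) {
  n <- check_arc_count(n, allow_long)
  if (is.null(visit)) {
    total <- sum(.enum_counts_cpp(n))
    return(invisible(total))
  }
  toks <- .enum_tokens_cpp(n)
  for (t in toks) visit(t)
  invisible(length(toks))
}

check_arc_count <- function(n, allow_long = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L)
    stop("no primitive pseudoknot exists with fewer than 2 arcs")
  if (n > 9L && !allow_long)
    stop("n > 9 takes very long; pass allow_long = TRUE to proceed")
  n
}

#' Count primitive pseudoknot shadows by genus
#'
#' Runs the tree enumeration for `n` arcs, evaluating each leaf token's
#' genus by closed-loop counting and incrementing the matching bin;
#' leaves are not stored, so memory stays proportional to the tree depth.
#' The result is the row/column table a(g, n) restricted to one `n`.
#'
#' @inheritParams enumerate_primitive
#' @return Named numeric vector: names are genus values, entries counts.
#' @examples
#' count_by_genus(4)  # c("1" = 1, "2" = 17)
#' @export
count_by_genus <- function(n, allow_long = FALSE) {
  n <- check_arc_count(n, allow_long)
  .enum_counts_cpp(n)
}

#' Total number of primitive pseudoknots of a given genus
#'
#' A primitive pseudoknot of genus g has between `2g` and `6g - 2` arcs,
#' so the total count N(g) is the sum of a(g, n) over that support.
#'
#' @param g Genus, at least 1.
#' @param allow_long Permit arc counts beyond 9 (needed for `g >= 2`,
#'   whose support extends to `6g - 2`; g = 2 completes in minutes,
#'   higher genera escalate steeply).
#' @return The count N(g), with the per-n contributions as attribute
#'   `"by_n"`.
#' @examples
#' count_for_genus_total(1)  # 4 = 1 + 2 + 1 over n = 2, 3, 4
#' @export
count_for_genus_total <- function(g, allow_long = FALSE) {
  g <- as.integer(g)
  if (is.na(g) || g < 1L) stop("genus must be at least 1")
  ns <- (2L * g):(6L * g - 2L)
  per_n <- vapply(ns, function(n) {
    cb <- count_by_genus(n, allow_long = allow_long)
    v <- cb[as.character(g)]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  names(per_n) <- ns
  structure(sum(per_n), by_n = per_n)
}

#' Brute-force oracle: primitive shadow counts via perfect matchings
#'
#' Generates all `(2n-1)!!` perfect matchings of `2n` ranked endpoints,
#' keeps those that are irreducible, whose non-nested closure from the
#' leftmost arc covers every arc, and which contain no collapsible
#' adjacent arc pair, then bins survivors by genus. Entirely independent
#' of the tree enumeration (pure R, direct filters); used to validate it.
#'
#' @param n Number of arcs; practical up to 7 (135135 matchings).
#' @return Named numeric vector as in [count_by_genus].
#' @export
brute_force_counts <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2")
  if (n > 7L) stop("brute force over (2n-1)!! matchings is limited to n <= 7")
  counts <- integer(n)  # genus can be at most floor(n / 2)
  arcs <- matrix(0L, n, 2L)
  used <- logical(2L * n)
  recurse <- function(depth) {
    if (depth > n) {
      if (matching_is_primitive_shadow(arcs)) {
        g <- matching_genus(arcs)
        counts[g] <<- counts[g] + 1L
      }
      return(invisible(NULL))
    }
    a <- which(!used)[1L]
    used[a] <<- TRUE
    for (b in which(!used)) {
      used[b] <<- TRUE
      arcs[depth, ] <<- c(a, b)
      recurse(depth + 1L)
      used[b] <<- FALSE
    }
    used[a] <<- FALSE
  }
  recurse(1L)
  out <- as.numeric(counts[counts > 0L])
  names(out) <- as.character(which(counts > 0L))
  out
}

# Direct filter: irreducible, closure-covering, collapse-free.  Written
# against the definitions, not via the decomposition code paths.
matching_is_primitive_shadow <- function(arcs) {
  n <- nrow(arcs)
  if (n < 2L) return(FALSE)
  arcs <- arcs[order(arcs[, 1L]), , drop = FALSE]
  # irreducible: sweeping by left endpoint, the covered interval must
  # never close before the next arc starts
  reach <- arcs[1L, 2L]
  for (r in 2:n) {
    if (arcs[r, 1L] > reach) return(FALSE)
    reach <- max(reach, arcs[r, 2L])
  }
  # closure from leftmost arc must cover all arcs
  M <- crossing_matrix(arcs)
  inc <- logical(n)
  inc[which.min(arcs[, 1L])] <- TRUE
  repeat {
    new <- which(!inc & apply(M[, inc, drop = FALSE], 1L, any))
    if (length(new) == 0L) break
    inc[new] <- TRUE
  }
  if (!all(inc)) return(FALSE)
  # no collapsible adjacent pair (i, j), (i+1, j-1)
  key <- paste(arcs[, 1L], arcs[, 2L])
  !any(paste(arcs[, 1L] + 1L, arcs[, 2L] - 1L) %in% key)
}

# Genus via the permutation-cycle loop count (independent small helper).
matching_genus <- function(arcs) {
  P <- nrow(arcs)
  n2 <- 2L * P
  sigma <- integer(n2)
  sigma[arcs[, 1L]] <- arcs[, 2L]
  sigma[arcs[, 2L]] <- arcs[, 1L]
  (P - perm_cycle_count(sigma, n2) + 1L) %/% 2L
}

#' Total number of primitive components with n arcs
#'
#' For `n >= 2` this is the genus sum of a(g, n); a pseudoknot-free
#' primitive component is either the empty structure or a single arc, so
#' the 0- and 1-arc totals are both 1.
#'
#' @inheritParams enumerate_primitive
#' @return A single count.
#' @examples
#' totals_per_arc(4)  # 18
#' @export
totals_per_arc <- function(n, allow_long = FALSE) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("n must be non-negative")
  if (n <= 1L) return(1)
  sum(count_by_genus(n, allow_long = allow_long))
}
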