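#' Chord diagram over ranked backbone positions
#'
#' A `pk_diagram` is a set of arcs over distinct backbone positions; only
#' the relative order of endpoints is semantic, so original coordinates
#' are preserved through decomposition and relabelling endpoints by rank
#' changes nothing downstream (genus, pattern token).
#'
#' @param arcs Two-column matrix of arc endpoints, all distinct.
#' @return An object of class `pk_diagram`.
#' @export
pk_diagram <- function(arcs = NULL) {
  arcs <- normalize_pairs(arcs)
  if (anyDuplicated(as.vector(arcs)))
    stop("arc endpoints must be pairwise distinct")
  structure(list(arcs = arcs), class = "pk_diagram")
}

#' @export
print.pk_diagram <- function(x, ...) {
  n <- nrow(x$arcs)
  cat(sprintf("chord diagram: %d arc%s", n, if (n == 1L) "" else "s"))
  if (n > 0L && n <= 26L) {
    tok <- tryCatch(pattern_token(x), error = function(e) NULL)
    if (!is.null(tok)) cat(", endpoint word", tok)
  }
  cat("\n")
  invisible(x)
}

# Coerce various inputs (structure, matrix, token) to a diagram.
as_pk_diagram <- function(x) {
  if (inherits(x, "pk_diagram")) return(x)
  if (inherits(x, "rna_structure")) return(pk_diagram(x$arcs %||% x$pairs))
  if (inherits(x, "pk_component")) return(x$diagram)
  if (is.matrix(x) || is.numeric(x)) return(pk_diagram(x))
  if (is.character(x) && length(x) == 1L) return(token_diagram(x))
  stop("cannot interpret input as a chord diagram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Do arcs a = (a1,a2) and x = (x1,x2) cross?  a1 < x1 < a2 < x2 or
# x1 < a1 < x2 < a2, endpoints strictly interleaved.
arcs_cross <- function(a, x) {
  (a[1L] < x[1L] && x[1L] < a[2L] && a[2L] < x[2L]) ||
  (x[1L] < a[1L] && a[1L] < x[2L] && x[2L] < a[2L])
}

# Symmetric logical crossing matrix of a diagram's arcs.
crossing_matrix <- function(arcs) {
  n <- nrow(arcs)
  M <- matrix(FALSE, n, n)
  if (n > 1L)
    for (i in 1:(n - 1L))
      for (j in (i + 1L):n)
        M[i, j] <- M[j, i] <- arcs_cross(arcs[i, ], arcs[j, ])
  M
}

#' Canonical pseudoknot pattern token of a shadow diagram
#'
#' Walks the endpoints in backbone order and letters the arcs A, B, C ...
#' in order of first (5') endpoint, emitting each arc's letter at both
#' endpoints. The token of a kissing hairpin is "ABACBC"; of an
#' H-pseudoknot, "ABAB". Beyond 26 arcs, letters continue as a1, a2, ...
#' (each still one token symbol).
#'
#' @param d A `pk_diagram`, typically a [collapse_stems] fixpoint.
#' @return Single string, the pattern token.
#' @examples
#' pattern_token(pk_diagram(rbind(c(1, 3), c(2, 4))))  # "ABAB"
#' @export
pattern_token <- function(d) {
  d <- as_pk_diagram(d)
  arcs <- d$arcs
  n <- nrow(arcs)
  if (n == 0L) return("")
  ranks <- rank(as.vector(t(arcs)))  # t() so arc r owns ranks at 2r-1, 2r
  word <- character(2L * n)
  labels <- token_alphabet(n)
  # arcs are sorted by left endpoint already, so arc r gets the r-th label
  for (r in seq_len(n)) {
    word[ranks[2L * r - 1L]] <- labels[r]
    word[ranks[2L * r]] <- labels[r]
  }
  paste(word, collapse = "")
}

token_alphabet <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0("a", seq_len(n - 26L)))[seq_len(n)]
}

#' Build the chord diagram named by a pattern token
#'
#' The inverse of [pattern_token]: endpoints are placed at ranks 1..2P and
#' each symbol's two occurrences become one arc. Symbols beyond `Z` are
#' written `a1`, `a2`, ... and parsed greedily.
#'
#' @param token Pattern string; every symbol must occur exactly twice.
#' @return A `pk_diagram` with endpoints at ranks `1..2P`.
#' @examples
#' token_diagram("ABACBC")
#' @export
token_diagram <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  if (token == "") return(pk_diagram())
  syms <- regmatches(token, gregexpr("a[0-9]+|[A-Z]", token))[[1L]]
  if (sum(nchar(syms)) != nchar(token))
    stop("malformed token: unrecognised symbols")
  tab <- table(syms)
  if (any(tab != 2L))
    stop(sprintf("malformed token: symbol(s) %s do not occur exactly twice",
                 paste(names(tab)[tab != 2L], collapse = ", ")))
  uniq <- unique(syms)
  arcs <- t(vapply(uniq, function(s) which(syms == s), integer(2)))
  pk_diagram(arcs)
}
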