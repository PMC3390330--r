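#' RNA secondary structure with arbitrary pseudoknots
#'
#' An `rna_structure` holds a backbone length, an optional nucleotide
#' sequence and a set of base pairs. Pairs are 1-based, stored as a
#' two-column integer matrix with `i < j` in each row, at most one pair per
#' position. Crossing pairs (pseudoknots) are allowed without restriction.
#'
#' @param length Number of nucleotides in the backbone.
#' @param pairs Two-column matrix (or empty) of paired positions; rows may
#'   be given in either order, they are normalised to `i < j` and sorted by
#'   the 5' endpoint.
#' @param sequence Optional string (or character vector of single bases) of
#'   exactly `length` nucleotides.
#' @return An object of class `rna_structure`.
#' @examples
#' rna_structure(6, rbind(c(1, 6), c(2, 5)))
#' @export
rna_structure <- function(length, pairs = NULL, sequence = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L)
    stop("'length' must be a non-negative integer")
  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L) || any(pairs > length))
      stop("pair endpoint outside 1..length")
    idx <- as.vector(pairs)
    if (anyDuplicated(idx))
      stop("a position participates in more than one pair")
  }
  if (!is.null(sequence)) {
    if (is.character(sequence) && length(sequence) > 1L)
      sequence <- paste(sequence, collapse = "")
    if (nchar(sequence) != length)
      stop(sprintf("sequence has %d bases but declared length is %d",
                   nchar(sequence), length))
  }
  structure(list(length = length, pairs = pairs, sequence = sequence),
            class = "rna_structure")
}

# Coerce pair input to a sorted integer matrix with i < j per row.
normalize_pairs <- function(pairs) {
  if (is.null(pairs) || (is.matrix(pairs) && nrow(pairs) == 0L) ||
      length(pairs) == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  if (!is.matrix(pairs)) pairs <- matrix(as.integer(pairs), ncol = 2L,
                                         byrow = TRUE)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("'pairs' must have two columns")
  swap <- pairs[, 1L] > pairs[, 2L]
  if (any(swap)) pairs[swap, ] <- pairs[swap, 2:1]
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pair (i, i) not allowed")
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d nt, %d base pairs%s\n",
              x$length, nrow(x$pairs),
              if (is.null(x$sequence)) "" else " (with sequence)"))
  db <- tryCatch(write_dotbracket(x), error = function(e) NULL)
  if (!is.null(db) && nchar(db) <= 120L) cat(" ", db, "\n")
  invisible(x)
}

#' @export
format.rna_structure <- function(x, ...) {
  sprintf("<rna_structure: %d nt, %d bp>", x$length, nrow(x$pairs))
}

# Bracket families understood on input/output, in first-fit order.
bracket_families <- function() {
  c("()", "[]", "{}", "<>", paste0(LETTERS, letters))
}

#' Parse an extended dot-bracket string
#'
#' Supports multiple bracket families for crossing stems: `()`, `[]`,
#' `{}`, `<>`, then `Aa` through `Zz`. Each closing bracket is matched to
#' the most recent unmatched opener of its own family. `.`, `:` and `-`
#' all denote unpaired positions.
#'
#' @param text A dot-bracket string.
#' @param sequence Optional nucleotide sequence of the same length.
#' @param alphabet Character vector of two-character bracket families.
#' @return An [rna_structure].
#' @examples
#' parse_dotbracket("((..))")
#' parse_dotbracket("([)]")   # H-pseudoknot shadow
#' @export
parse_dotbracket <- function(text, sequence = NULL,
                             alphabet = bracket_families()) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- strsplit(text, "")[[1]]
  n <- length(ch)
  openers <- substr(alphabet, 1L, 1L)
  closers <- substr(alphabet, 2L, 2L)
  stacks <- vector("list", length(alphabet))
  pairs <- matrix(integer(0), ncol = 2L)
  for (pos in seq_len(n)) {
    c0 <- ch[pos]
    if (c0 %in% c(".", ":", "-")) next
    fo <- match(c0, openers)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], pos)
      next
    }
    fc <- match(c0, closers)
    if (!is.na(fc)) {
      st <- stacks[[fc]]
      if (length(st) == 0L)
        stop(sprintf(
          "unbalanced bracket: unmatched '%s' (family %s) at position %d",
          c0, alphabet[fc], pos))
      pairs <- rbind(pairs, c(st[length(st)], pos))
      stacks[[fc]] <- st[-length(st)]
      next
    }
    stop(sprintf("unknown character '%s' at position %d", c0, pos))
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left) > 0L) {
    f <- left[1L]
    st <- stacks[[f]]
    stop(sprintf(
      "unbalanced bracket: unclosed '%s' (family %s) at position %d",
      openers[f], alphabet[f], st[length(st)]))
  }
  rna_structure(n, pairs, sequence)
}

#' Read secondary structures from a dot-bracket file
#'
#' One structure per record. A record is either a bare dot-bracket line or
#' a FASTA-style pair of lines `>id` then the structure string; an
#' additional sequence line may precede the structure (lines made of
#' nucleotide letters only are taken as sequence).
#'
#' @param path File path.
#' @return Named list of [rna_structure] objects.
#' @export
read_dotbracket_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  id <- NULL
  seq <- NULL
  auto <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      id <- trimws(sub("^>", "", ln))
      seq <- NULL
    } else if (grepl("^[ACGUTNacgutn]+$", ln)) {
      seq <- toupper(ln)
    } else {
      auto <- auto + 1L
      nm <- if (is.null(id)) sprintf("record_%d", auto) else id
      out[[nm]] <- parse_dotbracket(ln, sequence = seq)
      id <- NULL
      seq <- NULL
    }
  }
  out
}

# Shared reciprocity check for CT / BPSEQ partner columns.
pairs_from_partner <- function(idx, partner, what) {
  n <- length(idx)
  if (!identical(idx, seq_len(n)))
    stop(sprintf("%s: indices must run 1..n consecutively", what))
  if (any(partner < 0L | partner > n))
    stop(sprintf("%s: partner index out of range", what))
  paired <- which(partner > 0L)
  for (i in paired) {
    j <- partner[i]
    if (partner[j] != i)
      stop(sprintf(
        "%s: inconsistent pairing, row %d points to %d but row %d points to %d",
        what, i, j, j, partner[j]))
    if (j == i) stop(sprintf("%s: position %d paired with itself", what, i))
  }
  p <- cbind(paired, partner[paired])
  p[p[, 1L] < p[, 2L], , drop = FALSE]
}

#' Parse CT-format connectivity table lines
#'
#' Standard 6-column CT: position, base, 5' neighbour, 3' neighbour,
#' pairing partner (0 = unpaired), natural numbering. The first line is a
#' header whose first field is the sequence length.
#'
#' @param lines Character vector of file lines (or a path via [read_ct]).
#' @return An [rna_structure] with sequence.
#' @export
parse_ct <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 1L) stop("CT: empty input")
  hdr <- strsplit(lines[1L], "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(hdr[1L]))
  if (is.na(n)) stop("CT: header must start with the sequence length")
  body <- lines[-1L]
  if (length(body) != n)
    stop(sprintf("CT: header declares %d rows, found %d", n, length(body)))
  fld <- strsplit(body, "\\s+")
  if (any(lengths(fld) < 5L)) stop("CT: rows must have at least 5 columns")
  idx <- vapply(fld, function(f) as.integer(f[1L]), integer(1))
  base <- vapply(fld, function(f) f[2L], character(1))
  partner <- vapply(fld, function(f) as.integer(f[5L]), integer(1))
  pairs <- pairs_from_partner(idx, partner, "CT")
  rna_structure(n, pairs, paste(base, collapse = ""))
}

#' @rdname parse_ct
#' @param path Path to a CT file.
#' @export
read_ct <- function(path) parse_ct(readLines(path))

#' Parse BPSEQ-format lines
#'
#' Three columns: position, base, pairing partner (0 = unpaired), 1-based.
#'
#' @param lines Character vector of file lines.
#' @return An [rna_structure] with sequence.
#' @export
parse_bpseq <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(rna_structure(0L))
  fld <- strsplit(lines, "\\s+")
  if (any(lengths(fld) != 3L)) stop("BPSEQ: rows must have 3 columns")
  idx <- vapply(fld, function(f) as.integer(f[1L]), integer(1))
  ord <- order(idx)
  idx <- idx[ord]
  fld <- fld[ord]
  base <- vapply(fld, function(f) f[2L], character(1))
  partner <- vapply(fld, function(f) as.integer(f[3L]), integer(1))
  pairs <- pairs_from_partner(idx, partner, "BPSEQ")
  rna_structure(length(idx), pairs, paste(base, collapse = ""))
}

#' @rdname parse_bpseq
#' @param path Path to a BPSEQ file.
#' @export
read_bpseq <- function(path) parse_bpseq(readLines(path))

#' Keep only canonical base pairs
#'
#' Retains Watson-Crick pairs (A-U, G-C) and the G-U wobble;
#' case-insensitive, T treated as U. Length and sequence are unchanged, so
#' the operation is idempotent. The admitted set is recorded in the
#' `canonical_set` attribute of the result for provenance.
#'
#' @param s An [rna_structure] with sequence.
#' @return The filtered [rna_structure].
#' @export
filter_canonical <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  if (is.null(s$sequence))
    stop("canonical filtering requires a nucleotide sequence")
  canonical <- c("AU", "UA", "GC", "CG", "GU", "UG")
  bases <- chartr("T", "U", toupper(strsplit(s$sequence, "")[[1L]]))
  if (nrow(s$pairs) > 0L) {
    duo <- paste0(bases[s$pairs[, 1L]], bases[s$pairs[, 2L]])
    keep <- duo %in% canonical
  } else keep <- logical(0)
  out <- rna_structure(s$length, s$pairs[keep, , drop = FALSE], s$sequence)
  attr(out, "canonical_set") <- canonical
  out
}

#' Write a structure as an extended dot-bracket string
#'
#' Stems (maximal runs of directly stacked pairs) are assigned bracket
#' families by greedy first-fit over the stem crossing graph, ordered by 5'
#' endpoint, so that same-family pairs never cross and the output
#' round-trips through [parse_dotbracket].
#'
#' @param s An [rna_structure].
#' @param alphabet Bracket families available for assignment.
#' @return A dot-bracket string of length `s$length`.
#' @export
write_dotbracket <- function(s, alphabet = bracket_families()) {
  stopifnot(inherits(s, "rna_structure"))
  out <- rep(".", s$length)
  p <- s$pairs
  if (nrow(p) > 0L) {
    stem <- stem_groups(p)
    ns <- max(stem)
    fam <- integer(ns)
    for (g in seq_len(ns)) {
      mine <- p[stem == g, , drop = FALSE]
      used <- logical(length(alphabet))
      for (h in seq_len(g - 1L)) {
        if (used[fam[h]]) next
        other <- p[stem == h, , drop = FALSE]
        if (stems_cross(mine, other)) used[fam[h]] <- TRUE
      }
      f <- which(!used)[1L]
      if (is.na(f))
        stop("too many mutually crossing stems for the bracket alphabet")
      fam[g] <- f
    }
    for (r in seq_len(nrow(p))) {
      fm <- alphabet[fam[stem[r]]]
      out[p[r, 1L]] <- substr(fm, 1L, 1L)
      out[p[r, 2L]] <- substr(fm, 2L, 2L)
    }
  }
  paste(out, collapse = "")
}

# Group pairs into stems: runs of pairs stacked as (i, j), (i+1, j-1).
# Pairs must be sorted by i (normalize_pairs guarantees this).
stem_groups <- function(p) {
  n <- nrow(p)
  grp <- integer(n)
  key <- paste(p[, 1L], p[, 2L])
  inner <- match(paste(p[, 1L] + 1L, p[, 2L] - 1L), key)
  g <- 0L
  for (r in seq_len(n)) {
    if (grp[r] != 0L) next
    g <- g + 1L
    k <- r
    while (!is.na(k) && grp[k] == 0L) {
      grp[k] <- g
      k <- inner[k]
    }
  }
  grp
}

# TRUE if any pair of stem A crosses any pair of stem B.
stems_cross <- function(a, b) {
  for (r in seq_len(nrow(a)))
    for (q in seq_len(nrow(b)))
      if (arcs_cross(a[r, ], b[q, ])) return(TRUE)
  FALSE
}
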