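#' Generate a synthetic pseudoknotted structure with planted motifs
#'
#' Builds one structure record containing the requested pseudoknot motifs
#' side by side, with known ground truth, for end-to-end pipeline tests.
#' Each arc of a motif token is expanded into a stem of parallel base
#' pairs (size drawn uniformly from the motif's `stem` range, 1-20 bp),
#' optionally interrupted by unpaired bulges that do not break stem
#' collapse. Motifs are separated by unpaired spacers, and plain hairpins
#' (genus-0 decoys) can be nested into the gaps between stem blocks. A
#' random canonical sequence (paired positions get complementary or
#' wobble bases) is attached. Deterministic for a given seed; the
#' caller's RNG state is left untouched.
#'
#' @param motifs List of motif specs, each a list with `token` (pattern
#'   string), `stem` (length-2 range of stem sizes in bp, within 1-20)
#'   and optional `bulge` (per-stack probability of an unpaired bulge,
#'   default 0).
#' @param seed Integer seed; same seed, same bytes.
#' @param spacer Range of unpaired spacer lengths between blocks.
#' @param decoy_hairpins Number of plain hairpins to nest into gaps.
#' @return List with `record` (the [rna_structure]), `dotbracket` (its
#'   string form) and `truth` (data frame of planted token, genus, arcs,
#'   span per motif).
#' @examples
#' fx <- generate_fixture(list(list(token = "ABAB", stem = c(2, 2))), seed = 1)
#' fx$truth
#' @export
generate_fixture <- function(motifs, seed, spacer = c(3L, 6L),
                             decoy_hairpins = 0L) {
  stopifnot(is.list(motifs), length(motifs) > 0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  chars <- character(0)     # "." or "p" placeholder per position
  pairs <- matrix(integer(0), ncol = 2L)
  truth <- list()

  emit_unpaired <- function(k) chars <<- c(chars, rep(".", k))
  emit_spacer <- function() emit_unpaired(sample(spacer[1L]:spacer[2L], 1L))

  emit_hairpin <- function() {
    s <- sample(2:5, 1L)
    loop <- sample(3:6, 1L)
    base <- length(chars)
    emit_unpaired(2L * s + loop)  # reserve, then pair up
    for (t in seq_len(s))
      pairs <<- rbind(pairs, c(base + t, base + 2L * s + loop + 1L - t))
  }

  emit_motif <- function(m) {
    tok <- m$token
    stem_rng <- as.integer(m$stem %||% c(1L, 1L))
    if (any(stem_rng < 1L) || any(stem_rng > 20L))
      stop("stem sizes must be within 1..20 bp")
    bulge <- m$bulge %||% 0
    d <- token_diagram(tok)
    canon <- pattern_token(collapse_stems(d))
    if (!identical(canon, tok))
      stop(sprintf(
        "token %s is not a canonical shadow (collapses to %s): its stems would merge",
        tok, canon))
    arcs <- d$arcs
    n <- nrow(arcs)
    sizes <- sample(stem_rng[1L]:stem_rng[2L], n, replace = TRUE)
    # which arc occupies each rank, and which side
    rk_arc <- integer(2L * n)
    rk_side <- integer(2L * n)
    for (a in seq_len(n)) {
      rk_arc[arcs[a, 1L]] <- a; rk_side[arcs[a, 1L]] <- 1L
      rk_arc[arcs[a, 2L]] <- a; rk_side[arcs[a, 2L]] <- 2L
    }
    slot <- vector("list", n)  # per arc: list(left =, right =)
    for (r in seq_len(2L * n)) {
      a <- rk_arc[r]
      ps <- integer(sizes[a])
      for (t in seq_len(sizes[a])) {
        if (t > 1L && bulge > 0 && stats::runif(1) < bulge)
          emit_unpaired(sample(1:2, 1L))
        chars <<- c(chars, "p")
        ps[t] <- length(chars)
      }
      if (rk_side[r] == 1L) slot[[a]]$left <- ps else slot[[a]]$right <- ps
      if (r < 2L * n) emit_spacer()
    }
    span_start <- min(unlist(lapply(slot, `[[`, "left")))
    for (a in seq_len(n)) {
      s <- sizes[a]
      for (t in seq_len(s))
        pairs <<- rbind(pairs, c(slot[[a]]$left[t], slot[[a]]$right[s + 1L - t]))
    }
    span_end <- max(unlist(lapply(slot, `[[`, "right")))
    truth[[length(truth) + 1L]] <<- data.frame(
      token = tok, genus = genus_of_token(tok)$g, arcs = n,
      span_start = span_start, span_end = span_end,
      stringsAsFactors = FALSE)
  }

  for (i in seq_along(motifs)) {
    if (i > 1L) emit_spacer()
    emit_motif(motifs[[i]])
  }
  for (h in seq_len(decoy_hairpins)) {
    emit_spacer()
    emit_hairpin()
  }
  emit_spacer()

  seq <- random_canonical_sequence(length(chars), pairs)
  rec <- rna_structure(length(chars), pairs, seq)
  list(record = rec, dotbracket = write_dotbracket(rec),
       truth = do.call(rbind, truth))
}

# Random sequence in which every designated pair is canonical
# (Watson-Crick or G-U wobble) and other positions are uniform.
random_canonical_sequence <- function(n, pairs) {
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  duos <- c("AU", "UA", "GC", "CG", "GU", "UG")
  if (nrow(pairs) > 0L)
    for (r in seq_len(nrow(pairs))) {
      duo <- sample(duos, 1L)
      bases[pairs[r, 1L]] <- substr(duo, 1L, 1L)
      bases[pairs[r, 2L]] <- substr(duo, 2L, 2L)
    }
  paste(bases, collapse = "")
}

#' Generate a dataset of fixture structures
#'
#' Convenience wrapper over [generate_fixture]: one record per element of
#' `specs`, with per-record seeds derived from `seed`.
#'
#' @param specs List of motif-spec lists (each as the `motifs` argument
#'   of [generate_fixture]).
#' @param seed Integer master seed.
#' @param ... Passed to [generate_fixture].
#' @return List with `records` (named list of [rna_structure]) and
#'   `truth` (data frame with an `origin` column).
#' @export
generate_fixture_set <- function(specs, seed, ...) {
  records <- list()
  truths <- list()
  for (i in seq_along(specs)) {
    fx <- generate_fixture(specs[[i]], seed = as.integer(seed) + i, ...)
    id <- sprintf("fixture_%03d", i)
    records[[id]] <- fx$record
    tr <- fx$truth
    tr$origin <- id
    truths[[i]] <- tr
  }
  list(records = records, truth = do.call(rbind, truths))
}
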