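#' Drop redundant records sharing a base sequence
#'
#' Among records whose nucleotide sequences are identical, exactly the
#' first in input order is kept (a deterministic stand-in for an
#' arbitrary choice). Records without a sequence are kept as-is.
#'
#' @param records Named list of [rna_structure] objects.
#' @return The deduplicated list, input order preserved.
#' @export
dedupe <- function(records) {
  if (length(records) == 0L) return(records)
  seqs <- vapply(records, function(r) r$sequence %||% NA_character_,
                 character(1))
  keep <- is.na(seqs) | !duplicated(seqs, incomparables = NA)
  records[keep]
}

#' Classify a dataset of structures into pseudoknot subclasses
#'
#' For every structure: extract primitive components, drop genus-0 ones,
#' collapse stems and read off each component's pattern token and genus.
#' Components are then grouped by token; per token the table reports the
#' number of distinct source structures, the instance count, and the
#' mean, standard deviation (population form, divide by n) and minimum of
#' the component span length (distance between and including the leftmost
#' and rightmost paired nucleotide). Subclass ids `1A, 1B, 2A, ...`
#' are assigned within each genus by decreasing structure count, ties
#' broken by larger arc count then token order.
#'
#' @param records Named list of [rna_structure] objects.
#' @param canonical_only If `TRUE`, apply [filter_canonical] first
#'   (requires sequences).
#' @return List with elements `subclasses` (data frame: genus,
#'   subclass_id, token, n_sequences, n_instances, length_mean,
#'   length_sd, length_min), `components` (per-component data frame:
#'   origin, token, genus, span_start, span_end, length, arcs) and
#'   `discarded` (ids of structures left with no pseudoknot).
#' @export
classify_dataset <- function(records, canonical_only = FALSE) {
  if (is.null(names(records)) && length(records) > 0L)
    names(records) <- sprintf("record_%d", seq_along(records))
  rows <- list()
  discarded <- character(0)
  for (id in names(records)) {
    s <- records[[id]]
    if (canonical_only) s <- filter_canonical(s)
    comps <- extract_primitive(s, origin = id)
    had_pk <- FALSE
    for (co in comps) {
      g <- genus_of(co$diagram)$g
      if (g == 0L) next
      had_pk <- TRUE
      tok <- pattern_token(collapse_stems(co$diagram))
      rows[[length(rows) + 1L]] <- data.frame(
        origin = id, token = tok, genus = g,
        span_start = co$span[1L], span_end = co$span[2L],
        length = co$span[2L] - co$span[1L] + 1L,
        arcs = nrow(co$diagram$arcs),
        stringsAsFactors = FALSE)
    }
    if (!had_pk) discarded <- c(discarded, id)
  }
  components <- if (length(rows)) do.call(rbind, rows) else
    data.frame(origin = character(0), token = character(0),
               genus = integer(0), span_start = integer(0),
               span_end = integer(0), length = integer(0),
               arcs = integer(0), stringsAsFactors = FALSE)
  subclasses <- summarize_subclasses(components)
  list(subclasses = subclasses, components = components,
       discarded = discarded)
}

summarize_subclasses <- function(components) {
  empty <- data.frame(genus = integer(0), subclass_id = character(0),
                      token = character(0), n_sequences = integer(0),
                      n_instances = integer(0), length_mean = numeric(0),
                      length_sd = numeric(0), length_min = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(components) == 0L) return(empty)
  by_tok <- split(components, components$token)
  tab <- do.call(rbind, lapply(by_tok, function(df) {
    len <- df$length
    data.frame(
      genus = df$genus[1L], token = df$token[1L],
      n_sequences = length(unique(df$origin)),
      n_instances = nrow(df),
      length_mean = mean(len),
      length_sd = sqrt(mean((len - mean(len))^2)),  # population sd
      length_min = min(len),
      arcs = df$arcs[1L],
      stringsAsFactors = FALSE)
  }))
  # order: genus ascending, n_sequences descending, then larger arc
  # count, then token; assign letters within genus in that order
  tab <- tab[order(tab$genus, -tab$n_sequences, -tab$arcs, tab$token), ,
             drop = FALSE]
  tab$subclass_id <- unlist(lapply(split(seq_len(nrow(tab)), tab$genus),
    function(ix) paste0(tab$genus[ix], LETTERS[seq_along(ix)])),
    use.names = FALSE)
  rownames(tab) <- NULL
  tab[, c("genus", "subclass_id", "token", "n_sequences", "n_instances",
          "length_mean", "length_sd", "length_min")]
}

#' Histogram of total genus across a dataset
#'
#' Bins structures by their total genus (the sum over primitive
#' components), reporting counts and proportions.
#'
#' @param records Named list of [rna_structure] objects.
#' @return Data frame with columns `total_genus`, `n`, `proportion`.
#' @export
total_genus_histogram <- function(records) {
  tg <- vapply(records, total_genus, integer(1))
  if (length(tg) == 0L)
    return(data.frame(total_genus = integer(0), n = integer(0),
                      proportion = numeric(0)))
  tab <- table(tg)
  data.frame(total_genus = as.integer(names(tab)),
             n = as.integer(tab),
             proportion = as.numeric(tab) / length(tg),
             row.names = NULL)
}
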