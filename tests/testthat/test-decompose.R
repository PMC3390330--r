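test_that("irreducible splitting cuts where no pair spans the backbone", {
  two <- split_irreducible(parse_dotbracket("((..))((..))"))
  expect_length(two, 2L)
  expect_equal(unname(two[[1]]$arcs), rbind(c(1L, 6L), c(2L, 5L)))
  expect_equal(unname(two[[2]]$arcs), rbind(c(7L, 12L), c(8L, 11L)))

  expect_length(split_irreducible(parse_dotbracket("([)]")), 1L)
  expect_length(split_irreducible(parse_dotbracket("([)]..([)]([)]")), 3L)
  expect_length(split_irreducible(rna_structure(5)), 0L)
})

test_that("non-nested closure collects exactly the crossing closure of the leftmost arc", {
  cl <- nonnested_closure(pk_diagram(rbind(c(1, 5), c(3, 8), c(6, 7))))
  expect_equal(unname(cl), rbind(c(1L, 5L), c(3L, 8L)))  # (6,7) nested under (3,8)

  both <- nonnested_closure(pk_diagram(rbind(c(1, 3), c(2, 4))))
  expect_equal(nrow(both), 2L)

  hairpin <- nonnested_closure(pk_diagram(rbind(c(1, 6), c(2, 5))))
  expect_equal(unname(hairpin), rbind(c(1L, 6L)))  # seed arc only, no crossings
})

test_that("primitive extraction recurses into nested remainders", {
  # pseudoknot-free: one single-arc closure per nesting level
  comps <- extract_primitive(parse_dotbracket("((((..))))"))
  expect_length(comps, 4L)
  expect_true(all(vapply(comps, function(co) nrow(co$diagram$arcs), integer(1)) == 1L))
  expect_true(all(vapply(comps, function(co) genus_of(co$diagram)$g, integer(1)) == 0L))

  one <- extract_primitive(parse_dotbracket("([)]"))
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$diagram$arcs), 2L)

  # kissing-hairpin-shaped crossing chain with a plain hairpin nested in
  # one loop: the 3-arc crossing set and the hairpin come out separately
  kh <- rna_structure(13, rbind(c(1, 6), c(3, 10), c(8, 13), c(4, 5)))
  comps <- extract_primitive(kh)
  sizes <- sort(vapply(comps, function(co) nrow(co$diagram$arcs), integer(1)))
  expect_equal(sizes, c(1L, 3L))
  toks <- vapply(comps, function(co)
    pattern_token(collapse_stems(co$diagram)), character(1))
  expect_true("ABACBC" %in% toks)
})

test_that("arc conservation: primitive components partition the pairs", {
  for (seed in 1:10) {
    fx <- random_fixture(seed)
    comps <- extract_primitive(fx$record)
    got <- do.call(rbind, lapply(comps, function(co) co$diagram$arcs))
    got <- got[order(got[, 1L]), , drop = FALSE]
    expect_equal(unname(got), unname(fx$record$pairs))
  }
})

test_that("primitive components with 2+ arcs satisfy their invariants", {
  for (seed in 1:6) {
    fx <- random_fixture(seed)
    for (co in extract_primitive(fx$record)) {
      arcs <- co$diagram$arcs
      if (nrow(arcs) < 2L) next
      M <- pktopo:::crossing_matrix(arcs)
      expect_true(all(rowSums(M) > 0))                    # every arc crosses
      expect_equal(nrow(nonnested_closure(co$diagram)), nrow(arcs))
      expect_length(split_irreducible(co$diagram), 1L)    # irreducible
    }
  }
})

test_that("stem collapse merges stacked pairs across bulges to a fixpoint", {
  helix <- collapse_stems(pk_diagram(rbind(c(1, 8), c(2, 7), c(3, 6), c(4, 5))))
  expect_equal(nrow(helix$arcs), 1L)

  fixpoint <- pk_diagram(rbind(c(1, 4), c(2, 5), c(3, 6)))  # pseudotrefoil
  expect_equal(collapse_stems(fixpoint)$arcs, fixpoint$arcs)

  # a stem crossed through its loop region still collapses: (2,6),(3,5)
  # stack directly even though (1,4) crosses both
  tight <- collapse_stems(pk_diagram(rbind(c(1, 4), c(2, 6), c(3, 5))))
  expect_equal(nrow(tight$arcs), 2L)
  expect_identical(genus_of(tight)$g,
                   genus_of(pk_diagram(rbind(c(1, 4), c(2, 6), c(3, 5))))$g)

  hpk <- collapse_stems(pk_diagram(rbind(c(1, 7), c(2, 6), c(4, 10), c(5, 9))))
  expect_equal(nrow(hpk$arcs), 2L)
  expect_equal(pattern_token(hpk), "ABAB")

  # bulge between stacked pairs does not block the merge
  bulged <- collapse_stems(pk_diagram(rbind(c(1, 9), c(3, 8))))
  expect_equal(nrow(bulged$arcs), 1L)
})

test_that("pattern tokens are canonical and invariant under stem inflation", {
  expect_equal(pattern_token(pk_diagram(rbind(c(1, 3), c(2, 4)))), "ABAB")
  expect_equal(pattern_token(pk_diagram(rbind(c(1, 3), c(2, 5), c(4, 6)))),
               "ABACBC")
  expect_equal(pattern_token(pk_diagram(rbind(c(1, 4), c(2, 5), c(3, 6)))),
               "ABCABC")
  expect_equal(pattern_token(token_diagram("ABCACDBD")), "ABCACDBD")

  # planting a token through the generator (stems inflated to 1-4 bp,
  # random bulges) and collapsing recovers the token
  toks <- c("ABAB", "ABACBC", "ABCABC", "ABCACDBD", "ABCDCADB")
  for (seed in 1:10) {
    tok <- toks[1L + seed %% length(toks)]
    fx <- generate_fixture(list(list(token = tok, stem = c(1, 4),
                                     bulge = 0.3)), seed = seed)
    comps <- extract_primitive(fx$record)
    expect_length(comps, 1L)
    expect_equal(pattern_token(collapse_stems(comps[[1]]$diagram)), tok)
  }
})

test_that("token to diagram conversion validates its input", {
  expect_error(token_diagram("ABA"), "exactly twice")
  expect_error(token_diagram("AB!A"), "unrecognised")
  expect_equal(nrow(token_diagram("")$arcs), 0L)
  # extended alphabet beyond 26 arcs round-trips
  d <- token_diagram(paste0(paste(LETTERS, collapse = ""), "a1",
                            paste(rev(LETTERS), collapse = ""), "a1"))
  expect_equal(nrow(d$arcs), 27L)
})
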