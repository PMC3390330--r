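test_that("deduplication keeps the first record per identical sequence", {
  a <- rna_structure(4, c(1, 4), "GAAC")
  b <- rna_structure(4, c(2, 3), "GAAC")   # same sequence, other structure
  c_ <- rna_structure(4, c(1, 4), "GGCC")
  kept <- dedupe(list(a = a, b = b, c = c_))
  expect_equal(names(kept), c("a", "c"))
  expect_equal(nrow(kept$a$pairs), 1L)

  no_seq <- rna_structure(4, c(1, 4))
  expect_length(dedupe(list(x = no_seq, y = no_seq)), 2L)
  expect_length(dedupe(list()), 0L)
})

test_that("classification tabulates subclasses with span statistics", {
  # one H-pseudoknot with 2-bp stems arranged over a 17-nt span
  hpk <- rna_structure(20, rbind(c(2, 11), c(3, 10), c(7, 18), c(8, 17)))
  res <- classify_dataset(list(s1 = hpk))
  expect_equal(nrow(res$subclasses), 1L)
  row <- res$subclasses[1L, ]
  expect_equal(row$genus, 1L)
  expect_equal(row$subclass_id, "1A")
  expect_equal(row$token, "ABAB")
  expect_equal(row$n_sequences, 1L)
  expect_equal(row$length_min, 17L)
  expect_length(res$discarded, 0L)

  # empty dataset
  empty <- classify_dataset(list())
  expect_equal(nrow(empty$subclasses), 0L)

  # pseudoknot-free structures land in the discard list
  free <- classify_dataset(list(pf = parse_dotbracket("((..))")))
  expect_equal(free$discarded, "pf")
})

test_that("subclass letters follow structure counts within each genus", {
  mk <- function(seed, tokens) generate_fixture(
    lapply(tokens, function(t) list(token = t, stem = c(1, 2))), seed = seed)
  recs <- list(
    r1 = mk(1, "ABAB")$record,
    r2 = mk(2, "ABAB")$record,
    r3 = mk(3, c("ABAB", "ABACBC"))$record)
  res <- classify_dataset(recs)
  sub <- res$subclasses
  expect_equal(sub$token[sub$subclass_id == "1A"], "ABAB")
  expect_equal(sub$n_sequences[sub$subclass_id == "1A"], 3L)
  expect_equal(sub$token[sub$subclass_id == "1B"], "ABACBC")
  expect_equal(sub$n_sequences[sub$subclass_id == "1B"], 1L)
})

test_that("the pipeline recovers planted token-genus multisets", {
  specs <- list(
    list(list(token = "ABAB", stem = c(2, 4), bulge = 0.2)),
    list(list(token = "ABACBC", stem = c(1, 3)),
         list(token = "ABAB", stem = c(1, 2))),
    list(list(token = "ABCACDBD", stem = c(1, 3), bulge = 0.2),
         list(token = "ABAB", stem = c(2, 5))),
    list(list(token = "ABCDCADB", stem = c(1, 2)),
         list(token = "ABCABC", stem = c(1, 2))))
  fxs <- generate_fixture_set(specs, seed = 11, decoy_hairpins = 1L)
  res <- classify_dataset(fxs$records)
  got <- res$components[order(res$components$origin, res$components$token),
                        c("origin", "token", "genus")]
  want <- fxs$truth[order(fxs$truth$origin, fxs$truth$token),
                    c("origin", "token", "genus")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("total-genus histogram bins whole structures", {
  triple <- parse_dotbracket("([)]([)]([)]")
  h <- total_genus_histogram(list(t = triple))
  expect_equal(h$total_genus, 3L)
  expect_equal(h$n, 1L)

  flat <- list(a = parse_dotbracket("(..)"), b = parse_dotbracket("((..))"))
  h2 <- total_genus_histogram(flat)
  expect_equal(h2$total_genus, 0L)
  expect_equal(h2$n, 2L)

  fxs <- generate_fixture_set(list(
    list(list(token = "ABAB", stem = c(1, 2))),
    list(list(token = "ABAB", stem = c(1, 2)),
         list(token = "ABACBC", stem = c(1, 2))),
    list(list(token = "ABCACDBD", stem = c(1, 2)))), seed = 5)
  h3 <- total_genus_histogram(fxs$records)
  expect_equal(h3$total_genus, 1:2)
  expect_equal(h3$n, c(1L, 2L))
  expect_equal(sum(h3$n), length(fxs$records))
  expect_equal(sum(h3$proportion), 1)
})

test_that("classification is invariant under record reordering", {
  fxs <- generate_fixture_set(list(
    list(list(token = "ABAB", stem = c(1, 3))),
    list(list(token = "ABACBC", stem = c(1, 2))),
    list(list(token = "ABCABC", stem = c(1, 2)))), seed = 21)
  fwd <- classify_dataset(fxs$records)$subclasses
  rev_ <- classify_dataset(rev(fxs$records))$subclasses
  expect_equal(fwd, rev_)
})

test_that("the fixture generator is deterministic and validates its input", {
  spec <- list(list(token = "ABACBC", stem = c(1, 4), bulge = 0.3))
  f1 <- generate_fixture(spec, seed = 42, decoy_hairpins = 2L)
  f2 <- generate_fixture(spec, seed = 42, decoy_hairpins = 2L)
  expect_identical(f1$dotbracket, f2$dotbracket)
  expect_identical(f1$record$sequence, f2$record$sequence)
  f3 <- generate_fixture(spec, seed = 43, decoy_hairpins = 2L)
  expect_false(identical(f1$dotbracket, f3$dotbracket))

  expect_error(generate_fixture(list(list(token = "ABBA", stem = c(1, 2))),
                                seed = 1), "not a canonical shadow")
  expect_error(generate_fixture(list(list(token = "ABAB", stem = c(0, 2))),
                                seed = 1), "within 1..20")

  # generator leaves the caller's RNG state alone
  set.seed(7); before <- .Random.seed
  invisible(generate_fixture(spec, seed = 1))
  expect_identical(.Random.seed, before)
})
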