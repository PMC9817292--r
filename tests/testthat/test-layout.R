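test_that("layout atoms follow SMILES order with one coordinate per atom", {
  lay <- buildAtomLayout("CCO")
  expect_identical(nAtoms(lay), 3L)
  # first atom in the string is the first node of the depicted graph
  mol <- smivis:::obParseSmiles("OCC")
  expect_identical(mol$symbols, c("O", "C", "C"))

  lay1 <- buildAtomLayout("C")
  expect_identical(nAtoms(lay1), 1L)
  expect_identical(dim(atomCoords(lay1)), c(1L, 2L))
  expect_identical(nrow(atomBonds(lay1)), 0L)

  ring <- buildAtomLayout("C1CC1")
  expect_identical(atomRings(ring), list(1:3))
})

test_that("unparseable SMILES raise a parse error from the toolkit", {
  expect_error(buildAtomLayout("CXC"), "position|parseable")
  expect_error(smivis:::obParseSmiles("QQ"), "parseable")
})

test_that("branch hover resolves the full parenthesized span", {
  seq <- tokenizeSmiles("CC(C)O")
  lay <- buildAtomLayout("CC(C)O")
  h <- resolveHover(seq, lay, 3L)  # the "("
  expect_identical(highlightKind(h), "BRANCH")
  expect_identical(tokenIndices(h), 3:5)   # "(", "C", ")"
  expect_identical(atomIndices(h), 3L)
  # nested branches are included
  seq2 <- tokenizeSmiles("CC(C(N)C)O")
  lay2 <- buildAtomLayout("CC(C(N)C)O")
  h2 <- resolveHover(seq2, lay2, 3L)
  expect_identical(tokenIndices(h2), 3:9)
  expect_identical(atomIndices(h2), c(3L, 4L, 5L))
})

test_that("ring hover highlights both partner digits and the ring atoms", {
  seq <- tokenizeSmiles("C1CCCCC1")
  lay <- buildAtomLayout("C1CCCCC1")
  h <- resolveHover(seq, lay, 2L)  # first "1"
  expect_identical(highlightKind(h), "RING")
  expect_identical(tokenIndices(h), c(2L, 8L))
  expect_identical(atomIndices(h), 1:6)
  # fused system: the closure bond picks its own smallest ring
  seqN <- tokenizeSmiles("c1ccc2ccccc2c1")
  layN <- buildAtomLayout("c1ccc2ccccc2c1")
  h2 <- resolveHover(seqN, layN, 6L)  # the "2" digit
  expect_identical(highlightKind(h2), "RING")
  expect_length(atomIndices(h2), 6L)
})

test_that("bracket-group hover resolves from any token of the group", {
  seq <- tokenizeSmiles("[N+]C")
  lay <- buildAtomLayout("[N+]C")
  for (i in 1:4) {
    h <- resolveHover(seq, lay, i)
    expect_identical(highlightKind(h), "GROUP")
    expect_identical(tokenIndices(h), 1:4)
    expect_identical(atomIndices(h), 1L)
  }
})

test_that("bond and dot hover resolve to the atoms joined", {
  seq <- tokenizeSmiles("CC(C)=O")
  lay <- buildAtomLayout("CC(C)=O")
  h <- resolveHover(seq, lay, 6L)  # "=" after the branch
  expect_identical(highlightKind(h), "BOND")
  expect_identical(atomIndices(h), c(2L, 4L))  # joins C2 and O, not branch C
  seqD <- tokenizeSmiles("C.C")
  layD <- buildAtomLayout("C.C")
  hD <- resolveHover(seqD, layD, 2L)
  expect_identical(atomIndices(hD), integer(0))
})

test_that("structural errors name the offending token", {
  seq <- tokenizeSmiles("CC(")
  lay <- buildAtomLayout("CC(C)O")  # any layout; error comes first
  expect_error(resolveHover(seq, lay, 3L), "unmatched")
  expect_error(checkStructure(tokenizeSmiles("CC(")), "unmatched.*3")
  expect_error(checkStructure(tokenizeSmiles("C1CC")), "ring-closure")
  expect_error(checkStructure(tokenizeSmiles("[NH4")), "unmatched")
})

test_that("atom hover is the inverse of atom-token hover", {
  seq <- tokenizeSmiles("CCO")
  expect_identical(tokenIndices(resolveAtomHover(seq, 3L)), 3L)
  seqB <- tokenizeSmiles("[N+]C")
  expect_identical(tokenIndices(resolveAtomHover(seqB, 1L)), 2L)
  expect_identical(tokenIndices(resolveAtomHover(tokenizeSmiles("C"), 1L)), 1L)
  expect_error(resolveAtomHover(seq, 4L), "out of range")
})

test_that("hover map export is complete and symmetric", {
  seq <- tokenizeSmiles("CCO")
  hm <- exportHoverMap(seq, buildAtomLayout("CCO"))
  expect_length(hm$tokens, 3L)
  expect_length(hm$atoms, 3L)

  seqR <- tokenizeSmiles("C1CC1")
  hmR <- exportHoverMap(seqR, buildAtomLayout("C1CC1"))
  expect_length(hmR$tokens, 5L)
  expect_identical(hmR$tokens[[2]]$atoms, hmR$tokens[[5]]$atoms)

  seqB <- tokenizeSmiles("CC(C)O")
  hmB <- exportHoverMap(seqB, buildAtomLayout("CC(C)O"))
  expect_identical(hmB$tokens[[3]], hmB$tokens[[5]])
})

test_that("pair resolution matches brute-force oracles on all fixtures", {
  for (s in fixtureSet) {
    seq <- tokenizeSmiles(s)
    lay <- buildAtomLayout(s)
    tk <- tokenTable(seq)
    oracle <- stackMatchParens(s)
    for (i in seq_len(nrow(tk))) {
      if (tk$kind[i] == "BRANCH_OPEN") {
        h <- resolveHover(seq, lay, i)
        # character position of the matching ")" from the stack oracle
        expect_identical(tk$charEnd[max(tokenIndices(h))],
                         oracle[tk$charStart[i]])
        # branch symmetry: "(" and its ")" resolve identically
        h2 <- resolveHover(seq, lay, max(tokenIndices(h)))
        expect_identical(tokenIndices(h), tokenIndices(h2))
        expect_identical(atomIndices(h), atomIndices(h2))
      }
      if (tk$kind[i] == "RING_BOND") {
        h <- resolveHover(seq, lay, i)
        partner <- setdiff(tokenIndices(h), i)
        expect_length(partner, 1L)
        # ring partner symmetry: partner(partner(d)) == d
        expect_identical(tokenIndices(resolveHover(seq, lay, partner)),
                         tokenIndices(h))
      }
    }
    # atom/token inversion over every atom token
    for (p in atomTokenPositions(seq)) {
      a <- tk$atomIndex[p]
      expect_identical(tokenIndices(resolveAtomHover(seq, a)), p)
    }
  }
})
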