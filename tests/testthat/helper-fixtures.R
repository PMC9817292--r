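# Fixture SMILES set used by the property suites: built programmatically
# from scaffold x substituent combinations plus hand-picked strings
# covering brackets, isotopes, charges, ring-closure labels, dots, stereo
# bonds, fused and bridged rings. All strings are valid SMILES.

fixtureSet <- local({
  scaffolds <- c("c1ccccc1%s", "C1CCCCC1%s", "c1ccncc1%s",
                 "OC(=O)%s", "CC(=O)N%s", "c1ccc2c(c1)cccc2%s")
  subs <- c("C", "CC", "CCC", "O", "OC", "N", "NC", "F", "Cl", "Br", "I",
            "S", "SC", "C#N", "C=C", "CO", "C(C)C", "C(F)(F)F",
            "C(=O)OC", "CN(C)C", "COC", "CC(C)O", "C1CC1", "CC=O")
  generated <- as.vector(outer(scaffolds, subs,
                               function(sc, su) sprintf(sc, su)))
  hand <- c(
    "[N+]", "[NH4+]", "[O-]C(=O)C", "[13CH4]", "[2H]OC", "[nH]1cccc1",
    "C[C@H](N)C(=O)O", "C[C@@H](O)C", "N[C@@H](C)C(=O)O",
    "C/C=C/C", "C/C=C\\C", "F/C=C/F",
    "C%10CCCCC%10", "C%12CC%12", "C1CC2CCC1CC2", "C1CC11CC1",
    "[Na+].[Cl-]", "CC(=O)O.OCC", "C.C.C",
    "[nH]1ccc2c1cccc2", "c1cc[n+](C)cc1", "[O-][n+]1ccccc1",
    "O=S(=O)(O)O", "OP(=O)(O)O", "CSC", "CS(=O)C",
    "ClC(Cl)(Cl)Cl", "BrCCBr", "ICI",
    "C#CC", "CC#CC", "C=C=C", "OC=O",
    "c1ccc(cc1)c1ccccc1", "Cc1ccc(C)cc1", "COc1ccccc1OC",
    "C1=CC=CC=C1", "C1CCNCC1", "C1COCCO1", "O1CCOCC1",
    "CC(C)(C)C", "CCCCCCCCCC", "C(C(C(C)))C")
  unique(c(generated, hand, smivis::fixtureSmiles()))
})

# independent brute-force parenthesis matcher (character-level) used as the
# oracle for branch-span resolution
stackMatchParens <- function(smiles) {
  ch <- strsplit(smiles, "")[[1]]
  stack <- integer(0)
  partner <- rep(NA_integer_, length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  partner
}

# independent atom counts from RDKit (one batched call, cached per session)
rdkitAtomCounts <- function(smiles) {
  py <- Sys.which("python")
  script <- tempfile(fileext = ".py")
  fin <- tempfile(); fout <- tempfile()
  on.exit(unlink(c(script, fin, fout)))
  writeLines(c(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "out = []",
    "for line in open(sys.argv[1]):",
    "    m = Chem.MolFromSmiles(line.rstrip('\\n'), sanitize=False)",
    "    out.append(None if m is None else m.GetNumAtoms())",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  writeLines(smiles, fin)
  status <- system2(py, c(script, fin, fout), stdout = FALSE, stderr = FALSE)
  stopifnot(identical(status, 0L))
  vapply(jsonlite::fromJSON(fout, simplifyVector = FALSE),
         function(x) if (is.null(x)) NA_integer_ else as.integer(x),
         integer(1))
}

# small valid record file written on the fly for IO tests
writeRecordFile <- function(path, records) {
  jsonlite::write_json(list(schema_version = "1.0", records = records),
                       path, auto_unbox = TRUE, digits = NA)
  path
}
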