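test_that("overhang validation enforces directional ligation chemistry", {
  ov <- validate_overhang("AG")
  expect_s3_class(ov, "overhang_pair")
  expect_equal(ov$top, "AG")
  expect_equal(ov$bottom, "TC")
  expect_equal(validate_overhang("GG")$bottom, "CC")

  for (pal in c("AT", "TA", "GC", "CG")) {
    expect_error(validate_overhang(pal), class = "bs_palindrome_error")
  }
  expect_error(validate_overhang("AX"), class = "bs_alphabet_error")
  expect_error(validate_overhang("AGG"), class = "bs_alphabet_error")

  bases <- c("A", "C", "G", "T")
  dins <- as.vector(outer(bases, bases, paste0))
  ok <- vapply(dins, function(d) {
    !inherits(tryCatch(validate_overhang(d), error = identity), "error")
  }, logical(1))
  expect_equal(sum(ok), 12L)
  expect_setequal(dins[!ok], c("AT", "TA", "GC", "CG"))
})

test_that("degenerate expansion enumerates the IUPAC product exactly", {
  expect_equal(expand_degenerate("GAS"), c("GAC", "GAG"))
  expect_equal(expand_degenerate("ACGT"), "ACGT")
  expect_length(expand_degenerate("NN"), 16L)
  expect_error(expand_degenerate("AXC"), class = "bs_alphabet_error")

  codes <- names(Biostrings::IUPAC_CODE_MAP)
  set.seed(11)
  for (i in 1:25) {
    s <- paste(sample(codes, sample(1:6, 1), replace = TRUE), collapse = "")
    got <- expand_degenerate(s)
    expect_equal(got, oracle_expand(s), info = s)
    expect_equal(length(got), unname(iupac_degeneracy(s)), info = s)
  }
})

test_that("codon cover search matches a brute-force oracle and is minimal", {
  de <- find_degenerate_codons(c("D", "E"))
  expect_true(all(lengths(de) == 1L))
  expect_true("GAS" %in% unlist(de))
  expect_true("GAK" %in% unlist(de))

  expect_true("ATH" %in% unlist(find_degenerate_codons("I")))
  expect_true("GSN" %in% unlist(find_degenerate_codons(c("A", "G"))))

  for (target in list(c("D", "E"), c("S", "T"), c("A", "G"), "I",
                      c("D", "E", "S", "T"))) {
    got <- find_degenerate_codons(target)
    want <- oracle_codon_covers(target)
    norm <- function(x) sort(vapply(x, paste, "", collapse = "+"))
    expect_equal(norm(got), norm(want),
                 info = paste(target, collapse = ""))
    # deterministic lexicographic ordering
    keys <- vapply(got, paste, "", collapse = "+")
    expect_equal(keys, sort(keys))
    # every solution covers the target exactly, no stop, minimal cardinality
    for (sol in got) {
      res <- unique(unlist(lapply(sol, oracle_residues)))
      expect_setequal(res, target)
    }
  }

  expect_error(find_degenerate_codons(character(0)),
               class = "bs_alphabet_error")
  expect_error(find_degenerate_codons("Z"), class = "bs_alphabet_error")
})

test_that("block construction honours patterns, alphabets and the overhang frame", {
  pa <- list(P = c("D", "E"), N = "I")
  b <- build_block("PPPPPP", pa, overhang = validate_overhang("GA"),
                   block_id = "b1")
  expect_equal(nchar(b$top_strand), 18L)
  expect_equal(substr(b$top_strand, 1, 2), "GA")
  exps <- expand_degenerate(b$top_strand)
  expect_equal(length(exps), unname(iupac_degeneracy(b$top_strand)))
  pep <- unique(unlist(strsplit(
    as.character(Biostrings::translate(Biostrings::DNAStringSet(exps))),
    "")))
  expect_true(all(pep %in% c("D", "E")))
  expect_setequal(pep, c("D", "E"))

  # hexapeptide invariant: patterns must have length 6
  expect_error(build_block("PPPPP", pa, block_id = "x"),
               class = "bs_design_error")

  # pure codon arithmetic without an overhang frame: poly-Ile block maps to
  # a single peptide whatever the codon degeneracy chosen
  bi <- build_block("NNNNNN", pa, overhang = NULL, block_id = "ile")
  exps <- expand_degenerate(bi$top_strand)
  expect_equal(length(exps), unname(iupac_degeneracy(bi$top_strand)))
  pep <- unique(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(exps))))
  expect_equal(pep, "IIIIII")
  # the fully degenerate Ile codon is among the admissible solutions and
  # expands to 3^6 sequences over that one peptide
  expect_true("ATH" %in% unlist(find_degenerate_codons("I")))
  expect_length(expand_degenerate(strrep("ATH", 6)), 729L)

  # no Ile codon can start with the AG overhang dinucleotide
  expect_error(
    build_block("NPPPPP", pa, overhang = validate_overhang("AG"),
                block_id = "x"),
    class = "bs_design_error"
  )
})

test_that("the synthetic study-scale catalog has the published aggregate shape", {
  cat168 <- study_catalog()
  s <- catalog_stats(cat168)
  expect_equal(s$n_blocks, 168L)
  expect_equal(s$n_distinct_expansions, 8288L)
  expect_equal(s$alphabet_size, 10L)
  expect_equal(s$alphabet,
               c("A", "D", "E", "G", "I", "L", "P", "S", "T", "V"))
  expect_equal(unname(as.vector(s$per_structure)), c(56L, 56L, 56L))

  # every block: 18 nt, shared AG overhang in frame, stop-free expansions
  # inside the ten-residue alphabet
  expect_true(all(nchar(cat168$blocks$top_strand) == 18L))
  expect_true(all(startsWith(cat168$blocks$top_strand, "AG")))
  set.seed(3)
  for (i in sample(nrow(cat168$blocks), 12)) {
    exps <- expand_degenerate(cat168$blocks$top_strand[i])
    pep <- as.character(Biostrings::translate(Biostrings::DNAStringSet(exps)))
    expect_false(any(grepl("*", pep, fixed = TRUE)))
    expect_true(all(unlist(strsplit(pep, "")) %in% s$alphabet))
  }
})

test_that("catalog summaries use set semantics over expansions", {
  cat1 <- block_catalog(
    list(blockshuffler:::new_block(rep("GAC", 6), block_id = "only")),
    adapter5 = default_adapter5(), adapter3 = default_adapter3()
  )
  expect_equal(catalog_stats(cat1)$n_distinct_expansions, 1L)

  # two blocks with identical expansions: the union counts each once, and
  # decoding refuses the ambiguous catalog
  cat2 <- block_catalog(
    list(blockshuffler:::new_block(rep("GAC", 6), block_id = "a"),
         blockshuffler:::new_block(rep("GAC", 6), block_id = "b")),
    adapter5 = default_adapter5(), adapter3 = default_adapter3()
  )
  expect_equal(catalog_stats(cat2)$n_distinct_expansions, 1L)
  expect_error(decode_blocks(strrep("GAC", 6), cat2),
               class = "bs_ambiguous_error")
})

test_that("catalog TSV and adapter FASTA round-trip", {
  cat12 <- tiny_catalog()
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fa")
  write_catalog(cat12, tsv, header_comment = "seed=1")
  write_adapters(cat12, fa)
  back <- read_catalog(tsv, adapter_fasta = fa)
  expect_equal(back$blocks$top_strand, cat12$blocks$top_strand)
  expect_equal(back$blocks$block_id, cat12$blocks$block_id)
  expect_equal(back$adapter5, cat12$adapter5)
  expect_equal(back$adapter3, cat12$adapter3)
  expect_equal(back$overhang$top, "AG")
})
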