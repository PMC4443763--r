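test_that("co-occurrence counts ordered adjacent pairs of multi-block reads", {
  cat12 <- tiny_catalog()
  ids <- cat12$blocks$block_id

  d <- make_decoded(c(paste(ids[1], ids[2], ids[3], sep = ","),
                      ids[1], ids[4]))
  m <- cooccurrence(d, cat12)
  expect_equal(sum(m), 2L) # (b1,b2) and (b2,b3); single-block reads ignored
  expect_equal(m[ids[1], ids[2]], 1L)
  expect_equal(m[ids[2], ids[3]], 1L)
  # dimension covers blocks observed in multi-block reads only
  expect_setequal(rownames(m), ids[1:3])

  # UNMATCHED breaks adjacency: no pair spans the corrupted unit
  d2 <- make_decoded(paste(ids[1], "UNMATCHED", ids[3], sep = ","))
  m2 <- cooccurrence(d2, cat12)
  expect_equal(sum(m2), 0L)
  expect_setequal(rownames(m2), ids[c(1, 3)])
})

test_that("co-occurrence totals equal sum(n_blocks - 1) over clean multi-block reads", {
  cat12 <- tiny_catalog()
  set.seed(23)
  pool <- fragment_pool(cat12, 4000)
  prods <- simulate_ligation(cat12, pool, seed = 23)
  reads <- simulate_reads(prods, cat12,
                          sim_config(seed = 24, substitution_rate = 0,
                                     n_rate = 0, read_length = 5000))
  dec <- decode_reads(reads, cat12)
  m <- cooccurrence(dec, cat12)
  multi <- dec$n_blocks[!is.na(dec$n_blocks) & dec$n_blocks >= 2]
  expect_equal(sum(m), sum(multi - 1L))
  expect_equal(attr(m, "n_multi"), length(multi))
  # rows follow catalog order (grouped by structure)
  expect_equal(rownames(m),
               cat12$blocks$block_id[cat12$blocks$block_id %in% rownames(m)])
})

test_that("a block absent from the pool drops the matrix dimension by one", {
  cat12 <- tiny_catalog()
  gone <- cat12$blocks$block_id[7]
  set.seed(29)
  pool <- fragment_pool(cat12, 6000, exclude = gone)
  expect_equal(unname(pool$block_counts[gone]), 0L)
  prods <- simulate_ligation(cat12, pool, seed = 29)
  reads <- simulate_reads(prods, cat12,
                          sim_config(seed = 30, substitution_rate = 0,
                                     n_rate = 0, read_length = 5000))
  dec <- decode_reads(reads, cat12)
  m <- cooccurrence(dec, cat12)
  expect_equal(nrow(m), nrow(cat12$blocks) - 1L)
  expect_false(gone %in% rownames(m))
})

test_that("representation window search finds the best decade", {
  all_eq <- data.frame(count = rep(100L, 20))
  expect_equal(representation_stats(all_eq)$fraction, 1)

  spread <- data.frame(count = c(10L, 100L, 1000L, 100000L))
  rs <- representation_stats(spread)
  expect_equal(rs$fraction, 0.5)
  expect_equal(rs$n_in, 2L)

  # unbiased multinomial sampling concentrates within one decade
  set.seed(41)
  counts <- as.integer(table(factor(sample.int(50, 5e4, replace = TRUE),
                                    levels = 1:50)))
  expect_equal(representation_stats(data.frame(count = counts))$fraction, 1)

  expect_error(representation_stats(data.frame(count = integer(0))),
               class = "bs_config_error")
})

test_that("non-redundant counts use exact set semantics", {
  cat12 <- tiny_catalog()
  i1 <- strrep(expand_degenerate(cat12$blocks$top_strand[1])[1], 2)
  i2 <- strrep(expand_degenerate(cat12$blocks$top_strand[2])[1], 2)
  i3 <- strrep(expand_degenerate(cat12$blocks$top_strand[3])[1], 2)
  d <- make_decoded(rep("a,b", 4), insert = c(i1, i2, i3, i1))
  nr <- nonredundant_counts(d)
  expect_equal(nr$n_distinct[nr$n_blocks == 2], 3L)
  expect_equal(nr$n_reads[nr$n_blocks == 2], 4L)

  # error-free simulation tracks the occupancy expectation
  set.seed(43)
  pool <- fragment_pool(cat12, 4000)
  prods <- simulate_ligation(cat12, pool, seed = 43)
  reads <- simulate_reads(prods, cat12,
                          sim_config(seed = 44, substitution_rate = 0,
                                     n_rate = 0, read_length = 5000))
  dec <- decode_reads(reads, cat12)
  nr <- nonredundant_counts(dec)
  D <- catalog_stats(cat12)$n_distinct_expansions
  for (k in nr$n_blocks[nr$n_blocks <= 2]) {
    expl <- expected_distinct(nr$n_reads[nr$n_blocks == k], D^k)
    expect_equal(nr$n_distinct[nr$n_blocks == k], expl,
                 tolerance = 0.05)
  }
})

test_that("the NNK enumeration is exact and closed-form", {
  f <- nnk_frequencies()
  expect_equal(sum(f$frequency), 1, tolerance = 1e-12)
  expect_equal(attr(f, "n_codons"), 32L)
  # one stop codon present (TAG); TAA and TGA avoided
  expect_equal(attr(f, "stop_codons_present"), "TAG")
  expect_equal(f$frequency[f$residue == "*"], 1 / 32)
  # all twenty amino acids covered
  covered <- f$residue[f$frequency > 0 & f$residue != "*"]
  expect_length(covered, 20L)
  # spot-check known NNK codon multiplicities
  expect_equal(f$frequency[f$residue == "R"], 3 / 32) # CGG,CGT,AGG
  expect_equal(f$frequency[f$residue == "M"], 1 / 32) # ATG
  expect_equal(f$frequency[f$residue == "L"], 3 / 32) # CTG,CTT,TTG
  # independent recount straight from the genetic code
  codons <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                  paste0), c("G","T"), paste0))
  res <- unname(oracle_gc[codons])
  for (aa in unique(res)) {
    expect_equal(f$frequency[f$residue == aa], sum(res == aa) / 32,
                 info = aa)
  }
})

test_that("amino-acid frequency tables are normalized and consistent", {
  # single-block GAS x 6 catalog: Asp and Glu each at 0.5
  gas <- block_catalog(
    list(blockshuffler:::new_block(rep("GAS", 6), block_id = "gas")),
    adapter5 = default_adapter5(), adapter3 = default_adapter3()
  )
  f <- aa_frequencies(gas)
  expect_equal(sum(f$frequency), 1, tolerance = 1e-9)
  expect_equal(f$frequency[f$residue == "D"], 0.5)
  expect_equal(f$frequency[f$residue == "E"], 0.5)

  # design catalog restricted to ten residues: everything else at zero
  f168 <- aa_frequencies(study_catalog())
  expect_equal(sum(f168$frequency), 1, tolerance = 1e-9)
  ten <- c("A", "D", "E", "G", "I", "L", "P", "S", "T", "V")
  expect_true(all(f168$frequency[!(f168$residue %in% ten)] == 0))
  expect_true(all(f168$frequency[f168$residue %in% ten] > 0))

  # decoded error-free library matches the catalog design within
  # sampling error
  cat12 <- tiny_catalog()
  set.seed(47)
  pool <- fragment_pool(cat12, 6000)
  prods <- simulate_ligation(cat12, pool, seed = 47)
  reads <- simulate_reads(prods, cat12,
                          sim_config(seed = 48, substitution_rate = 0,
                                     n_rate = 0, read_length = 5000))
  dec <- decode_reads(reads, cat12)
  fo <- aa_frequencies(dec)
  fc <- aa_frequencies(cat12)
  expect_equal(sum(fo$frequency), 1, tolerance = 1e-9)
  for (aa in fc$residue[fc$frequency > 0]) {
    expect_equal(fo$frequency[fo$residue == aa],
                 fc$frequency[fc$residue == aa],
                 tolerance = 0.25, info = aa)
  }
})

test_that("unbiased simulation yields multinomial block representation", {
  cat12 <- tiny_catalog()
  rejections <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    pool <- fragment_pool(cat12, 3000)
    prods <- simulate_ligation(cat12, pool, seed = seed)
    reads <- simulate_reads(prods, cat12,
                            sim_config(seed = seed + 100,
                                       substitution_rate = 0, n_rate = 0,
                                       read_length = 5000))
    dec <- decode_reads(reads, cat12)
    counts <- representation_counts(dec, cat12)$count
    p <- suppressWarnings(stats::chisq.test(counts)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  # expected false rejections at alpha = 0.01 over 10 seeds: 0.1
  expect_lte(rejections, 2L)
})
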