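# Independent oracles and shared fixtures. The oracles deliberately avoid
# the package's own IUPAC/search code paths: they re-derive expansions and
# codon covers from Biostrings tables with plain loops.

oracle_iupac <- strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
oracle_gc <- Biostrings::GENETIC_CODE

# brute-force expansion of a degenerate string via expand.grid
oracle_expand <- function(seq) {
  sets <- oracle_iupac[strsplit(seq, "", fixed = TRUE)[[1]]]
  grid <- do.call(expand.grid,
                  c(rev(sets), list(stringsAsFactors = FALSE)))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste,
             collapse = ""))
}

oracle_residues <- function(codon) {
  sort(unique(unname(oracle_gc[oracle_expand(codon)])))
}

# all minimal codon covers of `target` up to pairs, by direct enumeration
# over admissible codons (a codon encoding anything outside the target can
# never be part of a valid cover)
oracle_codon_covers <- function(target) {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  all3 <- sort(as.vector(outer(outer(codes, codes, paste0), codes, paste0)))
  res <- lapply(all3, oracle_residues)
  adm <- vapply(res, function(r) !("*" %in% r) && all(r %in% target),
                logical(1))
  cods <- all3[adm]
  res <- res[adm]
  singles <- cods[vapply(res, function(r) setequal(r, target), logical(1))]
  if (length(singles)) {
    return(lapply(sort(singles), identity))
  }
  pairs <- list()
  for (i in seq_along(cods)) {
    for (j in seq_along(cods)) {
      if (j <= i) next
      if (setequal(union(res[[i]], res[[j]]), target)) {
        pairs[[length(pairs) + 1L]] <- c(cods[i], cods[j])
      }
    }
  }
  pairs
}

# Monte-Carlo occupancy: mean distinct values among N uniform draws from K
oracle_occupancy <- function(N, K, reps = 10) {
  mean(vapply(seq_len(reps), function(r) {
    length(unique(sample.int(K, N, replace = TRUE)))
  }, numeric(1)))
}

# analytic probability that a read of concatenated codons still classifies
# `correct` under per-base substitution rate e: for each truth codon, sum
# the probabilities of all 64 outcome codons whose residue stays inside the
# alphabet (and is not a stop)
oracle_correct_prob <- function(insert, e, alphabet) {
  bases <- c("A", "C", "G", "T")
  codons <- substring(insert, seq(1, nchar(insert), 3),
                      seq(3, nchar(insert), 3))
  p_codon <- vapply(codons, function(cd) {
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    out <- expand.grid(bases, bases, bases, stringsAsFactors = FALSE)
    p <- 0
    for (i in seq_len(nrow(out))) {
      o <- c(out[i, 1], out[i, 2], out[i, 3])
      pr <- prod(ifelse(unlist(o) == ch, 1 - e, e / 3))
      aa <- oracle_gc[paste(unlist(o), collapse = "")]
      if (aa != "*" && aa %in% alphabet) p <- p + pr
    }
    p
  }, numeric(1))
  prod(p_codon)
}

# one shared study-scale catalog (expensive to build; reused across files)
study_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_catalog()
    cache
  }
})

# small catalog for fast simulations: 12 blocks, same chemistry
tiny_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synthetic_catalog(n = c(helix = 4, strand = 4, loop = 4),
                                  n_full = c(helix = 3, strand = 3, loop = 3))
    }
    cache
  }
})

# build a read_set frame without simulation
make_reads <- function(sequence, quality = NULL,
                       read_id = sprintf("r%03d", seq_along(sequence))) {
  if (is.null(quality)) {
    quality <- vapply(nchar(sequence), function(n) {
      paste(rep("I", n), collapse = "")
    }, "")
  }
  structure(
    data.frame(read_id = read_id, sequence = sequence, quality = quality,
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame")
  )
}

# decoded_reads frame constructed directly (for libstats unit tests)
make_decoded <- function(block_calls, insert = NULL) {
  n_blocks <- vapply(strsplit(block_calls, ",", fixed = TRUE), length, 1L)
  if (is.null(insert)) {
    insert <- vapply(n_blocks, function(n) {
      paste(rep("AGCGACGACGACGACGAC", n), collapse = "")
    }, "")
  }
  structure(
    data.frame(
      read_id = sprintf("d%03d", seq_along(block_calls)),
      insert = insert,
      insert_len = nchar(insert),
      n_blocks = n_blocks,
      block_calls = block_calls,
      category = factor(rep("correct", length(block_calls)),
                        levels = c("correct", "nonsense", "missense",
                                   "wrong_length")),
      peptide = rep(NA_character_, length(block_calls)),
      stringsAsFactors = FALSE
    ),
    class = c("decoded_reads", "data.frame")
  )
}
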