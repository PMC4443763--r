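## One-pot directional ligation simulation, occupancy-based diversity
## estimation, and FASTQ read simulation.

#' Assemble a fragment pool for ligation
#'
#' Molecule counts for each block plus single-ended 5'/3' adapters. Block
#' identities are either given exactly (`block_counts`) or drawn
#' multinomially with uniform probabilities over the included blocks, which
#' models pipetting an equimolar block mix. Adapter counts follow the
#' bench stoichiometry, 1:8:1 (5' adapter : block : 3' adapter) by default.
#'
#' @param catalog a [block_catalog()].
#' @param n_blocks total number of block molecules.
#' @param ratio length-3 stoichiometry (adapter5 : block : adapter3).
#' @param exclude block ids absent from the pool (count zero).
#' @param block_counts optional named vector of exact per-block counts
#'   (overrides `n_blocks`/`exclude`).
#' @return object of class `fragment_pool`.
#' @export
fragment_pool <- function(catalog, n_blocks, ratio = c(1, 8, 1),
                          exclude = NULL, block_counts = NULL) {
  stopifnot(inherits(catalog, "block_catalog"), length(ratio) == 3)
  ids <- catalog$blocks$block_id
  if (is.null(block_counts)) {
    use <- setdiff(ids, exclude)
    if (!length(use) || n_blocks <= 0) {
      bs_stop("pool must contain at least one block molecule",
              "bs_config_error")
    }
    draw <- sample(use, n_blocks, replace = TRUE)
    block_counts <- setNames(integer(length(ids)), ids)
    tab <- table(draw)
    block_counts[names(tab)] <- as.integer(tab)
  } else {
    stopifnot(all(names(block_counts) %in% ids))
    full <- setNames(integer(length(ids)), ids)
    full[names(block_counts)] <- as.integer(block_counts)
    block_counts <- full
    n_blocks <- sum(block_counts)
    if (n_blocks <= 0) {
      bs_stop("pool must contain at least one block molecule",
              "bs_config_error")
    }
  }
  structure(
    list(block_counts = block_counts,
         adapter5_count = as.integer(round(n_blocks * ratio[1] / ratio[2])),
         adapter3_count = as.integer(round(n_blocks * ratio[3] / ratio[2])),
         stoichiometry = ratio),
    class = "fragment_pool"
  )
}

#' Read-simulation configuration
#'
#' @param seed integer RNG seed, or `NULL` to leave the RNG state alone.
#' @param n_products target number of ligation products (used by pipeline
#'   drivers when sizing pools).
#' @param substitution_rate per-base substitution probability.
#' @param n_rate per-base probability of an uncalled (N) base.
#' @param read_length bases sequenced from the 5' end (150 emulates a MiSeq
#'   single read).
#' @param q_start,q_end Phred qualities at read start/end; per-base quality
#'   decays linearly between them, emulating the end-of-read deterioration
#'   of Illumina runs.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL, n_products = 10000,
                       substitution_rate = 0.003, n_rate = 5e-4,
                       read_length = 150, q_start = 36, q_end = 18) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            n_rate >= 0, n_rate <= 1, read_length > 0)
  structure(
    list(seed = seed, n_products = n_products,
         substitution_rate = substitution_rate, n_rate = n_rate,
         read_length = as.integer(read_length),
         q_start = q_start, q_end = q_end),
    class = "sim_config"
  )
}

#' Simulate one-pot directional ligation to end-exhaustion
#'
#' Discrete random end-joining: molecules (blocks and single-ended adapters)
#' are joined two uniformly chosen compatible ends at a time until no two
#' distinct chains present a compatible pair. Adapters terminate growth on
#' their side; blocks cannot invert (single non-palindromic overhang) and
#' chains cannot circularize (adapters are mono-phosphorylated in-model).
#' Each block molecule carries a concrete sequence drawn uniformly from its
#' degenerate expansion set.
#'
#' @param catalog a [block_catalog()].
#' @param pool a [fragment_pool()].
#' @param seed optional integer seed.
#' @return a `ligation_products` data frame with columns `product_id`,
#'   `n_blocks`, `has_adapter5`, `has_adapter3`, `block_ids`
#'   (comma-separated, in 5' to 3' order) and `insert` (concatenated
#'   concrete 18-nt units).
#' @export
simulate_ligation <- function(catalog, pool, seed = NULL) {
  stopifnot(inherits(pool, "fragment_pool"))
  if (!is.null(seed)) set.seed(seed)
  counts <- pool$block_counts
  nb <- sum(counts)
  if (nb <= 0) bs_stop("pool contains no blocks", "bs_config_error")
  block_of <- rep.int(seq_along(counts), counts) # molecule -> block row
  type <- c(rep.int(0L, pool$adapter5_count),
            rep.int(1L, nb),
            rep.int(2L, pool$adapter3_count))
  mol_block <- c(rep.int(NA_integer_, pool$adapter5_count), block_of,
                 rep.int(NA_integer_, pool$adapter3_count))

  ## concrete expansion per block molecule
  mol_seq <- rep.int(NA_character_, length(type))
  strands <- catalog$blocks$top_strand
  for (b in which(counts > 0)) {
    e <- block_expansions(strands[b])
    idx <- which(mol_block == b)
    mol_seq[idx] <- e[sample.int(length(e), length(idx), replace = TRUE)]
  }

  lig <- ligate_chains(type)
  ord <- lig$order
  lens <- lig$len
  chain_id <- rep.int(seq_along(lens), lens)

  mol_t <- type[ord]
  first <- cumsum(lens) - lens + 1L
  last <- cumsum(lens)
  has5 <- mol_t[first] == 0L
  has3 <- mol_t[last] == 2L

  is_block <- mol_t == 1L
  ids <- catalog$blocks$block_id[mol_block[ord[is_block]]]
  seqs <- mol_seq[ord[is_block]]
  bchain <- chain_id[is_block]
  nblk <- tabulate(bchain, nbins = length(lens))
  block_ids <- character(length(lens))
  insert <- character(length(lens))
  if (any(is_block)) {
    sp <- split(seq_along(bchain), bchain)
    touched <- as.integer(names(sp))
    block_ids[touched] <- vapply(sp, function(i) paste(ids[i], collapse = ","),
                                 "")
    insert[touched] <- vapply(sp, function(i) paste(seqs[i], collapse = ""),
                              "")
  }
  out <- data.frame(
    product_id = sprintf("p%06d", seq_along(lens)),
    n_blocks = nblk,
    has_adapter5 = has5,
    has_adapter3 = has3,
    block_ids = block_ids,
    insert = insert,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ligation_products", "data.frame")
  attr(out, "n_input_blocks") <- nb
  out
}

#' Length distribution of ligation products
#'
#' @param products a `ligation_products` frame (or any frame with
#'   `n_blocks`).
#' @return data frame with `n_blocks`, `count` and `bp` (18 x n).
#' @export
length_distribution <- function(products) {
  if (!nrow(products)) bs_stop("no products", "bs_config_error")
  tab <- table(products$n_blocks)
  data.frame(
    n_blocks = as.integer(names(tab)),
    count = as.integer(tab),
    bp = 18L * as.integer(names(tab))
  )
}

#' Expected number of distinct sequences under uniform sampling
#'
#' Classic occupancy (birthday-problem) expectation: drawing `N` sequences
#' uniformly from `K` equally likely possibilities yields
#' `K * (1 - (1 - 1/K)^N)` distinct sequences in expectation, computed in
#' the numerically stable `expm1`/`log1p` form so that very large `K`
#' (e.g. `8288^11`) does not underflow.
#'
#' @param N number of molecules drawn (vectorized).
#' @param K number of possible distinct sequences.
#' @return expected distinct count (real, between 0 and `min(K, N)`).
#' @export
expected_distinct <- function(N, K) {
  if (any(N < 0) || any(K < 1)) {
    bs_stop("require N >= 0 and K >= 1", "bs_domain_error")
  }
  K * (-expm1(N * log1p(-1 / K)))
}

#' Theoretical diversity profile of a ligated library
#'
#' For each concatemer length `n`, converts the total block input into
#' molecule counts (`N_n = total_molecules * fraction(n) / n`; the input is
#' stated in blocks, and an `n`-block concatemer consumes `n` of them),
#' takes `K = D^n` possible sequences (`D` = distinct concrete block
#' expansions in the catalog, all treated as equiprobable) and reports the
#' occupancy expectation of distinct sequences.
#'
#' @param catalog a [block_catalog()].
#' @param length_histogram data frame with `n_blocks` and `count` (or
#'   `fraction`) columns, e.g. from [length_distribution()].
#' @param total_molecules total block input (the bench-scale figure is
#'   1e14 blocks).
#' @return data frame with `n_blocks`, `N_n`, `K`, `expected_distinct`.
#' @export
diversity_profile <- function(catalog, length_histogram, total_molecules) {
  D <- catalog_stats(catalog)$n_distinct_expansions
  h <- length_histogram
  frac <- if ("fraction" %in% names(h)) h$fraction else h$count / sum(h$count)
  n <- h$n_blocks
  N_n <- total_molecules * frac / n
  K <- D^n
  data.frame(
    n_blocks = n, N_n = N_n, K = K,
    expected_distinct = expected_distinct(N_n, K)
  )
}

#' Simulate sequencing reads from ligation products
#'
#' Complete products (both adapters) are eligible for sequencing; each read
#' is `adapter5 + insert + adapter3` truncated to `read_length`, with
#' per-base substitutions, per-base N replacement and a linearly decaying
#' Phred quality string. Deterministic for a fixed seed.
#'
#' @param products a `ligation_products` frame.
#' @param catalog a [block_catalog()] (adapters).
#' @param config a [sim_config()].
#' @return data frame of class `read_set`: `read_id`, `sequence`, `quality`,
#'   plus the truth `block_ids` carried over from the products.
#' @export
simulate_reads <- function(products, catalog, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  el <- products[products$has_adapter5 & products$has_adapter3, , drop = FALSE]
  seqs <- paste0(catalog$adapter5, el$insert, catalog$adapter3)
  seqs <- substr(seqs, 1L, config$read_length)
  lens <- nchar(seqs)

  if (config$substitution_rate > 0 || config$n_rate > 0) {
    chars <- strsplit(seqs, "", fixed = TRUE)
    all_chars <- unlist(chars, use.names = FALSE)
    total <- length(all_chars)
    sub_at <- which(runif(total) < config$substitution_rate)
    if (length(sub_at)) {
      bases <- c("A", "C", "G", "T")
      ## substitute with a uniformly chosen different base
      cur <- all_chars[sub_at]
      shift <- sample.int(3L, length(sub_at), replace = TRUE)
      all_chars[sub_at] <- bases[((match(cur, bases) - 1L + shift) %% 4L) + 1L]
    }
    n_at <- which(runif(total) < config$n_rate)
    if (length(n_at)) all_chars[n_at] <- "N"
    grp <- rep.int(seq_along(lens), lens)
    seqs <- vapply(split(all_chars, grp), paste, "", collapse = "")
  }

  qmax <- paste(intToUtf8(
    33L + as.integer(round(seq(config$q_start, config$q_end,
                               length.out = config$read_length))),
    multiple = TRUE
  ), collapse = "")
  quals <- substr(rep.int(qmax, length(seqs)), 1L, lens)

  out <- data.frame(
    read_id = el$product_id,
    sequence = unname(seqs),
    quality = quals,
    block_ids = el$block_ids,
    stringsAsFactors = FALSE
  )
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write reads as FASTQ (Phred+33) and the simulation truth as TSV
#'
#' @param reads a `read_set` frame.
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  rec <- rbind(paste0("@", reads$read_id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(rec), path)
  invisible(path)
}

#' @param truth_path output TSV path mapping `read_id` to the ligated block
#'   ids.
#' @rdname write_fastq
#' @export
write_truth <- function(reads, truth_path) {
  write.table(reads[, c("read_id", "block_ids")], truth_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(truth_path)
}
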