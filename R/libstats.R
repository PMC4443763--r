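## Library-level statistics over decoded reads: block co-occurrence,
## representation, non-redundant diversity, amino-acid frequencies and the
## analytic poly-NNK reference.

#' Block co-occurrence matrix
#'
#' Counts ordered adjacent block pairs (entry i,j = times block i is
#' immediately 5' of block j) over reads with at least two decoded blocks.
#' Unmatched units break adjacency: a pair spanning an `UNMATCHED` call is
#' not counted, because the junction cannot be verified. Rows/columns cover
#' every block observed at least once in a multi-block concatemer, in
#' catalog order (grouped by structure).
#'
#' @param decoded a `decoded_reads` frame.
#' @param catalog a [block_catalog()].
#' @return square integer matrix with block-id dimnames; the number of
#'   contributing multi-block reads is in attribute `"n_multi"`.
#' @export
cooccurrence <- function(decoded, catalog) {
  d <- decoded[!is.na(decoded$n_blocks) & decoded$n_blocks >= 2L, ,
               drop = FALSE]
  calls <- strsplit(d$block_calls, ",", fixed = TRUE)
  lens <- lengths(calls)
  flat <- unlist(calls, use.names = FALSE)
  last_of_read <- cumsum(lens)
  from <- flat[-last_of_read]
  keep_from <- rep.int(TRUE, length(flat))
  keep_from[last_of_read] <- FALSE
  to <- flat[which(keep_from) + 1L]
  ok <- from != "UNMATCHED" & to != "UNMATCHED"
  from <- from[ok]
  to <- to[ok]

  observed <- setdiff(unique(flat), "UNMATCHED")
  blocks <- catalog$blocks$block_id[catalog$blocks$block_id %in% observed]
  m <- matrix(0L, length(blocks), length(blocks),
              dimnames = list(from = blocks, to = blocks))
  if (length(from)) {
    tab <- table(factor(from, blocks), factor(to, blocks))
    m[] <- as.integer(tab)
  }
  attr(m, "n_multi") <- nrow(d)
  attr(m, "n_pairs") <- length(from)
  m
}

#' Per-block representation counts
#'
#' Cumulative instances of each block over all decoded positions (any read
#' with a defined length). Blocks never observed are reported with count 0.
#'
#' @param decoded a `decoded_reads` frame.
#' @param catalog a [block_catalog()].
#' @return data frame `block_id`, `structure`, `count`.
#' @export
representation_counts <- function(decoded, catalog) {
  d <- decoded[!is.na(decoded$n_blocks), , drop = FALSE]
  flat <- unlist(strsplit(d$block_calls, ",", fixed = TRUE),
                 use.names = FALSE)
  flat <- flat[flat != "UNMATCHED"]
  tab <- table(factor(flat, levels = catalog$blocks$block_id))
  data.frame(
    block_id = catalog$blocks$block_id,
    structure = catalog$blocks$structure,
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
}

#' Representation evenness within a fold window
#'
#' Finds the count interval `[c, fold_window * c]` (decade window by
#' default) containing the largest number of blocks; candidate lower bounds
#' are the observed counts. The published library had ~98% of blocks within
#' one order of magnitude (2000-20,000 instances).
#'
#' @param rep_table data frame from [representation_counts()] (or any frame
#'   with a `count` column).
#' @param fold_window width of the window as a fold change.
#' @return list: `fraction` of blocks inside the best window, `low`, `high`,
#'   `n_in`, `n_total`.
#' @export
representation_stats <- function(rep_table, fold_window = 10) {
  counts <- rep_table$count
  if (!length(counts)) bs_stop("empty representation table",
                               "bs_config_error")
  cand <- sort(unique(counts[counts > 0]))
  best <- list(n_in = -1L)
  for (c0 in cand) {
    n_in <- sum(counts >= c0 & counts <= fold_window * c0)
    if (n_in > best$n_in) {
      best <- list(n_in = n_in, low = c0, high = fold_window * c0)
    }
  }
  list(fraction = best$n_in / length(counts),
       low = best$low, high = best$high,
       n_in = best$n_in, n_total = length(counts))
}

#' Non-redundant insert counts per concatemer length
#'
#' Distinct DNA insert sequences observed at each length (exact set
#' semantics; duplicates counted once).
#'
#' @param decoded a `decoded_reads` frame.
#' @return data frame `n_blocks`, `n_reads`, `n_distinct`.
#' @export
nonredundant_counts <- function(decoded) {
  d <- decoded[!is.na(decoded$n_blocks), , drop = FALSE]
  n <- sort(unique(d$n_blocks))
  data.frame(
    n_blocks = n,
    n_reads = vapply(n, function(k) sum(d$n_blocks == k), integer(1)),
    n_distinct = vapply(n, function(k) {
      length(unique(d$insert[d$n_blocks == k]))
    }, integer(1))
  )
}

aa_levels <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "*")

aa_table <- function(residues, source) {
  lev <- union(aa_levels, unique(residues))
  tab <- table(factor(residues, levels = lev))
  data.frame(
    residue = lev,
    frequency = as.numeric(tab) / length(residues),
    source = source,
    stringsAsFactors = FALSE
  )
}

#' Analytic amino-acid frequencies of a poly-NNK library
#'
#' Enumerates the 32 NNK codons (positions 1-2 any base, position 3 G or T):
#' all twenty amino acids are covered and two of the three stop codons (TAA,
#' TGA) are avoided, leaving only TAG at frequency 1/32. Closed-form, no
#' randomness.
#'
#' @return data frame `residue`, `frequency`, `source` (frequencies sum
#'   to 1; the `*` row is the stop frequency).
#' @export
nnk_frequencies <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), c("G", "T"),
                            paste0))
  res <- unname(genetic_code()[codons])
  out <- aa_table(res, "NNK_analytic")
  attr(out, "n_codons") <- length(codons)
  attr(out, "stop_codons_present") <- unique(codons[res == "*"])
  out
}

#' Amino-acid frequencies of a catalog or of decoded reads
#'
#' Catalog mode weights every concrete block expansion equally and counts
#' residues over all six hexapeptide positions. Decoded mode counts the
#' translated residues of all extracted correct-length inserts
#' (wrong-length reads carry no frame and are excluded); stop codons from
#' nonsense reads appear in the `*` row.
#'
#' @param x a [block_catalog()] or a `decoded_reads` frame.
#' @return data frame `residue`, `frequency`, `source`.
#' @export
aa_frequencies <- function(x) UseMethod("aa_frequencies")

#' @export
aa_frequencies.block_catalog <- function(x) {
  exps <- unlist(lapply(x$blocks$top_strand, block_expansions),
                 use.names = FALSE)
  pep <- translate_dna(exps)
  res <- strsplit(paste(pep, collapse = ""), "")[[1]]
  aa_table(res, "catalog_design")
}

#' @export
aa_frequencies.decoded_reads <- function(x) {
  pep <- x$peptide[!is.na(x$peptide)]
  if (!length(pep)) bs_stop("no translated inserts", "bs_config_error")
  res <- strsplit(paste(pep, collapse = ""), "")[[1]]
  aa_table(res, "decoded_observed")
}
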