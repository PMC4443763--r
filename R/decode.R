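## Read processing: 3'-end quality trimming, N filtering, adapter-anchored
## insert extraction, IUPAC-aware 18-nt block calling and four-way
## classification (correct / nonsense / missense / wrong_length).

#' Trim low-quality 3' ends
#'
#' Bases are removed from the 3' end until the mean Phred quality of the
#' terminal `window` bases exceeds `q_threshold` (the QC15 / 50-bp sliding
#' window rule). Reads shorter than the window, or for which no terminal
#' window qualifies, are kept intact and flagged (`kept = FALSE`).
#'
#' @param reads a `read_set` frame (`read_id`, `sequence`, `quality`).
#' @param window window width in bases.
#' @param q_threshold Phred threshold the window mean must exceed.
#' @return the frame with trimmed `sequence`/`quality` plus a logical
#'   `kept` column.
#' @export
trim_reads <- function(reads, window = 50, q_threshold = 15) {
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    bs_stop("sequence/quality length mismatch", "bs_format_error")
  }
  n <- nrow(reads)
  newlen <- integer(n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(reads$quality[i]) - 33L
    if (any(q < 0L)) {
      bs_stop(sprintf("malformed quality string in read %s",
                      reads$read_id[i]),
              "bs_format_error")
    }
    L <- length(q)
    if (L < window) {
      newlen[i] <- L
      kept[i] <- FALSE
      next
    }
    cs <- c(0, cumsum(q))
    ## terminal-window means for candidate lengths window..L
    Lp <- window:L
    m <- (cs[Lp + 1L] - cs[Lp - window + 1L]) / window
    ok <- which(m > q_threshold)
    if (length(ok)) {
      newlen[i] <- Lp[max(ok)]
      kept[i] <- TRUE
    } else {
      newlen[i] <- L
      kept[i] <- FALSE
    }
  }
  reads$sequence <- substr(reads$sequence, 1L, newlen)
  reads$quality <- substr(reads$quality, 1L, newlen)
  reads$kept <- kept
  reads
}

#' Discard reads with more than one uncalled base
#'
#' @param reads a `read_set` frame.
#' @return list with `kept` (frame), `discarded` (frame) and
#'   `discarded_count`.
#' @export
filter_n <- function(reads) {
  n_count <- nchar(reads$sequence) - nchar(gsub("N", "", reads$sequence,
                                               fixed = TRUE))
  drop <- n_count > 1L
  list(kept = reads[!drop, , drop = FALSE],
       discarded = reads[drop, , drop = FALSE],
       discarded_count = sum(drop))
}

#' Extract the insert between adapter anchors
#'
#' A read must contain an exact match of the insert-proximal `anchor_len`-mer
#' of the 5' adapter and, downstream of it, of the 3' adapter; the sequence
#' strictly between the two anchors is the insert. `NA` when either anchor
#' is absent or mis-ordered.
#'
#' @param sequences character vector of read sequences.
#' @param adapter5,adapter3 adapter top strands.
#' @param anchor_len exact-match length required of each adapter (8 bp
#'   reproduces the published rule).
#' @return character vector of inserts (`NA` = not extractable; `""` is a
#'   legitimate empty insert between adjacent anchors).
#' @export
extract_insert <- function(sequences, adapter5, adapter3, anchor_len = 8) {
  a5 <- substr(adapter5, nchar(adapter5) - anchor_len + 1L, nchar(adapter5))
  a3 <- substr(adapter3, 1L, anchor_len)
  p5 <- regexpr(a5, sequences, fixed = TRUE)
  start <- ifelse(p5 > 0L, p5 + anchor_len, NA_integer_)
  rest <- substr(sequences, start, nchar(sequences))
  p3 <- regexpr(a3, rest, fixed = TRUE)
  ifelse(!is.na(start) & p3 > 0L,
         substr(rest, 1L, p3 - 1L),
         NA_character_)
}

#' Call 18-nt block units of an insert against the catalog
#'
#' The insert is split into consecutive 18-nt units from position 0; each
#' unit is assigned the unique catalog block whose degenerate pattern
#' matches it exactly (IUPAC-aware, per-position set containment), or
#' `"UNMATCHED"`. A unit matching several blocks is a catalog defect and
#' raises an ambiguity error.
#'
#' @param insert one DNA string whose length is a positive multiple of 18.
#' @param catalog a [block_catalog()].
#' @return character vector of block ids / `"UNMATCHED"`, one per unit.
#' @export
decode_blocks <- function(insert, catalog) {
  len <- nchar(insert)
  if (len <= 0L || len %% 18L != 0L) {
    bs_stop("insert length must be a positive multiple of 18",
            "bs_length_error")
  }
  starts <- seq(1L, len, 18L)
  units <- substring(insert, starts, starts + 17L)
  match_units(units, catalog)
}

## vectorized unit matcher: hash lookup over enumerated expansions with a
## per-position containment fallback for blocks too degenerate to enumerate
match_units <- function(units, catalog) {
  idx <- catalog_index(catalog)
  hit <- idx$owner[match(units, idx$units)]
  calls <- ifelse(is.na(hit), "UNMATCHED", catalog$blocks$block_id[hit])
  if (length(idx$fallback)) {
    regexes <- vapply(catalog$blocks$top_strand[idx$fallback], iupac_regex, "")
    for (u in which(is.na(hit))) {
      m <- which(vapply(regexes, function(rx) grepl(rx, units[u]), logical(1)))
      if (length(m) > 1L ||
          (length(m) == 1L && calls[u] != "UNMATCHED")) {
        bs_stop(sprintf("unit %s matches more than one block", units[u]),
                "bs_ambiguous_error")
      }
      if (length(m) == 1L) {
        calls[u] <- catalog$blocks$block_id[idx$fallback[m]]
      }
    }
  }
  calls
}

iupac_regex <- function(pattern) {
  sets <- iupac_map()[strsplit(pattern, "", fixed = TRUE)[[1]]]
  paste0("^", paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = ""), "$")
}

#' Classify an extracted insert
#'
#' Precedence: `wrong_length` if the insert length is not a positive
#' multiple of 18; otherwise the insert is translated in frame 0 and is
#' `nonsense` if any codon is a stop, `missense` if any residue (including
#' an unresolvable X from a surviving N base) lies outside the catalog's
#' design alphabet, else `correct`.
#'
#' @param inserts character vector of extracted inserts.
#' @param catalog a [block_catalog()].
#' @return list with `category` (factor with the four levels) and `peptide`
#'   (`NA` for wrong-length inserts).
#' @export
classify_inserts <- function(inserts, catalog) {
  len <- nchar(inserts)
  good <- !is.na(inserts) & len > 0L & len %% 18L == 0L
  category <- rep.int("wrong_length", length(inserts))
  peptide <- rep.int(NA_character_, length(inserts))
  if (any(good)) {
    pep <- translate_dna(inserts[good])
    has_stop <- grepl("*", pep, fixed = TRUE)
    outside <- vapply(strsplit(pep, "", fixed = TRUE), function(p) {
      any(!(p %in% c(catalog$alphabet, "*")))
    }, logical(1))
    cat_g <- ifelse(has_stop, "nonsense",
                    ifelse(outside, "missense", "correct"))
    category[good] <- cat_g
    peptide[good] <- pep
  }
  list(category = factor(category,
                         levels = c("correct", "nonsense", "missense",
                                    "wrong_length")),
       peptide = peptide)
}

#' Decode a set of reads end to end
#'
#' Runs the full chain: 3' quality trimming, N filtering, adapter-anchored
#' insert extraction, 18-nt block calling and classification. Per-stage
#' accounting (input = kept + removed at every stage) is attached as the
#' `"accounting"` attribute.
#'
#' @param reads a `read_set` frame (e.g. from [read_fastq()] or
#'   [simulate_reads()]).
#' @param catalog a [block_catalog()].
#' @param window,q_threshold trimming parameters (see [trim_reads()]).
#' @param anchor_len adapter anchor length (see [extract_insert()]).
#' @param trim set `FALSE` to skip quality trimming.
#' @return `decoded_reads` frame: `read_id`, `insert`, `insert_len`,
#'   `n_blocks` (`NA` for wrong-length), `block_calls` (comma-separated),
#'   `category`, `peptide`.
#' @export
decode_reads <- function(reads, catalog, window = 50, q_threshold = 15,
                         anchor_len = 8, trim = TRUE) {
  n_raw <- nrow(reads)
  if (trim && "quality" %in% names(reads)) {
    reads <- trim_reads(reads, window = window, q_threshold = q_threshold)
  }
  fl <- filter_n(reads)
  reads <- fl$kept
  inserts <- extract_insert(reads$sequence, catalog$adapter5,
                            catalog$adapter3, anchor_len = anchor_len)
  extractable <- !is.na(inserts)
  rd <- reads[extractable, , drop = FALSE]
  inserts <- inserts[extractable]

  cl <- classify_inserts(inserts, catalog)
  len <- nchar(inserts)
  n_blocks <- ifelse(cl$category == "wrong_length", NA_integer_,
                     len %/% 18L)

  ## block calls for correct-length inserts, batched over all units
  block_calls <- rep.int(NA_character_, length(inserts))
  which_good <- which(!is.na(n_blocks) & n_blocks > 0L)
  if (length(which_good)) {
    nb <- n_blocks[which_good]
    owner_read <- rep.int(which_good, nb)
    offset <- (sequence(nb) - 1L) * 18L + 1L
    units <- substring(inserts[owner_read], offset, offset + 17L)
    calls <- match_units(units, catalog)
    block_calls[which_good] <-
      vapply(split(calls, owner_read), paste, "", collapse = ",")
  }

  out <- data.frame(
    read_id = rd$read_id,
    insert = inserts,
    insert_len = len,
    n_blocks = n_blocks,
    block_calls = block_calls,
    category = cl$category,
    peptide = cl$peptide,
    stringsAsFactors = FALSE
  )
  class(out) <- c("decoded_reads", "data.frame")
  acct <- data.frame(
    stage = c("input", "n_filter", "anchor_extraction"),
    n_in = c(n_raw, n_raw, nrow(fl$kept)),
    n_kept = c(n_raw, nrow(fl$kept), length(inserts)),
    n_removed = c(0L, fl$discarded_count, nrow(fl$kept) - length(inserts))
  )
  stopifnot(acct$n_in == acct$n_kept + acct$n_removed)
  attr(out, "accounting") <- acct
  out
}

#' @export
summary.decoded_reads <- function(object, ...) {
  tab <- table(object$category)
  pct <- 100 * tab / sum(tab)
  cat(sprintf("%d decoded inserts\n", nrow(object)))
  for (nm in names(tab)) {
    cat(sprintf("  %-12s %8d  (%5.1f%%)\n", nm, tab[[nm]], pct[[nm]]))
  }
  invisible(list(counts = tab, percent = pct))
}

#' Per-length assembly accuracy
#'
#' Fraction of reads of each concatemer length classified `correct`.
#' Wrong-length reads have no defined length and are reported separately in
#' the `"wrong_length"` attribute.
#'
#' @param decoded a `decoded_reads` frame.
#' @return data frame `n_blocks`, `n_reads`, `fraction_correct`.
#' @export
per_length_accuracy <- function(decoded) {
  d <- decoded[!is.na(decoded$n_blocks), , drop = FALSE]
  if (!nrow(d)) {
    out <- data.frame(n_blocks = integer(0), n_reads = integer(0),
                      fraction_correct = numeric(0))
  } else {
    n <- sort(unique(d$n_blocks))
    out <- data.frame(
      n_blocks = n,
      n_reads = vapply(n, function(k) sum(d$n_blocks == k), integer(1)),
      fraction_correct = vapply(n, function(k) {
        mean(d$category[d$n_blocks == k] == "correct")
      }, numeric(1))
    )
  }
  attr(out, "wrong_length") <- sum(decoded$category == "wrong_length")
  out
}
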