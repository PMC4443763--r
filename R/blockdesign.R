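## Block and catalog design: non-palindromic overhang validation, degenerate
## codon exact-cover search for restricted amino-acid alphabets, block
## construction under binary (polar/nonpolar) patterning, catalog I/O.

#' Validate a dinucleotide sticky-end overhang
#'
#' Directional ligation requires a non-palindromic overhang: a dinucleotide
#' equal to its own reverse complement (AT, TA, GC, CG) would ligate in
#' either orientation and is rejected.
#'
#' @param top 2-nt DNA string (A/C/G/T), the 5' overhang on the top strand.
#' @return an object of class `overhang_pair` with elements `top` and
#'   `bottom` (`bottom` is the reverse complement of `top`).
#' @examples
#' validate_overhang("AG") # AG-TC, the default library chemistry
#' @export
validate_overhang <- function(top) {
  stopifnot(is.character(top), length(top) == 1L)
  if (nchar(top) != 2L) {
    bs_stop("overhang must be exactly 2 nt", "bs_alphabet_error")
  }
  check_iupac(top, allow = c("A", "C", "G", "T"))
  if (top == revcomp(top)) {
    bs_stop(
      sprintf("palindromic overhang %s permits non-directional ligation", top),
      "bs_palindrome_error"
    )
  }
  ## bottom is written base-by-base (3' to 5'), the figure-style pair
  ## notation: AG pairs with TC
  structure(list(top = top, bottom = chartr("ACGT", "TGCA", top)),
            class = "overhang_pair")
}

#' @export
print.overhang_pair <- function(x, ...) {
  cat(sprintf("<overhang %s-%s>\n", x$top, x$bottom))
  invisible(x)
}

aa_one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
            "M", "F", "P", "S", "T", "W", "Y", "V")

check_alphabet <- function(residues) {
  residues <- unique(toupper(residues))
  bad <- setdiff(residues, aa_one)
  if (length(bad)) {
    bs_stop(
      sprintf("not standard amino-acid one-letter codes: %s",
              paste(bad, collapse = ", ")),
      "bs_alphabet_error"
    )
  }
  if (!length(residues)) bs_stop("empty amino-acid set", "bs_alphabet_error")
  sort(residues)
}

#' Minimal degenerate-codon covers of an amino-acid set
#'
#' Searches all 3375 IUPAC codons for the smallest sets of degenerate codons
#' whose encoded residues jointly equal `target` exactly, with no codon
#' encoding a residue outside `target` and no stop codon in any expansion.
#' All minimal-cardinality solutions are returned, each solution sorted and
#' the list ordered lexicographically by codon code (deterministic output).
#'
#' @param target character vector of one-letter amino-acid codes (no stop).
#' @param max_solutions stop after this many solutions have been collected
#'   (the lexicographically first ones); `Inf` enumerates all.
#' @return list of character vectors, each a minimal codon set. The minimal
#'   cardinality is in attribute `"k"`.
#' @examples
#' find_degenerate_codons(c("D", "E"))[1:3]  # single-codon covers, e.g. GAS
#' find_degenerate_codons("I")[[1]]          # "ATA" (ATH also covers Ile)
#' @export
find_degenerate_codons <- function(target, max_solutions = Inf) {
  target <- check_alphabet(target)
  tab <- codon_residue_table()
  admissible <- names(tab)[vapply(tab, function(r) {
    !("*" %in% r) && all(r %in% target)
  }, logical(1))]
  if (!length(admissible)) {
    bs_stop("no stop-free degenerate codon lies within the target set",
            "bs_no_solution_error")
  }
  masks <- vapply(tab[admissible], function(r) {
    sum(bitwShiftL(1L, match(r, target) - 1L))
  }, integer(1))
  full <- sum(bitwShiftL(1L, seq_along(target) - 1L))
  n <- length(admissible)
  ## suffix unions for pruning
  suffix <- integer(n + 1L)
  for (i in n:1) suffix[i] <- bitwOr(suffix[i + 1L], masks[i])

  for (k in seq_along(target)) {
    sols <- vector("list", 0L)
    done <- FALSE
    rec <- function(start, chosen, mask) {
      if (done) return()
      if (length(chosen) == k) {
        if (mask == full) {
          sols[[length(sols) + 1L]] <<- admissible[chosen]
          if (length(sols) >= max_solutions) done <<- TRUE
        }
        return()
      }
      if (start > n) return()
      if (bitwOr(mask, suffix[start]) != full) return()
      for (i in start:n) {
        rec(i + 1L, c(chosen, i), bitwOr(mask, masks[i]))
        if (done) return()
      }
    }
    rec(1L, integer(0), 0L)
    if (length(sols)) {
      attr(sols, "k") <- k
      return(sols)
    }
  }
  bs_stop("no codon-set cover found", "bs_no_solution_error") # unreachable
}

## one codon for a position: first minimal solution, preferring the codon
## with the smallest expansion (synthesis economy), then lexicographic.
## `prefix` constrains the codon's literal first characters (overhang frame).
pick_codon <- function(target, prefix = NULL, variant = 1L) {
  if (is.null(prefix)) {
    sols <- find_degenerate_codons(target, max_solutions = 64L)
    cands <- unique(unlist(sols))
  } else {
    tab <- codon_residue_table()
    cands <- names(tab)[startsWith(names(tab), prefix)]
    cands <- cands[vapply(tab[cands], function(r) {
      !("*" %in% r) && all(r %in% target)
    }, logical(1))]
    if (!length(cands)) {
      bs_stop(
        sprintf("no codon with prefix %s encodes only residues in {%s}",
                prefix, paste(target, collapse = ",")),
        "bs_design_error"
      )
    }
    ## prefer codons that cover the whole class target under the prefix
    exact <- cands[vapply(tab[cands], function(r) setequal(r, target),
                          logical(1))]
    if (length(exact)) cands <- exact
  }
  ord <- order(iupac_degeneracy(cands), cands)
  cands <- cands[ord]
  cands[[((variant - 1L) %% length(cands)) + 1L]]
}

#' Build one degenerate hexapeptide-coding block
#'
#' Emits an 18-nt degenerate top strand (six codons) whose codon at each
#' position is selected by [find_degenerate_codons()] for that position's
#' polar/nonpolar class. When an overhang is given, the first codon is
#' additionally constrained to start with the literal overhang dinucleotide,
#' so that every concrete molecule presents the catalog's sticky end (the
#' 2-nt 5' overhang is the first 2 nt of the 18-nt repeat unit; the bottom
#' strand anneals offset by 2).
#'
#' @param pattern length-6 string over `P`/`N` (polar / nonpolar class per
#'   hexapeptide position), e.g. `"PNNPPN"`.
#' @param polar_assignment named list with elements `P` and `N`, each a
#'   character vector of one-letter residues (stop-free).
#' @param overhang an `overhang_pair` from [validate_overhang()], or `NULL`
#'   for no overhang frame constraint.
#' @param block_id,name,structure_label identifiers stored with the block.
#' @param variant integer; cycles deterministically through alternative codon
#'   choices so that several distinct blocks can be built from one pattern.
#' @return object of class `degenerate_block`: list with `block_id`, `name`,
#'   `structure`, `top_strand` (18-char IUPAC), `overhang`, `codons`.
#' @examples
#' b <- build_block("PPPPPP", list(P = c("D", "E"), N = "G"),
#'                  overhang = validate_overhang("GA"), block_id = "b1")
#' b$top_strand
#' @export
build_block <- function(pattern, polar_assignment, overhang = NULL,
                        block_id, name = block_id,
                        structure_label = "other", variant = 1L) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) != 6L ||
      !all(strsplit(pattern, "")[[1]] %in% c("P", "N"))) {
    bs_stop("pattern must be a length-6 string over {P, N} (hexapeptide)",
            "bs_design_error")
  }
  classes <- strsplit(pattern, "")[[1]]
  targets <- lapply(polar_assignment[classes], check_alphabet)
  if (!is.null(overhang) && !inherits(overhang, "overhang_pair")) {
    overhang <- validate_overhang(overhang)
  }
  codons <- character(6)
  for (i in 1:6) {
    prefix <- if (i == 1L && !is.null(overhang)) overhang$top else NULL
    codons[i] <- pick_codon(targets[[i]], prefix = prefix, variant = variant)
  }
  new_block(codons, block_id = block_id, name = name,
            structure_label = structure_label, overhang = overhang)
}

## low-level constructor from six codons; validates the block invariants
new_block <- function(codons, block_id, name = block_id,
                      structure_label = "other", overhang = NULL,
                      alphabet = NULL) {
  stopifnot(length(codons) == 6L)
  top <- paste(codons, collapse = "")
  stopifnot(nchar(top) == 18L)
  res <- unique(unlist(lapply(codons, codon_residues)))
  if ("*" %in% res) {
    bs_stop(sprintf("block %s expansion contains a stop codon", block_id),
            "bs_design_error")
  }
  if (!is.null(alphabet) && !all(res %in% alphabet)) {
    bs_stop(sprintf("block %s encodes residues outside the design alphabet",
                    block_id),
            "bs_design_error")
  }
  structure(
    list(block_id = block_id, name = name, structure = structure_label,
         top_strand = top, overhang = overhang, codons = codons,
         residues = sort(res)),
    class = "degenerate_block"
  )
}

#' @export
print.degenerate_block <- function(x, ...) {
  cat(sprintf("<block %s (%s) %s  %s residues: %s>\n",
              x$block_id, x$structure, x$top_strand,
              if (is.null(x$overhang)) "" else
                sprintf("overhang %s-%s", x$overhang$top, x$overhang$bottom),
              paste(x$residues, collapse = "")))
  invisible(x)
}

## expansion of a block's full 18-nt degenerate strand
block_expansions <- function(top_strand) expand_degenerate(top_strand)

#' Assemble a block catalog
#'
#' A catalog is the decoding reference: an ordered set of degenerate blocks
#' sharing one overhang pair, plus the two adapter sequences (each adapter is
#' ligation-competent on exactly one side, which caps concatemer growth).
#'
#' @param blocks list of `degenerate_block` objects (unique ids).
#' @param adapter5,adapter3 concrete DNA strings (top strand, 5' to 3').
#' @param overhang shared `overhang_pair` (default AG-TC).
#' @param alphabet optional design alphabet; defaults to the union of block
#'   residues.
#' @return object of class `block_catalog`.
#' @export
block_catalog <- function(blocks, adapter5, adapter3,
                          overhang = validate_overhang("AG"),
                          alphabet = NULL) {
  ids <- vapply(blocks, `[[`, "", "block_id")
  if (anyDuplicated(ids)) {
    bs_stop("duplicate block ids in catalog", "bs_design_error")
  }
  check_iupac(adapter5, allow = c("A", "C", "G", "T"))
  check_iupac(adapter3, allow = c("A", "C", "G", "T"))
  if (!inherits(overhang, "overhang_pair")) overhang <- validate_overhang(overhang)
  res <- sort(unique(unlist(lapply(blocks, `[[`, "residues"))))
  if (is.null(alphabet)) alphabet <- res
  alphabet <- check_alphabet(alphabet)
  if (!all(res %in% alphabet)) {
    bs_stop("catalog blocks encode residues outside the design alphabet",
            "bs_design_error")
  }
  df <- data.frame(
    block_id = ids,
    name = vapply(blocks, `[[`, "", "name"),
    structure = vapply(blocks, `[[`, "", "structure"),
    top_strand = vapply(blocks, `[[`, "", "top_strand"),
    overhang = overhang$top,
    stringsAsFactors = FALSE
  )
  structure(
    list(blocks = df, adapter5 = adapter5, adapter3 = adapter3,
         overhang = overhang, alphabet = alphabet,
         index = new.env(parent = emptyenv())),
    class = "block_catalog"
  )
}

#' @export
print.block_catalog <- function(x, ...) {
  st <- table(x$blocks$structure)
  cat(sprintf("<block_catalog: %d blocks (%s); overhang %s-%s; alphabet %s>\n",
              nrow(x$blocks),
              paste(sprintf("%s %d", names(st), st), collapse = ", "),
              x$overhang$top, x$overhang$bottom,
              paste(x$alphabet, collapse = "")))
  invisible(x)
}

## expansion index: concrete 18-mer -> block row index. Built once, cached.
## Duplicated expansions across blocks are a catalog defect (decoding would
## be ambiguous).
catalog_index <- function(catalog, max_block_degeneracy = 1e5) {
  env <- catalog$index
  if (!is.null(env$units)) return(env)
  deg <- iupac_degeneracy(catalog$blocks$top_strand)
  enum <- deg <= max_block_degeneracy
  exps <- lapply(which(enum), function(i) {
    block_expansions(catalog$blocks$top_strand[i])
  })
  units <- unlist(exps, use.names = FALSE)
  owner <- rep(which(enum), lengths(exps))
  if (anyDuplicated(units)) {
    d <- units[duplicated(units)][1]
    bs_stop(
      sprintf("catalog is ambiguous: unit %s matches more than one block", d),
      "bs_ambiguous_error"
    )
  }
  env$units <- units
  env$owner <- owner
  env$fallback <- which(!enum) # matched per-position when needed
  env$degeneracy <- deg
  env
}

#' Catalog summary statistics
#'
#' @param catalog a `block_catalog`.
#' @return list with `n_blocks`, `n_distinct_expansions` (size of the union
#'   of all blocks' concrete expansion sets), `alphabet_size` (distinct
#'   residues over all expansion translations) and `per_structure` counts.
#' @export
catalog_stats <- function(catalog) {
  stopifnot(inherits(catalog, "block_catalog"))
  exps <- unique(unlist(lapply(catalog$blocks$top_strand, block_expansions)))
  pept <- translate_dna(exps)
  res <- unique(strsplit(paste(pept, collapse = ""), "")[[1]])
  list(
    n_blocks = nrow(catalog$blocks),
    n_distinct_expansions = length(exps),
    alphabet_size = length(setdiff(res, "*")),
    alphabet = sort(setdiff(res, "*")),
    per_structure = table(catalog$blocks$structure)
  )
}

#' Write / read a catalog as TSV
#'
#' Columns: `block_id`, `name`, `structure`, `top_strand_iupac`, `overhang`;
#' header row required; comment lines starting `#` are ignored on read.
#'
#' @param catalog a `block_catalog`.
#' @param path file path.
#' @param header_comment optional `#`-prefixed first line (e.g. seed record).
#' @export
write_catalog <- function(catalog, path, header_comment = NULL) {
  df <- catalog$blocks
  names(df)[names(df) == "top_strand"] <- "top_strand_iupac"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param adapter5,adapter3 adapter sequences, or `adapter_fasta` a FASTA
#'   file with records named `adapter5` and `adapter3`.
#' @param adapter_fasta path to adapter FASTA (alternative to explicit
#'   sequences).
#' @rdname write_catalog
#' @export
read_catalog <- function(path, adapter5 = NULL, adapter3 = NULL,
                         adapter_fasta = NULL) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("block_id", "name", "structure", "top_strand_iupac", "overhang")
  if (!all(need %in% names(df))) {
    bs_stop(sprintf("catalog TSV must have columns: %s",
                    paste(need, collapse = ", ")),
            "bs_format_error")
  }
  if (!is.null(adapter_fasta)) {
    ad <- read_adapters(adapter_fasta)
    adapter5 <- ad$adapter5
    adapter3 <- ad$adapter3
  }
  if (is.null(adapter5) || is.null(adapter3)) {
    bs_stop("adapters required (explicit sequences or adapter_fasta)",
            "bs_config_error")
  }
  ov <- unique(df$overhang)
  if (length(ov) != 1L) {
    bs_stop("catalog must use a single shared overhang", "bs_design_error")
  }
  blocks <- lapply(seq_len(nrow(df)), function(i) {
    codons <- substring(df$top_strand_iupac[i], seq(1, 16, 3), seq(3, 18, 3))
    new_block(codons, block_id = df$block_id[i], name = df$name[i],
              structure_label = df$structure[i])
  })
  block_catalog(blocks, adapter5 = adapter5, adapter3 = adapter3,
                overhang = validate_overhang(ov))
}

#' Read or write adapter sequences as FASTA
#'
#' @param path FASTA path with records `adapter5` and `adapter3`.
#' @return list with `adapter5`, `adapter3`.
#' @export
read_adapters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (!all(c("adapter5", "adapter3") %in% names(x))) {
    bs_stop("adapter FASTA must contain records 'adapter5' and 'adapter3'",
            "bs_format_error")
  }
  list(adapter5 = as.character(x[["adapter5"]]),
       adapter3 = as.character(x[["adapter3"]]))
}

#' @param catalog a `block_catalog` whose adapters are written.
#' @rdname read_adapters
#' @export
write_adapters <- function(catalog, path) {
  x <- Biostrings::DNAStringSet(c(adapter5 = catalog$adapter5,
                                  adapter3 = catalog$adapter3))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export all concrete block expansions as FASTA
#'
#' @param catalog a `block_catalog`.
#' @param path output FASTA path.
#' @export
write_expansions_fasta <- function(catalog, path) {
  seqs <- lapply(seq_len(nrow(catalog$blocks)), function(i) {
    e <- block_expansions(catalog$blocks$top_strand[i])
    setNames(e, sprintf("%s_%03d", catalog$blocks$block_id[i], seq_along(e)))
  })
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}
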