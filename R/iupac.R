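## IUPAC degenerate-code arithmetic. Base sets come from
## Biostrings::IUPAC_CODE_MAP; the genetic code from Biostrings::GENETIC_CODE.

iupac_map <- function() {
  if (is.null(.bs_cache$iupac)) {
    m <- Biostrings::IUPAC_CODE_MAP
    .bs_cache$iupac <- strsplit(m, "", fixed = TRUE) # code -> base vector
  }
  .bs_cache$iupac
}

genetic_code <- function() Biostrings::GENETIC_CODE

# reverse complement (IUPAC-aware, via Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_iupac <- function(seq, allow = names(Biostrings::IUPAC_CODE_MAP)) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, allow)
  if (length(bad)) {
    bs_stop(
      sprintf("invalid nucleotide code(s) in %s: %s",
              dQuote(seq), paste(unique(bad), collapse = ", ")),
      "bs_alphabet_error"
    )
  }
  chars
}

#' Expand a degenerate IUPAC DNA string to all concrete sequences
#'
#' Every position written with an IUPAC ambiguity code (e.g. S = C/G,
#' N = A/C/G/T) is expanded; the result enumerates the full cartesian
#' product in deterministic lexicographic order.
#'
#' @param seq a single non-empty IUPAC DNA string.
#' @return character vector of concrete A/C/G/T sequences; its length equals
#'   the product of per-position degeneracies.
#' @examples
#' expand_degenerate("GAS")  # "GAC" "GAG"
#' expand_degenerate("ACGT") # identity on concrete input
#' @export
expand_degenerate <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) bs_stop("empty sequence", "bs_alphabet_error")
  chars <- check_iupac(seq)
  sets <- iupac_map()[chars]
  out <- sets[[1]]
  for (s in sets[-1]) {
    out <- as.vector(t(outer(out, s, paste0)))
  }
  sort(out)
}

#' Degeneracy (number of concrete expansions) of an IUPAC string
#'
#' @param seq character vector of IUPAC DNA strings.
#' @return numeric vector of expansion counts.
#' @export
iupac_degeneracy <- function(seq) {
  vapply(seq, function(s) {
    chars <- check_iupac(s)
    prod(lengths(iupac_map()[chars]))
  }, numeric(1), USE.NAMES = FALSE)
}

## residue set encoded by one degenerate codon; NULL cache built lazily over
## all 3375 IUPAC codons on first use of the codon search
codon_residues <- function(code) {
  tab <- codon_residue_table()
  tab[[code]]
}

codon_residue_table <- function() {
  if (is.null(.bs_cache$codon_res)) {
    codes <- names(Biostrings::IUPAC_CODE_MAP)
    all3 <- sort(as.vector(outer(outer(codes, codes, paste0), codes, paste0)))
    gc <- genetic_code()
    im <- iupac_map()
    .bs_cache$codon_res <- lapply(setNames(all3, all3), function(code) {
      ch <- strsplit(code, "", fixed = TRUE)[[1]]
      eg <- expand.grid(im[[ch[3]]], im[[ch[2]]], im[[ch[1]]],
                        stringsAsFactors = FALSE)
      sort(unique(unname(gc[paste0(eg[[3]], eg[[2]], eg[[1]])])))
    })
  }
  .bs_cache$codon_res
}

## vectorized translation of concrete in-frame DNA (length divisible by 3);
## fuzzy codons (containing N) become X
translate_dna <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "X"))
}
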