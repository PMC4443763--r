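## Synthetic study-scale catalog. The original oligo order list is not
## redistributed; this generator emits a catalog of the same shape:
## 168 degenerate blocks (56 helix / 56 strand / 56 loop binary patterns),
## a ten-residue alphabet (A, D, E, G, I, L, P, S, T, V), one shared AG-TC
## overhang, exactly 8288 distinct concrete DNA expansions, and pairwise
## expansion-disjoint blocks so decoding is unambiguous.

## Codon menu. Position 1 always starts with the literal AG overhang
## (AGY -> Ser). Polar (P) and nonpolar (N) classes each offer
## two-fold-degenerate variants plus one concrete variant; all variants are
## pairwise expansion-disjoint, which makes any two distinct variant
## selections yield disjoint block expansions.
.bs_menu <- list(
  first = "AGY",                                # {S}, 2 expansions
  P = c("GAS", "WCC"),                          # {D,E}, {S,T}
  P1 = "GAT",                                   # {D}, concrete
  N = c("GYC", "MTC", "GGM", "CCM"),            # {A,V},{I,L},{G},{P}
  N1 = "GGT"                                    # {G}, concrete
)

.bs_patterns <- c(helix = "PNNPPN", strand = "PNPNPN", loop = "PPPPPP")

## deterministic enumeration of variant selections for positions 2..6 of a
## pattern: first the fully degenerate combinations, then combinations with
## one position collapsed to the concrete class variant (deduplicated)
menu_combos <- function(pattern, n_full, n_single) {
  classes <- strsplit(pattern, "")[[1]][2:6]
  opts <- lapply(classes, function(cl) .bs_menu[[cl]])
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)[, 5:1, drop = FALSE]
  full <- lapply(seq_len(min(n_full, nrow(grid))), function(i) {
    unlist(grid[i, ], use.names = FALSE)
  })
  singles <- list()
  seen <- character(0)
  i <- 1L
  while (length(singles) < n_single && i <= nrow(grid)) {
    for (pos in 1:5) {
      if (length(singles) >= n_single) break
      sel <- unlist(grid[i, ], use.names = FALSE)
      sel[pos] <- .bs_menu[[paste0(classes[pos], "1")]]
      key <- paste(sel, collapse = " ")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        singles[[length(singles) + 1L]] <- sel
      }
    }
    i <- i + 1L
  }
  if (length(full) < n_full || length(singles) < n_single) {
    bs_stop("requested more blocks than the codon menu can enumerate",
            "bs_design_error")
  }
  c(full, singles)
}

#' Synthetic study-scale block catalog
#'
#' Generates a catalog emulating the aggregate shape of the sequenced
#' library: by default 168 degenerate hexapeptide blocks (56 each of helix,
#' strand and loop binary patterns), a ten-residue alphabet
#' (Ala, Asp, Glu, Gly, Ile, Leu, Pro, Ser, Thr, Val), one shared AG-TC
#' overhang, and exactly 8288 distinct concrete DNA expansions (91 blocks
#' with 64 expansions and 77 with 32). Blocks are pairwise
#' expansion-disjoint, so decoding is unambiguous. The sequences themselves
#' are synthetic: they are generated from a fixed codon menu, not recovered
#' from any published oligo list.
#'
#' @param n named integer vector: blocks per structure
#'   (default `c(helix = 56, strand = 56, loop = 56)`).
#' @param n_full named integer vector: how many blocks per structure are
#'   fully degenerate (64 expansions); the rest have one position collapsed
#'   to a concrete codon (32 expansions). Default `c(31, 30, 30)`.
#' @param adapter5,adapter3 adapter top strands (defaults are synthetic
#'   polylinker-style sequences whose 8-bp anchor-proximal ends cannot occur
#'   inside any block expansion).
#' @return a [block_catalog()].
#' @examples
#' cat168 <- synthetic_catalog()
#' catalog_stats(cat168)$n_distinct_expansions # 8288
#' @export
synthetic_catalog <- function(n = c(helix = 56, strand = 56, loop = 56),
                              n_full = c(helix = 31, strand = 30, loop = 30),
                              adapter5 = default_adapter5(),
                              adapter3 = default_adapter3()) {
  ov <- validate_overhang("AG")
  blocks <- list()
  for (st in names(n)) {
    pattern <- .bs_patterns[[st]]
    combos <- menu_combos(pattern, n_full[[st]], n[[st]] - n_full[[st]])
    for (i in seq_along(combos)) {
      codons <- c(.bs_menu$first, combos[[i]])
      id <- sprintf("%s_%02d", st, i)
      blocks[[length(blocks) + 1L]] <-
        new_block(codons, block_id = id, name = sprintf("%s %d", st, i),
                  structure_label = st, overhang = ov)
    }
  }
  block_catalog(blocks, adapter5 = adapter5, adapter3 = adapter3,
                overhang = ov)
}

#' Default synthetic adapter sequences
#'
#' Short polylinker-style adapters for simulation and decoding tests. The
#' insert-proximal 8-mers (the decoding anchors) contain base bigrams that
#' cannot arise inside or across block codons of [synthetic_catalog()], so
#' anchor matches are unambiguous.
#' @return a DNA string.
#' @export
default_adapter5 <- function() "TGCAGGTCGACTCTAGAGGATCC"

#' @rdname default_adapter5
#' @export
default_adapter3 <- function() "GAATTCGAGCTCGGTACCCGGG"
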