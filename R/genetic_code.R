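#' Amino-acid allele graph under the standard genetic code
#'
#' Builds the allele graph whose vertices are amino acids and whose arrows
#' connect two amino acids X and Y whenever some codon translating to X can
#' be turned into a codon translating to Y by a single nucleotide
#' substitution. This is the mutational structure seen by non-synonymous
#' point mutations: synonymous changes are free, so the relevant distance
#' between amino acids is the minimal number of amino-acid-changing
#' substitutions connecting them.
#'
#' The codon table is the standard nuclear genetic code (NCBI translation
#' table 1) as provided by [Biostrings::GENETIC_CODE]. By default stop is
#' kept as a 21st vertex (label `"*"`) with its own arrows, which is the
#' variant whose homopolymer thresholds match the published values to all
#' printed digits; `include_stop = FALSE` drops the three stop codons
#' entirely, treating mutations into stop as absent and leaving the 20
#' proteinogenic amino acids. The graph is symmetric by construction since
#' single-nucleotide substitutions are reversible.
#'
#' @param include_stop keep the stop "amino acid" as an extra vertex
#'   (default `TRUE`).
#' @param code optional named character vector mapping codons to one-letter
#'   amino-acid codes (stop = `"*"`), overriding the standard table. Must
#'   cover all 64 codons.
#' @return An [allele_graph()] with vertices in lexicographic order of the
#'   one-letter amino-acid codes.
#' @examples
#' aa <- graph_amino_acid()
#' allele_distance(aa, "Y", "M") # Tyr -> Met, the unique distance-3 pair
#' @export
graph_amino_acid <- function(include_stop = TRUE, code = NULL) {
  if (is.null(code)) {
    code <- Biostrings::GENETIC_CODE
  }
  codons <- names(code)
  if (length(codons) != 64L || anyDuplicated(codons) > 0) {
    abort("`code` must map all 64 codons.", class = "accperc_invalid_code")
  }
  aa <- unname(code)
  if (!include_stop) {
    keep <- aa != "*"
    codons <- codons[keep]
    aa <- aa[keep]
  }
  vertices <- sort(unique(aa))
  n <- length(vertices)
  adj <- matrix(0L, n, n, dimnames = list(vertices, vertices))
  nts <- c("A", "C", "G", "T")
  codon_chars <- strsplit(codons, "", fixed = TRUE)
  aa_of <- setNames(aa, codons)
  for (i in seq_along(codons)) {
    from_aa <- aa[i]
    chars <- codon_chars[[i]]
    for (pos in 1:3) {
      for (nt in nts) {
        if (nt == chars[pos]) next
        mutated <- chars
        mutated[pos] <- nt
        to_codon <- paste(mutated, collapse = "")
        to_aa <- unname(aa_of[to_codon])
        # codons dropped with the stop set look up as NA
        if (is.na(to_aa)) next
        if (to_aa != from_aa) {
          adj[from_aa, to_aa] <- 1L
        }
      }
    }
  }
  allele_graph(adj, labels = vertices)
}
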