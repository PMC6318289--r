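## A synthetic stand-in for the APP C-terminus coding region. This is NOT
## the real APP CDS: it is a deterministic, code-generated model carrying
## the documented sequence features of the APP695 editing site so that the
## sequence arithmetic (cut-to-codon mapping, ortholog protospacer
## distance, truncation counts) can be computed offline.

.appFiller <- c("GCT", "GAT", "CTC", "AAA", "TTC", "GGA", "CAT", "ATC",
                "CCA", "AGC", "GTG", "TAC", "ATG", "TGC", "GAG", "AAC",
                "CGT", "ACA", "TTG", "GAC")

#' Synthetic APP C-terminus coding model (human/mouse)
#'
#' A deterministic synthetic coding context modelling the C-terminal exon
#' region of a 695-residue APP-like protein, in full-protein numbering.
#' The model is built, not downloaded: the sequence is not the real APP
#' CDS, but it carries the documented structure of the APP695 editing
#' site -
#' \itemize{
#'   \item codons 601-695 followed by a stop and a short 3' tail;
#'   \item a plus-strand TGG PAM whose blunt cut (3 bp 5' of the PAM)
#'     falls exactly on the codon-659/660 boundary, so
#'     [mapCutToCodon()] returns 659;
#'   \item mouse and human protospacers at that site differing by exactly
#'     two (synonymous) nucleotides, so the encoded protein is identical;
#'   \item a downstream frame such that a 1-bp deletion at the cut yields
#'     a product retaining residues 1-659, appending Gly-Gly before a new
#'     stop (the "-659-GG" product), truncating the last 36 residues;
#'   \item a C-terminal antibody epitope spanning the last 20 residues
#'     (676-695).
#' }
#'
#' @param species `"human"` or `"mouse"`; the two differ only at the two
#'   protospacer positions.
#' @return list with `context` (nucleotide string), `map` (a
#'   [CodingMap-class]: cdsStart 0, upstreamAa 600, wtProteinLength 695),
#'   `label` (`"APP"`), `epitopes` (data.frame, the last-20-residue
#'   epitope), `guidePamStart` (0-based PAM position of the modelled
#'   guide), `cutSite` (0-based cut position, 177) and `assay` (an
#'   [AmpliconAssay-class] treating the whole context as the amplicon).
#' @examples
#' mod <- syntheticAppModel("human")
#' mapCutToCodon(mod$cutSite, mod$map)
#' @export
syntheticAppModel <- function(species = c("human", "mouse")) {
    species <- match.arg(species)
    codons <- rep(.appFiller, length.out = 95L)
    ## codon index i encodes residue 600 + i
    codons[56L] <- if (species == "human") "CTG" else "CTC"  # Leu
    codons[58L] <- if (species == "human") "GAA" else "GAG"  # Glu
    codons[59L] <- "CAA"  # Gln, residue 659
    codons[60L] <- "TGG"  # Trp, residue 660; first protospacer-3' codon
    codons[61L] <- "TGG"  # Trp, residue 661; doubles as the NGG PAM
    codons[62L] <- "GTA"  # Val; supplies TA of the frameshift stop
    codons[63L] <- "AAG"  # Lys; supplies the A completing TAA
    tail3p <- "GATCCTGCAGGTCGACTCTAGAGGATCCCCGGGTACCGAGCTCGA"
    context <- paste0(paste(codons, collapse = ""), "TAA", tail3p)
    cutSite <- 177L                       # codon-659/660 boundary
    list(context = context,
         map = codingMap(cdsStart = 0L, upstreamAa = 600L,
                         wtProteinLength = 695L),
         label = "APP",
         epitopes = data.frame(name = "Y188", start = 676L, end = 695L),
         guidePamStart = 180L,
         cutSite = cutSite,
         assay = ampliconAssay(
             reference = context,
             fwdPrimer = substr(context, 1L, 20L),
             revPrimer = .revcomp(substr(context, nchar(context) - 19L,
                                         nchar(context))),
             cutSite = cutSite))
}
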