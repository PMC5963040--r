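# Synthetic consensus peptides for the four protein domains the classifier
# recognizes: reverse transcriptase (RT), integrase (INT), endonuclease (EN)
# and transposase (TASE). These are generated, curated stand-ins for
# profile-HMM databanks: fixed pseudo-random 64-mers carrying the canonical
# short catalytic motifs of each domain class (LPQG/YMDD for RT, the D..D..E
# triad for INT and TASE, GDXN for APE-type EN). They are used both to build
# synthetic transposase ORFs and as the classifier's motif set.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.spliceMotif <- function(aa, motif, at) {
  paste0(substr(aa, 1, at - 1), motif,
         substr(aa, at + nchar(motif), nchar(aa)))
}

#' Domain consensus peptides
#'
#' @return named character vector of peptides for tokens RT, INT, EN, TASE
#' @export
domainPeptides <- function() {
  withSeed(73421L, {
    base <- vapply(1:4, function(i)
      paste(sample(.AA20, 64, replace = TRUE), collapse = ""), character(1))
    rt <- .spliceMotif(.spliceMotif(base[1], "LPQG", 12), "YMDD", 40)
    int <- .spliceMotif(.spliceMotif(.spliceMotif(base[2], "DAV", 10), "DGS", 30), "ESR", 52)
    en <- .spliceMotif(.spliceMotif(base[3], "GDFN", 14), "TDH", 44)
    tase <- .spliceMotif(.spliceMotif(.spliceMotif(base[4], "DLG", 8), "DTE", 34), "EWF", 55)
    c(RT = rt, INT = int, EN = en, TASE = tase)
  })
}

# One fixed codon per amino acid; reverse translation is deterministic, so a
# shared peptide yields identical nucleotide sequence wherever it is embedded.
.CODON_OF <- c(A = "GCT", R = "CGT", N = "AAC", D = "GAC", C = "TGC",
               Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
               L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCA",
               S = "TCT", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

#' Reverse-translate a peptide with a fixed codon table
#' @param aa peptide (single character string, 20-letter alphabet)
#' @return nucleotide string of length 3*nchar(aa)
#' @export
reverseTranslate <- function(aa) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  bad <- !ch %in% names(.CODON_OF)
  if (any(bad)) .stopf("cannot reverse-translate residue '%s'", ch[bad][1])
  paste(.CODON_OF[ch], collapse = "")
}
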