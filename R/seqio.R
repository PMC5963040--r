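# Readers and writers for the standard formats the pipeline touches.
# Sequence I/O delegates to Biostrings; annotation I/O to rtracklayer.
# Coordinates are 1-based inclusive internally and in GFF3; BED output is
# 0-based half-open (handled by rtracklayer on export).

#' Read a FASTA file into a validated DNAStringSet
#'
#' Residues are upper-cased on read; ids (header up to the first whitespace)
#' must be non-empty and unique. IUPAC ambiguity codes other than N are
#' collapsed to N so that downstream scoring (where N matches nothing) is
#' well-defined.
#'
#' @param path FASTA file path
#' @return named DNAStringSet; the part of each header after the first
#'   whitespace is kept in \code{mcols(x)$desc}
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  x <- tryCatch(readDNAStringSet(path, format = "fasta"),
                error = function(e) .stopf("malformed FASTA '%s': %s", path,
                                           conditionMessage(e)))
  hdr <- names(x)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (length(x) > 0 && any(ids == ""))
    .stopf("empty sequence id in '%s' (record %d)", path, which(ids == "")[1])
  if (anyDuplicated(ids))
    .stopf("duplicate sequence id '%s' in '%s'", ids[anyDuplicated(ids)], path)
  chs <- as.character(x)
  chs <- toupper(chs)
  chs <- gsub("[^ACGTN]", "N", chs)
  out <- DNAStringSet(chs)
  names(out) <- ids
  mcols(out)$desc <- desc
  out
}

#' Write sequences as wrapped FASTA
#'
#' Standard 60-column wrapping; an empty set writes an empty file. When a
#' \code{desc} metadata column is present it is appended to the header after
#' a space.
#'
#' @param seqs named DNAStringSet (or character vector)
#' @param path output file path
#' @return the path, invisibly
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (length(seqs) == 0L) { file.create(path); return(invisible(path)) }
  hdr <- names(seqs)
  d <- mcols(seqs)$desc
  if (!is.null(d)) {
    nz <- !is.na(d) & d != ""
    hdr[nz] <- paste(hdr[nz], d[nz])
  }
  out <- seqs
  names(out) <- hdr
  writeXStringSet(out, filepath = path, width = 60L)
  invisible(path)
}

## ---- Wicker code table -------------------------------------------------
## Three-letter codes (class, order, superfamily). The MITE/TRIM/LARD codes
## are an artifact convention: Wicker assigns no code to these derived
## non-autonomous forms.
.WICKER_TABLE <- rbind(
  c("RLC", "I",  "LTR",      "Copia"),
  c("RLG", "I",  "LTR",      "Gypsy"),
  c("RLX", "I",  "LTR",      "unknown"),
  c("RIL", "I",  "LINE",     "L1"),
  c("RIX", "I",  "LINE",     "unknown"),
  c("RSX", "I",  "SINE",     "unknown"),
  c("RLT", "I",  "TRIM",     "none"),
  c("RLD", "I",  "LARD",     "none"),
  c("DTA", "II", "TIR",      "hAT"),
  c("DTT", "II", "TIR",      "Mariner/Tc1"),
  c("DTH", "II", "TIR",      "Harbinger"),
  c("DTB", "II", "TIR",      "PiggyBac"),
  c("DTX", "II", "TIR",      "unknown"),
  c("DHH", "II", "Helitron", "Helitron"),
  c("DMM", "II", "MITE",     "none"))
colnames(.WICKER_TABLE) <- c("code", "wicker_class", "order", "superfamily")

#' Parse a Wicker-coded library header
#'
#' Headers follow the convention \code{<3-letter code>_<free text>} (e.g.
#' \code{RLC_fam1} for Class I / LTR / Copia) or an explicit
#' \code{Class/Order/Superfamily} triple. Unknown codes parse leniently to
#' \code{(unknown, noCat, none)}.
#'
#' @param header sequence id / header string
#' @return list(wicker_class, order, superfamily)
#' @examples
#' parseWickerCode("RLC_Tlut-1")
#' parseWickerCode("DTT_fam3")
#' @export
parseWickerCode <- function(header) {
  if (grepl("/", header, fixed = TRUE)) {
    parts <- strsplit(header, "/", fixed = TRUE)[[1]]
    if (length(parts) >= 3 && parts[1] %in% c("I", "II") && parts[2] %in% .ORDERS)
      return(list(wicker_class = parts[1], order = parts[2], superfamily = parts[3]))
  }
  code <- toupper(substr(header, 1, 3))
  i <- match(code, .WICKER_TABLE[, "code"])
  if (is.na(i))
    return(list(wicker_class = "unknown", order = "noCat", superfamily = "none"))
  list(wicker_class = unname(.WICKER_TABLE[i, "wicker_class"]),
       order = unname(.WICKER_TABLE[i, "order"]),
       superfamily = unname(.WICKER_TABLE[i, "superfamily"]))
}

#' Wicker code for a (order, superfamily) pair
#' @param order TE order
#' @param superfamily TE superfamily (or "unknown"/"none")
#' @return 3-letter code (falls back to "XXX")
#' @export
wickerCode <- function(order, superfamily = "unknown") {
  tb <- .WICKER_TABLE
  i <- which(tb[, "order"] == order & tb[, "superfamily"] == superfamily)
  if (length(i) == 0L) i <- which(tb[, "order"] == order & tb[, "superfamily"] == "unknown")
  if (length(i) == 0L) i <- which(tb[, "order"] == order)
  if (length(i) == 0L) return("XXX")
  unname(tb[i[1], "code"])
}

## ---- annotation I/O -----------------------------------------------------

.checkBounds <- function(gr, genome) {
  lens <- setNames(width(genome), names(genome))
  cn <- as.character(seqnames(gr))
  bad <- !cn %in% names(lens)
  if (any(bad)) .stopf("interval on unknown contig '%s'", cn[bad][1])
  over <- end(gr) > lens[cn] | start(gr) < 1L
  if (any(over)) .stopf("interval beyond contig bounds on '%s'", cn[over][1])
  invisible(TRUE)
}

#' Write annotation intervals as GFF3
#'
#' Features are typed \code{transposable_element}; attributes carry the
#' library id, classification code, identity, library coverage and FLC flag
#' when the corresponding metadata columns are present.
#'
#' @param gr GRanges of annotation intervals (1-based inclusive)
#' @param genome named DNAStringSet the intervals refer to (bounds check)
#' @param path output path
#' @return the path, invisibly
#' @export
writeAnnotationGFF3 <- function(gr, genome, path) {
  if (length(gr) > 0) .checkBounds(gr, genome)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(gr) == 0L) return(invisible(path))
  md <- mcols(gr)
  attr_of <- function(i) {
    parts <- c(sprintf("ID=te%05d", i))
    for (col in c("library_id", "classification", "pct_identity",
                  "library_coverage", "flc")) {
      if (col %in% colnames(md)) {
        v <- md[[col]][i]
        if (is.numeric(v)) v <- sprintf("%.4f", v)
        parts <- c(parts, sprintf("%s=%s", col, v))
      }
    }
    paste(parts, collapse = ";")
  }
  sc <- if ("score" %in% colnames(md)) sprintf("%.1f", md$score) else rep(".", length(gr))
  lines <- vapply(seq_along(gr), function(i) {
    paste(as.character(seqnames(gr))[i], "TEforge", "transposable_element",
          start(gr)[i], end(gr)[i], sc[i],
          as.character(strand(gr))[i], ".", attr_of(i), sep = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a TEforge GFF3 annotation back into GRanges
#' @param path GFF3 path
#' @return GRanges with available attribute columns
#' @export
readAnnotationGFF3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr
}

#' Write intervals as BED (0-based half-open on disk)
#' @param gr GRanges (1-based inclusive in memory)
#' @param path output path
#' @param names optional name column values
#' @export
writeBed <- function(gr, path, names = NULL) {
  if (!is.null(names)) mcols(gr)$name <- names
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into GRanges (1-based inclusive in memory)
#' @param path BED path
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' Read per-copy transcript coverage from a TSV (copy_id, covered_fraction)
#' @param path TSV path
#' @return data.frame(copy_id, covered_fraction)
#' @export
readCoverageTSV <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("copy_id", "covered_fraction")
  if (!all(need %in% colnames(df)))
    .stopf("coverage TSV must have columns %s", paste(need, collapse = ", "))
  df
}
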