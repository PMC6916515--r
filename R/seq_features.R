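#' Sequence records
#'
#' Minimal container for a DNA or protein sequence: an ID, an alphabet
#' tag and the residue string. DNA accepts the unambiguous IUPAC bases
#' plus N; protein accepts the 20 standard amino acids.
#'
#' @param id Accession / identifier string.
#' @param residues Sequence string (case-insensitive; stored upper-case).
#' @param alphabet `"dna"` or `"protein"`.
#' @return A list of class `sequence_record`.
#' @export
sequence_record <- function(id, residues, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  residues <- toupper(gsub("[ \t\r\n0-9]", "", residues))
  allowed <- if (alphabet == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWY"
  bad <- setdiff(strsplit(residues, "")[[1]], strsplit(allowed, "")[[1]])
  if (length(bad))
    stop("invalid ", alphabet, " residue(s): ",
         paste(unique(bad), collapse = ", "))
  structure(list(id = as.character(id), alphabet = alphabet,
                 residues = residues),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<%s> %s sequence, %d residues\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Read the first record of a FASTA or GenBank flat file
#'
#' FASTA parsing is delegated to seqinr; GenBank files are read with a
#' minimal flat-file reader that takes the LOCUS name and the ORIGIN
#' block.
#'
#' @param path File path.
#' @param alphabet `"dna"` (default) or `"protein"`.
#' @return A [sequence_record()].
#' @export
read_fasta_record <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  recs <- seqinr::read.fasta(path, seqtype = if (alphabet == "dna") "DNA"
                             else "AA", as.string = TRUE)
  if (!length(recs)) stop("no records in ", path)
  sequence_record(names(recs)[1], as.character(recs[[1]]), alphabet)
}

#' @rdname read_fasta_record
#' @export
read_genbank_record <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1]), "[ \t]+")[[1]][2]
        else "unknown"
  o <- grep("^ORIGIN", lines)
  if (!length(o)) stop("no ORIGIN block in ", path)
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > o[1]][1] - 1L else length(lines)
  seq <- paste(lines[(o[1] + 1L):end], collapse = "")
  sequence_record(id, seq, alphabet)
}

# average residue masses (Da); sum + one water = average protein mass
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.01524

# EMBOSS pKa values for ionizable groups
.pka_tables <- list(
  emboss = list(nterm = 8.6, cterm = 3.6,
                pos = c(K = 10.8, R = 12.5, H = 6.5),
                neg = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))
)

#' Translate the longest ATG-initiated open reading frame
#'
#' Scans the three forward frames (the input is an oriented cDNA) for
#' ATG-initiated ORFs terminated by an in-frame stop codon, selects the
#' longest (ties broken by smallest start position), and translates it
#' with the standard genetic code, stop excluded.
#'
#' @param dna A DNA [sequence_record()].
#' @return A protein [sequence_record()] with attributes `orf_start` and
#'   `orf_end` (1-based nucleotide coordinates, stop codon included).
#' @examples
#' longest_orf_translate(sequence_record("x", "ATGAAATAA"))
#' @export
longest_orf_translate <- function(dna) {
  stopifnot(inherits(dna, "sequence_record"), dna$alphabet == "dna")
  s <- dna$residues
  n <- nchar(s)
  chars <- strsplit(s, "")[[1]]
  best <- NULL
  for (frame in 0:2) {
    starts <- seq(frame + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    stop_at <- which(codons %in% c("TAA", "TAG", "TGA"))
    atg_at <- which(codons == "ATG")
    for (a in atg_at) {
      stops <- stop_at[stop_at > a]
      if (!length(stops)) next
      len <- (stops[1] - a) * 3L  # coding nt, stop excluded
      if (is.null(best) || len > best$len ||
          (len == best$len && starts[a] < best$start)) {
        best <- list(len = len, start = starts[a],
                     end = starts[stops[1]] + 2L)
      }
    }
  }
  if (is.null(best)) stop("no ATG-initiated ORF with a stop codon found")
  cds <- chars[best$start:(best$start + best$len - 1L)]
  aa <- paste(seqinr::translate(cds), collapse = "")
  out <- sequence_record(paste0(dna$id, "_orf"), aa, "protein")
  attr(out, "orf_start") <- best$start
  attr(out, "orf_end") <- best$end
  out
}

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water, in kDa. The empty chain
#' returns the mass of water (0.018 kDa) by convention.
#'
#' @param protein A protein [sequence_record()] or a plain string.
#' @return Mass in kDa.
#' @export
molecular_mass <- function(protein) {
  aa <- as_protein_chars(protein)
  unname(sum(.residue_mass[aa]) + .water_mass) / 1000
}

#' Isoelectric point by bisection on the net-charge curve
#'
#' Net charge is the Henderson-Hasselbalch sum over the N-terminus,
#' C-terminus and ionizable side chains; it is strictly decreasing in pH,
#' so the root is unique. Bisection runs until |charge| < 1e-4.
#'
#' @param protein A protein [sequence_record()] or string.
#' @param pka_set Name of the pKa table (currently `"emboss"`).
#' @return The pI.
#' @export
isoelectric_point <- function(protein, pka_set = "emboss") {
  aa <- as_protein_chars(protein)
  pk <- .pka_tables[[pka_set]]
  if (is.null(pk)) stop("unknown pKa set: ", pka_set)
  counts <- table(factor(aa, levels = names(.residue_mass)))
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pk$nterm)) +
      sum(counts[names(pk$pos)] / (1 + 10^(ph - pk$pos)))
    neg <- 1 / (1 + 10^(pk$cterm - ph)) +
      sum(counts[names(pk$neg)] / (1 + 10^(pk$neg - ph)))
    pos - neg
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    c_mid <- charge(mid)
    if (abs(c_mid) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (c_mid > 0) lo <- mid else hi <- mid
  }
}

#' N-glycosylation sequon positions
#'
#' Returns the 1-based positions i with asparagine at i, anything but
#' proline at i+1, and serine or threonine at i+2 (the N-X(!=P)-[S/T]
#' sequon). Overlapping sequons are all reported.
#'
#' @param protein A protein [sequence_record()] or string.
#' @return Ordered integer vector of positions (possibly empty).
#' @examples
#' nglyc_sequons("NNST")  # both positions 1 and 2
#' @export
nglyc_sequons <- function(protein) {
  aa <- as_protein_chars(protein)
  n <- length(aa)
  if (n < 3) return(integer(0))
  i <- seq_len(n - 2L)
  i[aa[i] == "N" & aa[i + 1L] != "P" & aa[i + 2L] %in% c("S", "T")]
}

as_protein_chars <- function(protein) {
  if (inherits(protein, "sequence_record")) {
    if (protein$alphabet != "protein") stop("need a protein record")
    s <- protein$residues
  } else {
    s <- sequence_record("x", protein, "protein")$residues
  }
  if (!nchar(s)) return(character(0))
  strsplit(s, "")[[1]]
}

#' Sequence-feature report for a self-marker cDNA
#'
#' Convenience wrapper: reads a cDNA, finds and translates the longest
#' forward ORF and reports length, coordinates, protein length, average
#' molecular mass, pI and N-glycosylation sequon positions.
#'
#' @param dna A DNA [sequence_record()].
#' @return A list of class `seq_features`.
#' @export
seq_features <- function(dna) {
  prot <- longest_orf_translate(dna)
  structure(list(
    id = dna$id,
    cdna_length = nchar(dna$residues),
    orf_start = attr(prot, "orf_start"),
    orf_end = attr(prot, "orf_end"),
    protein_length = nchar(prot$residues),
    mass_kda = molecular_mass(prot),
    pi = isoelectric_point(prot),
    sequons = nglyc_sequons(prot)
  ), class = "seq_features")
}

#' @export
print.seq_features <- function(x, ...) {
  cat(sprintf("<%s> cDNA %d bp; ORF %d..%d; protein %d aa\n", x$id,
              x$cdna_length, x$orf_start, x$orf_end, x$protein_length))
  cat(sprintf("  average mass %.3f kDa; pI %.2f; %d N-glycosylation sequon(s) at %s\n",
              x$mass_kda, x$pi, length(x$sequons),
              paste(x$sequons, collapse = ", ")))
  invisible(x)
}
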