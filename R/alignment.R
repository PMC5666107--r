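#' Partitioned multi-gene alignments
#'
#' A `partitioned_alignment` couples a character matrix of aligned sequences
#' (taxa x columns; gaps `-`, IUPAC ambiguity codes allowed, `?` missing)
#' with a partition table assigning every column span to a gene of a given
#' data kind: `"coding"` (nucleotide, in-frame), `"rRNA"` (nucleotide), or
#' `"aa"` (amino acid). Spans must tile the alignment without overlap.
#'
#' @param seq Character matrix with rownames (taxon labels); every entry one
#'   residue.
#' @param partitions Data frame with columns `gene`, `kind`, `start`, `end`
#'   and optionally `frame` (0-based reading-frame offset for coding genes,
#'   default 0).
#' @return A `partitioned_alignment` object.
#' @export
partitioned_alignment <- function(seq, partitions) {
  stopifnot(is.matrix(seq), !is.null(rownames(seq)), is.data.frame(partitions),
            all(c("gene", "kind", "start", "end") %in% names(partitions)))
  partitions <- tibble::as_tibble(partitions)
  if (!"frame" %in% names(partitions)) partitions$frame <- 0L
  partitions <- partitions[order(partitions$start), , drop = FALSE]
  if (!all(partitions$kind %in% c("coding", "rRNA", "aa"))) {
    stop("partition kind must be 'coding', 'rRNA' or 'aa'", call. = FALSE)
  }
  spans <- unlist(purrr::map2(partitions$start, partitions$end, seq.int))
  if (length(spans) != ncol(seq) || anyDuplicated(spans) ||
      !setequal(spans, seq_len(ncol(seq)))) {
    stop("partition spans must tile the alignment without overlap", call. = FALSE)
  }
  for (i in seq_len(nrow(partitions))) {
    p <- partitions[i, ]
    if (p$kind == "coding" && (p$end - p$start + 1 - p$frame) %% 3 != 0) {
      stop(sprintf("coding gene '%s' has length not divisible by 3 after frame offset",
                   p$gene), call. = FALSE)
    }
  }
  structure(list(seq = seq, partitions = partitions),
            class = "partitioned_alignment")
}

#' @export
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("Partitioned alignment: %d taxa x %d columns, %d gene(s)\n",
              nrow(x$seq), ncol(x$seq), nrow(x$partitions)))
  print(x$partitions)
  invisible(x)
}

#' Extract the columns of one gene
#' @param x A [partitioned_alignment].
#' @param gene Gene name.
#' @return Character matrix of that gene's columns.
#' @export
gene_columns <- function(x, gene) {
  p <- x$partitions[x$partitions$gene == gene, , drop = FALSE]
  if (nrow(p) == 0) stop(sprintf("no gene '%s' in the alignment", gene), call. = FALSE)
  x$seq[, seq.int(p$start[1], p$end[1]), drop = FALSE]
}

#' Read and write FASTA alignments
#'
#' Thin wrappers around `seqinr` that move between FASTA files and the
#' character-matrix representation used here.
#'
#' @param path FASTA path.
#' @return `read_fasta_alignment()`: a character matrix (taxa x columns).
#' @export
read_fasta_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1) {
    stop("sequences have unequal lengths; not an alignment", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(seqs, function(s) toupper(as.character(s))))
  rownames(mat) <- names(seqs)
  mat
}

#' @rdname read_fasta_alignment
#' @param seqmat Character matrix (taxa x columns) or [partitioned_alignment].
#' @export
write_fasta_alignment <- function(seqmat, path) {
  if (inherits(seqmat, "partitioned_alignment")) seqmat <- seqmat$seq
  seqinr::write.fasta(lapply(seq_len(nrow(seqmat)), function(i) seqmat[i, ]),
                      names = rownames(seqmat), file.out = path, nbchar = 80)
  invisible(path)
}

#' Read and write relaxed PHYLIP alignments
#'
#' @param path PHYLIP path.
#' @param type `"DNA"` or `"AA"`.
#' @return `read_phylip_alignment()`: a character matrix.
#' @export
read_phylip_alignment <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  pd <- phangorn::read.phyDat(path, format = "phylip",
                              type = if (type == "DNA") "DNA" else "AA")
  mat <- toupper(as.character(pd))
  rownames(mat) <- names(pd)
  mat
}

#' @rdname read_phylip_alignment
#' @param seqmat Character matrix (taxa x columns).
#' @export
write_phylip_alignment <- function(seqmat, path) {
  lines <- c(sprintf("%d %d", nrow(seqmat), ncol(seqmat)),
             sprintf("%s  %s", rownames(seqmat),
                     apply(seqmat, 1, paste, collapse = "")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a mixed-data NEXUS file
#'
#' Emits a NEXUS DATA block with `DATATYPE=MIXED` covering amino-acid and
#' nucleotide spans, plus a SETS block with one `CHARSET` per gene — the
#' layout used for the translated + rRNA dataset series.
#'
#' @param aln A [partitioned_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_mixed <- function(aln, path) {
  stopifnot(inherits(aln, "partitioned_alignment"))
  p <- aln$partitions
  kinds <- ifelse(p$kind == "aa", "PROTEIN", "DNA")
  spans <- split(seq_len(nrow(p)), cumsum(c(TRUE, kinds[-1] != kinds[-length(kinds)])))
  mixed <- paste(vapply(spans, function(i) {
    sprintf("%s:%d-%d", kinds[i[1]], min(p$start[i]), max(p$end[i]))
  }, character(1)), collapse = ",")
  pad <- max(nchar(rownames(aln$seq))) + 2
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(aln$seq), ncol(aln$seq)),
    sprintf("  FORMAT DATATYPE=MIXED(%s) GAP=- MISSING=?;", mixed),
    "  MATRIX",
    sprintf("    %-*s %s", pad, rownames(aln$seq),
            apply(aln$seq, 1, paste, collapse = "")),
    "  ;",
    "END;",
    "BEGIN SETS;",
    sprintf("  CHARSET %s = %d-%d;", p$gene, p$start, p$end),
    "END;")
  writeLines(lines, path)
  invisible(path)
}

.GENETIC_CODE_1 <- local({
  bases <- c("T", "C", "A", "G")
  # codons vary fastest in the third position within this standard layout
  codons <- apply(expand.grid(b3 = bases, b2 = bases, b1 = bases)[, 3:1], 1, paste0,
                  collapse = "")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

.IUPAC_EXPAND <- list(A="A",C="C",G="G",T="T",U="T",R=c("A","G"),Y=c("C","T"),
                      S=c("C","G"),W=c("A","T"),K=c("G","T"),M=c("A","C"),
                      B=c("C","G","T"),D=c("A","G","T"),H=c("A","C","T"),
                      V=c("A","C","G"),N=c("A","C","G","T"))

# translate one codon; gaps/irresolvable ambiguity -> X; returns "*" for stops
.translate_codon <- function(codon) {
  b <- strsplit(toupper(codon), "")[[1]]
  if (any(b %in% c("-", "?")) || !all(b %in% names(.IUPAC_EXPAND))) return("X")
  combos <- expand.grid(.IUPAC_EXPAND[[b[1]]], .IUPAC_EXPAND[[b[2]]],
                        .IUPAC_EXPAND[[b[3]]], stringsAsFactors = FALSE)
  aas <- unique(.GENETIC_CODE_1[apply(combos, 1, paste0, collapse = "")])
  if (length(aas) == 1) aas else "X"
}

#' Translate aligned coding nucleotide rows to amino acids
#'
#' Standard genetic code. Codons containing gaps, or ambiguity codes that do
#' not resolve to a unique amino acid, become `"X"`. A resolvable stop codon
#' before the final position is an error naming the taxon and codon index
#' (trailing stops are trimmed to `X` is not done — a final stop is also an
#' error since these are gene fragments, not full CDS; supply `trim_stop =
#' TRUE` to tolerate one trailing stop).
#'
#' @param seqmat Character matrix of coding nucleotides (taxa x columns).
#' @param frame 0-based reading-frame offset; leading off-frame columns are
#'   dropped.
#' @param trim_stop Tolerate a stop in the final codon (dropped as `X`).
#' @return Character matrix of amino acids (taxa x codons).
#' @examples
#' translate_cds(matrix(strsplit("ATGAAA", "")[[1]], nrow = 1,
#'                      dimnames = list("t1", NULL)))
#' @export
translate_cds <- function(seqmat, frame = 0, trim_stop = FALSE) {
  stopifnot(is.matrix(seqmat))
  if (frame > 0) seqmat <- seqmat[, -seq_len(frame), drop = FALSE]
  if (ncol(seqmat) %% 3 != 0) {
    stop(sprintf("coding length %d is not divisible by 3 after frame offset",
                 ncol(seqmat)), call. = FALSE)
  }
  n_codon <- ncol(seqmat) / 3
  out <- matrix(NA_character_, nrow(seqmat), n_codon,
                dimnames = list(rownames(seqmat), NULL))
  for (i in seq_len(nrow(seqmat))) {
    for (j in seq_len(n_codon)) {
      codon <- paste0(seqmat[i, (3 * j - 2):(3 * j)], collapse = "")
      aa <- .translate_codon(codon)
      if (aa == "*") {
        if (trim_stop && j == n_codon) { aa <- "X" } else {
          stop(sprintf("internal stop codon in taxon '%s' at codon %d (%s)",
                       rownames(seqmat)[i], j, codon), call. = FALSE)
        }
      }
      out[i, j] <- aa
    }
  }
  out
}
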