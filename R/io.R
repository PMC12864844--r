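#' Read and write transcript FASTA
#'
#' Sequences are held internally in the RNA alphabet; FASTA is written with T
#' and converted back on read.
#'
#' @param transcripts tibble with `gene_id`, `sequence`.
#' @param path file path.
#' @return `read_transcript_fasta` returns a tibble with `gene_id`,
#'   `sequence`, `length`, empty `eij_positions` and unit
#'   `expression_weight`; `write_transcript_fasta` returns `path` invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  x <- Biostrings::DNAStringSet(rna_to_dna(transcripts$sequence))
  names(x) <- transcripts$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_transcript_fasta
#' @export
read_transcript_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(gene_id = names(x),
         sequence = unname(dna_to_rna(as.character(x))),
         length = Biostrings::width(x),
         eij_positions = rep(list(integer(0)), length(x)),
         expression_weight = 1)
}

#' Read and write exon structure as BED
#'
#' Each exon is one 0-based half-open interval (`gene, start, end`); the
#' junction positions of a transcript are the internal interval boundaries.
#'
#' @param transcripts tibble with `gene_id`, `length`, `eij_positions`.
#' @param path file path.
#' @return `read_eij_bed` returns a tibble `gene_id`, `eij_positions` (list),
#'   `length`; the writer returns `path` invisibly.
#' @export
write_eij_bed <- function(transcripts, path) {
  rows <- purrr::pmap(transcripts[, c("gene_id", "length", "eij_positions")],
                      function(gene_id, length, eij_positions) {
    bounds <- c(0L, eij_positions, length)   # `length` = transcript length
    nb <- base::length(bounds)
    tibble(chrom = gene_id, start = bounds[-nb], end = bounds[-1])
  }) |> dplyr::bind_rows()
  readr::write_tsv(rows, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_eij_bed
#' @export
read_eij_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  bed |>
    dplyr::group_by(gene_id = .data$chrom) |>
    dplyr::summarise(
      eij_positions = list(sort(.data$end[.data$end < max(.data$end)])),
      length = max(.data$end), .groups = "drop")
}

#' Read and write the m6A site table
#'
#' Plain TSV with 0-based positions. `one_based = TRUE` on read shifts the
#' `pos` column by -1 for tables using 1-based coordinates.
#'
#' @param sites a site tibble (any columns; `gene_id` and `pos` expected).
#' @param path file path.
#' @param one_based whether the file on disk uses 1-based positions.
#' @return the site tibble (reader) or `path` invisibly (writer).
#' @export
write_site_table <- function(sites, path) {
  sites <- dplyr::select(sites, -dplyr::where(is.list))
  readr::write_tsv(sites, path)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path, one_based = FALSE) {
  sites <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (one_based) sites$pos <- sites$pos - 1L
  sites
}

#' Sites as BED6
#'
#' One interval per site (`pos`, `pos + 1`), the score column carried in the
#' BED score field, strand `+`.
#'
#' @param sites tibble with `gene_id`, `pos` and optionally a score column.
#' @param path file path.
#' @param score_col score column name (zeros if absent).
#' @return `path`, invisibly.
#' @export
write_site_bed <- function(sites, path, score_col = "score") {
  sc <- if (score_col %in% names(sites)) sites[[score_col]] else 0
  bed <- tibble(chrom = sites$gene_id, start = sites$pos,
                end = sites$pos + 1L,
                name = paste0(sites$gene_id, ":", sites$pos),
                score = sc, strand = "+")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read and write reads as TSV
#'
#' @param reads tibble with `gene_id`, `start`, `seq`, `sample_id`.
#' @param path file path.
#' @return the reads tibble (reader) or `path` invisibly (writer).
#' @export
write_reads_tsv <- function(reads, path) {
  readr::write_tsv(reads, path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read transcript-space alignments from a SAM text file
#'
#' Minimal SAM ingestion for unspliced transcript-space alignments: header
#' lines are skipped, unmapped records dropped, soft-clipped ends trimmed,
#' and minus-strand records (flag 0x10) reverse-complemented before pileup,
#' per the package's strand contract. Spliced or indel CIGARs (N/I/D) are
#' rejected with an error naming the line.
#'
#' @param path SAM file path.
#' @param sample_id sample label attached to all reads.
#' @return reads tibble `gene_id`, `start` (0-based), `seq` (RNA alphabet),
#'   `sample_id`.
#' @export
read_reads_sam <- function(path, sample_id = "sample1") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  out <- purrr::imap(lines, function(ln, i) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop("malformed SAM record at line ", i, call. = FALSE)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)   # unmapped
    cigar <- f[6]
    if (grepl("[NID]", cigar))
      stop("unsupported spliced/indel CIGAR '", cigar, "' at line ", i,
           call. = FALSE)
    seq <- f[10]
    ops <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
    lens <- as.integer(ops[, 2]); op <- ops[, 3]
    # trim soft clips
    if (length(op) && op[1] == "S") {
      seq <- substr(seq, lens[1] + 1L, nchar(seq))
      lens <- lens[-1]; op <- op[-1]
    }
    if (length(op) && op[length(op)] == "S") {
      seq <- substr(seq, 1L, nchar(seq) - lens[length(op)])
    }
    seq <- dna_to_rna(seq)
    if (bitwAnd(flag, 16L) > 0L) seq <- revcomp_rna(seq)
    tibble(gene_id = f[3], start = as.integer(f[4]) - 1L, seq = seq)
  }) |> dplyr::bind_rows()
  out$sample_id <- sample_id
  out
}
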