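# Fixtures built in code: tiny transcript sets with hand-checkable structure.

# A transcript tibble from explicit sequences (RNA alphabet).
tx_from_seqs <- function(seqs, eij = NULL, weights = NULL) {
  n <- length(seqs)
  tibble::tibble(
    gene_id = sprintf("t%03d", seq_len(n)),
    sequence = seqs,
    length = nchar(seqs),
    eij_positions = eij %||% rep(list(integer(0)), n),
    expression_weight = weights %||% rep(1, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Short transcripts fully covered by every read (coverage == depth), for
# calibration simulations where per-position depth must be controlled.
flat_coverage_params <- function(n_genes, tx_len, depth, efficiency = 1,
                                 seed = 1L, ...) {
  glorimap::sim_params(
    n_genes = n_genes, length_range = c(tx_len, tx_len),
    exon_count_range = c(1L, 1L), depth_mean = depth, read_length = tx_len,
    conversion_efficiency = efficiency, seed = seed, ...)
}

# Pick `k` adenosine positions per transcript (0-based, evenly spread) and
# attach the given stoichiometries (recycled).
sites_at_adenosines <- function(transcripts, k, stoich) {
  out <- purrr::pmap(
    transcripts[, c("gene_id", "sequence")],
    function(gene_id, sequence) {
      a_pos <- which(strsplit(sequence, "")[[1]] == "A") - 1L
      # keep full 13-nt contexts (no N padding at transcript ends)
      a_pos <- a_pos[a_pos >= 6L & a_pos <= nchar(sequence) - 7L]
      if (length(a_pos) < k) return(NULL)
      idx <- unique(round(seq(1, length(a_pos), length.out = k)))
      tibble::tibble(gene_id = gene_id, position = a_pos[idx])
    })
  out <- dplyr::bind_rows(out)
  out$stoichiometry <- rep_len(stoich, nrow(out))
  out$rule_class <- "plus1C"
  out
}

# Random RNA string.
random_rna <- function(n, gc = 0.32) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force Hamming scan: the definitional oracle for
# best_hamming_alignment, written as a naive per-window loop.
brute_hamming <- function(motif, sequence, max_hamming = 3) {
  m <- strsplit(chartr("Tt", "Uu", toupper(motif)), "")[[1]]
  s <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  k <- length(m)
  n <- length(s)
  if (n < k) return(NULL)
  d <- vapply(seq_len(n - k + 1L), function(i) {
    sum(s[i:(i + k - 1L)] != m)
  }, integer(1))
  best <- min(d)
  list(best_offset = which.min(d) - 1L,
       hamming_distance = best,
       ambiguous = sum(d == best) >= 2L,
       retained = sum(d == best) == 1L && best <= max_hamming)
}
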