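#' Simulate homolog sequences by per-nucleotide substitution
#'
#' Each transcript is copied with independent per-position substitutions:
#' A/U positions mutate at `sub_rate_AT`, C/G positions at `sub_rate_CG`
#' (emulating the elevated substitution rate of C/G in a low-GC genome). A
#' substituted base is replaced uniformly by one of the three other bases.
#' No indels are introduced, so homologs remain Hamming-comparable.
#'
#' Optionally, `site_offset_rates` overrides the substitution rate at fixed
#' offsets relative to planted site positions (names are offsets, e.g.
#' `c("1" = 0.3)` sets the +1 position rate), used to plant positional
#' conservation signals.
#'
#' @param transcripts tibble with `gene_id` and `sequence`.
#' @param sub_rate_AT,sub_rate_CG substitution rates in `[0, 1)` by reference
#'   base class.
#' @param seed integer seed.
#' @param species label attached to the output.
#' @param sites optional tibble with `gene_id`, `position` (required with
#'   `site_offset_rates`).
#' @param site_offset_rates optional named numeric of absolute rates at
#'   site-relative offsets.
#' @return tibble `gene_id`, `species`, `sequence`.
#' @export
simulate_homologs <- function(transcripts, sub_rate_AT = 0.05,
                              sub_rate_CG = 0.15, seed = 1L,
                              species = "homolog", sites = NULL,
                              site_offset_rates = NULL) {
  if (sub_rate_AT < 0 || sub_rate_AT >= 1 || sub_rate_CG < 0 || sub_rate_CG >= 1)
    stop("substitution rates must lie in [0, 1)", call. = FALSE)
  if (!is.null(site_offset_rates) && is.null(sites))
    stop("`site_offset_rates` requires `sites`", call. = FALSE)
  site_split <- if (!is.null(sites)) split(sites$position, sites$gene_id)
  withr::with_seed(as.integer(seed), {
    seqs <- purrr::map2_chr(transcripts$gene_id, transcripts$sequence,
                            function(gene_id, sequence) {
      v <- utf8ToInt(sequence)
      rate <- ifelse(v == .CODE_C | v == .CODE_G, sub_rate_CG, sub_rate_AT)
      if (!is.null(site_offset_rates)) {
        sp <- site_split[[gene_id]]
        if (!is.null(sp) && length(sp)) {
          for (k in seq_along(site_offset_rates)) {
            off <- as.integer(names(site_offset_rates)[k])
            idx <- sp + off + 1L            # 1-based index into v
            idx <- idx[idx >= 1L & idx <= length(v)]
            rate[idx] <- site_offset_rates[[k]]
          }
        }
      }
      hit <- which(runif(length(v)) < rate)
      if (length(hit)) {
        codes <- utf8ToInt(paste(.RNA_BASES, collapse = ""))
        repl <- vapply(v[hit], function(b) sample(setdiff(codes, b), 1L),
                       integer(1))
        v[hit] <- repl
      }
      intToUtf8(v)
    })
    tibble(gene_id = transcripts$gene_id, species = species, sequence = seqs)
  })
}

#' Simulate a differential-expression table with an expression-confounded
#' m6A label
#'
#' Emulates the input of the expression-matched bootstrap: log-normal
#' `baseMean`; an `has_m6a` label whose probability rises with expression
#' (the detectability confound); and a differential-expression indicator
#' whose probability also rises with expression and is shifted by `effect`
#' for m6A genes after conditioning on expression. `padj` is drawn below
#' `alpha` for DE genes and above otherwise; a small fraction of lowly
#' expressed genes has missing `padj` (NA).
#'
#' @param n_genes number of genes.
#' @param frac_m6a target overall fraction of m6A-labelled genes, in (0, 1).
#' @param effect additive shift in conditional DE probability for m6A genes.
#' @param seed integer seed.
#' @param alpha DE threshold used to place `padj` values.
#' @param na_frac fraction of genes with missing `padj`.
#' @return tibble `gene`, `baseMean`, `log2FoldChange`, `padj`, `has_m6a`,
#'   `de_true`.
#' @export
simulate_de_table <- function(n_genes = 5000, frac_m6a = 0.3, effect = 0,
                              seed = 1L, alpha = 0.05, na_frac = 0.02) {
  if (frac_m6a <= 0 || frac_m6a >= 1)
    stop("`frac_m6a` must lie in (0, 1)", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    base_mean <- rlnorm(n_genes, meanlog = log(500), sdlog = 1.2)
    z <- as.numeric(scale(log10(base_mean)))
    # logistic link centred so the marginal m6A fraction ~ frac_m6a
    p_m6a <- stats::plogis(stats::qlogis(frac_m6a) + 1.2 * z)
    has_m6a <- runif(n_genes) < p_m6a
    p_de <- pmin(pmax(stats::plogis(-1.6 + 0.5 * z) + effect * has_m6a, 0), 1)
    de <- runif(n_genes) < p_de
    padj <- ifelse(de, runif(n_genes, 0, alpha * 0.99),
                   runif(n_genes, alpha * 1.01, 1))
    miss <- order(base_mean)[seq_len(round(na_frac * n_genes))]
    padj[miss] <- NA_real_
    lfc <- ifelse(de, sample(c(-1, 1), n_genes, replace = TRUE) *
                    rnorm(n_genes, 1.5, 0.5),
                  rnorm(n_genes, 0, 0.2))
    tibble(gene = sprintf("gene%05d", seq_len(n_genes)),
           baseMean = base_mean, log2FoldChange = lfc, padj = padj,
           has_m6a = has_m6a, de_true = de)
  })
}

#' Simulate a gene universe with two overlapping labelled sets
#'
#' Draws two gene sets of the given sizes sharing exactly `overlap` members,
#' for exercising the Jaccard permutation and hypergeometric tests.
#'
#' @param universe_size size of the gene universe.
#' @param set_sizes integer pair of set sizes.
#' @param overlap exact number of shared members.
#' @param seed integer seed.
#' @return list with `universe`, `set_a`, `set_b` (character vectors).
#' @export
simulate_coexpression_sets <- function(universe_size, set_sizes, overlap,
                                       seed = 1L) {
  stopifnot(length(set_sizes) == 2)
  if (overlap > min(set_sizes))
    stop("`overlap` cannot exceed the smaller set size", call. = FALSE)
  if (sum(set_sizes) - overlap > universe_size)
    stop("sets of the requested sizes and overlap do not fit the universe",
         call. = FALSE)
  withr::with_seed(as.integer(seed), {
    universe <- sprintf("u%05d", seq_len(universe_size))
    pool <- sample(universe, sum(set_sizes) - overlap)
    shared <- pool[seq_len(overlap)]
    rest <- setdiff(pool, shared)
    a_only <- rest[seq_len(set_sizes[1] - overlap)]
    b_only <- setdiff(rest, a_only)
    list(universe = universe,
         set_a = c(shared, a_only),
         set_b = c(shared, b_only))
  })
}
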