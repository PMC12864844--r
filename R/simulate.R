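#' Simulate a low-GC transcriptome with exon junctions
#'
#' Draws `n_genes` transcripts with i.i.d. bases at the requested GC content,
#' uniform lengths within `length_range`, exon counts within
#' `exon_count_range` (junction positions uniform strictly inside the
#' transcript), and log-normal expression weights. Coordinates are 0-based
#' transcript space throughout; `eij_positions[j]` marks the junction between
#' positions `j - 1` and `j`.
#'
#' @param params a [sim_params()] object.
#' @return tibble with columns `gene_id`, `sequence` (RNA alphabet), `length`,
#'   `eij_positions` (list of sorted integer vectors) and `expression_weight`.
#' @examples
#' tx <- simulate_transcriptome(sim_params(n_genes = 5, seed = 1))
#' tx$length
#' @export
simulate_transcriptome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  # sample() from an explicit vector; a scalar x would mean sample(1:x)
  sample_range <- function(range, n) {
    if (range[1] == range[2]) rep(range[1], n)
    else sample(seq.int(range[1], range[2]), n, replace = TRUE)
  }
  withr::with_seed(params$seed, {
    lens <- sample_range(params$length_range, params$n_genes)
    gc <- params$gc_content
    base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(.RNA_BASES, L, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
    exon_n <- sample_range(params$exon_count_range, params$n_genes)
    eijs <- lapply(seq_len(params$n_genes), function(i) {
      k <- exon_n[i] - 1L
      if (k == 0L || lens[i] < 2L) return(integer(0))
      sort(sample(seq_len(lens[i] - 1L), min(k, lens[i] - 1L)))
    })
    weights <- rlnorm(params$n_genes, meanlog = 0, sdlog = 0.8)
    tibble(
      gene_id = sprintf("g%04d", seq_len(params$n_genes)),
      sequence = seqs,
      length = as.integer(lens),
      eij_positions = eijs,
      expression_weight = weights
    )
  })
}

#' Plant m6A sites according to the sequence and topology rules
#'
#' Eligible adenosines are those followed by C at +1 (class `plus1C`,
#' stoichiometry drawn from `stoich_high`) or by U at +1 together with U at +4
#' (class `plus1U_plus4U`, stoichiometry from `stoich_mid`). Candidates within
#' `eij_exclusion_nt` of an exon-intron junction are suppressed, and the
#' per-candidate placement probability rises toward the 3' end as
#' `site_prob * (pos/length)^three_prime_bias`. Sites are assigned
#' independently of one another.
#'
#' @param transcripts output of [simulate_transcriptome()].
#' @param params a [sim_params()] object.
#' @param include_suppressed also return selected candidates that fall inside
#'   the EIJ exclusion zone, flagged `suppressed = TRUE` with stoichiometry 0.
#'   These are the sequence-compatible but unmethylated positions used as
#'   negative examples by the context model.
#' @return tibble with `gene_id`, `position` (0-based, always an A),
#'   `rule_class`, `stoichiometry`, `eij_distance` and `suppressed`.
#' @export
plant_m6a_sites <- function(transcripts, params, include_suppressed = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed + 1L, {
    out <- purrr::pmap(
      list(transcripts$gene_id, transcripts$sequence, transcripts$length,
           transcripts$eij_positions),
      function(gene_id, sequence, tx_len, eij_positions) {
        v <- utf8ToInt(sequence)
        pos <- seq_len(tx_len) - 1L          # 0-based
        plus1 <- c(v[-1L], NA)
        plus4 <- c(v[-(1:4)], rep(NA, 4L))
        is_c <- v == .CODE_A & !is.na(plus1) & plus1 == .CODE_C
        is_u <- v == .CODE_A & !is.na(plus1) & plus1 == .CODE_U &
          !is.na(plus4) & plus4 == .CODE_U
        cand <- which(is_c | is_u)
        if (!length(cand)) return(NULL)
        p0 <- pos[cand]
        prob <- params$site_prob * ((p0 + 1) / tx_len)^params$three_prime_bias
        keep <- runif(length(cand)) < prob
        if (!any(keep)) return(NULL)
        p0 <- p0[keep]
        cls <- ifelse(is_c[cand][keep], "plus1C", "plus1U_plus4U")
        d <- eij_dist_scalar(p0, eij_positions)
        suppressed <- !is.na(d) & d < params$eij_exclusion_nt
        stoich <- ifelse(cls == "plus1C",
                         rbeta(length(p0), params$stoich_high[1], params$stoich_high[2]),
                         rbeta(length(p0), params$stoich_mid[1], params$stoich_mid[2]))
        stoich[suppressed] <- 0
        tibble(gene_id = gene_id, position = as.integer(p0), rule_class = cls,
               stoichiometry = stoich, eij_distance = d,
               suppressed = suppressed)
      })
    sites <- dplyr::bind_rows(out)
    if (!nrow(sites)) {
      sites <- tibble(gene_id = character(), position = integer(),
                      rule_class = character(), stoichiometry = double(),
                      eij_distance = double(), suppressed = logical())
    }
    if (!include_suppressed) sites <- dplyr::filter(sites, !.data$suppressed)
    sites
  })
}

# Min distance from each 0-based position to the nearest junction; NA if none.
eij_dist_scalar <- function(pos, eij_positions) {
  if (!length(eij_positions)) return(rep(NA_real_, length(pos)))
  vapply(pos, function(p) min(abs(p - eij_positions)), numeric(1))
}

#' Simulate GLORI-treated and untreated reads
#'
#' Reads are drawn per sample and transcript (depth Poisson with mean
#' proportional to the gene's expression weight), with uniform start
#' positions. In treated samples each molecule is methylated at each planted
#' site independently with probability `stoichiometry * stoich_scale`;
#' methylated adenosines stay A while every unmethylated A is read as G with
#' probability `conversion_efficiency` (inosine sequences as G). Untreated
#' samples emit reference bases. With `coupling = TRUE` the methylation events
#' of all sites on one molecule share a single latent uniform (comonotone
#' coupling), the positive control for the single-molecule linkage test.
#'
#' @param transcripts output of [simulate_transcriptome()].
#' @param sites output of [plant_m6a_sites()] (suppressed rows allowed; their
#'   stoichiometry is 0).
#' @param params a [sim_params()] object.
#' @param samples tibble describing the libraries with columns `sample_id`,
#'   `condition`, `treated` (logical) and `stoich_scale`. Default: three
#'   treated control replicates plus one untreated input library.
#' @param coupling share one methylation latent per molecule (see above).
#' @return tibble of reads: `gene_id`, `start` (0-based), `seq`, `sample_id`,
#'   `condition`, `treated`, `molecule_id`.
#' @export
simulate_glori_reads <- function(transcripts, sites, params,
                                 samples = NULL, coupling = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  if (is.null(samples)) {
    samples <- tibble(
      sample_id = c("control_1", "control_2", "control_3", "input_1"),
      condition = c("control", "control", "control", "input"),
      treated = c(TRUE, TRUE, TRUE, FALSE),
      stoich_scale = 1
    )
  }
  check_sites_consistent(transcripts, sites)
  site_split <- split(sites[, c("position", "stoichiometry")], sites$gene_id)
  mean_w <- mean(transcripts$expression_weight)

  withr::with_seed(params$seed + 2L, {
    per_sample <- purrr::pmap(samples, function(sample_id, condition, treated,
                                                stoich_scale) {
      recs <- purrr::pmap(
        list(transcripts$gene_id, transcripts$sequence, transcripts$length,
             transcripts$expression_weight),
        function(gene_id, sequence, tx_len, expression_weight) {
          L <- min(params$read_length, tx_len)
          n <- rpois(1L, params$depth_mean * expression_weight / mean_w)
          if (n == 0L) return(NULL)
          starts <- sample.int(tx_len - L + 1L, n, replace = TRUE) - 1L
          refv <- utf8ToInt(sequence)
          # long-form (read, position) expansion
          posl <- rep(starts, each = L) + rep.int(seq_len(L) - 1L, n)
          base <- refv[posl + 1L]
          if (treated) {
            st <- site_split[[gene_id]]
            meth <- rep(FALSE, length(base))
            if (!is.null(st) && nrow(st)) {
              hit <- match(posl, st$position)
              ih <- which(!is.na(hit))
              if (length(ih)) {
                s <- pmin(1, st$stoichiometry[hit[ih]] * stoich_scale)
                if (coupling) {
                  u <- runif(n)[rep(seq_len(n), each = L)][ih]
                  meth[ih] <- u < s
                } else {
                  meth[ih] <- runif(length(ih)) < s
                }
              }
            }
            convert <- base == .CODE_A & !meth &
              runif(length(base)) < params$conversion_efficiency
            base[convert] <- .CODE_G
          }
          all_seq <- intToUtf8(base)
          seqs <- substring(all_seq, seq(1L, by = L, length.out = n),
                            seq(L, by = L, length.out = n))
          tibble(gene_id = gene_id, start = starts, seq = seqs)
        })
      recs <- dplyr::bind_rows(recs)
      if (!nrow(recs)) return(NULL)
      recs$sample_id <- sample_id
      recs$condition <- condition
      recs$treated <- treated
      recs$molecule_id <- sprintf("%s_m%07d", sample_id, seq_len(nrow(recs)))
      recs
    })
    dplyr::bind_rows(per_sample)
  })
}

check_sites_consistent <- function(transcripts, sites) {
  if (!nrow(sites)) return(invisible(TRUE))
  idx <- match(sites$gene_id, transcripts$gene_id)
  if (anyNA(idx))
    stop("sites reference unknown gene_id(s)", call. = FALSE)
  ref <- substr(transcripts$sequence[idx], sites$position + 1L,
                sites$position + 1L)
  if (any(ref != "A"))
    stop("site position is not an adenosine in its transcript", call. = FALSE)
  invisible(TRUE)
}
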