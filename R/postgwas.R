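# Locus-level post-processing: distance clumping around lead SNPs,
# novel-locus calls against the original traits, per-locus trait counts and
# locus overlap matrices. Positions are 1-based and intervals inclusive.

#' Distance-based clumping of a GWAS into independent loci
#'
#' Greedy: repeatedly take the smallest-p SNP below `p_threshold` not yet
#' covered by a locus, emit a locus spanning `window_bp` either side of it,
#' and remove all SNPs within that window on the same chromosome. Ties on p
#' break by (chr, pos) ascending; output is ordered by (chr, lead position).
#'
#' @param stats Summary-statistics tibble with `rsid`, `chr`, `pos`, `p`.
#' @param p_threshold Genome-wide significance level (default 5e-8).
#' @param window_bp Half-width of a locus around its lead SNP
#'   (default 500 kb).
#' @return Tibble of loci: `rsid, chr, pos, start, end, p` (possibly empty).
#' @export
clump_loci <- function(stats, p_threshold = 5e-8, window_bp = 500000) {
  d <- dplyr::arrange(
    dplyr::filter(stats, .data$p < p_threshold),
    .data$p, .data$chr, .data$pos
  )
  leads <- list()
  while (nrow(d) > 0) {
    lead <- d[1, ]
    leads[[length(leads) + 1]] <- lead
    d <- dplyr::filter(d, .data$chr != lead$chr |
                         abs(.data$pos - lead$pos) > window_bp)
  }
  if (length(leads) == 0) {
    return(tibble::tibble(rsid = character(), chr = integer(),
                          pos = integer(), start = integer(),
                          end = integer(), p = numeric()))
  }
  out <- dplyr::bind_rows(leads)
  out <- dplyr::transmute(out,
                          rsid = .data$rsid, chr = .data$chr,
                          pos = .data$pos,
                          start = pmax(.data$pos - window_bp, 1),
                          end = .data$pos + window_bp,
                          p = .data$p)
  dplyr::arrange(out, .data$chr, .data$pos)
}

# TRUE for each row of `loci` whose lead lies inside any locus span of `other`
lead_in_spans <- function(loci, other) {
  if (nrow(other) == 0) return(rep(FALSE, nrow(loci)))
  vapply(seq_len(nrow(loci)), function(i) {
    any(other$chr == loci$chr[i] &
          other$start <= loci$pos[i] & loci$pos[i] <= other$end)
  }, logical(1))
}

#' Loci of a combined trait not explained by any original trait
#'
#' A target locus is novel when its lead SNP lies outside every locus span
#' of every original trait (spans are closed intervals; a lead exactly one
#' base beyond a span is novel).
#'
#' @param target_loci Locus tibble from [clump_loci()].
#' @param original_loci_list List of locus tibbles for the original traits.
#' @return The subset of `target_loci` that is novel.
#' @export
novel_loci <- function(target_loci, original_loci_list) {
  if (nrow(target_loci) == 0) return(target_loci)
  covered <- rep(FALSE, nrow(target_loci))
  for (orig in original_loci_list) {
    covered <- covered | lead_in_spans(target_loci, orig)
  }
  target_loci[!covered, , drop = FALSE]
}

#' Number of original traits associated with each locus
#'
#' For each locus, counts the original traits whose minimum p-value among
#' SNPs inside the locus span falls below `per_trait_p`, and pairs the count
#' with the locus lead -log10 p (for boxplot-style summaries of combined
#' traits against per-locus pleiotropy).
#'
#' @param loci Locus tibble (typically from the combined trait).
#' @param original_stats_list List of per-trait summary-statistic tibbles.
#' @param per_trait_p Per-trait significance threshold (1e-5 is a sensible
#'   default for strongly powered quantitative traits; 1e-3 for weakly
#'   powered ones).
#' @return Tibble: `rsid, chr, pos, n_traits, neg_log10_p`.
#' @export
trait_count_profile <- function(loci, original_stats_list,
                                per_trait_p = 1e-5) {
  counts <- vapply(seq_len(nrow(loci)), function(i) {
    sum(vapply(original_stats_list, function(d) {
      inside <- d$chr == loci$chr[i] &
        d$pos >= loci$start[i] & d$pos <= loci$end[i]
      any(inside) && min(d$p[inside]) < per_trait_p
    }, logical(1)))
  }, integer(1))
  tibble::tibble(
    rsid = loci$rsid, chr = loci$chr, pos = loci$pos,
    n_traits = counts,
    neg_log10_p = -log10(loci$p)
  )
}

#' Locus overlap counts between traits
#'
#' Entry (a, b) counts the loci of trait a whose lead SNP lies within any
#' locus span of trait b; the scaled matrix divides each count by the
#' smaller of the two locus-list sizes (0 when either list is empty). The
#' diagonal holds the locus counts. The count matrix need not be symmetric
#' (a's lead in b's span is not b's lead in a's span).
#'
#' @param loci_lists Named list of locus tibbles.
#' @return List with `counts` and `scaled` matrices.
#' @export
overlap_matrix <- function(loci_lists) {
  k <- length(loci_lists)
  nm <- names(loci_lists)
  counts <- matrix(0, k, k, dimnames = list(nm, nm))
  scaled <- counts
  sizes <- vapply(loci_lists, nrow, integer(1))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) {
      counts[a, b] <- sizes[a]
      scaled[a, b] <- as.numeric(sizes[a] > 0)
    } else {
      counts[a, b] <- sum(lead_in_spans(loci_lists[[a]], loci_lists[[b]]))
      denom <- min(sizes[a], sizes[b])
      scaled[a, b] <- if (denom > 0) counts[a, b] / denom else 0
    }
  }
  list(counts = counts, scaled = scaled)
}
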