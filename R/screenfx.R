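#' Flag rare OTUs by global relative abundance
#'
#' An OTU is rare when its reads divided by the grand-total reads of the
#' analysis stratum are at or below the threshold (boundary inclusive;
#' default 0.05\%). The stratum is the whole table as given — subset by
#' site first for per-site scoping (the default used by the reports).
#'
#' @param table A `read_table`.
#' @param threshold Proportion (default 5e-4).
#' @return Named logical vector over OTUs.
#' @examples
#' # 5 of 10000 reads = 0.05% -> rare (inclusive boundary)
#' @export
classify_rare <- function(table, threshold = 0.0005) {
  stopifnot(inherits(table, "read_table"))
  tot <- sum(table$counts)
  if (tot == 0) stop("empty table")
  colSums(table$counts) / tot <= threshold
}

#' Assign OTUs unique to a single design within a site
#'
#' An OTU is unique when all of its occurrences at the site fall in exactly
#' one design (any strategy rows of that design).
#'
#' @param table A `read_table`.
#' @param site Site id.
#' @return Named character vector over OTUs: the design name for unique
#'   OTUs, `NA` otherwise.
#' @export
classify_unique <- function(table, site) {
  sub <- subset_read_table(table, site = site)
  designs <- unique(sub$sample_meta$design)
  if (length(designs) < 2) stop("need >= 2 designs at site ", site)
  pres <- vapply(designs, function(d)
    colSums(sub$counts[sub$sample_meta$design == d, , drop = FALSE]) > 0,
    logical(ncol(sub$counts)))
  n_designs <- rowSums(pres)
  out <- rep(NA_character_, ncol(sub$counts))
  names(out) <- colnames(sub$counts)
  one <- n_designs == 1
  out[one] <- designs[apply(pres[one, , drop = FALSE], 1, which)]
  out
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment (via Biostrings' dynamic-programming
#' aligner) of an OTU query against a reference, returning the aligned
#' strings, the p-distance over gap-free columns, and the list of gap runs
#' (insertions or deletions) with their alignment positions.
#'
#' @param query,reference DNA sequences (character, A/C/G/T; other IUPAC
#'   letters allowed only with `iupac = TRUE`).
#' @param match,mismatch,gap_open,gap_extend Scoring (defaults 2, -3, 10, 1;
#'   gap penalties positive).
#' @param iupac Tolerate non-ACGT IUPAC symbols (default FALSE).
#' @return An object of class `aligned_pair`: list with `query_aln`,
#'   `ref_aln`, `length`, `p_distance`, `gap_runs` (data.frame: start
#'   (alignment column), length, in — "query" or "reference").
#' @examples
#' align_global("ACGT", "AGGT")$p_distance # 0.25
#' @export
align_global <- function(query, reference, match = 2, mismatch = -3,
                         gap_open = 10, gap_extend = 1, iupac = FALSE) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  ok <- if (iupac) "[ACGTRYSWKMBDHVN]+" else "[ACGT]+"
  for (s in c(query, reference))
    if (!grepl(paste0("^", ok, "$"), toupper(s)))
      stop("sequence contains symbols outside ",
           if (iupac) "IUPAC codes" else "A/C/G/T")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = !iupac)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(query)),
    Biostrings::DNAString(toupper(reference)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- as.character(Biostrings::alignedPattern(aln))
  ra <- as.character(Biostrings::alignedSubject(aln))
  qv <- strsplit(qa, "")[[1]]
  rv <- strsplit(ra, "")[[1]]
  no_gap <- qv != "-" & rv != "-"
  p_dist <- if (any(no_gap)) mean(qv[no_gap] != rv[no_gap]) else 0
  gap_runs <- rbind(run_table(qv == "-", "query"),
                    run_table(rv == "-", "reference"))
  structure(list(query_aln = qa, ref_aln = ra, length = length(qv),
                 p_distance = p_dist, gap_runs = gap_runs),
            class = "aligned_pair")
}

# runs of TRUE in a logical vector -> data.frame(start, length, in)
run_table <- function(flag, where) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep],
             `in` = rep(where, sum(keep)), check.names = FALSE,
             stringsAsFactors = FALSE)
}

# map a reference-coordinate position to its alignment column
ref_to_aln_col <- function(ref_aln_vec, pos) {
  ref_pos <- cumsum(ref_aln_vec != "-")
  idx <- which(ref_pos >= pos & ref_aln_vec != "-")
  if (!length(idx)) stop("window exceeds alignment coordinates")
  idx[1]
}

#' Screen an aligned OTU for molecular artefact signatures
#'
#' Applies the three screening rules: (i) `long_indel` — any gap run longer
#' than `long_indel_min - 1` bases (default: runs > 20 bases) anywhere in
#' the alignment; (ii) `multi_indel_window` — at least
#' `max_single_nt_indels + 1` single-nucleotide gap runs (runs of exactly
#' length 1) inside the anchored window (default: more than one in a
#' 200-base window, the region spanning the 5.8S gene and the start of
#' ITS2); (iii) `excess_divergence` — p-distance strictly greater than
#' `divergence_max` (default 2\%). An OTU is artefactual if any flag is set.
#'
#' @param pair An `aligned_pair` from [align_global()].
#' @param window_start Window start in reference coordinates (1-based).
#' @param window Window width in reference bases (default 200).
#' @param long_indel_min Minimal flagged gap-run length (default 21).
#' @param max_single_nt_indels Allowed single-base indels in the window
#'   (default 1).
#' @param divergence_max Divergence threshold, strict (default 0.02).
#' @return Named logical vector `long_indel`, `multi_indel_window`,
#'   `excess_divergence`, `artefact` (any).
#' @export
screen_artefacts <- function(pair, window_start, window = 200,
                             long_indel_min = 21, max_single_nt_indels = 1,
                             divergence_max = 0.02) {
  stopifnot(inherits(pair, "aligned_pair"))
  rv <- strsplit(pair$ref_aln, "")[[1]]
  ref_len <- sum(rv != "-")
  if (window_start < 1 || window_start + window - 1 > ref_len)
    stop("window [", window_start, ", ", window_start + window - 1,
         "] outside reference length ", ref_len)
  long_indel <- any(pair$gap_runs$length >= long_indel_min)
  col_lo <- ref_to_aln_col(rv, window_start)
  col_hi <- ref_to_aln_col(rv, window_start + window - 1)
  g <- pair$gap_runs
  in_window <- g$length == 1 & g$start >= col_lo & g$start <= col_hi
  multi_indel <- sum(in_window) > max_single_nt_indels
  excess <- pair$p_distance > divergence_max
  c(long_indel = long_indel, multi_indel_window = multi_indel,
    excess_divergence = excess,
    artefact = long_indel || multi_indel || excess)
}

#' Per-stratum accounting of artefact, rare and unique OTUs
#'
#' For each (site, strategy) stratum: OTU, artefact, rare, rare-artefact and
#' unique counts, and the proportions N(artefacts)/N(OTUs),
#' N(rare)/N(OTUs), N(rare artefacts)/N(rare). When pooling-effect results
#' are supplied, pooled strata are additionally split by PE > 1 vs PE < 1.
#' Zero denominators yield NA cells.
#'
#' @param table A `read_table`.
#' @param artefact_flags Named logical vector over OTUs (truth from the
#'   registry, or screening output); defaults to the registry's origin.
#' @param rare_threshold Passed to [classify_rare()] per site.
#' @param pe_results Optional data.frame from [pooling_effect()] rows.
#' @return data.frame, one row per stratum (and PE sign when available).
#' @export
pooling_artefact_report <- function(table, artefact_flags = NULL,
                                    rare_threshold = 0.0005,
                                    pe_results = NULL) {
  stopifnot(inherits(table, "read_table"))
  if (is.null(artefact_flags)) {
    artefact_flags <- stats::setNames(
      table$otu_registry$origin == "artefact", table$otu_registry$otu_id)
  }
  out <- list()
  for (site in unique(table$sample_meta$site)) {
    site_tab <- subset_read_table(table, site = site)
    rare <- classify_rare(site_tab, rare_threshold)
    uniq <- tryCatch(classify_unique(table, site), error = function(e) NULL)
    for (strat in unique(site_tab$sample_meta$strategy)) {
      st <- subset_read_table(site_tab, strategy = strat)
      ids <- colnames(st$counts)
      art <- artefact_flags[ids]
      rar <- rare[ids]
      n_otu <- length(ids)
      n_art <- sum(art, na.rm = TRUE)
      n_rare <- sum(rar)
      n_rare_art <- sum(art & rar, na.rm = TRUE)
      n_uniq <- if (is.null(uniq)) NA_integer_ else sum(!is.na(uniq[ids]))
      n_uniq_art <- if (is.null(uniq)) NA_integer_
                    else sum(!is.na(uniq[ids]) & art, na.rm = TRUE)
      pe_sign <- NA_character_
      if (!is.null(pe_results) && strat %in% pe_results$strategy) {
        pe <- pe_results$pe[pe_results$site == site &
                              pe_results$strategy == strat &
                              pe_results$fraction == 1]
        if (length(pe) && !all(is.na(pe)))
          pe_sign <- if (mean(pe, na.rm = TRUE) > 1) "PE>1" else "PE<1"
      }
      out[[length(out) + 1L]] <- data.frame(
        site = site, strategy = strat, pe_sign = pe_sign, n_otus = n_otu,
        n_artefacts = n_art, n_rare = n_rare, n_rare_artefacts = n_rare_art,
        n_unique = n_uniq, n_unique_artefacts = n_uniq_art,
        prop_artefact = if (n_otu > 0) n_art / n_otu else NA_real_,
        prop_rare = if (n_otu > 0) n_rare / n_otu else NA_real_,
        prop_rare_artefact = if (n_rare > 0) n_rare_art / n_rare
                             else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Generate synthetic OTU and reference sequences with planted artefacts
#'
#' Builds a FASTA-ready set for exercising the screening rules: every
#' biological OTU is a point-mutated copy of its reference (substitution
#' rate 0.5\%, well below the divergence threshold, no indels); every
#' artefact OTU gets exactly one planted signature chosen uniformly — a
#' long deletion (25 bases), a pair of single-base indels inside the
#' screening window, or excess divergence (4\% substitutions). The window
#' (the 5.8S + ITS2-start stand-in) is recorded in the reference header as
#' `window=<start>-<end>` (reference coordinates).
#'
#' @param registry OTU registry data.frame (`otu_id`, `origin`).
#' @param seed Integer seed.
#' @param ref_length Reference length in bases (default 600).
#' @param window_start,window Window anchor (defaults 150 and 200).
#' @return List with `sequences` (named character: references first, then
#'   OTUs), `truth` (data.frame otu_id, origin, planted signature,
#'   reference id), `window_start`, `window`.
#' @export
make_synthetic_alignment <- function(registry, seed = 1L, ref_length = 600,
                                     window_start = 150, window = 200) {
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(seed, "synthaln"), {
    ref <- sample(bases, ref_length, replace = TRUE)
    mutate <- function(s, k) {
      pos <- sample(length(s), k)
      for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
      s
    }
    seqs <- list()
    truth <- list()
    win_lo <- window_start; win_hi <- window_start + window - 1
    for (i in seq_len(nrow(registry))) {
      id <- registry$otu_id[i]
      if (registry$origin[i] == "biological") {
        s <- mutate(ref, max(1L, floor(0.005 * ref_length)))
        planted <- "none"
      } else {
        planted <- sample(c("long_indel", "multi_indel_window",
                            "excess_divergence"), 1)
        if (planted == "long_indel") {
          # 25-base deletion away from the ends
          at <- sample(seq(30L, ref_length - 60L), 1)
          s <- ref[-(at:(at + 24L))]
        } else if (planted == "multi_indel_window") {
          # two single-base deletions inside the window, far enough apart
          # that affine-gap alignment cannot merge them into one 2-base run
          # (merging pays ~3/4 mismatch per intervening base, so >= 12
          # bases of separation keeps two runs optimal)
          at <- sort(sample(seq(win_lo + 10L, win_hi - 10L), 2))
          while (diff(at) < 12L)
            at <- sort(sample(seq(win_lo + 10L, win_hi - 10L), 2))
          s <- ref[-at]
        } else {
          s <- mutate(ref, ceiling(0.04 * ref_length))
        }
      }
      seqs[[id]] <- paste(s, collapse = "")
      truth[[length(truth) + 1L]] <- data.frame(
        otu_id = id, origin = registry$origin[i], planted = planted,
        reference = "reference_1", stringsAsFactors = FALSE)
    }
    ref_id <- sprintf("reference_1 window=%d-%d", win_lo, win_hi)
    sequences <- c(stats::setNames(paste(ref, collapse = ""), ref_id),
                   unlist(seqs))
    list(sequences = sequences, truth = do.call(rbind, truth),
         window_start = win_lo, window = window)
  })
}

#' Write sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(unname(sequences))
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
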