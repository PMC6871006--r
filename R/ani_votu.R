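# Pairwise ANI / AF computation and species-rank vOTU clustering.
#
# Species-rank virus groups (vOTUs) are defined at >= 95% average
# nucleotide identity (ANI) over >= 85% alignment fraction (AF) relative
# to the shorter sequence. The default clustering mode follows the
# two-step rule: pairs are first gated on AF >= 85%, then whole-genome ANI
# (wgANI = ANI x AF) is compared with the derived cutoff
# 95 x 85 / 100 = 80.75%, which also admits pairs such as 90% ANI on 100%
# AF. A "plain" mode applying ANI >= 95% directly after the AF gate is
# provided as the alternative reading of the thresholds.
#
# The ANI engine is window-based (ANIb-style): the shorter genome is cut
# into non-overlapping windows, each window is mapped ungapped to the best
# location on either strand of the longer genome, windows reaching the
# minimum identity count as aligned, ANI is their length-weighted mean
# identity and AF the aligned fraction of the shorter genome.

#' Clustering parameters for vOTU assignment
#'
#' @param ani_threshold Species-rank ANI threshold in percent (default 95).
#' @param af_threshold Alignment-fraction threshold in percent, relative to
#'   the shorter genome (default 85).
#' @param mode `"wgani"` (AF gate then wgANI against the derived cutoff;
#'   default) or `"plain"` (AF gate then ANI against `ani_threshold`).
#' @param window_bp Window size for the ANI engine in bp (default 500).
#' @param min_window_identity Minimum percent identity for a window to
#'   count as aligned (default 70).
#' @return List of class `clustering_params`.
#' @examples
#' p <- clustering_params()
#' wgani_cutoff(p) # 80.75
#' @export
clustering_params <- function(ani_threshold = 95, af_threshold = 85,
                              mode = c("wgani", "plain"), window_bp = 500,
                              min_window_identity = 70) {
  mode <- match.arg(mode)
  stopifnot(ani_threshold > 0, ani_threshold <= 100,
            af_threshold > 0, af_threshold <= 100,
            window_bp >= 1, min_window_identity >= 0,
            min_window_identity <= 100)
  structure(list(ani_threshold = ani_threshold,
                 af_threshold = af_threshold, mode = mode,
                 window_bp = window_bp,
                 min_window_identity = min_window_identity),
            class = "clustering_params")
}

#' Whole-genome ANI from ANI and AF
#'
#' wgANI estimates identity over the whole length of the shorter genome by
#' multiplying the observed ANI by the observed AF.
#'
#' @param ani ANI in percent, in \[0, 100\].
#' @param af AF in percent, in \[0, 100\].
#' @return `ani * af / 100`, in percent.
#' @examples
#' wg_ani(95, 85) # 80.75
#' @export
wg_ani <- function(ani, af) {
  if (any(ani < 0 | ani > 100) || any(af < 0 | af > 100)) {
    stop("ani and af must be percentages in [0, 100]")
  }
  ani * af / 100
}

#' Derived whole-genome ANI cutoff
#'
#' The wgANI threshold applied after the AF gate: the species-rank ANI
#' threshold multiplied by the AF threshold. At the defaults (95% ANI,
#' 85% AF) this is 80.75%.
#'
#' @param params [clustering_params()].
#' @return Cutoff in percent.
#' @export
wgani_cutoff <- function(params = clustering_params()) {
  wg_ani(params$ani_threshold, params$af_threshold)
}

# cut a sequence into non-overlapping windows; a trailing remainder
# < 100 bp is merged into the previous window so identical genomes reach
# AF = 100 regardless of divisibility; sequences shorter than one window
# form a single whole-sequence window.
cut_windows <- function(sequence, window_bp) {
  L <- nchar(sequence)
  if (L <= window_bp) {
    return(sequence)
  }
  starts <- seq(1L, L, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, L)
  k <- length(starts)
  if (k > 1 && (ends[k] - starts[k] + 1L) < 100) {
    ends[k - 1] <- ends[k]
    starts <- starts[-k]
    ends <- ends[-k]
  }
  substring(sequence, starts, ends)
}

#' Pairwise ANI and alignment fraction of two genomes
#'
#' Cuts the shorter genome into windows of `window_bp`, maps each window
#' to its best ungapped hit on either strand of the longer genome, and
#' summarizes: ANI is the length-weighted mean identity of windows whose
#' best hit reaches `min_window_identity`; AF is the summed length of
#' those windows as a percent of the shorter genome. The result is
#' symmetric in the pair -- AF is always relative to the shorter member
#' (ties on length broken by lexicographic id, then argument order).
#'
#' @param a,b Sequences (single strings) or one-row `contig_set`s.
#' @param params [clustering_params()].
#' @param id_a,id_b Optional genome identifiers.
#' @return One-row data.frame of class `pairwise_comparison`: `query_id`
#'   (shorter), `target_id`, `ani`, `af`, `wg_ani`, `passes`.
#' @examples
#' g <- strrep("ACGTTGCA", 1250)
#' compute_ani_af(g, g)[, c("ani", "af")]
#' @export
compute_ani_af <- function(a, b, params = clustering_params(),
                           id_a = "a", id_b = "b") {
  if (is.data.frame(a)) { id_a <- a$id[1]; a <- a$sequence[1] }
  if (is.data.frame(b)) { id_b <- b$id[1]; b <- b$sequence[1] }
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0) {
    stop("empty sequence")
  }
  swap <- nchar(a) > nchar(b) ||
    (nchar(a) == nchar(b) && id_b < id_a)
  if (swap) {
    tmp <- a; a <- b; b <- tmp
    tmpi <- id_a; id_a <- id_b; id_b <- tmpi
  }
  windows <- cut_windows(a, params$window_bp)
  hits <- cpp_map_windows(windows, b, params$min_window_identity)
  aligned <- hits[hits$aligned, , drop = FALSE]
  if (nrow(aligned) == 0) {
    ani <- 0
    af <- 0
  } else {
    ani <- sum(aligned$identity * aligned$window_length) /
      sum(aligned$window_length)
    af <- 100 * sum(aligned$window_length) / nchar(a)
  }
  out <- data.frame(query_id = id_a, target_id = id_b, ani = ani, af = af,
                    wg_ani = wg_ani(ani, af), stringsAsFactors = FALSE)
  out$passes <- passes_votu_cutoff(out, params)
  class(out) <- c("pairwise_comparison", "data.frame")
  out
}

#' Does a genome pair pass the species-rank (vOTU) cutoff?
#'
#' In `wgani` mode a pair passes when AF is at least the AF threshold and
#' wgANI is at least the derived cutoff ([wgani_cutoff()]); in `plain`
#' mode when AF is at least the AF threshold and ANI at least the ANI
#' threshold. Every pair passing in plain mode also passes in wgani mode.
#'
#' @param pair One-row data.frame with `ani`, `af` (and `wg_ani`,
#'   recomputed if absent), or a `pairwise_comparison`.
#' @param params [clustering_params()].
#' @return Logical.
#' @examples
#' passes_votu_cutoff(data.frame(ani = 90, af = 100)) # TRUE
#' @export
passes_votu_cutoff <- function(pair, params = clustering_params()) {
  ani <- pair$ani
  af <- pair$af
  wg <- if (!is.null(pair$wg_ani)) pair$wg_ani else wg_ani(ani, af)
  if (params$mode == "wgani") {
    af >= params$af_threshold & wg >= wgani_cutoff(params)
  } else {
    af >= params$af_threshold & ani >= params$ani_threshold
  }
}

#' All pairwise comparisons of a genome set
#'
#' Computes every unordered pair. Optionally restricts the report to the
#' conventional window of informative pairs (ANI > 60% and AF > 20%).
#'
#' @param genomes Named character vector of sequences, `contig_set`, or
#'   `uvig_set` (each UViG's contigs concatenated in input order).
#' @param params [clustering_params()].
#' @param filter_report If TRUE, drop pairs with ANI <= `min_report_ani`
#'   or AF <= `min_report_af`.
#' @param min_report_ani,min_report_af Reporting window bounds (60, 20).
#' @return Data.frame with one row per retained pair.
#' @export
pairwise_matrix <- function(genomes, params = clustering_params(),
                            filter_report = FALSE, min_report_ani = 60,
                            min_report_af = 20) {
  seqs <- as_genome_vector(genomes)
  if (length(seqs) < 2) stop("need at least 2 genomes")
  ids <- names(seqs)
  pairs <- utils::combn(length(seqs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    compute_ani_af(seqs[[i]], seqs[[j]], params, ids[i], ids[j])
  })
  out <- do.call(rbind, rows)
  class(out) <- "data.frame"
  if (filter_report) {
    out <- out[out$ani > min_report_ani & out$af > min_report_af, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# coerce supported genome containers to a named character vector
as_genome_vector <- function(genomes) {
  if (inherits(genomes, "uvig_set")) {
    seqs <- vapply(genomes, function(u) paste(u$contigs$sequence,
                                              collapse = ""), character(1))
    names(seqs) <- vapply(genomes, `[[`, character(1), "uvig_id")
    return(seqs)
  }
  if (is.data.frame(genomes)) {
    return(setNames(genomes$sequence, genomes$id))
  }
  if (is.null(names(genomes)) || any(names(genomes) == "")) {
    names(genomes) <- paste0("g", seq_along(genomes))
  }
  genomes
}

#' Greedy clustering of genomes into vOTUs
#'
#' Genomes are sorted by length, longest first (ties broken by
#' lexicographic id), and processed in that order: each genome joins the
#' first existing cluster whose representative it passes the species
#' cutoff with, otherwise it founds a new cluster and becomes its
#' representative. The representative is therefore always the longest
#' member, a proxy for the most complete genome. Sorting plus the tie rule
#' make the outcome independent of input order.
#'
#' Genomes shorter than `min_length_warn` (default 10 kb) trigger a
#' warning: short fragments are unreliable for species-rank clustering
#' and their assignments are approximations.
#'
#' @param genomes As in [pairwise_matrix()]; at least one genome.
#' @param params [clustering_params()].
#' @param min_length_warn Warn when any genome is shorter than this
#'   (default 10000 bp); set to 0 to silence.
#' @return List of class `votu_clustering`: `clusters` (data.frame
#'   `cluster_id`, `representative_id`, `n_members`), `assignment`
#'   (data.frame `genome_id`, `cluster_id`, `representative_id`,
#'   `is_representative`), `params`.
#' @export
cluster_votus <- function(genomes, params = clustering_params(),
                          min_length_warn = 10000) {
  seqs <- as_genome_vector(genomes)
  if (length(seqs) < 1) stop("need at least 1 genome")
  lens <- nchar(seqs)
  if (min_length_warn > 0 && any(lens < min_length_warn)) {
    warning(sum(lens < min_length_warn),
            " genome(s) shorter than ", min_length_warn,
            " bp; species-rank clustering of short fragments is only an",
            " approximation", call. = FALSE)
  }
  ord <- order(-lens, names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  assignment <- integer(length(seqs))
  names(assignment) <- names(seqs)
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      cmp <- compute_ani_af(seqs[[i]], seqs[[reps[k]]], params,
                            names(seqs)[i], reps[k])
      if (cmp$passes) {
        assignment[i] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(seqs)[i])
      assignment[i] <- length(reps)
    }
  }
  clusters <- data.frame(
    cluster_id = seq_along(reps), representative_id = reps,
    n_members = as.integer(tabulate(assignment, nbins = length(reps))),
    stringsAsFactors = FALSE)
  assign_df <- data.frame(
    genome_id = names(assignment), cluster_id = unname(assignment),
    representative_id = reps[assignment],
    is_representative = names(assignment) == reps[assignment],
    stringsAsFactors = FALSE)
  rownames(assign_df) <- NULL
  structure(list(clusters = clusters, assignment = assign_df,
                 params = params),
            class = "votu_clustering")
}

#' @export
print.votu_clustering <- function(x, ...) {
  cat(sprintf(
    "<votu_clustering: %d genome(s) in %d vOTU(s) at ANI %g%% / AF %g%% (%s mode)>\n",
    nrow(x$assignment), nrow(x$clusters), x$params$ani_threshold,
    x$params$af_threshold, x$params$mode))
  invisible(x)
}
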