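# Completeness estimation and assembly-quality tiers.
#
# Completeness of a UViG is estimated either from sequence-level evidence
# (a direct or inverted terminal repeat, or a resolved provirus integration
# site, any of which marks the genome "predicted complete") or, for linear
# contigs with a taxonomic assignment, by comparison with reference genome
# lengths: genome length is relatively homogeneous (within about +/-10%)
# at the (sub)family/genus ranks, so the mean reference length of the
# assigned taxon serves as the expected genome size. Each genome is then
# placed in exactly one of three tiers: genome fragment(s), high-quality
# draft genome, or finished.

#' Read a reference genome-length table
#' @param path TSV with columns taxon, rank, length_bp (header optional but
#'   expected).
#' @return Data.frame with columns `taxon`, `rank`, `length_bp`.
#' @export
read_reference_lengths <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("taxon", "rank", "length_bp")
  if (!all(need %in% names(df))) {
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  }
  df$length_bp <- as.numeric(df$length_bp)
  if (any(is.na(df$length_bp) | df$length_bp <= 0)) {
    stop("reference lengths must be positive numbers")
  }
  df[need]
}

#' Expected genome length for a taxon
#'
#' Mean reference genome length of the taxon's members, with the
#' coefficient of variation (CV = standard deviation of group lengths
#' divided by their mean, computed only for groups with more than one
#' genome). A CV above 0.10 flags a group whose lengths are too
#' heterogeneous for a reliable completeness estimate.
#'
#' @param taxon Taxon name to look up.
#' @param table Reference table (see [read_reference_lengths()]).
#' @param cv_warn CV threshold for the homogeneity flag (default 0.10).
#' @return List: `taxon`, `n`, `mean_length`, `cv` (NA when n < 2),
#'   `homogeneity_warning`.
#' @examples
#' tab <- data.frame(taxon = "T", rank = "genus", length_bp = c(4e4, 6e4))
#' expected_length("T", tab)
#' @export
expected_length <- function(taxon, table, cv_warn = 0.10) {
  lens <- table$length_bp[table$taxon == taxon]
  if (length(lens) == 0) {
    return(list(taxon = taxon, n = 0L, mean_length = NA_real_, cv = NA_real_,
                homogeneity_warning = FALSE))
  }
  m <- mean(lens)
  cv <- if (length(lens) >= 2) sd(lens) / m else NA_real_
  list(taxon = taxon, n = length(lens), mean_length = m, cv = cv,
       homogeneity_warning = !is.na(cv) && cv > cv_warn)
}

#' Per-taxon genome-length statistics
#'
#' Summarizes a reference length table: member count, mean length, and CV
#' per taxon (CV only for taxa with at least two genomes), flagging taxa
#' whose length variation exceeds `cv_warn`.
#'
#' @inheritParams expected_length
#' @return Data.frame: `taxon`, `rank`, `n`, `mean_length`, `cv`,
#'   `flagged`.
#' @export
length_cv_report <- function(table, cv_warn = 0.10) {
  taxa <- unique(table$taxon)
  rows <- lapply(taxa, function(tx) {
    e <- expected_length(tx, table, cv_warn)
    data.frame(taxon = tx, rank = table$rank[match(tx, table$taxon)],
               n = e$n, mean_length = e$mean_length, cv = e$cv,
               flagged = e$homogeneity_warning, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate completeness of a UViG
#'
#' Evidence is used in order of directness: a DTR on a single-contig UViG,
#' then an ITR, then a resolved integration site flagged in the metadata,
#' then comparison of the summed contig length with the expected genome
#' length of the assigned taxon. The first three mark the genome
#' "predicted complete" without a percentage; the reference route yields
#' completeness_pct = 100 * observed / expected. With no usable evidence
#' the method is "none" and completeness stays undetermined.
#'
#' For segmented genomes the expected length applies per segment only when
#' the reference table carries segment-level rows; otherwise a note is
#' attached, as reference-based estimates are unreliable across segments.
#'
#' @param uvig A `uvig` record (see [group_contigs_to_uvigs()]).
#' @param termini Optional data.frame from [detect_termini()] for the
#'   UViG's contigs.
#' @param taxon Optional taxon name for the reference route.
#' @param table Optional reference table ([read_reference_lengths()]).
#' @param integration_site Logical; TRUE when provirus boundaries are
#'   resolved in the host context.
#' @return List of class `completeness_estimate`: `uvig_id`, `method`
#'   (dtr/itr/integration_site/reference_length/none), `expected_length`,
#'   `observed_length`, `completeness_pct`, `predicted_complete`,
#'   `homogeneity_warning`, `notes`.
#' @export
estimate_completeness <- function(uvig, termini = NULL, taxon = NULL,
                                  table = NULL, integration_site = FALSE) {
  observed <- uvig$total_length
  notes <- character(0)
  method <- "none"
  expected <- NA_real_
  pct <- NA_real_
  homog <- FALSE

  single <- nrow(uvig$contigs) == 1
  if (single && !is.null(termini)) {
    trow <- termini[termini$contig_id %in% uvig$contigs$id, , drop = FALSE]
    if (nrow(trow) >= 1) {
      if (any(trow$dtr_found)) {
        method <- "dtr"
      } else if (any(trow$itr_found)) {
        method <- "itr"
      }
    }
  }
  if (method == "none" && isTRUE(integration_site)) {
    method <- "integration_site"
  }
  if (method == "none" && !is.null(taxon) && !is.null(table)) {
    e <- expected_length(taxon, table)
    if (e$n >= 1) {
      method <- "reference_length"
      expected <- e$mean_length
      pct <- 100 * observed / expected
      homog <- e$homogeneity_warning
      if (homog) {
        notes <- c(notes, sprintf(
          "reference taxon '%s' length CV %.3f > 0.10; estimate unreliable",
          taxon, e$cv))
      }
      structure_term <- uvig$metadata$predicted_genome_structure
      if (identical(structure_term, "segmented") &&
          !any(grepl("segment", table$rank[table$taxon == taxon],
                     ignore.case = TRUE))) {
        notes <- c(notes, paste("segmented genome without segment-level",
                                "reference rows; expected length may span",
                                "multiple segments"))
      }
    } else {
      notes <- c(notes, sprintf("taxon '%s' absent from reference table",
                                taxon))
    }
  }
  structure(
    list(uvig_id = uvig$uvig_id, method = method,
         expected_length = expected, observed_length = observed,
         completeness_pct = pct,
         predicted_complete = method %in% c("dtr", "itr",
                                            "integration_site"),
         homogeneity_warning = homog, notes = notes),
    class = "completeness_estimate"
  )
}

#' @export
print.completeness_estimate <- function(x, ...) {
  cat(sprintf("<completeness %s: method=%s, observed=%s bp%s%s>\n",
              x$uvig_id, x$method, format(x$observed_length, big.mark = ","),
              if (!is.na(x$completeness_pct))
                sprintf(", %.1f%% of %s bp", x$completeness_pct,
                        format(x$expected_length, big.mark = ",")) else "",
              if (x$predicted_complete) ", predicted complete" else ""))
  invisible(x)
}

# longest run of N in a sequence
max_n_run <- function(sequence) {
  runs <- gregexpr("N+", sequence)[[1]]
  if (runs[1] == -1) 0L else max(attr(runs, "match.length"))
}

#' Default curation flags for tier assignment
#' @param manually_curated Extensive manual review and editing performed.
#' @param functions_annotated Putative gene functions annotated.
#' @param transcriptional_units_annotated Transcriptional units annotated.
#' @param gaps_in_repeats_only Any assembly gaps span (mostly) repetitive
#'   regions.
#' @return Named list of logical flags.
#' @export
curation_flags <- function(manually_curated = FALSE,
                           functions_annotated = FALSE,
                           transcriptional_units_annotated = FALSE,
                           gaps_in_repeats_only = FALSE) {
  list(manually_curated = manually_curated,
       functions_annotated = functions_annotated,
       transcriptional_units_annotated = transcriptional_units_annotated,
       gaps_in_repeats_only = gaps_in_repeats_only)
}

#' Assign the assembly-quality tier of a UViG
#'
#' Applies the three-tier scheme. "finished": a single contiguous sequence
#' per replicon without gaps or ambiguities (no run of 10+ Ns), complete
#' (predicted complete or 100% of the expected length), with extensive
#' manual review -- all three curation flags set. "high-quality draft
#' genome": predicted complete or completeness >= 90% of the expected
#' genome; UViGs derived from a single read rather than a consensus
#' assembly (i.e. `read_quality_phred` recorded) additionally need mean
#' phred > 20, i.e. >99% average base-call accuracy. Everything else --
#' including genomes whose size could not be estimated -- is "genome
#' fragment(s)". The returned rationale lists every rule that fired.
#'
#' @param uvig A `uvig` record.
#' @param completeness A `completeness_estimate` for the UViG.
#' @param flags Curation flags ([curation_flags()]).
#' @return List of class `quality_tier`: `uvig_id`, `tier` (one of
#'   "genome_fragment", "high_quality_draft", "finished"), `rationale`.
#' @examples
#' uv <- group_contigs_to_uvigs(contig_set("c", strrep("ACGT", 500)))[[1]]
#' cmp <- estimate_completeness(uv, taxon = "T",
#'   table = data.frame(taxon = "T", rank = "genus", length_bp = 2100))
#' classify_quality(uv, cmp)
#' @export
classify_quality <- function(uvig, completeness, flags = curation_flags()) {
  rationale <- character(0)
  pct <- completeness$completeness_pct
  has_pct <- !is.null(pct) && !is.na(pct)
  complete <- isTRUE(completeness$predicted_complete) ||
    (has_pct && pct >= 100)
  hq <- isTRUE(completeness$predicted_complete) || (has_pct && pct >= 90)

  if (isTRUE(completeness$predicted_complete)) {
    rationale <- c(rationale, sprintf("predicted complete (%s evidence)",
                                      completeness$method))
  } else if (has_pct) {
    rationale <- c(rationale,
                   sprintf("completeness %.1f%% of expected genome", pct))
  } else {
    rationale <- c(rationale, "no genome size could be estimated")
  }

  single <- nrow(uvig$contigs) == 1
  n_run <- max(vapply(uvig$contigs$sequence, max_n_run, integer(1)))
  gapless <- n_run < 10
  curated <- isTRUE(flags$manually_curated) &&
    isTRUE(flags$functions_annotated) &&
    isTRUE(flags$transcriptional_units_annotated)

  phred <- uvig$read_quality_phred
  phred_ok <- TRUE
  if (!is.null(phred) && !is.na(suppressWarnings(as.numeric(phred)))) {
    phred_ok <- as.numeric(phred) > 20
    rationale <- c(rationale, sprintf(
      "single-read UViG: mean phred %.1f %s the >20 (>99%% accuracy) rule",
      as.numeric(phred), if (phred_ok) "satisfies" else "fails"))
  }

  tier <- "genome_fragment"
  if (complete && single && gapless && curated && phred_ok) {
    tier <- "finished"
    rationale <- c(rationale,
                   paste("single contiguous sequence, no gaps or",
                         "ambiguities, complete, extensively curated"))
  } else if (hq && phred_ok) {
    tier <- "high_quality_draft"
    if (!curated && complete) {
      rationale <- c(rationale, "complete but lacking curation flags")
    }
    if (complete && !single) {
      rationale <- c(rationale, "multiple contigs preclude finished")
    }
    if (complete && !gapless) {
      rationale <- c(rationale, sprintf(
        "ambiguity run of %d N(s) counts as a gap, precluding finished",
        n_run))
    }
  }
  structure(list(uvig_id = uvig$uvig_id, tier = tier,
                 rationale = rationale),
            class = "quality_tier")
}

#' @export
print.quality_tier <- function(x, ...) {
  cat(sprintf("<quality_tier %s: %s>\n", x$uvig_id, x$tier))
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Convert a phred score to mean base-call accuracy
#' @param phred Phred quality score(s), `-10 log10` of the per-base error
#'   probability.
#' @return Percent accuracy, `100 * (1 - 10^(-phred/10))`.
#' @examples
#' phred_to_accuracy(20) # 99
#' @export
phred_to_accuracy <- function(phred) {
  if (any(phred < 0)) stop("phred scores must be >= 0")
  100 * (1 - 10^(-phred / 10))
}

#' Plausibility of a circular-contig completeness call
#'
#' Partial genomes are sometimes misassembled as circular contigs because
#' of repeats, so a DTR alone can mislabel a fragment as complete. When an
#' expected genome length is available for the assigned taxon, a circular
#' contig much shorter than that expectation (below
#' `plausibility_fraction` of it, default 0.5) is flagged implausible and
#' should be manually validated against reference genomes. Without a
#' reference expectation the call is unverifiable and passes by default.
#' The flag is advisory: it never changes the quality tier by itself.
#'
#' @param contig_length Length of the DTR-bearing contig in bp.
#' @param taxon Optional taxon name.
#' @param table Optional reference length table.
#' @param plausibility_fraction Minimum fraction of the expected length
#'   (default 0.5).
#' @return List: `plausible` (logical), `note`.
#' @export
circular_plausibility <- function(contig_length, taxon = NULL, table = NULL,
                                  plausibility_fraction = 0.5) {
  if (is.null(taxon) || is.null(table)) {
    return(list(plausible = TRUE,
                note = "no reference expectation; circularity unverifiable"))
  }
  e <- expected_length(taxon, table)
  if (e$n < 1) {
    return(list(plausible = TRUE,
                note = "taxon absent from reference table; unverifiable"))
  }
  if (contig_length < plausibility_fraction * e$mean_length) {
    warning(sprintf(
      paste("circular contig of %d bp is < %.0f%% of the expected %.0f bp;",
            "possibly a partial genome misassembled as circular"),
      contig_length, 100 * plausibility_fraction, e$mean_length),
      call. = FALSE)
    return(list(plausible = FALSE, note = sprintf(
      "length %d bp below %.0f%% of expected %.0f bp", contig_length,
      100 * plausibility_fraction, e$mean_length)))
  }
  list(plausible = TRUE,
       note = sprintf("length %d bp consistent with expected %.0f bp",
                      contig_length, e$mean_length))
}
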