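# End-to-end orchestration: validate -> termini -> quality -> cluster ->
# combined per-UViG report, plus a run manifest recording every threshold
# used (the checklist requires reporting methods, versions and cutoffs).

#' Default pipeline configuration
#'
#' @param ani_threshold,af_threshold,mode,window_bp,min_window_identity
#'   Clustering parameters (see [clustering_params()]).
#' @param min_repeat_len,max_mismatch Terminal-repeat detection settings
#'   (see [detect_dtr()]).
#' @param cv_warn Genome-length CV above which a reference taxon is
#'   flagged heterogeneous (default 0.10).
#' @param plausibility_fraction Circular-contig plausibility fraction
#'   (default 0.5; see [circular_plausibility()]).
#' @param min_length_warn Clustering length warning threshold (10 kb).
#' @param seed Integer seed recorded in the manifest.
#' @return Named list of configuration values.
#' @export
uvig_config <- function(ani_threshold = 95, af_threshold = 85,
                        mode = "wgani", window_bp = 500,
                        min_window_identity = 70, min_repeat_len = 20,
                        max_mismatch = 0, cv_warn = 0.10,
                        plausibility_fraction = 0.5,
                        min_length_warn = 10000, seed = 1) {
  list(ani_threshold = ani_threshold, af_threshold = af_threshold,
       mode = mode, window_bp = window_bp,
       min_window_identity = min_window_identity,
       min_repeat_len = min_repeat_len, max_mismatch = max_mismatch,
       cv_warn = cv_warn, plausibility_fraction = plausibility_fraction,
       min_length_warn = min_length_warn, seed = seed)
}

#' Run the full UViG assessment pipeline
#'
#' Reads contigs (and optional grouping, metadata, taxon assignments,
#' reference lengths), then: validates each metadata record against the
#' checklist, scans contigs for terminal repeats, estimates completeness
#' and assigns a quality tier per UViG, clusters the genomes into vOTUs,
#' and joins everything into one per-UViG report row. The effective
#' configuration -- every threshold and cutoff, the derived wgANI cutoff,
#' package version and seed -- is written to a manifest. Deterministic
#' given inputs and configuration. The reported `assembly_quality` column
#' is always the tier computed here; a user-supplied claim that disagrees
#' surfaces as a metadata violation in the same report.
#'
#' @param fasta Path to the contig FASTA (or a `contig_set`).
#' @param metadata Optional path to a metadata TSV (or list of records);
#'   matched to UViGs by `uvig_id`.
#' @param grouping Optional path to a contig-to-UViG TSV (or named
#'   vector); ungrouped contigs become single-contig UViGs.
#' @param reference_lengths Optional path to a taxon/rank/length_bp TSV
#'   (or data.frame).
#' @param taxa Optional named character vector (or two-column data.frame)
#'   mapping uvig_id to taxon for the reference completeness route.
#' @param flags Optional named list of [curation_flags()] per uvig_id.
#' @param config Configuration from [uvig_config()].
#' @param out_dir Optional output directory; writes `report.tsv`,
#'   `pairs.tsv`, `clusters.tsv`, `validation.tsv`, `manifest.yaml`.
#' @return List of class `uvig_report`: `report`, `pairs`, `clusters`,
#'   `validation`, `manifest`.
#' @export
run_pipeline <- function(fasta, metadata = NULL, grouping = NULL,
                         reference_lengths = NULL, taxa = NULL,
                         flags = NULL, config = uvig_config(),
                         out_dir = NULL) {
  needed <- names(uvig_config())
  missing_keys <- setdiff(needed, names(config))
  if (length(missing_keys) > 0) {
    stop("missing mandatory config key(s): ",
         paste(missing_keys, collapse = ", "))
  }

  contigs <- if (is.data.frame(fasta)) fasta else read_fasta(fasta)
  if (is.character(grouping) && length(grouping) == 1 &&
      file.exists(grouping)) {
    grouping <- read_grouping(grouping)
  }
  if (is.character(metadata) && length(metadata) == 1 &&
      file.exists(metadata)) {
    metadata <- parse_metadata(metadata, "tsv")
  }
  if (is.character(reference_lengths) && length(reference_lengths) == 1) {
    reference_lengths <- read_reference_lengths(reference_lengths)
  }
  if (is.data.frame(taxa)) taxa <- setNames(taxa[[2]], taxa[[1]])

  meta_by_id <- NULL
  if (!is.null(metadata)) {
    meta_by_id <- setNames(metadata, vapply(metadata, function(r) {
      if (is_blank(r$uvig_id)) NA_character_ else as.character(r$uvig_id)
    }, character(1)))
  }
  uvigs <- group_contigs_to_uvigs(contigs, grouping, meta_by_id)

  params <- clustering_params(config$ani_threshold, config$af_threshold,
                              config$mode, config$window_bp,
                              config$min_window_identity)
  termini <- detect_termini(contigs, config$min_repeat_len,
                            config$max_mismatch)
  clustering <- if (length(uvigs) >= 2) {
    suppressWarnings(cluster_votus(uvigs, params, config$min_length_warn))
  } else {
    NULL
  }

  rows <- list()
  validations <- list()
  for (uid in names(uvigs)) {
    uv <- uvigs[[uid]]
    taxon <- if (!is.null(taxa) && uid %in% names(taxa)) taxa[[uid]] else NULL
    cmp <- estimate_completeness(
      uv, termini, taxon, reference_lengths,
      integration_site = isTRUE(uv$metadata$integration_site_resolved))
    fl <- if (!is.null(flags) && uid %in% names(flags)) flags[[uid]] else
      curation_flags()
    tier <- classify_quality(uv, cmp, fl)

    rec <- uv$metadata
    has_record <- !is.null(meta_by_id) && uid %in% names(meta_by_id)
    vrep <- if (has_record) {
      validate_metadata(rec, uvig = uv, completeness = cmp)
    } else {
      NULL
    }
    claimed <- rec$assembly_quality
    tier_label <- c(genome_fragment = "genome fragment(s)",
                    high_quality_draft = "high-quality draft genome",
                    finished = "finished")[[tier$tier]]
    claim_conflict <- has_record && !is_blank(claimed) &&
      !identical(as.character(claimed), tier_label)
    if (claim_conflict && !is.null(vrep)) {
      vrep$violations <- rbind(vrep$violations, data.frame(
        field = "assembly_quality", rule = "cross_check",
        message = sprintf("record claims '%s' but computed tier is '%s'",
                          claimed, tier_label), stringsAsFactors = FALSE))
      vrep$status <- "invalid"
    }
    if (!is.null(vrep)) validations[[uid]] <- vrep

    utrow <- termini[termini$contig_id %in% uv$contigs$id, , drop = FALSE]
    rows[[uid]] <- data.frame(
      uvig_id = uid, n_contigs = nrow(uv$contigs),
      total_length = uv$total_length,
      metadata_status = if (has_record) vrep$status else "no_record",
      dtr_found = any(utrow$dtr_found), itr_found = any(utrow$itr_found),
      completeness_method = cmp$method,
      expected_length = cmp$expected_length,
      completeness_pct = cmp$completeness_pct,
      predicted_complete = cmp$predicted_complete,
      assembly_quality = tier_label,
      votu = if (is.null(clustering)) 1L else
        clustering$assignment$cluster_id[
          match(uid, clustering$assignment$genome_id)],
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  pairs <- if (length(uvigs) >= 2) {
    suppressWarnings(pairwise_matrix(uvigs, params))
  } else {
    NULL
  }

  validation_df <- if (length(validations) > 0) {
    do.call(rbind, lapply(names(validations), function(uid) {
      v <- validations[[uid]]
      if (nrow(v$violations) == 0) {
        data.frame(uvig_id = uid, status = v$status, field = NA, rule = NA,
                   message = NA, stringsAsFactors = FALSE)
      } else {
        cbind(uvig_id = uid, status = v$status, v$violations)
      }
    }))
  } else {
    data.frame(uvig_id = character(), status = character(),
               field = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  }

  manifest <- list(
    tool = "uvigkit",
    version = as.character(packageVersion("uvigkit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    thresholds = config,
    wgani_cutoff = wgani_cutoff(params),
    n_contigs = nrow(contigs), n_uvigs = length(uvigs))

  out <- structure(list(report = report, pairs = pairs,
                        clusters = if (is.null(clustering)) NULL else
                          clustering$clusters,
                        validation = validation_df, manifest = manifest),
                   class = "uvig_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, f) if (!is.null(df)) {
      write.table(df, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE, na = "")
    }
    wr(report, "report.tsv")
    wr(pairs, "pairs.tsv")
    wr(out$clusters, "clusters.tsv")
    wr(validation_df, "validation.tsv")
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.uvig_report <- function(x, ...) {
  cat(sprintf("<uvig_report: %d UViG(s), %d vOTU(s)>\n", nrow(x$report),
              if (is.null(x$clusters)) 1L else nrow(x$clusters)))
  print(x$report[, c("uvig_id", "n_contigs", "total_length",
                     "metadata_status", "completeness_method",
                     "assembly_quality", "votu")])
  invisible(x)
}
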