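# MIUViG checklist: schema, record validation, serialization.
#
# The schema returned by checklist_schema() is the single source of truth:
# validate_metadata() and the serializers are driven by it. Mandatory fields
# and controlled vocabularies follow the published checklist; optional
# fields are an open, extensible set.

#' Machine-readable MIUViG checklist schema
#'
#' Returns the checklist as a list of field definitions. Eight fields are
#' mandatory for every UViG record; vocabulary-constrained fields carry
#' their allowed value sets. Optional fields (vOTU method and cutoffs, host
#' prediction and its estimated accuracy, taxonomic classification, feature
#' prediction and similarity-search methods and databases, ...) are open:
#' any extra column is carried through validation and serialization.
#'
#' @param extra_vocab Optional named list extending a vocabulary, e.g.
#'   `list(source_of_uvigs = "ancient sample")`.
#' @return A list with elements `fields` (list of per-field definitions:
#'   `name`, `mandatory`, `vocabulary` or `NULL`, `description`) and
#'   `mandatory` (character vector of the eight mandatory field names).
#' @export
checklist_schema <- function(extra_vocab = NULL) {
  fields <- list(
    list(name = "source_of_uvigs", mandatory = TRUE,
         vocabulary = c("metagenome", "viral metagenome",
                        "metatranscriptome", "viral metatranscriptome",
                        "microbial genome (provirus)",
                        "single amplified genome", "single virus genome",
                        "targeted sequence capture", "other"),
         description = "Type of dataset from which the UViG was obtained"),
    list(name = "assembly_software", mandatory = TRUE, vocabulary = NULL,
         description = paste("Tool(s) used for assembly and/or binning,",
                             "including version number and parameters")),
    list(name = "virus_identification_software", mandatory = TRUE,
         vocabulary = NULL,
         description = paste("Tool(s) or protocol used to identify the",
                             "sequence as viral, including version number,",
                             "parameters, and cutoffs used")),
    list(name = "predicted_genome_type", mandatory = TRUE,
         vocabulary = c("dsDNA", "ssDNA", "dsRNA", "ssRNA(+)", "ssRNA(-)",
                        "ssRNA-RT", "dsDNA-RT", "undetermined"),
         description = paste("Type of genome predicted for the UViG",
                             "(Baltimore classification)")),
    list(name = "predicted_genome_structure", mandatory = TRUE,
         vocabulary = c("segmented", "nonsegmented", "undetermined"),
         description = "Expected structure of the viral genome"),
    list(name = "detection_type", mandatory = TRUE,
         vocabulary = c("independent sequence (UViG)", "provirus (UpViG)"),
         description = "Type of UViG detection"),
    list(name = "assembly_quality", mandatory = TRUE,
         vocabulary = c("finished", "high-quality draft genome",
                        "genome fragment(s)"),
         description = paste("Assembly quality category: finished (single,",
                             "validated, contiguous sequence per replicon",
                             "without gaps or ambiguities, extensively",
                             "curated); high-quality draft genome (one or",
                             "multiple fragments totaling >=90% of the",
                             "expected genome, or predicted complete);",
                             "genome fragment(s) (<90% or no genome size",
                             "estimate)")),
    list(name = "number_of_contigs", mandatory = TRUE, vocabulary = NULL,
         description = "Total number of contigs composing the UViG"),
    list(name = "votu_method", mandatory = FALSE, vocabulary = NULL,
         description = paste("vOTU clustering method, cutoffs, reference",
                             "database and genome alignment approach")),
    list(name = "host_prediction_method", mandatory = FALSE,
         vocabulary = NULL,
         description = paste("In silico host prediction method and its",
                             "estimated accuracy")),
    list(name = "taxonomic_classification_method", mandatory = FALSE,
         vocabulary = NULL,
         description = "Taxonomic classification method and database"),
    list(name = "new_taxon_rank", mandatory = FALSE, vocabulary = NULL,
         description = paste("Rank of any newly proposed taxon; use",
                             "'candidate' or 'putative' qualifiers, not a",
                             "bare rank name")),
    list(name = "feature_prediction_method", mandatory = FALSE,
         vocabulary = NULL,
         description = "Feature (gene) prediction method"),
    list(name = "similarity_search_method", mandatory = FALSE,
         vocabulary = NULL,
         description = "Similarity search method(s) and database(s) used"),
    list(name = "read_quality_phred", mandatory = FALSE, vocabulary = NULL,
         description = paste("Mean base-call phred score; required for",
                             "single-read (non-consensus) UViGs"))
  )
  if (!is.null(extra_vocab)) {
    for (nm in names(extra_vocab)) {
      i <- match(nm, vapply(fields, `[[`, character(1), "name"))
      if (!is.na(i) && !is.null(fields[[i]]$vocabulary)) {
        fields[[i]]$vocabulary <- c(fields[[i]]$vocabulary, extra_vocab[[nm]])
      }
    }
  }
  list(
    fields = fields,
    mandatory = vapply(Filter(function(f) f$mandatory, fields),
                       `[[`, character(1), "name")
  )
}

is_blank <- function(x) {
  is.null(x) || length(x) == 0 || is.na(x) || !nzchar(trimws(as.character(x)))
}

#' Validate a metadata record against the MIUViG checklist
#'
#' Checks one record (a named list or a one-row data.frame) for presence of
#' all mandatory fields, membership of vocabulary-constrained values in
#' their controlled vocabularies, and, when the corresponding UViG or a
#' completeness estimate is supplied, internal consistency:
#' `number_of_contigs` must equal the actual contig count, and the claimed
#' `assembly_quality` must not exceed what the completeness evidence
#' supports (a "high-quality draft genome" needs >=90% completeness or a
#' predicted-complete call; "finished" needs complete evidence).
#'
#' A record using a bare rank name ("genus", "family", ...) in
#' `new_taxon_rank` gets a warning, not a violation: newly proposed taxa
#' from uncultivated genomes should be flagged as "candidate"/"putative".
#'
#' @param record Named list or one-row data.frame of checklist fields.
#' @param uvig Optional `uvig` record for cross-checks.
#' @param completeness Optional completeness estimate
#'   (see [estimate_completeness()]) for the assembly-quality cross-check.
#' @param schema Schema from [checklist_schema()].
#' @return A list of class `validation_report`: `record_id`, `status`
#'   ("valid"/"invalid"), `violations` and `warnings` data.frames.
#' @examples
#' rec <- example_metadata_record()
#' validate_metadata(rec)
#' @export
validate_metadata <- function(record, uvig = NULL, completeness = NULL,
                              schema = checklist_schema()) {
  if (is.data.frame(record)) {
    if (nrow(record) != 1) stop("record must be a single row")
    record <- as.list(record)
  }
  if (!is.list(record)) stop("unparseable record: expected list or data.frame")
  viol <- list()
  warn <- list()
  add_viol <- function(field, rule, message) {
    viol[[length(viol) + 1]] <<- data.frame(
      field = field, rule = rule, message = message, stringsAsFactors = FALSE)
  }
  add_warn <- function(field, message) {
    warn[[length(warn) + 1]] <<- data.frame(
      field = field, message = message, stringsAsFactors = FALSE)
  }

  for (f in schema$fields) {
    val <- record[[f$name]]
    if (f$mandatory && is_blank(val)) {
      add_viol(f$name, "mandatory",
               sprintf("mandatory field '%s' is missing or empty", f$name))
      next
    }
    if (!is_blank(val) && !is.null(f$vocabulary) &&
        !(as.character(val) %in% f$vocabulary)) {
      add_viol(f$name, "vocabulary",
               sprintf("value '%s' not in allowed set {%s}", val,
                       paste(f$vocabulary, collapse = ", ")))
    }
  }

  noc <- record$number_of_contigs
  if (!is_blank(noc)) {
    n <- suppressWarnings(as.numeric(noc))
    if (is.na(n) || n < 1 || n != floor(n)) {
      add_viol("number_of_contigs", "type", "must be an integer >= 1")
    } else if (!is.null(uvig) && nrow(uvig$contigs) != n) {
      add_viol("number_of_contigs", "cross_check",
               sprintf("record says %d contig(s) but UViG has %d",
                       as.integer(n), nrow(uvig$contigs)))
    }
  }

  aq <- record$assembly_quality
  if (!is_blank(aq) && !is.null(completeness)) {
    pct <- completeness$completeness_pct
    complete_evidence <- isTRUE(completeness$predicted_complete) ||
      (!is.null(pct) && !is.na(pct) && pct >= 100)
    hq_evidence <- complete_evidence ||
      (!is.null(pct) && !is.na(pct) && pct >= 90)
    if (identical(as.character(aq), "high-quality draft genome") &&
        !hq_evidence) {
      add_viol("assembly_quality", "cross_check",
               paste("claimed high-quality draft genome but completeness",
                     "evidence is <90% and not predicted complete"))
    }
    if (identical(as.character(aq), "finished") && !complete_evidence) {
      add_viol("assembly_quality", "cross_check",
               "claimed finished but genome is not complete")
    }
  }

  rank_val <- record$new_taxon_rank
  if (!is_blank(rank_val) &&
      tolower(trimws(as.character(rank_val))) %in%
        c("species", "genus", "subfamily", "family", "order")) {
    add_warn("new_taxon_rank",
             sprintf(paste("'%s' is a bare rank name; new taxa from",
                           "uncultivated genomes should be labeled",
                           "'candidate %s' or 'putative %s'"),
                     rank_val, rank_val, rank_val))
  }

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(field = character(), rule = character(),
               message = character(), stringsAsFactors = FALSE)
  warnings <- if (length(warn)) do.call(rbind, warn) else
    data.frame(field = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(
    list(record_id = if (is_blank(record$uvig_id)) NA_character_ else
           as.character(record$uvig_id),
         status = if (nrow(violations) == 0) "valid" else "invalid",
         violations = violations, warnings = warnings),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report %s: %s; %d violation(s), %d warning(s)>\n",
              ifelse(is.na(x$record_id), "(unnamed)", x$record_id),
              x$status, nrow(x$violations), nrow(x$warnings)))
  if (nrow(x$violations)) print(x$violations)
  invisible(x)
}

#' Example checklist-complete metadata record
#' @param uvig_id Record identifier.
#' @return Named list passing [validate_metadata()] with zero violations.
#' @export
example_metadata_record <- function(uvig_id = "uvig_1") {
  list(
    uvig_id = uvig_id,
    source_of_uvigs = "viral metagenome",
    assembly_software = "metaSPAdes v3.13.0; default parameters",
    virus_identification_software = "VirSorter v1.0.5; categories 1-2",
    predicted_genome_type = "dsDNA",
    predicted_genome_structure = "nonsegmented",
    detection_type = "independent sequence (UViG)",
    assembly_quality = "genome fragment(s)",
    number_of_contigs = 1L
  )
}

metadata_column_order <- function(records, schema = checklist_schema()) {
  all_names <- unique(unlist(lapply(records, names)))
  canonical <- c("uvig_id", vapply(schema$fields, `[[`, character(1), "name"))
  c(intersect(canonical, all_names), setdiff(all_names, canonical))
}

records_to_frame <- function(records, schema = checklist_schema()) {
  cols <- metadata_column_order(records, schema)
  rows <- lapply(records, function(r) {
    vals <- lapply(cols, function(nm) {
      v <- r[[nm]]
      if (is_blank(v)) NA_character_ else as.character(v)
    })
    as.data.frame(setNames(vals, cols), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

frame_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    r <- lapply(r, as.character)
    r[!vapply(r, function(v) is.na(v), logical(1))]
  })
}

#' Serialize metadata records
#'
#' Writes checklist records to one of three formats: `tsv` (header row of
#' canonical snake_case names, one data row per record; lossless
#' round-trip through [parse_metadata()]), `json` (array of objects), or
#' `structured_comment` (one key/value block per UViG, suitable for
#' INSDC-style submission comments).
#'
#' @param records List of named-list records (or a data.frame, one row per
#'   record).
#' @param path Output path.
#' @param format One of `"tsv"`, `"json"`, `"structured_comment"`.
#' @param schema Schema from [checklist_schema()].
#' @return `path`, invisibly.
#' @export
serialize_metadata <- function(records, path,
                               format = c("tsv", "json",
                                          "structured_comment"),
                               schema = checklist_schema()) {
  format <- match.arg(format)
  if (is.data.frame(records)) records <- frame_to_records(records)
  df <- records_to_frame(records, schema)
  if (format == "tsv") {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
  } else if (format == "json") {
    jsonlite::write_json(records, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in records) {
      writeLines("##MIUViG-Data-START##", con)
      for (nm in names(r)) {
        if (!is_blank(r[[nm]])) {
          writeLines(paste(nm, as.character(r[[nm]]), sep = "\t"), con)
        }
      }
      writeLines("##MIUViG-Data-END##", con)
    }
  }
  invisible(path)
}

#' Parse metadata records written by [serialize_metadata()]
#' @param path Input path.
#' @param format One of `"tsv"`, `"json"`, `"structured_comment"`.
#' @return List of named-list records.
#' @export
parse_metadata <- function(path,
                           format = c("tsv", "json", "structured_comment")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, colClasses = "character", check.names = FALSE)
    df[df == ""] <- NA_character_
    frame_to_records(df)
  } else if (format == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(recs, function(r) lapply(r, as.character))
  } else {
    lines <- readLines(path)
    starts <- grep("^##MIUViG-Data-START##$", lines)
    ends <- grep("^##MIUViG-Data-END##$", lines)
    if (length(starts) != length(ends)) {
      stop("unparseable structured-comment file: unbalanced block markers")
    }
    lapply(seq_along(starts), function(i) {
      block <- lines[(starts[i] + 1):(ends[i] - 1)]
      kv <- strsplit(block, "\t", fixed = TRUE)
      setNames(lapply(kv, function(p) paste(p[-1], collapse = "\t")),
               vapply(kv, `[[`, character(1), 1))
    })
  }
}
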