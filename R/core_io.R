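# Sequence containers and FASTA / grouping-file I/O.
#
# A contig set is a plain data.frame with columns id, sequence, length and
# description; a UViG is a list bundling one or more contigs with its
# checklist metadata. Everything downstream (termini, quality, clustering)
# consumes these two shapes.

VALID_BASES <- c("A", "C", "G", "T", "N")
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a contig set
#'
#' Builds the standard contig table used throughout the package: one row per
#' assembled sequence. Sequences are normalized (uppercase, `U` to `T`) and
#' must use only `A`, `C`, `G`, `T`, `N` afterwards; IUPAC ambiguity codes
#' are collapsed to `N` with a warning so the alphabet stays closed for the
#' ANI engine, which treats `N` as a mismatch.
#'
#' @param id Character vector of unique contig identifiers.
#' @param sequence Character vector of nucleotide sequences.
#' @param description Optional free-text descriptions (recycled).
#' @return A `data.frame` of class `contig_set` with columns `id`,
#'   `sequence`, `length`, `description`.
#' @examples
#' contig_set("c1", "acgu")
#' @export
contig_set <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- normalize_sequence(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("'id' and 'sequence' must have the same length")
  }
  if (any(id == "" | is.na(id))) stop("contig ids must be non-empty")
  dup <- unique(id[duplicated(id)])
  if (length(dup) > 0) {
    stop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  }
  if (any(nchar(sequence) < 1)) stop("contig sequences must be non-empty")
  out <- data.frame(
    id = id, sequence = sequence, length = nchar(sequence),
    description = rep_len(as.character(description), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("contig_set", "data.frame")
  out
}

# uppercase, U->T, IUPAC ambiguity -> N (warn), anything else -> error
normalize_sequence <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  residues <- unique(unlist(strsplit(x, "", fixed = TRUE)))
  ambig <- intersect(residues, IUPAC_AMBIG)
  if (length(ambig) > 0) {
    warning("IUPAC ambiguity code(s) ", paste(ambig, collapse = ", "),
            " mapped to N", call. = FALSE)
    x <- chartr(paste(IUPAC_AMBIG, collapse = ""),
                strrep("N", length(IUPAC_AMBIG)), x)
    residues <- setdiff(residues, ambig)
  }
  bad <- setdiff(residues, c(VALID_BASES, "-"))
  if (length(bad) > 0) {
    stop("non-nucleotide character(s) in sequence: ",
         paste(bad, collapse = ", "))
  }
  gsub("-", "", x, fixed = TRUE)
}

#' Read a FASTA file into a contig set
#'
#' Parses a (multi-record) FASTA file and returns the normalized contig
#' table. The first whitespace-delimited token of each header is the contig
#' id; the remainder is kept as the description. Duplicate ids are a hard
#' error; an empty file yields an empty set with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A `contig_set` (see [contig_set()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    out <- data.frame(id = character(), sequence = character(),
                      length = integer(), description = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("contig_set", "data.frame")
    return(out)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  contig_set(ids, as.character(set), desc)
}

#' Write a contig set to FASTA
#'
#' @param contigs A `contig_set` (or data.frame with `id`, `sequence`,
#'   optionally `description`).
#' @param path Output path.
#' @param line_width Sequence line width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, line_width = 60) {
  if (line_width < 1) stop("line_width must be >= 1")
  if (nrow(contigs) == 0) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(contigs$sequence)
  desc <- if ("description" %in% names(contigs)) contigs$description else ""
  names(set) <- ifelse(desc == "" | is.na(desc), contigs$id,
                       paste(contigs$id, desc))
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Group contigs into UViG records
#'
#' Applies a contig-to-genome mapping and returns one UViG record per
#' genome. Contigs absent from the grouping become single-contig UViGs named
#' after the contig. The mandatory checklist field `number_of_contigs` is
#' filled from the actual member count.
#'
#' @param contigs A `contig_set`.
#' @param grouping Optional named character vector (`names` = contig id,
#'   values = UViG id) or two-column data.frame `(contig_id, uvig_id)`.
#' @param metadata Optional named list of metadata records (one per UViG
#'   id), merged into each record.
#' @return A list of class `uvig_set`; each element is a list with
#'   `uvig_id`, `contigs`, `total_length`, `read_quality_phred` and
#'   `metadata`.
#' @export
group_contigs_to_uvigs <- function(contigs, grouping = NULL, metadata = NULL) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(as.character(grouping[[2]]),
                         as.character(grouping[[1]]))
  }
  if (is.null(grouping)) grouping <- character(0)
  unknown <- setdiff(names(grouping), contigs$id)
  if (length(unknown) > 0) {
    stop("grouping references unknown contig id(s): ",
         paste(unknown, collapse = ", "))
  }
  uvig_of <- ifelse(contigs$id %in% names(grouping),
                    unname(grouping[contigs$id]), contigs$id)
  out <- lapply(unique(uvig_of), function(uid) {
    members <- contigs[uvig_of == uid, , drop = FALSE]
    class(members) <- c("contig_set", "data.frame")
    meta <- if (!is.null(metadata) && uid %in% names(metadata)) {
      metadata[[uid]]
    } else {
      list()
    }
    meta$number_of_contigs <- nrow(members)
    structure(
      list(uvig_id = uid, contigs = members,
           total_length = sum(members$length),
           read_quality_phred = meta$read_quality_phred,
           metadata = meta),
      class = "uvig"
    )
  })
  names(out) <- unique(uvig_of)
  class(out) <- "uvig_set"
  out
}

#' Read a two-column grouping file (contig_id, uvig_id; no header)
#' @param path Path to a TSV with columns contig_id, uvig_id.
#' @return Named character vector mapping contig id to UViG id.
#' @export
read_grouping <- function(path) {
  g <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(g) < 2) stop("grouping file must have two columns")
  setNames(g[[2]], g[[1]])
}

#' @export
print.uvig <- function(x, ...) {
  cat(sprintf("<UViG %s: %d contig(s), %s bp>\n", x$uvig_id,
              nrow(x$contigs), format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' @export
print.uvig_set <- function(x, ...) {
  cat(sprintf("<uvig_set of %d genome(s), %s bp total>\n", length(x),
              format(sum(vapply(x, `[[`, numeric(1), "total_length")),
                     big.mark = ",")))
  invisible(x)
}

# reverse complement for plain character vectors (strict A/C/G/T/N)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}
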