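# Test-side helpers and independent oracles. These deliberately avoid the
# package's own code paths: sequence generation and mutation are re-rolled
# here, and the repeat/identity oracles are naive O(L^2) enumerations.

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate each position with prob rate to a different base; returns the
# mutant and the exact positions changed (the mismatch-count oracle)
mutate_seq <- function(s, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
  list(seq = paste(b, collapse = ""), changed = hit)
}

rc_oracle <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# exhaustive terminal-repeat finder: tries every candidate length and
# counts mismatches position by position
brute_terminal_repeat <- function(s, min_len, max_mm, inverted) {
  L <- nchar(s)
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  best <- 0L
  for (l in seq_len(L %/% 2)) {
    if (l < min_len) next
    pre <- b[1:l]
    suf <- b[(L - l + 1):L]
    if (inverted) {
      suf <- strsplit(rc_oracle(paste(suf, collapse = "")), "",
                      fixed = TRUE)[[1]]
    }
    mm <- sum(pre != suf | pre == "N")
    if (mm <= max_mm) best <- l
  }
  best
}

# a checklist-complete record with an id and room for overrides
full_record <- function(uvig_id = "u1", ...) {
  rec <- example_metadata_record(uvig_id)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# random metadata record: valid checklist core plus optional noise fields
random_record <- function(i, schema = checklist_schema()) {
  vocab_of <- function(nm) {
    f <- Filter(function(x) x$name == nm, schema$fields)[[1]]
    sample(f$vocabulary, 1)
  }
  rec <- list(
    uvig_id = sprintf("uvig_%03d", i),
    source_of_uvigs = vocab_of("source_of_uvigs"),
    assembly_software = sprintf("assembler v%d.%d", sample(1:9, 1),
                                sample(0:9, 1)),
    virus_identification_software = "identifier v2.1; score >= 0.9",
    predicted_genome_type = vocab_of("predicted_genome_type"),
    predicted_genome_structure = vocab_of("predicted_genome_structure"),
    detection_type = vocab_of("detection_type"),
    assembly_quality = vocab_of("assembly_quality"),
    number_of_contigs = as.character(sample(1:5, 1))
  )
  if (runif(1) < 0.5) rec$votu_method <- "greedy ANI 95/AF 85"
  if (runif(1) < 0.3) rec$extra_note <- sprintf("free text %d", i)
  rec
}
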