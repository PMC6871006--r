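test_that("schema lists the eight mandatory checklist fields", {
  sch <- checklist_schema()
  expect_setequal(sch$mandatory,
                  c("source_of_uvigs", "assembly_software",
                    "virus_identification_software",
                    "predicted_genome_type", "predicted_genome_structure",
                    "detection_type", "assembly_quality",
                    "number_of_contigs"))
  expect_length(sch$mandatory, 8)
  vid <- Filter(function(f) f$name == "virus_identification_software",
                sch$fields)[[1]]
  expect_match(vid$description, "cutoffs")
  # every vocabulary value validates cleanly
  for (f in Filter(function(x) !is.null(x$vocabulary), sch$fields)) {
    for (v in f$vocabulary) {
      rec <- full_record()
      rec[[f$name]] <- v
      if (f$name == "assembly_quality") next # cross-checked separately
      expect_equal(validate_metadata(rec)$status, "valid")
    }
  }
})

test_that("missing mandatory fields and vocabulary violations are caught", {
  rec <- full_record()
  rec$assembly_software <- NULL
  rep <- validate_metadata(rec)
  expect_equal(rep$status, "invalid")
  expect_true("assembly_software" %in% rep$violations$field)

  ok <- validate_metadata(full_record())
  expect_equal(ok$status, "valid")
  expect_equal(nrow(ok$violations), 0)

  bad <- validate_metadata(full_record(predicted_genome_type = "triplex"))
  expect_equal(bad$status, "invalid")
  expect_match(bad$violations$message, "triplex")
  expect_match(bad$violations$message, "dsDNA")

  expect_error(validate_metadata("not a record"), "unparseable")
})

test_that("quality claims are cross-checked against completeness evidence", {
  half <- list(completeness_pct = 50, predicted_complete = FALSE)
  rep <- validate_metadata(
    full_record(assembly_quality = "high-quality draft genome"),
    completeness = half)
  expect_equal(rep$status, "invalid")
  expect_true("assembly_quality" %in% rep$violations$field)

  ok <- validate_metadata(
    full_record(assembly_quality = "high-quality draft genome"),
    completeness = list(completeness_pct = 92, predicted_complete = FALSE))
  expect_equal(ok$status, "valid")

  circ <- list(completeness_pct = NA, predicted_complete = TRUE)
  expect_equal(validate_metadata(
    full_record(assembly_quality = "high-quality draft genome"),
    completeness = circ)$status, "valid")
})

test_that("contig count mismatches and bare new-taxon ranks are flagged", {
  cs <- contig_set(c("c1", "c2"), c("ACGTACGT", "GGGGCCCC"))
  uv <- group_contigs_to_uvigs(cs, c(c1 = "u1", c2 = "u1"))$u1
  rep <- validate_metadata(full_record(number_of_contigs = 1), uvig = uv)
  expect_equal(rep$status, "invalid")
  expect_true("number_of_contigs" %in% rep$violations$field)

  warned <- validate_metadata(full_record(new_taxon_rank = "genus"))
  expect_equal(warned$status, "valid") # warning, not violation
  expect_true("new_taxon_rank" %in% warned$warnings$field)
  expect_match(warned$warnings$message, "candidate")

  fine <- validate_metadata(full_record(new_taxon_rank = "candidate genus"))
  expect_equal(nrow(fine$warnings), 0)
})

test_that("serialization round-trips across all three formats", {
  set.seed(21)
  recs <- lapply(1:20, random_record)

  for (fmt in c("tsv", "json", "structured_comment")) {
    f <- withr::local_tempfile()
    serialize_metadata(recs, f, fmt)
    back <- parse_metadata(f, fmt)
    expect_length(back, length(recs))
    for (i in seq_along(recs)) {
      orig <- lapply(recs[[i]], as.character)
      expect_equal(back[[i]][names(orig)], orig, info = fmt)
      # validation outcome is preserved through the round trip
      expect_equal(validate_metadata(back[[i]])$status,
                   validate_metadata(recs[[i]])$status, info = fmt)
    }
  }
})

test_that("TSV layout has canonical header and structured comments are keyed", {
  f <- withr::local_tempfile()
  serialize_metadata(list(full_record()), f, "tsv")
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(tab), 1)
  expect_true(all(checklist_schema()$mandatory %in% names(tab)))

  serialize_metadata(list(full_record(assembly_quality = "finished")), f,
                     "structured_comment")
  lines <- readLines(f)
  expect_true("assembly_quality\tfinished" %in% lines)
  expect_equal(lines[1], "##MIUViG-Data-START##")

  expect_error(serialize_metadata(list(full_record()), f, "xml"))
})
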